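# Project model, folder persistence, lock arbitration, attachments.

test_that("creating a project initialises an empty persisted folder", {
  d <- file.path(tempdir(), "proj-create")
  on.exit(unlink(d, recursive = TRUE))
  p <- ms_create(d, "demo")
  expect_length(p$entries, 0)
  expect_length(p$schema, 0)
  expect_true(file.exists(file.path(d, "project.json")))
  expect_true(dir.exists(file.path(d, "attachments")))
  expect_true(file.exists(file.path(d, "lock.json")))
  expect_error(ms_create(d, "again"), "already contains")
  q <- ms_open(d)
  expect_identical(q$name, "demo")
  expect_length(q$entries, 0)
})

test_that("save/load round-trips entries, schema, highlights and attachments", {
  d <- file.path(tempdir(), "proj-rt")
  on.exit(unlink(d, recursive = TRUE))
  p <- ms_create(d, "rt")
  p <- ms_add_molecule(p, "a", "OCC", list(MW = "46.07"))
  p <- ms_add_molecule(p, "b", "C1=CC=CC=C1", list(Note = "aromatic"))
  p <- ms_add_molecule(p, "c", "CCN")
  p <- ms_set_highlight(p, "b", "yellow")
  att <- tempfile(fileext = ".txt"); writeLines("hello", att)
  p <- ms_attach(p, "a", att)
  ms_save(p)
  q <- ms_open(d)
  expect_identical(ms_ids(q), c("a", "b", "c"))
  expect_identical(q$schema, c("MW", "Note"))
  expect_identical(ms_entry(q, "a")$smiles_input, "OCC")
  expect_identical(ms_entry(q, "a")$smiles_canonical, "CCO")
  expect_identical(ms_entry(q, "b")$highlight, "yellow")
  expect_identical(ms_entry(q, "a")$properties$MW, "46.07")
  expect_identical(ms_attachments(q, "a"), basename(att))
  expect_true(ms_has_attachments(q, "a"))
  expect_false(ms_has_attachments(q, "b"))
})

test_that("add_molecule rejects duplicates and invalid SMILES, canonicalizes input", {
  p <- ms_project("t")
  p <- ms_add_molecule(p, "mol1", "CCO")
  expect_identical(ms_entry(p, "mol1")$smiles_canonical, "CCO")
  expect_length(ms_entry(p, "mol1")$properties, 0)
  expect_error(ms_add_molecule(p, "mol1", "CCN"), "duplicate id: mol1")
  expect_error(ms_add_molecule(p, "mol2", "C1CC"), "invalid SMILES: C1CC")
  expect_error(ms_add_molecule(p, "", "CCO"), "non-empty")
  # spelling-insensitive storage: any spelling canonicalizes identically
  p <- ms_add_molecule(p, "mol3", "OCC")
  expect_identical(ms_entry(p, "mol3")$smiles_canonical,
                   ms_entry(p, "mol1")$smiles_canonical)
})

test_that("property set/overwrite and highlight enum behave per contract", {
  p <- ms_add_molecule(ms_project("t"), "mol1", "CCO")
  p <- ms_set_property(p, "mol1", "IC50_nM", "120")
  expect_identical(ms_entry(p, "mol1")$properties$IC50_nM, "120")
  p <- ms_set_property(p, "mol1", "IC50_nM", "95")
  expect_identical(ms_entry(p, "mol1")$properties$IC50_nM, "95")
  expect_identical(p$schema, "IC50_nM")
  expect_error(ms_set_property(p, "nope", "x", "1"), "unknown id")
  p <- ms_set_highlight(p, "mol1", "green")
  expect_identical(ms_entry(p, "mol1")$highlight, "green")
  p <- ms_set_highlight(p, "mol1", "none")
  expect_identical(ms_entry(p, "mol1")$highlight, "none")
  expect_error(ms_set_highlight(p, "mol1", "blue"), "unknown highlight")
})

test_that("first opener gets read_write, later openers read_only with owner reported", {
  d <- file.path(tempdir(), "proj-lock")
  on.exit(unlink(d, recursive = TRUE))
  ms_create(d, "shared", identity = "alice@lab")
  a <- ms_open(d, identity = "alice@lab")
  expect_identical(a$mode, "read_write")
  expect_message(b <- ms_open(d, identity = "bob@lab"), "alice@lab")
  expect_identical(b$mode, "read_only")
  expect_identical(b$lock_owner, "alice@lab")
  expect_error(ms_save(b), "read-only")
  # among several opens while the lock is live, exactly one holds read_write
  modes <- c(a$mode, b$mode,
             suppressMessages(ms_open(d, identity = "carol@lab"))$mode)
  expect_identical(sum(modes == "read_write"), 1L)
  ms_release(a)
  c2 <- ms_open(d, identity = "bob@lab")
  expect_identical(c2$mode, "read_write")
})

test_that("stale locks expire by TTL and can be stolen explicitly", {
  d <- file.path(tempdir(), "proj-stale")
  on.exit(unlink(d, recursive = TRUE))
  ms_create(d, "s", identity = "gone@host")
  # age the lock beyond the TTL
  lk <- jsonlite::fromJSON(file.path(d, "lock.json"))
  lk$acquired_at <- format(Sys.time() - 3 * 3600, "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(lk, file.path(d, "lock.json"), auto_unbox = TRUE)
  expect_identical(suppressMessages(
    ms_open(d, identity = "new@host", lock_ttl_hours = 24))$mode, "read_only")
  expect_identical(ms_open(d, identity = "new@host", lock_ttl_hours = 2)$mode,
                   "read_write")
  # explicit steal beats a live lock
  expect_identical(ms_open(d, identity = "thief@host", steal = TRUE)$mode,
                   "read_write")
})

test_that("sorting is stable, direction-aware, numeric-aware, missing-last", {
  p <- ms_project("s")
  p <- ms_add_molecule(p, "x1", "CCO", list(MW = "300.1"))
  p <- ms_add_molecule(p, "x2", "CCN", list(MW = "250.0"))
  p <- ms_add_molecule(p, "x3", "CCC", list(MW = "180.2"))
  p <- ms_add_molecule(p, "x4", "CCCl", list(Other = "z"))   # MW absent
  p <- ms_add_molecule(p, "x5", "CCBr", list(MW = "n/a"))    # unparsable
  asc <- ms_sort(p, "MW", "asc", numeric = TRUE)
  expect_identical(ms_ids(asc), c("x3", "x2", "x1", "x4", "x5"))
  desc <- ms_sort(p, "MW", "desc", numeric = TRUE)
  expect_identical(ms_ids(desc), c("x1", "x2", "x3", "x4", "x5"))
  # lexicographic vs numeric on "9" vs "10"
  q <- ms_add_molecule(ms_project("q"), "a", "CCO", list(v = "9"))
  q <- ms_add_molecule(q, "b", "CCN", list(v = "10"))
  expect_identical(ms_ids(ms_sort(q, "v")), c("b", "a"))               # "10" < "9"
  expect_identical(ms_ids(ms_sort(q, "v", numeric = TRUE)), c("a", "b")) # 9 < 10
  expect_error(ms_sort(q, "nope"), "unknown column")
})

test_that("attachments copy, list, open, delete; collisions get suffixes", {
  d <- file.path(tempdir(), "proj-att")
  on.exit(unlink(d, recursive = TRUE))
  p <- ms_create(d, "att")
  p <- ms_add_molecule(p, "m", "CCO")
  f1 <- file.path(tempdir(), "note.txt"); writeLines("v1", f1)
  f2 <- file.path(tempdir(), "extra.pdf"); writeLines("pdf-ish", f2)
  p <- ms_attach(p, "m", f1)
  p <- ms_attach(p, "m", f2)
  expect_setequal(ms_attachments(p, "m"), c("note.txt", "extra.pdf"))
  expect_true(ms_has_attachments(p, "m"))
  expect_identical(readLines(ms_attachment_path(p, "m", "note.txt")), "v1")
  # same name again: never overwrite, suffix instead
  writeLines("v2", f1)
  p <- ms_attach(p, "m", f1)
  expect_true("note_1.txt" %in% ms_attachments(p, "m"))
  expect_identical(readLines(ms_attachment_path(p, "m", "note.txt")), "v1")
  p <- ms_delete_attachment(p, "m", "extra.pdf")
  expect_false("extra.pdf" %in% ms_attachments(p, "m"))
  p <- ms_delete_attachment(p, "m", "note.txt")
  p <- ms_delete_attachment(p, "m", "note_1.txt")
  expect_false(ms_has_attachments(p, "m"))
  expect_error(ms_attach(p, "nope", f1), "unknown id")
  expect_error(ms_delete_attachment(p, "m", "ghost"), "no attachment")
})

test_that("the table view exposes ID, SMILES, # and schema columns in order", {
  p <- ms_add_molecule(ms_project("v"), "m1", "CCO", list(A = "1"))
  p <- ms_add_molecule(p, "m2", "CCN", list(B = "2"))
  df <- as.data.frame(p)
  expect_identical(names(df), c("ID", "SMILES", "#", "A", "B"))
  expect_identical(df$A, c("1", NA))
  expect_error(ms_set_property(p, "m1", "ID", "x"), "reserved")
})
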