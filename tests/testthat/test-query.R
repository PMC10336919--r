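# Property queries (eight comparators, AND-combined) and structural queries
# (substructure / superstructure / similarity).

test_that("single-filter matching follows the comparator contract", {
  e <- ms_entry(ms_add_molecule(ms_project("t"), "A", "CCO",
                                list(MW = "350.20", Formula = "C20H18N2O3",
                                     LogP = "n/a")), "A")
  expect_true(ms_match_filter(e, ms_filter("MW", "GE", "300")))
  expect_false(ms_match_filter(e, ms_filter("MW", "GT", "350.20")))
  expect_true(ms_match_filter(e, ms_filter("MW", "LE", "350.2")))
  expect_true(ms_match_filter(e, ms_filter("Formula", "CONTAINS", "N")))
  expect_false(ms_match_filter(e, ms_filter("Formula", "CONTAINS", "n")))  # case-sensitive
  expect_true(ms_match_filter(e, ms_filter("Formula", "EQ", "C20H18N2O3")))
  expect_false(ms_match_filter(e, ms_filter("Formula", "NE", "C20H18N2O3")))
  # numeric parse failure on the cell makes numeric comparators false
  expect_false(ms_match_filter(e, ms_filter("LogP", "LE", "2.0")))
  expect_false(ms_match_filter(e, ms_filter("LogP", "GE", "0")))
  # absent cell: false everywhere except NE / NOT_CONTAINS
  expect_false(ms_match_filter(e, ms_filter("Missing", "EQ", "x")))
  expect_false(ms_match_filter(e, ms_filter("Missing", "GE", "1")))
  expect_true(ms_match_filter(e, ms_filter("Missing", "NE", "x")))
  expect_true(ms_match_filter(e, ms_filter("Missing", "NOT_CONTAINS", "x")))
  # ID and SMILES are queryable pseudo-columns
  expect_true(ms_match_filter(e, ms_filter("ID", "EQ", "A")))
  expect_true(ms_match_filter(e, ms_filter("SMILES", "CONTAINS", "O")))
  expect_error(ms_filter("MW", "APPROX", "1"), "unknown comparator")
})

test_that("the three-condition conjunction selects exactly the hand-derived subset", {
  # MW >= 300 and LogP <= 2.0 and formula containing N:
  # A (350.2, 1.5, N2) passes; B fails MW and N; C fails LogP
  p <- toy_query_project()
  hits <- ms_query(p, list(ms_filter("MW", "GE", "300"),
                           ms_filter("LogP", "LE", "2.0"),
                           ms_filter("Formula", "CONTAINS", "N")))
  expect_identical(ms_ids(hits), "A")
  expect_identical(hits$schema, p$schema)
})

test_that("queries preserve order/highlights, never mutate the source, and may be empty", {
  p <- toy_query_project()
  p <- ms_set_highlight(p, "C", "red")
  before <- jsonlite::toJSON(p$entries)
  empty <- ms_query(p, ms_filter("MW", "GT", "10000"))
  expect_length(empty$entries, 0)
  all_of_them <- ms_query(p, ms_filter("MW", "NE", "never-this-value"))
  expect_identical(ms_ids(all_of_them), c("A", "B", "C"))
  expect_identical(ms_entry(all_of_them, "C")$highlight, "red")
  expect_identical(jsonlite::toJSON(p$entries), before)
  expect_error(ms_query(p, ms_filter("NoSuchColumn", "EQ", "1")),
               "NoSuchColumn")
  expect_error(ms_query(p, list()), "at least one")
})

test_that("random query specs agree with the brute-force row scan", {
  lib <- fixture_library()
  p <- fixture_project()
  p <- ms_compute_properties(p, c("molecular_weight", "logp",
                                  "molecular_formula"))
  cols <- c("ID", "SMILES", p$schema)
  refs <- c("100", "200.5", "C", "N", "c1", "2.0", "O2", "x")
  set.seed(7)
  for (k in 1:60) {
    filters <- lapply(seq_len(sample(1:3, 1)), function(j)
      ms_filter(sample(cols, 1), sample(molstash:::COMPARATORS, 1),
                sample(refs, 1)))
    expect_identical(ms_ids(ms_query(p, filters)),
                     oracle_property_query(p, filters))
  }
})

test_that("fingerprints are spelling-invariant, non-empty, and discriminate", {
  a <- ms_fingerprint("CCO")
  expect_length(a, 2048)
  expect_identical(a, ms_fingerprint("OCC"))
  expect_identical(a, ms_fingerprint("C(O)C"))
  # frozen regression fixture: the ethanol environment bits
  expect_identical(which(a),
                   c(198L, 346L, 520L, 598L, 1011L, 1126L, 1254L, 1712L, 1994L))
  b <- ms_fingerprint("CCN")
  expect_false(identical(a, b))
  expect_true(sum(ms_fingerprint("C")) > 0)
  expect_error(ms_fingerprint("C1CC"), "invalid SMILES")
})

test_that("tanimoto has identity, symmetry, range and the empty-set convention", {
  x <- ms_fingerprint("O=c1ccc2ccccc2o1")
  y <- ms_fingerprint("c1ccncc1")
  expect_identical(ms_tanimoto(x, x), 1)
  expect_identical(ms_tanimoto(x, y), ms_tanimoto(y, x))
  expect_identical(ms_tanimoto(logical(8), logical(8)), 1)
  a <- c(TRUE, TRUE, FALSE); b <- c(FALSE, TRUE, TRUE)
  expect_equal(ms_tanimoto(a, b), 1 / 3)
  expect_identical(ms_tanimoto(c(TRUE, FALSE), c(FALSE, TRUE)), 0)
  expect_error(ms_tanimoto(logical(3), logical(4)), "lengths differ")
  set.seed(11)
  for (k in 1:200) {
    u <- runif(64) < 0.3; v <- runif(64) < 0.3
    tv <- ms_tanimoto(u, v)
    expect_true(tv >= 0 && tv <= 1)
    expect_identical(tv, ms_tanimoto(v, u))
    expect_identical(ms_tanimoto(u, u), 1)
    if (tv == 1) expect_identical(u, v)
  }
})

test_that("substructure decisions agree with the brute-force subgraph oracle", {
  lib <- fixture_library()
  queries <- c("O=c1ccc2ccccc2o1",       # coumarin core
               "c1ccncc1",               # pyridine
               "c1ccc2c(c1)cc[nH]2",     # indole
               "c1ccccc1",               # benzene
               "[N+](=O)[O-]",           # nitro group
               "Nc1ccccc1")              # aniline
  for (q in queries) {
    impl <- ms_has_substructure(lib$smiles, q)
    orac <- oracle_has_substructure(lib$smiles, q)
    expect_identical(impl, orac, label = paste("query", q))
  }
})

test_that("the planted coumarin cores are retrieved exactly", {
  lib <- fixture_library()
  p <- fixture_project()
  hits <- ms_structural_query(p, "substructure", "O=c1ccc2ccccc2o1")
  expect_identical(sort(ms_ids(hits)), sort(lib$id[lib$is_coumarin]))
  expect_length(hits$entries, 20)
})

test_that("superstructure keeps molecules contained in the query", {
  p <- ms_add_molecule(ms_project("s"), "benzene", "c1ccccc1")
  p <- ms_add_molecule(p, "naphthalene", "c1ccc2ccccc2c1")
  hits <- ms_structural_query(p, "superstructure", "Cc1ccccc1")  # toluene
  expect_identical(ms_ids(hits), "benzene")
})

test_that("substructure and superstructure are dual", {
  lib <- fixture_library()[seq(1, 100, by = 7), ]
  for (i in seq_len(nrow(lib))) for (j in seq_len(nrow(lib))) {
    p <- ms_add_molecule(ms_project("d"), "e", lib$smiles[i])
    sub <- length(ms_structural_query(p, "substructure", lib$smiles[j])$entries)
    sup <- length(ms_structural_query(
      ms_add_molecule(ms_project("d"), "q", lib$smiles[j]),
      "superstructure", lib$smiles[i])$entries)
    expect_identical(sub, sup,
                     label = paste(lib$smiles[i], "vs", lib$smiles[j]))
  }
})

test_that("similarity mode thresholds, adds the Similarity column, and is inclusive at 0", {
  p <- fixture_project()
  all_in <- ms_structural_query(p, "similarity", "O=c1ccc2ccccc2o1",
                                threshold = 0)
  expect_length(all_in$entries, length(p$entries))
  expect_true("Similarity" %in% all_in$schema)
  sims <- as.numeric(vapply(all_in$entries, function(e)
    e$properties$Similarity, character(1)))
  expect_true(all(sims >= 0 & sims <= 1))
  expect_match(all_in$entries[[1]]$properties$Similarity, "^[01]\\.[0-9]{4}$")
  # a coumarin query at a high threshold returns coumarins
  strict <- ms_structural_query(p, "similarity", "O=c1ccc2ccccc2o1",
                                threshold = 0.8)
  lib <- fixture_library()
  expect_true(all(ms_ids(strict) %in% lib$id[lib$is_coumarin]))
  expect_true(length(strict$entries) >= 1)
  expect_error(ms_structural_query(p, "similarity", "CCO", threshold = 1.5),
               "threshold")
  expect_error(ms_structural_query(p, "substructure", "C1CC"),
               "invalid query SMILES")
})

test_that("structural queries never mutate the saved source project", {
  d <- file.path(tempdir(), "immut")
  on.exit(unlink(d, recursive = TRUE))
  p <- ms_create(d, "src")
  for (i in 1:5)
    p <- ms_add_molecule(p, paste0("m", i), fixture_library()$smiles[i])
  ms_save(p)
  before <- tools::md5sum(file.path(d, "project.json"))
  invisible(ms_structural_query(p, "substructure", "c1ccccc1"))
  invisible(ms_query(p, ms_filter("ID", "NE", "zzz")))
  expect_identical(tools::md5sum(file.path(d, "project.json")), before)
})
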