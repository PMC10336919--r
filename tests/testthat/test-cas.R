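# CAS number validation, resolution through the recorded-fixture client,
# caching, and import into projects. No test touches the network.

test_that("the checksum accepts known CAS numbers and rejects perturbations", {
  # 50-00-0 (formaldehyde): weighted sum 5*4 = 20, 20 mod 10 = 0
  expect_true(cas_validate("50-00-0"))
  expect_false(cas_validate("50-00-1"))
  # 64-17-5 (ethanol): 6*4+4*3+1*2+7*1 = 45, mod 10 = 5
  expect_true(cas_validate("64-17-5"))
  expect_false(cas_validate("abc"))
  expect_false(cas_validate("1-2-3-4"))
  expect_false(cas_validate("1-22-3"))      # first group needs 2-7 digits
  expect_identical(cas_validate(c("50-00-0", "64-17-5", "50-00-1")),
                   c(TRUE, TRUE, FALSE))
})

test_that("validation agrees with a brute-force checksum recomputation", {
  set.seed(99)
  for (k in 1:1000) {
    body <- paste0(sample(0:9, sample(4:9, 1), replace = TRUE), collapse = "")
    check <- cas_check_digit(body)
    if (k %% 2 == 0) check <- (check + sample(1:9, 1)) %% 10   # perturb half
    cas <- paste0(substr(body, 1, nchar(body) - 2), "-",
                  substr(body, nchar(body) - 1, nchar(body)), "-", check)
    expect_identical(cas_validate(cas), oracle_cas_valid(cas))
  }
})

fixture_map <- list(
  "64-17-5" = list(smiles = "CCO", iupac_name = "ethanol"),
  "71-43-2" = list(smiles = "c1ccccc1", iupac_name = "benzene"),
  "91-22-5" = list(smiles = "c1ccc2ncccc2c1", iupac_name = "quinoline"))

test_that("resolution returns fixture values, not_found, and invalid_cas correctly", {
  client <- cas_client_fixture(fixture_map)
  rec <- cas_resolve("64-17-5", client)
  expect_identical(rec$status, "resolved")
  expect_identical(rec$smiles, "CCO")
  expect_identical(rec$iupac_name, "ethanol")
  expect_identical(cas_resolve("50-00-0", client)$status, "not_found")
  bad <- cas_resolve("1-2-3-4", client)
  expect_identical(bad$status, "invalid_cas")
  # malformed numbers never reach the client
  expect_identical(client$state$n_lookups, 2L)
})

test_that("the cache serves repeated CAS numbers with a single lookup", {
  client <- cas_client_fixture(fixture_map)
  r1 <- cas_resolve("71-43-2", client)
  r2 <- cas_resolve("71-43-2", client)
  expect_identical(r1, r2)
  expect_identical(client$state$n_lookups, 1L)
})

test_that("a transport failure becomes status network_error, not an exception", {
  broken <- molstash:::.new_client(function(cas) stop("socket down"), "broken")
  rec <- cas_resolve("64-17-5", broken)
  expect_identical(rec$status, "network_error")
})

test_that("a CAS list file resolves per line, order preserved, blanks ignored", {
  client <- cas_client_fixture(fixture_map)
  f <- tempfile(fileext = ".txt")
  writeLines(c("64-17-5", "", "71-43-2", "50-00-0", "64-17-5"), f)
  recs <- cas_resolve_file(f, client)
  expect_identical(vapply(recs, `[[`, character(1), "status"),
                   c("resolved", "resolved", "not_found", "resolved"))
  expect_identical(as.integer(attr(recs, "summary")[["resolved"]]), 3L)
  # duplicate line came from the cache
  expect_identical(client$state$n_lookups, 3L)
  empty <- tempfile(); writeLines(character(0), empty)
  expect_length(cas_resolve_file(empty, client), 0)
})

test_that("resolved records import with CAS as ID and the IUPAC name property", {
  client <- cas_client_fixture(fixture_map)
  recs <- list(cas_resolve("64-17-5", client), cas_resolve("71-43-2", client),
               cas_resolve("50-00-0", client))
  res <- ms_import_cas(ms_project("cas"), recs)
  expect_identical(ms_ids(res$project), c("64-17-5", "71-43-2"))
  expect_identical(ms_entry(res$project, "64-17-5")$properties[["IUPAC name"]],
                   "ethanol")
  expect_identical(res$report$n_imported, 2L)
  expect_match(res$report$invalid_structures$reason, "not_found")
  # re-import of an already-present CAS is reported as duplicate
  res2 <- ms_import_cas(res$project, recs[1])
  expect_identical(res2$report$duplicates$id, "64-17-5")
  expect_length(res2$project$entries, 2)
})

test_that("the shipped recorded client resolves well-known registry numbers", {
  client <- cas_client_fixture(system.file("extdata", "cas_recorded.json",
                                           package = "molstash"))
  rec <- cas_resolve("91-64-5", client)     # coumarin
  expect_identical(rec$status, "resolved")
  expect_identical(smiles_canonical(rec$smiles),
                   smiles_canonical("O=c1ccc2ccccc2o1"))
  expect_true(all(cas_validate(c("50-00-0", "64-17-5", "71-43-2",
                                 "50-78-2", "91-64-5"))))
})

test_that("the generated CAS fixture file is valid and resolvable end-to-end", {
  lib <- fixture_library()[1:10, ]
  fdir <- file.path(tempdir(), "casfx")
  on.exit(unlink(fdir, recursive = TRUE))
  paths <- ms_write_fixture_files(lib, fdir)
  map <- jsonlite::fromJSON(paths[["cas_json"]], simplifyVector = FALSE)
  expect_true(all(cas_validate(names(map))))
  client <- cas_client_fixture(paths[["cas_json"]])
  recs <- lapply(names(map), cas_resolve, client = client)
  expect_true(all(vapply(recs, `[[`, character(1), "status") == "resolved"))
  res <- ms_import_cas(ms_project("c"), recs)
  expect_identical(res$report$n_imported, 10L)
})
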