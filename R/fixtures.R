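# Synthetic molecule libraries with planted ground truth. Molecules are
# assembled from a scaffold x substituent grammar (benzene, pyridine,
# coumarin, indole cores; small substituents including nitro), which
# guarantees every generated SMILES is valid and makes the planted
# features -- coumarin core, nitrogen presence, nitro group -- knowable by
# construction. This stands in for a real screening library (e.g. a random
# ZINC sample) so that import, query and scoring can be exercised offline
# and checked against exact expected answers.

.SCAFFOLDS <- list(
  benzene = c("c1ccccc1", "c1ccc(%s)cc1", "c1cc(%s)ccc1%s"),
  pyridine = c("c1ccncc1", "c1ccnc(%s)c1", "c1cc(%s)ncc1%s"),
  coumarin = c("O=c1ccc2ccccc2o1", "O=c1ccc2cc(%s)ccc2o1",
               "O=c1cc(%s)c2cc(%s)ccc2o1"),
  indole = c("c1ccc2c(c1)cc[nH]2", "c1ccc2c(c1)c(%s)c[nH]2",
             "c1cc(%s)c2c(c1)c(%s)c[nH]2"))

.SUBS_PLAIN <- c(methyl = "C", hydroxy = "O", methoxy = "OC",
                 chloro = "Cl", fluoro = "F", bromo = "Br")
.SUB_AMINO <- "N"
.SUB_NITRO <- "[N+](=O)[O-]"
COUMARIN_CORE_SMILES <- "O=c1ccc2ccccc2o1"

#' Specification for a synthetic molecule library
#'
#' @param n library size (>= 1).
#' @param seed integer seed; the whole library is a pure function of the
#'   spec.
#' @param coumarin_fraction fraction of molecules built on the coumarin
#'   scaffold.
#' @param nitrogen_fraction fraction carrying at least one nitrogen atom.
#' @param nitro_fraction fraction carrying a nitro group (a subset of the
#'   nitrogen carriers, so it cannot exceed `nitrogen_fraction`).
#' @return a `molstash_fixture_spec`.
#' @export
ms_fixture_spec <- function(n, seed = 1, coumarin_fraction = 0.2,
                            nitrogen_fraction = 0.5, nitro_fraction = 0.25) {
  if (n < 1) .stop_user("n must be >= 1")
  for (f in c(coumarin_fraction, nitrogen_fraction, nitro_fraction))
    if (f < 0 || f > 1) .stop_user("fractions must lie in [0, 1]")
  if (round(n * nitro_fraction) > round(n * nitrogen_fraction))
    .stop_user("infeasible: nitro_fraction exceeds nitrogen_fraction")
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 coumarin_fraction = coumarin_fraction,
                 nitrogen_fraction = nitrogen_fraction,
                 nitro_fraction = nitro_fraction),
            class = "molstash_fixture_spec")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic molecule library
#'
#' @param spec a `molstash_fixture_spec` (or arguments to build one, via
#'   `ms_generate_library(ms_fixture_spec(...))`).
#' @return data.frame with columns `id`, `smiles`, `is_coumarin`,
#'   `has_nitrogen`, `has_nitro`; exactly `round(n * fraction)` molecules
#'   carry each planted feature, every SMILES parses, and the same spec
#'   always returns the identical library.
#' @export
ms_generate_library <- function(spec) {
  if (!inherits(spec, "molstash_fixture_spec"))
    .stop_user("use ms_fixture_spec() to build the library spec")
  n <- spec$n
  n_cou <- round(n * spec$coumarin_fraction)
  n_nit <- round(n * spec$nitrogen_fraction)
  n_no2 <- round(n * spec$nitro_fraction)
  .with_seed(spec$seed, {
    is_coumarin <- seq_len(n) %in% sample.int(n, n_cou)
    has_nitrogen <- seq_len(n) %in% sample.int(n, n_nit)
    nitro_pool <- which(has_nitrogen)
    has_nitro <- seq_len(n) %in%
      (if (n_no2 > 0L) sample(nitro_pool, n_no2) else integer(0))
    smiles <- character(n)
    for (i in seq_len(n)) {
      # the required substituent enforces the nitrogen/nitro flag; N-bearing
      # scaffolds are an alternative nitrogen source for non-coumarin rows
      required <- NULL
      if (has_nitro[i]) {
        scaffold <- if (is_coumarin[i]) "coumarin" else sample(c("benzene", "pyridine", "indole"), 1)
        required <- .SUB_NITRO
        if (!is_coumarin[i] && scaffold != "benzene" && stats::runif(1) < 0.5)
          scaffold <- "benzene"
      } else if (has_nitrogen[i]) {
        if (is_coumarin[i]) {
          scaffold <- "coumarin"; required <- .SUB_AMINO
        } else if (stats::runif(1) < 0.5) {
          scaffold <- sample(c("pyridine", "indole"), 1)
        } else {
          scaffold <- "benzene"; required <- .SUB_AMINO
        }
      } else {
        scaffold <- if (is_coumarin[i]) "coumarin" else "benzene"
      }
      decoration <- if (stats::runif(1) < 0.6) sample(.SUBS_PLAIN, 1) else NULL
      subs <- c(required, decoration)
      k <- length(subs)
      tpl <- .SCAFFOLDS[[scaffold]][k + 1L]
      smiles[i] <- if (k == 0L) tpl else do.call(sprintf, c(list(tpl), as.list(subs)))
    }
    data.frame(id = sprintf("m%04d", seq_len(n)), smiles = smiles,
               is_coumarin = is_coumarin, has_nitrogen = has_nitrogen,
               has_nitro = has_nitro, stringsAsFactors = FALSE)
  })
}

#' Materialise a library as importable fixture files
#'
#' Writes the exact dialects the import layer reads: comma and semicolon
#' CSV, XLSX, V2000 SDF, a recorded CAS-fixture JSON (synthetic CAS numbers
#' with valid check digits mapping to the first molecules), and a ready
#' project folder.
#'
#' @param library a library data.frame from [ms_generate_library()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
ms_write_fixture_files <- function(library, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    .stop_io("cannot create fixture directory: ", dir)
  p <- ms_project("fixture")
  for (i in seq_len(nrow(library)))
    p <- ms_add_molecule(p, library$id[i], library$smiles[i],
                         list(Coumarin = as.character(library$is_coumarin[i]),
                              HasN = as.character(library$has_nitrogen[i]),
                              Nitro = as.character(library$has_nitro[i])))
  paths <- c(csv_comma = file.path(dir, "library_comma.csv"),
             csv_semicolon = file.path(dir, "library_semicolon.csv"),
             xlsx = file.path(dir, "library.xlsx"),
             sdf = file.path(dir, "library.sdf"),
             cas_json = file.path(dir, "cas_fixture.json"),
             project = file.path(dir, "project"))
  ms_export_table(p, paths[["csv_comma"]], "csv", separator = "comma")
  ms_export_table(p, paths[["csv_semicolon"]], "csv", separator = "semicolon")
  ms_export_table(p, paths[["xlsx"]], "xlsx")
  ms_export_sdf(p, paths[["sdf"]])
  k <- min(20L, nrow(library))
  cas <- vapply(seq_len(k), function(i) {
    body <- sprintf("%04d%02d", 1000L + i, 10L + i %% 80L)
    paste0(substr(body, 1, 4), "-", substr(body, 5, 6), "-", cas_check_digit(body))
  }, character(1))
  map <- stats::setNames(lapply(seq_len(k), function(i)
    list(smiles = library$smiles[i],
         iupac_name = paste0("synthetic-name-", library$id[i]))), cas)
  jsonlite::write_json(map, paths[["cas_json"]], auto_unbox = TRUE)
  if (dir.exists(paths[["project"]]))
    unlink(paths[["project"]], recursive = TRUE)
  saved <- ms_create(paths[["project"]], "fixture")
  saved$entries <- p$entries
  saved$schema <- p$schema
  ms_save(saved)
  paths
}

#' Synthetic structure-toxicity dataset
#'
#' Binary labels planted on a structural marker: label 1 iff the molecule
#' carries a nitro group, with 5% label noise. Half the library carries the
#' marker, so the class balance stays within a 0.3-0.7 band.
#'
#' @param n dataset size, at least 20 (smaller sets cannot be stratified
#'   meaningfully).
#' @param seed integer seed.
#' @return data.frame with columns `smiles`, `label` (0/1) and
#'   `true_marker` (the noise-free planted flag).
#' @export
ms_generate_tox_dataset <- function(n, seed = 1) {
  if (n < 20) .stop_user("n must be >= 20")
  lib <- ms_generate_library(ms_fixture_spec(
    n, seed = seed, coumarin_fraction = 0.2,
    nitrogen_fraction = 0.75, nitro_fraction = 0.5))
  .with_seed(seed + 7919L, {
    flip <- stats::runif(n) < 0.05
    label <- as.integer(xor(lib$has_nitro, flip))
    data.frame(smiles = lib$smiles, label = label,
               true_marker = lib$has_nitro, stringsAsFactors = FALSE)
  })
}
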