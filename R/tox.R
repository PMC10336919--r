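# Consensus toxicity scoring. Four endpoints (mutagenicity,
# carcinogenicity, estrogenicity, hepatotoxicity) are scored on a 0-100
# scale by an ensemble of probabilistic classifiers over circular
# fingerprints: the score is the arithmetic-mean probability times 100,
# rounded half-up. The bundled ensembles are placeholder models trained
# deterministically on this package's synthetic structure-toxicity data;
# they demonstrate the scoring contract and carry no toxicological
# validity.

TOX_ENDPOINTS <- c("mutagenicity", "carcinogenicity", "estrogenicity",
                   "hepatotoxicity")

TOX_COLUMNS <- c(mutagenicity = "Tox_Mutagenicity",
                 carcinogenicity = "Tox_Carcinogenicity",
                 estrogenicity = "Tox_Estrogenicity",
                 hepatotoxicity = "Tox_Hepatotoxicity")

#' Train a placeholder scoring ensemble
#'
#' Fits `n_models` random-forest classifiers on bootstrap resamples of the
#' fingerprinted training set. Fully reproducible: the same (dataset,
#' n_models, seed) triple gives bit-identical scores.
#'
#' @param smiles training SMILES.
#' @param labels binary labels (0/1 or logical), both classes required.
#' @param n_models ensemble size, at least 1.
#' @param seed integer seed driving the bootstrap resampling and the forests.
#' @param ntree trees per forest member.
#' @return a `molstash_ensemble`.
#' @export
ms_train_ensemble <- function(smiles, labels, n_models = 5, seed = 1,
                              ntree = 60) {
  labels <- as.integer(as.logical(as.integer(labels)))
  if (length(labels) != length(smiles)) .stop_user("smiles/labels length mismatch")
  if (length(unique(labels)) < 2L)
    .stop_user("training set must contain both classes")
  if (n_models < 1L) .stop_user("n_models must be >= 1")
  fp <- ms_fingerprint(smiles)
  if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1L)
  # constant-zero columns carry no signal; dropping them keeps the forests
  # small. The kept column indices are part of the frozen model.
  keep_cols <- which(colSums(fp) > 0L)
  x <- fp[, keep_cols, drop = FALSE] * 1L
  colnames(x) <- paste0("b", keep_cols)
  n <- nrow(x)
  models <- vector("list", n_models)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  for (m in seq_len(n_models)) {
    set.seed(seed * 1000L + m)
    repeat {                       # bootstrap must contain both classes
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2L) break
    }
    models[[m]] <- randomForest::randomForest(
      x = x[idx, , drop = FALSE], y = factor(labels[idx], levels = c(0, 1)),
      ntree = ntree)
  }
  structure(list(models = models, keep_cols = keep_cols,
                 meta = list(seed = seed, n_models = n_models, ntree = ntree,
                             fingerprint = list(bits = FP_BITS,
                                                radius = FP_RADIUS))),
            class = "molstash_ensemble")
}

#' @export
print.molstash_ensemble <- function(x, ...) {
  cat("toxicity scoring ensemble: ", length(x$models),
      " fingerprint classifiers (seed ", x$meta$seed, ")\n", sep = "")
  invisible(x)
}

.ensemble_probs <- function(fp_matrix, ensemble) {
  x <- fp_matrix[, ensemble$keep_cols, drop = FALSE] * 1L
  colnames(x) <- paste0("b", ensemble$keep_cols)
  probs <- vapply(ensemble$models, function(m)
    stats::predict(m, x, type = "prob")[, "1"], numeric(nrow(x)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = nrow(x))
  rowMeans(probs)
}

#' Consensus toxicity score of one molecule
#'
#' `round(100 * mean(model probabilities))`, rounded half-up, so the score
#' of an ensemble of identical models equals the single-model score.
#'
#' @param smiles one SMILES string.
#' @param ensemble a `molstash_ensemble`.
#' @return integer score in `[0, 100]`.
#' @export
ms_consensus_score <- function(smiles, ensemble) {
  if (!inherits(ensemble, "molstash_ensemble")) .stop_user("not an ensemble")
  fp <- ms_fingerprint(smiles)
  if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1L)
  p <- .ensemble_probs(fp, ensemble)
  as.integer(floor(100 * p + 0.5))           # half-up
}

# per-session cache of the bundled placeholder ensembles
.tox_cache <- new.env(parent = emptyenv())

#' Bundled placeholder ensemble for an endpoint
#'
#' Trained deterministically at first use on this package's synthetic
#' structure-toxicity dataset (a fixed seed per endpoint) and memoised for
#' the session, so repeated prediction runs give identical values.
#' @param endpoint one of `r paste(TOX_ENDPOINTS, collapse=", ")`.
#' @return a `molstash_ensemble`.
#' @export
ms_default_ensemble <- function(endpoint) {
  if (!endpoint %in% TOX_ENDPOINTS)
    .stop_user("unknown endpoint: ", endpoint)
  if (is.null(.tox_cache[[endpoint]])) {
    seed <- 100L + match(endpoint, TOX_ENDPOINTS)
    ds <- ms_generate_tox_dataset(200, seed = seed)
    .tox_cache[[endpoint]] <- ms_train_ensemble(ds$smiles, ds$label,
                                                n_models = 5, seed = seed)
  }
  .tox_cache[[endpoint]]
}

#' Predict toxicity columns for a whole project
#'
#' Adds one property column per endpoint (`Tox_Mutagenicity`, ...), each
#' cell an integer 0-100. All computation is local; no network access.
#' Entries that fail to process keep an absent cell and are listed in the
#' `"failed"` attribute of the result.
#'
#' @param project a read-write `molstash_project`.
#' @param endpoints subset of `r paste(TOX_ENDPOINTS, collapse=", ")`.
#' @param ensembles named list mapping endpoint to `molstash_ensemble`;
#'   defaults to the bundled placeholder ensembles.
#' @return the modified project.
#' @export
ms_predict_tox <- function(project, endpoints = TOX_ENDPOINTS,
                           ensembles = NULL) {
  .check_project(project)
  if (!identical(project$mode, "read_write")) .stop_user("project is read-only")
  bad <- setdiff(endpoints, TOX_ENDPOINTS)
  if (length(bad)) .stop_user("unknown endpoint: ", paste(bad, collapse = ", "))
  if (length(project$entries) == 0L) return(project)
  smiles <- vapply(project$entries, `[[`, character(1), "smiles_canonical")
  can <- smiles_canonical(smiles)
  ok <- which(!is.na(can))
  failed <- ms_ids(project)[is.na(can)]
  fp <- NULL
  if (length(ok)) {
    sdf <- .smiles_to_sdfset(can[ok])
    fp <- t(vapply(seq_along(ok), function(i) .fp_graph(.mol_graph(sdf[[i]])),
                   logical(FP_BITS)))
  }
  for (ep in endpoints) {
    ens <- if (!is.null(ensembles)) ensembles[[ep]] else ms_default_ensemble(ep)
    if (!inherits(ens, "molstash_ensemble"))
      .stop_user("no ensemble supplied for endpoint ", ep)
    col <- TOX_COLUMNS[[ep]]
    project <- .add_schema_columns(project, col)
    project$computed <- union(project$computed, col)
    if (length(ok)) {
      scores <- as.integer(floor(100 * .ensemble_probs(fp, ens) + 0.5))
      for (j in seq_along(ok))
        project$entries[[ok[j]]]$properties[[col]] <- as.character(scores[j])
    }
  }
  attr(project, "failed") <- failed
  project
}
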