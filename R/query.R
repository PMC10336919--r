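# Query engine. Property queries AND-combine filters built from the eight
# comparators (>=, >, <, <=, equal, different, contains, not-contains);
# structural queries run substructure / superstructure matching through
# OpenBabel's SMARTS engine (the query SMILES is canonicalized first so
# query and target share one aromaticity perception) or Tanimoto similarity
# over Morgan-style circular fingerprints. Queries always return a new
# project and never touch the source.

COMPARATORS <- c("GE", "GT", "LT", "LE", "EQ", "NE", "CONTAINS", "NOT_CONTAINS")

#' Build a property filter
#'
#' @param column `"ID"`, `"SMILES"`, or a property column name.
#' @param comparator one of `GE`, `GT`, `LT`, `LE` (numeric comparison),
#'   `EQ`, `NE` (exact string match), `CONTAINS`, `NOT_CONTAINS`
#'   (case-sensitive substring).
#' @param reference the reference value, as a string.
#' @return a `molstash_filter`.
#' @examples
#' ms_filter("MW", "GE", "300")
#' @export
ms_filter <- function(column, comparator, reference) {
  if (!comparator %in% COMPARATORS)
    .stop_user("unknown comparator: ", comparator,
               " (one of ", paste(COMPARATORS, collapse = ", "), ")")
  structure(list(column = as.character(column), comparator = comparator,
                 reference = as.character(reference)),
            class = "molstash_filter")
}

#' @export
print.molstash_filter <- function(x, ...) {
  cat("filter: ", x$column, " ", x$comparator, " \"", x$reference, "\"\n",
      sep = "")
  invisible(x)
}

# Evaluate one filter against one cell value (NA = absent).
# Numeric comparators parse both sides as decimals; a parse failure on
# either side makes the filter FALSE. Absence is FALSE for everything except
# NE and NOT_CONTAINS (an absent value differs from any reference).
.match_value <- function(value, comparator, reference) {
  if (is.na(value))
    return(comparator %in% c("NE", "NOT_CONTAINS"))
  switch(comparator,
    GE = , GT = , LT = , LE = {
      v <- suppressWarnings(as.numeric(value))
      r <- suppressWarnings(as.numeric(reference))
      if (is.na(v) || is.na(r)) return(FALSE)
      switch(comparator, GE = v >= r, GT = v > r, LT = v < r, LE = v <= r)
    },
    EQ = identical(value, reference),
    NE = !identical(value, reference),
    CONTAINS = grepl(reference, value, fixed = TRUE),
    NOT_CONTAINS = !grepl(reference, value, fixed = TRUE))
}

#' Evaluate a filter against one entry
#'
#' @param entry an entry as returned by [ms_entry()].
#' @param filter a `molstash_filter`.
#' @return logical.
#' @export
ms_match_filter <- function(entry, filter) {
  value <- switch(filter$column,
                  ID = entry$id,
                  SMILES = entry$smiles_canonical,
                  { v <- entry$properties[[filter$column]]
                    if (is.null(v)) NA_character_ else v })
  .match_value(value, filter$comparator, filter$reference)
}

#' Filter a project by property comparisons
#'
#' Keeps exactly the entries for which every filter is true (filters are
#' AND-combined), preserving order, schema, highlights and attachment
#' references; the source project is untouched. The result is a new,
#' unsaved project.
#'
#' @param project a `molstash_project`.
#' @param filters one `molstash_filter` or a list of them (non-empty).
#' @return a new `molstash_project`.
#' @examples
#' \donttest{
#' p <- ms_project("toy")
#' p <- ms_add_molecule(p, "A", "CCO", list(MW = "350.2", LogP = "1.5"))
#' hits <- ms_query(p, list(ms_filter("MW", "GE", "300"),
#'                          ms_filter("LogP", "LE", "2.0")))
#' }
#' @export
ms_query <- function(project, filters) {
  .check_project(project)
  if (inherits(filters, "molstash_filter")) filters <- list(filters)
  if (!length(filters)) .stop_user("query needs at least one filter")
  for (f in filters) {
    if (!inherits(f, "molstash_filter")) .stop_user("not a filter object")
    if (!f$column %in% c("ID", "SMILES", project$schema))
      .stop_user("unknown column: ", f$column)
  }
  keep <- vapply(project$entries, function(e)
    all(vapply(filters, function(f) ms_match_filter(e, f), logical(1))),
    logical(1))
  out <- .new_project(paste0(chartr(" ", "_", project$name), "_query"),
                      entries = project$entries[keep],
                      schema = project$schema)
  out$computed <- project$computed
  out
}

#' In-memory project constructor
#'
#' Creates an unsaved project (no folder, no lock) for programmatic use;
#' [ms_create()] is the persistent equivalent.
#' @param name project name.
#' @return an empty `molstash_project` in read-write mode.
#' @export
ms_project <- function(name = "untitled") .new_project(name)

# ---- fingerprints ---------------------------------------------------------

FP_BITS <- 2048L
FP_RADIUS <- 2L

# Deterministic polynomial string hash below 2^26 so all arithmetic stays
# exact in doubles.
.HASH_MOD <- 67108859
.hash_chr <- function(s) {
  h <- 17
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% .HASH_MOD
  h
}
.hash_num <- function(values) {
  h <- 23
  for (v in values) h <- (h * 31 + v) %% .HASH_MOD
  h
}

# Morgan-style circular fingerprint of one molecular graph: atom invariants
# (element, heavy degree, bond-order sum, ring membership) refined over
# FP_RADIUS neighbourhood-hashing rounds; every environment from every round
# sets one bit.
.fp_graph <- function(graph) {
  bits <- logical(FP_BITS)
  n <- graph$n
  if (n == 0L) return(bits)
  nbr <- vector("list", n)
  if (nrow(graph$bonds)) {
    for (k in seq_len(nrow(graph$bonds))) {
      a <- graph$bonds[k, 1]; b <- graph$bonds[k, 2]; o <- graph$bonds[k, 3]
      nbr[[a]] <- rbind(nbr[[a]], c(b, o))
      nbr[[b]] <- rbind(nbr[[b]], c(a, o))
    }
  }
  inv <- vapply(seq_len(n), function(i) {
    deg <- if (is.null(nbr[[i]])) 0L else nrow(nbr[[i]])
    osum <- if (is.null(nbr[[i]])) 0L else sum(nbr[[i]][, 2])
    .hash_num(c(.hash_chr(graph$atoms[i]), deg, osum,
                as.integer(graph$in_ring[i])))
  }, numeric(1))
  bits[inv %% FP_BITS + 1L] <- TRUE
  for (round in seq_len(FP_RADIUS)) {
    inv_new <- vapply(seq_len(n), function(i) {
      if (is.null(nbr[[i]])) return(.hash_num(c(round, inv[i])))
      env <- nbr[[i]]
      pairs <- cbind(env[, 2], inv[env[, 1]])
      ord <- order(pairs[, 1], pairs[, 2])
      .hash_num(c(round, inv[i], t(pairs[ord, , drop = FALSE])))
    }, numeric(1))
    inv <- inv_new
    bits[inv %% FP_BITS + 1L] <- TRUE
  }
  bits
}

#' Circular fingerprint of a molecule
#'
#' 2048-bit Morgan-style fingerprint (radius 2) computed on the canonical
#' molecular graph, so any spelling of the same molecule gives an identical
#' bit set.
#'
#' @param smiles one SMILES string or a character vector of them.
#' @return for one molecule a logical vector of length 2048; for several, a
#'   logical matrix with one row per molecule.
#' @export
ms_fingerprint <- function(smiles) {
  can <- smiles_canonical(smiles)
  if (anyNA(can))
    .stop_user("invalid SMILES: ",
               paste(smiles[is.na(can)], collapse = ", "))
  sdf <- .smiles_to_sdfset(can)
  fps <- t(vapply(seq_along(can), function(i) .fp_graph(.mol_graph(sdf[[i]])),
                  logical(FP_BITS)))
  if (length(can) == 1L) fps[1L, ] else fps
}

#' Tanimoto coefficient of two fingerprints
#'
#' `|a AND b| / |a OR b|`; defined as 1 when both bit sets are empty.
#' @param a,b logical vectors of equal length.
#' @return numeric in `[0, 1]`.
#' @export
ms_tanimoto <- function(a, b) {
  if (length(a) != length(b)) .stop_user("fingerprint lengths differ")
  u <- sum(a | b)
  if (u == 0L) return(1.0)
  sum(a & b) / u
}

# ---- structural queries ---------------------------------------------------

# Turn a query structure into the SMARTS pattern used for matching: the
# canonical SMILES with explicit hydrogen counts stripped from bracket
# atoms. Canonicalization fills in implicit hydrogens (e.g. a lone nitro
# fragment becomes O=[NH+][O-]), and a literal H count in SMARTS would
# wrongly demand that hydrogen on the target; substructure containment is
# about the heavy-atom graph.
.query_smarts <- function(canonical_smiles) {
  gsub("\\[([0-9]*)([A-Za-z][a-z]?|\\*)(@{0,2})H[0-9]*([^]]*)\\]",
       "[\\1\\2\\3\\4]", canonical_smiles)
}

#' Test substructure containment
#'
#' Vectorised over targets: is `query_smiles` contained in each target as a
#' subgraph? Both sides are canonicalized by the same engine before matching
#' so aromaticity is perceived consistently; the query is interpreted as a
#' plain structure (SMILES), not a SMARTS expression.
#'
#' @param target_smiles character vector of molecule SMILES.
#' @param query_smiles one SMILES string.
#' @return logical vector (`NA` for unparsable targets).
#' @export
ms_has_substructure <- function(target_smiles, query_smiles) {
  qcan <- smiles_canonical(query_smiles)
  if (is.na(qcan)) .stop_user("invalid query SMILES: ", query_smiles)
  tcan <- smiles_canonical(target_smiles)
  out <- rep(NA, length(tcan))
  ok <- which(!is.na(tcan))
  if (!length(ok)) return(out)
  out[ok] <- .smarts_count(tcan[ok], .query_smarts(qcan)) > 0
  out
}

#' Run a structural query over a project
#'
#' Three modes: `substructure` keeps entries containing the query as a
#' subgraph; `superstructure` keeps entries whose whole graph is contained
#' in the query; `similarity` keeps entries whose Tanimoto coefficient
#' against the query fingerprint reaches `threshold`, and adds a
#' `Similarity` column (4 decimals) to the result. Entries that cannot be
#' processed are skipped and listed in the result's `"skipped"` attribute.
#' The source project is never modified.
#'
#' @param project a `molstash_project`.
#' @param mode `"substructure"`, `"superstructure"` or `"similarity"`.
#' @param query_smiles the reference structure, as SMILES.
#' @param threshold similarity threshold in `[0, 1]` (similarity mode only).
#' @return a new `molstash_project` with the matching entries.
#' @export
ms_structural_query <- function(project,
                                mode = c("substructure", "superstructure",
                                         "similarity"),
                                query_smiles, threshold = 0.7) {
  .check_project(project)
  mode <- match.arg(mode)
  qcan <- smiles_canonical(query_smiles)
  if (is.na(qcan)) .stop_user("invalid query SMILES: ", query_smiles)
  n <- length(project$entries)
  smiles <- vapply(project$entries, `[[`, character(1), "smiles_canonical")
  keep <- logical(n)
  sim <- rep(NA_real_, n)
  skipped <- character(0)
  if (n > 0L) {
    tcan <- smiles_canonical(smiles)
    bad <- is.na(tcan)
    skipped <- ms_ids(project)[bad]
    ok <- which(!bad)
    if (length(ok)) {
      if (mode == "substructure") {
        keep[ok] <- .smarts_count(tcan[ok], .query_smarts(qcan)) > 0
      } else if (mode == "superstructure") {
        keep[ok] <- vapply(ok, function(i)
          .smarts_count(qcan, .query_smarts(tcan[i])) > 0, logical(1))
      } else {
        if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
          .stop_user("similarity threshold must be in [0, 1]")
        qfp <- ms_fingerprint(qcan)
        sdf <- .smiles_to_sdfset(tcan[ok])
        for (j in seq_along(ok)) {
          fp <- .fp_graph(.mol_graph(sdf[[j]]))
          sim[ok[j]] <- ms_tanimoto(fp, qfp)
        }
        keep[ok] <- sim[ok] >= threshold
      }
    }
  }
  out <- .new_project(paste0(chartr(" ", "_", project$name), "_", mode),
                      entries = project$entries[keep],
                      schema = project$schema)
  out$computed <- project$computed
  if (mode == "similarity") {
    out <- .add_schema_columns(out, "Similarity")
    kidx <- which(keep)
    for (j in seq_along(kidx))
      out$entries[[j]]$properties[["Similarity"]] <-
        sprintf("%.4f", sim[kidx[j]])
  }
  attr(out, "skipped") <- skipped
  out
}
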