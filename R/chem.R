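#' @importFrom ChemmineOB convertFormat
#' @importFrom ChemmineR read.SDFset atomblock bondblock propOB
NULL

# Low-level chemistry helpers. All structure handling is delegated to
# OpenBabel (through ChemmineOB) and ChemmineR; this file only adapts their
# batch interfaces to per-molecule, NA-tolerant vectorised calls.

#' Canonicalize SMILES strings
#'
#' Converts each SMILES to the canonical spelling produced by OpenBabel, so
#' that two spellings of the same molecular graph compare equal as strings.
#' Invalid SMILES yield `NA` rather than an error.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where the input does
#'   not parse.
#' @examples
#' \donttest{
#' smiles_canonical(c("OCC", "C1=CC=CC=C1", "C1CC"))
#' }
#' @export
smiles_canonical <- function(smiles) {
  smiles <- as.character(smiles)
  out <- rep(NA_character_, length(smiles))
  if (length(smiles) == 0L) return(out)
  # whitespace would corrupt the title-tagged batch input
  clean <- !is.na(smiles) & nzchar(smiles) & !grepl("[[:space:]]", smiles)
  idx <- which(clean)
  if (length(idx) == 0L) return(out)
  batch <- .ob_convert_batch(smiles[idx])
  if (is.null(batch)) {
    # at least one bad molecule aborts the OpenBabel batch: fall back per-row
    for (i in idx) out[i] <- .ob_canonical_one(smiles[i])
  } else {
    out[idx] <- batch
  }
  out
}

#' Test whether SMILES strings parse
#'
#' @param smiles character vector of SMILES strings.
#' @return logical vector.
#' @export
smiles_valid <- function(smiles) !is.na(smiles_canonical(smiles))

# batch SMILES -> canonical SMILES; returns NULL if any input fails
.ob_convert_batch <- function(smiles) {
  n <- length(smiles)
  inp <- paste0(paste(smiles, paste0("t", seq_len(n))), "\n", collapse = "")
  res <- tryCatch(convertFormat("SMI", "CAN", inp), error = function(e) "")
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines) != n) return(NULL)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  can <- vapply(parts, `[`, character(1), 1L)
  ttl <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else "", character(1))
  if (!identical(ttl, paste0("t", seq_len(n)))) return(NULL)
  can
}

.ob_canonical_one <- function(smi) {
  res <- tryCatch(convertFormat("SMI", "CAN", paste0(smi, " t1\n")),
                  error = function(e) "")
  line <- strsplit(res, "\n", fixed = TRUE)[[1]]
  line <- line[nzchar(line)][1]
  if (is.na(line)) return(NA_character_)
  strsplit(line, "\t", fixed = TRUE)[[1]][1]
}

# SMILES vector (all valid) -> SDFset with the given ids as molecule titles.
# ids must be free of whitespace-sensitive content; they are passed through
# the SMILES title field.
.smiles_to_sdfset <- function(smiles, ids = paste0("m", seq_along(smiles))) {
  stopifnot(length(smiles) == length(ids), length(smiles) > 0L)
  safe_ids <- paste0("t", seq_along(smiles))
  inp <- paste0(paste(smiles, safe_ids), "\n", collapse = "")
  txt <- convertFormat("SMI", "SDF", inp)
  sdf <- suppressWarnings(read.SDFset(strsplit(txt, "\n", fixed = TRUE)[[1]]))
  if (length(sdf) != length(smiles))
    stop("internal: SDF conversion dropped molecules")
  ChemmineR::cid(sdf) <- as.character(ids)
  sdf
}

# SMARTS match counts for a vector of (valid) SMILES. The molecules are
# read by OpenBabel straight from SMILES, so formal charges and aromaticity
# are exactly what the canonicalizer perceived.
.smarts_count <- function(smiles, pattern, unique_matches = FALSE) {
  if (length(smiles) == 0L) return(integer(0))
  inp <- paste0(paste(smiles, paste0("t", seq_along(smiles))), "\n",
                collapse = "")
  counts <- ChemmineOB::forEachMol("SMILES", inp, function(mol)
    ChemmineOB::smartsSearch_OB(list(mol), pattern,
                                uniqueMatches = unique_matches))
  as.integer(unlist(counts))
}

# Molecular graph of one molecule: atoms (element symbols), bonds
# (from, to, order), and ring membership flags. Explicit hydrogens are not
# produced by the SMILES->SDF route, so atoms are the heavy atoms.
.mol_graph <- function(sdf_component) {
  ab <- atomblock(sdf_component)
  bb <- bondblock(sdf_component)
  sym <- sub("_[0-9]+$", "", rownames(ab))
  n <- length(sym)
  if (is.null(bb) || nrow(bb) == 0L || ncol(bb) < 3L) {
    # bond-free molecules come back as a zero-filled placeholder block
    bonds <- matrix(integer(0), ncol = 3,
                    dimnames = list(NULL, c("from", "to", "order")))
  } else {
    bonds <- cbind(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                   order = as.integer(bb[, 3]))
    bonds <- bonds[bonds[, 1] > 0 & bonds[, 2] > 0, , drop = FALSE]
  }
  list(atoms = sym, bonds = bonds, n = n, in_ring = .ring_atoms(n, bonds))
}

# Atoms that lie on at least one cycle: endpoints of non-bridge edges.
# Bridges found by edge-removal connectivity tests; molecules are small.
.ring_atoms <- function(n, bonds) {
  in_ring <- rep(FALSE, n)
  m <- nrow(bonds)
  if (m == 0L) return(in_ring)
  adj <- vector("list", n)
  for (k in seq_len(m)) {
    adj[[bonds[k, 1]]] <- c(adj[[bonds[k, 1]]], k)
    adj[[bonds[k, 2]]] <- c(adj[[bonds[k, 2]]], k)
  }
  reachable <- function(src, dst, skip) {
    seen <- rep(FALSE, n)
    seen[src] <- TRUE
    queue <- src
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (k in adj[[v]]) {
        if (k == skip) next
        w <- if (bonds[k, 1] == v) bonds[k, 2] else bonds[k, 1]
        if (!seen[w]) {
          if (w == dst) return(TRUE)
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    FALSE
  }
  for (k in seq_len(m)) {
    if (reachable(bonds[k, 1], bonds[k, 2], k)) {
      in_ring[bonds[k, 1]] <- TRUE
      in_ring[bonds[k, 2]] <- TRUE
    }
  }
  in_ring
}

# Number of smallest rings (cyclomatic number summed over components).
.ring_count <- function(graph) {
  n <- graph$n
  m <- nrow(graph$bonds)
  if (n == 0L) return(0L)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in seq_len(m)) {
    a <- find(graph$bonds[k, 1]); b <- find(graph$bonds[k, 2])
    if (a != b) parent[a] <- b
  }
  comps <- length(unique(vapply(seq_len(n), find, integer(1))))
  as.integer(m - n + comps)
}
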