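# Physicochemical descriptors. All chemistry is computed by OpenBabel on the
# canonical molecular graph, so the values are independent of how the input
# SMILES is spelled. Molecular weight uses average (not monoisotopic) atomic
# masses, matching chemistry-inventory convention; logP is the
# Wildman-Crippen atomic-contribution estimate; TPSA the Ertl topological
# polar surface area in square Angstrom.

DESCRIPTOR_NAMES <- c("molecular_weight", "heavy_atom_count",
                      "molecular_formula", "logp", "hbd", "hba",
                      "rotatable_bonds", "ring_count", "tpsa")

# Project column name for each descriptor
DESCRIPTOR_COLUMNS <- c(molecular_weight = "MW", heavy_atom_count = "HeavyAtoms",
                        molecular_formula = "Formula", logp = "LogP",
                        hbd = "HBD", hba = "HBA", rotatable_bonds = "RotB",
                        ring_count = "Rings", tpsa = "TPSA")

.ROTATABLE_SMARTS <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

#' Compute physicochemical descriptors for SMILES strings
#'
#' @param smiles character vector of SMILES.
#' @param set descriptors to compute, a subset of
#'   `molecular_weight` (g/mol, average masses), `heavy_atom_count`,
#'   `molecular_formula` (Hill order: C, H, then alphabetical), `logp`
#'   (Wildman-Crippen atomic contributions), `hbd`, `hba`,
#'   `rotatable_bonds`, `ring_count`, `tpsa` (Angstrom^2).
#' @return data.frame with one row per input molecule and one column per
#'   descriptor (plus `smiles`); rows for unparsable SMILES are `NA` and
#'   flagged in the logical column `failed`.
#' @examples
#' \donttest{
#' ms_descriptors("CCO", c("molecular_weight", "molecular_formula"))
#' }
#' @export
ms_descriptors <- function(smiles, set = DESCRIPTOR_NAMES) {
  set <- match.arg(set, DESCRIPTOR_NAMES, several.ok = TRUE)
  if (!length(set)) .stop_user("descriptor set must be non-empty")
  n <- length(smiles)
  out <- data.frame(smiles = as.character(smiles), stringsAsFactors = FALSE)
  can <- smiles_canonical(smiles)
  out$failed <- is.na(can)
  counts <- c("heavy_atom_count", "hbd", "hba", "rotatable_bonds",
              "ring_count")
  for (d in set)
    out[[d]] <- if (d == "molecular_formula") NA_character_
                else if (d %in% counts) NA_integer_ else NA_real_
  ok <- which(!out$failed)
  if (!length(ok)) return(out)
  sdf <- .smiles_to_sdfset(can[ok])
  pr <- suppressWarnings(propOB(sdf))
  if ("molecular_weight" %in% set) out$molecular_weight[ok] <- pr$MW
  if ("molecular_formula" %in% set) out$molecular_formula[ok] <- pr$formula
  if ("logp" %in% set) out$logp[ok] <- pr$logP
  if ("hbd" %in% set) out$hbd[ok] <- as.integer(pr$HBD)
  if ("hba" %in% set) out$hba[ok] <- as.integer(pr$HBA1)
  if ("tpsa" %in% set) out$tpsa[ok] <- pr$TPSA
  if ("heavy_atom_count" %in% set)
    out$heavy_atom_count[ok] <- vapply(seq_along(ok), function(j)
      nrow(atomblock(sdf[[j]])), integer(1))
  if ("ring_count" %in% set)
    out$ring_count[ok] <- vapply(seq_along(ok), function(j)
      .ring_count(.mol_graph(sdf[[j]])), integer(1))
  if ("rotatable_bonds" %in% set)
    out$rotatable_bonds[ok] <-
      .smarts_count(can[ok], .ROTATABLE_SMARTS, unique_matches = TRUE)
  out
}

#' Compute descriptors into project columns
#'
#' Adds (or refills) one property column per requested descriptor:
#' `MW`, `HeavyAtoms`, `Formula`, `LogP`, `HBD`, `HBA`, `RotB`, `Rings`,
#' `TPSA`. MW, LogP and TPSA are formatted with 2 decimals, counts as plain
#' integers; values are stored as strings like any other property and stay
#' editable. Recomputing overwrites previous descriptor values (including
#' manual edits of those cells). Entries whose structure fails to process
#' keep an absent cell and are returned in the `failed` attribute.
#'
#' @param project a read-write `molstash_project`.
#' @param set descriptors, as in [ms_descriptors()].
#' @param overwrite_user_columns allow filling a column that already exists
#'   in the schema but was not created by this function's naming scheme.
#' @return the modified project; attribute `"failed"` lists ids that could
#'   not be processed.
#' @export
ms_compute_properties <- function(project, set = DESCRIPTOR_NAMES,
                                  overwrite_user_columns = FALSE) {
  .check_project(project)
  if (!identical(project$mode, "read_write")) .stop_user("project is read-only")
  set <- match.arg(set, DESCRIPTOR_NAMES, several.ok = TRUE)
  if (length(project$entries) == 0L) return(project)
  smiles <- vapply(project$entries, `[[`, character(1), "smiles_canonical")
  desc <- ms_descriptors(smiles, set)
  for (d in set) {
    col <- DESCRIPTOR_COLUMNS[[d]]
    if (col %in% project$schema && !overwrite_user_columns &&
        !col %in% project$computed)
      .stop_user("column ", col, " already exists; set overwrite_user_columns=TRUE")
    project <- .add_schema_columns(project, col)
    project$computed <- union(project$computed, col)
    vals <- .format_descriptor(d, desc[[d]])
    for (i in seq_along(project$entries)) {
      if (is.na(vals[i])) {
        project$entries[[i]]$properties[[col]] <- NULL   # absent, not ""
      } else {
        project$entries[[i]]$properties[[col]] <- vals[i]
      }
    }
  }
  attr(project, "failed") <- ms_ids(project)[desc$failed]
  project
}

.format_descriptor <- function(d, values) {
  if (d == "molecular_formula") return(as.character(values))
  if (d %in% c("molecular_weight", "logp", "tpsa"))
    return(ifelse(is.na(values), NA_character_, sprintf("%.2f", values)))
  ifelse(is.na(values), NA_character_,
         as.character(as.integer(round(values))))
}

# ---- formula arithmetic ---------------------------------------------------

# IUPAC 2021 standard atomic weights (conventional values), elements that
# occur in small organic molecules.
.ATOMIC_MASSES <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998403163,
  Si = 28.085, P = 30.973761998, S = 32.06, Cl = 35.45, Br = 79.904,
  I = 126.90447, Na = 22.98976928, K = 39.0983, Li = 6.94, Ca = 40.078,
  Mg = 24.305, Fe = 55.845, Zn = 65.38, Se = 78.971)

#' Molecular mass from a Hill formula string
#'
#' Parses a molecular formula such as `"C9H6O2"` and sums standard average
#' atomic masses. Independent of any structure handling, so it serves as a
#' cross-check of descriptor output.
#' @param formula character vector of formula strings.
#' @return numeric vector, g/mol.
#' @examples
#' ms_formula_mass("C2H6O")
#' @export
ms_formula_mass <- function(formula) {
  vapply(as.character(formula), function(f) {
    if (is.na(f) || !nzchar(f)) return(NA_real_)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    if (!nzchar(paste(toks, collapse = "")) ||
        nchar(paste(toks, collapse = "")) != nchar(gsub("[+-]", "", f)))
      return(NA_real_)
    total <- 0
    for (t in toks) {
      el <- sub("^([A-Z][a-z]?).*$", "\\1", t)
      cnt <- sub("^[A-Z][a-z]?", "", t)
      cnt <- if (nzchar(cnt)) as.numeric(cnt) else 1
      if (!el %in% names(.ATOMIC_MASSES)) return(NA_real_)
      total <- total + .ATOMIC_MASSES[[el]] * cnt
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}
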