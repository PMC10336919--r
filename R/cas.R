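# CAS registry-number resolution. A CAS number is 2-7 digits, 2 digits and a
# single check digit (dd..d-dd-d); the check digit is the weighted digit sum
# modulo 10, weights counted 1,2,3,... from the rightmost digit before the
# check digit. Structure/name lookup goes through a pluggable client so the
# whole pipeline runs offline against recorded fixtures; a live PubChem
# PUG-REST client is provided for interactive use only.

#' Validate a CAS registry number
#'
#' Checks both the `dd..d-dd-d` format (2-7 digits, 2 digits, 1 digit) and
#' the mod-10 positional check digit.
#'
#' @param cas character vector of candidate CAS numbers.
#' @return logical vector.
#' @examples
#' cas_validate(c("50-00-0", "64-17-5", "50-00-1", "abc"))
#' @export
cas_validate <- function(cas) {
  vapply(as.character(cas), function(x) {
    if (is.na(x) || !grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", x)) return(FALSE)
    digits <- as.integer(strsplit(gsub("-", "", x), "")[[1]])
    check <- digits[length(digits)]
    body <- rev(digits[-length(digits)])         # rightmost first
    sum(body * seq_along(body)) %% 10 == check
  }, logical(1), USE.NAMES = FALSE)
}

#' Compute the check digit for a CAS number body
#'
#' Given the digits before the check digit (e.g. `"5000"` for `50-00-?`),
#' returns the digit making the full number checksum-valid. Used by the
#' fixture generator to mint synthetic but well-formed CAS numbers.
#' @param body string of 4-9 digits (the digits before the check digit).
#' @return integer 0-9.
#' @export
cas_check_digit <- function(body) {
  digits <- rev(as.integer(strsplit(as.character(body), "")[[1]]))
  as.integer(sum(digits * seq_along(digits)) %% 10)
}

# ---- clients --------------------------------------------------------------

.new_client <- function(lookup, label) {
  env <- new.env(parent = emptyenv())
  env$cache <- new.env(parent = emptyenv())
  env$n_lookups <- 0L
  structure(list(lookup = lookup, state = env, label = label),
            class = "molstash_cas_client")
}

#' @export
print.molstash_cas_client <- function(x, ...) {
  cat("CAS resolver client (", x$label, "), ", x$state$n_lookups,
      " lookups performed\n", sep = "")
  invisible(x)
}

#' Recorded-fixture CAS client
#'
#' Replays stored responses: a named list (or JSON file holding one) mapping
#' CAS numbers to `list(smiles=, iupac_name=)`. Deterministic and fully
#' offline; this is the client the test-suite and fixtures use.
#'
#' @param map named list, or path to a JSON file of the same shape.
#' @return a client usable with [cas_resolve()].
#' @export
cas_client_fixture <- function(map) {
  if (is.character(map) && length(map) == 1L) {
    if (!file.exists(map)) .stop_io("cannot read CAS fixture file: ", map)
    map <- jsonlite::fromJSON(map, simplifyVector = FALSE)
  }
  force(map)
  .new_client(function(cas) {
    hit <- map[[cas]]
    if (is.null(hit)) return(NULL)
    list(smiles = as.character(hit$smiles),
         iupac_name = as.character(hit$iupac_name))
  }, "recorded fixture")
}

#' Live PubChem PUG-REST CAS client
#'
#' Resolves a CAS number by registry-name lookup against the PubChem
#' PUG-REST service, returning SMILES and IUPAC name of the first hit.
#' Requires network access; requests are rate-limited to one per 200 ms with
#' 3 retries. Never used by the test-suite -- pass it explicitly when you
#' want live resolution.
#'
#' @param base_url service root.
#' @param min_interval minimum seconds between requests.
#' @param retries attempts per CAS before reporting a network error.
#' @return a client usable with [cas_resolve()].
#' @export
cas_client_pubchem <- function(
    base_url = "https://pubchem.ncbi.nlm.nih.gov/rest/pug",
    min_interval = 0.2, retries = 3) {
  last <- new.env(parent = emptyenv())
  last$t <- 0
  .new_client(function(cas) {
    url <- paste0(base_url, "/compound/name/", utils::URLencode(cas),
                  "/property/CanonicalSMILES,IUPACName/JSON")
    for (k in seq_len(retries)) {
      wait <- min_interval - (as.numeric(Sys.time()) - last$t)
      if (wait > 0) Sys.sleep(wait)
      last$t <- as.numeric(Sys.time())
      ans <- tryCatch(jsonlite::fromJSON(url), error = function(e) NULL)
      if (!is.null(ans)) {
        p <- ans$PropertyTable$Properties
        if (is.null(p) || nrow(p) == 0L) return(NULL)
        return(list(smiles = as.character(p$CanonicalSMILES[1]),
                    iupac_name = as.character(p$IUPACName[1])))
      }
      Sys.sleep(min_interval * k)
    }
    stop("network failure resolving ", cas)
  }, "PubChem PUG-REST")
}

# ---- resolution -----------------------------------------------------------

.cas_record <- function(cas, smiles = NA_character_,
                        iupac_name = NA_character_, status) {
  list(cas = cas, smiles = smiles, iupac_name = iupac_name, status = status)
}

#' Resolve one CAS number to structure and IUPAC name
#'
#' Malformed numbers are rejected without touching the client; results are
#' cached on the client so repeated resolution of the same CAS performs one
#' lookup. Transport failures surface as status `network_error`, never as an
#' exception.
#'
#' @param cas a CAS number string.
#' @param client a client from [cas_client_fixture()] or
#'   [cas_client_pubchem()].
#' @return a record: list(cas, smiles, iupac_name, status) with status one
#'   of `resolved`, `not_found`, `invalid_cas`, `network_error`.
#' @export
cas_resolve <- function(cas, client) {
  cas <- as.character(cas)
  if (!inherits(client, "molstash_cas_client")) .stop_user("not a CAS client")
  if (!cas_validate(cas)) return(.cas_record(cas, status = "invalid_cas"))
  cached <- client$state$cache[[cas]]
  if (!is.null(cached)) return(cached)
  hit <- tryCatch(client$lookup(cas), error = function(e) e)
  rec <- if (inherits(hit, "error")) {
    .cas_record(cas, status = "network_error")
  } else if (is.null(hit) || is.na(smiles_canonical(hit$smiles))) {
    .cas_record(cas, status = "not_found")
  } else {
    .cas_record(cas, hit$smiles, hit$iupac_name, "resolved")
  }
  if (!inherits(hit, "error")) {
    client$state$n_lookups <- client$state$n_lookups + 1L
    client$state$cache[[cas]] <- rec
  }
  rec
}

#' Resolve a text file of CAS numbers
#'
#' One CAS per line, blank lines ignored; order preserved.
#' @param path text file.
#' @param client resolver client.
#' @return list of records (as [cas_resolve()]) with a `summary` attribute
#'   counting each status.
#' @export
cas_resolve_file <- function(path, client) {
  if (!file.exists(path)) .stop_io("cannot read CAS list: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  records <- lapply(lines, cas_resolve, client = client)
  status <- vapply(records, `[[`, character(1), "status")
  attr(records, "summary") <- table(factor(
    status, levels = c("resolved", "not_found", "invalid_cas", "network_error")))
  records
}

#' Import resolved CAS records into a project
#'
#' Each resolved record becomes an entry whose id is the CAS number itself,
#' with the IUPAC name stored in the `"IUPAC name"` property column.
#' Unresolved records are counted as invalid; duplicate CAS numbers follow
#' the usual first-instance rule.
#'
#' @param project a `molstash_project`.
#' @param records list of records from [cas_resolve()]/[cas_resolve_file()].
#' @return list with `$project` and `$report`.
#' @export
ms_import_cas <- function(project, records) {
  .check_project(project)
  n <- length(records)
  ids <- character(n); smiles <- character(n); props <- vector("list", n)
  for (r in seq_len(n)) {
    rec <- records[[r]]
    if (identical(rec$status, "resolved")) {
      ids[r] <- rec$cas
      smiles[r] <- rec$smiles
      props[[r]] <- c("IUPAC name" = rec$iupac_name)
    } else {
      ids[r] <- rec$cas
      smiles[r] <- ""       # forces the invalid path with a clear reason
      props[[r]] <- character(0)
    }
  }
  res <- .ingest_records(project, ids, smiles, props)
  inv <- res$report$invalid_structures
  if (nrow(inv)) {
    for (k in seq_len(nrow(inv))) {
      st <- records[[inv$row[k]]]$status
      if (!identical(st, "resolved"))
        inv$reason[k] <- paste0("unresolved (", st, ")")
    }
    res$report$invalid_structures <- inv
  }
  res
}
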