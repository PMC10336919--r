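# Table import/export: CSV (comma/semicolon/tab, RFC-4180-style quoting),
# XLSX (first sheet), and V2000 SDF. Imports report duplicates and invalid
# structures instead of failing; "only the first instance" of a repeated ID
# is kept, whether the clash is within the file or against the project.

.new_report <- function(n_read, n_imported, duplicates, invalid) {
  structure(list(n_read = n_read, n_imported = n_imported,
                 duplicates = duplicates, invalid_structures = invalid),
            class = "molstash_report")
}

#' @export
print.molstash_report <- function(x, ...) {
  cat("import report: read ", x$n_read, ", imported ", x$n_imported,
      ", duplicates ", nrow(x$duplicates), ", invalid ",
      nrow(x$invalid_structures), "\n", sep = "")
  if (nrow(x$duplicates)) {
    cat("  duplicate IDs (first instance kept):\n")
    for (k in seq_len(nrow(x$duplicates)))
      cat("    row ", x$duplicates$row[k], ": ", x$duplicates$id[k], "\n", sep = "")
  }
  if (nrow(x$invalid_structures)) {
    cat("  invalid records:\n")
    for (k in seq_len(nrow(x$invalid_structures)))
      cat("    row ", x$invalid_structures$row[k], ": ",
          x$invalid_structures$reason[k], "\n", sep = "")
  }
  invisible(x)
}

# Shared ingest core. records: list with character vectors $id, $smiles and
# list $props (named character vectors/lists per record). Returns
# list(project, report).
.ingest_records <- function(project, ids, smiles, props,
                            precomputed_canonical = NULL) {
  n <- length(ids)
  seen <- vapply(project$entries, `[[`, character(1), "id")
  dup_id <- character(0); dup_row <- integer(0)
  bad_row <- integer(0); bad_reason <- character(0)
  can <- if (is.null(precomputed_canonical)) smiles_canonical(smiles)
         else precomputed_canonical
  for (r in seq_len(n)) {
    id <- ids[r]
    if (is.na(id) || !nzchar(id)) {
      bad_row <- c(bad_row, r); bad_reason <- c(bad_reason, "missing ID")
      next
    }
    if (id %in% seen) {
      dup_id <- c(dup_id, id); dup_row <- c(dup_row, r)
      next
    }
    if (is.na(can[r])) {
      bad_row <- c(bad_row, r)
      bad_reason <- c(bad_reason, paste0("invalid SMILES: ", smiles[r]))
      next
    }
    p <- props[[r]]
    p <- p[!is.na(p) & nzchar(p)]            # empty cells import as absent
    project <- .add_schema_columns(project, names(p))
    project$entries[[length(project$entries) + 1L]] <-
      .new_entry(id, smiles[r], can[r], as.list(p))
    seen <- c(seen, id)
  }
  report <- .new_report(n, n - length(dup_row) - length(bad_row),
                        data.frame(id = dup_id, row = dup_row,
                                   stringsAsFactors = FALSE),
                        data.frame(row = bad_row, reason = bad_reason,
                                   stringsAsFactors = FALSE))
  list(project = project, report = report)
}

.sep_char <- function(sep) {
  switch(sep,
         comma = ",", semicolon = ";", tab = "\t",
         if (sep %in% c(",", ";", "\t")) sep
         else .stop_user("separator must be comma, semicolon or tab"))
}

#' Import a CSV or XLSX compound table
#'
#' Reads a table with a header row, takes the molecule id and SMILES from
#' the two mapped columns, and turns every other column into a property
#' column. Rows whose ID already exists (in the project or earlier in the
#' file) are skipped and reported; rows whose SMILES does not parse are
#' skipped and reported. Empty cells are imported as absent values.
#'
#' @param project a `molstash_project` to import into (may be non-empty).
#' @param path file to read.
#' @param format `"csv"` or `"xlsx"`.
#' @param id_field name of the ID column.
#' @param smiles_field name of the SMILES column.
#' @param separator CSV field separator: `"comma"`, `"semicolon"` or
#'   `"tab"` (or the literal character). Ignored for XLSX.
#' @return list with `$project` (the grown project) and `$report`
#'   (a `molstash_report`).
#' @export
ms_import_table <- function(project, path, format = c("csv", "xlsx"),
                            id_field = "ID", smiles_field = "SMILES",
                            separator = "comma") {
  .check_project(project)
  format <- match.arg(format)
  if (identical(id_field, smiles_field))
    .stop_user("id_field and smiles_field must differ")
  if (!file.exists(path)) .stop_io("cannot read file: ", path)
  df <- if (format == "csv") {
    tryCatch(utils::read.table(path, header = TRUE, sep = .sep_char(separator),
                               quote = "\"", colClasses = "character",
                               check.names = FALSE, stringsAsFactors = FALSE,
                               comment.char = "", na.strings = NULL),
             error = function(e) .stop_io("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  } else {
    as.data.frame(suppressMessages(
      readxl::read_xlsx(path, col_types = "text")), check.names = FALSE)
  }
  for (col in c(id_field, smiles_field))
    if (!col %in% names(df)) .stop_user("mapped column not in header: ", col)
  prop_cols <- setdiff(names(df), c(id_field, smiles_field))
  props <- lapply(seq_len(nrow(df)), function(r) {
    v <- as.character(unlist(df[r, prop_cols, drop = FALSE]))
    names(v) <- prop_cols
    v
  })
  .ingest_records(project, as.character(df[[id_field]]),
                  as.character(df[[smiles_field]]), props)
}

#' Export a project as CSV or XLSX
#'
#' Columns are ordered ID, SMILES (canonical), then the property schema.
#' CSV embedded separators/quotes are quoted RFC-4180 style.
#'
#' @inheritParams ms_import_table
#' @param path output file.
#' @return the path, invisibly.
#' @export
ms_export_table <- function(project, path, format = c("csv", "xlsx"),
                            separator = "comma") {
  .check_project(project)
  format <- match.arg(format)
  df <- as.data.frame(project)
  df[["#"]] <- NULL
  df[is.na(df)] <- ""
  if (format == "csv") {
    ok <- tryCatch({
      utils::write.table(df, path, sep = .sep_char(separator), quote = TRUE,
                         qmethod = "double", row.names = FALSE, na = "")
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) .stop_io("cannot write ", path)
  } else {
    .write_xlsx_minimal(df, path)
  }
  invisible(path)
}

# Minimal single-sheet XLSX writer (inline strings). OOXML is a zip of XML
# parts; only the parts a spreadsheet reader requires are emitted.
.write_xlsx_minimal <- function(df, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  rows <- c(list(names(df)),
            lapply(seq_len(nrow(df)), function(r) as.character(unlist(df[r, ]))))
  rowxml <- vapply(seq_along(rows), function(i) {
    cells <- paste0('<c t="inlineStr"><is><t xml:space="preserve">',
                    esc(rows[[i]]), "</t></is></c>", collapse = "")
    paste0('<row r="', i, '">', cells, "</row>")
  }, character(1))
  decl <- '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>'
  tmp <- tempfile("xlsx")
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  dir.create(file.path(tmp, "xl", "worksheets"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "_rels"), recursive = TRUE)
  writeLines(c(decl, paste0(
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    "</Types>")), file.path(tmp, "[Content_Types].xml"))
  writeLines(c(decl, paste0(
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    "</Relationships>")), file.path(tmp, "_rels", ".rels"))
  writeLines(c(decl, paste0(
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets><sheet name="Sheet1" sheetId="1" r:id="rId1"/></sheets></workbook>')),
    file.path(tmp, "xl", "workbook.xml"))
  writeLines(c(decl, paste0(
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>',
    "</Relationships>")), file.path(tmp, "xl", "_rels", "workbook.xml.rels"))
  writeLines(c(decl, paste0(
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main"><sheetData>',
    paste(rowxml, collapse = ""), "</sheetData></worksheet>")),
    file.path(tmp, "xl", "worksheets", "sheet1.xml"))
  target <- if (grepl("^(/|[A-Za-z]:)", path)) path
            else file.path(getwd(), path)
  owd <- setwd(tmp)
  on.exit(setwd(owd), add = TRUE, after = FALSE)
  zip::zip(target,
           list.files(recursive = TRUE, all.files = TRUE, include.dirs = FALSE))
  invisible(path)
}

# ---- SDF ------------------------------------------------------------------

#' Import a V2000 SDF file
#'
#' The structure is taken from each record's connection table, the entry id
#' from the molecule title line or a named data field, and every other data
#' field becomes a property. Duplicate and invalid records are skipped and
#' reported, as in [ms_import_table()].
#'
#' @param project a `molstash_project`.
#' @param path SDF file.
#' @param id_source `"title"` to use the molecule title line, or the name of
#'   an SDF data field.
#' @return list with `$project` and `$report`.
#' @export
ms_import_sdf <- function(project, path, id_source = "title") {
  .check_project(project)
  if (!file.exists(path)) .stop_io("cannot read file: ", path)
  lines <- tryCatch(readLines(path, warn = FALSE, encoding = "UTF-8"),
                    error = function(e) .stop_io("cannot read file: ", path))
  records <- .split_sdf_records(lines)
  n <- length(records)
  ids <- rep(NA_character_, n)
  smiles <- rep(NA_character_, n)
  props <- vector("list", n)
  malformed <- logical(n)
  for (r in seq_len(n)) {
    rec <- records[[r]]
    # structure: hand the raw (unreformatted) connection table to OpenBabel
    smiles[r] <- .sdf_text_to_smiles(rec)
    malformed[r] <- is.na(smiles[r])
    fields <- .sdf_data_fields(rec)
    if (identical(id_source, "title")) {
      ids[r] <- trimws(rec[1])
    } else if (id_source %in% names(fields)) {
      ids[r] <- fields[[id_source]]
      fields <- fields[setdiff(names(fields), id_source)]
    }  # else leave NA -> reported as "missing ID"
    if (!is.na(ids[r]) && !nzchar(ids[r])) ids[r] <- NA_character_
    props[[r]] <- fields
  }
  res <- .ingest_records(project, ifelse(is.na(ids), "", ids),
                         ifelse(is.na(smiles), "", smiles), props,
                         precomputed_canonical = smiles)
  inv <- res$report$invalid_structures
  if (nrow(inv)) {
    inv$reason[inv$row %in% which(malformed)] <- "malformed record"
    res$report$invalid_structures <- inv
  }
  res
}

# split SDF text into records at the "$$$$" terminator lines
.split_sdf_records <- function(lines) {
  ends <- which(trimws(lines) == "$$$$")
  records <- list()
  start <- 1L
  for (e in ends) {
    if (e > start) records[[length(records) + 1L]] <- lines[start:(e - 1L)]
    start <- e + 1L
  }
  # trailing record without terminator
  if (start <= length(lines) && any(nzchar(trimws(lines[start:length(lines)]))))
    records[[length(records) + 1L]] <- lines[start:length(lines)]
  records
}

.sdf_text_to_smiles <- function(record_lines) {
  txt <- paste(c(record_lines, "$$$$", ""), collapse = "\n")
  res <- tryCatch(convertFormat("SDF", "CAN", txt), error = function(e) "")
  line <- strsplit(res, "\n", fixed = TRUE)[[1]]
  line <- line[nzchar(line)][1]
  if (is.na(line)) return(NA_character_)
  strsplit(line, "\t", fixed = TRUE)[[1]][1]
}

# "> <name>" data blocks: value lines up to the next blank line
.sdf_data_fields <- function(record_lines) {
  fields <- character(0)
  i <- 1L
  n <- length(record_lines)
  while (i <= n) {
    m <- regmatches(record_lines[i],
                    regexec("^>\\s*<(.+)>", record_lines[i]))[[1]]
    if (length(m) == 2L) {
      j <- i + 1L
      vals <- character(0)
      while (j <= n && nzchar(trimws(record_lines[j]))) {
        vals <- c(vals, record_lines[j])
        j <- j + 1L
      }
      fields[[m[2]]] <- paste(vals, collapse = "\n")
      i <- j
    }
    i <- i + 1L
  }
  fields
}

#' Export a project as a V2000 SDF file
#'
#' One record per entry: the id on the molecule title line, the connection
#' table generated from the canonical SMILES, and one data field per stored
#' property. Entries whose structure cannot be rendered are reported and the
#' rest are written.
#'
#' @param project a `molstash_project`.
#' @param path output file.
#' @return invisibly, a character vector of entry ids that could not be
#'   rendered (empty on full success).
#' @export
ms_export_sdf <- function(project, path) {
  .check_project(project)
  if (length(project$entries) == 0L) {
    writeLines(character(0), path)
    return(invisible(character(0)))
  }
  ids <- ms_ids(project)
  smiles <- vapply(project$entries, `[[`, character(1), "smiles_canonical")
  renderable <- !is.na(smiles_canonical(smiles))
  failed <- ids[!renderable]
  if (length(failed))
    warning("entries not rendered to SDF: ", paste(failed, collapse = ", "))
  keep <- which(renderable)
  if (!length(keep)) { writeLines(character(0), path); return(invisible(failed)) }
  # OpenBabel writes the connection tables; its raw text is used verbatim
  inp <- paste0(paste(smiles[keep], paste0("t", seq_along(keep))), "\n",
                collapse = "")
  txt <- convertFormat("SMI", "SDF", inp)
  records <- .split_sdf_records(strsplit(txt, "\n", fixed = TRUE)[[1]])
  if (length(records) != length(keep))
    .stop_io("SDF rendering dropped molecules")
  out <- character(0)
  for (j in seq_along(keep)) {
    rec <- records[[j]]
    rec[1] <- ids[keep[j]]           # our id on the title line
    p <- project$entries[[keep[j]]]$properties
    dataline <- unlist(lapply(names(p), function(nm)
      c(paste0(">  <", nm, ">"), as.character(p[[nm]]), "")))
    out <- c(out, rec, dataline, "$$$$")
  }
  ok <- tryCatch({ writeLines(out, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) .stop_io("cannot write ", path)
  invisible(failed)
}

# ---- grid report ----------------------------------------------------------

#' Write a self-contained HTML grid view of a project
#'
#' One cell per molecule showing its id and structure (as SMILES text) on
#' the entry's highlight colour.
#'
#' @param project a `molstash_project`.
#' @param path output HTML file.
#' @return the path, invisibly.
#' @export
ms_grid_report <- function(project, path) {
  .check_project(project)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  colors <- c(none = "#ffffff", green = "#c8e6c9", yellow = "#fff9c4",
              red = "#ffcdd2")
  cells <- vapply(project$entries, function(e) {
    paste0('<div class="cell" data-highlight="', e$highlight,
           '" style="background:', colors[[e$highlight]], '">',
           "<b>", esc(e$id), "</b><br/><code>", esc(e$smiles_canonical),
           "</code></div>")
  }, character(1))
  html <- c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'/>",
            paste0("<title>", esc(project$name), "</title>"),
            "<style>.grid{display:flex;flex-wrap:wrap}",
            ".cell{border:1px solid #999;margin:4px;padding:8px;width:220px;",
            "font-family:sans-serif;word-wrap:break-word}</style></head>",
            paste0("<body><h1>", esc(project$name), "</h1><div class='grid'>"),
            cells, "</div></body></html>")
  ok <- tryCatch({ writeLines(html, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) .stop_io("cannot write ", path)
  invisible(path)
}
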