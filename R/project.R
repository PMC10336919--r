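# Project store: in-memory model of a compound library plus its folder-based
# persistence. A project folder contains
#   project.json       the table: name, property schema, ordered entries
#   attachments/<id>/  per-molecule attached files
#   lock.json          single-writer lock record (owner, timestamp, mode)
# JSON is UTF-8; timestamps ISO-8601. The layout is plain text so a folder
# synced through Google Drive / OneDrive style services diffs cleanly.

HIGHLIGHT_LEVELS <- c("none", "green", "yellow", "red")
RESERVED_COLUMNS <- c("ID", "SMILES", "#")
LOCK_TTL_HOURS_DEFAULT <- 24

.new_entry <- function(id, smiles_input, smiles_canonical,
                       properties = list(), highlight = "none",
                       attachments = character()) {
  list(id = id, smiles_input = smiles_input,
       smiles_canonical = smiles_canonical,
       properties = properties, highlight = highlight,
       attachments = attachments)
}

.new_project <- function(name, entries = list(), schema = character(),
                         path = NULL, mode = "read_write",
                         identity = ms_identity()) {
  structure(list(name = name, entries = entries, schema = schema,
                 path = path, mode = mode, identity = identity,
                 lock_owner = NULL, computed = character()),
            class = "molstash_project")
}

#' Default user identity for lock records
#'
#' `user@host`, used to mark lock ownership in shared project folders.
#' @return length-one character.
#' @export
ms_identity <- function() {
  user <- Sys.info()[["user"]]
  host <- Sys.info()[["nodename"]]
  paste0(user, "@", host)
}

.stop_user <- function(...) stop(errorCondition(paste0(...),
                                                class = c("molstash_error", "error")))
.stop_io <- function(...) stop(errorCondition(paste0(...),
                                              class = c("molstash_io_error", "molstash_error", "error")))

.check_project <- function(project) {
  if (!inherits(project, "molstash_project"))
    .stop_user("not a molstash project object")
  project
}

.entry_index <- function(project, id) {
  ids <- vapply(project$entries, `[[`, character(1), "id")
  match(id, ids)
}

#' Create a new project folder
#'
#' Initialises an empty project at `path`: writes `project.json`, an empty
#' `attachments/` directory and a `lock.json` owned by the caller in
#' read-write mode.
#'
#' @param path folder to create; must not already contain a project.
#' @param name project display name.
#' @param identity lock owner identity string, default [ms_identity()].
#' @return a `molstash_project` in read-write mode.
#' @export
ms_create <- function(path, name, identity = ms_identity()) {
  if (file.exists(file.path(path, "project.json")))
    .stop_user("path already contains a project: ", path)
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok) .stop_io("cannot create project folder: ", path)
  dir.create(file.path(path, "attachments"), showWarnings = FALSE)
  project <- .new_project(name, path = normalizePath(path), identity = identity)
  .write_lock(project$path, identity)
  ms_save(project)
  project
}

#' Open an existing project folder
#'
#' The first opener of a shared project folder receives read-write access and
#' records itself in `lock.json`; while that lock is live every later opener
#' is dropped to read-only and told who holds the lock (available as
#' `$lock_owner` on the returned project, alongside a message).
#'
#' @param path project folder.
#' @param identity caller identity, default [ms_identity()].
#' @param read_only force read-only mode even if the lock is free.
#' @param steal break a foreign lock regardless of age. The TTL rule already
#'   expires locks whose owner is likely gone; `steal` is the explicit
#'   override for a known-dead owner.
#' @param lock_ttl_hours age in hours after which a lock is considered stale
#'   and may be taken over.
#' @return a `molstash_project` whose `$mode` is `"read_write"` or
#'   `"read_only"`.
#' @export
ms_open <- function(path, identity = ms_identity(), read_only = FALSE,
                    steal = FALSE, lock_ttl_hours = LOCK_TTL_HOURS_DEFAULT) {
  table_file <- file.path(path, "project.json")
  if (!file.exists(table_file))
    .stop_io("not a project folder (missing project.json): ", path)
  raw <- tryCatch(jsonlite::fromJSON(table_file, simplifyVector = FALSE),
                  error = function(e) NULL)
  if (is.null(raw) || is.null(raw$name) || is.null(raw$entries))
    .stop_io("corrupt project table: ", table_file)
  project <- .project_from_json(raw)
  project$path <- normalizePath(path)
  project$identity <- identity

  lock <- .read_lock(project$path)
  live <- !is.null(lock) && !.lock_stale(lock, lock_ttl_hours)
  if (read_only) {
    project$mode <- "read_only"
    project$lock_owner <- if (live) lock$owner else NULL
  } else if (live && !identical(lock$owner, identity) && !steal) {
    project$mode <- "read_only"
    project$lock_owner <- lock$owner
    message("project is open in Read/Write mode by ", lock$owner,
            "; opening in Read-only mode")
  } else {
    .write_lock(project$path, identity)
    project$mode <- "read_write"
  }
  project
}

#' Release a project's read-write lock
#'
#' Removes `lock.json` if the caller owns it, letting the next opener take
#' read-write mode.
#' @param project a project opened in read-write mode.
#' @return the project, invisibly, switched to read-only.
#' @export
ms_release <- function(project) {
  .check_project(project)
  if (!is.null(project$path)) {
    lock <- .read_lock(project$path)
    if (!is.null(lock) && identical(lock$owner, project$identity))
      unlink(file.path(project$path, "lock.json"))
  }
  project$mode <- "read_only"
  invisible(project)
}

.write_lock <- function(path, identity) {
  jsonlite::write_json(
    list(owner = identity,
         acquired_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         mode = "read_write"),
    file.path(path, "lock.json"), auto_unbox = TRUE)
}

.read_lock <- function(path) {
  f <- file.path(path, "lock.json")
  if (!file.exists(f)) return(NULL)
  tryCatch(jsonlite::fromJSON(f, simplifyVector = TRUE),
           error = function(e) NULL)
}

.lock_stale <- function(lock, ttl_hours) {
  ts <- tryCatch(as.POSIXct(lock$acquired_at, format = "%Y-%m-%dT%H:%M:%S%z"),
                 error = function(e) NA)
  if (is.na(ts)) return(TRUE)
  difftime(Sys.time(), ts, units = "hours") > ttl_hours
}

#' Save a project to its folder
#'
#' Writes `project.json` so that the folder state equals the in-memory state;
#' [ms_open()] of the folder reproduces the project field for field. Requires
#' read-write mode.
#' @param project a `molstash_project` with a path.
#' @return the project, invisibly.
#' @export
ms_save <- function(project) {
  .check_project(project)
  if (is.null(project$path)) .stop_user("project has no folder; use ms_create()")
  if (!identical(project$mode, "read_write"))
    .stop_user("project is open read-only; cannot save")
  json <- .project_to_json(project)
  tmp <- file.path(project$path, "project.json.tmp")
  ok <- tryCatch({ writeLines(json, tmp, useBytes = TRUE); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) .stop_io("cannot write project table under ", project$path)
  file.rename(tmp, file.path(project$path, "project.json"))
  invisible(project)
}

.project_to_json <- function(project) {
  entries <- lapply(project$entries, function(e) {
    props <- e$properties
    if (length(props) == 0L) props <- structure(list(), names = character())
    list(id = jsonlite::unbox(e$id),
         smiles_input = jsonlite::unbox(e$smiles_input),
         smiles_canonical = jsonlite::unbox(e$smiles_canonical),
         properties = lapply(props, jsonlite::unbox),
         highlight = jsonlite::unbox(e$highlight),
         attachments = as.character(e$attachments))
  })
  jsonlite::toJSON(list(format = jsonlite::unbox("molstash-project"),
                        version = jsonlite::unbox(1L),
                        name = jsonlite::unbox(project$name),
                        schema = as.character(project$schema),
                        computed = as.character(project$computed),
                        entries = entries),
                   pretty = TRUE)
}

.project_from_json <- function(raw) {
  entries <- lapply(raw$entries, function(e) {
    props <- e$properties
    .new_entry(id = as.character(e$id),
               smiles_input = as.character(e$smiles_input),
               smiles_canonical = as.character(e$smiles_canonical),
               properties = lapply(props, as.character),
               highlight = as.character(e$highlight),
               attachments = as.character(unlist(e$attachments)))
  })
  p <- .new_project(name = as.character(raw$name), entries = entries,
                    schema = as.character(unlist(raw$schema)))
  p$computed <- as.character(unlist(raw$computed))
  p
}

.add_schema_columns <- function(project, names) {
  new <- setdiff(names, project$schema)
  bad <- intersect(new, RESERVED_COLUMNS)
  if (length(bad)) .stop_user("reserved column name: ", paste(bad, collapse = ", "))
  if (any(!nzchar(new))) .stop_user("empty property name")
  project$schema <- c(project$schema, new)
  project
}

#' Add one molecule to a project
#'
#' Appends an entry with the given id and SMILES; unseen property names are
#' appended to the project schema and the canonical SMILES is computed.
#' Duplicate ids and unparsable SMILES are refused.
#'
#' @param project a `molstash_project`.
#' @param id unique, non-empty entry id.
#' @param smiles SMILES string, stored verbatim alongside its canonical form.
#' @param properties named list/character of property values (stored as
#'   strings).
#' @return the modified project.
#' @export
ms_add_molecule <- function(project, id, smiles, properties = list()) {
  .check_project(project)
  id <- as.character(id)
  if (length(id) != 1L || is.na(id) || !nzchar(id)) .stop_user("id must be a non-empty string")
  if (!is.na(.entry_index(project, id))) .stop_user("duplicate id: ", id)
  can <- smiles_canonical(smiles)
  if (is.na(can)) .stop_user("invalid SMILES: ", smiles)
  props <- lapply(as.list(properties), as.character)
  if (length(props) && (is.null(names(props)) || any(!nzchar(names(props)))))
    .stop_user("properties must be named")
  project <- .add_schema_columns(project, names(props))
  project$entries[[length(project$entries) + 1L]] <-
    .new_entry(id, smiles, can, props)
  project
}

#' Set a property value on an entry
#'
#' Stores `value` as a string; creates the schema column if it is new.
#' Setting an existing property overwrites it (edit-in-place semantics).
#' @param project a `molstash_project`.
#' @param id entry id.
#' @param name property column name.
#' @param value value, coerced to a string.
#' @return the modified project.
#' @export
ms_set_property <- function(project, id, name, value) {
  .check_project(project)
  i <- .entry_index(project, id)
  if (is.na(i)) .stop_user("unknown id: ", id)
  project <- .add_schema_columns(project, name)
  project$entries[[i]]$properties[[name]] <- as.character(value)
  project
}

#' Set or remove an entry's highlight colour
#'
#' @param project a `molstash_project`.
#' @param id entry id.
#' @param color one of `"none"`, `"green"`, `"yellow"`, `"red"`; `"none"`
#'   removes highlighting.
#' @return the modified project.
#' @export
ms_set_highlight <- function(project, id, color) {
  .check_project(project)
  i <- .entry_index(project, id)
  if (is.na(i)) .stop_user("unknown id: ", id)
  if (!color %in% HIGHLIGHT_LEVELS)
    .stop_user("unknown highlight color: ", color,
               " (use ", paste(HIGHLIGHT_LEVELS, collapse = "/"), ")")
  project$entries[[i]]$highlight <- color
  project
}

#' Sort project entries by a column
#'
#' Returns a re-ordered copy of the project. With `numeric = TRUE` values are
#' parsed as decimal numbers; entries whose value is missing or unparsable
#' are placed last, keeping their original relative order. The sort is
#' stable.
#'
#' @param project a `molstash_project`.
#' @param column `"ID"`, `"SMILES"`, or a schema column name.
#' @param direction `"asc"` or `"desc"`.
#' @param numeric parse values as numbers instead of comparing as strings.
#' @return the re-ordered project.
#' @export
ms_sort <- function(project, column, direction = c("asc", "desc"),
                    numeric = FALSE) {
  .check_project(project)
  direction <- match.arg(direction)
  vals <- .column_values(project, column)
  if (numeric) {
    key <- suppressWarnings(as.numeric(vals))
  } else {
    key <- vals
  }
  missing <- is.na(key)
  if (direction == "desc") {
    ord <- order(missing, -xtfrm(key), seq_along(key), method = "radix")
  } else {
    ord <- order(missing, xtfrm(key), seq_along(key), method = "radix")
  }
  project$entries <- project$entries[ord]
  project
}

.column_values <- function(project, column) {
  if (identical(column, "ID"))
    return(vapply(project$entries, `[[`, character(1), "id"))
  if (identical(column, "SMILES"))
    return(vapply(project$entries, `[[`, character(1), "smiles_canonical"))
  if (!column %in% project$schema) .stop_user("unknown column: ", column)
  vapply(project$entries, function(e) {
    v <- e$properties[[column]]
    if (is.null(v)) NA_character_ else v
  }, character(1))
}

# ---- attachments (the "Chemical Notebook") -------------------------------

.attach_dir <- function(project, id) file.path(project$path, "attachments", id)

#' Attach a file to a molecule entry
#'
#' Copies the file into `attachments/<id>/` inside the project folder and
#' records the name on the entry. Name collisions get a `_1`, `_2`, ...
#' suffix so existing attachments are never overwritten.
#' @param project a saved `molstash_project` (read-write).
#' @param id entry id.
#' @param source_path readable file to attach.
#' @return the modified project.
#' @export
ms_attach <- function(project, id, source_path) {
  .check_project(project)
  if (is.null(project$path)) .stop_user("project has no folder")
  if (!identical(project$mode, "read_write")) .stop_user("project is read-only")
  i <- .entry_index(project, id)
  if (is.na(i)) .stop_user("unknown id: ", id)
  if (!file.exists(source_path)) .stop_io("cannot read attachment source: ", source_path)
  dir.create(.attach_dir(project, id), recursive = TRUE, showWarnings = FALSE)
  name <- basename(source_path)
  existing <- project$entries[[i]]$attachments
  if (name %in% existing) {
    stem <- tools::file_path_sans_ext(name)
    ext <- tools::file_ext(name)
    k <- 1L
    repeat {
      cand <- if (nzchar(ext)) paste0(stem, "_", k, ".", ext) else paste0(stem, "_", k)
      if (!cand %in% existing) { name <- cand; break }
      k <- k + 1L
    }
  }
  if (!file.copy(source_path, file.path(.attach_dir(project, id), name)))
    .stop_io("failed to copy attachment into project")
  project$entries[[i]]$attachments <- c(existing, name)
  project
}

#' List a molecule's attachments
#' @param project a `molstash_project`.
#' @param id entry id.
#' @return character vector of attachment file names.
#' @export
ms_attachments <- function(project, id) {
  .check_project(project)
  i <- .entry_index(project, id)
  if (is.na(i)) .stop_user("unknown id: ", id)
  project$entries[[i]]$attachments
}

#' Path of a stored attachment (for opening it)
#' @param project a `molstash_project`.
#' @param id entry id.
#' @param name attachment name as returned by [ms_attachments()].
#' @return absolute file path.
#' @export
ms_attachment_path <- function(project, id, name) {
  .check_project(project)
  if (!name %in% ms_attachments(project, id))
    .stop_user("no attachment '", name, "' on entry ", id)
  file.path(.attach_dir(project, id), name)
}

#' Delete an attachment
#' @param project a read-write `molstash_project`.
#' @param id entry id.
#' @param name attachment name.
#' @return the modified project.
#' @export
ms_delete_attachment <- function(project, id, name) {
  .check_project(project)
  if (!identical(project$mode, "read_write")) .stop_user("project is read-only")
  i <- .entry_index(project, id)
  if (is.na(i)) .stop_user("unknown id: ", id)
  if (!name %in% project$entries[[i]]$attachments)
    .stop_user("no attachment '", name, "' on entry ", id)
  unlink(file.path(.attach_dir(project, id), name))
  project$entries[[i]]$attachments <-
    setdiff(project$entries[[i]]$attachments, name)
  project
}

#' Does an entry carry attachments? (the "#" paperclip flag)
#' @param project a `molstash_project`.
#' @param id entry id.
#' @return logical.
#' @export
ms_has_attachments <- function(project, id) length(ms_attachments(project, id)) > 0L

# ---- views ----------------------------------------------------------------

#' Project table as a data.frame
#'
#' Columns `ID`, `SMILES` (canonical), `#` (attachment flag), then the
#' property schema in order; missing property cells are `NA`.
#' @param x a `molstash_project`.
#' @param ... unused.
#' @return data.frame with one row per entry.
#' @export
as.data.frame.molstash_project <- function(x, ...) {
  n <- length(x$entries)
  df <- data.frame(ID = vapply(x$entries, `[[`, character(1), "id"),
                   SMILES = vapply(x$entries, `[[`, character(1), "smiles_canonical"),
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (n == 0L) df <- data.frame(ID = character(), SMILES = character(),
                                check.names = FALSE)
  df[["#"]] <- vapply(x$entries, function(e) length(e$attachments) > 0L, logical(1))
  for (col in x$schema)
    df[[col]] <- vapply(x$entries, function(e) {
      v <- e$properties[[col]]
      if (is.null(v)) NA_character_ else v
    }, character(1))
  df
}

#' @export
print.molstash_project <- function(x, ...) {
  cat("molstash project '", x$name, "' (", length(x$entries), " molecules, ",
      length(x$schema), " property columns, mode ", x$mode, ")\n", sep = "")
  if (!is.null(x$path)) cat("  folder: ", x$path, "\n", sep = "")
  if (!is.null(x$lock_owner))
    cat("  read/write lock held by ", x$lock_owner, "\n", sep = "")
  if (length(x$schema))
    cat("  columns: ID, SMILES, #, ", paste(x$schema, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.molstash_project <- function(object, ...) {
  df <- as.data.frame(object)
  hl <- vapply(object$entries, `[[`, character(1), "highlight")
  cat("Project:   ", object$name, "\n")
  cat("Molecules: ", nrow(df), "\n")
  cat("Columns:   ", paste(c("ID", "SMILES", "#", object$schema), collapse = ", "), "\n")
  if (length(hl)) {
    tab <- table(factor(hl, levels = HIGHLIGHT_LEVELS))
    cat("Highlights:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(df)
}

#' Retrieve one entry by id
#' @param project a `molstash_project`.
#' @param id entry id.
#' @return the entry as a list (id, smiles_input, smiles_canonical,
#'   properties, highlight, attachments).
#' @export
ms_entry <- function(project, id) {
  .check_project(project)
  i <- .entry_index(project, id)
  if (is.na(i)) .stop_user("unknown id: ", id)
  project$entries[[i]]
}

#' Entry ids in table order
#' @param project a `molstash_project`.
#' @return character vector.
#' @export
ms_ids <- function(project) {
  .check_project(project)
  vapply(project$entries, `[[`, character(1), "id")
}
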