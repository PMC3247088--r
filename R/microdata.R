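#' @name microdata-module
#' @title Person-level microdata with attribute roles
#'
#' @description
#' A `microdata` object is an ordered table of person-level records together
#' with an [attribute_schema()] declaring, for every column, its disclosure
#' role -- `identifier` (names, phone numbers), `quasi_identifier`
#' (gender, location, birthdate: attributes that identify in combination),
#' `sensitive` (e.g. diagnoses) or `other` -- and its value kind
#' (`text`, `date`, `integer`, `category`). Tables are read and written as
#' RFC 4180 CSV; a missing value is an empty field; dates are ISO-8601 text.
NULL

ATTR_ROLES <- c("identifier", "quasi_identifier", "sensitive", "other")
ATTR_KINDS <- c("text", "date", "integer", "category")

#' Declare an attribute-role schema
#'
#' @param ... one named argument per attribute: a character vector
#'   `c(role, kind)` with role one of `identifier`, `quasi_identifier`,
#'   `sensitive`, `other` and kind one of `text`, `date`, `integer`,
#'   `category`.
#' @return An `attribute_schema` object (a data frame with columns
#'   `name`, `role`, `kind`).
#' @examples
#' attribute_schema(
#'   first  = c("identifier", "text"),
#'   gender = c("quasi_identifier", "category")
#' )
#' @export
attribute_schema <- function(...) {
  entries <- list(...)
  if (length(entries) == 0L)
    stop_privrisk("a schema needs at least one attribute")
  nm <- names(entries)
  if (is.null(nm) || any(!nzchar(nm)))
    stop_privrisk("every schema entry must be named")
  if (anyDuplicated(nm))
    stop_privrisk(sprintf("duplicate attribute name(s): %s",
                          paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  role <- character(length(entries))
  kind <- character(length(entries))
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    if (!is.character(e) || length(e) != 2L)
      stop_privrisk(sprintf("entry '%s' must be c(role, kind)", nm[i]))
    if (!e[1] %in% ATTR_ROLES)
      stop_privrisk(sprintf("unknown role '%s' for attribute '%s'", e[1], nm[i]))
    if (!e[2] %in% ATTR_KINDS)
      stop_privrisk(sprintf("unknown value kind '%s' for attribute '%s'", e[2], nm[i]))
    role[i] <- e[1]; kind[i] <- e[2]
  }
  structure(data.frame(name = nm, role = role, kind = kind,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("attribute_schema", "data.frame"))
}

#' Read an attribute schema from a JSON config file
#'
#' The file maps column name to `{"role": ..., "kind": ...}`.
#'
#' @param path path to a JSON file.
#' @return An [attribute_schema()].
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop_privrisk(sprintf("no such schema file: %s", path))
  raw <- jsonlite::read_json(path)
  args <- lapply(raw, function(e) c(e$role %||% "", e$kind %||% ""))
  names(args) <- names(raw)
  do.call(attribute_schema, args)
}

#' Write an attribute schema to a JSON config file
#' @param schema an [attribute_schema()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "attribute_schema"))
  obj <- lapply(seq_len(nrow(schema)), function(i)
    list(role = schema$role[i], kind = schema$kind[i]))
  names(obj) <- schema$name
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_microdata <- function(schema, record_id, data) {
  structure(list(schema = schema, record_id = record_id, data = data),
            class = "microdata")
}

#' Construct a microdata object from a data frame
#'
#' @param df data frame whose columns cover the schema attributes.
#' @param schema an [attribute_schema()].
#' @param record_id optional character vector of unique ids; default
#'   `"r0" ... "r{n-1}"` by row order.
#' @return A `microdata` object.
#' @export
microdata <- function(df, schema, record_id = NULL) {
  stopifnot(inherits(schema, "attribute_schema"))
  missing_cols <- setdiff(schema$name, names(df))
  if (length(missing_cols))
    stop_privrisk(sprintf("missing declared column(s): %s",
                          paste(missing_cols, collapse = ", ")))
  n <- nrow(df)
  if (is.null(record_id)) {
    record_id <- sprintf("r%d", seq_len(n) - 1L)
  } else {
    record_id <- as.character(record_id)
    if (length(record_id) != n || anyDuplicated(record_id) || anyNA(record_id))
      stop_privrisk("record_id must be unique, non-missing, one per row")
  }
  data <- df[, schema$name, drop = FALSE]
  rownames(data) <- NULL
  new_microdata(schema, record_id, data)
}

parse_column <- function(x, name, kind) {
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  ok <- !is.na(x)
  if (kind == "integer") {
    bad <- ok & !grepl("^[+-]?[0-9]+$", x)
    if (any(bad))
      stop_privrisk(sprintf("column '%s': unparseable integer at row %d ('%s')",
                            name, which(bad)[1], x[which(bad)[1]]))
    return(as.integer(x))
  }
  if (kind == "date") {
    bad <- ok & (!grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", x) |
                   is.na(as.Date(x, format = "%Y-%m-%d")))
    if (any(bad))
      stop_privrisk(sprintf("column '%s': unparseable ISO date at row %d ('%s')",
                            name, which(bad)[1], x[which(bad)[1]]))
    return(x)
  }
  x
}

#' Read a CSV table as microdata
#'
#' One record per data row, in file order. Record ids come from `id_col`
#' when given (the column is then not a schema attribute) and otherwise are
#' assigned deterministically from row order as `"r0", "r1", ...`.
#'
#' @param path CSV file (RFC 4180, UTF-8, header row required).
#' @param schema an [attribute_schema()]; every declared attribute must be a
#'   column of the file.
#' @param id_col optional name of an id column in the file.
#' @return A `microdata` object.
#' @export
read_table <- function(path, schema, id_col = NULL) {
  stopifnot(inherits(schema, "attribute_schema"))
  if (!file.exists(path)) stop_privrisk(sprintf("no such file: %s", path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character(0), fileEncoding = "UTF-8")
  need <- c(schema$name, id_col)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop_privrisk(sprintf("missing declared column(s): %s",
                          paste(missing_cols, collapse = ", ")))
  n <- nrow(raw)
  cols <- lapply(seq_len(nrow(schema)), function(i)
    parse_column(raw[[schema$name[i]]], schema$name[i], schema$kind[i]))
  names(cols) <- schema$name
  data <- as.data.frame(cols, optional = TRUE, stringsAsFactors = FALSE)
  if (n == 0L)
    data <- as.data.frame(lapply(cols, function(c) c[0]), optional = TRUE)
  record_id <- if (is.null(id_col)) NULL else raw[[id_col]]
  microdata(data, schema, record_id = record_id)
}

#' Write microdata to CSV
#'
#' Writes the `record_id` as the first column, so that
#' `read_table(path, schema, id_col = "record_id")` round-trips values,
#' order, ids and missing markers exactly.
#'
#' @param md a `microdata` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(md, path) {
  stopifnot(inherits(md, "microdata"))
  df <- cbind(data.frame(record_id = md$record_id, stringsAsFactors = FALSE),
              md$data)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8", quote = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_privrisk(sprintf("cannot write '%s': %s", path, conditionMessage(ok)))
  invisible(path)
}

#' Project records onto a subset of attributes
#'
#' @param md a `microdata` object.
#' @param attrs character vector of attribute names (may be empty).
#' @return A data frame with one row per record, in record order, one column
#'   per requested attribute; missing values are `NA`.
#' @export
project <- function(md, attrs) {
  stopifnot(inherits(md, "microdata"))
  attrs <- as.character(attrs)
  unknown <- setdiff(attrs, md$schema$name)
  if (length(unknown))
    stop_privrisk(sprintf("unknown attribute(s): %s", paste(unknown, collapse = ", ")))
  out <- md$data[, attrs, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Number of records in a microdata object
#' @param md a `microdata` object.
#' @return Integer record count.
#' @export
n_records <- function(md) {
  stopifnot(inherits(md, "microdata"))
  nrow(md$data)
}

#' Extract one attribute's values in record order
#' @param md a `microdata` object.
#' @param field attribute name.
#' @return Vector of values (character or integer), `NA` for missing.
#' @export
md_values <- function(md, field) {
  stopifnot(inherits(md, "microdata"))
  if (length(field) != 1L || !field %in% md$schema$name)
    stop_privrisk(sprintf("unknown attribute: %s", paste(field, collapse = ", ")))
  md$data[[field]]
}

#' Subset a microdata object by record position
#' @param md a `microdata` object.
#' @param idx integer positions (or logical mask) of records to keep.
#' @return A `microdata` object with the selected records, original order
#'   preserved for sorted `idx`.
#' @export
md_subset <- function(md, idx) {
  stopifnot(inherits(md, "microdata"))
  new_microdata(md$schema, md$record_id[idx],
                { d <- md$data[idx, , drop = FALSE]; rownames(d) <- NULL; d })
}

#' @export
print.microdata <- function(x, ...) {
  cat(sprintf("<microdata: %d records, %d attributes>\n",
              nrow(x$data), nrow(x$schema)))
  roles <- split(x$schema$name, x$schema$role)
  for (r in names(roles))
    cat(sprintf("  %s: %s\n", r, paste(roles[[r]], collapse = ", ")))
  invisible(x)
}

#' @export
print.attribute_schema <- function(x, ...) {
  cat(sprintf("<attribute_schema: %d attributes>\n", nrow(x)))
  print.data.frame(x)
  invisible(x)
}
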