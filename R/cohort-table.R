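#' Cohort tables and column schemas
#'
#' A cohort table is an ordinary tibble of one row per transplant recipient,
#' accompanied by a *schema*: a tag for every column classifying it as
#' `"identifier"`, `"preop"` (pre-operative covariate), `"postop"`
#' (post-operative measurement), `"date"`, or `"outcome"`. The schema drives
#' cleaning (identifier and post-operative columns are removed before
#' modelling) and label derivation (date columns). It travels with the table
#' as the `"schema"` attribute and is written alongside CSV exports as a
#' plain-text sidecar file of `column=tag` lines.
#'
#' @param data A data frame of patient records.
#' @param schema Named character vector mapping every column of `data` to one
#'   of the five tags.
#' @return `cohort_table()` returns `data` as a tibble with the schema
#'   attached; `cohort_schema()` returns the named tag vector.
#' @examples
#' tbl <- cohort_table(
#'   data.frame(id = 1:3, age = c(40, 55, 61), graft_survival = c(1, 0, 1)),
#'   c(id = "identifier", age = "preop", graft_survival = "outcome")
#' )
#' cohort_schema(tbl)
#' @export
cohort_table <- function(data, schema) {
  data <- as_tibble(data)
  validate_schema(data, schema)
  attr(data, "schema") <- schema
  data
}

#' @rdname cohort_table
#' @export
cohort_schema <- function(data) {
  sc <- attr(data, "schema")
  if (is.null(sc)) {
    abort("No schema attached; build the table with `cohort_table()` or `read_cohort()`.",
          class = "graftann_data_error")
  }
  sc
}

schema_tags <- c("identifier", "preop", "postop", "date", "outcome")

validate_schema <- function(data, schema) {
  if (is.null(names(schema)) || !all(nzchar(names(schema)))) {
    abort("Schema must be a named character vector.", class = "graftann_data_error")
  }
  missing <- setdiff(names(data), names(schema))
  if (length(missing)) {
    abort(paste0("Schema does not cover columns: ", toString(missing)),
          class = "graftann_data_error")
  }
  bad <- setdiff(unique(schema), schema_tags)
  if (length(bad)) {
    abort(paste0("Unknown schema tags: ", toString(bad)),
          class = "graftann_data_error")
  }
  if (sum(schema[names(data)] == "outcome") > 1L) {
    abort("Schema must tag at most one outcome column.",
          class = "graftann_data_error")
  }
  invisible(TRUE)
}

# Column names carrying a given tag, in table order.
cols_with_tag <- function(data, tag) {
  sc <- cohort_schema(data)
  names(data)[sc[names(data)] %in% tag]
}

# Subset columns while preserving the schema attribute (dplyr/tibble
# subsetting drops bespoke attributes).
keep_cols <- function(data, cols) {
  sc <- cohort_schema(data)
  out <- data[, cols, drop = FALSE]
  attr(out, "schema") <- sc[cols]
  out
}

keep_rows <- function(data, idx) {
  sc <- cohort_schema(data)
  out <- data[idx, , drop = FALSE]
  attr(out, "schema") <- sc
  out
}

#' Read and write cohort CSV files with a schema sidecar
#'
#' `write_cohort()` writes the table as CSV plus a sidecar text file of
#' `column=tag` lines; `read_cohort()` reads both back, restoring column
#' types (date-tagged columns are parsed as `Date`). Round-trips are
#' byte-stable, so identical inputs produce identical files.
#'
#' @param data A cohort table with an attached schema.
#' @param path Path of the CSV file.
#' @param schema_path Path of the sidecar; defaults to `<path>.schema`.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   a cohort table.
#' @export
write_cohort <- function(data, path, schema_path = paste0(path, ".schema")) {
  sc <- cohort_schema(data)
  readr::write_csv(data, path, progress = FALSE)
  writeLines(paste0(names(data), "=", unname(sc[names(data)])), schema_path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, schema_path = paste0(path, ".schema")) {
  lines <- readLines(schema_path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  schema <- setNames(
    vapply(kv, function(p) trimws(p[[2]]), character(1)),
    vapply(kv, function(p) trimws(p[[1]]), character(1))
  )
  date_cols <- names(schema)[schema == "date"]
  spec <- readr::cols(.default = readr::col_guess())
  for (dc in date_cols) spec$cols[[dc]] <- readr::col_date(format = "")
  data <- readr::read_csv(path, col_types = spec, progress = FALSE)
  cohort_table(data, schema)
}
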