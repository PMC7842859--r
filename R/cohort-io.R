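#' Write and read cohort CSV files
#'
#' The on-disk format is a UTF-8 CSV with one patient per row, a header of
#' feature names plus `outcome`, and a leading `# site=<name>` comment line
#' carrying the site label. `read_cohort_csv()` validates the file against a
#' schema, coercing binary columns to 0/1 integers, categoricals to schema
#' levels, and continuous columns to doubles; any unparseable or missing
#' value raises an error naming the column and row. Writing then reading a
#' cohort reproduces it field for field.
#'
#' @param cohort A cohort tibble (features plus `outcome`).
#' @param path File path.
#' @return `write_cohort_csv()`: `path`, invisibly. `read_cohort_csv()`: a
#'   cohort tibble with `site_name` and `schema` attributes.
#' @export
write_cohort_csv <- function(cohort, path) {
  site <- attr(cohort, "site_name") %||% "unknown"
  writeLines(sprintf("# site=%s", site), path)
  readr::write_csv(as_tibble(as.data.frame(cohort)), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @param schema The `fc_schema` the file must conform to.
#' @export
read_cohort_csv <- function(path, schema) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path, n = 1)
  if (length(lines) == 0) abort(sprintf("file is empty: %s", path))
  site <- if (grepl("^# site=", lines[1])) sub("^# site=", "", lines[1]) else NA_character_
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) abort(sprintf("file has no data rows: %s", path))
  expected <- c(schema$name, "outcome")
  missing <- setdiff(expected, names(raw))
  if (length(missing)) {
    abort(sprintf("file %s is missing column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  parse_col <- function(name, kind, levels) {
    v <- raw[[name]]
    if (kind == "categorical") {
      bad <- which(!(v %in% levels) & !is.na(v))
      if (length(bad)) {
        abort(sprintf("column `%s`, row %d: value `%s` is not a schema level",
                      name, bad[1], v[bad[1]]))
      }
      return(v)
    }
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v))
    if (length(bad)) {
      abort(sprintf("column `%s`, row %d: cannot parse `%s` as a number",
                    name, bad[1], v[bad[1]]))
    }
    if (kind == "binary") {
      bad <- which(!(num %in% c(0, 1)) & !is.na(num))
      if (length(bad)) {
        abort(sprintf("column `%s`, row %d: binary value must be 0 or 1, got `%s`",
                      name, bad[1], v[bad[1]]))
      }
      return(as.integer(num))
    }
    num
  }
  cols <- purrr::pmap(schema[, c("name", "kind", "levels")], function(name, kind, levels) {
    parse_col(name, kind, levels)
  })
  names(cols) <- schema$name
  cohort <- as_tibble(cols)
  cohort$outcome <- parse_col("outcome", "binary", NULL)
  attr(cohort, "schema") <- schema
  attr(cohort, "site_name") <- site
  class(cohort) <- c("fc_cohort", class(cohort))
  cohort
}
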