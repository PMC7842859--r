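#' Feature schema for hospital cohorts
#'
#' A feature schema is a tibble with one row per feature and columns
#' `name` (unique identifier), `kind` (`"binary"`, `"categorical"` or
#' `"continuous"`), `levels` (list column of category labels, `NULL` unless
#' categorical) and `units` (free text). The outcome column (`outcome`,
#' 1 = death within 7 days of admission) is never part of the schema.
#'
#' @param features A data frame with columns `name`, `kind`, and optionally
#'   `levels` (list column) and `units`.
#' @return A validated `fc_schema` tibble.
#' @export
#' @examples
#' feature_schema(tibble::tibble(
#'   name = c("age", "diabetes"), kind = c("continuous", "binary")
#' ))
feature_schema <- function(features) {
  features <- as_tibble(features)
  if (!all(c("name", "kind") %in% names(features))) {
    abort("a feature schema needs `name` and `kind` columns")
  }
  if (!"levels" %in% names(features)) features$levels <- vector("list", nrow(features))
  if (!"units" %in% names(features)) features$units <- NA_character_
  if (anyDuplicated(features$name)) abort("feature names must be unique")
  if ("outcome" %in% features$name) abort("`outcome` is reserved and cannot be a feature")
  bad_kind <- setdiff(unique(features$kind), c("binary", "categorical", "continuous"))
  if (length(bad_kind)) {
    abort(sprintf("unknown feature kind(s): %s", paste(bad_kind, collapse = ", ")))
  }
  cat_rows <- features$kind == "categorical"
  n_levels <- vapply(features$levels, length, integer(1))
  if (any(cat_rows & n_levels < 2)) {
    abort("categorical features need at least 2 levels")
  }
  features <- features[, c("name", "kind", "levels", "units")]
  class(features) <- c("fc_schema", class(features))
  features
}

#' Default cohort schema
#'
#' The feature set used by the bundled five-hospital simulation: gender and
#' age, ethnicity and race as categoricals, nineteen past-medical-history
#' flags, and eight admission vitals/labs. The exact feature panel of the
#' source health system is not public; this panel is a documented stand-in
#' with the same structure (demographics, comorbidity flags, continuous
#' vitals and labs).
#'
#' @return An `fc_schema` tibble with 31 features (35 encoded columns).
#' @export
#' @examples
#' default_schema()
default_schema <- function() {
  comorbidities <- c(
    "acute_mi", "ards", "acute_vte", "asthma", "atrial_fibrillation",
    "cancer", "chronic_kidney_disease", "copd", "chronic_viral_hepatitis",
    "coronary_artery_disease", "diabetes", "heart_failure", "hiv",
    "hypertension", "intracerebral_hemorrhage", "liver_disease", "obesity",
    "obstructive_sleep_apnea", "stroke"
  )
  vitals <- tibble::tibble(
    name = c(
      "heart_rate", "resp_rate", "temperature", "spo2",
      "systolic_bp", "creatinine", "crp", "d_dimer"
    ),
    units = c(
      "beats/min", "breaths/min", "degC", "%",
      "mmHg", "mg/dL", "mg/L", "ug/mL"
    )
  )
  feature_schema(tibble(
    name = c("gender_male", "age", "ethnicity", "race", comorbidities, vitals$name),
    kind = c(
      "binary", "continuous", "categorical", "categorical",
      rep("binary", length(comorbidities)), rep("continuous", nrow(vitals))
    ),
    levels = c(
      list(NULL, NULL,
        c("hispanic", "non_hispanic", "unknown"),
        c("asian", "black", "other", "unknown", "white")
      ),
      rep(list(NULL), length(comorbidities) + nrow(vitals))
    ),
    units = c("0/1", "years", NA, NA, rep("0/1", length(comorbidities)), vitals$units)
  ))
}

#' Encoded design-matrix column names implied by a schema
#'
#' Binary features map to themselves (0/1), categoricals to one indicator per
#' non-reference level (first level dropped), continuous to themselves.
#' Column order follows the schema row order; this order is the contract the
#' outcome-model coefficient vector and all trained models rely on.
#'
#' @param schema An `fc_schema`.
#' @return Character vector of encoded column names.
#' @export
encoded_columns <- function(schema) {
  unlist(purrr::pmap(schema, function(name, kind, levels, units) {
    switch(kind,
      binary = name,
      continuous = name,
      categorical = paste(name, levels[-1], sep = "_")
    )
  }), use.names = FALSE)
}
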