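#' Outcome models for cohort simulation
#'
#' The generator's outcome mechanism is a logistic linear model shared across
#' all sites, with a per-site intercept offset solved at generation time so
#' every site hits its configured mortality prevalence exactly (in
#' expectation). Sharing the coefficient vector gives cross-site learning a
#' recoverable common signal; the per-site offsets reproduce the prevalence
#' differences between hospitals.
#'
#' @param coefficients Named numeric vector on the log-odds scale, one entry
#'   per encoded design-matrix column (see [encoded_columns()]).
#' @param base_intercept Log-odds intercept shared by all sites.
#' @return An `fc_outcome_model` object.
#' @export
outcome_model <- function(coefficients, base_intercept = -2) {
  if (!is.numeric(coefficients) || is.null(names(coefficients))) {
    abort("`coefficients` must be a named numeric vector")
  }
  if (any(!is.finite(coefficients))) abort("coefficients must be finite")
  structure(
    list(
      coefficients = coefficients,
      base_intercept = base_intercept,
      site_intercepts = list()
    ),
    class = "fc_outcome_model"
  )
}

#' Default sparse outcome model
#'
#' A sparse risk model on the default schema: five nonzero coefficients
#' (age +0.05 per year, SpO2 -0.10 per %, CRP +0.006 per mg/L,
#' heart failure +0.8, diabetes +0.5) and zeros elsewhere. Sparsity makes
#' coefficient-sign recovery by L1-regularized training a testable property
#' of the simulation.
#'
#' @param schema Feature schema (default [default_schema()]).
#' @return An `fc_outcome_model` whose coefficient vector spans the encoded
#'   columns of `schema`.
#' @export
#' @examples
#' m <- default_outcome_model()
#' names(which(m$coefficients != 0))
default_outcome_model <- function(schema = default_schema()) {
  cols <- encoded_columns(schema)
  beta <- setNames(rep(0, length(cols)), cols)
  nonzero <- c(age = 0.05, spo2 = -0.10, crp = 0.006,
               heart_failure = 0.8, diabetes = 0.5)
  missing <- setdiff(names(nonzero), cols)
  if (length(missing)) {
    abort(sprintf("schema lacks columns needed by the default model: %s",
                  paste(missing, collapse = ", ")))
  }
  beta[names(nonzero)] <- nonzero
  outcome_model(beta, base_intercept = -2)
}

#' Calibrate a site intercept to a target prevalence
#'
#' Finds the offset `c` such that the mean predicted risk
#' `mean(sigmoid(c + base_intercept + X beta))` over the rows of `design`
#' equals `target_prevalence` to within 1e-6, by bisection on `c` over
#' \[-20, 20\]. The mean predicted risk is continuous and strictly increasing
#' in `c`, so bisection converges unconditionally for attainable targets.
#'
#' @param model An `fc_outcome_model`.
#' @param design Numeric matrix whose columns match `model$coefficients`.
#' @param target_prevalence Target mean risk, strictly inside (0, 1).
#' @param tol Convergence tolerance on the mean risk (default 1e-6).
#' @return The scalar offset `c` (log-odds).
#' @export
calibrate_site_intercept <- function(model, design, target_prevalence,
                                     tol = 1e-6) {
  if (!inherits(model, "fc_outcome_model")) abort("`model` must be an fc_outcome_model")
  if (!is.matrix(design) || nrow(design) == 0) abort("`design` must be a non-empty matrix")
  if (target_prevalence <= 0 || target_prevalence >= 1) {
    abort("`target_prevalence` of 0 or 1 is unattainable with finite log-odds")
  }
  eta <- model$base_intercept + drop(design %*% model$coefficients[colnames(design)])
  mean_risk <- function(c) mean(sigmoid(c + eta))
  lo <- -20; hi <- 20
  if (mean_risk(lo) > target_prevalence || mean_risk(hi) < target_prevalence) {
    abort("target prevalence not bracketed by offsets in [-20, 20]")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    r <- mean_risk(mid)
    if (abs(r - target_prevalence) < tol) return(mid)
    if (r < target_prevalence) lo <- mid else hi <- mid
  }
  abort("bisection failed to reach the requested tolerance")
}
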