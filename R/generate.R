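#' Generate one hospital cohort
#'
#' Draws `profile$n` patients: gender Bernoulli(`gender_p_male`), age from a
#' Normal fitted to the profile's median and IQR (sd = IQR/1.349) truncated
#' to \[18, 110\], categorical features from the profile's probability
#' vectors, comorbidity flags Bernoulli(prevalence), and continuous
#' vitals/labs Normal(mean, sd). Outcomes are then drawn
#' Bernoulli(sigmoid(linear predictor)) under `model`, with the site
#' intercept calibrated by [calibrate_site_intercept()] so the expected
#' mortality rate equals `profile$target_prevalence`. The same
#' (profile, model, seed) triple reproduces the cohort bit-identically.
#'
#' @param profile A one-row `fc_profiles` tibble (see [site_profile()]).
#' @param schema Feature schema; must be consistent with the profile.
#' @param model An `fc_outcome_model`.
#' @param seed Integer seed.
#' @param missing_rate Optional fraction of feature cells set missing
#'   completely at random (default 0, i.e. complete data).
#' @return A cohort tibble (features plus `outcome`) with attributes
#'   `site_name`, `schema` and `site_intercept`.
#' @export
#' @examples
#' p <- default_mshs_profiles()[1, ]
#' cohort <- generate_site(p, default_schema(), default_outcome_model(), seed = 1)
#' nrow(cohort) # 611
generate_site <- function(profile, schema, model, seed, missing_rate = 0) {
  if (nrow(profile) != 1) abort("`profile` must be a single profile row")
  check_profile_schema(profile, schema)
  n <- profile$n
  cat_probs <- profile$category_probs[[1]]
  comorb <- profile$comorbidity_prevalences[[1]]
  cont <- profile$continuous_params[[1]]
  age_sd <- (profile$age_q3 - profile$age_q1) / 1.349

  with_seed(seed, {
    cols <- purrr::pmap(schema, function(name, kind, levels, units) {
      if (name == "gender_male") return(rbinom(n, 1, profile$gender_p_male))
      if (name == "age") return(rnorm_truncated(n, profile$age_median, age_sd, 18, 110))
      switch(kind,
        binary = rbinom(n, 1, comorb[[name]]),
        categorical = sample(levels, n, replace = TRUE,
                             prob = cat_probs[[name]][levels]),
        continuous = {
          row <- cont[cont$name == name, ]
          rnorm(n, row$mean, row$sd)
        }
      )
    })
    names(cols) <- schema$name
    cohort <- as_tibble(cols)
    cohort$outcome <- 0L
    attr(cohort, "schema") <- schema
    attr(cohort, "site_name") <- profile$site

    dm <- encode_cohort(cohort, schema)
    offset <- calibrate_site_intercept(model, dm$x, profile$target_prevalence)
    eta <- offset + model$base_intercept +
      drop(dm$x %*% model$coefficients[colnames(dm$x)])
    cohort$outcome <- rbinom(n, 1, sigmoid(eta))

    if (missing_rate > 0) {
      for (nm in schema$name) {
        miss <- runif(n) < missing_rate
        cohort[[nm]][miss] <- NA
      }
    }
    attr(cohort, "site_intercept") <- offset
    class(cohort) <- c("fc_cohort", class(cohort))
    cohort
  })
}

# Truncated-normal draws by rejection; the truncation interval is wide
# relative to the sd, so acceptance is near 1 and the loop terminates fast.
rnorm_truncated <- function(n, mean, sd, lower, upper) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

check_profile_schema <- function(profile, schema) {
  cat_probs <- profile$category_probs[[1]]
  comorb <- profile$comorbidity_prevalences[[1]]
  cont <- profile$continuous_params[[1]]
  for (i in seq_len(nrow(schema))) {
    name <- schema$name[i]; kind <- schema$kind[i]
    ok <- switch(kind,
      binary = name == "gender_male" || name %in% names(comorb),
      categorical = name %in% names(cat_probs) &&
        setequal(names(cat_probs[[name]]), schema$levels[[i]]),
      continuous = name == "age" || name %in% cont$name
    )
    if (!ok) {
      abort(sprintf("profile `%s` has no distribution for %s feature `%s`",
                    profile$site, kind, name))
    }
  }
  invisible(TRUE)
}

#' Generate a multi-hospital system of cohorts
#'
#' One cohort per profile row, with per-site seeds derived deterministically
#' from the master seed (`seed + site index`), so a single integer
#' reproduces the whole system.
#'
#' @param profiles An `fc_profiles` tibble (one row per site).
#' @param schema Feature schema shared by all sites.
#' @param model Shared `fc_outcome_model`.
#' @param seed Master integer seed.
#' @param missing_rate Passed through to [generate_site()].
#' @return Named list of cohort tibbles, one per site.
#' @export
#' @examples
#' cohorts <- generate_system(default_mshs_profiles(), default_schema(),
#'                            default_outcome_model(), seed = 1)
#' sum(vapply(cohorts, nrow, integer(1))) # 4029
generate_system <- function(profiles, schema, model, seed, missing_rate = 0) {
  if (nrow(profiles) < 1) abort("need at least one profile")
  cohorts <- lapply(seq_len(nrow(profiles)), function(i) {
    generate_site(profiles[i, ], schema, model, seed = seed + i,
                  missing_rate = missing_rate)
  })
  names(cohorts) <- profiles$site
  cohorts
}
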