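#' Site generative profiles
#'
#' A profile tibble has one row per hospital with the parameters the cohort
#' generator draws from: site size, 7-day mortality prevalence, gender split,
#' age median and interquartile range, per-categorical-feature probability
#' vectors, per-comorbidity prevalences, and per-continuous-feature
#' (mean, sd) pairs.
#'
#' @param site Character site name.
#' @param n Positive patient count.
#' @param target_prevalence 7-day mortality fraction in (0, 1).
#' @param gender_p_male Fraction male in \[0, 1\].
#' @param age_median,age_q1,age_q3 Age summary in years.
#' @param category_probs Named list (per categorical feature) of named
#'   probability vectors summing to 1.
#' @param comorbidity_prevalences Named numeric vector of binary-feature
#'   prevalences in \[0, 1\].
#' @param continuous_params Tibble with columns `name`, `mean`, `sd` for each
#'   continuous feature other than age.
#' @return A one-row `fc_profiles` tibble; rows from several calls can be
#'   combined with [dplyr::bind_rows()].
#' @export
site_profile <- function(site, n, target_prevalence, gender_p_male,
                         age_median, age_q1, age_q3,
                         category_probs, comorbidity_prevalences,
                         continuous_params) {
  if (n <= 0 || n != round(n)) abort("`n` must be a positive integer")
  assert_scalar_number(target_prevalence, "target_prevalence", 0, 1)
  assert_scalar_number(gender_p_male, "gender_p_male", 0, 1)
  for (nm in names(category_probs)) {
    p <- category_probs[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      abort(sprintf("category probabilities for `%s` must be non-negative and sum to 1", nm))
    }
  }
  if (any(comorbidity_prevalences < 0 | comorbidity_prevalences > 1)) {
    abort("comorbidity prevalences must lie in [0, 1]")
  }
  out <- tibble(
    site = site, n = as.integer(n), target_prevalence = target_prevalence,
    gender_p_male = gender_p_male,
    age_median = age_median, age_q1 = age_q1, age_q3 = age_q3,
    category_probs = list(category_probs),
    comorbidity_prevalences = list(comorbidity_prevalences),
    continuous_params = list(as_tibble(continuous_params))
  )
  class(out) <- c("fc_profiles", class(out))
  out
}

# Published five-site cohort description: counts per site for the two
# categorical demographics (used as exact probability vectors) and printed
# prevalences for the comorbidity flags. Dashes in the published table
# (cells describing fewer than 10 patients, masked for privacy) are NA here
# and replaced by `suppressed_prevalence` at profile-build time.
mshs_site_names <- c("MSB", "MSH", "MSM", "MSQ", "MSW")
mshs_site_n <- c(611L, 1644L, 749L, 540L, 485L)
mshs_mortality <- c(0.242, 0.072, 0.124, 0.230, 0.056)
mshs_p_male <- c(0.553, 0.578, 0.549, 0.637, 0.530)
mshs_age <- tibble::tibble(
  median = c(72.5, 63.3, 69.8, 68.1, 66.3),
  q1 = c(63.6, 51.3, 57.4, 57.1, 52.5),
  q3 = c(82.7, 73.2, 80.3, 78.8, 77.6)
)
mshs_ethnicity_counts <- rbind(
  hispanic     = c(21, 460, 259, 198, 111),
  non_hispanic = c(416, 892, 452, 287, 349),
  unknown      = c(174, 292, 38, 55, 25)
)
mshs_race_counts <- rbind(
  asian   = c(13, 83, 16, 56, 27),
  black   = c(323, 388, 266, 64, 109),
  other   = c(54, 705, 343, 288, 164),
  unknown = c(27, 87, 25, 14, 14),
  white   = c(194, 381, 99, 118, 171)
)
mshs_comorbidity_prev <- rbind(
  acute_mi                = c(0.023, 0.010, NA, 0.028, 0.014),
  ards                    = c(NA, 0.017, NA, NA, NA),
  acute_vte               = c(NA, 0.007, NA, NA, NA),
  asthma                  = c(NA, 0.061, 0.052, 0.035, 0.056),
  atrial_fibrillation     = c(0.038, 0.069, 0.059, 0.091, 0.058),
  cancer                  = c(0.036, 0.116, 0.063, 0.039, 0.085),
  chronic_kidney_disease  = c(0.075, 0.127, 0.100, 0.150, 0.068),
  copd                    = c(0.018, 0.039, 0.041, 0.052, 0.039),
  chronic_viral_hepatitis = c(NA, 0.010, 0.019, NA, NA),
  coronary_artery_disease = c(0.092, 0.102, 0.123, 0.152, 0.105),
  diabetes                = c(0.152, 0.214, 0.220, 0.285, 0.157),
  heart_failure           = c(0.059, 0.067, 0.081, 0.080, 0.062),
  hiv                     = c(NA, 0.019, 0.015, NA, 0.029),
  hypertension            = c(0.183, 0.334, 0.332, 0.417, 0.287),
  intracerebral_hemorrhage = c(NA, NA, NA, NA, NA),
  liver_disease           = c(NA, 0.032, 0.020, 0.028, NA),
  obesity                 = c(NA, 0.107, 0.099, 0.070, 0.060),
  obstructive_sleep_apnea = c(NA, 0.033, 0.020, NA, NA),
  stroke                  = c(NA, 0.015, NA, NA, NA)
)

# Baseline (mean, sd) for the admission vitals/labs; site means are offset by
# shift_sd * sd * z_site to emulate the significant cross-site shifts the
# source system reports for most clinical features.
mshs_vitals_base <- tibble::tibble(
  name = c("heart_rate", "resp_rate", "temperature", "spo2",
           "systolic_bp", "creatinine", "crp", "d_dimer"),
  mean = c(88, 22, 37.2, 93, 125, 1.4, 80, 1.8),
  sd   = c(18, 6, 0.8, 5, 20, 1.2, 70, 2.0)
)

#' Default five-hospital site profiles
#'
#' Generative profiles for the five Mount-Sinai-like hospitals the package
#' simulates: sizes 611/1644/749/540/485 (total 4029), 7-day mortality
#' prevalences 24.2/7.2/12.4/23.0/5.6%, and site-specific gender, age,
#' ethnicity, race and comorbidity distributions taken from the published
#' cohort description. Cells masked in that description (fewer than 10
#' patients) default to `suppressed_prevalence`. Continuous vitals/labs get a
#' per-site mean shift of `shift_sd` standard deviations times an evenly
#' spaced site factor in \[-1, 1\], emulating cross-site distribution shift.
#'
#' @param shift_sd Site shift for continuous features, in sd units
#'   (default 0.25; 0 disables the shift).
#' @param suppressed_prevalence Prevalence assigned to masked comorbidity
#'   cells (default 0.01, consistent with the <10-patient masking threshold).
#' @return An `fc_profiles` tibble with 5 rows.
#' @export
#' @examples
#' profiles <- default_mshs_profiles()
#' sum(profiles$n) # 4029
default_mshs_profiles <- function(shift_sd = 0.25, suppressed_prevalence = 0.01) {
  site_z <- seq(-1, 1, length.out = 5)
  rows <- lapply(seq_along(mshs_site_names), function(i) {
    comorb <- mshs_comorbidity_prev[, i]
    comorb[is.na(comorb)] <- suppressed_prevalence
    vit <- mshs_vitals_base
    vit$mean <- vit$mean + shift_sd * vit$sd * site_z[i]
    site_profile(
      site = mshs_site_names[i], n = mshs_site_n[i],
      target_prevalence = mshs_mortality[i],
      gender_p_male = mshs_p_male[i],
      age_median = mshs_age$median[i], age_q1 = mshs_age$q1[i],
      age_q3 = mshs_age$q3[i],
      category_probs = list(
        ethnicity = mshs_ethnicity_counts[, i] / sum(mshs_ethnicity_counts[, i]),
        race = mshs_race_counts[, i] / sum(mshs_race_counts[, i])
      ),
      comorbidity_prevalences = comorb,
      continuous_params = vit
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fc_profiles", class(out))
  out
}
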