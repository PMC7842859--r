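# Shared fixture builders; everything is generated in code at test time.

# A tiny 3-feature schema for fast unit tests.
tiny_schema <- function() {
  feature_schema(tibble::tibble(
    name = c("flag", "grade", "marker"),
    kind = c("binary", "categorical", "continuous"),
    levels = list(NULL, c("a", "b", "c"), NULL),
    units = c("0/1", NA, "au")
  ))
}

# One-row profile matching tiny_schema(); age/gender columns are required by
# the generator so the tiny schema is extended with them on demand.
tiny_profiles <- function(n = c(120, 80), prevalence = c(0.3, 0.15)) {
  schema <- tiny_full_schema()
  dplyr::bind_rows(lapply(seq_along(n), function(i) {
    site_profile(
      site = paste0("S", i), n = n[i], target_prevalence = prevalence[i],
      gender_p_male = 0.5, age_median = 65, age_q1 = 55, age_q3 = 75,
      category_probs = list(grade = c(a = 0.5, b = 0.3, c = 0.2)),
      comorbidity_prevalences = c(flag = 0.2),
      continuous_params = tibble::tibble(name = "marker", mean = 10, sd = 2)
    )
  }))
}

tiny_full_schema <- function() {
  feature_schema(tibble::tibble(
    name = c("gender_male", "age", "flag", "grade", "marker"),
    kind = c("binary", "continuous", "binary", "categorical", "continuous"),
    levels = list(NULL, NULL, NULL, c("a", "b", "c"), NULL),
    units = NA_character_
  ))
}

tiny_outcome_model <- function() {
  cols <- encoded_columns(tiny_full_schema())
  beta <- stats::setNames(rep(0, length(cols)), cols)
  beta[c("age", "flag", "marker")] <- c(0.05, 0.9, 0.25)
  outcome_model(beta, base_intercept = -1.5)
}

tiny_system <- function(seed = 1) {
  generate_system(tiny_profiles(), tiny_full_schema(), tiny_outcome_model(),
                  seed = seed)
}

# Random logistic site data for trainer/federation tests.
random_site <- function(n, d, seed, beta = NULL) {
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n * d), n, d,
                dimnames = list(NULL, paste0("x", seq_len(d))))
    beta <- beta %||% c(1.5, -1, rep(0, d - 2))
    y <- stats::rbinom(n, 1, stats::plogis(drop(x %*% beta)))
    list(x = x, y = y)
  })
}

`%||%` <- rlang::`%||%`

# Independent brute-force oracles -------------------------------------------

# Pearson chi-square by the explicit sum over observed/expected cells.
chisq_oracle <- function(counts) {
  n <- sum(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / n
  sum((counts - expected)^2 / expected)
}

# AUROC by exhaustive positive-negative pair counting (ties count 1/2).
auroc_oracle <- function(y, scores) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  wins / (length(pos) * length(neg))
}

# Kruskal-Wallis H with midrank ties, from first principles.
kw_oracle <- function(samples) {
  pooled <- unlist(samples)
  r <- rank(pooled)
  n <- length(pooled)
  idx <- rep(seq_along(samples), lengths(samples))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(pooled)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Finite-difference gradient of the mean BCE with respect to every parameter.
numeric_gradient <- function(params, x, y, eps = 1e-6) {
  f <- function(p) bce_loss(y, predict_proba(p, x))
  lapply(seq_along(params$layers), function(l) {
    gW <- params$layers[[l]]$W
    for (i in seq_along(gW)) {
      up <- params; up$layers[[l]]$W[i] <- up$layers[[l]]$W[i] + eps
      dn <- params; dn$layers[[l]]$W[i] <- dn$layers[[l]]$W[i] - eps
      gW[i] <- (f(up) - f(dn)) / (2 * eps)
    }
    gb <- params$layers[[l]]$b
    for (i in seq_along(gb)) {
      up <- params; up$layers[[l]]$b[i] <- up$layers[[l]]$b[i] + eps
      dn <- params; dn$layers[[l]]$b[i] <- dn$layers[[l]]$b[i] - eps
      gb[i] <- (f(up) - f(dn)) / (2 * eps)
    }
    list(W = gW, b = gb)
  })
}

flatten_params <- function(params) {
  unlist(lapply(params$layers, function(l) c(l$W, l$b)))
}
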