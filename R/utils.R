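# Internal numerical helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

# Soft-threshold operator used by the proximal L1 step.
soft_threshold <- function(x, lambda) sign(x) * pmax(abs(x) - lambda, 0)

# Run `code` under a fixed RNG seed, restoring the caller's RNG state on exit,
# so seeded package functions never disturb the user's random stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Percent to one decimal, as rendered in cohort tables.
percent1 <- function(count, n) round(100 * count / n, 1)

is_binary_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x %in% c(0, 1))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}
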