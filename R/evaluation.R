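#' Area under the ROC curve
#'
#' Rank-based (normalized Mann-Whitney U) AUROC with midrank tie handling:
#' `(sum of positive ranks - n_pos (n_pos + 1) / 2) / (n_pos * n_neg)`.
#' Equals the probability that a random positive is scored above a random
#' negative, ties counting one half.
#'
#' @param y Binary labels containing both classes.
#' @param scores Numeric risk scores.
#' @return AUROC in \[0, 1\].
#' @export
#' @examples
#' auroc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)) # 0.75
auroc <- function(y, scores) {
  if (length(y) != length(scores)) abort("`y` and `scores` must have equal length")
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) abort("AUROC needs both classes present")
  r <- rank(scores)
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Mean and 95% interval from bootstrap iterations
#'
#' Summarizes a vector of per-iteration metric values by its mean and a
#' percentile interval (2.5th/97.5th percentiles at the default level,
#' linear interpolation). A normal-approximation interval
#' (mean +/- z * sd) is available for comparison.
#'
#' @param values Numeric vector with at least 2 entries.
#' @param level Coverage level (default 0.95).
#' @param method `"percentile"` (default) or `"normal"`.
#' @return A tibble with `mean`, `low`, `high`.
#' @export
ci_from_iterations <- function(values, level = 0.95,
                               method = c("percentile", "normal")) {
  method <- match.arg(method)
  if (length(values) < 2) abort("need at least 2 iteration values")
  alpha <- (1 - level) / 2
  if (method == "percentile") {
    qs <- unname(quantile(values, c(alpha, 1 - alpha), type = 7))
  } else {
    z <- qnorm(1 - alpha)
    qs <- mean(values) + c(-z, z) * stats::sd(values)
  }
  tibble(mean = mean(values), low = qs[1], high = qs[2])
}

#' Bootstrap evaluation configuration
#'
#' The evaluation protocol: B independent stratified 70/30 train/test
#' resplits (Monte-Carlo cross-validation), each initialized with its own
#' seed derived as `master_seed + iteration`. The reference protocol uses
#' B = 490; the desk default is 50.
#'
#' @param n_iterations Number of resplits B (default 50).
#' @param test_fraction Held-out fraction (default 0.30).
#' @param master_seed Integer master seed.
#' @return An `fc_boot_config`.
#' @export
bootstrap_config <- function(n_iterations = 50, test_fraction = 0.30,
                             master_seed = 1) {
  if (n_iterations < 1) abort("`n_iterations` must be >= 1")
  structure(list(n_iterations = as.integer(n_iterations),
                 test_fraction = test_fraction,
                 master_seed = as.integer(master_seed)),
            class = "fc_boot_config")
}

# Split, scale and balance one site's design matrix for one iteration.
# Single-class test parts are handled by deterministic re-splits (seed
# offset 100000 per attempt) so B stays fixed and reproducible.
prepare_site_iteration <- function(dm, boot_cfg, iter_seed, balancing,
                                   balance_seed) {
  events <- character(0)
  for (attempt in 0:20) {
    sp <- stratified_split(dm, boot_cfg$test_fraction,
                           seed = iter_seed + 100000L * attempt)
    if (length(unique(sp$test$y)) == 2 && length(unique(sp$train$y)) == 2) {
      if (attempt > 0) {
        events <- sprintf("site %s: re-split %d time(s) for single-class part",
                          dm$site, attempt)
      }
      scaler <- fit_scaler(sp$train)
      train <- apply_scaler(scaler, sp$train)
      test <- apply_scaler(scaler, sp$test)
      bal <- balance_classes(train, balancing, seed = balance_seed)
      return(list(
        train = list(x = bal$data$x, y = bal$data$y,
                     weights = if (balancing == "class_weight") bal$weights else NULL,
                     name = dm$site),
        test = list(x = test$x, y = test$y, name = dm$site),
        n_train_raw = nrow(sp$train$x), events = events
      ))
    }
  }
  abort(sprintf("site %s: could not obtain a two-class split", dm$site))
}

#' Bootstrap experiment over sites, one strategy and one model family
#'
#' For each of B iterations: every site gets a fresh stratified 70/30 split
#' (iteration seed = master seed + iteration), per-site standardization
#' fitted on the training part, and class balancing of the training part
#' only. The strategy then trains on training parts alone — locally (one
#' model per site), pooled (one model on concatenated training parts), or
#' federated (per-site parts through the aggregator) — and every resulting
#' model is scored on every site's test part. Per-site AUROC vectors are
#' summarized with [ci_from_iterations()]. For the local strategy the
#' site-level summary uses each site's own model (the diagonal of the
#' train-site by test-site matrix); the full matrix is kept in `samples`.
#'
#' @param cohorts Named list of cohort tibbles (or `fc_design` objects).
#' @param family `"lasso"` or `"mlp"`.
#' @param strategy `"local"`, `"pooled"` or `"federated"`.
#' @param train_cfg An `fc_train_config`.
#' @param fed_cfg An `fc_fed_config` (federated strategy only); its `rounds`
#'   also sets the epoch budget of local and pooled runs so all strategies
#'   make the same number of passes over the data.
#' @param boot_cfg An `fc_boot_config`.
#' @param balancing Class-balancing method (see [balance_classes()]).
#' @return An `fc_experiment` object with elements `samples` (long tibble:
#'   iteration, family, strategy, train_site, site, auroc), `summary`
#'   (per-site mean and 95% CI), and `events` (re-split log).
#' @export
run_bootstrap <- function(cohorts, family = c("lasso", "mlp"),
                          strategy = c("local", "pooled", "federated"),
                          train_cfg = train_config(),
                          fed_cfg = NULL,
                          boot_cfg = bootstrap_config(),
                          balancing = "oversample_minority") {
  family <- match.arg(family)
  strategy <- match.arg(strategy)
  dms <- purrr::imap(cohorts, function(c, nm) {
    if (inherits(c, "fc_design")) {
      c$site <- c$site %||% nm
      c
    } else {
      dm <- encode_cohort(c)
      if (is.na(dm$site)) dm$site <- nm
      dm
    }
  })
  site_names <- unname(vapply(dms, function(d) d$site, character(1)))
  rounds <- if (!is.null(fed_cfg)) fed_cfg$rounds else default_rounds(family)
  local_epochs <- if (!is.null(fed_cfg)) fed_cfg$local_epochs else 1L
  noise_sigma <- if (!is.null(fed_cfg)) fed_cfg$noise_sigma else 0

  all_rows <- vector("list", boot_cfg$n_iterations)
  events <- character(0)
  for (b in seq_len(boot_cfg$n_iterations)) {
    iter_seed <- boot_cfg$master_seed + b
    prep <- lapply(seq_along(dms), function(k) {
      prepare_site_iteration(dms[[k]], boot_cfg, iter_seed + 1000L * k,
                             balancing, balance_seed = iter_seed + 31L * k)
    })
    events <- c(events, unlist(lapply(prep, function(p) p$events)))
    trains <- lapply(prep, function(p) p$train)
    tests <- lapply(prep, function(p) p$test)

    eval_model <- function(params, train_site) {
      tibble(
        iteration = b, family = family, strategy = strategy,
        train_site = train_site, site = site_names,
        auroc = vapply(tests, function(tp) {
          auroc(tp$y, predict_proba(params, tp$x))
        }, numeric(1))
      )
    }
    rows <- switch(strategy,
      local = purrr::list_rbind(lapply(seq_along(trains), function(k) {
        fit <- run_local(trains[[k]], family, train_cfg, epochs = rounds,
                         seed = iter_seed + 7L)
        eval_model(fit$params, site_names[k])
      })),
      pooled = {
        fit <- run_pooled(trains, family, train_cfg, epochs = rounds,
                          seed = iter_seed + 7L)
        eval_model(fit$params, "pooled")
      },
      federated = {
        fcfg <- federation_config(rounds = rounds, local_epochs = local_epochs,
                                  noise_sigma = noise_sigma,
                                  seed = iter_seed + 7L)
        fit <- run_federated(trains, family, train_cfg, fcfg)
        eval_model(fit$params, "federated")
      }
    )
    all_rows[[b]] <- rows
  }
  samples <- purrr::list_rbind(all_rows)

  own <- if (strategy == "local") {
    dplyr::filter(samples, .data$train_site == .data$site)
  } else {
    samples
  }
  summarise_auroc <- function(v) {
    if (length(v) >= 2) ci_from_iterations(v) else tibble(mean = v, low = v, high = v)
  }
  summary <- own |>
    group_by(.data$site) |>
    summarise(summarise_auroc(.data$auroc), n_iterations = dplyr::n(),
              .groups = "drop") |>
    rename(auroc_mean = "mean", ci_low = "low", ci_high = "high") |>
    mutate(family = family, strategy = strategy, .before = 1)

  structure(list(samples = samples, summary = summary, events = events,
                 family = family, strategy = strategy,
                 boot_cfg = boot_cfg),
            class = "fc_experiment")
}

#' @export
print.fc_experiment <- function(x, ...) {
  cat(sprintf("<fc_experiment> %s / %s, B = %d\n", x$family, x$strategy,
              x$boot_cfg$n_iterations))
  print(x$summary)
  invisible(x)
}

#' Learning curves from a federated round log
#'
#' Reshapes the per-round log into plot-ready per-site series of held-out
#' AUROC and training binary cross-entropy versus round, preserving site
#' order.
#'
#' @param round_log An `fc_round_log` from [run_federated()].
#' @return A tibble with columns `round`, `site`, `auroc`, `bce`.
#' @export
learning_curves <- function(round_log) {
  if (nrow(round_log) == 0) abort("empty round log")
  out <- round_log |>
    select(all_of(c("round", "site", "auroc", "train_loss"))) |>
    rename(bce = "train_loss")
  out$site <- factor(out$site, levels = unique(round_log$site))
  out
}

#' Strategy comparison table
#'
#' Combines experiment results into the familiar models-by-sites comparison:
#' one row per model family and strategy, one column per site, cells
#' `mean (low-high)` to 3 decimals. Missing grid cells render blank with a
#' warning.
#'
#' @param results A list of `fc_experiment` objects (or a pre-combined
#'   summary tibble with the same columns).
#' @return A wide character tibble.
#' @export
strategy_table <- function(results) {
  summary <- if (is.data.frame(results)) {
    results
  } else {
    purrr::list_rbind(lapply(results, function(r) r$summary))
  }
  grid <- summary |>
    mutate(cell = sprintf("%.3f (%.3f-%.3f)", .data$auroc_mean,
                          .data$ci_low, .data$ci_high)) |>
    select(all_of(c("family", "strategy", "site", "cell"))) |>
    pivot_wider(names_from = "site", values_from = "cell")
  if (anyNA(grid)) {
    warning("strategy table has missing cells; rendered blank")
    grid[is.na(grid)] <- ""
  }
  grid |>
    arrange(.data$family, factor(.data$strategy,
                                 levels = c("local", "pooled", "federated")))
}
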