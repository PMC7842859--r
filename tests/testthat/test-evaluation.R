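test_that("AUROC equals exhaustive pair counting and its closed forms", {
  expect_equal(auroc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_equal(auroc(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1.0)
  expect_equal(auroc(c(0, 1, 0, 1), rep(0.4, 4)), 0.5)
  withr::with_seed(21, {
    for (rep in 1:100) {
      n <- sample(10:200, 1)
      y <- rbinom(n, 1, runif(1, 0.2, 0.8))
      if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
      # coarse grid forces ties
      s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
      expect_equal(auroc(y, s), auroc_oracle(y, s), tolerance = 1e-12)
    }
  })
  expect_error(auroc(rep(1, 5), runif(5)), "both classes")
})

test_that("AUROC is monotone-invariant and label-flip symmetric", {
  withr::with_seed(3, {
    y <- rbinom(50, 1, 0.4)
    s <- rnorm(50) # continuous: ties have probability zero
  })
  expect_equal(auroc(y, exp(2 * s)), auroc(y, s))
  expect_equal(auroc(y, rank(s)), auroc(y, s))
  expect_equal(auroc(1 - y, s), 1 - auroc(y, s))
})

test_that("percentile intervals follow the stated interpolation rule", {
  expect_equal(ci_from_iterations(rep(0.7, 5)),
               tibble::tibble(mean = 0.7, low = 0.7, high = 0.7))
  got <- ci_from_iterations(as.numeric(1:100))
  expect_equal(got$mean, 50.5)
  expect_equal(got$low, 3.475)    # 1 + 0.025 * 99
  expect_equal(got$high, 97.525)  # 1 + 0.975 * 99
  # mean inside the interval for unimodal samples
  withr::with_seed(9, {
    for (rep in 1:10) {
      v <- rnorm(200, mean = runif(1, -2, 2))
      ci <- ci_from_iterations(v)
      expect_true(ci$low <= ci$mean && ci$mean <= ci$high)
    }
  })
  norm <- ci_from_iterations(as.numeric(1:100), method = "normal")
  expect_true(norm$low < got$low)
  expect_error(ci_from_iterations(0.5), "at least 2")
})

test_that("bootstrap harness is deterministic and covers the site grid", {
  cohorts <- tiny_system(seed = 2)
  boot <- bootstrap_config(n_iterations = 2, master_seed = 11)
  fed_cfg <- federation_config(rounds = 5, seed = 11)
  ex <- run_bootstrap(cohorts, "lasso", "federated",
                      train_config(batch_size = 0, learning_rate = 0.1,
                                   optimizer = "sgd"),
                      fed_cfg = fed_cfg, boot_cfg = boot)
  expect_s3_class(ex, "fc_experiment")
  expect_equal(nrow(ex$samples), 2 * 2) # iterations x evaluation sites
  expect_true(all(ex$samples$auroc >= 0 & ex$samples$auroc <= 1))
  expect_equal(sort(ex$summary$site), c("S1", "S2"))
  expect_true(all(ex$summary$ci_low <= ex$summary$auroc_mean &
                    ex$summary$auroc_mean <= ex$summary$ci_high))
  ex2 <- run_bootstrap(cohorts, "lasso", "federated",
                       train_config(batch_size = 0, learning_rate = 0.1,
                                    optimizer = "sgd"),
                       fed_cfg = fed_cfg, boot_cfg = boot)
  expect_identical(ex$samples, ex2$samples)
  # B = 1 yields a degenerate summary (single iteration)
  one <- run_bootstrap(cohorts, "lasso", "pooled",
                       train_config(batch_size = 0, learning_rate = 0.1,
                                    optimizer = "sgd"),
                       boot_cfg = bootstrap_config(n_iterations = 1,
                                                   master_seed = 1))
  expect_equal(unique(one$summary$n_iterations), 1)
  # local strategy keeps the full train-site x test-site matrix
  loc <- run_bootstrap(cohorts, "lasso", "local",
                       train_config(batch_size = 0, learning_rate = 0.1,
                                    optimizer = "sgd"),
                       boot_cfg = bootstrap_config(n_iterations = 1,
                                                   master_seed = 1))
  expect_equal(nrow(loc$samples), 4) # 2 models x 2 test sites
  diag_rows <- loc$samples[loc$samples$train_site == loc$samples$site, ]
  expect_equal(nrow(diag_rows), 2)
})

test_that("tidy/glance and the strategy table summarize experiments", {
  cohorts <- tiny_system(seed = 4)
  cfg <- train_config(batch_size = 0, learning_rate = 0.1, optimizer = "sgd")
  boot <- bootstrap_config(n_iterations = 2, master_seed = 3)
  exps <- list(
    run_bootstrap(cohorts, "lasso", "local", cfg, boot_cfg = boot),
    run_bootstrap(cohorts, "lasso", "pooled", cfg, boot_cfg = boot)
  )
  expect_equal(tidy(exps[[1]]), exps[[1]]$summary)
  gl <- glance(exps[[1]])
  expect_equal(gl$n_iterations, 2)
  st <- strategy_table(exps)
  expect_equal(nrow(st), 2)
  expect_named(st, c("family", "strategy", "S1", "S2"))
  expect_match(st$S1[1], "^0\\.\\d{3} \\(0\\.\\d{3}-0\\.\\d{3}\\)$")
  # cells parse back to numbers through CSV
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(st, path)
  expect_equal(nrow(readr::read_csv(path, show_col_types = FALSE)), 2)
  # a missing grid cell warns and renders blank
  combined <- dplyr::bind_rows(exps[[1]]$summary, exps[[2]]$summary)
  expect_warning(st2 <- strategy_table(combined[-1, ]), "missing")
  expect_true(any(st2 == ""))
})

test_that("learning curves trend and preserve site order", {
  sites <- list(random_site(60, 5, seed = 1), random_site(40, 5, seed = 2))
  fed <- run_federated(sites, "lasso",
                       train_config(learning_rate = 0.2, batch_size = 0,
                                    optimizer = "sgd"),
                       federation_config(rounds = 15, seed = 4),
                       eval_sites = sites)
  curves <- learning_curves(fed$log)
  expect_equal(levels(curves$site), c("site1", "site2"))
  for (s in unique(curves$site)) {
    series <- curves[curves$site == s, ]
    expect_equal(nrow(series), 15)
    # a converging run ends below its starting loss
    expect_lt(series$bce[15], series$bce[1])
  }
  expect_error(learning_curves(fed$log[0, ]), "empty")
})

test_that("experiment and curve plots build without evaluation errors", {
  cohorts <- tiny_system(seed = 7)
  ex <- run_bootstrap(cohorts, "lasso", "pooled",
                      train_config(batch_size = 0, learning_rate = 0.1,
                                   optimizer = "sgd"),
                      boot_cfg = bootstrap_config(n_iterations = 2,
                                                  master_seed = 5))
  p1 <- autoplot(ex)
  expect_s3_class(p1, "ggplot")
  sites <- list(random_site(30, 4, seed = 1))
  fed <- run_federated(sites, "lasso", train_config(),
                       federation_config(rounds = 3, seed = 1),
                       eval_sites = sites)
  p2 <- autoplot(fed$log)
  expect_s3_class(p2, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p1))
  expect_no_error(ggplot2::ggplot_build(p2))
})

test_that("AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(14, {
    for (rep in 1:5) {
      y <- rbinom(80, 1, 0.4)
      if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
      s <- sample(seq(0, 1, 0.1), 80, replace = TRUE)
      ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                            direction = "<")))
      expect_equal(auroc(y, s), ref, tolerance = 1e-12)
    }
  })
})
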