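test_that("federated averaging implements the n-weighted mean exactly", {
  arch <- lasso_architecture(1)
  scalar_params <- function(w) {
    p <- init_params(arch, 1)
    p$layers[[1]]$W[] <- w
    p$layers[[1]]$b <- 0
    p
  }
  # single update passes through bit-identically
  single <- init_params(lasso_architecture(4), seed = 2)
  expect_identical(federated_average(list(list(params = single, n = 50))),
                   single)
  # equal n: plain mean
  avg <- federated_average(list(list(params = scalar_params(1), n = 10),
                                list(params = scalar_params(2), n = 10)))
  expect_equal(avg$layers[[1]]$W[1, 1], 1.5)
  # (n=100, w=1) + (n=300, w=2) -> 1.75
  avg <- federated_average(list(list(params = scalar_params(1), n = 100),
                                list(params = scalar_params(2), n = 300)))
  expect_equal(avg$layers[[1]]$W[1, 1], 1.75)
  # convex-combination property: entrywise within site min/max
  ups <- lapply(1:4, function(s) {
    list(params = init_params(mlp_architecture(5, hidden = 3), seed = s),
         n = s * 10)
  })
  avg <- federated_average(ups)
  for (l in seq_along(avg$layers)) {
    stack <- sapply(ups, function(u) as.vector(u$params$layers[[l]]$W))
    v <- as.vector(avg$layers[[l]]$W)
    expect_true(all(v >= apply(stack, 1, min) - 1e-12))
    expect_true(all(v <= apply(stack, 1, max) + 1e-12))
  }
  # errors
  expect_error(federated_average(list()), "no site updates")
  expect_error(federated_average(list(
    list(params = init_params(lasso_architecture(3), 1), n = 5),
    list(params = init_params(lasso_architecture(4), 1), n = 5)
  )), "mismatch")
})

test_that("Gaussian parameter noise honors sigma, seed and identity", {
  params <- init_params(lasso_architecture(9999), seed = 1)
  expect_identical(add_gaussian_noise(params, 0, seed = 4), params)
  noised <- add_gaussian_noise(params, 1, seed = 4)
  delta <- c(noised$layers[[1]]$W - params$layers[[1]]$W,
             noised$layers[[1]]$b - params$layers[[1]]$b)
  expect_length(delta, 10000)
  expect_gt(sd(delta), 0.97)
  expect_lt(sd(delta), 1.03)
  expect_identical(add_gaussian_noise(params, 1, seed = 4), noised)
  expect_error(add_gaussian_noise(params, -0.1, seed = 1), "non-negative")
})

test_that("noise is neutral in expectation through the aggregator", {
  params <- init_params(lasso_architecture(3), seed = 5)
  sigma <- 0.5
  sums <- numeric(4)
  n_seeds <- 600
  for (s in seq_len(n_seeds)) {
    out <- federated_average(list(list(
      params = add_gaussian_noise(params, sigma, seed = s), n = 10
    )))
    sums <- sums + c(out$layers[[1]]$W, out$layers[[1]]$b)
  }
  se <- sigma / sqrt(n_seeds)
  expect_true(all(abs(sums / n_seeds -
                        c(params$layers[[1]]$W, params$layers[[1]]$b)) < 4 * se))
})

test_that("degenerate federation equals local training", {
  site <- random_site(50, 6, seed = 2)
  cfg <- train_config(batch_size = 0, optimizer = "sgd", learning_rate = 0.1,
                      l1_lambda = 0)
  fed <- run_federated(list(site), "lasso", cfg,
                       federation_config(rounds = 5, seed = 3))
  loc <- run_local(site, "lasso", cfg, epochs = 5, seed = 3)
  expect_equal(flatten_params(fed$params), flatten_params(loc$params),
               tolerance = 1e-12)
})

test_that("federated averaging reproduces pooled gradient descent", {
  # full-batch plain SGD, 1 local epoch, no noise: the pooled mean-loss
  # gradient is the n-weighted mean of site gradients, so R rounds of
  # federation equal R pooled steps.
  sites <- list(random_site(60, 8, seed = 1), random_site(40, 8, seed = 2),
                random_site(20, 8, seed = 3))
  cfg <- train_config(learning_rate = 0.2, batch_size = 0, optimizer = "sgd",
                      l1_lambda = 0)
  for (family in c("lasso", "mlp")) {
    fed <- run_federated(sites, family, cfg,
                         federation_config(rounds = 20, seed = 7))
    pooled <- run_pooled(sites, family, cfg, epochs = 20, seed = 7)
    f <- flatten_params(fed$params); p <- flatten_params(pooled$params)
    expect_lt(max(abs(f - p) / pmax(abs(p), 1e-12)), 1e-8)
  }
  # identical data at every site matches pooled round-for-round too
  copies <- list(sites[[1]], sites[[1]], sites[[1]])
  fed <- run_federated(copies, "lasso", cfg, federation_config(rounds = 8, seed = 1))
  pooled <- run_pooled(copies, "lasso", cfg, epochs = 8, seed = 1)
  expect_equal(flatten_params(fed$params), flatten_params(pooled$params),
               tolerance = 1e-10)
})

test_that("round log records losses, evaluation AUROC and param hashes", {
  sites <- list(random_site(40, 4, seed = 4), random_site(30, 4, seed = 5))
  evals <- list(random_site(20, 4, seed = 6), random_site(20, 4, seed = 7))
  fed <- run_federated(sites, "mlp", train_config(),
                       federation_config(rounds = 3, seed = 2),
                       eval_sites = evals)
  expect_s3_class(fed$log, "fc_round_log")
  expect_equal(nrow(fed$log), 6) # 3 rounds x 2 sites
  expect_true(all(is.finite(fed$log$train_loss)))
  expect_true(all(fed$log$auroc >= 0 & fed$log$auroc <= 1))
  # one hash per round, shared across sites within a round
  expect_equal(length(unique(fed$log$params_hash)), 3)
  curves <- learning_curves(fed$log)
  expect_equal(nrow(curves), 6)
  expect_named(curves, c("round", "site", "auroc", "bce"))
  # rounds = 1 performs exactly one aggregation
  one <- run_federated(sites, "mlp", train_config(),
                       federation_config(rounds = 1, seed = 2))
  expect_equal(max(one$log$round), 1)
  expect_error(federation_config(rounds = 0), ">= 1")
})

test_that("a diverging site is reported with its name and round", {
  sites <- list(list(x = matrix(1e160, 4, 1, dimnames = list(NULL, "x1")),
                     y = c(0, 1, 0, 1), name = "fragile"))
  expect_error(
    run_federated(sites, "lasso",
                  train_config(learning_rate = 1e250, batch_size = 0,
                               optimizer = "sgd"),
                  federation_config(rounds = 2, seed = 1)),
    "fragile.*round"
  )
})

test_that("pooled training concatenates sites in order", {
  sites <- list(random_site(30, 3, seed = 8), random_site(20, 3, seed = 9))
  cfg <- train_config(batch_size = 0, optimizer = "sgd", l1_lambda = 0)
  pooled <- run_pooled(sites, "lasso", cfg, epochs = 3, seed = 1)
  manual <- run_local(list(x = rbind(sites[[1]]$x, sites[[2]]$x),
                           y = c(sites[[1]]$y, sites[[2]]$y)),
                      "lasso", cfg, epochs = 3, seed = 1)
  expect_equal(flatten_params(pooled$params), flatten_params(manual$params))
  expect_error(run_pooled(list(random_site(10, 3, 1), random_site(10, 4, 2)),
                          "lasso"), "mismatch")
  # training loss is non-increasing on a convex full-batch problem
  site <- random_site(80, 4, seed = 10)
  fit <- run_local(site, "lasso",
                   train_config(learning_rate = 0.05, batch_size = 0,
                                optimizer = "sgd", l1_lambda = 0),
                   epochs = 40, seed = 1)
  expect_true(all(diff(fit$log$loss) <= 1e-12))
})
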