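test_that("parameter initialization is shaped, bounded and seeded", {
  lp <- init_params(lasso_architecture(10), seed = 1)
  expect_length(lp$layers, 1)
  expect_equal(dim(lp$layers[[1]]$W), c(10, 1))
  expect_equal(lp$layers[[1]]$b, 0)
  lim <- sqrt(6 / 11)
  expect_true(all(abs(lp$layers[[1]]$W) <= lim))
  expect_identical(lp, init_params(lasso_architecture(10), seed = 1))
  expect_false(identical(lp$layers[[1]]$W,
                         init_params(lasso_architecture(10), seed = 2)$layers[[1]]$W))

  mp <- init_params(mlp_architecture(8, hidden = c(6, 4)), seed = 3)
  expect_length(mp$layers, 3)
  expect_equal(dim(mp$layers[[1]]$W), c(8, 6))
  expect_equal(dim(mp$layers[[2]]$W), c(6, 4))
  expect_equal(dim(mp$layers[[3]]$W), c(4, 1))
})

test_that("predict_proba implements the forward pass exactly", {
  # all-zero parameters score 0.5 everywhere
  p0 <- init_params(mlp_architecture(4), seed = 1)
  for (l in seq_along(p0$layers)) p0$layers[[l]]$W[] <- 0
  x <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("x", 1:4)))
  expect_equal(predict_proba(p0, x), rep(0.5, 5))
  # single-layer closed form: sigmoid(w.x + b)
  lp <- init_params(lasso_architecture(4), seed = 2)
  lp$layers[[1]]$b <- 0.3
  manual <- 1 / (1 + exp(-(drop(x %*% lp$layers[[1]]$W) + 0.3)))
  expect_equal(predict_proba(lp, x), manual, tolerance = 1e-12)
  # scores strictly inside (0, 1)
  mp <- init_params(mlp_architecture(4), seed = 3)
  s <- predict_proba(mp, x)
  expect_true(all(s > 0 & s < 1))
  expect_error(predict_proba(lp, x[, 1:3]), "expects")
})

test_that("binary cross-entropy matches its closed forms", {
  expect_equal(bce_loss(1, 0.5), log(2))
  expect_equal(bce_loss(c(1, 0), c(1, 0)), 0, tolerance = 1e-10)
  # mean property over equal-size batches
  y <- c(1, 0, 1, 0); p <- c(0.8, 0.3, 0.6, 0.1)
  expect_equal(bce_loss(y, p),
               mean(c(bce_loss(y[1:2], p[1:2]), bce_loss(y[3:4], p[3:4]))))
  # weights reweight the mean
  expect_equal(bce_loss(c(1, 0), c(0.6, 0.6), weights = c(2, 1)),
               (2 * -log(0.6) + 1 * -log(0.4)) / 3)
})

test_that("backpropagated gradients match central finite differences", {
  site <- random_site(5, 3, seed = 10)
  for (arch in list(lasso_architecture(3), mlp_architecture(3, hidden = 4))) {
    params <- init_params(arch, seed = 4)
    analytic <- fedcohort:::bce_gradient(params, site$x, site$y)$grads
    numeric <- numeric_gradient(params, site$x, site$y)
    for (l in seq_along(analytic)) {
      expect_equal(as.vector(analytic[[l]]$W), as.vector(numeric[[l]]$W),
                   tolerance = 1e-5)
      expect_equal(as.vector(analytic[[l]]$b), as.vector(numeric[[l]]$b),
                   tolerance = 1e-5)
    }
  }
})

test_that("train_epoch respects limits, penalties and determinism", {
  site <- random_site(40, 5, seed = 3)
  params <- init_params(lasso_architecture(5), seed = 1)
  # vanishing learning rate leaves parameters unchanged
  tiny <- train_epoch(params, site$x, site$y,
                      train_config(learning_rate = 1e-15, batch_size = 0,
                                   optimizer = "sgd", l1_lambda = 0))
  expect_equal(flatten_params(tiny$params), flatten_params(params),
               tolerance = 1e-12)
  # one full-batch sgd step equals params - lr * gradient
  lr <- 0.05
  step <- train_epoch(params, site$x, site$y,
                      train_config(learning_rate = lr, batch_size = 0,
                                   optimizer = "sgd", l1_lambda = 0))
  g <- fedcohort:::bce_gradient(params, site$x, site$y)$grads
  expect_equal(step$params$layers[[1]]$W, params$layers[[1]]$W - lr * g[[1]]$W,
               tolerance = 1e-12)
  # full batch removes all seed dependence
  a <- train_epoch(params, site$x, site$y,
                   train_config(batch_size = 0), seed = 1)
  b <- train_epoch(params, site$x, site$y,
                   train_config(batch_size = 0), seed = 999)
  expect_identical(flatten_params(a$params), flatten_params(b$params))
  # overwhelming L1 zeroes all weights (bias spared)
  crushed <- train_epoch(params, site$x, site$y,
                         train_config(learning_rate = 0.1, l1_lambda = 1e6,
                                      batch_size = 0, optimizer = "sgd"))
  expect_true(all(crushed$params$layers[[1]]$W == 0))
  # divergent learning rate raises
  expect_error(
    train_epoch(params, site$x * 1e150, site$y,
                train_config(learning_rate = 1e200, batch_size = 0,
                             optimizer = "sgd")),
    "divergent|non-finite"
  )
})

test_that("L1 path: weight sparsity is non-decreasing in lambda", {
  site <- random_site(60, 8, seed = 6)
  zeros <- vapply(c(0, 0.05, 0.2, 1, 10), function(lam) {
    params <- init_params(lasso_architecture(8), seed = 2)
    cfg <- train_config(learning_rate = 0.1, batch_size = 0,
                        optimizer = "sgd", l1_lambda = lam)
    for (e in 1:20) params <- train_epoch(params, site$x, site$y, cfg)$params
    sum(params$layers[[1]]$W == 0)
  }, numeric(1))
  expect_true(all(diff(zeros) >= 0))
  expect_equal(zeros[length(zeros)], 8)
})

test_that("LASSO separates linearly separable toy data perfectly", {
  withr::with_seed(11, {
    x <- matrix(rnorm(120), 60, 2, dimnames = list(NULL, c("u", "v")))
    y <- as.integer(x[, 1] + x[, 2] > 0)
  })
  params <- init_params(lasso_architecture(2), seed = 1)
  cfg <- train_config(learning_rate = 1, batch_size = 0, optimizer = "sgd",
                      l1_lambda = 1e-3)
  for (e in 1:500) params <- train_epoch(params, x, y, cfg)$params
  expect_equal(auroc(y, predict_proba(params, x)), 1.0)
})

test_that("parameters serialize to JSON and back without loss", {
  for (arch in list(lasso_architecture(6), mlp_architecture(6, hidden = 5))) {
    params <- init_params(arch, seed = 9)
    back <- params_from_json(params_to_json(params))
    expect_equal(back$layers, params$layers, tolerance = 1e-15)
    expect_equal(unclass(back$arch), unclass(params$arch))
  }
})

test_that("tidy and glance expose coefficients and sparsity", {
  site <- random_site(50, 4, seed = 5)
  params <- init_params(lasso_architecture(4), seed = 2)
  td <- tidy(params)
  expect_equal(td$term[1], "(Intercept)")
  expect_equal(nrow(td), 5)
  gl <- glance(params)
  expect_equal(gl$n_parameters, 5)
  mlp <- init_params(mlp_architecture(4, hidden = 3), seed = 2)
  expect_equal(nrow(tidy(mlp)), glance(mlp)$n_parameters)
})

test_that("proximal-L1 training converges to the glmnet solution", {
  skip_if_not_installed("glmnet")
  withr::with_seed(3, {
    n <- 200; d <- 5
    x <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("x", 1:d)))
    y <- rbinom(n, 1, plogis(x[, 1] - 0.5 * x[, 2]))
  })
  lam <- 0.05
  params <- init_params(lasso_architecture(d), seed = 1)
  cfg <- train_config(learning_rate = 0.5, batch_size = 0, optimizer = "sgd",
                      l1_lambda = lam)
  for (e in 1:4000) params <- train_epoch(params, x, y, cfg)$params
  mine <- unname(c(params$layers[[1]]$b, drop(params$layers[[1]]$W)))
  ref <- as.numeric(glmnet::coef.glmnet(glmnet::glmnet(
    x, y, family = "binomial", lambda = lam, standardize = FALSE,
    thresh = 1e-12)))
  # both minimize mean BCE + lam * ||w||_1; solutions coincide, zeros included
  expect_equal(mine, ref, tolerance = 1e-6)
  expect_equal(mine[4:6], rep(0, 3))
})
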