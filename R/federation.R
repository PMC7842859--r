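#' Federation configuration
#'
#' The aggregator contract: number of aggregation rounds, local epochs per
#' site per round (the reference protocol uses 1), the standard deviation of
#' Gaussian noise each site adds to its outgoing parameters (0 disables
#' noise), and the seed that derives all federation randomness.
#'
#' @param rounds Aggregation cycles, at least 1. Defaults to 50 for LASSO
#'   and 30 for the MLP when left `NULL` in the experiment harness.
#' @param local_epochs Epochs each site trains per round (default 1).
#' @param noise_sigma Per-entry Gaussian noise sd, >= 0 (default 0).
#' @param seed Integer seed.
#' @return An `fc_fed_config`.
#' @export
federation_config <- function(rounds = 50, local_epochs = 1, noise_sigma = 0,
                              seed = 1) {
  if (rounds < 1 || rounds != round(rounds)) abort("`rounds` must be an integer >= 1")
  if (local_epochs < 1) abort("`local_epochs` must be >= 1")
  if (noise_sigma < 0) abort("`noise_sigma` must be non-negative")
  structure(list(rounds = as.integer(rounds),
                 local_epochs = as.integer(local_epochs),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "fc_fed_config")
}

default_rounds <- function(family) switch(family, lasso = 50L, mlp = 30L)

#' Sample-weighted federated averaging
#'
#' The aggregation rule at the heart of the federated strategy: every layer
#' entry of the global model is the mean of the corresponding site entries,
#' weighted by each site's available sample count, i.e.
#' `sum_k (n_k / sum_j n_j) * value_k`. No other transformation is applied,
#' so each aggregated entry lies between the smallest and largest site
#' value.
#'
#' @param updates Non-empty list of site updates, each a list with `params`
#'   (an `fc_params`) and `n` (positive training-sample count).
#' @return The aggregated `fc_params`.
#' @export
#' @examples
#' arch <- lasso_architecture(2)
#' a <- init_params(arch, 1); b <- init_params(arch, 2)
#' avg <- federated_average(list(list(params = a, n = 100),
#'                               list(params = b, n = 300)))
federated_average <- function(updates) {
  if (length(updates) == 0) abort("no site updates to average")
  archs <- lapply(updates, function(u) u$params$arch)
  for (a in archs[-1]) {
    if (!identical(unclass(a), unclass(archs[[1]]))) {
      abort("site updates have mismatched architectures")
    }
  }
  ns <- vapply(updates, function(u) u$n, numeric(1))
  if (any(ns <= 0)) abort("site sample counts must be positive")
  w <- ns / sum(ns)
  out <- updates[[1]]$params
  for (l in seq_along(out$layers)) {
    out$layers[[l]]$W <- Reduce(`+`, lapply(seq_along(updates), function(k) {
      w[k] * updates[[k]]$params$layers[[l]]$W
    }))
    out$layers[[l]]$b <- Reduce(`+`, lapply(seq_along(updates), function(k) {
      w[k] * updates[[k]]$params$layers[[l]]$b
    }))
  }
  out
}

#' Perturb parameters with Gaussian noise
#'
#' Adds independent Normal(0, sigma^2) noise to every weight and bias entry;
#' the privacy-motivated variant in which sites perturb parameters before
#' transmitting them to the aggregator. `sigma = 0` returns an exact copy.
#'
#' @param params An `fc_params`.
#' @param sigma Noise standard deviation, >= 0.
#' @param seed Integer seed; the same seed reproduces the perturbation.
#' @return A perturbed `fc_params`.
#' @export
add_gaussian_noise <- function(params, sigma, seed) {
  if (sigma < 0) abort("`sigma` must be non-negative")
  if (sigma == 0) return(params)
  with_seed(seed, {
    for (l in seq_along(params$layers)) {
      params$layers[[l]]$W <- params$layers[[l]]$W +
        matrix(rnorm(length(params$layers[[l]]$W), 0, sigma),
               nrow(params$layers[[l]]$W))
      params$layers[[l]]$b <- params$layers[[l]]$b +
        rnorm(length(params$layers[[l]]$b), 0, sigma)
    }
    params
  })
}

site_training_data <- function(site, weights_ok = TRUE) {
  if (!is.list(site) || is.null(site$x) || is.null(site$y)) {
    abort("each site needs `x` and `y` (and optionally `weights`, `name`)")
  }
  site
}

#' Run the federated training strategy
#'
#' Simulates the central-aggregator protocol: the aggregator initializes a
#' global model from the federation seed; each round it sends the current
#' global parameters to every site, each site trains `local_epochs` epochs
#' on its own data only (optimizer state never leaves the site and is reset
#' every round; only weights and biases are exchanged), optionally perturbs
#' its outgoing parameters with Gaussian noise, and the aggregator replaces
#' the global model with the sample-count-weighted average of the site
#' parameters. Sites never see another site's rows.
#'
#' @param sites Non-empty list of per-site training data: each element a
#'   list with `x` (matrix), `y` (0/1 labels), optional `weights` and
#'   `name`.
#' @param family `"lasso"` or `"mlp"`.
#' @param train_cfg An `fc_train_config`.
#' @param fed_cfg An `fc_fed_config`.
#' @param eval_sites Optional list (parallel structure) of held-out data on
#'   which per-round AUROC is recorded.
#' @param arch Optional explicit `fc_arch`; defaults to the family's
#'   standard architecture at the data's input width.
#' @return List with `params` (final global model) and `log` (an
#'   `fc_round_log` tibble: round, site, train_loss, auroc, params_hash).
#' @export
run_federated <- function(sites, family = c("lasso", "mlp"),
                          train_cfg = train_config(),
                          fed_cfg = federation_config(),
                          eval_sites = NULL, arch = NULL) {
  family <- match.arg(family)
  if (length(sites) == 0) abort("need at least one site")
  sites <- lapply(sites, site_training_data)
  d <- ncol(sites[[1]]$x)
  arch <- arch %||% switch(family, lasso = lasso_architecture(d),
                           mlp = mlp_architecture(d))
  site_names <- purrr::imap_chr(sites, function(s, i) s$name %||% paste0("site", i))
  global <- init_params(arch, fed_cfg$seed)
  log_rows <- vector("list", fed_cfg$rounds)

  for (r in seq_len(fed_cfg$rounds)) {
    updates <- vector("list", length(sites))
    losses <- numeric(length(sites))
    for (k in seq_along(sites)) {
      s <- sites[[k]]
      params_k <- global
      opt_state <- NULL  # optimizer state stays local and restarts each round
      loss_k <- NA_real_
      for (e in seq_len(fed_cfg$local_epochs)) {
        step <- tryCatch(
          train_epoch(params_k, s$x, s$y, train_cfg,
                      seed = fed_cfg$seed + 1009L * r + 131L * k + e,
                      weights = s$weights, opt_state = opt_state),
          error = function(err) {
            abort(sprintf("site %s diverged at round %d: %s",
                          site_names[k], r, conditionMessage(err)))
          }
        )
        params_k <- step$params; opt_state <- step$opt_state
        loss_k <- step$loss
      }
      if (fed_cfg$noise_sigma > 0) {
        params_k <- add_gaussian_noise(params_k, fed_cfg$noise_sigma,
                                       seed = fed_cfg$seed + 7919L * r + k)
      }
      updates[[k]] <- list(params = params_k, n = nrow(s$x))
      losses[k] <- loss_k
    }
    global <- federated_average(updates)
    auroc_r <- rep(NA_real_, length(sites))
    if (!is.null(eval_sites)) {
      auroc_r <- vapply(eval_sites, function(ev) {
        auroc(ev$y, predict_proba(global, ev$x))
      }, numeric(1))
    }
    log_rows[[r]] <- tibble(
      round = r, site = site_names, train_loss = losses, auroc = auroc_r,
      params_hash = rlang::hash(global$layers)
    )
  }
  log <- purrr::list_rbind(log_rows)
  class(log) <- c("fc_round_log", class(log))
  list(params = global, log = log)
}

#' Run the local training strategy
#'
#' Conventional training on a single site's data for a fixed number of
#' epochs, threading optimizer state across epochs. This is both the local
#' baseline strategy and the building block the pooled strategy reuses.
#'
#' @param site One site's training data (list with `x`, `y`, optional
#'   `weights`, `name`).
#' @param family `"lasso"` or `"mlp"`.
#' @param train_cfg An `fc_train_config`.
#' @param epochs Training epochs; defaults to the family's standard round
#'   count so local, pooled and federated models see the data equally often.
#' @param seed Integer seed (initialization and batch shuffles).
#' @param arch Optional explicit `fc_arch`.
#' @return List with `params` and `log` (tibble: epoch, loss).
#' @export
run_local <- function(site, family = c("lasso", "mlp"),
                      train_cfg = train_config(), epochs = NULL, seed = 1,
                      arch = NULL) {
  family <- match.arg(family)
  site <- site_training_data(site)
  epochs <- epochs %||% default_rounds(family)
  d <- ncol(site$x)
  arch <- arch %||% switch(family, lasso = lasso_architecture(d),
                           mlp = mlp_architecture(d))
  params <- init_params(arch, seed)
  opt_state <- NULL
  losses <- numeric(epochs)
  for (e in seq_len(epochs)) {
    step <- train_epoch(params, site$x, site$y, train_cfg,
                        seed = seed + 131L * e, weights = site$weights,
                        opt_state = opt_state)
    params <- step$params; opt_state <- step$opt_state
    losses[e] <- step$loss
  }
  list(params = params, log = tibble(epoch = seq_len(epochs), loss = losses))
}

#' Run the pooled training strategy
#'
#' Concatenates all sites' training rows (site order, then row order) into
#' one superset and trains on it as a single site — the idealized
#' full-data-sharing reference the federated strategy is compared against.
#'
#' @inheritParams run_federated
#' @param epochs,seed As in [run_local()].
#' @return List with `params` and `log`.
#' @export
run_pooled <- function(sites, family = c("lasso", "mlp"),
                       train_cfg = train_config(), epochs = NULL, seed = 1,
                       arch = NULL) {
  family <- match.arg(family)
  if (length(sites) == 0) abort("need at least one site")
  sites <- lapply(sites, site_training_data)
  widths <- vapply(sites, function(s) ncol(s$x), integer(1))
  if (length(unique(widths)) != 1) abort("sites have mismatched design widths")
  pooled <- list(
    x = do.call(rbind, lapply(sites, function(s) s$x)),
    y = unlist(lapply(sites, function(s) s$y), use.names = FALSE),
    weights = if (all(vapply(sites, function(s) is.null(s$weights), logical(1)))) {
      NULL
    } else {
      unlist(lapply(sites, function(s) s$weights %||% rep(1, nrow(s$x))),
             use.names = FALSE)
    },
    name = "pooled"
  )
  run_local(pooled, family, train_cfg, epochs = epochs, seed = seed, arch = arch)
}
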