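#' Model architectures
#'
#' Both classifier families share one trainable-parameter abstraction so the
#' federation layer can treat them uniformly. `lasso_architecture()` is a
#' single sigmoid layer (logistic regression) trained with a proximal L1
#' step — an iterative, parameter-space realization of L1-regularized
#' logistic regression whose parameters can be averaged across sites.
#' `mlp_architecture()` is a feed-forward network with rectifier hidden
#' layers and a single sigmoid output; the architecture is held identical
#' across all training strategies within one experiment.
#'
#' @param d Input width (number of encoded feature columns).
#' @param hidden Integer vector of hidden-layer widths (default 32).
#' @param activation Hidden activation, currently `"relu"`.
#' @return An `fc_arch` list with fields `family`, `input`, `hidden`,
#'   `activation`.
#' @export
lasso_architecture <- function(d) {
  structure(list(family = "lasso", input = as.integer(d), hidden = integer(0),
                 activation = "identity"), class = "fc_arch")
}

#' @rdname lasso_architecture
#' @export
mlp_architecture <- function(d, hidden = 32, activation = "relu") {
  if (length(hidden) < 1 || any(hidden < 1)) abort("need at least one hidden layer")
  activation <- match.arg(activation, "relu")
  structure(list(family = "mlp", input = as.integer(d),
                 hidden = as.integer(hidden), activation = activation),
            class = "fc_arch")
}

arch_layer_dims <- function(arch) {
  widths <- c(arch$input, arch$hidden, 1L)
  lapply(seq_len(length(widths) - 1), function(i) c(widths[i], widths[i + 1]))
}

#' Initialize model parameters
#'
#' Glorot-uniform weights (uniform on +/- sqrt(6 / (fan_in + fan_out))) and
#' zero biases, deterministic per seed. The returned object is the unit
#' exchanged with the central aggregator during federation.
#'
#' @param arch An `fc_arch` from [lasso_architecture()] or
#'   [mlp_architecture()].
#' @param seed Integer seed.
#' @return An `fc_params` object: ordered list of `(W, b)` layers plus the
#'   architecture tag.
#' @export
init_params <- function(arch, seed) {
  if (!inherits(arch, "fc_arch")) abort("`arch` must be an fc_arch")
  layers <- with_seed(seed, {
    lapply(arch_layer_dims(arch), function(dd) {
      lim <- sqrt(6 / (dd[1] + dd[2]))
      list(W = matrix(runif(dd[1] * dd[2], -lim, lim), dd[1], dd[2]),
           b = rep(0, dd[2]))
    })
  })
  structure(list(layers = layers, arch = arch), class = "fc_params")
}

#' @export
print.fc_params <- function(x, ...) {
  dims <- vapply(x$layers, function(l) paste(dim(l$W), collapse = "x"), character(1))
  cat(sprintf("<fc_params> %s: %s\n", x$arch$family, paste(dims, collapse = " -> ")))
  invisible(x)
}

n_parameters <- function(params) {
  sum(vapply(params$layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

# Forward pass; keeps pre-activations and activations for backprop.
forward_pass <- function(params, x) {
  L <- length(params$layers)
  a <- vector("list", L + 1)
  z <- vector("list", L)
  a[[1]] <- x
  for (l in seq_len(L)) {
    z[[l]] <- sweep(a[[l]] %*% params$layers[[l]]$W, 2, params$layers[[l]]$b, "+")
    a[[l + 1]] <- if (l < L) pmax(z[[l]], 0) else sigmoid(z[[l]])
  }
  list(a = a, z = z, p = drop(a[[L + 1]]))
}

#' Predicted risk scores
#'
#' Forward pass through the model: rectifier hidden layers (MLP only) and a
#' final sigmoid, returning a probability in (0, 1) per row.
#'
#' @param params An `fc_params`.
#' @param x Numeric matrix whose width matches the model input.
#' @return Numeric vector of risk scores.
#' @export
predict_proba <- function(params, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != params$arch$input) {
    abort(sprintf("input has %d columns; model expects %d", ncol(x), params$arch$input))
  }
  forward_pass(params, x)$p
}

#' Binary cross-entropy loss
#'
#' Weighted mean of `-[y log p + (1 - y) log(1 - p)]` with scores clipped to
#' \[1e-12, 1 - 1e-12\]; the negative Bernoulli log-likelihood the trainers
#' minimize and the learning curves report.
#'
#' @param y Binary labels.
#' @param p Predicted risks.
#' @param weights Optional per-observation weights (default uniform).
#' @return Non-negative scalar.
#' @export
bce_loss <- function(y, p, weights = NULL) {
  if (length(y) != length(p)) abort("`y` and `p` must have equal length")
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ll <- -(y * log(p) + (1 - y) * log(1 - p))
  if (is.null(weights)) mean(ll) else sum(weights * ll) / sum(weights)
}

#' Training configuration
#'
#' @param learning_rate Positive step size (default 1e-3).
#' @param batch_size Mini-batch size; 0 means full batch (default 32).
#' @param l1_lambda L1 penalty strength, applied to LASSO weights through a
#'   proximal soft-threshold of magnitude `learning_rate * l1_lambda` after
#'   each update; biases are never penalized (default 1e-3).
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @return An `fc_train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 32,
                         l1_lambda = 1e-3, optimizer = c("adam", "sgd")) {
  if (learning_rate <= 0) abort("`learning_rate` must be positive")
  if (l1_lambda < 0) abort("`l1_lambda` must be non-negative")
  if (batch_size < 0 || batch_size != round(batch_size)) {
    abort("`batch_size` must be a non-negative integer (0 = full batch)")
  }
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 l1_lambda = l1_lambda, optimizer = match.arg(optimizer)),
            class = "fc_train_config")
}

# Back-propagated gradient of the weighted-mean BCE for one batch.
# Returns (W, b) gradients matching params$layers plus the batch loss.
bce_gradient <- function(params, x, y, weights = NULL) {
  fp <- forward_pass(params, x)
  L <- length(params$layers)
  w <- if (is.null(weights)) rep(1, length(y)) else weights
  wn <- w / sum(w)
  delta <- matrix((fp$p - y) * wn, ncol = 1)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(fp$a[[l]], delta),
                       b = colSums(delta))
    if (l > 1) {
      delta <- (delta %*% t(params$layers[[l]]$W)) * (fp$z[[l - 1]] > 0)
    }
  }
  list(grads = grads, loss = bce_loss(y, fp$p, weights))
}

new_opt_state <- function(params) {
  list(t = 0, m = lapply(params$layers, function(l) {
    list(W = l$W * 0, b = l$b * 0)
  }), v = lapply(params$layers, function(l) {
    list(W = l$W * 0, b = l$b * 0)
  }))
}

apply_update <- function(params, grads, cfg, state) {
  L <- length(params$layers)
  lr <- cfg$learning_rate
  if (cfg$optimizer == "sgd") {
    for (l in seq_len(L)) {
      params$layers[[l]]$W <- params$layers[[l]]$W - lr * grads[[l]]$W
      params$layers[[l]]$b <- params$layers[[l]]$b - lr * grads[[l]]$b
    }
  } else {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    state$t <- state$t + 1
    corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
    for (l in seq_len(L)) {
      for (part in c("W", "b")) {
        g <- grads[[l]][[part]]
        state$m[[l]][[part]] <- b1 * state$m[[l]][[part]] + (1 - b1) * g
        state$v[[l]][[part]] <- b2 * state$v[[l]][[part]] + (1 - b2) * g^2
        step <- lr * (state$m[[l]][[part]] / corr1) /
          (sqrt(state$v[[l]][[part]] / corr2) + eps)
        params$layers[[l]][[part]] <- params$layers[[l]][[part]] - step
      }
    }
  }
  if (params$arch$family == "lasso" && cfg$l1_lambda > 0) {
    params$layers[[1]]$W <- soft_threshold(params$layers[[1]]$W,
                                           lr * cfg$l1_lambda)
  }
  list(params = params, state = state)
}

#' Train for one epoch
#'
#' One full pass over the data in mini-batches (shuffled by `seed`;
#' `batch_size = 0` trains on the full batch, removing all seed
#' dependence). Each batch applies a back-propagated gradient step of the
#' weighted-mean binary cross-entropy, followed — for the LASSO family — by
#' a proximal soft-threshold on the weights. Optimizer state (Adam moments)
#' can be threaded through consecutive epochs via `opt_state`.
#'
#' @param params An `fc_params`.
#' @param x,y Design matrix and binary labels.
#' @param cfg An `fc_train_config`.
#' @param seed Integer seed for the batch shuffle.
#' @param weights Optional per-row sample weights.
#' @param opt_state Optimizer state from a previous call, or `NULL` to start
#'   fresh.
#' @return List with `params`, `loss` (mean over batches of the batch
#'   training loss) and `opt_state`.
#' @export
train_epoch <- function(params, x, y, cfg = train_config(), seed = 1,
                        weights = NULL, opt_state = NULL) {
  n <- nrow(x)
  if (length(y) != n) abort("`y` length must equal nrow(x)")
  if (ncol(x) != params$arch$input) abort("input width does not match the model")
  if (is.null(opt_state)) opt_state <- new_opt_state(params)
  bs <- if (cfg$batch_size == 0) n else min(cfg$batch_size, n)
  order <- if (cfg$batch_size == 0) seq_len(n) else with_seed(seed, sample.int(n))
  starts <- seq(1, n, by = bs)
  losses <- numeric(length(starts))
  for (i in seq_along(starts)) {
    idx <- order[starts[i]:min(starts[i] + bs - 1, n)]
    xb <- x[idx, , drop = FALSE]; yb <- y[idx]
    wb <- if (is.null(weights)) NULL else weights[idx]
    bg <- bce_gradient(params, xb, yb, wb)
    losses[i] <- bg$loss
    upd <- apply_update(params, bg$grads, cfg, opt_state)
    params <- upd$params; opt_state <- upd$state
  }
  loss <- mean(losses)
  finite_params <- all(vapply(params$layers, function(l) {
    all(is.finite(l$W)) && all(is.finite(l$b))
  }, logical(1)))
  if (!is.finite(loss) || !finite_params) {
    abort("non-finite training loss or parameters: learning rate likely divergent")
  }
  list(params = params, loss = loss, opt_state = opt_state)
}

#' Serialize parameters to and from JSON
#'
#' Nested arrays plus the architecture tag: the wire format a site would
#' transmit to the central aggregator.
#'
#' @param params An `fc_params`.
#' @return `params_to_json()`: a JSON string; `params_from_json()`: an
#'   `fc_params`.
#' @export
params_to_json <- function(params) {
  jsonlite::toJSON(list(
    arch = unclass(params$arch),
    layers = lapply(params$layers, function(l) list(W = l$W, b = l$b))
  ), digits = NA)
}

#' @rdname params_to_json
#' @param json A JSON string from `params_to_json()`.
#' @export
params_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  arch <- structure(list(
    family = obj$arch$family, input = as.integer(obj$arch$input),
    hidden = as.integer(obj$arch$hidden), activation = obj$arch$activation
  ), class = "fc_arch")
  layers <- lapply(obj$layers, function(l) {
    W <- l$W
    if (!is.matrix(W)) W <- matrix(W, ncol = 1)
    list(W = W, b = as.numeric(l$b))
  })
  structure(list(layers = layers, arch = arch), class = "fc_params")
}
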