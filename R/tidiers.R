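#' Tidy model parameters
#'
#' For the LASSO family, one row per input feature with its coefficient (and
#' the intercept as term `(Intercept)`), mirroring the output of linear-model
#' tidiers; exact zeros are features the L1 penalty removed. For the MLP,
#' one row per scalar parameter with its layer, role and indices.
#'
#' @param x An `fc_params`.
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @method tidy fc_params
tidy.fc_params <- function(x, ...) {
  if (x$arch$family == "lasso") {
    W <- x$layers[[1]]$W
    terms <- rownames(W) %||% paste0("x", seq_len(nrow(W)))
    return(tibble(
      term = c("(Intercept)", terms),
      estimate = c(x$layers[[1]]$b, drop(W))
    ))
  }
  purrr::list_rbind(purrr::imap(x$layers, function(l, i) {
    bind_rows(
      tibble(layer = i, role = "weight",
             row = rep(seq_len(nrow(l$W)), ncol(l$W)),
             col = rep(seq_len(ncol(l$W)), each = nrow(l$W)),
             value = as.numeric(l$W)),
      tibble(layer = i, role = "bias", row = NA_integer_,
             col = seq_along(l$b), value = l$b)
    )
  }))
}

#' @rdname tidy.fc_params
#' @export
#' @method glance fc_params
glance.fc_params <- function(x, ...) {
  tibble(
    family = x$arch$family,
    n_layers = length(x$layers),
    n_parameters = n_parameters(x),
    n_zero_weights = sum(vapply(x$layers, function(l) sum(l$W == 0), numeric(1)))
  )
}

#' Tidy bootstrap experiment results
#'
#' `tidy()` returns the per-site summary (mean AUROC with 95% CI);
#' `glance()` a one-row overview.
#'
#' @param x An `fc_experiment` from [run_bootstrap()].
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @method tidy fc_experiment
tidy.fc_experiment <- function(x, ...) x$summary

#' @rdname tidy.fc_experiment
#' @export
#' @method glance fc_experiment
glance.fc_experiment <- function(x, ...) {
  tibble(
    family = x$family, strategy = x$strategy,
    n_sites = length(unique(x$summary$site)),
    n_iterations = x$boot_cfg$n_iterations,
    mean_auroc = mean(x$summary$auroc_mean),
    n_resplit_events = length(x$events)
  )
}

#' @rdname build_comparison_table
#' @param x An `fc_comparison`.
#' @param ... Unused.
#' @export
#' @method tidy fc_comparison
tidy.fc_comparison <- function(x, ...) as_tibble(as.data.frame(x))
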