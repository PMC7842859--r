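#' Design matrices
#'
#' A design matrix bundles the encoded numeric feature matrix `x` (with
#' column names), the binary outcome vector `y`, and the originating site
#' name. It is the unit all trainers, splitters and scalers operate on.
#'
#' @param x Numeric matrix with column names and no non-finite entries.
#' @param y Binary 0/1 outcome vector, one per row of `x`.
#' @param site Optional site label.
#' @return An `fc_design` object.
#' @export
design_matrix <- function(x, y, site = NA_character_) {
  if (!is.matrix(x) || is.null(colnames(x))) abort("`x` must be a matrix with column names")
  if (any(!is.finite(x))) abort("`x` must not contain non-finite entries")
  if (length(y) != nrow(x)) abort("`y` length must equal nrow(x)")
  if (!is_binary_vector(as.numeric(y))) abort("`y` must be binary 0/1")
  structure(list(x = x, y = as.integer(y), site = site), class = "fc_design")
}

#' @export
print.fc_design <- function(x, ...) {
  cat(sprintf("<fc_design> site=%s  %d x %d, prevalence %.3f\n",
              x$site, nrow(x$x), ncol(x$x), mean(x$y)))
  invisible(x)
}

#' Encode a cohort into a design matrix
#'
#' Deterministic encoding in schema order: binary features pass through as
#' 0/1, categorical features become one indicator per non-reference level
#' (the first schema level is the dropped reference), continuous features
#' pass through unchanged. Two cohorts sharing a schema always yield the
#' same column set, which is what lets locally encoded matrices be federated.
#'
#' @param cohort A cohort tibble from [generate_site()] or
#'   [read_cohort_csv()] (feature columns plus `outcome`).
#' @param schema The `fc_schema`; defaults to the one attached to `cohort`.
#' @return An `fc_design`.
#' @export
encode_cohort <- function(cohort, schema = attr(cohort, "schema")) {
  if (is.null(schema)) abort("no schema supplied or attached to the cohort")
  if (nrow(cohort) == 0) abort("cannot encode an empty cohort")
  missing <- setdiff(c(schema$name, "outcome"), names(cohort))
  if (length(missing)) {
    abort(sprintf("cohort lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  blocks <- purrr::pmap(schema, function(name, kind, levels, units) {
    v <- cohort[[name]]
    if (kind %in% c("binary", "continuous")) {
      m <- matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, name))
      return(m)
    }
    unseen <- setdiff(unique(as.character(v)), levels)
    if (length(unseen)) {
      abort(sprintf("feature `%s` has level(s) not in the schema: %s",
                    name, paste(unseen, collapse = ", ")))
    }
    ind <- vapply(levels[-1], function(l) as.numeric(v == l), numeric(length(v)))
    ind <- matrix(ind, ncol = length(levels) - 1,
                  dimnames = list(NULL, paste(name, levels[-1], sep = "_")))
    ind
  })
  x <- do.call(cbind, blocks)
  design_matrix(x, cohort$outcome,
                site = attr(cohort, "site_name") %||% NA_character_)
}

#' Stratified train/test split
#'
#' Splits a design matrix into disjoint, exhaustive train and test parts.
#' The test part holds `round(test_fraction * n)` rows; under stratification
#' the positive count in the test part is `round(test_fraction * n_pos)`, so
#' class proportions in both parts track the full-data proportion as closely
#' as integer counts allow.
#'
#' @param dm An `fc_design`.
#' @param test_fraction Fraction held out, strictly in (0, 1). Default 0.30,
#'   the 70/30 split used throughout the experiment harness.
#' @param seed Integer seed; the same seed always reproduces the same split.
#' @param stratified Preserve class balance in both parts (default `TRUE`).
#' @return List with elements `train` and `test`, both `fc_design`.
#' @export
stratified_split <- function(dm, test_fraction = 0.30, seed = 1,
                             stratified = TRUE) {
  if (test_fraction <= 0 || test_fraction >= 1) abort("`test_fraction` must be in (0, 1)")
  n <- nrow(dm$x)
  n_test <- round(test_fraction * n)
  if (n_test < 1 || n_test >= n) abort("split leaves an empty part")
  idx_test <- with_seed(seed, {
    if (stratified) {
      pos <- which(dm$y == 1); neg <- which(dm$y == 0)
      if (length(pos) < 2 || length(neg) < 2) {
        abort("stratified split needs at least 2 members of each class")
      }
      n_test_pos <- max(0L, min(length(pos), round(test_fraction * length(pos))))
      n_test_neg <- n_test - n_test_pos
      if (n_test_neg < 0 || n_test_neg > length(neg)) {
        abort("test fraction incompatible with class counts")
      }
      c(sample(pos, n_test_pos), sample(neg, n_test_neg))
    } else {
      sample.int(n, n_test)
    }
  })
  idx_test <- sort(idx_test)
  idx_train <- setdiff(seq_len(n), idx_test)
  subset_dm <- function(i) design_matrix(dm$x[i, , drop = FALSE], dm$y[i], dm$site)
  list(train = subset_dm(idx_train), test = subset_dm(idx_test))
}

#' Standardize continuous columns with training-set statistics
#'
#' `fit_scaler()` records mean and sd of every non-indicator column of the
#' training matrix; `apply_scaler()` centers and scales those columns of any
#' compatible matrix with the stored statistics. Columns containing only 0/1
#' values are left untouched, as are near-constant columns (sd below 1e-12).
#' Fitting on the training part only, per split, prevents test-set leakage.
#'
#' @param train An `fc_design` (the training part).
#' @return `fit_scaler()`: an `fc_scaler` (serializable with
#'   [scaler_to_json()]); `apply_scaler()`: a rescaled `fc_design`.
#' @export
fit_scaler <- function(train) {
  x <- train$x
  scale_col <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    !all(v %in% c(0, 1)) && stats::sd(v) > 1e-12
  }, logical(1))
  structure(
    list(
      columns = colnames(x),
      scaled = colnames(x)[scale_col],
      center = colMeans(x[, scale_col, drop = FALSE]),
      scale = apply(x[, scale_col, drop = FALSE], 2, stats::sd)
    ),
    class = "fc_scaler"
  )
}

#' @rdname fit_scaler
#' @param scaler An `fc_scaler` from `fit_scaler()`.
#' @param dm An `fc_design` with the same columns as the training matrix.
#' @export
apply_scaler <- function(scaler, dm) {
  if (!identical(colnames(dm$x), scaler$columns)) {
    abort("design-matrix columns do not match the fitted scaler")
  }
  x <- dm$x
  for (nm in scaler$scaled) {
    x[, nm] <- (x[, nm] - scaler$center[[nm]]) / scaler$scale[[nm]]
  }
  design_matrix(x, dm$y, dm$site)
}

#' @rdname fit_scaler
#' @export
scaler_to_json <- function(scaler) {
  jsonlite::toJSON(unclass(scaler), auto_unbox = TRUE, digits = NA)
}

#' Class-balancing strategies for training data
#'
#' Applied to training folds only, after splitting, so no balancing decision
#' ever sees test rows. Methods:
#' `"none"` (identity), `"undersample_majority"` (drop majority rows without
#' replacement until classes match the minority count),
#' `"oversample_minority"` (append with-replacement copies of minority rows
#' until classes match the majority count; the default used by the
#' experiment harness), and `"class_weight"` (leave rows untouched, return
#' per-row weights inversely proportional to class frequency, normalized to
#' mean 1). Balancing never alters feature values — only row multiplicity or
#' weights.
#'
#' @param train An `fc_design` containing both classes.
#' @param method One of `"none"`, `"undersample_majority"`,
#'   `"oversample_minority"`, `"class_weight"`.
#' @param seed Integer seed for the resampling draws.
#' @return List with elements `data` (an `fc_design`) and `weights`
#'   (numeric, mean 1; all ones except under `"class_weight"`).
#' @export
balance_classes <- function(train, method = "oversample_minority", seed = 1) {
  method <- match.arg(method,
    c("none", "undersample_majority", "oversample_minority", "class_weight"))
  y <- train$y
  if (length(unique(y)) < 2) abort("balancing needs both classes present")
  pos <- which(y == 1); neg <- which(y == 0)
  minority <- if (length(pos) <= length(neg)) pos else neg
  majority <- if (length(pos) <= length(neg)) neg else pos
  keep <- switch(method,
    none = seq_along(y),
    undersample_majority = with_seed(seed,
      sort(c(minority, sample(majority, length(minority))))),
    oversample_minority = with_seed(seed,
      c(seq_along(y),
        sample(minority, length(majority) - length(minority), replace = TRUE))),
    class_weight = seq_along(y)
  )
  data <- design_matrix(train$x[keep, , drop = FALSE], y[keep], train$site)
  weights <- rep(1, length(keep))
  if (method == "class_weight") {
    freq <- c(`0` = mean(y == 0), `1` = mean(y == 1))
    w <- 1 / freq[as.character(y)]
    weights <- as.numeric(w / mean(w))
  }
  list(data = data, weights = weights)
}
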