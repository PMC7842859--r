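#' Pearson chi-square test of independence
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square on a
#' sites-by-categories contingency table, the test used for every
#' categorical characteristic in the interhospital comparison table.
#'
#' @param counts Non-negative integer matrix with at least 2 rows and 2
#'   columns; rows are sites, columns categories.
#' @return A tibble with `statistic`, `df` and `p_value`.
#' @export
#' @examples
#' males <- c(338, 951, 411, 344, 257)
#' females <- c(273, 693, 338, 196, 228)
#' chi_square_independence(cbind(males, females)) # p rounds to .004
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) abort("need at least a 2 x 2 table")
  if (any(counts < 0) || any(!is.finite(counts))) abort("counts must be non-negative and finite")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("zero row or column marginal: chi-square undefined")
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = unname(ht$p.value)
  )
}

#' Kruskal-Wallis rank test
#'
#' Rank-based k-group comparison with midrank tie correction, used for every
#' numeric characteristic in the interhospital comparison table. The H
#' statistic is referred to a chi-square distribution with k - 1 degrees of
#' freedom.
#'
#' @param samples List of 2 or more non-empty numeric vectors, one per group.
#' @return A tibble with `statistic`, `df` and `p_value`.
#' @export
kruskal_wallis <- function(samples) {
  if (!is.list(samples) || length(samples) < 2) abort("need at least 2 groups")
  if (any(vapply(samples, length, integer(1)) == 0)) abort("groups must be non-empty")
  pooled <- unlist(samples)
  if (length(unique(pooled)) == 1) {
    # every observation tied: no evidence of a rank shift by construction
    return(tibble(statistic = 0, df = length(samples) - 1, p_value = 1))
  }
  ht <- stats::kruskal.test(samples)
  tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = unname(ht$p.value)
  )
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the number of tests `m` and caps at 1,
#' preserving order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param m Number of tests; must be at least `length(p_values)`.
#' @return Adjusted p-values, same length and order.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (length(p_values) < 1) abort("need at least one p-value")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  if (m < length(p_values)) abort("`m` must be at least the number of p-values")
  pmin(1, p_values * m)
}

#' Interhospital comparison table
#'
#' Builds the sites-by-characteristics summary used to describe a
#' multi-hospital cohort: counts and percentages (1 decimal) for binary and
#' categorical features, median and IQR for continuous features, and the
#' 7-day mortality outcome row. Categorical characteristics are tested with
#' uncorrected Pearson chi-square across sites, numeric ones with
#' Kruskal-Wallis; by default Bonferroni adjustment is applied to the
#' numeric (Kruskal-Wallis) tests only, with `m` equal to the number of
#' tests in scope. Cells describing fewer than `suppress_below` patients are
#' flagged and masked as `--` in rendered output, mirroring small-cell
#' privacy suppression.
#'
#' @param cohorts List of 2 or more cohort tibbles sharing one schema.
#' @param suppress_below Suppression threshold in patients (default 10).
#' @param adjust Which p-values receive Bonferroni adjustment:
#'   `"numeric"` (default), `"all"`, or `"none"`.
#' @return An `fc_comparison` object: a long tibble with one row per
#'   characteristic-level-site cell (`characteristic`, `level`, `site`,
#'   `site_n`, `count`, `percent`, `median`, `q1`, `q3`, `suppressed`,
#'   `test`, `p_value`, `p_adjusted`).
#' @export
build_comparison_table <- function(cohorts, suppress_below = 10,
                                   adjust = c("numeric", "all", "none")) {
  adjust <- match.arg(adjust)
  if (length(cohorts) < 2) abort("need at least 2 cohorts to compare")
  schema <- attr(cohorts[[1]], "schema")
  if (is.null(schema)) abort("cohorts must carry a schema attribute")
  for (c2 in cohorts[-1]) {
    s2 <- attr(c2, "schema")
    if (is.null(s2) || !identical(s2$name, schema$name) || !identical(s2$kind, schema$kind)) {
      abort("all cohorts must share one schema")
    }
  }
  sites <- vapply(cohorts, function(c) attr(c, "site_name") %||% NA_character_,
                  character(1))
  if (anyNA(sites)) sites <- paste0("site", seq_along(cohorts))
  site_n <- vapply(cohorts, nrow, integer(1))

  spec <- dplyr::bind_rows(
    schema[, c("name", "kind", "levels")],
    tibble(name = "outcome", kind = "binary", levels = list(NULL))
  )

  rows <- purrr::pmap(spec, function(name, kind, levels) {
    vals <- lapply(cohorts, function(c) c[[name]])
    if (kind == "continuous") {
      ht <- kruskal_wallis(vals)
      return(tibble(
        characteristic = name, level = NA_character_, site = sites,
        site_n = site_n, count = NA_integer_, percent = NA_real_,
        median = vapply(vals, stats::median, numeric(1)),
        q1 = vapply(vals, function(v) unname(quantile(v, 0.25)), numeric(1)),
        q3 = vapply(vals, function(v) unname(quantile(v, 0.75)), numeric(1)),
        suppressed = FALSE, test = "kruskal_wallis", p_value = ht$p_value
      ))
    }
    if (kind == "binary") {
      cnt <- vapply(vals, function(v) sum(v == 1), numeric(1))
      tab <- cbind(cnt, site_n - cnt)
      ht <- chi_square_independence(tab)
      return(tibble(
        characteristic = name, level = NA_character_, site = sites,
        site_n = site_n, count = as.integer(cnt),
        percent = percent1(cnt, site_n),
        median = NA_real_, q1 = NA_real_, q3 = NA_real_,
        suppressed = cnt < suppress_below, test = "chi_square",
        p_value = ht$p_value
      ))
    }
    counts <- t(vapply(vals, function(v) {
      vapply(levels, function(l) sum(v == l), numeric(1))
    }, numeric(length(levels))))
    ht <- chi_square_independence(counts)
    purrr::list_rbind(lapply(seq_along(levels), function(j) {
      tibble(
        characteristic = name, level = levels[j], site = sites,
        site_n = site_n, count = as.integer(counts[, j]),
        percent = percent1(counts[, j], site_n),
        median = NA_real_, q1 = NA_real_, q3 = NA_real_,
        suppressed = counts[, j] < suppress_below, test = "chi_square",
        p_value = ht$p_value
      )
    }))
  })
  out <- purrr::list_rbind(rows)

  tests <- dplyr::distinct(out[, c("characteristic", "test", "p_value")])
  in_scope <- switch(adjust,
    none = rep(FALSE, nrow(tests)),
    numeric = tests$test == "kruskal_wallis",
    all = rep(TRUE, nrow(tests))
  )
  tests$p_adjusted <- tests$p_value
  if (any(in_scope)) {
    tests$p_adjusted[in_scope] <-
      bonferroni_adjust(tests$p_value[in_scope], m = sum(in_scope))
  }
  out <- dplyr::left_join(out, tests[, c("characteristic", "p_adjusted")],
                          by = "characteristic")
  class(out) <- c("fc_comparison", class(out))
  out
}

#' Format a p-value in clinical-table style
#'
#' Three decimals with the leading zero dropped; values below 0.0005 render
#' as `<.001`.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_p_value <- function(p) {
  ifelse(p < 5e-4, "<.001", sub("^0", "", sprintf("%.3f", p)))
}

#' Render a comparison table
#'
#' Pivots an `fc_comparison` to one row per characteristic (or
#' characteristic level) and one column per site, with cells
#' `count (percent)` or `median (q1-q3)` and suppressed cells shown as
#' `--`. `write_comparison_csv()` and `write_comparison_markdown()` emit
#' the rendered table.
#'
#' @param comparison An `fc_comparison` from [build_comparison_table()].
#' @return A wide tibble with character cells.
#' @export
render_comparison <- function(comparison) {
  cells <- comparison |>
    mutate(cell = dplyr::case_when(
      suppressed ~ "--",
      test == "chi_square" ~ sprintf("%d (%.1f)", count, percent),
      TRUE ~ sprintf("%.1f (%.1f-%.1f)", median, q1, q3)
    ))
  wide <- cells |>
    select(all_of(c("characteristic", "level", "site", "cell"))) |>
    pivot_wider(names_from = "site", values_from = "cell")
  p <- comparison |>
    dplyr::distinct(.data$characteristic, .data$level, .data$p_adjusted)
  dplyr::left_join(wide, p, by = c("characteristic", "level")) |>
    mutate(p = format_p_value(.data$p_adjusted)) |>
    select(-all_of("p_adjusted"))
}

#' @rdname render_comparison
#' @param path Output file path.
#' @export
write_comparison_csv <- function(comparison, path) {
  readr::write_csv(render_comparison(comparison), path)
  invisible(path)
}

#' @rdname render_comparison
#' @export
write_comparison_markdown <- function(comparison, path) {
  wide <- render_comparison(comparison)
  header <- paste0("| ", paste(names(wide), collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---", ncol(wide)), collapse = "|"), "|")
  body <- apply(wide, 1, function(r) {
    paste0("| ", paste(ifelse(is.na(r), "", r), collapse = " | "), " |")
  })
  writeLines(c(header, rule, body), path)
  invisible(path)
}
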