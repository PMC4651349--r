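## Auxiliary nonparametric tests and descriptive summaries: Wilcoxon
## signed-rank (paired scores), Mann-Whitney U (group comparisons),
## one-sample Kolmogorov-Smirnov normality check, median/IQR.

test_result <- function(statistic, p_value, n_effective, method_notes) {
  structure(list(statistic = statistic, p_value = p_value,
                 n_effective = n_effective, method_notes = method_notes),
            class = "np_test")
}

#' @export
print.np_test <- function(x, ...) {
  cat(sprintf("statistic = %s, p = %.4g, n = %d\n  [%s]\n",
              format(x$statistic), x$p_value, x$n_effective,
              x$method_notes))
  invisible(x)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped (classic zero-drop rule, not Pratt's), ties
#' among the absolute differences are midranked. Exact enumeration of the
#' signed-rank distribution is used when the nonzero sample is tie-free with
#' `n <= exact_limit`; otherwise the normal approximation with tie and
#' continuity corrections. All-zero differences yield a degenerate result
#' (p = 1, statistic NA).
#'
#' @param x numeric vector of paired differences (or first sample if `y`
#'   given).
#' @param y optional second sample; differences `x - y` are tested.
#' @param exact_limit largest nonzero n for exact-mode enumeration
#'   (default 12).
#' @return an `"np_test"` result (statistic = V, the positive-rank sum).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_limit = 12) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  n_zero <- length(d) - length(nz)
  if (length(nz) == 0)
    return(test_result(NA_real_, 1, 0L,
                       "all differences zero; degenerate"))
  ties <- any(duplicated(abs(nz)))
  exact <- !ties && length(nz) <= exact_limit
  res <- suppressWarnings(
    stats::wilcox.test(nz, exact = exact, correct = TRUE)
  )
  notes <- sprintf(
    "signed-rank; %d zero(s) dropped; %s mode%s%s",
    n_zero, if (exact) "exact" else "normal approximation",
    if (!exact) " with tie and continuity correction" else "",
    if (ties) "; midranked ties" else "")
  test_result(unname(res$statistic), res$p.value, length(nz), notes)
}

#' Mann-Whitney U test for two independent groups
#'
#' U computed from midranks; exact enumeration when `n_x * n_y <=
#' exact_limit` and there are no cross- or within-group ties, otherwise the
#' normal approximation with tie and continuity corrections.
#'
#' @param x,y numeric samples from the two groups (non-empty).
#' @param exact_limit product-of-sizes bound for exact mode (default 400).
#' @return an `"np_test"` (statistic = U for the first group).
#' @export
mann_whitney_u <- function(x, y, exact_limit = 400) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  ties <- any(duplicated(c(x, y)))
  exact <- !ties && length(x) * length(y) <= exact_limit
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  notes <- sprintf(
    "Mann-Whitney U from midranks; %s mode%s",
    if (exact) "exact" else "normal approximation",
    if (!exact) " with tie and continuity correction" else "")
  test_result(unname(res$statistic), res$p.value,
              length(x) + length(y), notes)
}

#' One-sample Kolmogorov-Smirnov check against normality
#'
#' D statistic against a normal with the sample's own mean and SD,
#' asymptotic p. Because the parameters are estimated from the same data the
#' asymptotic p is conservative (the Lilliefors caveat, recorded in the
#' method notes); set `lilliefors = TRUE` for the corrected test.
#'
#' @param x numeric sample, `n >= 5`, nonzero variance.
#' @param lilliefors use the Lilliefors-corrected distribution of D.
#' @return an `"np_test"` (statistic = D).
#' @export
ks_normality <- function(x, lilliefors = FALSE) {
  x <- x[!is.na(x)]
  if (length(x) < 5) stop("need n >= 5", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero variance sample", call. = FALSE)
  if (lilliefors) {
    res <- nortest::lillie.test(x)
    test_result(unname(res$statistic), res$p.value, length(x),
                "Lilliefors-corrected KS (parameters estimated)")
  } else {
    res <- suppressWarnings(
      stats::ks.test(x, "pnorm", mean(x), stats::sd(x))
    )
    test_result(unname(res$statistic), res$p.value, length(x),
                paste("one-sample KS vs fitted normal; parameters",
                      "estimated from the sample, p is conservative"))
  }
}

#' Median and quartiles
#'
#' Linear-interpolation quantiles (the default convention of
#' [stats::quantile()], type 7).
#'
#' @param x non-empty numeric sample.
#' @return named numeric `c(median, q25, q75)`.
#' @export
median_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("empty sample", call. = FALSE)
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q25 = q[2], q75 = q[3])
}
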