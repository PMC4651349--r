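## Empirical ROC curves over the ordinal score, AUC with DeLong variance,
## paired and unpaired AUC comparisons.

check_two_classes <- function(labels) {
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("need at least one positive and one negative label", call. = FALSE)
  c(n_pos = n_pos, n_neg = n_neg)
}

#' Empirical ROC operating points
#'
#' One operating point per distinct score value used as a threshold
#' (predicted positive = score >= threshold), plus the (0,0) and (1,1)
#' anchors. With an ordinal 0-8 score the curve is a staircase through at
#' most 10 distinct points.
#'
#' @param scores numeric/integer score vector (higher = more suspicious).
#' @param labels logical disease labels.
#' @return object of class `"roc_curve"`: data.frame with `threshold`,
#'   `fpr`, `tpr`, plus attributes `n_pos`, `n_neg`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  n <- check_two_classes(labels)
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(cuts, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(cuts, function(t) mean(scores[!labels] >= t), numeric(1))
  out <- data.frame(threshold = cuts, fpr = fpr, tpr = tpr)
  ## lowest threshold always yields (1,1); Inf yields (0,0)
  attr(out, "n_pos") <- unname(n["n_pos"])
  attr(out, "n_neg") <- unname(n["n_neg"])
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Trapezoidal area under an ROC curve
#'
#' @param curve a `"roc_curve"` from [roc_points()].
#' @return area in \[0, 1\].
#' @export
auc_trapezoid <- function(curve) {
  f <- curve$fpr; t <- curve$tpr
  sum(diff(f) * (utils::head(t, -1) + utils::tail(t, -1)) / 2)
}

#' Mann-Whitney (pair-counting) AUC
#'
#' The probability that a randomly chosen case scores above a randomly
#' chosen control, with half credit for ties — computed via midranks, which
#' is algebraically the pair count `[case > control] + 0.5 [tie]` averaged
#' over all case/control pairs. Identical to the trapezoidal area under the
#' empirical ROC curve.
#'
#' @param scores numeric scores.
#' @param labels logical labels.
#' @return AUC point estimate in \[0, 1\].
#' @export
auc_mw <- function(scores, labels) {
  labels <- as.logical(labels)
  n <- check_two_classes(labels)
  r <- rank(scores)                               # midranks handle ties
  unname((sum(r[labels]) - n["n_pos"] * (n["n_pos"] + 1) / 2) /
           (as.numeric(n["n_pos"]) * n["n_neg"]))
}

delong_placements <- function(scores, labels) {
  x <- scores[labels]; y <- scores[!labels]
  ## placement of each case among controls and vice versa (midrank credit)
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = 1 - colMeans(psi))
}

#' AUC with DeLong variance and confidence interval
#'
#' Variance from the DeLong structural components: per-case and per-control
#' placement values (midrank convention for ties),
#' `var = var(V10)/n_pos + var(V01)/n_neg`; the CI is the normal
#' approximation truncated to \[0, 1\].
#'
#' @param scores numeric scores.
#' @param labels logical labels.
#' @param level confidence level.
#' @return object of class `"auc_estimate"`: list with `auc`, `variance`,
#'   `ci` (lo, hi), `level`, `n_pos`, `n_neg`, `truncated` flag.
#' @export
auc_ci_delong <- function(scores, labels, level = 0.95) {
  labels <- as.logical(labels)
  n <- check_two_classes(labels)
  if (n["n_pos"] < 2 || n["n_neg"] < 2)
    stop("DeLong variance needs at least 2 cases and 2 controls",
         call. = FALSE)
  pl <- delong_placements(scores, labels)
  a <- mean(pl$v10)
  v <- stats::var(pl$v10) / n["n_pos"] + stats::var(pl$v01) / n["n_neg"]
  z <- stats::qnorm(1 - (1 - level) / 2)
  raw <- a + c(-1, 1) * z * sqrt(v)
  ci <- pmin(1, pmax(0, raw))
  structure(list(auc = unname(a), variance = unname(v),
                 ci = c(lo = ci[1], hi = ci[2]), level = level,
                 n_pos = unname(n["n_pos"]), n_neg = unname(n["n_neg"]),
                 truncated = !isTRUE(all.equal(raw, ci))),
            class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC %.3f (%g%% CI %.3f-%.3f; DeLong var %.2e; %d cases/%d controls)\n",
              x$auc, 100 * x$level, x$ci[1], x$ci[2], x$variance,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Compare two AUCs from independent cohorts
#'
#' Independent-samples z test: `z = (auc_a - auc_b)/sqrt(var_a + var_b)`
#' with DeLong variances, two-sided normal p.
#'
#' @param a,b `"auc_estimate"` objects from disjoint subject sets.
#' @return list `z`, `p_value`, `diff`.
#' @export
compare_auc_unpaired <- function(a, b) {
  v <- a$variance + b$variance
  if (v <= 0) stop("zero combined variance: AUCs degenerate", call. = FALSE)
  z <- (a$auc - b$auc) / sqrt(v)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), diff = a$auc - b$auc)
}

#' Compare two paired AUCs (same subjects, two scores)
#'
#' Paired DeLong test: the variance of the AUC difference subtracts twice
#' the covariance of the placement values, which the shared subjects induce.
#'
#' @param scores_1,scores_2 two score vectors on the same subjects.
#' @param labels shared logical labels.
#' @param level confidence level used for the component estimates.
#' @return list `auc_1`, `auc_2`, `diff`, `variance`, `z`, `p_value`.
#' @export
compare_auc_paired <- function(scores_1, scores_2, labels, level = 0.95) {
  labels <- as.logical(labels)
  if (length(scores_1) != length(scores_2) ||
      length(scores_1) != length(labels))
    stop("paired comparison needs equal-length score and label vectors",
         call. = FALSE)
  n <- check_two_classes(labels)
  if (n["n_pos"] < 2 || n["n_neg"] < 2)
    stop("DeLong variance needs at least 2 cases and 2 controls",
         call. = FALSE)
  p1 <- delong_placements(scores_1, labels)
  p2 <- delong_placements(scores_2, labels)
  a1 <- mean(p1$v10); a2 <- mean(p2$v10)
  v1 <- stats::var(p1$v10) / n["n_pos"] + stats::var(p1$v01) / n["n_neg"]
  v2 <- stats::var(p2$v10) / n["n_pos"] + stats::var(p2$v01) / n["n_neg"]
  cv <- stats::cov(p1$v10, p2$v10) / n["n_pos"] +
    stats::cov(p1$v01, p2$v01) / n["n_neg"]
  vd <- unname(v1 + v2 - 2 * cv)
  if (vd <= 1e-15) {
    if (isTRUE(all.equal(a1, a2))) {
      ## identical scores: no difference to test
      return(list(auc_1 = a1, auc_2 = a2, diff = 0, variance = 0,
                  z = 0, p_value = 1))
    }
    stop("degenerate paired variance", call. = FALSE)
  }
  z <- unname((a1 - a2) / sqrt(vd))
  list(auc_1 = a1, auc_2 = a2, diff = a1 - a2, variance = vd,
       z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Plot an empirical ROC curve
#'
#' @param x a `"roc_curve"`.
#' @param ... passed to [plot()].
#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate (1 - specificity)",
       ylab = "True positive rate (sensitivity)", ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}
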