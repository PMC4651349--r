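## Diagnostic test accuracy: 2x2 tables, characteristics, likelihood ratios
## (plain and prevalence-adjusted), proportion and LR confidence intervals.

#' Build a 2x2 contingency table at a score threshold
#'
#' Predicted positive means score >= threshold.
#'
#' @param total integer score vector.
#' @param is_osa logical disease labels, same length.
#' @param threshold integer score cut.
#' @return object of class `"contingency_table"` with `tp`, `fp`, `fn`, `tn`,
#'   `threshold`.
#' @export
build_contingency <- function(total, is_osa, threshold) {
  if (length(total) == 0) stop("empty input", call. = FALSE)
  if (length(total) != length(is_osa))
    stop("total and is_osa must have equal length", call. = FALSE)
  pred <- total >= threshold
  structure(list(tp = sum(pred & is_osa), fp = sum(pred & !is_osa),
                 fn = sum(!pred & is_osa), tn = sum(!pred & !is_osa),
                 threshold = threshold),
            class = "contingency_table")
}

#' Construct a contingency table directly from counts
#'
#' @param tp,fp,fn,tn non-negative integer cell counts.
#' @param threshold optional score cut for provenance.
#' @return a `"contingency_table"`.
#' @export
contingency_table <- function(tp, fp, fn, tn, threshold = NA) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, threshold = threshold),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("score >= cut", "score < cut"),
                              c("OSA", "no OSA")))
  print(m)
  invisible(x)
}

#' Sensitivity, specificity and predictive values from a 2x2 table
#'
#' Quantities with a zero denominator are returned as `NA` (flagged
#' undefined), never silently as 0.
#'
#' @param tab a `"contingency_table"`.
#' @return named list: `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
test_characteristics <- function(tab) {
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  list(sensitivity = safe_div(tab$tp, tab$tp + tab$fn),
       specificity = safe_div(tab$tn, tab$fp + tab$tn),
       ppv = safe_div(tab$tp, tab$tp + tab$fp),
       npv = safe_div(tab$tn, tab$tn + tab$fn))
}

#' Likelihood ratios from sensitivity and specificity
#'
#' `LR+ = sens / (1 - spec)`, `LR- = (1 - sens) / spec`. A perfect
#' specificity yields an infinite LR+ (returned as `Inf`, flagged).
#'
#' @param sensitivity,specificity proportions in \[0, 1\].
#' @return list `lr_pos`, `lr_neg`, `lr_pos_infinite` (logical flag).
#' @export
likelihood_ratios <- function(sensitivity, specificity) {
  lr_pos <- if (specificity < 1) sensitivity / (1 - specificity) else Inf
  lr_neg <- if (specificity > 0) (1 - sensitivity) / specificity else NA_real_
  list(lr_pos = lr_pos, lr_neg = lr_neg,
       lr_pos_infinite = !is.finite(lr_pos))
}

#' Prevalence-adjusted likelihood ratios (post-test odds)
#'
#' When cohort prevalence is far from 0.5, raw likelihood ratios can
#' overstate a test's practical value. The prevalence-adjusted LR multiplies
#' the likelihood ratio by the pre-test odds `p/(1-p)`, giving the post-test
#' odds of disease after a positive (`lr_pos_prev`) or negative
#' (`lr_neg_prev`) result. Equivalently `lr_pos_prev = PPV/(1-PPV)` and
#' `lr_neg_prev = (1-NPV)/NPV` when the predictive values are computed at the
#' same prevalence via Bayes' theorem.
#'
#' @inheritParams likelihood_ratios
#' @param prevalence disease prevalence in (0, 1).
#' @return list `lr_pos_prev`, `lr_neg_prev`.
#' @export
prevalence_adjusted_lrs <- function(sensitivity, specificity, prevalence) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must be in (0, 1)", call. = FALSE)
  odds <- prevalence / (1 - prevalence)
  lr <- likelihood_ratios(sensitivity, specificity)
  list(lr_pos_prev = lr$lr_pos * odds, lr_neg_prev = lr$lr_neg * odds)
}

#' Predictive values at a specified prevalence (Bayes)
#'
#' @inheritParams prevalence_adjusted_lrs
#' @return list `ppv`, `npv`.
#' @export
predictive_values <- function(sensitivity, specificity, prevalence) {
  p <- prevalence
  ppv <- sensitivity * p / (sensitivity * p + (1 - specificity) * (1 - p))
  npv <- specificity * (1 - p) /
    (specificity * (1 - p) + (1 - sensitivity) * p)
  list(ppv = ppv, npv = npv)
}

#' Binomial proportion confidence interval
#'
#' Wilson score interval by default (closed-form solution of the score
#' quadratic); Clopper-Pearson (exact beta quantiles) by option. The interval
#' always contains `k/n` and lies in \[0, 1\].
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials, `> 0`.
#' @param level confidence level, default 0.95.
#' @param method `"wilson"` or `"clopper-pearson"`.
#' @return numeric `c(lo, hi)`.
#' @export
proportion_ci <- function(k, n, level = 0.95,
                          method = c("wilson", "clopper-pearson")) {
  method <- match.arg(method)
  if (n <= 0 || k < 0 || k > n) stop("need 0 <= k <= n, n > 0", call. = FALSE)
  if (method == "wilson") {
    z <- stats::qnorm(1 - (1 - level) / 2)
    p <- k / n
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    ci <- c(max(0, centre - half), min(1, centre + half))
  } else {
    a <- (1 - level) / 2
    lo <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
    hi <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
    ci <- c(lo, hi)
  }
  names(ci) <- c("lo", "hi")
  ci
}

#' Log-method confidence interval for a likelihood ratio
#'
#' `exp(log(LR) +/- z * sqrt(var))` with
#' `var(log LR+) = 1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn)` (and the analogous
#' form with fn/tn for LR-). Zero cells trigger a +0.5 continuity correction
#' to all four cells, reported in the `continuity` flag.
#'
#' @param tab a `"contingency_table"`.
#' @param which `"pos"` or `"neg"`.
#' @param level confidence level.
#' @return list `estimate`, `lo`, `hi`, `continuity` (logical),
#'   `undefined` (logical, degenerate table).
#' @export
lr_ci <- function(tab, which = c("pos", "neg"), level = 0.95) {
  which <- match.arg(which)
  cells <- c(tab$tp, tab$fp, tab$fn, tab$tn)
  if (sum(cells > 0) <= 1)
    return(list(estimate = NA_real_, lo = NA_real_, hi = NA_real_,
                continuity = FALSE, undefined = TRUE))
  continuity <- any(cells == 0)
  if (continuity) cells <- cells + 0.5
  tp <- cells[1]; fp <- cells[2]; fn <- cells[3]; tn <- cells[4]
  sens <- tp / (tp + fn); spec <- tn / (fp + tn)
  if (which == "pos") {
    est <- sens / (1 - spec)
    v <- 1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn)
  } else {
    est <- (1 - sens) / spec
    v <- 1 / fn - 1 / (tp + fn) + 1 / tn - 1 / (fp + tn)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(estimate = est,
       lo = exp(log(est) - z * sqrt(v)),
       hi = exp(log(est) + z * sqrt(v)),
       continuity = continuity, undefined = FALSE)
}

#' Full test-characteristics panel across thresholds and strata
#'
#' Reproduces the structure of a threshold-sensitivity table: one row per
#' (threshold, stratum) with sensitivity, specificity, PPV, NPV (each with a
#' binomial CI), LR+/LR- (log-method CIs) and the prevalence-adjusted LRs.
#' Prevalence for the adjusted LRs defaults to the whole analyzed cohort's
#' own prevalence, matching the convention of using one cohort-wide pre-test
#' odds in every stratum.
#'
#' @param total integer score vector.
#' @param is_osa logical labels.
#' @param stratum factor/character stratum label per subject (e.g. from
#'   [stratify()]); the `"all"` stratum is always included.
#' @param thresholds integer score cuts (default 2, 3, 4).
#' @param prevalence pre-test probability used for the adjusted LRs;
#'   default `mean(is_osa)`.
#' @param ci_method `"wilson"` or `"clopper-pearson"` for the proportion CIs.
#' @param level confidence level.
#' @return data.frame, one row per (threshold, stratum).
#' @export
summary_table <- function(total, is_osa, stratum = NULL,
                          thresholds = c(2, 3, 4),
                          prevalence = mean(is_osa),
                          ci_method = "wilson", level = 0.95) {
  if (is.null(stratum)) stratum <- rep("all", length(total))
  stratum <- as.character(stratum)
  strata <- c("all", setdiff(unique(stratum), "all"))
  rows <- list()
  for (th in thresholds) {
    for (st in strata) {
      in_st <- if (st == "all") rep(TRUE, length(total)) else stratum == st
      tab <- build_contingency(total[in_st], is_osa[in_st], th)
      ch <- test_characteristics(tab)
      lr <- likelihood_ratios(ch$sensitivity, ch$specificity)
      plr <- prevalence_adjusted_lrs(ch$sensitivity, ch$specificity,
                                     prevalence)
      ci <- function(k, n) {
        if (n > 0) proportion_ci(k, n, level, ci_method) else c(NA, NA)
      }
      s_ci <- ci(tab$tp, tab$tp + tab$fn)
      sp_ci <- ci(tab$tn, tab$fp + tab$tn)
      ppv_ci <- ci(tab$tp, tab$tp + tab$fp)
      npv_ci <- ci(tab$tn, tab$tn + tab$fn)
      lp <- lr_ci(tab, "pos", level); ln <- lr_ci(tab, "neg", level)
      odds <- prevalence / (1 - prevalence)
      rows[[length(rows) + 1]] <- data.frame(
        stratum = st, threshold = th, n = tab$tp + tab$fp + tab$fn + tab$tn,
        tp = tab$tp, fp = tab$fp, fn = tab$fn, tn = tab$tn,
        sensitivity = ch$sensitivity, sens_lo = s_ci[1], sens_hi = s_ci[2],
        specificity = ch$specificity, spec_lo = sp_ci[1], spec_hi = sp_ci[2],
        ppv = ch$ppv, ppv_lo = ppv_ci[1], ppv_hi = ppv_ci[2],
        npv = ch$npv, npv_lo = npv_ci[1], npv_hi = npv_ci[2],
        lr_pos = lr$lr_pos, lr_pos_lo = lp$lo, lr_pos_hi = lp$hi,
        lr_neg = lr$lr_neg, lr_neg_lo = ln$lo, lr_neg_hi = ln$hi,
        lr_pos_prev = plr$lr_pos_prev,
        lr_pos_prev_lo = lp$lo * odds, lr_pos_prev_hi = lp$hi * odds,
        lr_neg_prev = plr$lr_neg_prev,
        lr_neg_prev_lo = ln$lo * odds, lr_neg_prev_hi = ln$hi * odds,
        prevalence = prevalence,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Round half-up at a fixed number of decimals
#'
#' Display-rounding convention for report tables (printed precision:
#' 1 decimal for likelihood ratios, 2 for proportions). Internal computations
#' are never rounded.
#'
#' @param x numeric.
#' @param digits decimals.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
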