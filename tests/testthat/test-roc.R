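test_that("ROC curves have anchors and staircase monotonicity", {
  # perfect separation passes through (0, 1)
  curve <- roc_points(c(3, 0), c(TRUE, FALSE))
  expect_equal(curve$fpr[1], 0); expect_equal(curve$tpr[1], 0)
  expect_true(any(curve$fpr == 0 & curve$tpr == 1))
  expect_equal(curve$fpr[nrow(curve)], 1)
  expect_equal(curve$tpr[nrow(curve)], 1)
  # constant scores collapse to the diagonal endpoints
  flat <- roc_points(rep(2, 6), c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(nrow(flat), 2)
  expect_equal(flat$fpr, c(0, 1)); expect_equal(flat$tpr, c(0, 1))
  # monotone staircase on random ordinal input
  set.seed(5)
  for (i in 1:20) {
    d <- simulate_scores(60, 0.3, 0.5, 0.2)
    if (sum(d$is_osa) == 0 || all(d$is_osa)) next
    cv <- roc_points(d$total, d$is_osa)
    expect_true(all(diff(cv$fpr) >= 0))
    expect_true(all(diff(cv$tpr) >= 0))
    expect_true(all(cv$fpr >= 0 & cv$fpr <= 1 & cv$tpr >= 0 & cv$tpr <= 1))
  }
  expect_error(roc_points(c(1, 2), c(TRUE, TRUE)), "negative")
})

test_that("pair-counting AUC matches hand enumeration and extremes", {
  expect_equal(auc_mw(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc_mw(rep(4, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  # cases {2,1}, controls {2,0}: pairs credit 0.5 + 1 + 0 + 1 over 4
  expect_equal(auc_mw(c(2, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE)), 0.625)
})

test_that("trapezoid and pair-counting AUC agree to 1e-12 everywhere", {
  set.seed(17)
  for (i in 1:300) {
    n <- sample(10:80, 1)
    d <- simulate_scores(n, runif(1, 0.1, 0.5), runif(1), runif(1))
    if (sum(d$is_osa) == 0 || all(d$is_osa)) next
    a1 <- auc_mw(d$total, d$is_osa)
    a2 <- auc_trapezoid(roc_points(d$total, d$is_osa))
    expect_equal(a1, a2, tolerance = 1e-12)
    # complement identity
    a_neg <- auc_mw(-d$total, d$is_osa)
    expect_equal(a1 + a_neg, 1, tolerance = 1e-12)
  }
})

test_that("AUC and DeLong variance agree with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (i in 1:10) {
    d <- simulate_scores(150, 0.25, 0.45, 0.15)
    est <- auc_ci_delong(d$total, d$is_osa)
    r <- pROC::roc(d$is_osa, d$total, quiet = TRUE, direction = "<")
    expect_equal(est$auc, as.numeric(pROC::auc(r)), tolerance = 1e-12)
    expect_equal(est$variance, as.numeric(pROC::var(r, method = "delong")),
                 tolerance = 1e-10)
    ci <- pROC::ci.auc(r, method = "delong")
    expect_equal(unname(est$ci), as.numeric(ci[c(1, 3)]), tolerance = 1e-9)
  }
})

test_that("DeLong variance approximates the bootstrap variance", {
  set.seed(61)
  d <- simulate_scores(200, 0.3, 0.5, 0.2)
  est <- auc_ci_delong(d$total, d$is_osa)
  boot <- replicate(2000, {
    idx <- sample.int(200, replace = TRUE)
    if (sum(d$is_osa[idx]) < 2 || sum(!d$is_osa[idx]) < 2) NA
    else auc_mw(d$total[idx], d$is_osa[idx])
  })
  expect_lt(abs(est$variance - var(boot, na.rm = TRUE)) / est$variance, 0.15)
  expect_true(est$ci[1] <= est$auc && est$auc <= est$ci[2])
})

test_that("perfect separation collapses the DeLong interval at 1", {
  est <- auc_ci_delong(c(5, 6, 7, 1, 2, 3), rep(c(TRUE, FALSE), each = 3))
  expect_equal(est$auc, 1)
  expect_equal(est$variance, 0)
  expect_equal(unname(est$ci), c(1, 1))
})

test_that("unpaired AUC comparison is an antisymmetric normal z-test", {
  set.seed(3)
  d1 <- simulate_scores(150, 0.3, 0.5, 0.2)
  d2 <- simulate_scores(150, 0.3, 0.4, 0.25)
  a <- auc_ci_delong(d1$total, d1$is_osa)
  b <- auc_ci_delong(d2$total, d2$is_osa)
  ab <- compare_auc_unpaired(a, b); ba <- compare_auc_unpaired(b, a)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(compare_auc_unpaired(a, a)$z, 0)
  expect_equal(compare_auc_unpaired(a, a)$p_value, 1)
  # closed-form arithmetic: var 0.0025 each, diff 0.139
  fake <- function(auc, v) structure(list(auc = auc, variance = v),
                                     class = "auc_estimate")
  cmp <- compare_auc_unpaired(fake(0.839, 0.0025), fake(0.700, 0.0025))
  expect_equal(cmp$z, 0.139 / sqrt(0.005), tolerance = 1e-12)
  expect_equal(cmp$p_value, 2 * pnorm(-0.139 / sqrt(0.005)),
               tolerance = 1e-12)
})

test_that("paired DeLong comparison uses the placement covariance", {
  set.seed(29)
  d <- simulate_scores(200, 0.25, 0.5, 0.2)
  noisy <- pmax(0, pmin(8, d$total + sample(-1:1, 200, replace = TRUE)))
  # identical scores: no difference to test
  same <- compare_auc_paired(d$total, d$total, d$is_osa)
  expect_equal(c(same$z, same$p_value), c(0, 1))
  cmp <- compare_auc_paired(d$total, noisy, d$is_osa)
  v1 <- auc_ci_delong(d$total, d$is_osa)$variance
  v2 <- auc_ci_delong(noisy, d$is_osa)$variance
  # positively correlated scores: paired variance below the independent sum
  expect_lt(cmp$variance, v1 + v2)
  expect_true(cmp$p_value >= 0 && cmp$p_value <= 1)
})

test_that("paired comparison matches pROC and approaches unpaired under independence", {
  skip_if_not_installed("pROC")
  set.seed(37)
  d <- simulate_scores(250, 0.3, 0.5, 0.2)
  other <- simulate_scores(250, 0.3, 0.45, 0.25)$total  # independent scores
  cmp <- compare_auc_paired(d$total, other, d$is_osa)
  r1 <- pROC::roc(d$is_osa, d$total, quiet = TRUE, direction = "<")
  r2 <- pROC::roc(d$is_osa, other, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  expect_equal(cmp$p_value, as.numeric(ref$p.value), tolerance = 1e-9)
  # with independent scores the covariance is near zero: paired z close to
  # the unpaired z
  unp <- compare_auc_unpaired(auc_ci_delong(d$total, d$is_osa),
                              auc_ci_delong(other, d$is_osa))
  expect_equal(cmp$z, unp$z, tolerance = 0.35)
})
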