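test_that("contingency tables enumerate predictions against labels", {
  tab <- build_contingency(c(3, 2, 3, 0), c(TRUE, TRUE, FALSE, FALSE), 3)
  expect_equal(c(tab$tp, tab$fn, tab$fp, tab$tn), c(1, 1, 1, 1))
  # degenerate cuts
  t0 <- build_contingency(c(3, 2, 3, 0), c(TRUE, TRUE, FALSE, FALSE), 0)
  expect_equal(c(t0$fn, t0$tn), c(0, 0))
  t9 <- build_contingency(c(3, 2, 3, 0), c(TRUE, TRUE, FALSE, FALSE), 9)
  expect_equal(c(t9$tp, t9$fp), c(0, 0))
  expect_error(build_contingency(integer(0), logical(0), 3), "empty")
})

test_that("test characteristics divide the right margins", {
  # counts consistent with a 64%-sensitive, 82%-specific screen
  tab <- contingency_table(tp = 9, fp = 29, fn = 5, tn = 133)
  ch <- test_characteristics(tab)
  expect_equal(round(ch$sensitivity, 2), 0.64)
  expect_equal(round(ch$specificity, 2), 0.82)
  expect_equal(round(ch$ppv, 2), 0.24)
  expect_equal(round(ch$npv, 2), 0.96)
  # exact count conservation
  expect_equal(ch$sensitivity * (tab$tp + tab$fn), tab$tp)
  expect_equal(ch$specificity * (tab$fp + tab$tn), tab$tn)
  # perfect classifier
  perf <- test_characteristics(contingency_table(10, 0, 0, 20))
  expect_equal(unlist(perf), c(sensitivity = 1, specificity = 1,
                               ppv = 1, npv = 1))
  # zero-cell behavior: ppv 0 when tp = 0 but predictions exist; NA when
  # the margin is empty
  expect_equal(test_characteristics(contingency_table(0, 5, 3, 12))$ppv, 0)
  expect_true(is.na(test_characteristics(contingency_table(0, 0, 3, 12))$ppv))
})

test_that("likelihood ratios and their infinities", {
  lr <- likelihood_ratios(0.64, 0.82)
  expect_equal(round(lr$lr_pos, 1), 3.6)
  expect_equal(round(lr$lr_neg, 1), 0.4)
  perfect <- likelihood_ratios(1, 1)
  expect_true(is.infinite(perfect$lr_pos) && perfect$lr_pos_infinite)
  expect_equal(perfect$lr_neg, 0)
  unif <- likelihood_ratios(0.5, 0.5)
  expect_equal(c(unif$lr_pos, unif$lr_neg), c(1, 1))
})

test_that("prevalence-adjusted LRs are post-test odds", {
  p <- 25 / 312
  adj <- prevalence_adjusted_lrs(0.56, 0.84, p)
  expect_equal(round(adj$lr_pos_prev, 2), 0.30)
  expect_equal(round(adj$lr_neg_prev, 2), 0.05)
  adj_teen <- prevalence_adjusted_lrs(0.64, 0.82, p)
  expect_equal(round(adj_teen$lr_neg_prev, 2), 0.04)
  # at prevalence 0.5 the pre-test odds are 1: adjusted = raw
  lr <- likelihood_ratios(0.7, 0.9)
  adj5 <- prevalence_adjusted_lrs(0.7, 0.9, 0.5)
  expect_equal(adj5$lr_pos_prev, lr$lr_pos)
  expect_error(prevalence_adjusted_lrs(0.7, 0.9, 0), "prevalence")
})

test_that("adjusted LRs equal the Bayes predictive-value identities", {
  set.seed(31)
  for (i in 1:200) {
    sens <- runif(1, 0.05, 0.95); spec <- runif(1, 0.05, 0.95)
    p <- runif(1, 0.01, 0.6)
    adj <- prevalence_adjusted_lrs(sens, spec, p)
    pv <- predictive_values(sens, spec, p)
    expect_equal(adj$lr_pos_prev, pv$ppv / (1 - pv$ppv), tolerance = 1e-12)
    expect_equal(adj$lr_neg_prev, (1 - pv$npv) / pv$npv, tolerance = 1e-12)
  }
})

test_that("Wilson interval matches the quadratic solution and prop.test", {
  # direct quadratic: roots of (p - phat)^2 = z^2 p(1-p)/n
  wilson_roots <- function(k, n, level = 0.95) {
    z <- qnorm(1 - (1 - level) / 2)
    ph <- k / n
    a <- 1 + z^2 / n
    b <- -(2 * ph + z^2 / n)
    cc <- ph^2
    c((-b - sqrt(b^2 - 4 * a * cc)) / (2 * a),
      (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a))
  }
  for (kn in list(c(9, 14), c(1, 30), c(25, 312), c(133, 138))) {
    got <- proportion_ci(kn[1], kn[2])
    expect_equal(unname(got), wilson_roots(kn[1], kn[2]), tolerance = 1e-12)
    pt <- prop.test(kn[1], kn[2], correct = FALSE)$conf.int
    expect_equal(unname(got), as.numeric(pt), tolerance = 1e-9)
  }
  # boundaries
  expect_equal(proportion_ci(0, 10)[["lo"]], 0)
  expect_equal(proportion_ci(10, 10)[["hi"]], 1)
})

test_that("Clopper-Pearson interval matches binom.test", {
  for (kn in list(c(9, 14), c(0, 10), c(10, 10), c(25, 312))) {
    got <- proportion_ci(kn[1], kn[2], method = "clopper-pearson")
    bt <- binom.test(kn[1], kn[2])$conf.int
    expect_equal(unname(got), as.numeric(bt), tolerance = 1e-9)
  }
})

test_that("log-method LR interval behaves like a variance in 1/n", {
  tab <- contingency_table(20, 40, 10, 130)
  ci <- lr_ci(tab, "pos")
  expect_true(ci$lo < ci$estimate && ci$estimate < ci$hi)
  # scaling all cells x4 halves the log-width (variance ~ 1/n)
  tab4 <- contingency_table(80, 160, 40, 520)
  w1 <- log(ci$hi) - log(ci$lo)
  w4 <- log(lr_ci(tab4, "pos")$hi) - log(lr_ci(tab4, "pos")$lo)
  expect_equal(w4, w1 / 2, tolerance = 0.01)
  # zero cell triggers the continuity flag
  ci0 <- lr_ci(contingency_table(5, 0, 3, 20), "pos")
  expect_true(ci0$continuity)
  # degenerate table flagged undefined
  expect_true(lr_ci(contingency_table(7, 0, 0, 0), "pos")$undefined)
})

test_that("summary_table produces one row per threshold x stratum", {
  set.seed(12)
  d <- simulate_scores(400, 0.15, 0.4, 0.18)
  stratum <- sample(c("teen", "preteen"), 400, replace = TRUE)
  tab <- summary_table(d$total, d$is_osa, stratum)
  expect_equal(nrow(tab), 9)
  expect_setequal(unique(tab$stratum), c("all", "teen", "preteen"))
  # sens/spec monotone across the threshold sweep within each stratum
  for (st in unique(tab$stratum)) {
    rows <- tab[tab$stratum == st, ]
    rows <- rows[order(rows$threshold), ]
    expect_true(all(diff(rows$sensitivity) <= 0))
    expect_true(all(diff(rows$specificity) >= 0))
  }
  # adjusted LRs recompute from the panel's own columns
  odds <- tab$prevalence / (1 - tab$prevalence)
  expect_equal(tab$lr_pos_prev, tab$lr_pos * odds, tolerance = 1e-12)
})

test_that("threshold monotonicity holds across the full 0-9 sweep", {
  set.seed(99)
  d <- simulate_scores(500, 0.2, 0.45, 0.15)
  sens <- spec <- numeric(0)
  for (th in 0:9) {
    tab <- build_contingency(d$total, d$is_osa, th)
    ch <- test_characteristics(tab)
    sens <- c(sens, ch$sensitivity); spec <- c(spec, ch$specificity)
  }
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(spec) >= 0))
})

test_that("half-up display rounding matches the printed conventions", {
  expect_equal(round_half_up(3.55, 1), 3.6)
  expect_equal(round_half_up(0.045, 2), 0.05)
  expect_equal(round_half_up(0.235, 2), 0.24)
  expect_equal(round_half_up(-1.25, 1), -1.3)
})
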