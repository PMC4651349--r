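test_that("BMI arithmetic is exact and linear in weight", {
  expect_equal(round(compute_bmi(60, 170), 2), 20.76)
  expect_equal(compute_bmi(50, 100), 50)
  expect_equal(compute_bmi(90, 170), 1.5 * compute_bmi(60, 170))
  expect_error(compute_bmi(-1, 170), "positive")
})

test_that("LMS z-score matches its closed forms and inverts", {
  expect_equal(lms_zscore(20, 1, 20, 0.1), 0)
  expect_equal(lms_percentile(20, 1, 20, 0.1), 50)
  # L = 1, M = 20, S = 0.1, x = 22 -> z = 1 -> 84.13th percentile
  expect_equal(lms_zscore(22, 1, 20, 0.1), 1)
  expect_equal(round(lms_percentile(22, 1, 20, 0.1), 2), 84.13)
  # L -> 0 continuity against the log form
  grid <- expand.grid(x = c(15, 18, 22, 26), M = c(17, 20), S = c(0.08, 0.13))
  z_small_l <- lms_zscore(grid$x, 1e-8, grid$M, grid$S)
  z_log <- log(grid$x / grid$M) / grid$S
  expect_true(all(abs(z_small_l - z_log) < 1e-6))
  # invertibility to 1e-9 relative tolerance
  set.seed(42)
  for (i in 1:50) {
    L <- runif(1, -3, 3); M <- runif(1, 10, 30); S <- runif(1, 0.05, 0.2)
    z <- runif(1, -2.5, 2.5)
    x <- lms_inverse(z, L, M, S)
    expect_equal(lms_zscore(x, L, M, S), z, tolerance = 1e-9)
  }
})

test_that("BMI percentile interpolates L,M,S linearly in age", {
  refs <- toy_refs()
  refs$bmi_lms <- toy_lms()
  # midpoint age 126 mo: M interpolates to 19, so bmi 19 sits at the median
  expect_equal(bmi_percentile(19, "male", 126, refs), 50)
  expect_equal(bmi_percentile(18, "male", 120, refs), 50)
  # strictly increasing in bmi at fixed age
  p <- vapply(seq(15, 24, by = 0.5),
              function(b) bmi_percentile(b, "male", 126, refs), numeric(1))
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 100))
  expect_error(bmi_percentile(19, "male", 300, refs), "range")
})

test_that("LMS percentile is continuous in age across tabulated knots", {
  refs <- default_reference_set()
  knots <- sort(unique(refs$bmi_lms$age_months[refs$bmi_lms$sex == "male"]))
  inner <- knots[knots > min(knots) & knots < max(knots)]
  for (k in inner) {
    below <- bmi_percentile(20, "male", k - 1e-7, refs)
    above <- bmi_percentile(20, "male", k + 1e-7, refs)
    expect_lt(abs(below - above), 1e-6)
  }
})

test_that("BP percentile reduces to a plain normal CDF with zero terms", {
  refs <- toy_refs()  # intercepts 100/60, polynomial terms all zero, sd 10
  expect_equal(bp_percentile(100, "male", "systolic", 12, 150, refs), 50)
  expect_equal(round(bp_percentile(110, "male", "systolic", 12, 150, refs),
                     2), 84.13)
  expect_equal(bp_percentile(100 + 1.645 * 10, "male", "systolic", 12, 150,
                             refs), 95, tolerance = 1e-3)
  # matches pnorm for arbitrary observed values (closed-form limit)
  obs <- seq(70, 130, by = 5)
  got <- vapply(obs, function(o)
    bp_percentile(o, "female", "systolic", 14, 160, refs), numeric(1))
  expect_equal(got, 100 * pnorm((obs - 100) / 10))
})

test_that("BP expected value uses the age and height polynomials", {
  refs <- toy_refs()
  refs$bp_coeffs$a1 <- 2          # +2 mmHg per year past age 10
  refs$bp_coeffs$h1 <- 3          # +3 mmHg per height z
  # male height LMS: M interpolates 130->175 over 96-240 mo; at 168 mo M=152.5
  # choose height one SD above: z = 1
  h <- 152.5 * (1 + 0.045)
  expected <- 100 + 2 * 4 + 3 * 1
  expect_equal(bp_percentile(expected, "male", "systolic", 14, h, refs), 50,
               tolerance = 1e-6)
})

test_that("anthropometric flags apply the max/strict/boundary rules", {
  refs <- toy_refs()
  # bp: max of systolic/diastolic percentiles with >= 95 rule
  subj <- make_subject(sbp = 100 + 1.7 * 10, dbp = 60, height = 152.5,
                       weight = 46.5, neck = 30)
  fl <- anthropometric_flags(subj, refs)
  expect_true(fl$bp_flag)       # systolic at ~95.5th, diastolic at 50th
  subj$sbp_mmhg <- 100 + 1.5 * 10   # 93.3rd
  expect_false(anthropometric_flags(subj, refs)$bp_flag)

  # bmi flag is strictly greater-than the cut
  m_at_14 <- approx(c(96, 240), c(16.5, 21.5), xout = 14 * 12)$y
  bmi95 <- lms_inverse(qnorm(0.95), 1, m_at_14, 0.12)
  subj$weight_kg <- bmi95 * (subj$height_cm / 100)^2
  fl <- anthropometric_flags(subj, refs)
  expect_equal(fl$bmi_percentile, 95, tolerance = 1e-9)
  expect_false(fl$bmi_flag)
  subj2 <- subj; subj2$weight_kg <- subj$weight_kg * 1.001
  expect_true(anthropometric_flags(subj2, refs)$bmi_flag)
  # configurable cut
  expect_true(anthropometric_flags(subj, refs, bmi_cut = 90)$bmi_flag)

  # neck: strict > p95 at nearest integer age (age 14 -> p95 = 34.8)
  subj$neck_cm <- 34.8 + 0.1
  expect_true(anthropometric_flags(subj, refs)$neck_flag)
  subj$neck_cm <- 34.8 - 0.1
  expect_false(anthropometric_flags(subj, refs)$neck_flag)
})

test_that("bundled synthetic reference set loads and is well-formed", {
  refs <- default_reference_set()
  expect_s3_class(refs, "reference_set")
  for (tab in list(refs$bmi_lms, refs$height_lms)) {
    expect_true(all(tab$M > 0) && all(tab$S > 0))
  }
  expect_true(all(refs$bp_coeffs$sd > 0))
  # percentile outputs strictly inside (0, 100) over a realistic grid
  set.seed(7)
  for (i in 1:30) {
    p <- bmi_percentile(runif(1, 14, 30), sample(c("male", "female"), 1),
                        runif(1, 108, 210), refs)
    expect_true(p > 0 && p < 100)
  }
})
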