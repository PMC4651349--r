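## Pediatric growth references: LMS percentiles, BP regression, neck lookup.

#' Body mass index
#'
#' @param weight_kg weight in kg, `> 0`.
#' @param height_cm height in cm, `> 0`.
#' @return BMI in kg/m^2.
#' @export
compute_bmi <- function(weight_kg, height_cm) {
  if (any(weight_kg <= 0) || any(height_cm <= 0))
    stop("weight and height must be positive", call. = FALSE)
  weight_kg / (height_cm / 100)^2
}

#' LMS (Box-Cox) z-score
#'
#' Growth references parameterize a measurement's age- and sex-conditional
#' distribution by a Box-Cox power `L`, median `M` and coefficient of
#' variation `S`. The z-score of a measurement `x` is
#' `((x/M)^L - 1) / (L*S)` for `L != 0` and `log(x/M)/S` at `L = 0`
#' (the continuous limit).
#'
#' @param x measurement, `> 0`.
#' @param L Box-Cox power (unitless).
#' @param M median of the measure at this age/sex, `> 0`.
#' @param S coefficient of variation, `> 0`.
#' @return z-score (vectorized over all arguments).
#' @seealso [lms_inverse()], [lms_percentile()]
#' @export
lms_zscore <- function(x, L, M, S) {
  if (any(x <= 0) || any(M <= 0) || any(S <= 0))
    stop("x, M and S must be positive", call. = FALSE)
  n <- max(length(x), length(L), length(M), length(S))
  x <- rep_len(x, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  z <- ifelse(L == 0, log(x / M) / S, ((x / M)^L - 1) / (L * S))
  z
}

#' Inverse LMS transform: measurement at a given z-score
#'
#' @inheritParams lms_zscore
#' @param z z-score.
#' @return measurement `x` such that `lms_zscore(x, L, M, S) == z`.
#' @export
lms_inverse <- function(z, L, M, S) {
  ifelse(L == 0, M * exp(S * z), M * (1 + L * S * z)^(1 / L))
}

#' Percentile from an LMS z-score
#'
#' @inheritParams lms_zscore
#' @return percentile in (0, 100): `pnorm(z) * 100`.
#' @export
lms_percentile <- function(x, L, M, S) {
  100 * stats::pnorm(lms_zscore(x, L, M, S))
}

## Reference table container ---------------------------------------------------

#' Assemble a reference set
#'
#' Bundles the four lookup tables the anthropometric flags need, under a
#' common (sex, age) contract:
#' \describe{
#'   \item{bmi_lms}{columns `sex`, `age_months`, `L`, `M`, `S` — BMI-for-age.}
#'   \item{height_lms}{same schema — height-for-age (feeds the BP model's
#'     height z-score).}
#'   \item{bp_coeffs}{columns `sex`, `measure` (systolic/diastolic),
#'     `intercept`, `a1..a4` (polynomial in age - 10 years), `h1..h4`
#'     (polynomial in height z-score), `sd` — expected-BP regression.}
#'   \item{neck_p95}{columns `sex`, `age_years` (integer), `p95_cm` —
#'     neck-circumference 95th percentile.}
#' }
#'
#' @param bmi_lms,height_lms,bp_coeffs,neck_p95 data.frames with the schemas
#'   above.
#' @return object of class `"reference_set"`.
#' @export
reference_set <- function(bmi_lms, height_lms, bp_coeffs, neck_p95) {
  check_lms <- function(tab, what) {
    need <- c("sex", "age_months", "L", "M", "S")
    if (!all(need %in% names(tab)))
      stop(what, " table needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    if (any(tab$M <= 0) || any(tab$S <= 0))
      stop(what, " table: M and S must be positive", call. = FALSE)
    for (sx in unique(tab$sex)) {
      a <- tab$age_months[tab$sex == sx]
      if (is.unsorted(a, strictly = TRUE))
        stop(what, " table: ages must be strictly increasing within sex",
             call. = FALSE)
    }
    tab
  }
  check_lms(bmi_lms, "bmi_lms")
  check_lms(height_lms, "height_lms")
  need_bp <- c("sex", "measure", "intercept", paste0("a", 1:4),
               paste0("h", 1:4), "sd")
  if (!all(need_bp %in% names(bp_coeffs)))
    stop("bp_coeffs needs columns: ", paste(need_bp, collapse = ", "),
         call. = FALSE)
  if (any(bp_coeffs$sd <= 0)) stop("bp_coeffs: sd must be positive",
                                   call. = FALSE)
  if (!all(c("sex", "age_years", "p95_cm") %in% names(neck_p95)))
    stop("neck_p95 needs columns: sex, age_years, p95_cm", call. = FALSE)
  if (any(neck_p95$p95_cm <= 0)) stop("neck_p95: p95_cm must be positive",
                                      call. = FALSE)
  structure(list(bmi_lms = bmi_lms, height_lms = height_lms,
                 bp_coeffs = bp_coeffs, neck_p95 = neck_p95),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  rng <- range(x$bmi_lms$age_months) / 12
  cat(sprintf(paste0("Pediatric reference set: BMI/height LMS ages ",
                     "%.1f-%.1f y, %d BP coefficient rows, ",
                     "%d neck p95 rows\n"),
              rng[1], rng[2], nrow(x$bp_coeffs), nrow(x$neck_p95)))
  invisible(x)
}

#' Read a reference set from a directory of CSV files
#'
#' Expects `bmi_lms.csv`, `height_lms.csv`, `bp_coefficients.csv`,
#' `neck_p95.csv` (a `synthetic_` filename prefix is also accepted, as used by
#' the bundled default tables).
#'
#' @param dir directory containing the four CSVs.
#' @return a [reference_set()].
#' @export
read_reference_set <- function(dir) {
  find1 <- function(base) {
    for (nm in c(base, paste0("synthetic_", base))) {
      p <- file.path(dir, nm)
      if (file.exists(p)) return(p)
    }
    stop("reference file not found in ", dir, ": ", base, call. = FALSE)
  }
  rd <- function(base) utils::read.csv(find1(base), stringsAsFactors = FALSE)
  reference_set(rd("bmi_lms.csv"), rd("height_lms.csv"),
                rd("bp_coefficients.csv"), rd("neck_p95.csv"))
}

#' Bundled default reference set (synthetic)
#'
#' The package ships a default set of smooth, plausibly shaped reference
#' tables covering ages ~8.5-18 years. They are SYNTHETIC: constructed to
#' have realistic magnitudes and age trends, not copied from any published
#' growth reference, and therefore suitable for testing the percentile
#' machinery and for simulation, not for clinical use. Plug in real tables
#' via [reference_set()] / [read_reference_set()] for clinical work.
#'
#' @return a [reference_set()].
#' @export
default_reference_set <- function() {
  dir <- system.file("extdata", package = "teenstopbang")
  read_reference_set(dir)
}

interp_lms <- function(tab, sex, age_months) {
  rows <- tab[tab$sex == sex, , drop = FALSE]
  if (nrow(rows) < 2)
    stop("reference table has no rows for sex: ", sex, call. = FALSE)
  lo <- min(rows$age_months); hi <- max(rows$age_months)
  if (any(age_months < lo | age_months > hi))
    stop(sprintf("age %.1f months outside supported range [%g, %g] for %s",
                 age_months[age_months < lo | age_months > hi][1], lo, hi,
                 sex), call. = FALSE)
  list(L = stats::approx(rows$age_months, rows$L, xout = age_months)$y,
       M = stats::approx(rows$age_months, rows$M, xout = age_months)$y,
       S = stats::approx(rows$age_months, rows$S, xout = age_months)$y)
}

#' BMI-for-age percentile
#'
#' Interpolates L, M, S linearly in age between the bracketing tabulated
#' rows for the subject's sex, then applies the LMS z-score and the standard
#' normal CDF.
#'
#' @param bmi BMI in kg/m^2.
#' @param sex `"male"` or `"female"`.
#' @param age_months age in months; must lie within the table's range.
#' @param refs a [reference_set()] (default: bundled synthetic tables).
#' @return percentile in (0, 100).
#' @export
bmi_percentile <- function(bmi, sex, age_months,
                           refs = default_reference_set()) {
  p <- interp_lms(refs$bmi_lms, sex, age_months)
  lms_percentile(bmi, p$L, p$M, p$S)
}

#' Blood-pressure percentile for sex, age and height
#'
#' The expected BP is modeled as
#' `intercept + sum_j a_j (age - 10)^j + sum_k h_k z_height^k` (j, k = 1..4),
#' where `z_height` is the height-for-age LMS z-score; the percentile is the
#' normal CDF of `(observed - expected) / sd` times 100. The observed value
#' should be the mean of the 2nd and 3rd seated readings (averaging happens
#' at data entry, upstream of this function).
#'
#' @param observed observed BP, mmHg.
#' @param sex `"male"` or `"female"`.
#' @param measure `"systolic"` or `"diastolic"`.
#' @param age_years decimal age in years.
#' @param height_cm height in cm (converted to a z-score internally).
#' @param refs a [reference_set()].
#' @return percentile in (0, 100).
#' @export
bp_percentile <- function(observed, sex, measure = c("systolic", "diastolic"),
                          age_years, height_cm,
                          refs = default_reference_set()) {
  measure <- match.arg(measure)
  co <- refs$bp_coeffs[refs$bp_coeffs$sex == sex &
                         refs$bp_coeffs$measure == measure, , drop = FALSE]
  if (nrow(co) != 1)
    stop("no BP coefficients for ", sex, "/", measure, call. = FALSE)
  hz <- lms_zscore_for(refs$height_lms, height_cm, sex, age_years * 12)
  y <- age_years - 10
  expected <- co$intercept +
    co$a1 * y + co$a2 * y^2 + co$a3 * y^3 + co$a4 * y^4 +
    co$h1 * hz + co$h2 * hz^2 + co$h3 * hz^3 + co$h4 * hz^4
  100 * stats::pnorm((observed - expected) / co$sd)
}

lms_zscore_for <- function(tab, x, sex, age_months) {
  p <- interp_lms(tab, sex, age_months)
  lms_zscore(x, p$L, p$M, p$S)
}

#' Anthropometric score flags for a cohort
#'
#' Derives, for each subject, the three measurement-based score items:
#' \itemize{
#'   \item `bmi_flag`: BMI-for-age percentile strictly greater than
#'     `bmi_cut` (default 95; 90 and 99 are the usual sensitivity-analysis
#'     cuts);
#'   \item `bp_flag`: max(systolic percentile, diastolic percentile) at or
#'     above the 95th for height and age;
#'   \item `neck_flag`: neck circumference strictly greater than the
#'     reference 95th percentile at the nearest integer age for the
#'     subject's sex.
#' }
#'
#' @param cohort cohort data.frame (complete anthropometrics required).
#' @param refs a [reference_set()].
#' @param bmi_cut BMI percentile cut (strict `>`), default 95.
#' @return data.frame with `subject_id`, `bmi`, `bmi_percentile`,
#'   `bp_percentile_max`, `bmi_flag`, `bp_flag`, `neck_flag`.
#' @export
anthropometric_flags <- function(cohort, refs = default_reference_set(),
                                 bmi_cut = 95) {
  bmi <- compute_bmi(cohort$weight_kg, cohort$height_cm)
  n <- nrow(cohort)
  bmi_pct <- numeric(n); sys_pct <- numeric(n); dia_pct <- numeric(n)
  neck_flag <- logical(n)
  for (i in seq_len(n)) {
    sx <- cohort$sex[i]
    bmi_pct[i] <- bmi_percentile(bmi[i], sx, cohort$age_years[i] * 12, refs)
    sys_pct[i] <- bp_percentile(cohort$sbp_mmhg[i], sx, "systolic",
                                cohort$age_years[i], cohort$height_cm[i], refs)
    dia_pct[i] <- bp_percentile(cohort$dbp_mmhg[i], sx, "diastolic",
                                cohort$age_years[i], cohort$height_cm[i], refs)
    neck_flag[i] <- cohort$neck_cm[i] > neck_p95_lookup(
      refs, sx, cohort$age_years[i])
  }
  bp_max <- pmax(sys_pct, dia_pct)
  data.frame(subject_id = cohort$subject_id,
             bmi = bmi,
             bmi_percentile = bmi_pct,
             bp_percentile_max = bp_max,
             bmi_flag = bmi_pct > bmi_cut,
             bp_flag = bp_max >= 95,
             neck_flag = neck_flag,
             stringsAsFactors = FALSE)
}

#' Neck-circumference 95th-percentile lookup
#'
#' Reference tabulated by integer year; the subject's decimal age is rounded
#' to the nearest year (clamped to the table's range is NOT done — out-of-range
#' ages error).
#'
#' @param refs a [reference_set()].
#' @param sex `"male"` or `"female"`.
#' @param age_years decimal age.
#' @return p95 neck circumference in cm.
#' @export
neck_p95_lookup <- function(refs, sex, age_years) {
  age <- round(age_years)
  row <- refs$neck_p95[refs$neck_p95$sex == sex &
                         refs$neck_p95$age_years == age, , drop = FALSE]
  if (nrow(row) != 1)
    stop(sprintf("no neck reference for %s at age %d (supported: %s)",
                 sex, age,
                 paste(range(refs$neck_p95$age_years), collapse = "-")),
         call. = FALSE)
  row$p95_cm
}
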