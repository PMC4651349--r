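## Synthetic cohort generator: seeded, class-conditional Bernoulli items,
## anthropometrics back-solved against the reference set so the percentile
## machinery reproduces the intended flags.

score_item_names <- function() {
  c("snoring", "tired", "observed_apnea", "bp", "bmi", "academic", "neck",
    "male")
}

#' Calibrate exchangeable item probabilities to a target operating point
#'
#' With eight conditionally independent items sharing a per-class positivity
#' probability, the score is binomial and the score >= threshold rate is a
#' binomial upper tail. This inverts that tail: it finds `p_osa` such that
#' `P(Binom(8, p_osa) >= threshold) = target_sens` and `p_healthy` such that
#' `P(Binom(8, p_healthy) >= threshold) = 1 - target_spec`.
#'
#' @param target_sens desired sensitivity at the threshold, in \[0, 1\].
#' @param target_spec desired specificity, in \[0, 1\].
#' @param threshold integer score cut in 1..8.
#' @param n_items number of items (8 full instrument, 7 neck-free).
#' @return list `p_osa`, `p_healthy`, `achieved_sens`, `achieved_spec`.
#' @export
calibrate_items <- function(target_sens, target_spec, threshold = 3,
                            n_items = 8) {
  if (threshold < 1 || threshold > n_items)
    stop("threshold must be in 1..n_items (tail rate is degenerate outside)",
         call. = FALSE)
  tail_rate <- function(p) 1 - stats::pbinom(threshold - 1, n_items, p)
  invert <- function(target) {
    if (target <= 0) return(0)
    if (target >= 1) return(1)
    stats::uniroot(function(p) tail_rate(p) - target, c(0, 1),
                   tol = 1e-12)$root
  }
  p_osa <- invert(target_sens)
  p_healthy <- invert(1 - target_spec)
  list(p_osa = p_osa, p_healthy = p_healthy,
       achieved_sens = tail_rate(p_osa),
       achieved_spec = 1 - tail_rate(p_healthy))
}

#' Exact AUC of the binomial score model
#'
#' For scores distributed Binom(`n_items`, `p_osa`) in cases and
#' Binom(`n_items`, `p_healthy`) in controls, the population AUC is
#' `P(S_case > S_control) + 0.5 P(tie)`, computable exactly from the two
#' binomial mass functions. Used as ground truth in coverage simulations.
#'
#' @param p_osa,p_healthy per-item positivity probabilities.
#' @param n_items number of items.
#' @return AUC in \[0, 1\].
#' @export
binomial_score_auc <- function(p_osa, p_healthy, n_items = 8) {
  s <- 0:n_items
  d1 <- stats::dbinom(s, n_items, p_osa)
  d0 <- stats::dbinom(s, n_items, p_healthy)
  gt <- outer(s, s, ">"); eq <- outer(s, s, "==")
  sum(outer(d1, d0) * (gt + 0.5 * eq))
}

#' Simulation configuration
#'
#' Defaults encode the emulated study conditions: 312 children aged 9-17,
#' OSA prevalence 0.08, item probabilities calibrated so that the score
#' reaches sensitivity 0.64 and specificity 0.82 at the >= 3 cut (which also
#' yields healthy-median 1 / OSA-median 3 scores), child answers agreeing
#' with the parent's on 80% of items, and AHI medians near 0.2 (healthy) and
#' 2.2 (OSA).
#'
#' @param n cohort size.
#' @param prevalence OSA prevalence in (0, 1).
#' @param seed integer seed; the generator is deterministic given it.
#' @param age_range numeric length-2, years.
#' @param sex_ratio proportion male, used only if the `male` item probability
#'   is `NA` (by default sex is driven by the male item flag so the
#'   exchangeable calibration stays exact).
#' @param item_prob_given_osa,item_prob_given_healthy named numeric vectors
#'   over the eight items (see `score_item_names()`); default: exchangeable
#'   calibrated probabilities.
#' @param reporter_agreement probability a child response matches the
#'   parent's, per item.
#' @param smr_age_slope logistic slope (per year, centred at 13.5 y) for
#'   P(SMR >= 4).
#' @param smr_missing probability the self-assessed SMR is missing.
#' @param bmi_cut BMI percentile cut the generator back-solves against.
#' @return list of class `"simulation_config"`.
#' @export
simulation_config <- function(n = 312, prevalence = 0.08, seed = 1,
                              age_range = c(9, 17), sex_ratio = 0.5,
                              item_prob_given_osa = NULL,
                              item_prob_given_healthy = NULL,
                              reporter_agreement = 0.8,
                              smr_age_slope = 1.5,
                              smr_missing = 21 / 312,
                              bmi_cut = 95) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must be in (0, 1)", call. = FALSE)
  cal <- calibrate_items(0.64, 0.82, threshold = 3, n_items = 8)
  fill <- function(x, default) {
    if (is.null(x)) x <- stats::setNames(rep(default, 8), score_item_names())
    if (!all(score_item_names() %in% names(x)))
      stop("item probabilities must be named over: ",
           paste(score_item_names(), collapse = ", "), call. = FALSE)
    x <- x[score_item_names()]
    if (any(!is.na(x) & (x < 0 | x > 1)))
      stop("item probabilities must lie in [0, 1]", call. = FALSE)
    x
  }
  probs <- c(reporter_agreement, smr_missing, sex_ratio)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(
    n = n, prevalence = prevalence, seed = seed, age_range = age_range,
    sex_ratio = sex_ratio,
    item_prob_given_osa = fill(item_prob_given_osa, cal$p_osa),
    item_prob_given_healthy = fill(item_prob_given_healthy, cal$p_healthy),
    reporter_agreement = reporter_agreement,
    smr_age_slope = smr_age_slope, smr_missing = smr_missing,
    bmi_cut = bmi_cut), class = "simulation_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

sample_response <- function(positive) {
  if (positive) {
    sample(c("frequently", "almost_always"), 1, prob = c(0.6, 0.4))
  } else {
    sample(c("dont_know", "never", "rarely", "occasionally"), 1,
           prob = c(0.05, 0.45, 0.30, 0.20))
  }
}

#' Simulate a full synthetic cohort
#'
#' Draws OSA status Bernoulli(prevalence) and AHI from class-conditional
#' lognormals (healthy median 0.2 truncated below the diagnostic cut, OSA
#' median 2.2 above it) so labels and AHI are always mutually consistent at
#' the 1.5 events/hour cut. Each of the eight score items is Bernoulli given
#' status; the questionnaire items are rendered as ordinal responses that
#' collapse back to the intended flag, and the anthropometrics (BMI, blood
#' pressure, neck) are back-solved against the reference set — a fixed offset
#' above or below the relevant percentile cutoff — so
#' [anthropometric_flags()] reproduces the intended flags exactly. Child
#' responses copy the parent's with probability `reporter_agreement`, else
#' are resampled from the item's class-conditional law.
#'
#' @param config a [simulation_config()].
#' @param refs a [reference_set()] used for the back-solving.
#' @return list of class `"synthetic_cohort"`: `records` (cohort
#'   data.frame), `truth` (`subject_id`, `is_osa`), `config`.
#' @export
simulate_cohort <- function(config = simulation_config(),
                            refs = default_reference_set()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n <- config$n
    is_osa <- stats::runif(n) < config$prevalence
    ahi <- numeric(n)
    nh <- sum(!is_osa)
    h <- stats::rlnorm(nh, log(0.2), 0.7)
    while (any(h >= 1.4)) h[h >= 1.4] <- stats::rlnorm(sum(h >= 1.4),
                                                       log(0.2), 0.7)
    ahi[!is_osa] <- h
    ahi[is_osa] <- 1.5 + stats::rlnorm(sum(is_osa), log(0.7), 0.8)

    p_mat <- matrix(config$item_prob_given_healthy, n, 8, byrow = TRUE,
                    dimnames = list(NULL, score_item_names()))
    p_osa_mat <- matrix(config$item_prob_given_osa, n, 8, byrow = TRUE)
    p_mat[is_osa, ] <- p_osa_mat[is_osa, ]
    flags <- matrix(stats::runif(n * 8) < p_mat, n, 8,
                    dimnames = list(NULL, score_item_names()))

    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    sex <- if (is.na(config$item_prob_given_osa["male"])) {
      ifelse(stats::runif(n) < config$sex_ratio, "male", "female")
    } else {
      ifelse(flags[, "male"], "male", "female")
    }
    ethnicity <- sample(c("caucasian", "hispanic"), n, replace = TRUE,
                        prob = c(0.65, 0.35))

    height <- numeric(n); weight <- numeric(n)
    sbp <- numeric(n); dbp <- numeric(n); neck <- numeric(n)
    z_h <- pmin(2.2, pmax(-2.2, stats::rnorm(n)))
    bmi_pct <- ifelse(flags[, "bmi"], config$bmi_cut + 2.5,
                      config$bmi_cut - 30)
    bp_off <- ifelse(flags[, "bp"], 1.8, -0.2)
    for (sx in unique(sex)) {
      idx <- which(sex == sx)
      hp <- interp_lms(refs$height_lms, sx, age[idx] * 12)
      height[idx] <- lms_inverse(z_h[idx], hp$L, hp$M, hp$S)
      bpar <- interp_lms(refs$bmi_lms, sx, age[idx] * 12)
      bmi_i <- lms_inverse(stats::qnorm(bmi_pct[idx] / 100),
                           bpar$L, bpar$M, bpar$S)
      weight[idx] <- bmi_i * (height[idx] / 100)^2
      sbp[idx] <- expected_bp(refs, sx, "systolic", age[idx], height[idx]) +
        bp_off[idx] * bp_sd(refs, sx, "systolic")
      dbp[idx] <- expected_bp(refs, sx, "diastolic", age[idx], height[idx]) -
        0.2 * bp_sd(refs, sx, "diastolic")
      nk <- refs$neck_p95[refs$neck_p95$sex == sx, ]
      pos <- match(round(age[idx]), nk$age_years)
      if (anyNA(pos))
        stop("no neck reference for ", sx, " at age ",
             round(age[idx])[is.na(pos)][1], call. = FALSE)
      neck[idx] <- nk$p95_cm[pos] + ifelse(flags[idx, "neck"], 0.5, -0.5)
    }

    q_items <- c("snoring", "tired", "observed_apnea", "academic")
    parent <- matrix("", n, 4, dimnames = list(NULL, q_items))
    child <- parent
    for (i in seq_len(n)) {
      for (j in seq_along(q_items)) {
        parent[i, j] <- sample_response(flags[i, q_items[j]])
        if (stats::runif(1) < config$reporter_agreement) {
          child[i, j] <- parent[i, j]
        } else {
          p_item <- p_mat[i, q_items[j]]
          child[i, j] <- sample_response(stats::runif(1) < p_item)
        }
      }
    }

    p_high <- stats::plogis(config$smr_age_slope * (age - 13.5))
    smr <- ifelse(stats::runif(n) < p_high,
                  sample(4:5, n, replace = TRUE, prob = c(0.6, 0.4)),
                  sample(1:3, n, replace = TRUE, prob = c(0.2, 0.35, 0.45)))
    smr[stats::runif(n) < config$smr_missing] <- NA

    records <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      age_years = age, sex = sex, ethnicity = ethnicity,
      height_cm = height, weight_kg = weight,
      sbp_mmhg = sbp, dbp_mmhg = dbp, neck_cm = neck,
      smr = as.integer(smr), ahi = ahi,
      parent_snoring = parent[, "snoring"], parent_tired = parent[, "tired"],
      parent_observed = parent[, "observed_apnea"],
      parent_academic = parent[, "academic"],
      child_snoring = child[, "snoring"], child_tired = child[, "tired"],
      child_observed = child[, "observed_apnea"],
      child_academic = child[, "academic"],
      stringsAsFactors = FALSE
    )
    structure(list(records = records,
                   truth = data.frame(subject_id = records$subject_id,
                                      is_osa = is_osa,
                                      stringsAsFactors = FALSE),
                   config = config),
              class = "synthetic_cohort")
  })
}

expected_bp <- function(refs, sex, measure, age_years, height_cm) {
  co <- refs$bp_coeffs[refs$bp_coeffs$sex == sex &
                         refs$bp_coeffs$measure == measure, ]
  hz <- lms_zscore_for(refs$height_lms, height_cm, sex, age_years * 12)
  y <- age_years - 10
  co$intercept + co$a1 * y + co$a2 * y^2 + co$a3 * y^3 + co$a4 * y^4 +
    co$h1 * hz + co$h2 * hz^2 + co$h3 * hz^3 + co$h4 * hz^4
}

bp_sd <- function(refs, sex, measure) {
  refs$bp_coeffs$sd[refs$bp_coeffs$sex == sex &
                      refs$bp_coeffs$measure == measure]
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: n = %d, %d OSA (prevalence %.3f), seed %d\n",
              nrow(x$records), sum(x$truth$is_osa), mean(x$truth$is_osa),
              x$config$seed))
  invisible(x)
}

#' Simulate score/label pairs only (score-level marginal)
#'
#' The marginal law of the count score under the full generator: labels
#' Bernoulli(prevalence), scores Binom(`n_items`, class probability). Used
#' for large replicate studies (CI coverage, type-I error) where the
#' anthropometric rendering is irrelevant.
#'
#' @param n subjects.
#' @param prevalence OSA prevalence.
#' @param p_osa,p_healthy per-item probabilities (exchangeable).
#' @param n_items number of items.
#' @return data.frame `total`, `is_osa`.
#' @export
simulate_scores <- function(n, prevalence, p_osa, p_healthy, n_items = 8) {
  is_osa <- stats::runif(n) < prevalence
  total <- ifelse(is_osa, stats::rbinom(n, n_items, p_osa),
                  stats::rbinom(n, n_items, p_healthy))
  data.frame(total = total, is_osa = is_osa)
}
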