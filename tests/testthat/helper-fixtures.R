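# Shared fixtures: a tiny in-code cohort and a toy reference set with
# hand-checkable numbers.

make_subject <- function(id = "S1", age = 14, sex = "male", ahi = 0.3,
                         height = 160, weight = 50, sbp = 105, dbp = 62,
                         neck = 32, smr = 4,
                         parent = rep("never", 4), child = rep("never", 4)) {
  data.frame(
    subject_id = id, age_years = age, sex = sex, ethnicity = "caucasian",
    height_cm = height, weight_kg = weight, sbp_mmhg = sbp, dbp_mmhg = dbp,
    neck_cm = neck, smr = smr, ahi = ahi,
    parent_snoring = parent[1], parent_tired = parent[2],
    parent_observed = parent[3], parent_academic = parent[4],
    child_snoring = child[1], child_tired = child[2],
    child_observed = child[3], child_academic = child[4],
    stringsAsFactors = FALSE
  )
}

make_cohort <- function(n = 6, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n), function(i) {
    make_subject(
      id = sprintf("S%03d", i),
      age = runif(1, 9, 17),
      sex = sample(c("male", "female"), 1),
      ahi = sample(c(0.2, 0.4, 2.5), 1, prob = c(0.6, 0.25, 0.15)),
      parent = sample(response_levels(), 4, replace = TRUE),
      child = sample(response_levels(), 4, replace = TRUE)
    )
  }))
}

# Toy LMS table: L = 1 throughout so z = (x - M)/(M*S) is hand-computable;
# M goes 18 -> 20 between 120 and 132 months.
toy_lms <- function() {
  data.frame(sex = rep(c("male", "female"), each = 2),
             age_months = rep(c(120, 132), 2),
             L = 1, M = rep(c(18, 20), 2), S = 0.1)
}

toy_refs <- function() {
  height <- data.frame(sex = rep(c("male", "female"), each = 2),
                       age_months = rep(c(96, 240), 2),
                       L = 1, M = rep(c(130, 175), 2), S = 0.045)
  bp <- expand.grid(sex = c("male", "female"),
                    measure = c("systolic", "diastolic"),
                    stringsAsFactors = FALSE)
  bp <- cbind(bp, intercept = ifelse(bp$measure == "systolic", 100, 60),
              a1 = 0, a2 = 0, a3 = 0, a4 = 0,
              h1 = 0, h2 = 0, h3 = 0, h4 = 0, sd = 10)
  neck <- data.frame(sex = rep(c("male", "female"), each = 11),
                     age_years = rep(8:18, 2),
                     p95_cm = rep(30 + 0.8 * (8:18 - 8), 2))
  bmi <- data.frame(sex = rep(c("male", "female"), each = 2),
                    age_months = rep(c(96, 240), 2),
                    L = 1, M = rep(c(16.5, 21.5), 2), S = 0.12)
  reference_set(bmi, height, bp, neck)
}
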