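## Teen STOP-Bang scoring: response collapsing and the 0-8 count score.

#' Collapse an ordinal response to a positive/negative item
#'
#' A response of frequently or almost always counts as positive; don't know,
#' never, rarely and occasionally are all negative.
#'
#' @param level character vector of canonical response levels
#'   (see [response_levels()]); raw strings are normalized first.
#' @return logical vector (`NA` where the response is missing).
#' @export
collapse_response <- function(level) {
  lv <- normalize_response(level)
  ifelse(is.na(lv), NA, lv %in% c("frequently", "almost_always"))
}

score_items <- function(variant) {
  base <- c("snoring", "tired", "observed_apnea", "bp", "bmi", "academic",
            "neck", "male")
  if (variant == "stop_bag") setdiff(base, "neck") else base
}

#' Score a cohort on the teen STOP-Bang (or STOP-Bag) instrument
#'
#' Combines the reporter's four collapsed questionnaire items (snoring,
#' tired, observed apnea, academic problems) with the measured anthropometric
#' flags (elevated blood pressure, BMI, neck circumference) and male sex into
#' a count score: 0-8 for the full instrument, 0-7 for the neck-free
#' `"stop_bag"` variant. Child-reported scores use the child's questionnaire
#' answers but the same measured flags and sex — only the questionnaire
#' reporter differs between variants of the score.
#'
#' @param cohort cohort data.frame, complete for the reporter (see
#'   [filter_complete()]).
#' @param flags output of [anthropometric_flags()] for the same rows.
#' @param reporter `"parent"` or `"child"`.
#' @param variant `"stop_bang"` (8 items) or `"stop_bag"` (no neck item).
#' @return data.frame of class `"stopbang_scores"`: `subject_id`, `reporter`,
#'   `variant`, one logical column per item, and `total`.
#' @export
score_cohort <- function(cohort, flags, reporter = c("parent", "child"),
                         variant = c("stop_bang", "stop_bag")) {
  reporter <- match.arg(reporter)
  variant <- match.arg(variant)
  if (nrow(cohort) != nrow(flags))
    stop("cohort and flags must have the same rows", call. = FALSE)
  cols <- response_cols(reporter)
  for (col in cols) {
    if (any(is.na(cohort[[col]])))
      stop("missing questionnaire item for reporter ", reporter, ": ", col,
           call. = FALSE)
  }
  items <- data.frame(
    snoring = collapse_response(cohort[[cols[1]]]),
    tired = collapse_response(cohort[[cols[2]]]),
    observed_apnea = collapse_response(cohort[[cols[3]]]),
    academic = collapse_response(cohort[[cols[4]]]),
    bp = flags$bp_flag,
    bmi = flags$bmi_flag,
    neck = flags$neck_flag,
    male = cohort$sex == "male"
  )
  keep <- score_items(variant)
  items <- items[keep]
  out <- data.frame(subject_id = cohort$subject_id,
                    reporter = reporter, variant = variant,
                    stringsAsFactors = FALSE)
  out <- cbind(out, items)
  out$total <- as.integer(rowSums(items))
  class(out) <- c("stopbang_scores", "data.frame")
  out
}

#' Score a single subject from explicit item flags
#'
#' Low-level constructor used mainly for worked examples and property tests:
#' takes the eight item positivities directly.
#'
#' @param item_flags named logical vector over
#'   `snoring, tired, observed_apnea, bp, bmi, academic, neck, male`
#'   (neck ignored for `"stop_bag"`).
#' @param variant `"stop_bang"` or `"stop_bag"`.
#' @return integer total.
#' @export
score_from_flags <- function(item_flags, variant = c("stop_bang", "stop_bag")) {
  variant <- match.arg(variant)
  keep <- score_items(variant)
  missing_items <- setdiff(keep, names(item_flags))
  if (length(missing_items) > 0)
    stop("missing item flag(s): ", paste(missing_items, collapse = ", "),
         call. = FALSE)
  as.integer(sum(item_flags[keep]))
}

#' Dichotomize a score into low vs elevated OSA risk
#'
#' A score at or above the threshold (default 3) marks elevated risk; below
#' it, OSA is considered unlikely.
#'
#' @param total integer score vector.
#' @param threshold integer in 1..8.
#' @return factor with levels `low`, `elevated`.
#' @export
classify_risk <- function(total, threshold = 3) {
  if (length(threshold) != 1 || threshold < 1 || threshold > 8)
    stop("threshold must be in 1..8", call. = FALSE)
  factor(ifelse(total >= threshold, "elevated", "low"),
         levels = c("low", "elevated"))
}

#' @export
print.stopbang_scores <- function(x, ...) {
  cat(sprintf("%s scores (%s-reported), n = %d, range %d-%d\n",
              x$variant[1], x$reporter[1], nrow(x),
              min(x$total), max(x$total)))
  print(table(score = x$total))
  invisible(x)
}
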