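#' @keywords internal
"_PACKAGE"

## Questionnaire response vocabulary -----------------------------------------

#' Admissible questionnaire response levels
#'
#' The four symptom questions (snoring, daytime tiredness, observed apnea,
#' academic problems) are answered on a six-level ordinal scale. These are the
#' only admissible levels; anything else is rejected at parse time.
#'
#' @return Character vector of the six canonical level names, in increasing
#'   symptom-frequency order (with `"dont_know"` first).
#' @export
response_levels <- function() {
  c("dont_know", "never", "rarely", "occasionally", "frequently",
    "almost_always")
}

#' Normalize a questionnaire response string
#'
#' Trims whitespace, lowercases, converts internal spaces/apostrophes so that
#' e.g. "Don't know", "dont know" and "unknown" all map to `"dont_know"`.
#' Missing values (`NA` or empty string) stay missing.
#'
#' @param x character vector of raw response strings.
#' @return character vector of canonical levels (or `NA`).
#' @export
normalize_response <- function(x) {
  out <- tolower(trimws(as.character(x)))
  out[out == ""] <- NA_character_
  out <- gsub("['’]", "", out)
  out <- gsub("[ -]+", "_", out)
  out[out == "unknown"] <- "dont_know"
  bad <- !is.na(out) & !(out %in% response_levels())
  if (any(bad)) {
    stop(sprintf(
      "invalid questionnaire response(s): %s; admissible levels are: %s",
      paste(unique(x[bad]), collapse = ", "),
      paste(response_levels(), collapse = ", ")
    ), call. = FALSE)
  }
  out
}

## Cohort data frame contract -------------------------------------------------

#' Column dictionary of the cohort CSV format
#'
#' One row per child. Questionnaire columns exist per reporter
#' (`parent_*`, `child_*`) and per item (snoring, tired, observed, academic).
#'
#' @return data.frame with `column`, `type`, `description`.
#' @export
cohort_columns <- function() {
  data.frame(
    column = c("subject_id", "age_years", "sex", "ethnicity", "height_cm",
               "weight_kg", "sbp_mmhg", "dbp_mmhg", "neck_cm", "smr", "ahi",
               "parent_snoring", "parent_tired", "parent_observed",
               "parent_academic", "child_snoring", "child_tired",
               "child_observed", "child_academic"),
    type = c("character", "numeric", "male|female",
             "caucasian|hispanic|other", rep("numeric", 5),
             "integer 1-5 or empty", "numeric >= 0",
             rep("six-level response", 8)),
    description = c(
      "opaque subject identifier",
      "decimal age in years",
      "biological sex",
      "ethnicity category",
      "standing height, cm",
      "weight, kg",
      "systolic blood pressure, mmHg (mean of readings 2 and 3)",
      "diastolic blood pressure, mmHg (mean of readings 2 and 3)",
      "neck circumference, cm",
      "self-assessed sexual maturity rating (Tanner stage)",
      "apnea-hypopnea index, events/hour of total sleep time",
      rep("ordinal response, see response_levels()", 8)),
    stringsAsFactors = FALSE
  )
}

item_names <- function() c("snoring", "tired", "observed", "academic")

response_cols <- function(reporter) paste(reporter, item_names(), sep = "_")

anthro_cols <- function() {
  c("age_years", "sex", "height_cm", "weight_kg", "sbp_mmhg", "dbp_mmhg",
    "neck_cm")
}

#' Read a cohort CSV
#'
#' Parses and validates a cohort table in the format of
#' [cohort_columns()]. Response strings are normalized case-insensitively;
#' missing cells are preserved as `NA`. Malformed values raise an error naming
#' the row and column.
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @param column_map optional named character vector mapping canonical column
#'   names to the names used in the file, e.g. `c(age_years = "AgeYrs")`.
#' @return data.frame with one row per subject and canonical columns.
#' @export
read_cohort_csv <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw))
        stop("column_map names absent column: ", src, call. = FALSE)
      names(raw)[names(raw) == src] <- canon
    }
  }
  need <- cohort_columns()$column
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0)
    stop("cohort CSV lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  raw <- raw[need]
  blank_to_na <- function(x) { x[trimws(x) == ""] <- NA; trimws(x) }
  raw[] <- lapply(raw, blank_to_na)

  parse_num <- function(col, min = -Inf, strict_pos = FALSE) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(x))
    if (length(bad) > 0)
      stop(sprintf("row %d, column %s: not numeric ('%s')",
                   bad[1], col, raw[[col]][bad[1]]), call. = FALSE)
    low <- which(!is.na(x) & (x < min | (strict_pos & x <= 0)))
    if (length(low) > 0)
      stop(sprintf("row %d, column %s: value %g out of range",
                   low[1], col, x[low[1]]), call. = FALSE)
    x
  }
  parse_enum <- function(col, levels) {
    x <- tolower(raw[[col]])
    bad <- which(!is.na(x) & !(x %in% levels))
    if (length(bad) > 0)
      stop(sprintf("row %d, column %s: '%s' not one of {%s}",
                   bad[1], col, raw[[col]][bad[1]],
                   paste(levels, collapse = ", ")), call. = FALSE)
    x
  }

  out <- data.frame(subject_id = raw$subject_id, stringsAsFactors = FALSE)
  out$age_years <- parse_num("age_years")
  bad_age <- which(!is.na(out$age_years) &
                     (out$age_years < 5 | out$age_years > 25))
  if (length(bad_age) > 0)
    stop(sprintf("row %d, column age_years: %g outside sanity window [5, 25]",
                 bad_age[1], out$age_years[bad_age[1]]), call. = FALSE)
  out$sex <- parse_enum("sex", c("male", "female"))
  out$ethnicity <- parse_enum("ethnicity", c("caucasian", "hispanic", "other"))
  for (col in c("height_cm", "weight_kg", "neck_cm"))
    out[[col]] <- parse_num(col, strict_pos = TRUE)
  out$sbp_mmhg <- parse_num("sbp_mmhg", strict_pos = TRUE)
  out$dbp_mmhg <- parse_num("dbp_mmhg", strict_pos = TRUE)
  smr <- parse_num("smr")
  bad_smr <- which(!is.na(smr) & !(smr %in% 1:5))
  if (length(bad_smr) > 0)
    stop(sprintf("row %d, column smr: %g not in 1..5",
                 bad_smr[1], smr[bad_smr[1]]), call. = FALSE)
  out$smr <- as.integer(smr)
  out$ahi <- parse_num("ahi", min = 0)
  for (rp in c("parent", "child"))
    for (col in response_cols(rp)) {
      out[[col]] <- tryCatch(normalize_response(raw[[col]]),
        error = function(e) stop("column ", col, ": ", conditionMessage(e),
                                 call. = FALSE))
    }
  out[cohort_columns()$column]
}

#' Write a cohort data frame to CSV
#'
#' Inverse of [read_cohort_csv()]: a written file read back yields identical
#' records.
#'
#' @param cohort cohort data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

## Completeness filter ---------------------------------------------------------

#' Split a cohort into analyzable and incomplete records
#'
#' A record is complete for a reporter when every anthropometric field, the
#' reporter's four questionnaire items, and the AHI are present. Missing
#' questionnaire responses make a record incomplete (they are never treated as
#' negative answers).
#'
#' @param cohort cohort data.frame.
#' @param reporter `"parent"` or `"child"`: whose questionnaire must be
#'   complete.
#' @return list with `kept` (complete rows), `dropped` (incomplete rows) and
#'   `reasons` (character vector, one comma-separated missing-field list per
#'   dropped row). `nrow(kept) + nrow(dropped) == nrow(cohort)` always.
#' @export
filter_complete <- function(cohort, reporter = c("parent", "child")) {
  reporter <- match.arg(reporter)
  need <- c(anthro_cols(), response_cols(reporter), "ahi")
  if (nrow(cohort) == 0) {
    return(list(kept = cohort, dropped = cohort, reasons = character(0)))
  }
  miss <- sapply(need, function(col) is.na(cohort[[col]]))
  miss <- matrix(miss, nrow = nrow(cohort),
                 dimnames = list(NULL, need))
  incomplete <- rowSums(miss) > 0
  reasons <- apply(miss[incomplete, , drop = FALSE], 1,
                   function(m) paste(need[m], collapse = ","))
  list(kept = cohort[!incomplete, , drop = FALSE],
       dropped = cohort[incomplete, , drop = FALSE],
       reasons = unname(reasons))
}

## OSA labeling ----------------------------------------------------------------

#' Label OSA status from the apnea-hypopnea index
#'
#' OSA is present when AHI is at or above the diagnostic threshold
#' (1.5 events/hour by default; 1 and 3 are the usual sensitivity-analysis
#' alternatives).
#'
#' @param ahi numeric vector of AHI values (events/hour, non-negative).
#' @param threshold diagnostic cut in events/hour, `> 0`.
#' @return list of class `"osa_label"`: `is_osa` (logical vector) and
#'   `threshold`.
#' @export
classify_osa <- function(ahi, threshold = 1.5) {
  if (length(threshold) != 1 || !is.finite(threshold) || threshold <= 0)
    stop("threshold must be a single positive number", call. = FALSE)
  if (any(!is.na(ahi) & ahi < 0))
    stop("ahi must be non-negative", call. = FALSE)
  structure(list(is_osa = !is.na(ahi) & ahi >= threshold,
                 threshold = threshold),
            class = "osa_label")
}

#' @export
print.osa_label <- function(x, ...) {
  cat(sprintf("OSA labels (AHI >= %g): %d of %d positive\n",
              x$threshold, sum(x$is_osa), length(x$is_osa)))
  invisible(x)
}

## Stratification --------------------------------------------------------------

#' Assign each subject to an analysis stratum
#'
#' Two stratifications are supported: `age_group` (preteen = age < 13 years,
#' teen = age >= 13) and `smr_group` (low = sexual maturity rating < 4,
#' high = SMR >= 4, unknown when SMR is missing). Strata always partition the
#' cohort.
#'
#' @param cohort cohort data.frame.
#' @param by `"age_group"` or `"smr_group"`.
#' @return factor of stratum labels, one per row.
#' @export
stratify <- function(cohort, by = c("age_group", "smr_group")) {
  by <- match.arg(by)
  if (by == "age_group") {
    factor(ifelse(cohort$age_years >= 13, "teen", "preteen"),
           levels = c("preteen", "teen"))
  } else {
    lab <- ifelse(is.na(cohort$smr), "unknown",
                  ifelse(cohort$smr >= 4, "high", "low"))
    factor(lab, levels = c("low", "high", "unknown"))
  }
}
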