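## Pipeline orchestration: score -> evaluate -> ROC -> describe, with
## machine-readable report output.

#' Run the full evaluation pipeline on a cohort
#'
#' Orchestrates the whole analysis sequence on one cohort table: complete-case
#' filtering, anthropometric flagging, scoring for both reporters, the
#' threshold x stratum test-characteristics panel, per-stratum/per-reporter
#' ROC AUCs with DeLong CIs, unpaired (teen vs preteen; SMR high vs low) and
#' paired (parent vs child; full vs neck-free instrument) AUC comparisons,
#' and median/IQR reporter summaries with Wilcoxon signed-rank p-values.
#'
#' @param cohort cohort data.frame (see [read_cohort_csv()]).
#' @param refs a [reference_set()].
#' @param variant `"stop_bang"` or `"stop_bag"`.
#' @param thresholds score cuts for the characteristics panel.
#' @param ahi_threshold diagnostic AHI cut, events/hour.
#' @param bmi_cut BMI percentile cut.
#' @param prevalence override for the adjusted-LR pre-test probability
#'   (default: the analyzed cohort's own prevalence).
#' @param ci_method `"wilson"` or `"clopper-pearson"`.
#' @param out_dir optional directory; when given, writes `scores.csv`,
#'   `characteristics.csv`, `report.json`.
#' @return list of class `"stopbang_report"`: `scores` (both reporters),
#'   `characteristics`, `auc` (data.frame), `comparisons`,
#'   `reporter_summary`, `dropped`, `config`.
#' @export
run_full_evaluation <- function(cohort, refs = default_reference_set(),
                                variant = c("stop_bang", "stop_bag"),
                                thresholds = c(2, 3, 4),
                                ahi_threshold = 1.5, bmi_cut = 95,
                                prevalence = NULL, ci_method = "wilson",
                                out_dir = NULL) {
  variant <- match.arg(variant)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  fc_parent <- stage("filter", filter_complete(cohort, "parent"))
  fc_child <- stage("filter", filter_complete(cohort, "child"))
  keep_ids <- intersect(fc_parent$kept$subject_id, fc_child$kept$subject_id)
  data <- cohort[cohort$subject_id %in% keep_ids, , drop = FALSE]
  dropped <- cohort[!cohort$subject_id %in% keep_ids, , drop = FALSE]

  flags <- stage("anthropometry",
                 anthropometric_flags(data, refs, bmi_cut = bmi_cut))
  labels <- stage("labeling", classify_osa(data$ahi, ahi_threshold))
  is_osa <- labels$is_osa
  prev <- if (is.null(prevalence)) mean(is_osa) else prevalence

  scores <- stage("scoring", rbind(
    score_cohort(data, flags, "parent", variant),
    score_cohort(data, flags, "child", variant)))

  age_stratum <- stratify(data, "age_group")
  smr_stratum <- stratify(data, "smr_group")
  parent_total <- scores$total[scores$reporter == "parent"]
  child_total <- scores$total[scores$reporter == "child"]

  characteristics <- stage("characteristics", summary_table(
    parent_total, is_osa, age_stratum, thresholds = thresholds,
    prevalence = prev, ci_method = ci_method))

  auc_rows <- list()
  auc_objs <- list()
  for (rp in c("parent", "child")) {
    tot <- if (rp == "parent") parent_total else child_total
    for (st in c("all", "preteen", "teen")) {
      in_st <- if (st == "all") rep(TRUE, nrow(data)) else age_stratum == st
      est <- stage("roc", auc_ci_delong(tot[in_st], is_osa[in_st]))
      auc_objs[[paste(rp, st, sep = ".")]] <- est
      auc_rows[[length(auc_rows) + 1]] <- data.frame(
        reporter = rp, stratum = st, n = sum(in_st),
        auc = est$auc, variance = est$variance,
        ci_lo = est$ci[1], ci_hi = est$ci[2], stringsAsFactors = FALSE)
    }
  }
  auc <- do.call(rbind, auc_rows); rownames(auc) <- NULL

  comparisons <- stage("comparisons", {
    out <- list()
    out$parent_teen_vs_preteen <- compare_auc_unpaired(
      auc_objs[["parent.teen"]], auc_objs[["parent.preteen"]])
    known_smr <- smr_stratum != "unknown"
    if (sum(is_osa[smr_stratum == "high"]) >= 2 &&
        sum(is_osa[smr_stratum == "low"]) >= 2) {
      out$parent_smr_high_vs_low <- compare_auc_unpaired(
        auc_ci_delong(parent_total[smr_stratum == "high"],
                      is_osa[smr_stratum == "high"]),
        auc_ci_delong(parent_total[smr_stratum == "low"],
                      is_osa[smr_stratum == "low"]))
    }
    for (st in c("all", "preteen", "teen")) {
      in_st <- if (st == "all") rep(TRUE, nrow(data)) else age_stratum == st
      out[[paste0("parent_vs_child_", st)]] <- compare_auc_paired(
        parent_total[in_st], child_total[in_st], is_osa[in_st])
    }
    out
  })

  reporter_summary <- stage("describe", {
    rows <- list()
    for (st in c("all", "preteen", "teen")) {
      in_st <- if (st == "all") rep(TRUE, nrow(data)) else age_stratum == st
      w <- wilcoxon_signed_rank(parent_total[in_st], child_total[in_st])
      mp <- median_iqr(parent_total[in_st])
      mc <- median_iqr(child_total[in_st])
      rows[[st]] <- data.frame(
        stratum = st, n = sum(in_st),
        parent_median = mp["median"], parent_q25 = mp["q25"],
        parent_q75 = mp["q75"],
        child_median = mc["median"], child_q25 = mc["q25"],
        child_q75 = mc["q75"],
        p_value = w$p_value, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows); rownames(out) <- NULL
    out
  })

  config <- list(variant = variant, thresholds = thresholds,
                 ahi_threshold = ahi_threshold, bmi_cut = bmi_cut,
                 prevalence = prev, ci_method = ci_method,
                 n_analyzed = nrow(data), n_dropped = nrow(dropped),
                 package_version = as.character(
                   utils::packageVersion("teenstopbang")))
  report <- structure(list(scores = scores,
                           characteristics = characteristics,
                           auc = auc, comparisons = comparisons,
                           reporter_summary = reporter_summary,
                           dropped = dropped, config = config),
                      class = "stopbang_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a report bundle to disk
#'
#' Emits `scores.csv`, `characteristics.csv` and `report.json` (AUCs,
#' comparisons, reporter summary, config, package version). All numeric
#' fields are finite or `NA`-flagged; nothing is silently dropped.
#'
#' @param report a `"stopbang_report"`.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$scores, file.path(out_dir, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(report$characteristics,
                   file.path(out_dir, "characteristics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(auc = report$auc, comparisons = report$comparisons,
         reporter_summary = report$reporter_summary,
         config = report$config),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, na = "string", pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.stopbang_report <- function(x, ...) {
  cat(sprintf("teen STOP-Bang evaluation: %d subjects analyzed, %d dropped\n",
              x$config$n_analyzed, x$config$n_dropped))
  cat(sprintf("  variant %s, AHI cut %g, prevalence %.3f\n",
              x$config$variant, x$config$ahi_threshold, x$config$prevalence))
  cat("\nAUC by reporter and age stratum:\n")
  print(x$auc, digits = 3)
  cat("\nCharacteristics panel: ", nrow(x$characteristics),
      " rows (see $characteristics)\n", sep = "")
  invisible(x)
}
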