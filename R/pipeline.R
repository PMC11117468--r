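#' Run the full validation analysis on a cohort
#'
#' The end-to-end pipeline: quotient classification, four-field tables
#' and accuracy metrics overall and per light-chain stratum, ROC/AUC on
#' the raw quotient, per-histology-group summaries, Kruskal-Wallis plus
#' Dunn/Benjamini-Hochberg comparisons for each lab variable, and Welch
#' t-tests of creatinine and eGFR for cast nephropathy versus other
#' kidney disease. Deterministic given the cohort and configuration;
#' every reported number is recomputable from the embedded counts.
#'
#' @param cohort A cohort tibble, or a path passed to [read_cohort()].
#' @param thresholds A [rule_thresholds()] object.
#' @param ci_level Confidence level for exact binomial intervals.
#' @param gate_alpha Omnibus gate for the post hoc tests (see
#'   [compare_groups()]).
#' @return A list of class `lcq_report`: `counts`, `accuracy`
#'   (a [stratified_accuracy()] object), `group_summary`,
#'   `group_tests` (per-variable omnibus + pairwise), `cn_vs_okd`
#'   (Welch t results for creatinine and eGFR), `excluded`, `config`.
#' @export
#' @examples
#' rep <- run_analysis(generate_cohort(seed = 3))
#' rep$accuracy$all$report
run_analysis <- function(cohort, thresholds = rule_thresholds(),
                         ci_level = 0.95, gate_alpha = 0.05) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "lcq_cohort"))
  preds <- apply_rule(cohort, thresholds)
  accuracy <- stratified_accuracy(preds, ci_level = ci_level)
  group_tests <- lapply(
    c("quotient", "egfr", "involved_flc_serum", "involved_lc_urine"),
    function(v) compare_groups(cohort, v, gate_alpha = gate_alpha)
  )
  names(group_tests) <- vapply(group_tests, `[[`, character(1), "variable")
  is_cn <- cohort$histology == "cast_nephropathy"
  cn_vs_okd <- if (sum(is_cn) >= 2 && sum(!is_cn) >= 2) {
    list(
      serum_creatinine = two_sample_t(cohort$serum_creatinine[is_cn],
                                      cohort$serum_creatinine[!is_cn]),
      egfr = two_sample_t(cohort$egfr[is_cn], cohort$egfr[!is_cn])
    )
  } else NULL
  structure(
    list(
      counts = cohort_summary_counts(cohort),
      accuracy = accuracy,
      group_summary = summarize_groups(cohort),
      group_tests = group_tests,
      cn_vs_okd = cn_vs_okd,
      excluded = attr(preds, "excluded"),
      config = list(thresholds = unclass(thresholds), ci_level = ci_level,
                    gate_alpha = gate_alpha,
                    package_version = as.character(utils::packageVersion("lcquotient")))
    ),
    class = "lcq_report"
  )
}

#' @export
print.lcq_report <- function(x, ...) {
  cat(sprintf("Cohort: %d patients, %d biopsy-proven cast nephropathy\n",
              x$counts$n, x$counts$n_cn))
  if (nrow(x$excluded) > 0) {
    cat(sprintf("Excluded from classification: %d (see $excluded)\n",
                nrow(x$excluded)))
  }
  for (s in names(x$accuracy)) {
    print(x$accuracy[[s]]$report)
    if (!is.null(x$accuracy[[s]]$roc)) {
      cat(sprintf("  AUC (quotient)  %.3f\n", x$accuracy[[s]]$roc$auc))
    }
  }
  invisible(x)
}

#' Reference validation counts
#'
#' The stratified 2x2 tables (all / lambda / kappa) of the original
#' two-center validation cohort, together with the accuracy metrics as
#' printed there, shipped as a plain-text fixture.
#'
#' @return A tibble with columns `stratum`, `tp`, `fp`, `fn`, `tn` and
#'   `printed_*` metric columns.
#' @export
reference_counts <- function() {
  path <- system.file("extdata", "reference_counts.csv",
                      package = "lcquotient", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Recompute the reference accuracy table from its counts
#'
#' Feeds the stratified reference 2x2 counts through
#' [accuracy_metrics()] and lays the recomputed sensitivity, specificity,
#' PPV and NPV beside the printed values, rounded to the printed
#' precision (three decimals). Full-precision values are kept in the
#' `computed_*` columns; rounding is presentation-only.
#'
#' @param counts A tibble like [reference_counts()] (the default).
#' @param ci_level Confidence level for the exact intervals.
#' @return A tibble of class `reference_replication` with one row per
#'   stratum and metric: `stratum`, `metric`, `computed`, `printed`,
#'   `rounded`, `match` (rounded == printed).
#' @export
#' @examples
#' replicate_reference_metrics()
replicate_reference_metrics <- function(counts = reference_counts(),
                                        ci_level = 0.95) {
  stopifnot(all(c("stratum", "tp", "fp", "fn", "tn") %in% names(counts)))
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    rec <- counts[i, ]
    rep <- accuracy_metrics(
      contingency_table(rec$tp, rec$fp, rec$fn, rec$tn),
      ci_level = ci_level, stratum = rec$stratum
    )
    m <- rep$metrics
    printed_col <- paste0("printed_", m$metric)
    printed <- if (all(printed_col %in% names(rec))) {
      as.numeric(rec[1, printed_col])
    } else rep(NA_real_, nrow(m))
    tibble::tibble(
      stratum = rec$stratum, metric = m$metric, computed = m$estimate,
      printed = printed, rounded = round(m$estimate, 3),
      match = !is.na(printed) & round(m$estimate, 3) == printed
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("reference_replication", class(out))
  out
}

#' @export
print.reference_replication <- function(x, ...) {
  cat("Recomputed vs printed accuracy metrics\n")
  for (s in unique(x$stratum)) {
    sub <- x[x$stratum == s, ]
    cat(sprintf("  %-7s %s\n", s, paste(
      sprintf("%s %.3f%s", sub$metric, sub$rounded,
              ifelse(sub$match, "", sprintf(" (printed %.3f)", sub$printed))),
      collapse = "  ")))
  }
  invisible(x)
}

#' Serialise an analysis report to JSON
#'
#' @param report An `lcq_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "lcq_report"))
  strip <- function(x) {
    if (is.data.frame(x)) return(as.data.frame(x))
    if (is.list(x)) return(lapply(unclass(x), strip))
    if (is.factor(x)) return(as.character(x))
    x
  }
  x <- strip(report)
  if (is.null(path)) {
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
    invisible(path)
  }
}
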