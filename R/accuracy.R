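#' Four-field (2x2) contingency table
#'
#' Cross-classifies rule predictions against biopsy-proven disease.
#'
#' @param predictions Logical vector: rule positive.
#' @param truths Logical vector of the same length, aligned patient by
#'   patient: biopsy-proven cast nephropathy.
#' @return A list of class `contingency_table` with integer cells `tp`,
#'   `fp`, `fn`, `tn`.
#' @export
#' @examples
#' build_contingency(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
build_contingency <- function(predictions, truths) {
  stopifnot(is.logical(predictions), is.logical(truths),
            length(predictions) == length(truths),
            !anyNA(predictions), !anyNA(truths))
  if (length(predictions) == 0) abort("empty input")
  structure(
    list(
      tp = sum(predictions & truths),
      fp = sum(predictions & !truths),
      fn = sum(!predictions & truths),
      tn = sum(!predictions & !truths)
    ),
    class = "contingency_table"
  )
}

#' Build a contingency table from explicit cell counts
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts.
#' @return A `contingency_table`.
#' @export
contingency_table <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(is.numeric(cells), all(cells >= 0), all(cells == round(cells)),
            sum(cells) >= 1)
  structure(as.list(setNames(as.integer(cells), names(cells))),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), nrow = 2, byrow = TRUE,
              dimnames = list(c("rule positive", "rule negative"),
                              c("CN yes", "CN no")))
  print(m)
  invisible(x)
}

cp_interval <- function(successes, total, level) {
  if (total == 0) return(c(NA_real_, NA_real_))
  as.numeric(binom.test(successes, total, conf.level = level)$conf.int)
}

#' Diagnostic accuracy metrics with exact binomial confidence intervals
#'
#' Sensitivity, specificity, positive and negative predictive value from
#' a four-field table, each with a Clopper-Pearson exact interval. A
#' metric whose denominator is zero is reported as `NA` (undefined),
#' never coerced to 0 or 1.
#'
#' @param table A `contingency_table`.
#' @param ci_level Confidence level (default 0.95).
#' @param stratum Optional stratum label carried into the report
#'   (`"all"`, `"kappa"`, `"lambda"`, ...).
#' @return A list of class `accuracy_report`: tibble `metrics` (columns
#'   `metric`, `estimate`, `lower`, `upper`, `numerator`, `denominator`),
#'   the underlying `table`, `ci_level` and `stratum`.
#' @export
#' @examples
#' accuracy_metrics(contingency_table(18, 7, 0, 42))
accuracy_metrics <- function(table, ci_level = 0.95, stratum = "all") {
  stopifnot(inherits(table, "contingency_table"),
            ci_level > 0, ci_level < 1)
  defs <- list(
    sensitivity = c(table$tp, table$tp + table$fn),
    specificity = c(table$tn, table$tn + table$fp),
    ppv         = c(table$tp, table$tp + table$fp),
    npv         = c(table$tn, table$tn + table$fn)
  )
  rows <- lapply(names(defs), function(m) {
    num <- defs[[m]][1]; den <- defs[[m]][2]
    if (den == 0) {
      tibble::tibble(metric = m, estimate = NA_real_, lower = NA_real_,
                     upper = NA_real_, numerator = num, denominator = den)
    } else {
      ci <- cp_interval(num, den, ci_level)
      tibble::tibble(metric = m, estimate = num / den, lower = ci[1],
                     upper = ci[2], numerator = num, denominator = den)
    }
  })
  structure(
    list(metrics = dplyr::bind_rows(rows), table = table,
         ci_level = ci_level, stratum = stratum),
    class = "accuracy_report"
  )
}

#' @export
print.accuracy_report <- function(x, digits = 3, ...) {
  cat(sprintf("Diagnostic accuracy (stratum: %s, %.0f%% exact CI)\n",
              x$stratum, 100 * x$ci_level))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    if (is.na(m$estimate[i])) {
      cat(sprintf("  %-12s undefined (0 denominator)\n", m$metric[i]))
    } else {
      cat(sprintf("  %-12s %.*f  [%.*f, %.*f]  (%d/%d)\n", m$metric[i],
                  digits, m$estimate[i], digits, m$lower[i], digits,
                  m$upper[i], m$numerator[i], m$denominator[i]))
    }
  }
  invisible(x)
}

#' ROC curve and AUC for a continuous score
#'
#' One operating point per distinct score value plus the (0,0)/(1,1)
#' anchors; higher scores indicate disease. The AUC is the normalised
#' Mann-Whitney concordance (ties credited one half), which equals the
#' trapezoidal area under the tie-grouped polyline.
#'
#' @param scores Numeric vector (e.g. the urine-LC/eGFR quotient).
#' @param truths Logical vector: diseased.
#' @return A list of class `roc_curve`: tibble `points` (columns
#'   `threshold`, `tpr`, `fpr`, sorted by increasing threshold) and
#'   scalar `auc`.
#' @export
#' @examples
#' roc_curve(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE))$auc
roc_curve <- function(scores, truths) {
  stopifnot(is.numeric(scores), is.logical(truths),
            length(scores) == length(truths),
            all(is.finite(scores)), !anyNA(truths))
  n_pos <- sum(truths); n_neg <- sum(!truths)
  if (n_pos == 0 || n_neg == 0) {
    abort("ROC needs at least one diseased and one non-diseased subject")
  }
  thr <- sort(unique(scores))
  # point at threshold t: predict positive when score > t
  tpr <- vapply(thr, function(t) sum(scores > t & truths) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores > t & !truths) / n_neg, numeric(1))
  points <- tibble::tibble(
    threshold = c(-Inf, thr),
    tpr = c(1, tpr),
    fpr = c(1, fpr)
  )
  # rank-based Mann-Whitney AUC with mid-ranks for ties
  r <- rank(scores)
  auc <- (sum(r[truths]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(points = points, auc = auc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' Trapezoidal area under a ROC curve
#'
#' @param roc A [roc_curve()] object.
#' @return Area under the (FPR, TPR) polyline.
#' @export
auc_trapezoid <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  p <- roc$points[order(roc$points$fpr, roc$points$tpr), ]
  x <- c(0, p$fpr, 1); y <- c(0, p$tpr, 1)
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d operating points, %d diseased / %d non-diseased, AUC %.3f\n",
              nrow(x$points), x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' Accuracy and ROC, overall and stratified by light-chain type
#'
#' @param predictions A predictions tibble from [apply_rule()] (needs
#'   columns `lc_type`, `quotient`, `positive`, `is_cn`).
#' @param ci_level Confidence level for the exact intervals.
#' @return A list of class `stratified_accuracy` with elements `all`,
#'   `kappa`, `lambda`; each is a list of `report` ([accuracy_metrics()])
#'   and `roc` ([roc_curve()], `NULL` when the stratum has a single
#'   truth class). A stratum absent from the data is skipped with a
#'   message.
#' @export
stratified_accuracy <- function(predictions, ci_level = 0.95) {
  stopifnot(is.data.frame(predictions),
            all(c("lc_type", "quotient", "positive", "is_cn") %in%
                  names(predictions)))
  strata <- list(all = rep(TRUE, nrow(predictions)),
                 kappa = predictions$lc_type == "kappa",
                 lambda = predictions$lc_type == "lambda")
  out <- list()
  for (s in names(strata)) {
    idx <- strata[[s]]
    if (!any(idx)) {
      inform(paste0("stratum '", s, "' is empty; skipped"))
      next
    }
    tab <- build_contingency(predictions$positive[idx], predictions$is_cn[idx])
    roc <- if (sum(predictions$is_cn[idx]) %in% c(0, sum(idx))) {
      inform(paste0("stratum '", s, "' has a single truth class; no ROC"))
      NULL
    } else {
      roc_curve(predictions$quotient[idx], predictions$is_cn[idx])
    }
    out[[s]] <- list(report = accuracy_metrics(tab, ci_level, stratum = s),
                     roc = roc)
  }
  structure(out, class = "stratified_accuracy")
}
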