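#' Per-group medians and interquartile ranges
#'
#' Summarises eGFR, involved serum FLC, involved urine LC and the
#' urine-LC/eGFR quotient per histology group (CN / ALA / MIDD / Others),
#' as median and IQR. Quartiles use linear interpolation between order
#' statistics (`quantile` type 7), the convention the synthetic-cohort
#' calibration assumes.
#'
#' @param cohort A cohort tibble.
#' @return A tibble with columns `group`, `variable`, `n`, `median`,
#'   `iqr`.
#' @export
#' @examples
#' summarize_groups(generate_cohort(seed = 1))
summarize_groups <- function(cohort) {
  stopifnot(inherits(cohort, "lcq_cohort"), nrow(cohort) > 0)
  df <- tibble::tibble(
    group = histology_group(cohort$histology),
    egfr = cohort$egfr,
    involved_flc_serum = cohort$involved_flc_serum,
    involved_lc_urine = cohort$involved_lc_urine,
    quotient = lc_egfr_quotient(cohort$involved_lc_urine, cohort$egfr)
  )
  long <- tidyr::pivot_longer(df, -"group", names_to = "variable",
                              values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$group, .data$variable),
    n = sum(!is.na(.data$value)),
    median = median(.data$value, na.rm = TRUE),
    iqr = unname(diff(quantile(.data$value, c(0.25, 0.75),
                               na.rm = TRUE, type = 7))),
    .groups = "drop"
  )
  out$variable <- factor(out$variable, levels = c(
    "egfr", "involved_flc_serum", "involved_lc_urine", "quotient"
  ))
  dplyr::arrange(out, .data$variable, .data$group)
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based comparison of two or more groups, with the standard tie
#' correction. A degenerate input (all values identical) yields H = 0,
#' p = 1 and is flagged.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector of the same length (>= 2 non-empty
#'   groups, total n >= 3).
#' @return A list of class `omnibus_result`: `statistic` (H), `df`,
#'   `p_value`, `tie_correction` (the factor C in [0, 1] dividing the
#'   uncorrected H), `method`, `degenerate`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- droplevels(factor(groups))
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2,
            length(values) >= 3, !anyNA(values))
  tie_sizes <- table(values)
  n <- length(values)
  tie_corr <- 1 - sum(tie_sizes^3 - tie_sizes) / (n^3 - n)
  if (tie_corr == 0) {
    return(structure(list(statistic = 0, df = nlevels(groups) - 1L,
                          p_value = 1, tie_correction = 0,
                          method = "kruskal-wallis", degenerate = TRUE),
                     class = "omnibus_result"))
  }
  kt <- kruskal.test(values, groups)
  structure(
    list(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value, tie_correction = tie_corr,
         method = "kruskal-wallis", degenerate = FALSE),
    class = "omnibus_result"
  )
}

#' @export
print.omnibus_result <- function(x, ...) {
  lab <- switch(x$method, `kruskal-wallis` = "H", anova = "F", "stat")
  cat(sprintf("%s: %s = %.4g, df = %s, p = %.4g%s\n", x$method, lab,
              x$statistic, paste(x$df, collapse = "/"), x$p_value,
              if (isTRUE(x$degenerate)) " (degenerate: all values tied)" else ""))
  invisible(x)
}

#' Dunn's post hoc test on pooled mid-ranks
#'
#' Pairwise z statistics after a Kruskal-Wallis omnibus: for groups i, j
#' the difference of mean pooled ranks is divided by
#' \eqn{\sqrt{(N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j)}} where
#' \eqn{T = \sum_t (t^3 - t)} over tie groups. Two-sided p-values from
#' the standard normal, Benjamini-Hochberg adjusted across the pairs of
#' one variable (the adjustment family is the pairwise comparisons of a
#' single variable, not pooled across variables).
#'
#' @inheritParams kruskal_wallis
#' @param adjust P-value adjustment method (default `"BH"`); any method
#'   of [stats::p.adjust()].
#' @return A tibble with columns `group1`, `group2`, `z`, `p_raw`,
#'   `p_adjusted`.
#' @export
dunn_posthoc <- function(values, groups, adjust = "BH") {
  groups <- droplevels(factor(groups))
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2,
            !anyNA(values))
  n <- length(values)
  r <- rank(values) # mid-ranks
  tie_sizes <- table(values)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (n - 1))
  var_unit <- n * (n + 1) / 12 - tie_term
  mean_rank <- tapply(r, groups, mean)
  sizes <- tapply(r, groups, length)
  pairs <- utils::combn(levels(groups), 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(var_unit * (1 / sizes[[i]] + 1 / sizes[[j]]))
    z <- if (se == 0) 0 else (mean_rank[[i]] - mean_rank[[j]]) / se
    c(z = z, p = if (se == 0) 1 else 2 * pnorm(-abs(z)))
  })
  tibble::tibble(
    group1 = pairs[1, ], group2 = pairs[2, ],
    z = unname(res["z", ]), p_raw = unname(res["p", ]),
    p_adjusted = unname(benjamini_hochberg(res["p", ], method = adjust))
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; a thin wrapper over
#' [stats::p.adjust()] kept as an explicit seam so the adjustment family
#' is visible at call sites.
#'
#' @param pvals Numeric vector of raw p-values in [0, 1].
#' @param method Adjustment method, default `"BH"`.
#' @return Adjusted p-values, same length and order as `pvals`.
#' @export
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.04))
benjamini_hochberg <- function(pvals, method = "BH") {
  stopifnot(is.numeric(pvals), all(pvals >= 0 & pvals <= 1))
  p.adjust(pvals, method = method)
}

#' Two-sample t-test (Welch by default)
#'
#' @param a,b Numeric vectors, n >= 2 each.
#' @param pooled Use the classical pooled-variance form instead of Welch.
#' @return A list with `statistic`, `df`, `p_value`, `method`.
#' @export
two_sample_t <- function(a, b, pooled = FALSE) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 2, length(b) >= 2)
  tt <- t.test(a, b, var.equal = pooled)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       method = if (pooled) "pooled t" else "welch t")
}

#' One-way analysis of variance (classical F)
#'
#' @inheritParams kruskal_wallis
#' @return An `omnibus_result` with the F statistic and both degrees of
#'   freedom.
#' @export
one_way_anova <- function(values, groups) {
  groups <- droplevels(factor(groups))
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2)
  ow <- oneway.test(values ~ groups, var.equal = TRUE)
  structure(
    list(statistic = unname(ow$statistic),
         df = unname(ow$parameter), p_value = ow$p.value,
         tie_correction = NA_real_, method = "anova", degenerate = FALSE),
    class = "omnibus_result"
  )
}

#' Four-group comparison battery for one variable
#'
#' Kruskal-Wallis omnibus and, when it reaches `gate_alpha`, Dunn's post
#' hoc with Benjamini-Hochberg adjustment — the per-variable analysis
#' behind the histology-group comparison tables.
#'
#' @param cohort A cohort tibble.
#' @param variable One of `"egfr"`, `"involved_flc_serum"`,
#'   `"involved_lc_urine"`, `"quotient"`.
#' @param gate_alpha Omnibus significance gate for running the post hoc
#'   (default 0.05); set to 1 to always run it.
#' @return A list with `variable`, `omnibus` and `pairwise` (`NULL` when
#'   gated out).
#' @export
compare_groups <- function(cohort, variable = c("quotient", "egfr",
                                                "involved_flc_serum",
                                                "involved_lc_urine"),
                           gate_alpha = 0.05) {
  variable <- match.arg(variable)
  stopifnot(inherits(cohort, "lcq_cohort"))
  vals <- switch(variable,
    quotient = lc_egfr_quotient(cohort$involved_lc_urine, cohort$egfr),
    cohort[[variable]]
  )
  grp <- histology_group(cohort$histology)
  keep <- !is.na(vals)
  omnibus <- kruskal_wallis(vals[keep], grp[keep])
  pairwise <- if (omnibus$p_value <= gate_alpha) {
    dunn_posthoc(vals[keep], grp[keep])
  } else NULL
  list(variable = variable, omnibus = omnibus, pairwise = pairwise)
}
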