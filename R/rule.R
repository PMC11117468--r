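#' Decision-rule thresholds
#'
#' Cut-offs of the light-chain-type-specific quotient rule. Defaults are
#' the published ones: a lambda patient is called positive when the
#' urine-LC/eGFR quotient exceeds 2; a kappa patient when the quotient
#' exceeds 5, or when it lies in (1, 5] with 24-h proteinuria below
#' 8 g/day. All comparisons are strict.
#'
#' @param lambda_cut Quotient threshold for lambda light chains (default 2).
#' @param kappa_high_cut Upper kappa quotient threshold (default 5).
#' @param kappa_low_cut Lower kappa quotient threshold (default 1).
#' @param proteinuria_cut Proteinuria threshold in mg/24 h (default 8000).
#' @return A list of class `rule_thresholds`.
#' @export
rule_thresholds <- function(lambda_cut = 2, kappa_high_cut = 5,
                            kappa_low_cut = 1, proteinuria_cut = 8000) {
  stopifnot(
    lambda_cut > 0, proteinuria_cut > 0,
    kappa_low_cut > 0, kappa_low_cut < kappa_high_cut
  )
  structure(
    list(lambda_cut = lambda_cut, kappa_high_cut = kappa_high_cut,
         kappa_low_cut = kappa_low_cut, proteinuria_cut = proteinuria_cut),
    class = "rule_thresholds"
  )
}

#' Urine light chain / eGFR quotient
#'
#' The quotient exploits the signature of cast nephropathy: massive
#' involved-light-chain excretion despite severely reduced filtration.
#' Units: (mg/dL) / (mL/min/1.73 m\eqn{^2}).
#'
#' @param involved_lc_urine Involved urine light chain, mg/dL, >= 0.
#' @param egfr eGFR, mL/min/1.73 m\eqn{^2}, > 0. The quotient is
#'   undefined in anuria (eGFR effectively zero); non-positive eGFR is a
#'   domain error.
#' @return `involved_lc_urine / egfr`.
#' @export
#' @examples
#' lc_egfr_quotient(171.5, 7.5) # cast-nephropathy scale
#' lc_egfr_quotient(15.9, 44.4) # AL-amyloidosis scale
lc_egfr_quotient <- function(involved_lc_urine, egfr) {
  if (!is.numeric(egfr) || any(!is.finite(egfr)) || any(egfr <= 0)) {
    abort("`egfr` must be > 0: the quotient is undefined in anuria.")
  }
  if (!is.numeric(involved_lc_urine) || any(!is.finite(involved_lc_urine)) ||
      any(involved_lc_urine < 0)) {
    abort("`involved_lc_urine` must be finite and >= 0.")
  }
  involved_lc_urine / egfr
}

#' Classify one quotient value under the cast-nephropathy rule
#'
#' Vectorised over `lc_type`, `quotient` and `proteinuria`. Lambda
#' patients are positive iff quotient > `lambda_cut`. Kappa patients are
#' positive iff quotient > `kappa_high_cut`, or quotient in
#' (`kappa_low_cut`, `kappa_high_cut`] with proteinuria <
#' `proteinuria_cut`. Proteinuria is only consulted in the kappa
#' branch-sensitive range; a kappa patient with missing proteinuria and a
#' quotient in that range is unclassifiable.
#'
#' @param lc_type `"kappa"` or `"lambda"`.
#' @param quotient Urine-LC/eGFR quotient, >= 0.
#' @param proteinuria mg/24 h; may be `NA` where not consulted.
#' @param thresholds A [rule_thresholds()] object.
#' @return A tibble with columns `quotient`, `positive` and `branch`
#'   (`lambda_main`, `kappa_high`, `kappa_low_with_proteinuria`, or
#'   `negative`).
#' @export
#' @examples
#' classify_cn("lambda", 33.1, 3929)
#' classify_cn("kappa", 3, c(9000, 5000))
classify_cn <- function(lc_type, quotient, proteinuria = NA_real_,
                        thresholds = rule_thresholds()) {
  stopifnot(inherits(thresholds, "rule_thresholds"))
  lc_type <- as.character(lc_type)
  if (!all(lc_type %in% c("kappa", "lambda"))) {
    abort("`lc_type` must be 'kappa' or 'lambda'")
  }
  if (!is.numeric(quotient) || any(!is.finite(quotient)) || any(quotient < 0)) {
    abort("`quotient` must be finite and >= 0")
  }
  n <- max(length(lc_type), length(quotient), length(proteinuria))
  lc_type <- rep_len(lc_type, n)
  quotient <- rep_len(quotient, n)
  proteinuria <- rep_len(as.numeric(proteinuria), n)

  kappa_mid <- lc_type == "kappa" &
    quotient > thresholds$kappa_low_cut & quotient <= thresholds$kappa_high_cut
  needs_prot <- kappa_mid & is.na(proteinuria)
  if (any(needs_prot)) {
    abort(paste0(
      "unclassifiable: kappa patient(s) with quotient in (",
      thresholds$kappa_low_cut, ", ", thresholds$kappa_high_cut,
      "] require proteinuria to decide the low branch"
    ))
  }

  branch <- rep("negative", n)
  branch[lc_type == "lambda" & quotient > thresholds$lambda_cut] <- "lambda_main"
  branch[lc_type == "kappa" & quotient > thresholds$kappa_high_cut] <- "kappa_high"
  branch[kappa_mid & !is.na(proteinuria) &
           proteinuria < thresholds$proteinuria_cut] <- "kappa_low_with_proteinuria"

  tibble::tibble(
    lc_type = lc_type,
    quotient = quotient,
    proteinuria = proteinuria,
    positive = branch != "negative",
    branch = branch
  )
}

#' Apply the cast-nephropathy rule to a cohort
#'
#' Computes each patient's quotient and classification. Kappa patients
#' with missing proteinuria and a quotient in the branch-sensitive range
#' are excluded (not errors) and reported in the `"excluded"` attribute;
#' lambda patients never need proteinuria.
#'
#' @param cohort A cohort tibble (see [as_cohort()]).
#' @param thresholds A [rule_thresholds()] object.
#' @return A tibble with one row per classifiable patient: `id`,
#'   `lc_type`, `quotient`, `proteinuria`, `positive`, `branch`, and the
#'   biopsy ground truth `is_cn`. Attribute `"excluded"` is a tibble of
#'   `id`, `reason`.
#' @export
#' @examples
#' ch <- generate_cohort(seed = 42)
#' preds <- apply_rule(ch)
#' table(predicted = preds$positive, biopsy_cn = preds$is_cn)
apply_rule <- function(cohort, thresholds = rule_thresholds()) {
  stopifnot(inherits(cohort, "lcq_cohort"), nrow(cohort) > 0)
  q <- lc_egfr_quotient(cohort$involved_lc_urine, cohort$egfr)
  undecidable <- cohort$lc_type == "kappa" & is.na(cohort$proteinuria) &
    q > thresholds$kappa_low_cut & q <= thresholds$kappa_high_cut
  excluded <- tibble::tibble(
    id = cohort$id[undecidable],
    reason = rep("kappa_missing_proteinuria_in_branch_sensitive_range",
                 sum(undecidable))
  )
  keep <- !undecidable
  if (!any(keep)) abort("no classifiable patients in cohort")
  pred <- classify_cn(cohort$lc_type[keep], q[keep],
                      cohort$proteinuria[keep], thresholds)
  out <- tibble::tibble(
    id = cohort$id[keep],
    lc_type = pred$lc_type,
    quotient = pred$quotient,
    proteinuria = pred$proteinuria,
    positive = pred$positive,
    branch = pred$branch,
    is_cn = cohort$histology[keep] == "cast_nephropathy"
  )
  structure(out, excluded = excluded,
            class = c("lcq_predictions", class(out)))
}
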