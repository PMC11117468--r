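#' Log-normal sigma from a median and interquartile range
#'
#' A log-normal with median \eqn{m} and log-scale sigma \eqn{\sigma} has
#' quartiles \eqn{m e^{\pm z \sigma}} with \eqn{z = \Phi^{-1}(0.75)}, so
#' its IQR is \eqn{2 m \sinh(z\sigma)}; inverting gives the unique
#' \eqn{\sigma = \mathrm{asinh}(IQR / 2m) / z}. This is the closed-form
#' calibration the generator uses to match published median (IQR)
#' summaries.
#'
#' @param median Distribution median, > 0.
#' @param iqr Interquartile range, >= 0.
#' @return The log-scale standard deviation.
#' @export
#' @examples
#' s <- sigma_from_median_iqr(33.1, 46.9)
#' m <- 33.1; z <- qnorm(0.75)
#' m * (exp(z * s) - exp(-z * s)) # recovers 46.9
sigma_from_median_iqr <- function(median, iqr) {
  if (!is.numeric(median) || any(!is.finite(median)) || any(median <= 0)) {
    abort("`median` must be finite and > 0")
  }
  if (!is.numeric(iqr) || any(!is.finite(iqr)) || any(iqr < 0)) {
    abort("`iqr` must be finite and >= 0")
  }
  asinh(iqr / (2 * median)) / qnorm(0.75)
}

# Per-histology-group calibration of the two-center validation cohort:
# median (IQR) of eGFR, involved serum FLC and involved urine LC, group
# sizes 18/13/3/33, 11 of 18 CN patients kappa, 38 kappa / 29 lambda
# overall (so 27 of 49 non-CN kappa), proteinuria matched to the group
# means 3929 (CN) / 2565 (non-CN) mg/24 h with log-scale sigma 1.0.
default_group_table <- function() {
  prot_sigma <- 1.0
  prot_median <- function(mean) mean * exp(-prot_sigma^2 / 2)
  tibble::tibble(
    group = c("CN", "ALA", "MIDD", "Others"),
    n = c(18L, 13L, 3L, 33L),
    kappa_fraction = c(11 / 18, 27 / 49, 27 / 49, 27 / 49),
    egfr_median = c(7.5, 44.4, 23.7, 34.9),
    egfr_iqr = c(8.4, 34.8, 11.6, 19.9),
    flc_serum_median = c(598.0, 21.1, 95.5, 29.3),
    flc_serum_iqr = c(789.0, 61.8, 1124.6, 125.0),
    lc_urine_median = c(171.5, 15.9, 48.6, 5.7),
    lc_urine_iqr = c(244.8, 8.9, 81.7, 20.8),
    proteinuria_median = prot_median(c(3929, 2565, 2565, 2565)),
    proteinuria_sigma = prot_sigma
  )
}

# histology labels drawn within the catch-all group, in validation-cohort
# proportions (9 proximal tubulopathy, 6 nephroangiosclerosis, 2
# thrombotic microangiopathy, 16 other of 33)
others_composition <- function() {
  c(light_chain_proximal_tubulopathy = 9, nephroangiosclerosis = 6,
    thrombotic_microangiopathy = 2, other = 16) / 33
}

#' Synthetic cohort specification
#'
#' Defines the virtual-cohort generator: per-group sample sizes, kappa
#' fractions and log-normal parameters for eGFR, involved serum FLC,
#' involved urine LC and proteinuria, calibrated to the per-histology
#' median (IQR) summaries of the original two-center validation cohort;
#' plus the cohort-level age distribution (median 72, range 38--90) and
#' sex composition (24 female of 67).
#'
#' @param groups A tibble like `default_cohort_spec()$groups`; columns
#'   `group`, `n`, `kappa_fraction`, `<var>_median`, `<var>_iqr` for
#'   eGFR/serum FLC/urine LC, and `proteinuria_median`,
#'   `proteinuria_sigma`.
#' @param n_scale Integer multiplier applied to every group size (e.g.
#'   for large calibration-recovery runs).
#' @param female_fraction Cohort-level probability-mass of female sex.
#' @param log_cor_egfr_urine Log-scale correlation between eGFR and
#'   urine LC within a patient (default 0: the source summaries are
#'   marginal only, so any non-zero value is an extrapolation).
#' @param ckdepi [ckdepi_params()] used to back-fill creatinine.
#' @return A list of class `cohort_spec` with the derived log-normal
#'   sigmas filled in.
#' @export
cohort_spec <- function(groups = default_group_table(), n_scale = 1L,
                        female_fraction = 24 / 67,
                        log_cor_egfr_urine = 0,
                        ckdepi = ckdepi_params()) {
  stopifnot(is.data.frame(groups), all(groups$n >= 0),
            all(groups$kappa_fraction >= 0 & groups$kappa_fraction <= 1),
            n_scale >= 1, female_fraction >= 0, female_fraction <= 1,
            abs(log_cor_egfr_urine) <= 1)
  groups <- tibble::as_tibble(groups)
  groups$n <- as.integer(groups$n * n_scale)
  for (v in c("egfr", "flc_serum", "lc_urine")) {
    groups[[paste0(v, "_sigma")]] <- sigma_from_median_iqr(
      groups[[paste0(v, "_median")]], groups[[paste0(v, "_iqr")]]
    )
  }
  structure(
    list(groups = groups,
         age = list(min = 38, max = 90, shape1 = 3, shape2 = 1.745),
         female_fraction = female_fraction,
         log_cor_egfr_urine = log_cor_egfr_urine,
         ckdepi = ckdepi),
    class = "cohort_spec"
  )
}

#' @rdname cohort_spec
#' @export
default_cohort_spec <- function() cohort_spec()

# deterministic largest-remainder allocation of n into proportions
allocate_counts <- function(n, prop) {
  raw <- n * prop / sum(prop)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a virtual patient cohort
#'
#' Samples a cohort from a [cohort_spec()]: group and light-chain type by
#' deterministic count allocation (so the default spec reproduces the
#' published composition exactly: 18/13/3/33 per group, 38 kappa / 29
#' lambda, 24 female), lab values from per-group log-normals, age from a
#' scaled Beta matching median 72 on [38, 90], and creatinine back-filled
#' through the CKD-EPI inverse so every patient is internally consistent.
#' The output is a pure function of `(spec, seed)`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed fixing the full cohort.
#' @return A validated synthetic cohort tibble (see [as_cohort()]).
#' @export
#' @examples
#' ch <- generate_cohort(seed = 7)
#' cohort_summary_counts(ch)$lc_type
generate_cohort <- function(spec = default_cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"), is.numeric(seed), length(seed) == 1L)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")

  g <- spec$groups
  n_total <- sum(g$n)
  if (n_total == 0) abort("cohort_spec has zero total size")
  rows <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    n <- g$n[i]
    if (n == 0) next
    rho <- spec$log_cor_egfr_urine
    z_e <- rnorm(n)
    z_u <- rho * z_e + sqrt(1 - rho^2) * rnorm(n)
    egfr <- exp(log(g$egfr_median[i]) + g$egfr_sigma[i] * z_e)
    lc_urine <- exp(log(g$lc_urine_median[i]) + g$lc_urine_sigma[i] * z_u)
    flc_serum <- exp(log(g$flc_serum_median[i]) + g$flc_serum_sigma[i] * rnorm(n))
    proteinuria <- exp(log(g$proteinuria_median[i]) +
                         g$proteinuria_sigma[i] * rnorm(n))
    n_kappa <- allocate_counts(n, c(g$kappa_fraction[i], 1 - g$kappa_fraction[i]))[1]
    lc_type <- sample(rep(c("kappa", "lambda"), c(n_kappa, n - n_kappa)))
    histology <- switch(g$group[i],
      CN = rep("cast_nephropathy", n),
      ALA = rep("al_amyloidosis", n),
      MIDD = rep("midd", n),
      Others = {
        comp <- others_composition()
        sample(rep(names(comp), allocate_counts(n, comp)))
      }
    )
    rows[[i]] <- tibble::tibble(
      group = g$group[i], lc_type = lc_type, histology = histology,
      egfr = egfr, involved_lc_urine = lc_urine,
      involved_flc_serum = flc_serum, proteinuria = proteinuria
    )
  }
  df <- dplyr::bind_rows(rows)

  n_female <- allocate_counts(n_total, c(spec$female_fraction,
                                         1 - spec$female_fraction))[1]
  df$sex <- sample(rep(c("female", "male"), c(n_female, n_total - n_female)))
  b <- rbeta(n_total, spec$age$shape1, spec$age$shape2)
  df$age <- pmin(pmax(round(spec$age$min + (spec$age$max - spec$age$min) * b),
                      spec$age$min), spec$age$max)
  df$serum_creatinine <- creatinine_from_egfr(df$egfr, df$age, df$sex,
                                              spec$ckdepi)
  df$id <- sprintf("S%0*d", nchar(n_total), seq_len(n_total))
  as_cohort(df[, c(cohort_columns)], provenance = "synthetic",
            seed = as.integer(seed), strict = TRUE, ckdepi = spec$ckdepi)
}
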