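#' CKD-EPI equation parameters
#'
#' Constants of the CKD-EPI serum-creatinine eGFR equations. The 2009
#' equation is the default, with the race coefficient fixed at 1.0 as in
#' typical European laboratory practice; the 2021 race-free refit is
#' selectable. All creatinine values are in mg/dL, eGFR in
#' mL/min/1.73 m\eqn{^2}.
#'
#' The equation has the piecewise power-law form
#' \deqn{eGFR = c_0 \cdot \min(Scr/\kappa, 1)^{\alpha} \cdot
#'       \max(Scr/\kappa, 1)^{\beta} \cdot a^{Age} \cdot f \cdot r}
#' with a sex-specific knot \eqn{\kappa} (0.7 female, 0.9 male), a
#' sex-specific low-range exponent \eqn{\alpha}, a shared high-range
#' exponent \eqn{\beta}, an age base \eqn{a}, a female factor \eqn{f} and
#' a race factor \eqn{r}.
#'
#' @param version `"2009"` (default) or `"2021"`.
#' @param race_factor Multiplicative race coefficient, default 1.0. Only
#'   meaningful for the 2009 equation; the 2021 refit has no race term.
#'
#' @return A list of class `ckdepi_params` with elements `version`,
#'   `knot`, `alpha`, `high_exponent`, `age_base`, `female_factor`,
#'   `scale` and `race_factor`; the sex-specific entries are named
#'   vectors with components `female` and `male`.
#' @export
#' @examples
#' ckdepi_params()
#' ckdepi_params("2021")
ckdepi_params <- function(version = c("2009", "2021"), race_factor = 1.0) {
  version <- match.arg(version)
  stopifnot(is.numeric(race_factor), length(race_factor) == 1L, race_factor > 0)
  p <- switch(version,
    "2009" = list(
      scale         = 141,
      knot          = c(female = 0.7, male = 0.9),
      alpha         = c(female = -0.329, male = -0.411),
      high_exponent = -1.209,
      age_base      = 0.993,
      female_factor = 1.018
    ),
    "2021" = list(
      scale         = 142,
      knot          = c(female = 0.7, male = 0.9),
      alpha         = c(female = -0.241, male = -0.302),
      high_exponent = -1.200,
      age_base      = 0.9938,
      female_factor = 1.012
    )
  )
  p$version <- version
  p$race_factor <- if (version == "2021") 1.0 else race_factor
  structure(p, class = "ckdepi_params")
}

check_sex <- function(sex) {
  sex <- as.character(sex)
  ok <- sex %in% c("female", "male")
  if (!all(ok)) {
    abort(paste0("`sex` must be 'female' or 'male'; got: ",
                 paste(unique(sex[!ok]), collapse = ", ")))
  }
  sex
}

check_adult_age <- function(age) {
  if (!is.numeric(age) || any(!is.finite(age)) || any(age < 18) || any(age > 110)) {
    abort("`age` must be numeric in [18, 110] years (adult equation).")
  }
  age
}

#' Estimated glomerular filtration rate (CKD-EPI, creatinine-based)
#'
#' Forward map from serum creatinine, age and sex to eGFR. Vectorised over
#' `creatinine`, `age` and `sex`.
#'
#' @param creatinine Serum creatinine in mg/dL, > 0.
#' @param age Age in years, 18--110.
#' @param sex `"female"` or `"male"` (recycled).
#' @param params A [ckdepi_params()] object.
#'
#' @return eGFR in mL/min/1.73 m\eqn{^2}. Strictly decreasing in
#'   creatinine and in age.
#' @export
#' @examples
#' egfr_ckdepi(0.7, 60, "female")
#' egfr_ckdepi(6.85, 72, "male") # severe kidney failure
egfr_ckdepi <- function(creatinine, age, sex, params = ckdepi_params()) {
  stopifnot(inherits(params, "ckdepi_params"))
  if (!is.numeric(creatinine) || any(!is.finite(creatinine)) || any(creatinine <= 0)) {
    abort("`creatinine` must be finite and > 0 (mg/dL).")
  }
  check_adult_age(age)
  sex <- check_sex(sex)
  n <- max(length(creatinine), length(age), length(sex))
  creatinine <- rep_len(creatinine, n)
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)

  kappa <- params$knot[sex]
  alpha <- params$alpha[sex]
  ratio <- creatinine / kappa
  sexf <- ifelse(sex == "female", params$female_factor, 1)
  unname(
    params$scale *
      pmin(ratio, 1)^alpha *
      pmax(ratio, 1)^params$high_exponent *
      params$age_base^age *
      sexf * params$race_factor
  )
}

#' Serum creatinine consistent with a given eGFR (CKD-EPI inverse)
#'
#' Closed-form analytic inverse of [egfr_ckdepi()] at fixed age and sex:
#' the piecewise power law is strictly monotone in creatinine, so each
#' branch inverts exactly; the branch is selected by comparing the target
#' eGFR with its value at the sex-specific knot. Used to back-fill a
#' physiologically consistent creatinine for simulated patients.
#'
#' @param egfr Target eGFR in mL/min/1.73 m\eqn{^2}, > 0.
#' @inheritParams egfr_ckdepi
#'
#' @return Creatinine in mg/dL such that `egfr_ckdepi(result, age, sex)`
#'   reproduces `egfr` to floating-point accuracy.
#' @export
#' @examples
#' cr <- creatinine_from_egfr(9.93, 72, "male")
#' egfr_ckdepi(cr, 72, "male")
creatinine_from_egfr <- function(egfr, age, sex, params = ckdepi_params()) {
  stopifnot(inherits(params, "ckdepi_params"))
  if (!is.numeric(egfr) || any(!is.finite(egfr)) || any(egfr <= 0)) {
    abort("`egfr` must be finite and > 0 (mL/min/1.73 m^2).")
  }
  check_adult_age(age)
  sex <- check_sex(sex)
  n <- max(length(egfr), length(age), length(sex))
  egfr <- rep_len(egfr, n)
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)

  kappa <- params$knot[sex]
  alpha <- params$alpha[sex]
  sexf <- ifelse(sex == "female", params$female_factor, 1)
  base <- params$scale * params$age_base^age * sexf * params$race_factor
  # eGFR at the knot; above it we are on the low-creatinine branch
  at_knot <- base
  exponent <- ifelse(egfr > at_knot, alpha, params$high_exponent)
  unname(kappa * (egfr / base)^(1 / exponent))
}
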