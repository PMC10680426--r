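#' Equivalent dose in 2 Gy fractions (EQD2)
#'
#' Linear-quadratic conversion of a total physical dose delivered in
#' `n_fractions` to the biologically equivalent total dose delivered in 2 Gy
#' fractions:
#' \deqn{EQD2 = D \cdot \frac{D/n + \alpha/\beta}{2 + \alpha/\beta}}
#' With `alpha_beta_Gy = 3` (late rectal effects), 60 Gy in 20 fractions maps
#' to 72 Gy and 57 Gy in 19 fractions to 68.4 Gy; any dose delivered at
#' exactly 2 Gy per fraction is a fixed point.
#'
#' @param total_dose_Gy Total physical dose (Gy), > 0. Vectorised.
#' @param n_fractions Number of fractions, > 0.
#' @param alpha_beta_Gy Tissue fractionation-sensitivity ratio (Gy), > 0;
#'   3 Gy is the conventional value for late rectal toxicity.
#' @return EQD2 in Gy.
#' @export
eqd2 <- function(total_dose_Gy, n_fractions, alpha_beta_Gy = 3) {
  check_positive(total_dose_Gy, "total_dose_Gy")
  check_positive(n_fractions, "n_fractions")
  check_positive(alpha_beta_Gy, "alpha_beta_Gy")
  total_dose_Gy * (total_dose_Gy / n_fractions + alpha_beta_Gy) /
    (2 + alpha_beta_Gy)
}

#' Physical dose with a prescribed EQD2
#'
#' Inverts [eqd2()]: finds the total physical dose `D` delivered in
#' `n_fractions` whose EQD2 equals `target_eqd2_Gy`, i.e. the positive root of
#' `D^2/n + (alpha/beta) D - target * (2 + alpha/beta) = 0`. The root is
#' computed with the cancellation-safe quadratic formula
#' `D = 2c / (ab + sqrt(ab^2 + 4c/n))` with `c = target * (2 + ab)`, exact to
#' floating precision for all positive inputs.
#'
#' @param target_eqd2_Gy Target EQD2 (Gy), > 0. Vectorised.
#' @inheritParams eqd2
#' @return Physical dose in Gy satisfying
#'   `eqd2(result, n_fractions, alpha_beta_Gy) == target_eqd2_Gy` to 1e-9.
#' @export
physical_dose_for_eqd2 <- function(target_eqd2_Gy, n_fractions,
                                   alpha_beta_Gy = 3) {
  check_positive(target_eqd2_Gy, "target_eqd2_Gy")
  check_positive(n_fractions, "n_fractions")
  check_positive(alpha_beta_Gy, "alpha_beta_Gy")
  cc <- target_eqd2_Gy * (2 + alpha_beta_Gy)
  2 * cc / (alpha_beta_Gy + sqrt(alpha_beta_Gy^2 + 4 * cc / n_fractions))
}

check_positive <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(what, " must be strictly positive and finite", call. = FALSE)
  }
  invisible(x)
}

#' Reference dose levels of interest
#'
#' The dose levels (Gy) at which DVH volumes are extracted, defined on the
#' 74 Gy / 37-fraction regimen. The default seven-level set includes 65 Gy;
#' the six-level alternative omits it.
#'
#' @param levels `"seven"` (default) or `"six"`.
#' @return Named numeric vector of reference dose levels in Gy.
#' @export
reference_dose_levels <- function(levels = c("seven", "six")) {
  levels <- match.arg(levels)
  v <- if (levels == "seven") c(30, 40, 50, 60, 65, 70, 74) else
    c(30, 40, 50, 60, 70, 74)
  names(v) <- paste0("v", v)
  v
}

#' Fractionation arms
#'
#' The three regimens: conventional 74 Gy in 37 fractions and the
#' hypofractionated 60 Gy in 20 and 57 Gy in 19 fractions.
#' @return Character vector of arm labels.
#' @export
arm_levels <- function() c("37Fr_74Gy", "20Fr_60Gy", "19Fr_57Gy")

arm_fractions <- function(arm) {
  switch(arm, "37Fr_74Gy" = 37L, "20Fr_60Gy" = 20L, "19Fr_57Gy" = 19L,
         stop("unknown arm '", arm, "'", call. = FALSE))
}

arm_prescription <- function(arm) {
  switch(arm, "37Fr_74Gy" = 74, "20Fr_60Gy" = 60, "19Fr_57Gy" = 57,
         stop("unknown arm '", arm, "'", call. = FALSE))
}

#' EQD2-equivalent dose levels for a fractionation arm
#'
#' Maps the reference dose levels (defined on the 74 Gy / 37 Fr regimen,
#' where 2 Gy per fraction makes physical dose and EQD2 coincide) onto an
#' arm's physical dose scale so that each mapped level is EQD2-equivalent
#' (alpha/beta = 3 Gy) to its reference level. The 37-fraction arm returns
#' the reference levels unchanged. Mapped levels are starred (V30*, ... Gy)
#' when reported across arms.
#'
#' @param arm One of [arm_levels()].
#' @param reference_levels_Gy Ascending reference levels, by default
#'   [reference_dose_levels()].
#' @param alpha_beta_Gy Fractionation-sensitivity ratio (Gy).
#' @return A tibble with columns `arm`, `level_name`, `reference_Gy`,
#'   `mapped_Gy` (strictly increasing).
#' @export
dose_levels_for_arm <- function(arm,
                                reference_levels_Gy = reference_dose_levels(),
                                alpha_beta_Gy = 3) {
  if (!arm %in% arm_levels()) {
    stop("unknown arm '", arm, "'; expected one of ",
         paste(arm_levels(), collapse = ", "), call. = FALSE)
  }
  stopifnot(all(diff(reference_levels_Gy) > 0))
  n <- arm_fractions(arm)
  mapped <- if (arm == "37Fr_74Gy") as.numeric(reference_levels_Gy) else
    unname(physical_dose_for_eqd2(reference_levels_Gy, n, alpha_beta_Gy))
  tibble::tibble(
    arm = arm,
    level_name = names(reference_levels_Gy) %||%
      paste0("v", reference_levels_Gy),
    reference_Gy = as.numeric(reference_levels_Gy),
    mapped_Gy = mapped
  )
}

#' Bonferroni-corrected significance threshold
#'
#' Family-wise threshold `alpha / m`, floored at `digits` decimal places as
#' printed in reports (0.05 over 32 primary tests gives 0.0015).
#'
#' @param alpha Family-wise error rate.
#' @param m Number of tests in the family.
#' @param digits Decimal places the printed threshold is floored to.
#' @return The printed threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 32, digits = 4) {
  floor(alpha / m * 10^digits) / 10^digits
}
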