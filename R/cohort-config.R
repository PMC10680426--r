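#' Synthetic cohort configuration
#'
#' Parameters of the synthetic-cohort generator. Defaults emulate the study
#' conditions of a three-arm hypofractionation trial: arms 74 Gy/37 Fr,
#' 60 Gy/20 Fr and 57 Gy/19 Fr in equal proportion; rectum modelled as a
#' stack of filled circles along z (length ~ 10 cm, volume ~ 65 cc); PTV
#' cranio-caudal extent ~ 7 cm; interobserver border review changing the
#' superior border of 43% and the inferior border of 32% of contours; and
#' late toxicity drawn from a logistic model on the true whole-rectum
#' relative dose-bin covariates.
#'
#' @param n_patients Number of patients (>= 0).
#' @param arm_weights Probabilities of the three arms in [arm_levels()]
#'   order; must sum to 1.
#' @param grid_spacing Voxel size `(dx, dy, dz)` cm; default
#'   `c(0.2, 0.2, 0.5)` — coarse but sufficient for DVH behaviour at desk
#'   scale.
#' @param rectum_length_dist,rectum_radius_dist,ptv_extent_dist Mean/SD (cm)
#'   of the normal draws for rectum length, rectum radius and PTV
#'   cranio-caudal extent.
#' @param border_shift_prob_sup,border_shift_prob_inf Probability that review
#'   changes the superior / inferior rectal border.
#' @param border_shift_slices Integer slice shifts drawn uniformly when a
#'   border changes; positive = extension, negative = removal. 0 is excluded
#'   by default so that a drawn shift always changes the border.
#' @param dose_falloff_scale Exponential length scale (cm) of dose fall-off
#'   with distance from the PTV.
#' @param toxicity_coefficients Named list per symptom, each a list with
#'   `intercept_g1`, `intercept_g2`, and `slopes` (7 values on the
#'   relative-volume dose-bin covariates, per percentage point); see
#'   [default_toxicity_coefficients()].
#' @param followup_completion_prob Probability that each late follow-up visit
#'   is completed.
#' @param baseline_g1plus_prob Probability of grade >= 1 baseline symptoms
#'   (such patients are excluded from that endpoint downstream).
#' @param seed Integer master seed; per-patient substreams are derived from
#'   it so cohorts are reproducible and order-independent.
#' @return A validated object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 200,
                          arm_weights = c(1, 1, 1) / 3,
                          grid_spacing = c(0.2, 0.2, 0.5),
                          rectum_length_dist = c(mean = 10, sd = 1.3),
                          rectum_radius_dist = c(mean = 1.4, sd = 0.15),
                          ptv_extent_dist = c(mean = 7, sd = 0.8),
                          border_shift_prob_sup = 0.43,
                          border_shift_prob_inf = 0.32,
                          border_shift_slices = setdiff(-4:4, 0),
                          dose_falloff_scale = 1.2,
                          toxicity_coefficients = default_toxicity_coefficients(),
                          followup_completion_prob = 0.85,
                          baseline_g1plus_prob = 0.08,
                          seed = 1L) {
  cfg <- structure(
    list(n_patients = n_patients, arm_weights = arm_weights,
         grid_spacing = grid_spacing,
         rectum_length_dist = rectum_length_dist,
         rectum_radius_dist = rectum_radius_dist,
         ptv_extent_dist = ptv_extent_dist,
         border_shift_prob_sup = border_shift_prob_sup,
         border_shift_prob_inf = border_shift_prob_inf,
         border_shift_slices = border_shift_slices,
         dose_falloff_scale = dose_falloff_scale,
         toxicity_coefficients = toxicity_coefficients,
         followup_completion_prob = followup_completion_prob,
         baseline_g1plus_prob = baseline_g1plus_prob,
         seed = seed),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
}

config_error <- function(field, msg) {
  stop(sprintf("invalid cohort configuration field '%s': %s", field, msg),
       call. = FALSE)
}

validate_cohort_config <- function(cfg) {
  chk_prob <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      config_error(field, "must be a probability in [0, 1]")
  }
  chk_dist <- function(x, field) {
    if (!is.numeric(x) || length(x) != 2 || any(!is.finite(x)))
      config_error(field, "must be numeric (mean, sd)")
    if (x[2] < 0) config_error(field, "SD must be >= 0")
  }
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
      is.na(cfg$n_patients) || cfg$n_patients < 0 ||
      cfg$n_patients != round(cfg$n_patients))
    config_error("n_patients", "must be a non-negative integer")
  if (!is.numeric(cfg$arm_weights) || length(cfg$arm_weights) != 3 ||
      any(cfg$arm_weights < 0) || abs(sum(cfg$arm_weights) - 1) > 1e-8)
    config_error("arm_weights", "must be 3 non-negative weights summing to 1")
  if (!is.numeric(cfg$grid_spacing) || length(cfg$grid_spacing) != 3 ||
      any(cfg$grid_spacing <= 0))
    config_error("grid_spacing", "must be 3 strictly positive voxel sizes")
  chk_dist(cfg$rectum_length_dist, "rectum_length_dist")
  chk_dist(cfg$rectum_radius_dist, "rectum_radius_dist")
  chk_dist(cfg$ptv_extent_dist, "ptv_extent_dist")
  chk_prob(cfg$border_shift_prob_sup, "border_shift_prob_sup")
  chk_prob(cfg$border_shift_prob_inf, "border_shift_prob_inf")
  if (!is.numeric(cfg$border_shift_slices) || length(cfg$border_shift_slices) < 1 ||
      any(cfg$border_shift_slices != round(cfg$border_shift_slices)))
    config_error("border_shift_slices", "must be a set of integer slice shifts")
  if (!is.numeric(cfg$dose_falloff_scale) || cfg$dose_falloff_scale <= 0)
    config_error("dose_falloff_scale", "must be > 0 (cm)")
  validate_toxicity_coefficients(cfg$toxicity_coefficients)
  chk_prob(cfg$followup_completion_prob, "followup_completion_prob")
  chk_prob(cfg$baseline_g1plus_prob, "baseline_g1plus_prob")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed))
    config_error("seed", "must be a single integer")
  cfg
}

validate_toxicity_coefficients <- function(tc) {
  if (!is.list(tc) || is.null(names(tc)) ||
      !all(names(tc) %in% symptom_levels()))
    config_error("toxicity_coefficients",
                 paste("must be a named list over symptoms",
                       paste(symptom_levels(), collapse = ", ")))
  for (nm in names(tc)) {
    s <- tc[[nm]]
    if (!is.list(s) || !all(c("intercept_g1", "intercept_g2", "slopes") %in% names(s)))
      config_error("toxicity_coefficients",
                   paste0("symptom '", nm,
                          "' needs intercept_g1, intercept_g2 and slopes"))
    if (!is.numeric(s$slopes) || length(s$slopes) != 7 || any(!is.finite(s$slopes)))
      config_error("toxicity_coefficients",
                   paste0("symptom '", nm, "' slopes must be 7 finite values"))
    if (!is.finite(s$intercept_g1) || !is.finite(s$intercept_g2))
      config_error("toxicity_coefficients", "intercepts must be finite")
    if (s$intercept_g2 > s$intercept_g1)
      config_error("toxicity_coefficients",
                   paste0("symptom '", nm,
                          "': intercept_g2 must not exceed intercept_g1 (grade nesting)"))
  }
  invisible(tc)
}

#' Graded symptoms of the unified late-toxicity scale
#'
#' The five symptoms from which the eight binary endpoints are derived
#' (frequency and bleeding and proctitis at G1+ and G2+, sphincter control
#' and stricture/ulcer at G1+ only).
#' @return Character vector of symptom names.
#' @export
symptom_levels <- function() {
  c("frequency", "bleeding", "proctitis", "sphincter_control", "stricture_ulcer")
}

#' Late follow-up schedule
#'
#' Months of the scheduled toxicity assessments: baseline (0) and seven late
#' follow-ups.
#' @return Integer vector of visit months.
#' @export
visit_months <- function() c(0L, 6L, 12L, 18L, 24L, 36L, 48L, 60L)

#' Default toxicity-generating coefficients
#'
#' Logistic coefficients used by the synthetic generator, one set per
#' symptom. Slopes act on the seven whole-rectum relative-volume dose-bin
#' covariates (percentage points) and are weighted toward the mid-to-high
#' dose bins, reflecting the usual dose-response for late rectal effects.
#' Intercepts set grade >= 1 prevalences of roughly 0.25-0.35 for the common
#' symptoms and 0.05-0.1 for stricture/ulcer, with grade >= 2 events about a
#' third as common — producing deliberately weak predictors
#' (model AUC ~ 0.6), the regime the comparison machinery is designed for.
#'
#' @return Named list, one element per [symptom_levels()] entry, each with
#'   `intercept_g1`, `intercept_g2` and 7 `slopes`.
#' @export
default_toxicity_coefficients <- function() {
  slopes <- c(v30 = 0, v40 = 0.005, v50 = 0.01, v60 = 0.02,
              v65 = 0.02, v70 = 0.015, v74 = 0.01)
  mk <- function(a1, a2, sc = 1) {
    list(intercept_g1 = a1, intercept_g2 = a2, slopes = slopes * sc)
  }
  list(
    frequency         = mk(-1.6, -3.0),
    bleeding          = mk(-1.8, -3.2),
    proctitis         = mk(-1.5, -3.1),
    sphincter_control = mk(-2.6, -4.0),
    stricture_ulcer   = mk(-3.6, -5.0)
  )
}

#' Read a cohort configuration from a YAML file
#'
#' Reads a key-value (optionally nested) text file holding [cohort_config()]
#' fields. Unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A validated `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    config_error(unknown[1], "unknown configuration key")
  }
  for (f in c("rectum_length_dist", "rectum_radius_dist", "ptv_extent_dist")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  if (!is.null(raw$toxicity_coefficients)) {
    raw$toxicity_coefficients <- lapply(raw$toxicity_coefficients, function(s) {
      s$slopes <- unlist(s$slopes)
      s
    })
  }
  do.call(cohort_config, raw)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> n=%d, arms (%s), seed=%d\n",
              x$n_patients, paste(sprintf("%.2f", x$arm_weights), collapse = ", "),
              as.integer(x$seed)))
  invisible(x)
}
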