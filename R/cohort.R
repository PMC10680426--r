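# Synthetic cohort generation: geometry, dose field, border perturbation,
# toxicity simulation.

# Counter-based substream: one root seed, deterministic per-patient streams
# independent of generation order. Kept below 2^31 - 1.
substream_seed <- function(seed, counter) {
  as.integer((abs(as.numeric(seed)) + as.numeric(counter) * 1000003) %% 2147483629 + 1)
}

#' Synthetic planned dose distribution around a PTV
#'
#' Builds a dose grid equal to the prescription inside the PTV, decaying
#' exponentially with the Euclidean distance from the PTV with length scale
#' `falloff_scale`: `dose = Rx * exp(-d / s)`. The dose is strictly positive
#' everywhere, never exceeds the prescription, and is non-increasing with
#' distance; as `falloff_scale` grows, dose tends to the prescription
#' everywhere. When the PTV occupancy is a filled axis-aligned box (as in the
#' synthetic generator) the distance is the exact closed-form point-to-box
#' distance; otherwise an exact brute-force distance to the occupied voxel
#' centres is used (intended for small masks).
#'
#' @param ptv A non-empty [structure_mask()].
#' @param prescription_Gy Prescribed dose (Gy), > 0.
#' @param falloff_scale Exponential fall-off length scale (cm), > 0.
#' @return A [dose_grid()] on the PTV's grid.
#' @export
build_dose_field <- function(ptv, prescription_Gy, falloff_scale) {
  stopifnot(inherits(ptv, "structure_mask"))
  if (!any(ptv$occupancy)) stop("PTV mask is empty", call. = FALSE)
  check_positive(prescription_Gy, "prescription_Gy")
  check_positive(falloff_scale, "falloff_scale")
  d <- distance_to_mask(ptv)
  dose_grid(prescription_Gy * exp(-d / falloff_scale), ptv$spacing,
            ptv$grid_origin)
}

# Euclidean distance (cm) from each voxel centre to the mask region
# (0 inside). Closed form for filled boxes; brute force otherwise.
distance_to_mask <- function(mask) {
  occ <- mask$occupancy
  dims <- dim(occ)
  ax <- mask$grid_origin[1] + (seq_len(dims[1]) - 1) * mask$spacing[1]
  ay <- mask$grid_origin[2] + (seq_len(dims[2]) - 1) * mask$spacing[2]
  az <- mask$grid_origin[3] + (seq_len(dims[3]) - 1) * mask$spacing[3]
  idx <- which(occ, arr.ind = TRUE)
  if (is_filled_box(occ, idx)) {
    lo <- c(ax[min(idx[, 1])], ay[min(idx[, 2])], az[min(idx[, 3])])
    hi <- c(ax[max(idx[, 1])], ay[max(idx[, 2])], az[max(idx[, 3])])
    dx <- pmax(lo[1] - ax, ax - hi[1], 0)
    dy <- pmax(lo[2] - ay, ay - hi[2], 0)
    dz <- pmax(lo[3] - az, az - hi[3], 0)
    d2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
    return(array(sqrt(d2), dims))
  }
  pts <- cbind(ax[idx[, 1]], ay[idx[, 2]], az[idx[, 3]])
  grid <- as.matrix(expand.grid(x = ax, y = ay, z = az))
  d <- vapply(seq_len(nrow(grid)), function(i) {
    sqrt(min((pts[, 1] - grid[i, 1])^2 + (pts[, 2] - grid[i, 2])^2 +
               (pts[, 3] - grid[i, 3])^2))
  }, numeric(1))
  d[as.vector(occ)] <- 0
  array(d, dims)
}

is_filled_box <- function(occ, idx = which(occ, arr.ind = TRUE)) {
  ext <- apply(idx, 2, function(i) max(i) - min(i) + 1L)
  sum(occ) == prod(ext)
}

#' Perturb the superior/inferior borders of a structure
#'
#' Emulates interobserver disagreement at the open cranio-caudal borders of
#' the rectum: with probability `prob_sup` the superior border is shifted by
#' a uniform draw from `shift_slices` slices (positive shifts extend the
#' structure by copying the terminal slice's cross-section; negative shifts
#' delete slices), and analogously (independently) for the inferior border.
#' In-plane voxels are never altered. A removal that would empty the
#' structure is clamped so at least one slice remains, with a warning.
#'
#' Uses the current RNG stream; seed it (or use the cohort substreams) for
#' reproducibility.
#'
#' @param mask A non-empty [structure_mask()].
#' @param prob_sup,prob_inf Border-change probabilities in `[0, 1]`.
#' @param shift_slices Integer shifts drawn uniformly when a border changes.
#' @return A `structure_mask` on the same grid.
#' @export
perturb_borders <- function(mask, prob_sup, prob_inf,
                            shift_slices = setdiff(-4:4, 0)) {
  stopifnot(inherits(mask, "structure_mask"))
  if (!any(mask$occupancy)) stop("mask is empty", call. = FALSE)
  stopifnot(prob_sup >= 0, prob_sup <= 1, prob_inf >= 0, prob_inf <= 1,
            all(shift_slices == round(shift_slices)))
  occ <- mask$occupancy
  nz <- dim(occ)[3]
  draw <- function(p) {
    if (stats::runif(1) < p) sample(as.integer(shift_slices), 1) else 0L
  }
  s_sup <- draw(prob_sup)
  s_inf <- draw(prob_inf)

  apply_shift <- function(occ, shift, side) {
    if (shift == 0L) return(occ)
    slc <- which(apply(occ, 3, any))
    lo <- min(slc); hi <- max(slc)
    if (side == "sup") {
      if (shift > 0) {
        new_hi <- min(hi + shift, nz)
        if (new_hi > hi) occ[, , (hi + 1):new_hi] <- occ[, , hi]
      } else {
        new_hi <- hi + shift
        if (new_hi < lo) {
          warning("superior removal clamped to keep one slice", call. = FALSE)
          new_hi <- lo
        }
        if (new_hi < hi) occ[, , (new_hi + 1):hi] <- FALSE
      }
    } else {
      if (shift > 0) {
        new_lo <- max(lo - shift, 1L)
        if (new_lo < lo) occ[, , new_lo:(lo - 1)] <- occ[, , lo]
      } else {
        new_lo <- lo - shift
        if (new_lo > hi) {
          warning("inferior removal clamped to keep one slice", call. = FALSE)
          new_lo <- hi
        }
        if (new_lo > lo) occ[, , lo:(new_lo - 1)] <- FALSE
      }
    }
    occ
  }
  occ <- apply_shift(occ, s_sup, "sup")
  occ <- apply_shift(occ, s_inf, "inf")
  structure_mask(occ, mask$spacing, mask$grid_origin,
                 name = paste0(mask$name, "_reviewed"))
}

#' Simulate longitudinal graded toxicity for one symptom
#'
#' Draws a patient's maximal late grade from nested logistic models on the
#' dose-bin covariates — `P(grade >= 1) = plogis(intercept_g1 + slopes . x)`,
#' `P(grade >= 2) = plogis(intercept_g2 + slopes . x)` with a shared uniform
#' draw so grade >= 2 implies grade >= 1 — then scatters per-visit grades over
#' the seven late follow-ups, each completed independently with
#' `followup_completion_prob` (if an event occurred, one visit is forced
#' complete and carries the maximal grade). Baseline grade is >= 1 with
#' `baseline_g1plus_prob`, independent of dose.
#'
#' Uses the current RNG stream.
#'
#' @param covariates 7 finite dose-bin covariate values (relative volumes, %).
#' @param coefficients List with `intercept_g1`, `intercept_g2`, `slopes`
#'   (length 7).
#' @param followup_completion_prob,baseline_g1plus_prob Probabilities.
#' @param symptom Symptom label stored in the output.
#' @param patient_id Identifier stored in the output.
#' @return A tibble with columns `patient_id`, `symptom`, `visit_month`,
#'   `grade` (NA = visit not completed).
#' @export
simulate_toxicity <- function(covariates, coefficients,
                              followup_completion_prob = 0.85,
                              baseline_g1plus_prob = 0.08,
                              symptom = "symptom", patient_id = "p1") {
  if (length(covariates) != 7 || any(!is.finite(covariates))) {
    stop("covariates must be 7 finite values", call. = FALSE)
  }
  lp1 <- coefficients$intercept_g1 + sum(coefficients$slopes * covariates)
  lp2 <- coefficients$intercept_g2 + sum(coefficients$slopes * covariates)
  if (!is.finite(lp1) || !is.finite(lp2)) {
    stop("non-finite linear predictor in toxicity simulation", call. = FALSE)
  }
  u <- stats::runif(1)
  max_grade <- if (u < stats::plogis(lp2)) 2L else if (u < stats::plogis(lp1)) 1L else 0L

  months <- visit_months()
  late <- months[months > 0]
  completed <- stats::runif(length(late)) < followup_completion_prob
  if (max_grade >= 1L && !any(completed)) {
    completed[sample.int(length(late), 1)] <- TRUE
  }
  grades <- rep(NA_integer_, length(late))
  if (any(completed)) {
    ic <- which(completed)
    if (max_grade == 0L) {
      grades[ic] <- 0L
    } else {
      w <- c(0.6, 0.3, 0.1)[seq_len(max_grade + 1)]
      grades[ic] <- sample(0:max_grade, length(ic), replace = TRUE,
                           prob = w / sum(w))
      grades[ic[sample.int(length(ic), 1)]] <- max_grade
    }
  }
  baseline <- if (stats::runif(1) < baseline_g1plus_prob) 1L else 0L
  tibble::new_tibble(
    list(patient_id = rep(patient_id, length(months)),
         symptom = rep(symptom, length(months)),
         visit_month = months,
         grade = c(baseline, grades)),
    nrow = length(months)
  )
}

#' Fast covariate-level cohort simulation
#'
#' Draws per-patient seven-bin relative-volume covariates directly from a
#' smooth parametric DVH family, `V(d) = 100 * exp(-(d / d0)^k)` with
#' patient-specific log-normal `d0` (mid-dose scale) and `k` (steepness) —
#' monotone non-increasing in dose and marginally similar to the voxel-level
#' generator's covariates, but orders of magnitude faster. Intended for
#' statistical calibration studies (parameter recovery, coverage) where the
#' voxel geometry is irrelevant.
#'
#' @param n Number of patients.
#' @param reference_levels_Gy Dose levels at which covariates are evaluated.
#' @param d0_meanlog,d0_sdlog,k_meanlog,k_sdlog Log-normal parameters of the
#'   DVH family.
#' @param seed Optional seed.
#' @return A tibble `patient_id`, `v30`, ..., `v74` (%).
#' @export
simulate_dvh_covariates <- function(n,
                                    reference_levels_Gy = reference_dose_levels(),
                                    d0_meanlog = log(45), d0_sdlog = 0.25,
                                    k_meanlog = log(2.5), k_sdlog = 0.2,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d0 <- stats::rlnorm(n, d0_meanlog, d0_sdlog)
  k <- stats::rlnorm(n, k_meanlog, k_sdlog)
  v <- vapply(reference_levels_Gy,
              function(d) 100 * exp(-(d / d0)^k), numeric(n))
  v <- matrix(v, nrow = n,
              dimnames = list(NULL, names(reference_levels_Gy)))
  dplyr::bind_cols(
    tibble::tibble(patient_id = sprintf("p%05d", seq_len(max(n, 0)))),
    tibble::as_tibble(v)
  )
}

#' Generate a synthetic cohort
#'
#' Generates `config$n_patients` patients, each with: an arm drawn from
#' `arm_weights`; a voxelised rectum (stack of filled circles along z) and
#' box PTV on a shared per-patient grid; a planned dose field from
#' [build_dose_field()] at the arm's prescription; a "reviewed" rectum that
#' differs from the original only by slice additions/removals at the two
#' borders ([perturb_borders()]); the true seven whole-rectum relative-volume
#' covariates at the arm's EQD2-mapped dose levels; and longitudinal graded
#' toxicity for the five symptoms from [simulate_toxicity()] on those true
#' covariates. Fully deterministic given `config$seed` (per-patient
#' counter-based substreams).
#'
#' @param config A [cohort_config()].
#' @return A list of `synthetic_patient` objects (class
#'   `synthetic_cohort`), each with fields `patient_id`, `arm`, `dose`,
#'   `rectum_original`, `rectum_reviewed`, `ptv`, `true_covariates`,
#'   `toxicity`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  n <- config$n_patients
  if (n == 0) return(structure(list(), class = "synthetic_cohort"))
  patients <- lapply(seq_len(n), function(i) {
    generate_patient(config, i)
  })
  structure(patients, class = "synthetic_cohort")
}

# first draw of a patient's substream; exposed internally so arm marginals
# can be checked without voxel geometry
draw_patient_arm <- function(config, i) {
  set.seed(substream_seed(config$seed, i))
  sample(arm_levels(), 1, prob = config$arm_weights)
}

generate_patient <- function(config, i) {
  arm <- draw_patient_arm(config, i)
  sp <- config$grid_spacing

  rtrunc_norm <- function(dist, lo) max(stats::rnorm(1, dist[1], dist[2]), lo)
  len <- rtrunc_norm(config$rectum_length_dist, 3)
  radius <- rtrunc_norm(config$rectum_radius_dist, 0.6)
  ptv_len <- rtrunc_norm(config$ptv_extent_dist, 3)
  overlap <- max(stats::rnorm(1, 0.4, 0.1), 0.05)   # rectal depth inside PTV, cm
  z_center <- stats::rnorm(1, 0.5, 0.8)             # rectum offset vs PTV centre

  # per-patient grid: x/y cover rectum and PTV; z leaves headroom for border
  # extension (max |shift| slices each side)
  headroom <- max(abs(config$border_shift_slices)) * sp[3]
  ptv_ap <- 4; ptv_lr <- 4.8
  x_lo <- -max(radius, ptv_lr / 2) - 2 * sp[1]
  y_lo <- -(radius - overlap) - ptv_ap - 2 * sp[2]
  y_hi <- radius + 2 * sp[2]
  z_lo <- min(z_center - len / 2, -ptv_len / 2) - headroom - sp[3]
  z_hi <- max(z_center + len / 2, ptv_len / 2) + headroom + sp[3]
  ax <- seq(x_lo, -x_lo, by = sp[1])
  ay <- seq(y_lo, y_hi, by = sp[2])
  az <- seq(z_lo, z_hi, by = sp[3])
  origin <- c(ax[1], ay[1], az[1])
  dims <- c(length(ax), length(ay), length(az))

  circle <- outer(ax^2, ay^2, `+`) <= radius^2
  rect_z <- az >= z_center - len / 2 & az <= z_center + len / 2
  rectum <- array(FALSE, dims)
  rectum[, , rect_z] <- circle
  rectum <- structure_mask(rectum, sp, origin, name = "rectum")

  ptv_x <- abs(ax) <= ptv_lr / 2
  ptv_y <- ay <= (overlap - radius) & ay >= (overlap - radius) - ptv_ap
  ptv_z <- abs(az) <= ptv_len / 2
  ptv <- array(FALSE, dims)
  ptv[ptv_x, ptv_y, ptv_z] <- TRUE
  ptv <- structure_mask(ptv, sp, origin, name = "ptv")

  dose <- build_dose_field(ptv, arm_prescription(arm), config$dose_falloff_scale)
  reviewed <- perturb_borders(rectum, config$border_shift_prob_sup,
                              config$border_shift_prob_inf,
                              config$border_shift_slices)

  dvh <- compute_dvh(dose, rectum)
  true_cov <- dvh_covariates(dvh, arm, mode = "relative")

  patient_id <- sprintf("p%05d", i)
  toxicity <- purrr::map_dfr(symptom_levels(), function(sym) {
    simulate_toxicity(true_cov, config$toxicity_coefficients[[sym]],
                      config$followup_completion_prob,
                      config$baseline_g1plus_prob,
                      symptom = sym, patient_id = patient_id)
  })

  structure(
    list(patient_id = patient_id, arm = arm, dose = dose,
         rectum_original = rectum, rectum_reviewed = reviewed, ptv = ptv,
         true_covariates = true_cov, toxicity = toxicity),
    class = "synthetic_patient"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients\n", length(x)))
  invisible(x)
}

#' Cohort manifest
#'
#' @param cohort A [generate_cohort()] result.
#' @return A tibble `patient_id`, `arm`.
#' @export
cohort_manifest <- function(cohort) {
  purrr::map_dfr(cohort, function(p) {
    tibble::tibble(patient_id = p$patient_id, arm = p$arm)
  })
}

#' Long-format toxicity records for a cohort
#'
#' @param cohort A [generate_cohort()] result.
#' @return A tibble `patient_id`, `symptom`, `visit_month`, `grade`.
#' @export
cohort_toxicity <- function(cohort) {
  purrr::map_dfr(cohort, function(p) p$toxicity)
}
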