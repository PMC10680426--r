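test_that("invalid configuration fields are rejected by name", {
  expect_error(cohort_config(n_patients = -1), "n_patients")
  expect_error(cohort_config(arm_weights = c(0.5, 0.5, 0.5)), "arm_weights")
  expect_error(cohort_config(grid_spacing = c(0.2, 0, 0.5)), "grid_spacing")
  expect_error(cohort_config(rectum_length_dist = c(10, -1)),
               "rectum_length_dist")
  expect_error(cohort_config(border_shift_prob_sup = 1.3),
               "border_shift_prob_sup")
  expect_error(cohort_config(dose_falloff_scale = 0), "dose_falloff_scale")
  tc <- default_toxicity_coefficients()
  tc$frequency$slopes <- tc$frequency$slopes[1:3]
  expect_error(cohort_config(toxicity_coefficients = tc),
               "toxicity_coefficients")
})

test_that("YAML configs round-trip and unknown keys are rejected", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_patients: 5", "seed: 3",
               "rectum_length_dist: {mean: 9.0, sd: 1.0}"), path)
  cfg <- read_cohort_config(path)
  expect_s3_class(cfg, "cohort_config")
  expect_equal(cfg$n_patients, 5)
  expect_equal(unname(cfg$rectum_length_dist), c(9, 1))

  writeLines(c("n_patients: 5", "rectum_lenght: 9"), path)
  expect_error(read_cohort_config(path), "unknown configuration key")
})

test_that("empty cohorts and determinism contracts hold", {
  expect_length(generate_cohort(cohort_config(n_patients = 0)), 0)
  cfg <- cohort_config(n_patients = 6, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  # different seed, different cohort
  c_ <- generate_cohort(cohort_config(n_patients = 6, seed = 100))
  expect_false(identical(a, c_))
})

test_that("arm assignment matches the configured weights (binomial bound)", {
  cfg <- cohort_config(n_patients = 10000, seed = 12)
  arms <- vapply(seq_len(10000), function(i) dosetox:::draw_patient_arm(cfg, i),
                 character(1))
  counts <- table(factor(arms, levels = arm_levels()))
  sd_bin <- sqrt(10000 * (1 / 3) * (2 / 3))
  for (k in counts) expect_lt(abs(k - 10000 / 3), 4 * sd_bin)
})

test_that("synthetic patients are internally consistent", {
  cohort <- shared_cohort(25, seed = 5)
  for (p in cohort[1:8]) {
    expect_true(any(p$rectum_original$occupancy))
    expect_true(any(p$rectum_reviewed$occupancy))
    expect_true(any(p$ptv$occupancy))
    expect_identical(dim(p$dose$dose), dim(p$rectum_original$occupancy))
    expect_length(p$true_covariates, 7)
    expect_true(all(diff(p$true_covariates) <= 1e-9))  # cumulative DVH order
    # reviewed differs from original only at whole z-slices
    diff_vox <- p$rectum_original$occupancy != p$rectum_reviewed$occupancy
    changed <- apply(diff_vox, 3, any)
    same_plane <- apply(p$rectum_original$occupancy, 3, any) &
      apply(p$rectum_reviewed$occupancy, 3, any)
    expect_true(all(!diff_vox[, , same_plane & !changed]))
  }
})

test_that("dose field is the prescription inside the PTV with monotone falloff", {
  ptv <- slice_mask(3:6, nz = 10, dz = 0.5, nx = 5, ny = 5,
                    spacing = c(0.2, 0.2, 0.5))
  d <- build_dose_field(ptv, 74, falloff_scale = 1.2)
  expect_true(all(d$dose[ptv$occupancy] == 74))
  expect_true(all(d$dose > 0))
  expect_true(all(d$dose <= 74))
  # dose ordered by distance from the PTV
  dist <- dosetox:::distance_to_mask(ptv)
  o <- order(dist)
  expect_true(all(diff(d$dose[o]) <= 1e-9))
  # falloff_scale -> infinity: prescription everywhere
  d_inf <- build_dose_field(ptv, 74, falloff_scale = 1e9)
  expect_equal(max(abs(d_inf$dose - 74)), 0, tolerance = 1e-5)
  expect_error(build_dose_field(slice_mask(integer(0), nz = 3), 74, 1),
               "empty")
})

test_that("closed-form box distance matches the brute-force voxel distance", {
  occ <- array(FALSE, c(4, 4, 5))
  occ[2:3, 2:3, 2:3] <- TRUE   # interior box
  box <- structure_mask(occ, c(0.4, 0.4, 0.5))
  d_box <- dosetox:::distance_to_mask(box)
  # diagonal corner voxel: one voxel away on each axis
  expect_equal(d_box[1, 1, 1], sqrt(0.4^2 + 0.4^2 + 0.5^2), tolerance = 1e-12)
  expect_true(all(d_box[occ] == 0))

  # non-box mask takes the brute-force path; removing a corner voxel can
  # only increase distances, and both paths agree where unaffected
  occ2 <- occ; occ2[2, 2, 2] <- FALSE
  d_bf <- dosetox:::distance_to_mask(
    structure_mask(occ2, c(0.4, 0.4, 0.5)))
  expect_true(all(d_bf >= d_box - 1e-12))
  expect_equal(d_bf[4, 4, 5], d_box[4, 4, 5], tolerance = 1e-12)
})

test_that("border perturbation is a no-op at zero probability or zero shift", {
  m <- slice_mask(4:12, nz = 20, dz = 0.5, nx = 4, ny = 4,
                  spacing = c(0.2, 0.2, 0.5))
  set.seed(1)
  expect_identical(perturb_borders(m, 0, 0)$occupancy, m$occupancy)
  expect_identical(perturb_borders(m, 1, 1, shift_slices = 0L)$occupancy,
                   m$occupancy)
})

test_that("a fixed +4 superior shift lengthens the structure by 4 * dz", {
  m <- slice_mask(4:12, nz = 20, dz = 0.5, nx = 4, ny = 4,
                  spacing = c(0.2, 0.2, 0.5))
  set.seed(1)
  out <- perturb_borders(m, prob_sup = 1, prob_inf = 0, shift_slices = 4L)
  expect_equal(structure_length(out), structure_length(m) + 2.0)
  # extension copies the terminal cross-section
  expect_identical(out$occupancy[, , 13], m$occupancy[, , 12])
  # removal clamps rather than emptying the structure
  tiny <- slice_mask(5:6, nz = 20, dz = 0.5)
  set.seed(2)
  expect_warning(res <- perturb_borders(tiny, 1, 0, shift_slices = -10L),
                 "clamped")
  expect_true(any(res$occupancy))
})

test_that("border-change marginals match the configured probabilities", {
  m <- slice_mask(3:8, nz = 14, dz = 0.5, nx = 2, ny = 2,
                  spacing = c(0.5, 0.5, 0.5))
  n <- 4000
  set.seed(77)
  changed_sup <- logical(n)
  for (i in seq_len(n)) {
    out <- perturb_borders(m, prob_sup = 0.43, prob_inf = 0,
                           shift_slices = setdiff(-4:4, 0))
    sl <- which(apply(out$occupancy, 3, any))
    changed_sup[i] <- max(sl) != 8
  }
  sd_bin <- sqrt(0.43 * 0.57 / n)
  expect_lt(abs(mean(changed_sup) - 0.43), 3 * sd_bin)
})

test_that("toxicity simulation has the analytic event probabilities", {
  cf <- list(intercept_g1 = 0, intercept_g2 = -20, slopes = rep(0, 7))
  # intercept 0, zero slopes: event probability one half
  set.seed(3)
  n <- 4000
  ev <- vapply(seq_len(n), function(i) {
    r <- simulate_toxicity(rep(10, 7), cf, followup_completion_prob = 1,
                           baseline_g1plus_prob = 0)
    any(r$grade[r$visit_month > 0] >= 1, na.rm = TRUE)
  }, logical(1))
  expect_lt(abs(mean(ev) - 0.5), 3 * sqrt(0.25 / n))

  # degenerate logits
  cf_never <- list(intercept_g1 = -1e6, intercept_g2 = -1e6,
                   slopes = rep(0, 7))
  set.seed(4)
  r <- simulate_toxicity(rep(10, 7), cf_never, 1, 0)
  expect_true(all(r$grade[r$visit_month > 0] == 0))

  expect_error(simulate_toxicity(rep(NA_real_, 7), cf, 1, 0), "finite")
  cf_bad <- list(intercept_g1 = Inf, intercept_g2 = -1, slopes = rep(0, 7))
  expect_error(simulate_toxicity(rep(10, 7), cf_bad, 1, 0),
               "linear predictor")
})

test_that("empirical event rate matches inverse-logit(-1) at scale", {
  cf <- list(intercept_g1 = -1, intercept_g2 = -20, slopes = rep(0, 7))
  set.seed(5)
  n <- 50000
  ev <- vapply(seq_len(n), function(i) {
    r <- simulate_toxicity(rep(0, 7), cf, followup_completion_prob = 1,
                           baseline_g1plus_prob = 0)
    any(r$grade[r$visit_month > 0] >= 1, na.rm = TRUE)
  }, logical(1))
  p_true <- plogis(-1)  # 0.26894...
  expect_lt(abs(mean(ev) - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
})

test_that("covariate-level simulator gives monotone DVH-shaped covariates", {
  cov <- simulate_dvh_covariates(500, seed = 8)
  v <- as.matrix(cov[, -1])
  expect_true(all(v >= 0 & v <= 100))
  expect_true(all(apply(v, 1, function(x) all(diff(x) <= 1e-12))))
  # deterministic under a seed
  expect_identical(cov, simulate_dvh_covariates(500, seed = 8))
})
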