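# Programmatic fixtures shared across test files.

# mask with given z-slices occupied (single in-plane voxel column by default)
slice_mask <- function(slices, nz, dz = 1, nx = 1, ny = 1,
                       spacing = c(1, 1, dz), origin = c(0, 0, 0),
                       name = "m") {
  occ <- array(FALSE, c(nx, ny, nz))
  occ[, , slices] <- TRUE
  structure_mask(occ, spacing, origin, name = name)
}

mask_from_array <- function(occ, spacing = c(1, 1, 1)) {
  structure_mask(occ, spacing)
}

# cached synthetic cohorts so expensive generation happens once per run
.fixture_env <- new.env(parent = emptyenv())

shared_cohort <- function(n, seed) {
  key <- sprintf("cohort_%d_%d", n, seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_cohort(
      cohort_config(n_patients = n, seed = seed))
  }
  .fixture_env[[key]]
}

shared_pipeline_report <- function() {
  if (is.null(.fixture_env$report)) {
    .fixture_env$report <- run_pipeline(
      config = cohort_config(n_patients = 2000, seed = 20260922),
      B = 200, seed = 104729)
  }
  .fixture_env$report
}
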