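test_that("truncation keeps exactly the slices whose centres lie in the PTV z-window", {
  organ <- slice_mask(1:12, nz = 12, dz = 1)           # slice centres 0..11
  ptv <- slice_mask(5:9, nz = 12, dz = 1, name = "ptv") # z-extent [4, 8]

  t0 <- truncate_to_ptv(organ, ptv, margin_cm = 0)
  expect_equal(which(apply(t0$occupancy, 3, any)), 5:9)   # 5 slices
  expect_equal(structure_length(t0), 5)

  t2 <- truncate_to_ptv(organ, ptv, margin_cm = 2)
  expect_equal(which(apply(t2$occupancy, 3, any)), 3:11)  # 9 slices
  expect_equal(structure_length(t2), 9)

  # organ already inside the PTV window: identity
  inner <- slice_mask(6:8, nz = 12, dz = 1)
  expect_identical(truncate_to_ptv(inner, ptv, 0)$occupancy, inner$occupancy)

  # grid mismatch and negative margin are geometry errors
  other <- slice_mask(1:3, nz = 5, dz = 1)
  expect_error(truncate_to_ptv(organ, other, 0), "same grid")
  expect_error(truncate_to_ptv(organ, ptv, -1), "margin")
  # empty truncation is permitted but flagged
  far <- slice_mask(1:2, nz = 12, dz = 1)
  ptv_hi <- slice_mask(10:12, nz = 12, dz = 1)
  expect_warning(truncate_to_ptv(far, ptv_hi, 0), "empty")
})

test_that("length uses occupied-slice span times dz", {
  expect_equal(structure_length(slice_mask(4, nz = 10, dz = 0.5)), 0.5)
  expect_equal(structure_length(slice_mask(3:22, nz = 25, dz = 0.5)), 10)
  # gaps do not shorten the span
  expect_equal(structure_length(slice_mask(c(3, 22), nz = 25, dz = 0.5)), 10)
  expect_error(structure_length(slice_mask(integer(0), nz = 4)), "empty")
})

test_that("truncation never increases length and volumes nest monotonically", {
  cohort <- shared_cohort(25, seed = 5)
  for (p in cohort) {
    whole <- p$rectum_original
    t2 <- truncate_to_ptv(whole, p$ptv, 2)
    t0 <- truncate_to_ptv(whole, p$ptv, 0)
    expect_true(all(t0$occupancy <= t2$occupancy))   # voxelwise nesting
    expect_true(all(t2$occupancy <= whole$occupancy))
    expect_lte(structure_length(t0), structure_length(t2))
    expect_lte(structure_length(t2), structure_length(whole))
    expect_lte(structure_volume(t0), structure_volume(t2))
  }
})

test_that("volume is voxel count times voxel volume and additive over disjoint masks", {
  occ <- array(FALSE, c(10, 10, 10))
  occ[seq_len(1000)] <- TRUE
  expect_equal(structure_volume(structure_mask(occ, c(0.2, 0.2, 0.5))), 20)
  expect_equal(structure_volume(slice_mask(integer(0), nz = 3)), 0)

  a <- slice_mask(1:2, nz = 6, dz = 0.5)
  b <- slice_mask(5:6, nz = 6, dz = 0.5)
  u <- structure_mask(a$occupancy | b$occupancy, a$spacing)
  expect_equal(structure_volume(u),
               structure_volume(a) + structure_volume(b))
})

test_that("Dice matches direct voxel counting and is symmetric in [0, 1]", {
  a <- slice_mask(1:4, nz = 8)
  expect_equal(dice(a, a), 1)
  b <- slice_mask(5:8, nz = 8)
  expect_equal(dice(a, b), 0)
  # |a| = |b| = 4, overlap 2 -> 2*2 / 8 = 0.5
  c_ <- slice_mask(3:6, nz = 8)
  expect_equal(dice(a, c_), 0.5)
  expect_error(dice(slice_mask(integer(0), nz = 8),
                    slice_mask(integer(0), nz = 8)), "undefined")

  set.seed(42)
  for (i in 1:20) {
    x <- mask_from_array(array(runif(60) < 0.4, c(3, 4, 5)))
    y <- mask_from_array(array(runif(60) < 0.4, c(3, 4, 5)))
    if (sum(x$occupancy) + sum(y$occupancy) == 0) next
    d1 <- dice(x, y)
    expect_identical(d1, dice(y, x))
    expect_gte(d1, 0); expect_lte(d1, 1)
  }
})

test_that("truncating closer to the PTV increases original-reviewed Dice agreement", {
  cohort <- shared_cohort(200, seed = 31)
  d <- purrr::map_dfr(cohort, function(p) {
    tibble::tibble(
      whole = dice(p$rectum_original, p$rectum_reviewed),
      ptv2 = dice(truncate_to_ptv(p$rectum_original, p$ptv, 2),
                  truncate_to_ptv(p$rectum_reviewed, p$ptv, 2)),
      ptv0 = dice(truncate_to_ptv(p$rectum_original, p$ptv, 0),
                  truncate_to_ptv(p$rectum_reviewed, p$ptv, 0))
    )
  })
  expect_gte(median(d$ptv2), median(d$whole))
  expect_gte(median(d$ptv0), median(d$ptv2))
})

test_that("morphology table reports reviewed-minus-original differences per definition", {
  cohort <- shared_cohort(25, seed = 5)
  morph <- morphology_table(cohort)
  expect_equal(nrow(morph), 3 * length(cohort))
  expect_setequal(unique(morph$definition), c("whole", "ptv2", "ptv0"))
  expect_equal(morph$length_diff_cm,
               morph$length_reviewed_cm - morph$length_original_cm)
  expect_true(all(morph$dice >= 0 & morph$dice <= 1, na.rm = TRUE))
  sm <- summarise_morphology(morph)
  expect_equal(nrow(sm), 3)
  # truncation closer to the PTV shrinks the median absolute length change
  expect_lte(abs(sm$length_diff_med[sm$definition == "ptv0"]),
             abs(sm$length_diff_med[sm$definition == "whole"]))
})
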