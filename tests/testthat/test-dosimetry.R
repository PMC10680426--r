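test_that("cumulative DVH is a step function with conserved mass", {
  organ <- mask_from_array(array(TRUE, c(4, 4, 4)), spacing = c(0.5, 0.5, 0.5))
  uni <- dose_grid(array(50, c(4, 4, 4)), c(0.5, 0.5, 0.5))
  v <- compute_dvh(uni, organ)
  expect_equal(volume_at_dose(v, c(0, 30, 49.9)), c(100, 100, 100))
  expect_equal(volume_at_dose(v, 50.2), 0)
  expect_equal(v$cum_abs[1], v$total_volume_cc)
  expect_equal(v$total_volume_cc, structure_volume(organ))

  # two equal-volume regions at 20 and 80 Gy: half the organ >= 50 Gy
  d2 <- array(20, c(4, 4, 4)); d2[, , 3:4] <- 80
  v2 <- compute_dvh(dose_grid(d2, c(0.5, 0.5, 0.5)), organ)
  expect_equal(volume_at_dose(v2, 50), 50)
  expect_equal(volume_at_dose(v2, 50, mode = "absolute"),
               v2$total_volume_cc / 2)

  # step bracketing around a pure step at 50 Gy
  expect_equal(volume_at_dose(v, 49.999), 100, tolerance = 1e-3)
  expect_equal(volume_at_dose(v, 50.001 + 0.1), 0)

  expect_error(compute_dvh(uni, mask_from_array(array(FALSE, c(4, 4, 4)),
                                                spacing = c(0.5, 0.5, 0.5))),
               "empty")
})

test_that("DVH invariants: normalisation, monotone decrease, unit link", {
  cohort <- shared_cohort(25, seed = 5)
  for (p in cohort[1:10]) {
    v <- compute_dvh(p$dose, p$rectum_original)
    expect_equal(v$cum_rel[1], 100)
    expect_true(all(diff(v$cum_rel) <= 1e-12))
    expect_true(all(diff(v$cum_abs) <= 1e-12))
    expect_equal(v$cum_abs, v$cum_rel * v$total_volume_cc / 100)
  }
})

test_that("mean DVH averages patient volumes and ignores ordering", {
  organ <- mask_from_array(array(TRUE, c(2, 2, 2)))
  va <- compute_dvh(dose_grid(array(30, c(2, 2, 2)), c(1, 1, 1)), organ)
  vb <- compute_dvh(dose_grid(array(70, c(2, 2, 2)), c(1, 1, 1)), organ)
  expect_equal(mean_dvh(list(va), 50)$mean_volume, 0)
  m <- mean_dvh(list(va, vb), 50)
  expect_equal(m$mean_volume, 50)
  expect_equal(mean_dvh(list(vb, va), 50)$mean_volume, m$mean_volume)
  expect_error(mean_dvh(list(), 50), "at least one")
})

test_that("EQD2 has the printed reference values and 2 Gy/Fr fixed point", {
  expect_equal(eqd2(74, 37, 3), 74)
  expect_equal(eqd2(60, 20, 3), 72)     # 60 * (3 + 3) / 5
  expect_equal(eqd2(57, 19, 3), 68.4)   # 57 * (3 + 3) / 5
  expect_equal(eqd2(2 * 13, 13, 3), 26) # any 2 Gy/Fr schedule is fixed
  expect_error(eqd2(-1, 20, 3), "positive")
  expect_error(eqd2(60, 0, 3), "positive")
})

test_that("physical dose inversion matches a bisection oracle and round-trips", {
  for (n in c(19, 20, 37)) {
    for (E in c(30, 40, 50, 60, 65, 70, 74)) {
      expect_equal(physical_dose_for_eqd2(E, n, 3),
                   physical_dose_bisect_oracle(E, n, 3), tolerance = 1e-9)
    }
  }
  for (D in c(0.5, 2, 10, 57, 74, 120)) {
    for (n in c(19, 20, 37)) {
      expect_equal(physical_dose_for_eqd2(eqd2(D, n, 3), n, 3), D,
                   tolerance = 1e-9)
    }
  }
})

arm_fractions_for_test <- function(arm) {
  c("37Fr_74Gy" = 37, "20Fr_60Gy" = 20, "19Fr_57Gy" = 19)[[arm]]
}

test_that("arm dose-level mapping is the identity for 37 Fr and monotone for all arms", {
  lv37 <- dose_levels_for_arm("37Fr_74Gy")
  expect_equal(lv37$mapped_Gy, c(30, 40, 50, 60, 65, 70, 74))
  for (arm in arm_levels()) {
    lv <- dose_levels_for_arm(arm)
    expect_true(all(diff(lv$mapped_Gy) > 0))
    expect_equal(lv$mapped_Gy,
                 vapply(lv$reference_Gy, function(E) {
                   if (arm == "37Fr_74Gy") E else
                     physical_dose_for_eqd2(E, arm_fractions_for_test(arm))
                 }, numeric(1)))
  }
  # hypofractionated physical dose is below the reference only where the
  # mapped dose per fraction exceeds 2 Gy (crossover at EQD2 = 2n(2+ab)/... ,
  # i.e. 38 Gy for 19 Fr, 40 Gy for 20 Fr); the 30 Gy bin maps *upward*
  lv19 <- dose_levels_for_arm("19Fr_57Gy")
  expect_gt(lv19$mapped_Gy[lv19$reference_Gy == 30], 30)
  high <- lv19$reference_Gy >= 40
  expect_true(all(lv19$mapped_Gy[high] < lv19$reference_Gy[high]))
  lv20 <- dose_levels_for_arm("20Fr_60Gy")
  expect_true(all(lv20$mapped_Gy[lv20$reference_Gy > 40] <
                    lv20$reference_Gy[lv20$reference_Gy > 40]))
  expect_error(dose_levels_for_arm("26Fr"), "unknown arm")

  # six-level configuration drops the 65 Gy bin
  expect_equal(dose_levels_for_arm("37Fr_74Gy",
                                   reference_dose_levels("six"))$mapped_Gy,
               c(30, 40, 50, 60, 70, 74))
})

test_that("EQD2 round trip is tight over a dense grid", {
  for (n in c(19, 20, 37)) {
    E <- seq(1, 100, by = 0.5)
    back <- eqd2(physical_dose_for_eqd2(E, n, 3), n, 3)
    expect_lt(max(abs(back - E)), 1e-9)
  }
})
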