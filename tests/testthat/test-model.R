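test_that("threshold model closed forms match the calibrated constants", {
  ## only the intercept survives at x = 0, y = 0, z = 1
  expect_equal(vmsbr_log_threshold(0, 0, 1), -0.9504, tolerance = 1e-12)
  ## ln z term: z = e leaves the ln z and intercept terms
  expect_equal(vmsbr_log_threshold(0, 0, exp(1)), 0.7327 - 0.9504,
               tolerance = 1e-12)
  ## full-basis evaluation against an independently summed value
  expect_equal(vmsbr_log_threshold(21.1, 10.8, 30.0625642625),
               1.47550604519, tolerance = 1e-9)
  expect_equal(vmsbr_threshold(21.1, 10.8, 30.0625642625), 4.37324827432,
               tolerance = 1e-9)
  expect_error(vmsbr_log_threshold(1, 1, 0), "positive")
  expect_error(vmsbr_log_threshold(-1, 1, 2), "non-negative")
  expect_error(vmsbr_log_threshold(NA, 1, 2), "finite")
})

test_that("recovery coefficient matches its closed forms and limits", {
  expect_equal(recovery_coefficient(1, 0), 1.0830, tolerance = 1e-12)
  ## large-volume stationary limit: only the intercept survives
  expect_equal(recovery_coefficient(1e9, 0), 0.8839, tolerance = 1e-6)
  expect_equal(recovery_coefficient(21.1, 10.8), 1.0773250237,
               tolerance = 1e-9)
  expect_error(recovery_coefficient(0, 1), "> 0")
  expect_error(recovery_coefficient(-2, 1), "> 0")
})

test_that("recovery coefficient is monotone: decreasing in volume, increasing in motion", {
  xs <- seq(0.1, 50, length.out = 60)
  ys <- seq(0, 30, length.out = 40)
  for (y in c(0, 7.5, 15, 30)) {
    rc <- recovery_coefficient(xs, rep(y, length(xs)))
    expect_true(all(diff(rc) < 0))
  }
  for (x in c(0.1, 1, 10, 50)) {
    rc <- recovery_coefficient(rep(x, length(ys)), ys)
    expect_true(all(diff(rc) > 0))
  }
})

test_that("log threshold is finite over the working domain", {
  grid <- expand.grid(x = seq(0, 50, length.out = 11),
                      y = seq(0, 30, length.out = 11),
                      z = seq(1.01, 60, length.out = 11))
  lw <- vmsbr_log_threshold(grid$x, grid$y, grid$z)
  expect_true(all(is.finite(lw)))
})

test_that("the full lesion chain reproduces hand-computed values for cohort row 1", {
  l <- lung_cohort(as_list = TRUE)[[1]]
  res <- vmsbr_lesion_threshold(l)
  expect_equal(res$degraded_sbr, 27.9048231511, tolerance = 1e-9)
  expect_equal(res$rc, 1.0773250237, tolerance = 1e-9)
  expect_equal(res$recovered_sbr, 30.0625642625, tolerance = 1e-9)
  expect_equal(res$w, 4.37324827432, tolerance = 1e-8)
  expect_equal(res$threshold_ac, 15640.9224531, tolerance = 1e-6)
})

test_that("every cohort lesion yields a finite positive threshold", {
  res <- lapply(lung_cohort(as_list = TRUE), vmsbr_lesion_threshold)
  thr <- vapply(res, `[[`, 0, "threshold_ac")
  w <- vapply(res, `[[`, 0, "w")
  expect_true(all(is.finite(thr) & thr > 0))
  expect_true(all(is.finite(w) & w > 0))
})

test_that("SBR measurement on piecewise-constant scenes is exact", {
  ## uniform tumor cube c over uniform background b
  arr <- array(2000, c(20, 20, 20))
  arr[8:13, 8:13, 8:13] <- 30000
  pet <- image_volume(arr, c(2, 2, 2))
  lung <- binary_mask(array(TRUE, c(20, 20, 20)), geometry_from = pet)
  tumor_zone <- array(FALSE, c(20, 20, 20)); tumor_zone[5:16, 5:16, 5:16] <- TRUE
  lung$data <- !tumor_zone
  sr <- measure_sbr(pet, c(10, 10, 10), lung,
                    auto_exclude_high_uptake = FALSE)
  expect_equal(sr$tumor_ac_mean, 30000)
  expect_equal(sr$background_ac_mean, 2000)
  expect_equal(sr$degraded_sbr, 15)
  ## recovery fields populated when size and motion are supplied
  sr2 <- measure_sbr(pet, c(10, 10, 10), lung, volume_cm3 = 2, motion_mm = 4,
                     auto_exclude_high_uptake = FALSE)
  expect_equal(sr2$rc, recovery_coefficient(2, 4))
  expect_equal(sr2$recovered_sbr, 15 * recovery_coefficient(2, 4))
})

test_that("SBR measurement degrades with partial volume and recovers structure", {
  ## equal true SBR, small vs large sphere: measured SBR must be smaller
  ## for the small sphere (partial-volume averaging pulls the plateau down)
  small <- vmsbr_segment_phantom(
    lesion_phantom(sphere_volume_cm3(10), 0, 8, spacing_mm = c(2, 2, 2)),
    mesh_separation = FALSE)
  large <- vmsbr_segment_phantom(
    lesion_phantom(sphere_volume_cm3(37), 0, 8, spacing_mm = c(2, 2, 2)),
    mesh_separation = FALSE)
  expect_lt(small$sbr$degraded_sbr, large$sbr$degraded_sbr)
  expect_lt(large$sbr$degraded_sbr, 8 + 1e-9)
  ## adding motion degrades further at fixed size
  moving <- vmsbr_segment_phantom(
    lesion_phantom(sphere_volume_cm3(10), 15, 8, spacing_mm = c(2, 2, 2)),
    mesh_separation = FALSE)
  expect_lt(moving$sbr$degraded_sbr, small$sbr$degraded_sbr)
})

test_that("SBR measurement rejects degenerate scenes", {
  pet <- image_volume(array(1000, c(6, 6, 6)), c(2, 2, 2))
  empty_lung <- binary_mask(array(FALSE, c(6, 6, 6)), geometry_from = pet)
  expect_error(measure_sbr(pet, c(3, 3, 3), empty_lung), "empty")
  lung <- binary_mask(array(TRUE, c(6, 6, 6)), geometry_from = pet)
  excl <- binary_mask(array(TRUE, c(6, 6, 6)), geometry_from = pet)
  expect_error(measure_sbr(pet, c(3, 3, 3), lung, exclusions = excl),
               "background region empty")
})
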