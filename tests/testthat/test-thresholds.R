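test_that("ACmax statistics respect their search region", {
  arr <- array(1000, c(10, 10, 10))
  arr[5, 5, 5] <- 9000; arr[2, 2, 2] <- 4000
  pet <- image_volume(arr, c(2, 2, 2))
  expect_equal(ac_max(pet), 9000)
  reg <- binary_mask(array(FALSE, c(10, 10, 10)), geometry_from = pet)
  reg$data[1:3, 1:3, 1:3] <- TRUE
  expect_equal(ac_max(pet, reg), 4000)
  one <- binary_mask(array(FALSE, c(10, 10, 10)), geometry_from = pet)
  one$data[7, 7, 7] <- TRUE
  expect_equal(ac_max(pet, one), 1000)
  empty <- binary_mask(array(FALSE, c(10, 10, 10)), geometry_from = pet)
  expect_error(ac_max(pet, empty), "empty")
})

test_that("percent-of-maximum thresholds compute and flag correctly", {
  arr <- array(500, c(8, 8, 8)); arr[4, 4, 4] <- 1e5
  pet <- image_volume(arr, c(2, 2, 2))
  r <- percent_max_threshold(pet, fraction = 0.42)
  expect_equal(r$threshold_ac, 42000)
  expect_false(r$not_segmentable)
  ## cohort lesion 3: 15% of ACmax falls below the lung background
  arr3 <- array(100, c(8, 8, 8)); arr3[4, 4, 4] <- 11910.4
  pet3 <- image_volume(arr3, c(2, 2, 2))
  r3 <- percent_max_threshold(pet3, fraction = 0.15, background_ac = 3127.5)
  expect_equal(r3$threshold_ac, 0.15 * 11910.4)
  expect_true(r3$not_segmentable)
  expect_error(percent_max_threshold(pet, fraction = 1), "within")
  expect_error(percent_max_threshold(pet, fraction = 0), "within")
})

test_that("SUV thresholds convert through the calibration and flag low-contrast scans", {
  cal <- scan_calibration(370e6, 74000)
  r <- suv_threshold(cal, 2.5)
  expect_equal(r$threshold_ac, 12500)
  expect_equal(ac_to_suv(cal, r$threshold_ac), 2.5)
  ## background above the SUV-2.5 level: not segmentable
  r2 <- suv_threshold(cal, 2.5, background_ac = 13000)
  expect_true(r2$not_segmentable)
  expect_error(suv_threshold(cal, -1), "> 0")
})

test_that("the mean-plus-background threshold is exact on piecewise-constant scenes", {
  arr <- array(2500, c(16, 16, 16))
  arr[7:10, 7:10, 7:10] <- 20000
  pet <- image_volume(arr, c(2, 2, 2))
  roi <- binary_mask(array(FALSE, c(16, 16, 16)), geometry_from = pet)
  roi$data[1:3, 1:3, 1:3] <- TRUE
  r <- nestle_threshold(pet, background_roi = roi)
  expect_equal(r$ac_mean, 20000)         # plateau above 70% of ACmax
  expect_equal(r$background_ac, 2500)
  expect_equal(r$threshold_ac, 0.15 * 20000 + 2500)
  ## zero background: pure fraction of the plateau mean
  arr0 <- arr; arr0[arr0 == 2500] <- 0
  pet0 <- image_volume(arr0, c(2, 2, 2))
  r0 <- nestle_threshold(pet0, background_roi = roi)
  expect_equal(r0$threshold_ac, 0.15 * 20000)
  expect_error(nestle_threshold(pet, background_roi =
    binary_mask(array(FALSE, c(16, 16, 16)), geometry_from = pet)), "empty")
})

test_that("the mean-plus-background threshold tracks a simulated blurred sphere", {
  spec <- lesion_phantom(sphere_volume_cm3(22), 0, 8, background_ac = 2500,
                         spacing_mm = c(2, 2, 2), pad_mm = 35)
  sim <- simulate_pet(spec)
  lung <- phantom_background_mask(sim$envelope_truth, 13)
  roi <- background_cube_roi(sim$pet, lung, edge_mm = 20)
  r <- nestle_threshold(sim$pet, background_roi = roi)
  ## oracle: direct array arithmetic on the simulated volume
  vals <- as.numeric(sim$pet$data)
  plateau_mean <- mean(vals[vals > 0.7 * max(vals)])
  expect_equal(r$threshold_ac, 0.15 * plateau_mean + mean(sim$pet$data[roi$data]),
               tolerance = 1e-12)
  expect_equal(r$threshold_ac, 0.15 * plateau_mean + 2500, tolerance = 0.05)
})

test_that("the iterated SUVmean threshold reaches its fixed point on constant lesions", {
  cal <- scan_calibration(400e6, 80000)
  s <- 10  # SUV of a homogeneous lesion
  arr <- array(0, c(12, 12, 12))
  arr[5:8, 5:8, 5:8] <- suv_to_ac(cal, s)
  pet <- image_volume(arr, c(2, 2, 2))
  r <- black_iterative_threshold(pet, cal = cal)
  expect_equal(r$threshold_suv, 0.307 * s + 0.588)
  expect_equal(r$threshold_suv, 3.658)
  ## constant image: every iterate equals the fixed point
  expect_true(all(abs(r$history - 3.658) < 1e-12))
  expect_length(r$history, 5L)
  expect_error(black_iterative_threshold(pet, cal = cal, iterations = 0),
               ">= 1")
})

test_that("the iterated threshold converges on a graded simulated sphere", {
  cal <- scan_calibration(477e6, 75000)
  sim <- shared_lesion_sim()
  r <- black_iterative_threshold(sim$pet, cal = cal)
  steps <- abs(diff(c(0.70 * ac_max(sim$pet), suv_to_ac(cal, r$history))))
  expect_true(all(diff(steps) <= 1e-9))  # shrinking updates
  ## explicit 5-step loop oracle
  vals <- as.numeric(sim$pet$data)
  thr <- 0.70 * max(vals)
  for (k in 1:5) {
    suv_mean <- ac_to_suv(cal, mean(vals[vals >= thr]))
    thr <- suv_to_ac(cal, 0.307 * suv_mean + 0.588)
  }
  expect_equal(r$threshold_ac, thr, tolerance = 1e-12)
})

test_that("the VMSBR method threshold reproduces the hand-evaluated chain", {
  l <- lung_cohort(as_list = TRUE)[[1]]
  r <- vmsbr_method_threshold(l)
  expect_equal(r$recovered_sbr, 30.0625642625, tolerance = 1e-8)
  expect_equal(r$w, 4.37324827432, tolerance = 1e-8)
  expect_equal(r$threshold_ac, 15640.9224531, tolerance = 1e-5)
  expect_false(r$not_segmentable)
  ## all cohort rows give finite positive thresholds
  thr <- vapply(lung_cohort(as_list = TRUE),
                function(x) vmsbr_method_threshold(x)$threshold_ac, 0)
  expect_true(all(is.finite(thr) & thr > 0))
})

test_that("percent-max masks nest: 15% contains 35% contains 42%", {
  sim <- shared_lesion_sim()
  bg <- mean(sim$pet$data[sim$lung$data])
  masks <- lapply(c("p15", "p35", "p42"), function(m)
    segment_method(sim$pet, sim$seed, m, background_ac = bg))
  segmentable <- !vapply(masks, `[[`, TRUE, "not_segmentable")
  expect_true(all(segmentable[2:3]))
  got <- masks[segmentable]
  for (i in seq_len(length(got) - 1)) {
    expect_true(all(got[[i + 1]]$mask$data <= got[[i]]$mask$data))
  }
  vols <- vapply(got, `[[`, 0, "volume_cm3")
  expect_true(all(diff(vols) < 0))
})

test_that("methods flag not-segmentable rather than returning empty masks", {
  ## a low-contrast lesion: 15% of ACmax sits below background
  spec <- lesion_phantom(1, 10, 3, spacing_mm = c(2.5, 2.5, 2.5))
  sim <- simulate_pet(spec)
  lung <- phantom_background_mask(sim$envelope_truth, 13)
  bg <- mean(sim$pet$data[lung$data])
  seed <- round(world_to_index(sim$pet, c(0, 0, 0)))
  res <- segment_method(sim$pet, seed, "p15", background_ac = bg)
  expect_true(res$not_segmentable)
  expect_null(res$mask)
  expect_true(is.na(res$volume_cm3))
  expect_lte(res$threshold_ac, bg)
  ## SUV pathway: background above the SUV-2.5 activity level
  cal <- scan_calibration(300e6, 300000)  # low dose per mass -> low AC cutoff
  res2 <- segment_method(sim$pet, seed, "suv2.5", background_ac = bg,
                         cal = cal)
  expect_true(res2$not_segmentable)
  expect_output(print(res2), "not segmentable")
})
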