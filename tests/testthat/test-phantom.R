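test_that("the arcsine motion kernel is a proper dwell-time discretization", {
  expect_identical(motion_kernel(0, 2), 1)
  for (extent in c(3, 10, 20, 27.5)) {
    for (sp in c(1, 2, 3.27)) {
      k <- motion_kernel(extent, sp)
      expect_equal(sum(k), 1, tolerance = 1e-12)
      expect_equal(k, rev(k))
      expect_true(all(k >= 0))
    }
  }
  ## second moment of the arcsine density is A^2 / 2
  k <- motion_kernel(20, 1)
  offs <- seq_along(k) - (length(k) + 1) / 2
  expect_equal(sum(k * offs^2), 50, tolerance = 0.02 * 50)
  expect_error(motion_kernel(-1, 1), ">= 0")
})

test_that("phantom specs validate geometry and activities", {
  expect_error(phantom_spec(list(center = c(0, 0, 0), diameter = -5),
                            source_ac = 2, background_ac = 1), "> 0 mm")
  expect_error(phantom_spec(list(center = c(0, 0, 0), diameter = 20),
                            source_ac = 1, background_ac = 2), "source_ac")
  expect_error(phantom_spec(list(center = c(0, 0, 0), diameter = 20),
                            source_ac = 2, background_ac = 1,
                            shape = c(8, 8, 8), spacing_mm = c(2, 2, 2)),
               "geometry error")
  sp <- lesion_phantom(8, 10, 15)
  expect_equal(true_sbr(sp), 15)
  expect_equal(sphere_volume_cm3(sp$spheres[[1]]$diameter), 8,
               tolerance = 1e-12)
})

test_that("a motionless noiseless phantom reduces to the static sphere", {
  spec <- phantom_spec(list(center = c(0, 0, 0), diameter = 24),
                       motion_extent_mm = 0, source_ac = 8000,
                       background_ac = 1000, psf_fwhm_mm = 0,
                       spacing_mm = c(2, 2, 2), pad_mm = 10)
  sim <- simulate_pet(spec)
  expect_identical(sim$envelope_truth$data, sim$static_truth$data)
  ## identity limit: no PSF, no motion -> source inside, background outside,
  ## partial-volume values only on the one-voxel boundary shell
  interior <- sim$static_truth$data & !dilate_mask(
    binary_mask(!sim$static_truth$data, geometry_from = sim$pet), 2.1)$data
  expect_true(all(abs(sim$pet$data[interior] - 8000) < 1e-9))
  exterior <- !dilate_mask(sim$static_truth, 2.1)$data
  expect_true(all(abs(sim$pet$data[exterior] - 1000) < 1e-9))
  boundary_vals <- sim$pet$data[!interior & !exterior]
  expect_true(all(boundary_vals >= 1000 - 1e-9 & boundary_vals <= 8000 + 1e-9))
})

test_that("blur and motion conserve total activity with adequate padding", {
  for (extent in c(0, 12)) {
    spec <- lesion_phantom(8, extent, 12, spacing_mm = c(2, 2, 2))
    sim <- simulate_pet(spec)
    vgrid <- prod(dim(sim$pet$data)) * voxel_volume_ml(sim$pet)
    expected <- spec$source_ac * 8 + spec$background_ac * (vgrid - 8)
    total <- sum(sim$pet$data) * voxel_volume_ml(sim$pet)
    expect_equal(total, expected, tolerance = 1e-3)
  }
})

test_that("the motion envelope contains the static sphere and grows with motion", {
  sim0 <- shared_lesion_sim()
  expect_true(all(sim0$static_truth$data <= sim0$envelope_truth$data))
  expect_gt(mask_volume_cm3(sim0$envelope_truth),
            mask_volume_cm3(sim0$static_truth))
  ## sub-voxel motion: the envelope can differ from the static mask only in
  ## the boundary shell, by at most a small fraction of the sphere
  tiny <- simulate_pet(lesion_phantom(8, 0.5, 15, spacing_mm = c(2, 2, 2)))
  expect_true(all(tiny$static_truth$data <= tiny$envelope_truth$data))
  extra <- sum(tiny$envelope_truth$data) - sum(tiny$static_truth$data)
  expect_lt(extra / sum(tiny$static_truth$data), 0.1)
  shell <- dilate_mask(tiny$static_truth, 2.1)$data & !tiny$static_truth$data
  expect_true(all(tiny$envelope_truth$data <= (tiny$static_truth$data | shell)))
})

test_that("noisy simulations are bit-reproducible under a fixed seed", {
  spec <- lesion_phantom(4, 6, 10, spacing_mm = c(3, 3, 3),
                         noise_sd = 200, seed = 123)
  a <- simulate_pet(spec)
  b <- simulate_pet(spec)
  expect_identical(a$pet$data, b$pet$data)
  expect_error(simulate_pet(lesion_phantom(4, 6, 10, spacing_mm = c(3, 3, 3),
                                           noise_sd = 200)), "seed")
})

test_that("the calibration grid enumerates the full factorial design", {
  specs <- calibration_grid()
  expect_length(specs, 252L)
  combos <- unique(t(vapply(specs, function(s)
    c(attr(s, "diameter_mm"), attr(s, "motion_mm"), attr(s, "sbr")),
    numeric(3))))
  expect_equal(nrow(combos), 252L)
  expect_length(calibration_grid(10, 0, 2), 1L)
  expect_error(calibration_grid(numeric(0), 0, 2), "non-empty")
  expect_error(calibration_grid(45, 0, 2), "10-37")
  expect_error(calibration_grid(20, 40, 2), "0-30")
  expect_error(calibration_grid(20, 0, 60), "50")
})

test_that("the CT-like MIP supports -425 HU envelope recovery", {
  spec <- lesion_phantom(6, 10, 8, spacing_mm = c(2, 2, 2))
  ## no blur: exactly the two configured HU values
  sharp <- simulate_ct_mip(spec, ct_blur_fwhm_mm = 0,
                           spacing_mm = c(2, 2, 2))
  expect_setequal(unique(as.numeric(sharp$mip$data)), c(-800, 0))
  ## default blur: region growing at -425 HU recovers the envelope within a
  ## one-voxel boundary band
  ct <- simulate_ct_mip(spec, spacing_mm = c(2, 2, 2))
  seed <- round(world_to_index(ct$mip, c(0, 0, 0)))
  grown <- region_grow(ct$mip, seed, -425, "above")
  env <- ct$envelope_truth
  band <- dilate_mask(env, 2.1)$data &
    !(env$data & !dilate_mask(binary_mask(!env$data, geometry_from = ct$mip),
                              2.1)$data)
  mismatch <- xor(grown$data, env$data)
  expect_true(all(!mismatch | band))
})
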