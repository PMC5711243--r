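#' Dilate a mask by a world-mm margin
#'
#' Separable box dilation (1D running maximum along each axis with
#' half-width `margin_mm`), used to carve a lesion's blur halo out of the
#' background compartment before measuring background AC.
#'
#' @param mask a [binary_mask()].
#' @param margin_mm dilation half-width, mm.
#' @return the dilated [binary_mask()].
#' @export
dilate_mask <- function(mask, margin_mm) {
  stopifnot(inherits(mask, "binary_mask"))
  if (margin_mm <= 0) return(mask)
  m <- mask$data
  for (a in 1:3) {
    half <- as.integer(ceiling(margin_mm / mask$spacing[a]))
    if (half == 0L) next
    kernel_len <- 2L * half + 1L
    num <- array(as.numeric(m), dim(m))
    ## running max via repeated pairwise shifts would be O(half); a simple
    ## convolution + threshold is equivalent for 0/1 data
    k <- rep(1, kernel_len)
    num <- convolve_axis(num, k, a)
    m <- num > 0.5
  }
  binary_mask(array(m, dim(mask$data)), mask$spacing, mask$origin)
}

#' Background mask for a single-lesion phantom scene
#'
#' The analogue of the segmented ipsilateral lung: every voxel outside the
#' lesion's motion envelope dilated by `margin_mm` (default twice the PSF
#' FWHM, excluding the spill-in halo).
#'
#' @param envelope_truth the lesion's envelope [binary_mask()].
#' @param margin_mm halo margin, mm.
#' @return a [binary_mask()] of the background compartment.
#' @export
phantom_background_mask <- function(envelope_truth, margin_mm) {
  dil <- dilate_mask(envelope_truth, margin_mm)
  binary_mask(!dil$data, envelope_truth$spacing, envelope_truth$origin)
}

#' VMSBR segmentation of a simulated phantom lesion
#'
#' Runs the full image-based chain on one [phantom_spec()]: simulate the
#' PET volume, measure the degraded SBR (tumor plateau mean over lung
#' background mean), recover it with the RC model using the known sphere
#' volume and motion (the synthetic stand-ins for the 4D CT measurements),
#' evaluate the VMSBR threshold, region-grow at `w * background`, and
#' compare the resulting ITV surface with the true motion envelope.
#'
#' @param spec a single-sphere [phantom_spec()].
#' @param coeffs,rc_coeffs model coefficient sets.
#' @param bg_margin_mm margin carved around the envelope for background
#'   measurement; default `2 * psf_fwhm_mm`.
#' @param mesh_separation also mesh result and truth and compute the
#'   one-sided mean surface separation (truth as reference).
#' @param connectivity passed to [region_grow()].
#' @return list with `spec`, `pet`, `envelope_truth`, `sbr`
#'   (an `sbr_measurement`), `threshold_ac`, `w`, `result`
#'   (a [segmentation_result()]), and `surface_separation_mm` (or `NA`).
#' @export
vmsbr_segment_phantom <- function(spec, coeffs = vmsbr_coefficients(),
                                  rc_coeffs = rc_coefficients(),
                                  bg_margin_mm = NULL,
                                  mesh_separation = TRUE,
                                  connectivity = 6) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(spec$spheres) != 1L)
    stop("the single-lesion pipeline expects one sphere", call. = FALSE)
  sim <- simulate_pet(spec)
  if (is.null(bg_margin_mm)) bg_margin_mm <- 2 * spec$psf_fwhm_mm
  lung <- phantom_background_mask(sim$envelope_truth, bg_margin_mm)

  x <- sphere_volume_cm3(spec$spheres[[1]]$diameter)
  y <- spec$motion_extent_mm
  seed <- round(world_to_index(sim$pet, spec$spheres[[1]]$center))
  sbr <- measure_sbr(sim$pet, seed, lung,
                     volume_cm3 = x, motion_mm = y, rc_coeffs = rc_coeffs)
  lw <- vmsbr_log_threshold(x, y, sbr$recovered_sbr, coeffs)
  w <- exp(lw)
  threshold_ac <- w * sbr$background_ac_mean

  result <- if (threshold_ac <= sbr$background_ac_mean ||
                sim$pet$data[seed[1], seed[2], seed[3]] < threshold_ac) {
    segmentation_result("vmsbr", threshold_ac, NULL)
  } else {
    mask <- region_grow(sim$pet, seed, threshold_ac, "above",
                        connectivity = connectivity)
    segmentation_result("vmsbr", threshold_ac, mask)
  }

  sep <- NA_real_
  if (mesh_separation && !result$not_segmentable) {
    ref <- mask_to_mesh(sim$envelope_truth)
    got <- mask_to_mesh(result$mask)
    sep <- surface_separation(ref, got)
  }
  list(spec = spec, pet = sim$pet, envelope_truth = sim$envelope_truth,
       sbr = sbr, threshold_ac = threshold_ac, w = w, result = result,
       surface_separation_mm = sep)
}

#' Volume of a sphere of given diameter, in cm^3
#' @param diameter_mm sphere diameter, mm.
#' @return volume, cm^3.
#' @export
sphere_volume_cm3 <- function(diameter_mm) {
  (4 / 3) * pi * (diameter_mm / 2)^3 / 1000
}

#' Default synthetic validation lesions
#'
#' Six noiseless single-sphere lesions spanning the evaluation cohort's
#' ranges: volumes 1-28 cm^3, peak-to-peak motion 0-15 mm, true SBR 5-30.
#'
#' @return data.frame with columns `volume_cm3`, `motion_mm`, `sbr`.
#' @export
validation_lesions <- function() {
  data.frame(
    volume_cm3 = c(1, 2.5, 4, 8, 15, 28),
    motion_mm = c(5, 10, 0, 8, 12, 15),
    sbr = c(5, 8, 10, 15, 20, 30)
  )
}

#' End-to-end VMSBR validation on synthetic lesions
#'
#' For each lesion, builds a noiseless phantom, runs
#' [vmsbr_segment_phantom()], and reports the one-sided mean surface
#' separation between the VMSBR-thresholded ITV and the true motion
#' envelope.
#'
#' @param lesions data.frame with `volume_cm3`, `motion_mm`, `sbr`
#'   (default [validation_lesions()]).
#' @param spacing_mm simulation voxel spacing (default 2 mm isotropic, a
#'   deliberate desk-scale choice balancing surface fidelity and runtime).
#' @param psf_fwhm_mm PSF FWHM, mm.
#' @param background_ac background activity, Bq/mL.
#' @param ... passed to [vmsbr_segment_phantom()].
#' @return data.frame with the lesion parameters, measured/recovered SBR,
#'   threshold, segmented volume, truth volume and
#'   `surface_separation_mm`; mean separation as attribute
#'   `mean_separation_mm`.
#' @export
vmsbr_validation <- function(lesions = validation_lesions(),
                             spacing_mm = c(2, 2, 2), psf_fwhm_mm = 6.5,
                             background_ac = 3000, ...) {
  rows <- lapply(seq_len(nrow(lesions)), function(i) {
    spec <- lesion_phantom(lesions$volume_cm3[i], lesions$motion_mm[i],
                           lesions$sbr[i], background_ac = background_ac,
                           spacing_mm = spacing_mm, psf_fwhm_mm = psf_fwhm_mm)
    run <- vmsbr_segment_phantom(spec, ...)
    data.frame(
      volume_cm3 = lesions$volume_cm3[i], motion_mm = lesions$motion_mm[i],
      sbr_true = lesions$sbr[i],
      sbr_degraded = run$sbr$degraded_sbr,
      sbr_recovered = run$sbr$recovered_sbr,
      w = run$w, threshold_ac = run$threshold_ac,
      itv_volume_cm3 = run$result$volume_cm3,
      envelope_volume_cm3 = mask_volume_cm3(run$envelope_truth),
      surface_separation_mm = run$surface_separation_mm
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_separation_mm") <- mean(out$surface_separation_mm)
  out
}

#' Calibration records from simulated phantoms
#'
#' Re-enacts the model-development measurement on each phantom spec:
#' simulate, scan thresholds in 1% steps against the true motion envelope
#' to find the optimal fraction of ACmax, measure the degraded SBR, and
#' record the tuple the model fits consume.  The background-normalized
#' optimal threshold is `w_opt = fraction_opt * ACmax / background AC`,
#' the explicit bridge between the two threshold normalizations.
#' Records whose optimal fraction hits the scan boundary are flagged
#' (`boundary = TRUE`) and are dropped by default before fitting.
#'
#' @param specs list of [phantom_spec()]s, e.g. from [calibration_grid()].
#' @param fractions scan grid (default 1%-99% in 1% steps).
#' @param drop_boundary drop records whose optimum hit the scan edge.
#' @param verbose print progress.
#' @return data.frame with columns `x`, `y`, `z_true`, `z_measured`,
#'   `rc_ratio` (= z_true / z_measured), `fraction_opt`, `w_opt`,
#'   `separation_mm`, `boundary`.
#' @export
calibration_records <- function(specs, fractions = seq(0.01, 0.99, by = 0.01),
                                drop_boundary = TRUE, verbose = FALSE) {
  rows <- lapply(seq_along(specs), function(i) {
    spec <- specs[[i]]
    sim <- simulate_pet(spec)
    lung <- phantom_background_mask(sim$envelope_truth, 2 * spec$psf_fwhm_mm)
    seed <- round(world_to_index(sim$pet, spec$spheres[[1]]$center))
    x <- sphere_volume_cm3(spec$spheres[[1]]$diameter)
    y <- spec$motion_extent_mm
    sbr <- measure_sbr(sim$pet, seed, lung, volume_cm3 = x, motion_mm = y)
    scan <- optimal_threshold_scan(sim$pet, seed, sim$envelope_truth,
                                   fractions = fractions)
    scanned <- fractions[!is.na(scan$separations)]
    boundary <- scan$optimal_fraction %in% range(scanned)
    if (verbose)
      message(sprintf("[%d/%d] d=%.0fmm y=%.0fmm z=%.0f -> opt %.0f%%",
                      i, length(specs), spec$spheres[[1]]$diameter, y,
                      true_sbr(spec), 100 * scan$optimal_fraction))
    data.frame(
      x = x, y = y, z_true = true_sbr(spec), z_measured = sbr$degraded_sbr,
      rc_ratio = true_sbr(spec) / sbr$degraded_sbr,
      fraction_opt = scan$optimal_fraction,
      w_opt = scan$optimal_fraction * scan$ac_max / sbr$background_ac_mean,
      separation_mm = scan$optimal_separation,
      boundary = boundary
    )
  })
  out <- do.call(rbind, rows)
  if (drop_boundary) out <- out[!out$boundary, , drop = FALSE]
  out
}

#' Synthetic-cohort evaluation of all seven delineation methods
#'
#' For each lesion, simulates a noiseless PET scan and a CT-like MIP,
#' forms the reference ITV by region growing at -425 HU on the MIP,
#' segments the PET with all seven methods, and tabulates per-method
#' volumes.  Scan calibration is fixed so that the background corresponds
#' to a typical lung SUV, and the mean-plus-background ROI is a 2 cm cube
#' placed in the background compartment.
#'
#' @param lesions data.frame with `volume_cm3`, `motion_mm`, `sbr`.
#' @param spacing_mm PET simulation spacing.
#' @param psf_fwhm_mm PSF FWHM, mm.
#' @param background_ac background activity, Bq/mL.
#' @param cal a [scan_calibration()]; the default (477 MBq, 75 kg) gives
#'   the background an SUV of about 0.47.
#' @param ct_spacing_mm CT-like grid spacing for the MIP.
#' @param coeffs,rc_coeffs VMSBR coefficient sets used by the `"vmsbr"`
#'   method; supply refit values (see [vmsbr_fit()]) to evaluate a model
#'   calibrated on the same imaging chain.
#' @return list with `volumes` (data.frame: lesion parameters, `ct` and one
#'   column per method, `NA` = not segmentable) and `comparisons` (list of
#'   [paired_volume_comparison()] per method).
#' @export
run_synthetic_cohort <- function(lesions,
                                 spacing_mm = c(2.5, 2.5, 2.5),
                                 psf_fwhm_mm = 6.5,
                                 background_ac = 3000,
                                 cal = scan_calibration(477e6, 75000),
                                 ct_spacing_mm = c(2, 2, 2),
                                 coeffs = vmsbr_coefficients(),
                                 rc_coeffs = rc_coefficients()) {
  methods <- c("p15", "p35", "p42", "suv2.5", "nestle", "black", "vmsbr")
  rows <- lapply(seq_len(nrow(lesions)), function(i) {
    spec <- lesion_phantom(lesions$volume_cm3[i], lesions$motion_mm[i],
                           lesions$sbr[i], background_ac = background_ac,
                           spacing_mm = spacing_mm, psf_fwhm_mm = psf_fwhm_mm,
                           pad_mm = 3 * psf_fwhm_mm + 25)
    sim <- simulate_pet(spec)
    lung <- phantom_background_mask(sim$envelope_truth, 2 * psf_fwhm_mm)
    seed <- round(world_to_index(sim$pet, spec$spheres[[1]]$center))

    ## reference ITV from the CT-like MIP at -425 HU
    ct <- simulate_ct_mip(spec, spacing_mm = ct_spacing_mm)
    ct_seed <- round(world_to_index(ct$mip, spec$spheres[[1]]$center))
    itv_ct <- region_grow(ct$mip, ct_seed, -425, "above")

    ## measured lesion scalars feeding the adaptive methods
    sbr <- measure_sbr(sim$pet, seed, lung,
                       volume_cm3 = lesions$volume_cm3[i],
                       motion_mm = lesions$motion_mm[i])
    lesion <- lesion_measurements(i, NA, lesions$volume_cm3[i],
                                  lesions$motion_mm[i],
                                  sbr$tumor_ac_mean, sbr$background_ac_mean)
    bg_roi <- background_cube_roi(sim$pet, lung, edge_mm = 20)

    vols <- vapply(methods, function(m) {
      res <- tryCatch(
        segment_method(sim$pet, seed, m,
                       background_ac = sbr$background_ac_mean,
                       cal = cal, background_roi = bg_roi, lesion = lesion,
                       coeffs = coeffs, rc_coeffs = rc_coeffs),
        error = function(e) NULL)
      if (is.null(res) || res$not_segmentable) NA_real_ else res$volume_cm3
    }, 0)
    c(lesion = i, volume_cm3 = lesions$volume_cm3[i],
      motion_mm = lesions$motion_mm[i], sbr = lesions$sbr[i],
      ct = mask_volume_cm3(itv_ct), vols)
  })
  volumes <- as.data.frame(do.call(rbind, rows))
  comparisons <- lapply(methods, function(m)
    tryCatch(paired_volume_comparison(volumes[[m]], volumes$ct),
             error = function(e) NULL))
  names(comparisons) <- methods
  list(volumes = volumes, comparisons = comparisons)
}

#' Cubic background ROI inside a background mask
#'
#' Places an axis-aligned cube of the given edge length at the background
#' voxel farthest-corner-most in index order that fits entirely inside the
#' background compartment; deterministic, for synthetic scenes.
#'
#' @param pet the [image_volume()] (for geometry).
#' @param background_mask [binary_mask()] of allowed voxels.
#' @param edge_mm cube edge length, mm (default 20, a 2 cm cube).
#' @return a [binary_mask()] of the ROI.
#' @export
background_cube_roi <- function(pet, background_mask, edge_mm = 20) {
  half <- pmax(1L, as.integer(round(edge_mm / pet$spacing / 2)))
  d <- dim(pet$data)
  ## search from the grid corner inward for a cube fully inside background
  for (i in seq(1L + half[1], d[1] - half[1])) {
    for (j in seq(1L + half[2], d[2] - half[2])) {
      for (k in seq(1L + half[3], d[3] - half[3])) {
        rng1 <- (i - half[1]):(i + half[1])
        rng2 <- (j - half[2]):(j + half[2])
        rng3 <- (k - half[3]):(k + half[3])
        if (all(background_mask$data[rng1, rng2, rng3])) {
          m <- array(FALSE, d)
          m[rng1, rng2, rng3] <- TRUE
          return(binary_mask(m, pet$spacing, pet$origin))
        }
      }
    }
  }
  stop("no cube of the requested size fits inside the background mask",
       call. = FALSE)
}
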