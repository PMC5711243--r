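#' Coefficients of the VMSBR threshold model
#'
#' The VMSBR model predicts the log of the optimal segmentation threshold
#' `w` (normalized to background activity) as a linear combination of the
#' basis \{x^(1/3), y^(1/3), ln z, x^(1/3) ln z, y^(1/3) ln z, (xy)^(1/3),
#' 1\}, where `x` is tumor volume (cm^3), `y` motion extent (mm) and `z`
#' the (recovered) source-to-background ratio.  The default coefficients are
#' the published phantom-calibrated values; [vmsbr_fit()] produces refitted
#' ones.
#'
#' @param values the seven coefficients, in basis order (constant last).
#' @return numeric vector of class `vmsbr_coefficients`, named by basis term.
#' @export
vmsbr_coefficients <- function(values = c(0.0634, 0.1202, 0.7327, 0.0597,
                                          -0.1221, -0.0248, -0.9504)) {
  values <- as.numeric(values)
  if (length(values) != 7L || any(!is.finite(values)))
    stop("the VMSBR model has exactly 7 finite coefficients", call. = FALSE)
  names(values) <- vmsbr_basis_names()
  structure(values, class = "vmsbr_coefficients")
}

vmsbr_basis_names <- function() {
  c("x^(1/3)", "y^(1/3)", "ln(z)", "x^(1/3):ln(z)", "y^(1/3):ln(z)",
    "(xy)^(1/3)", "(intercept)")
}

#' Design row(s) of the VMSBR basis
#' @keywords internal
vmsbr_basis <- function(x, y, z) {
  cbind(x^(1/3), y^(1/3), log(z), x^(1/3) * log(z), y^(1/3) * log(z),
        (x * y)^(1/3), 1)
}

#' Coefficients of the SBR recovery-coefficient model
#'
#' The recovery coefficient RC multiplies an image-measured (degraded) SBR
#' to correct for partial-volume and motion blur:
#' `RC = r0/x + r1*y + r2*y/x + r3`.  Defaults are the published
#' phantom-derived values; [rc_fit()] produces refitted ones.
#'
#' @param values the four coefficients, in basis \{1/x, y, y/x, 1\} order.
#' @return numeric vector of class `rc_coefficients`.
#' @export
rc_coefficients <- function(values = c(0.1991, 0.0136, 0.0725, 0.8839)) {
  values <- as.numeric(values)
  if (length(values) != 4L || any(!is.finite(values)))
    stop("the RC model has exactly 4 finite coefficients", call. = FALSE)
  names(values) <- rc_basis_names()
  structure(values, class = "rc_coefficients")
}

rc_basis_names <- function() c("1/x", "y", "y/x", "(intercept)")

rc_basis <- function(x, y) cbind(1 / x, y, y / x, 1)

#' Log optimal threshold of the VMSBR model
#'
#' Evaluates `ln(w)` where `w` is the optimal activity-concentration
#' threshold normalized to background.  Vectorized over `x`, `y`, `z`.
#'
#' @param x tumor volume, cm^3 (>= 0).
#' @param y motion extent, mm (>= 0).
#' @param z source-to-background ratio (> 0), normally the recovered SBR.
#' @param coeffs a [vmsbr_coefficients()]; defaults to the calibrated values.
#' @return `ln(w)`, dimensionless.
#' @export
vmsbr_log_threshold <- function(x, y, z, coeffs = vmsbr_coefficients()) {
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(z)))
    stop("x, y, z must be finite", call. = FALSE)
  if (any(x < 0) || any(y < 0))
    stop("volume and motion must be non-negative", call. = FALSE)
  if (any(z <= 0))
    stop("SBR must be strictly positive (ln z is taken)", call. = FALSE)
  drop(vmsbr_basis(x, y, z) %*% as.numeric(coeffs))
}

#' Optimal threshold normalized to background
#' @inheritParams vmsbr_log_threshold
#' @return `w = exp(ln w)`, the threshold as a multiple of background AC.
#' @export
vmsbr_threshold <- function(x, y, z, coeffs = vmsbr_coefficients()) {
  exp(vmsbr_log_threshold(x, y, z, coeffs))
}

#' SBR recovery coefficient
#'
#' Corrects a degraded (image-measured) SBR for partial-volume and motion
#' degradation: `recovered = degraded * RC(x, y)`.  RC decreases with tumor
#' volume and increases with motion extent: small, fast-moving lesions need
#' the most correction.
#'
#' @param x tumor volume, cm^3 (> 0).
#' @param y motion extent, mm (>= 0).
#' @param rc_coeffs an [rc_coefficients()]; defaults to the calibrated values.
#' @return RC, dimensionless (> 0 over the physiological range).
#' @export
recovery_coefficient <- function(x, y, rc_coeffs = rc_coefficients()) {
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  if (any(x <= 0))
    stop("tumor volume must be > 0 (1/x is taken)", call. = FALSE)
  if (any(y < 0))
    stop("motion extent must be >= 0", call. = FALSE)
  drop(rc_basis(x, y) %*% as.numeric(rc_coeffs))
}

#' Source-to-background ratio measured on a PET image
#'
#' Reproduces the clinical measurement procedure.  Tumor mean AC uses a
#' two-step rule inside `search_region`: first the mean of voxels above 70%
#' of ACmax (a plateau estimate), then the mean of voxels at or above 80%
#' of that plateau mean.  Background mean AC is taken over `lung_mask`
#' after removing `exclusions` and, optionally, automatic removal of
#' high-uptake voxels (above median + `mad_k` * MAD), emulating the removal
#' of tumors and inflammation from the ipsilateral-lung background.
#'
#' If `volume_cm3` and `motion_mm` are supplied, the recovery coefficient
#' and recovered SBR are populated.
#'
#' @param pet an [image_volume()], Bq/mL.
#' @param seed voxel index (length 3) inside the lesion.
#' @param lung_mask [binary_mask()] of the background compartment.
#' @param exclusions optional [binary_mask()] removed from the background
#'   (e.g. the lesion and its blur halo).
#' @param search_region optional [binary_mask()] restricting tumor
#'   statistics; defaults to a box of `search_factor` times the lesion
#'   extent is not available here, so the default is the whole grid minus
#'   nothing — pass a region for multi-lesion scenes.
#' @param volume_cm3,motion_mm lesion size/motion for SBR recovery.
#' @param auto_exclude_high_uptake remove background voxels above
#'   median + `mad_k` * MAD before averaging (default `TRUE`).
#' @param mad_k robustness multiplier for the automatic exclusion.
#' @param rc_coeffs [rc_coefficients()] used for recovery.
#' @return object of class `sbr_measurement`: a list with
#'   `tumor_ac_mean`, `background_ac_mean`, `degraded_sbr`, and (when
#'   size/motion are given) `rc` and `recovered_sbr`.
#' @export
measure_sbr <- function(pet, seed, lung_mask, exclusions = NULL,
                        search_region = NULL,
                        volume_cm3 = NULL, motion_mm = NULL,
                        auto_exclude_high_uptake = TRUE, mad_k = 3,
                        rc_coeffs = rc_coefficients()) {
  stopifnot(inherits(pet, "image_volume"))
  seed <- check_seed(pet, seed)
  if (sum(lung_mask$data) == 0L)
    stop("lung mask is empty", call. = FALSE)
  check_same_geometry(pet, lung_mask)

  ## tumor plateau mean
  region <- if (is.null(search_region)) NULL else {
    check_same_geometry(pet, search_region); search_region$data
  }
  vals <- if (is.null(region)) as.numeric(pet$data) else pet$data[region]
  if (length(vals) == 0L)
    stop("tumor search region is empty", call. = FALSE)
  acmax <- max(vals)
  plateau <- vals[vals > 0.70 * acmax]
  if (length(plateau) == 0L)
    stop("degenerate lesion: no voxels above 70% of ACmax", call. = FALSE)
  acmean0 <- mean(plateau)
  roi <- vals[vals >= 0.80 * acmean0]
  if (length(roi) == 0L)
    stop("degenerate lesion: tumor ROI at 80% of ACmean is empty", call. = FALSE)
  tumor_ac_mean <- mean(roi)

  ## background mean over lung minus exclusions
  bg_sel <- lung_mask$data
  if (!is.null(exclusions)) {
    check_same_geometry(pet, exclusions)
    bg_sel <- bg_sel & !exclusions$data
  }
  bg_vals <- pet$data[bg_sel]
  if (length(bg_vals) == 0L)
    stop("background region empty after exclusions", call. = FALSE)
  if (auto_exclude_high_uptake && length(bg_vals) > 3L) {
    med <- stats::median(bg_vals)
    md <- stats::mad(bg_vals)
    if (md > 0) bg_vals <- bg_vals[bg_vals <= med + mad_k * md]
  }
  background_ac_mean <- mean(bg_vals)

  out <- list(
    tumor_ac_mean = tumor_ac_mean,
    background_ac_mean = background_ac_mean,
    degraded_sbr = tumor_ac_mean / background_ac_mean,
    rc = NULL, recovered_sbr = NULL
  )
  if (!is.null(volume_cm3) && !is.null(motion_mm)) {
    out$rc <- recovery_coefficient(volume_cm3, motion_mm, rc_coeffs)
    out$recovered_sbr <- out$degraded_sbr * out$rc
  }
  structure(out, class = "sbr_measurement")
}

#' @export
print.sbr_measurement <- function(x, ...) {
  cat(sprintf("SBR measurement: tumor ACmean %.6g, background ACmean %.6g Bq/mL\n",
              x$tumor_ac_mean, x$background_ac_mean))
  cat(sprintf("  degraded SBR %.4g", x$degraded_sbr))
  if (!is.null(x$recovered_sbr))
    cat(sprintf(", RC %.4g, recovered SBR %.4g", x$rc, x$recovered_sbr))
  cat("\n")
  invisible(x)
}

#' Recovered SBR and absolute VMSBR threshold for a measured lesion
#'
#' Convenience wrapper taking per-lesion scalars (as in [lung_cohort()]):
#' forms the degraded SBR from the two ACs, recovers it with the RC model,
#' evaluates the VMSBR threshold `w`, and converts it to an absolute
#' activity concentration by multiplying by background AC (the model's `w`
#' is normalized to background).
#'
#' @param lesion a [lesion_measurements()] (or one row of [lung_cohort()]
#'   coerced via [lesion_measurements()]).
#' @param coeffs,rc_coeffs model coefficient sets.
#' @return list with `degraded_sbr`, `rc`, `recovered_sbr`, `log_w`, `w`,
#'   `threshold_ac` (Bq/mL).
#' @export
vmsbr_lesion_threshold <- function(lesion, coeffs = vmsbr_coefficients(),
                                   rc_coeffs = rc_coefficients()) {
  stopifnot(inherits(lesion, "lesion_measurements"))
  z0 <- degraded_sbr(lesion)
  rc <- recovery_coefficient(lesion$volume_cm3, lesion$motion_mm, rc_coeffs)
  z <- z0 * rc
  lw <- vmsbr_log_threshold(lesion$volume_cm3, lesion$motion_mm, z, coeffs)
  w <- exp(lw)
  list(degraded_sbr = z0, rc = rc, recovered_sbr = z,
       log_w = lw, w = w, threshold_ac = w * lesion$background_ac)
}
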