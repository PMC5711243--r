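#' Maximum activity concentration within a region
#'
#' @param pet an [image_volume()].
#' @param search_region optional non-empty [binary_mask()] restricting the
#'   statistic; `NULL` uses the whole grid.
#' @return ACmax in Bq/mL.
#' @export
ac_max <- function(pet, search_region = NULL) {
  stopifnot(inherits(pet, "image_volume"))
  if (is.null(search_region)) return(max(pet$data))
  check_same_geometry(pet, search_region)
  if (sum(search_region$data) == 0L)
    stop("search region is empty", call. = FALSE)
  max(pet$data[search_region$data])
}

#' Fixed-percentage-of-maximum threshold
#'
#' The single-threshold family: the threshold is `fraction * ACmax` within
#' the search region.  When a background level is supplied and the result
#' does not exceed it, the method is flagged not segmentable — the
#' grown region would spill into background indefinitely.
#'
#' @inheritParams ac_max
#' @param fraction fraction of ACmax in (0, 1); 0.15, 0.35 and 0.42 are
#'   the published variants.
#' @param background_ac optional background level (Bq/mL) used for the
#'   segmentability check.
#' @return list with `threshold_ac` and logical `not_segmentable`.
#' @export
percent_max_threshold <- function(pet, search_region = NULL, fraction,
                                  background_ac = NULL) {
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly within (0, 1)", call. = FALSE)
  thr <- fraction * ac_max(pet, search_region)
  flag <- !is.null(background_ac) && thr <= background_ac
  list(threshold_ac = thr, not_segmentable = flag)
}

#' Fixed SUV threshold
#'
#' Converts an SUV cutoff (default 2.5 g/mL) to an absolute activity
#' concentration via the scan calibration:
#' `threshold_ac = suv_cutoff * injected_activity / body_weight`.
#'
#' @param cal a [scan_calibration()].
#' @param suv_cutoff SUV threshold, g/mL.
#' @param background_ac optional background level for the segmentability
#'   check.
#' @return list with `threshold_ac` and `not_segmentable`.
#' @export
suv_threshold <- function(cal, suv_cutoff = 2.5, background_ac = NULL) {
  stopifnot(inherits(cal, "scan_calibration"))
  if (!is.finite(suv_cutoff) || suv_cutoff <= 0)
    stop("SUV cutoff must be > 0", call. = FALSE)
  thr <- suv_to_ac(cal, suv_cutoff)
  flag <- !is.null(background_ac) && thr <= background_ac
  list(threshold_ac = thr, not_segmentable = flag)
}

#' Mean-plus-background adaptive threshold
#'
#' `threshold = 0.15 * ACmean + BG`, where ACmean is the mean of voxels
#' above 70% of ACmax within the search region (the tumor plateau) and BG
#' is the mean over a background ROI placed in the adjacent structure with
#' the highest background activity.
#'
#' @inheritParams ac_max
#' @param background_roi non-empty [binary_mask()], disjoint from the
#'   tumor, over which background is averaged.
#' @param fraction fraction of the plateau mean added to background
#'   (default 0.15).
#' @return list with `threshold_ac`, `ac_mean`, `background_ac` and
#'   `not_segmentable` (always `FALSE`: the threshold exceeds background
#'   by construction).
#' @export
nestle_threshold <- function(pet, search_region = NULL, background_roi,
                             fraction = 0.15) {
  stopifnot(inherits(background_roi, "binary_mask"))
  check_same_geometry(pet, background_roi)
  if (sum(background_roi$data) == 0L)
    stop("background ROI is empty", call. = FALSE)
  vals <- if (is.null(search_region)) as.numeric(pet$data)
          else pet$data[search_region$data]
  acmax <- ac_max(pet, search_region)
  plateau <- vals[vals > 0.70 * acmax]
  if (length(plateau) == 0L)
    stop("degenerate lesion: no voxels above 70% of ACmax", call. = FALSE)
  ac_mean <- mean(plateau)
  bg <- mean(pet$data[background_roi$data])
  list(threshold_ac = fraction * ac_mean + bg, ac_mean = ac_mean,
       background_ac = bg, not_segmentable = FALSE)
}

#' Iterated linear-SUVmean threshold
#'
#' The regression-function method: the threshold in SUV units is
#' `0.307 * SUVmean + 0.588`, where SUVmean is measured in the ROI defined
#' by the current threshold.  Starting from a 70%-of-ACmax ROI, the
#' function is iterated a fixed number of times (default 5); on nearly
#' homogeneous lesions it reaches its fixed point after one step.
#'
#' @inheritParams ac_max
#' @param cal a [scan_calibration()] for AC/SUV conversion.
#' @param slope,intercept coefficients of the linear function of SUVmean.
#' @param iterations number of iterations (>= 1).
#' @param start_fraction starting ROI threshold as a fraction of ACmax.
#' @param background_ac optional background level for the segmentability
#'   check.
#' @return list with `threshold_ac`, `threshold_suv`, `history` (SUV
#'   threshold per iteration) and `not_segmentable`.
#' @export
black_iterative_threshold <- function(pet, search_region = NULL, cal,
                                      slope = 0.307, intercept = 0.588,
                                      iterations = 5L, start_fraction = 0.70,
                                      background_ac = NULL) {
  stopifnot(inherits(cal, "scan_calibration"))
  if (iterations < 1L) stop("iteration count must be >= 1", call. = FALSE)
  vals <- if (is.null(search_region)) as.numeric(pet$data)
          else pet$data[search_region$data]
  acmax <- ac_max(pet, search_region)
  thr_ac <- start_fraction * acmax
  history <- numeric(iterations)
  for (k in seq_len(iterations)) {
    roi <- vals[vals >= thr_ac]
    if (length(roi) == 0L)
      stop("degenerate lesion: ROI emptied during threshold iteration",
           call. = FALSE)
    suv_mean <- ac_to_suv(cal, mean(roi))
    thr_suv <- slope * suv_mean + intercept
    thr_ac <- suv_to_ac(cal, thr_suv)
    history[k] <- thr_suv
  }
  flag <- !is.null(background_ac) && thr_ac <= background_ac
  list(threshold_ac = thr_ac, threshold_suv = thr_suv,
       history = history, not_segmentable = flag)
}

#' VMSBR adaptive threshold for a measured lesion
#'
#' Applies the full VMSBR chain to per-lesion scalars: degrade-corrected
#' SBR via the recovery coefficient, optimal normalized threshold `w` from
#' the threshold model, absolute threshold `w * background_ac`.
#'
#' @param lesion a [lesion_measurements()].
#' @param coeffs,rc_coeffs coefficient sets (defaults: calibrated values).
#' @param background_ac optional override of the background used for the
#'   segmentability check (defaults to the lesion's own background AC).
#' @return list with `threshold_ac`, `w`, `recovered_sbr`, `rc`,
#'   `not_segmentable`.
#' @export
vmsbr_method_threshold <- function(lesion, coeffs = vmsbr_coefficients(),
                                   rc_coeffs = rc_coefficients(),
                                   background_ac = NULL) {
  res <- vmsbr_lesion_threshold(lesion, coeffs, rc_coeffs)
  bg <- if (is.null(background_ac)) lesion$background_ac else background_ac
  list(threshold_ac = res$threshold_ac, w = res$w,
       recovered_sbr = res$recovered_sbr, rc = res$rc,
       not_segmentable = res$threshold_ac <= bg)
}

#' Segmentation result container
#'
#' Pairs a method label with its absolute threshold and, when the method is
#' applicable, the region-grown mask and its volume.  A method whose
#' threshold does not exceed background is recorded as not segmentable with
#' no mask — never as a silently empty mask.
#'
#' @param method method label (`"p15"`, `"p35"`, `"p42"`, `"suv2.5"`,
#'   `"nestle"`, `"black"`, `"vmsbr"`, or free text).
#' @param threshold_ac absolute threshold, Bq/mL (may be `NA` when not
#'   segmentable).
#' @param mask a [binary_mask()] or `NULL`.
#' @return object of class `segmentation_result`.
#' @export
segmentation_result <- function(method, threshold_ac, mask = NULL) {
  not_seg <- is.null(mask)
  structure(
    list(method = method, threshold_ac = threshold_ac,
         not_segmentable = not_seg, mask = mask,
         volume_cm3 = if (not_seg) NA_real_ else mask_volume_cm3(mask)),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  if (x$not_segmentable) {
    cat(sprintf("[%s] not segmentable (threshold %.6g Bq/mL at or below background)\n",
                x$method, x$threshold_ac))
  } else {
    cat(sprintf("[%s] threshold %.6g Bq/mL -> %.4g cm^3\n",
                x$method, x$threshold_ac, x$volume_cm3))
  }
  invisible(x)
}

#' Apply one delineation method to a PET image
#'
#' Computes the method's absolute threshold and, if it exceeds the supplied
#' background level, region-grows from the seed.  This is the common
#' driver for all seven delineation methods.
#'
#' @param pet an [image_volume()].
#' @param seed voxel index of a point inside the lesion.
#' @param method one of `"p15"`, `"p35"`, `"p42"`, `"suv2.5"`, `"nestle"`,
#'   `"black"`, `"vmsbr"`.
#' @param background_ac measured lung background mean AC (Bq/mL); used for
#'   the not-segmentable decision of the single-threshold methods.
#' @param search_region optional [binary_mask()] for ACmax/ACmean
#'   statistics.
#' @param cal [scan_calibration()], required by `"suv2.5"` and `"black"`.
#' @param background_roi [binary_mask()], required by `"nestle"`.
#' @param lesion [lesion_measurements()], required by `"vmsbr"`.
#' @param coeffs,rc_coeffs VMSBR coefficient sets.
#' @param connectivity passed to [region_grow()].
#' @return a [segmentation_result()].
#' @export
segment_method <- function(pet, seed, method, background_ac,
                           search_region = NULL, cal = NULL,
                           background_roi = NULL, lesion = NULL,
                           coeffs = vmsbr_coefficients(),
                           rc_coeffs = rc_coefficients(),
                           connectivity = 6) {
  method <- match.arg(method, c("p15", "p35", "p42", "suv2.5", "nestle",
                                "black", "vmsbr"))
  res <- switch(method,
    p15 = percent_max_threshold(pet, search_region, 0.15, background_ac),
    p35 = percent_max_threshold(pet, search_region, 0.35, background_ac),
    p42 = percent_max_threshold(pet, search_region, 0.42, background_ac),
    "suv2.5" = {
      if (is.null(cal)) stop("suv2.5 needs a scan_calibration", call. = FALSE)
      suv_threshold(cal, 2.5, background_ac)
    },
    nestle = {
      if (is.null(background_roi))
        stop("the mean-plus-background method needs a background ROI",
             call. = FALSE)
      nestle_threshold(pet, search_region, background_roi)
    },
    black = {
      if (is.null(cal)) stop("the iterated SUVmean method needs a scan_calibration",
                             call. = FALSE)
      black_iterative_threshold(pet, search_region, cal,
                                background_ac = background_ac)
    },
    vmsbr = {
      if (is.null(lesion))
        stop("the VMSBR method needs lesion_measurements", call. = FALSE)
      vmsbr_method_threshold(lesion, coeffs, rc_coeffs, background_ac)
    })
  if (isTRUE(res$not_segmentable))
    return(segmentation_result(method, res$threshold_ac, NULL))
  mask <- region_grow(pet, seed, res$threshold_ac, "above",
                      connectivity = connectivity)
  segmentation_result(method, res$threshold_ac, mask)
}
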