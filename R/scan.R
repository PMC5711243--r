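#' Measure the optimal threshold by a surface-separation scan
#'
#' The optimality oracle against which predicted thresholds are judged:
#' the PET image is segmented by region growing at every threshold from 1%
#' to 99% of ACmax in 1% steps; each resulting volume is meshed and the
#' mean surface separation from the reference ITV mesh is computed; the
#' fraction minimizing the separation is the measured optimal threshold.
#' Ties are broken toward the lower fraction (the more inclusive contour).
#' Fractions at which the seed fails the predicate or the mask cannot be
#' formed are recorded as `NA`.
#'
#' @param pet an [image_volume()].
#' @param seed voxel index inside the lesion.
#' @param reference_itv non-empty [binary_mask()] (e.g. the CT-derived
#'   motion envelope), resampled/aligned to world coordinates — its mesh is
#'   the reference surface.
#' @param search_region optional [binary_mask()] for the ACmax statistic
#'   (lesion-local maximum); `NULL` uses the whole grid.
#' @param fractions thresholds to scan, as fractions of ACmax.
#' @param connectivity passed to [region_grow()].
#' @param smooth_sigma_vox passed to [mask_to_mesh()].
#' @return object of class `threshold_scan`: list with `fractions`,
#'   `separations` (mm, `NA` where absent), `volumes_cm3`,
#'   `optimal_fraction`, `optimal_separation`, `ac_max`.
#' @export
optimal_threshold_scan <- function(pet, seed, reference_itv,
                                   search_region = NULL,
                                   fractions = seq(0.01, 0.99, by = 0.01),
                                   connectivity = 6,
                                   smooth_sigma_vox = 1) {
  stopifnot(inherits(pet, "image_volume"), inherits(reference_itv, "binary_mask"))
  if (sum(reference_itv$data) == 0L)
    stop("reference ITV is empty", call. = FALSE)
  seed <- check_seed(pet, seed)
  acmax <- ac_max(pet, search_region)
  ref_mesh <- mask_to_mesh(reference_itv, smooth_sigma_vox)
  seps <- rep(NA_real_, length(fractions))
  vols <- rep(NA_real_, length(fractions))
  sv <- pet$data[seed[1], seed[2], seed[3]]
  for (i in seq_along(fractions)) {
    thr <- fractions[i] * acmax
    if (sv < thr) next  # seed lost; recorded as absent
    mask <- region_grow(pet, seed, thr, "above", connectivity = connectivity)
    if (sum(mask$data) == 0L) next
    mesh <- mask_to_mesh(mask, smooth_sigma_vox)
    if (nrow(mesh$faces) == 0L) next
    seps[i] <- surface_separation(ref_mesh, mesh)
    vols[i] <- mask_volume_cm3(mask)
  }
  if (all(is.na(seps)))
    stop("scan failure: no scanned threshold produced a valid mask",
         call. = FALSE)
  best <- which(seps == min(seps, na.rm = TRUE))[1]  # ties -> lower fraction
  structure(
    list(fractions = fractions, separations = seps, volumes_cm3 = vols,
         optimal_fraction = fractions[best], optimal_separation = seps[best],
         ac_max = acmax),
    class = "threshold_scan"
  )
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf(
    "threshold scan: %d fractions, optimal %.0f%% of ACmax (separation %.3g mm)\n",
    length(x$fractions), 100 * x$optimal_fraction, x$optimal_separation))
  invisible(x)
}

#' @export
plot.threshold_scan <- function(x, ...) {
  graphics::plot(100 * x$fractions, x$separations, type = "l",
                 xlab = "threshold (% of ACmax)",
                 ylab = "mean surface separation (mm)", ...)
  graphics::abline(v = 100 * x$optimal_fraction, lty = 2)
  invisible(x)
}
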