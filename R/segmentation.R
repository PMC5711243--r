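#' Seed-based 3D region growing
#'
#' Returns the connected component, under face (6-) connectivity by
#' default, of the thresholded voxel set containing the seed.  This is the
#' segmentation primitive behind every contour in the package: CT motion
#' envelopes at -425 HU and PET ITVs at method-specific activity
#' thresholds.  The threshold predicate is inclusive (`>=` for `above`,
#' `<=` for `below`), so ties at the exact threshold are handled
#' deterministically.
#'
#' @param image an [image_volume()].
#' @param seed voxel index, length 3 (1-based), or a world-mm point when
#'   `seed_is_world = TRUE`.
#' @param threshold scalar threshold in the image's units.
#' @param direction `"above"` (grow over values >= threshold) or
#'   `"below"` (<=).
#' @param connectivity 6 (faces, default) or 26 (faces + edges + corners).
#' @param seed_is_world interpret `seed` as world mm coordinates.
#' @return a [binary_mask()] on the image grid.
#' @export
region_grow <- function(image, seed, threshold,
                        direction = c("above", "below"),
                        connectivity = 6, seed_is_world = FALSE) {
  stopifnot(inherits(image, "image_volume"))
  direction <- match.arg(direction)
  if (!connectivity %in% c(6, 26))
    stop("connectivity must be 6 or 26", call. = FALSE)
  if (seed_is_world)
    seed <- round(world_to_index(image, seed))
  seed <- check_seed(image, seed)
  sv <- image$data[seed[1], seed[2], seed[3]]
  ok <- if (direction == "above") sv >= threshold else sv <= threshold
  if (!ok)
    stop(sprintf(
      "seed error: seed voxel value %.6g fails the %s-threshold predicate (threshold %.6g)",
      sv, direction, threshold), call. = FALSE)
  pass <- if (direction == "above") image$data >= threshold
          else image$data <= threshold
  grown <- .region_grow_cpp(as.logical(pass), dim(image$data),
                            as.integer(seed) - 1L, as.integer(connectivity))
  binary_mask(array(grown, dim(image$data)), geometry_from = image)
}

#' Validate a seed index against a grid
#' @keywords internal
check_seed <- function(geom, seed) {
  seed <- as.integer(round(seed))
  if (length(seed) != 3L || anyNA(seed))
    stop("seed must be a length-3 voxel index", call. = FALSE)
  d <- dim(geom$data)
  if (any(seed < 1L) || any(seed > d))
    stop(sprintf("geometry error: seed (%s) lies outside the %s grid",
                 paste(seed, collapse = ","), paste(d, collapse = "x")),
         call. = FALSE)
  seed
}

#' Restrict a mask to an allowed region
#'
#' Voxelwise intersection; the automated surrogate for manual trimming of
#' PET contours that bleed across anatomical boundaries (e.g. restrict an
#' ITV to a lung mask to remove chest-wall or mediastinal spillover).
#'
#' @param mask,allowed_region [binary_mask()]s sharing geometry.
#' @return the trimmed [binary_mask()].
#' @export
trim_mask <- function(mask, allowed_region) {
  stopifnot(inherits(mask, "binary_mask"), inherits(allowed_region, "binary_mask"))
  check_same_geometry(mask, allowed_region)
  binary_mask(mask$data & allowed_region$data, mask$spacing, mask$origin)
}
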