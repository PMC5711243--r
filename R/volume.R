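#' 3D image volume with voxel geometry
#'
#' The universal image carrier of the package: a 3D scalar array (activity
#' concentration in Bq/mL for PET, Hounsfield units for CT) together with the
#' voxel spacing in mm and the world-mm coordinate of the centre of voxel
#' `(1,1,1)`.  Voxel `(i,j,k)` (1-based, R convention) maps to world position
#' `origin + ((i,j,k) - 1) * spacing`.
#'
#' @param data numeric 3D array; all values must be finite.
#' @param spacing numeric length-3, voxel edge lengths `(dx, dy, dz)` in mm;
#'   strictly positive.
#' @param origin numeric length-3, world-mm position of the first voxel
#'   centre.  Defaults to `c(0, 0, 0)`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  if (any(!is.finite(data)))
    stop("volume data contains non-finite values", call. = FALSE)
  structure(
    list(data = data, spacing = spacing, origin = origin),
    class = "image_volume"
  )
}

#' Binary mask sharing an image volume's geometry
#'
#' Represents segmented regions: internal target volumes (ITVs), lung masks,
#' background ROIs.  A mask always carries the same grid shape, spacing and
#' origin as the image it annotates, so that derived volumes in cm^3 are
#' consistent by construction.
#'
#' @param data logical 3D array (coerced with `as.logical` if numeric).
#' @param spacing,origin voxel geometry, as in [image_volume()].
#' @param geometry_from optionally an `image_volume` or `binary_mask` whose
#'   spacing/origin are copied; `data` must match its shape.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing = NULL, origin = NULL, geometry_from = NULL) {
  if (!is.null(geometry_from)) {
    spacing <- geometry_from$spacing
    origin <- geometry_from$origin
    if (!identical(dim(data), dim(geometry_from$data)))
      stop("mask shape does not match the geometry source", call. = FALSE)
  }
  if (is.null(origin)) origin <- c(0, 0, 0)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  storage.mode(data) <- "logical"
  if (anyNA(data)) stop("mask data contains NA", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite values (mm)", call. = FALSE)
  structure(
    list(data = data, spacing = spacing, origin = origin),
    class = "binary_mask"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "image_volume: %d x %d x %d voxels, spacing (%.4g, %.4g, %.4g) mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.4g, %.4g, %.4g) mm, value range [%.6g, %.6g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "binary_mask: %d x %d x %d voxels, %d set (%.4g cm^3)\n",
    d[1], d[2], d[3], sum(x$data), mask_volume_cm3(x)))
  invisible(x)
}

#' Voxel volume in mL (= cm^3)
#' @param x an `image_volume` or `binary_mask`.
#' @return scalar, `dx*dy*dz / 1000`.
#' @export
voxel_volume_ml <- function(x) prod(x$spacing) / 1000

#' Volume of a binary mask in cm^3
#' @param mask a `binary_mask`.
#' @return number of set voxels times the voxel volume, in cm^3.
#' @export
mask_volume_cm3 <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$data) * voxel_volume_ml(mask)
}

#' Convert voxel indices to world coordinates and back
#'
#' Indices are 1-based (R convention); `index_to_world` accepts a length-3
#' index or an n-by-3 matrix of indices.  Fractional indices are allowed.
#'
#' @param geom an `image_volume` or `binary_mask` supplying spacing/origin.
#' @param index voxel index (length 3 or n x 3 matrix).
#' @param world world-mm point (length 3 or n x 3 matrix).
#' @return matrix (or vector) of converted coordinates.
#' @export
index_to_world <- function(geom, index) {
  ix <- if (is.matrix(index)) index else matrix(index, ncol = 3)
  w <- sweep(sweep(ix - 1, 2, geom$spacing, "*"), 2, geom$origin, "+")
  if (is.matrix(index)) w else drop(w)
}

#' @rdname index_to_world
#' @export
world_to_index <- function(geom, world) {
  wx <- if (is.matrix(world)) world else matrix(world, ncol = 3)
  ix <- sweep(sweep(wx, 2, geom$origin, "-"), 2, geom$spacing, "/") + 1
  if (is.matrix(world)) ix else drop(ix)
}

#' Check that two gridded objects share geometry
#' @param a,b `image_volume` / `binary_mask` objects.
#' @param tol relative tolerance on spacing/origin.
#' @return `TRUE` invisibly, or an error.
#' @keywords internal
check_same_geometry <- function(a, b, tol = 1e-6) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("grid shapes differ", call. = FALSE)
  if (max(abs(a$spacing - b$spacing)) > tol * max(a$spacing) ||
      max(abs(a$origin - b$origin)) > tol * max(1, max(abs(a$origin))))
    stop("voxel geometries (spacing/origin) differ", call. = FALSE)
  invisible(TRUE)
}

#' Scan calibration for SUV computation
#'
#' Standardized uptake value normalizes activity concentration by injected
#' activity per unit body weight: `SUV = ac * body_weight / injected_activity`
#' in g/mL, with activity decay-corrected to scan time.
#'
#' @param injected_activity_bq injected activity in Bq, decay-corrected.
#' @param body_weight_g patient body weight in grams.
#' @return object of class `scan_calibration`.
#' @export
scan_calibration <- function(injected_activity_bq, body_weight_g) {
  if (!is.finite(injected_activity_bq) || injected_activity_bq <= 0)
    stop("injected activity must be a positive number of Bq", call. = FALSE)
  if (!is.finite(body_weight_g) || body_weight_g <= 0)
    stop("body weight must be a positive number of grams", call. = FALSE)
  structure(
    list(injected_activity_bq = injected_activity_bq,
         body_weight_g = body_weight_g),
    class = "scan_calibration"
  )
}

#' Convert between activity concentration and SUV
#' @param cal a [scan_calibration()].
#' @param ac activity concentration, Bq/mL.
#' @param suv standardized uptake value, g/mL.
#' @return the converted quantity.
#' @export
ac_to_suv <- function(cal, ac) ac * cal$body_weight_g / cal$injected_activity_bq

#' @rdname ac_to_suv
#' @export
suv_to_ac <- function(cal, suv) suv * cal$injected_activity_bq / cal$body_weight_g
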