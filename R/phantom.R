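#' Specification of a moving-sphere PET phantom
#'
#' Describes a synthetic scan of one or more uptake spheres in a uniform
#' background compartment, undergoing 1D sinusoidal motion, imaged with an
#' isotropic Gaussian point-spread function.  This is the digital stand-in
#' for a NEMA IEC body phantom on a moving platform: the post-reconstruction
#' image is modelled as ideal object, then arcsine motion blur along one
#' axis, then PSF blur, then optional additive Gaussian noise — not a
#' tomographic reconstruction.
#'
#' @param spheres list of `list(center = c(x,y,z) mm, diameter = mm)`; a
#'   single `list(center=, diameter=)` is also accepted.
#' @param motion_extent_mm peak-to-peak displacement of the sinusoid, mm
#'   (amplitude is half of this).
#' @param motion_axis axis of motion, 1..3 (default 3, cranio-caudal).
#' @param source_ac,background_ac activity concentrations, Bq/mL; must
#'   satisfy `source_ac > background_ac >= 0`.
#' @param psf_fwhm_mm isotropic Gaussian PSF full width at half maximum, mm.
#'   Default 6.5 mm, representative of whole-body PET after OSEM
#'   reconstruction.
#' @param spacing_mm voxel spacing; default `c(3.91, 3.91, 3.27)` mm
#'   (a 50 cm transaxial field of view on a 128 x 128 matrix, 3.27 mm
#'   slices).
#' @param shape grid dimensions; if `NULL`, the smallest grid containing
#'   every sphere plus motion plus `3 * psf_fwhm_mm` padding is used.
#' @param origin world position of the first voxel centre; if `NULL`,
#'   chosen so the grid is centred on the spheres' bounding box.
#' @param noise_sd additive Gaussian noise sigma in Bq/mL (0 = noiseless,
#'   the default: optimal-threshold geometry is a noiseless-limit concept).
#' @param pad_mm padding between each sphere's motion envelope and the grid
#'   boundary when the grid is auto-sized; default `3 * psf_fwhm_mm` plus two
#'   voxels.  Enlarge to leave room for background ROIs.
#' @param seed RNG seed for the noise draw; required when `noise_sd > 0`
#'   for reproducibility.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(spheres, motion_extent_mm = 0, motion_axis = 3,
                         source_ac, background_ac,
                         psf_fwhm_mm = 6.5,
                         spacing_mm = c(3.91, 3.91, 3.27),
                         shape = NULL, origin = NULL,
                         noise_sd = 0, seed = NULL, pad_mm = NULL) {
  if (!is.null(spheres$center)) spheres <- list(spheres)
  for (s in spheres) {
    if (is.null(s$center) || is.null(s$diameter) || length(s$center) != 3L)
      stop("each sphere needs a length-3 center (mm) and a diameter (mm)",
           call. = FALSE)
    if (!is.finite(s$diameter) || s$diameter <= 0)
      stop("sphere diameters must be > 0 mm", call. = FALSE)
  }
  if (!is.finite(motion_extent_mm) || motion_extent_mm < 0)
    stop("motion extent must be >= 0 mm", call. = FALSE)
  if (!motion_axis %in% 1:3) stop("motion axis must be 1, 2 or 3", call. = FALSE)
  if (!is.finite(source_ac) || !is.finite(background_ac) ||
      source_ac <= background_ac || background_ac < 0 || source_ac <= 0)
    stop("activities must satisfy source_ac > background_ac >= 0", call. = FALSE)
  if (psf_fwhm_mm < 0) stop("PSF FWHM must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise sigma must be >= 0", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)

  pad <- if (is.null(pad_mm)) 3 * psf_fwhm_mm + 2 * max(spacing_mm) else pad_mm
  centers <- do.call(rbind, lapply(spheres, `[[`, "center"))
  radii <- vapply(spheres, function(s) s$diameter / 2, 0)
  half_motion <- rep(0, 3); half_motion[motion_axis] <- motion_extent_mm / 2
  lo <- apply(sweep(centers, 2, radii + pad, "-"), 2, min) - half_motion
  hi <- apply(sweep(centers, 2, radii + pad, "+"), 2, max) + half_motion
  if (is.null(shape)) {
    shape <- as.integer(ceiling((hi - lo) / spacing_mm)) + 1L
    origin <- lo
  } else {
    shape <- as.integer(shape)
    if (is.null(origin)) {
      origin <- (lo + hi) / 2 - (shape - 1) * spacing_mm / 2
    }
    grid_hi <- origin + (shape - 1) * spacing_mm
    if (any(lo < origin - spacing_mm / 2) || any(hi > grid_hi + spacing_mm / 2))
      stop(paste("geometry error: sphere plus motion plus 3*FWHM padding",
                 "does not fit inside the stated grid"), call. = FALSE)
  }
  structure(
    list(spheres = spheres, motion_extent_mm = motion_extent_mm,
         motion_axis = motion_axis, source_ac = source_ac,
         background_ac = background_ac, psf_fwhm_mm = psf_fwhm_mm,
         spacing_mm = spacing_mm, shape = shape, origin = origin,
         noise_sd = noise_sd, seed = seed),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "phantom_spec: %d sphere(s), motion %.3g mm along axis %d, SBR %s\n",
    length(x$spheres), x$motion_extent_mm, x$motion_axis,
    if (x$background_ac > 0) sprintf("%.3g", x$source_ac / x$background_ac)
    else "Inf (zero background)"))
  cat(sprintf("  grid %s @ (%s) mm, PSF FWHM %.3g mm, noise sd %.3g\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing_mm, digits = 3), collapse = ", "),
              x$psf_fwhm_mm, x$noise_sd))
  invisible(x)
}

#' True SBR of a phantom spec
#' @param spec a [phantom_spec()].
#' @return `source_ac / background_ac` (Inf for zero background).
#' @export
true_sbr <- function(spec) {
  if (spec$background_ac > 0) spec$source_ac / spec$background_ac else Inf
}

#' Discrete arcsine motion-blur kernel
#'
#' The time-averaged position density of a sinusoidal displacement
#' `u(t) = A sin(2 pi t / T)` is the arcsine (dwell-time) density
#' `p(u) = 1 / (pi sqrt(A^2 - u^2))` on `(-A, A)`, `A = extent / 2`.  The
#' kernel integrates this density over voxel-width bins, so it sums to 1
#' exactly and is mirror-symmetric; its variance approaches `A^2 / 2`.
#'
#' @param extent_mm peak-to-peak motion extent, mm (>= 0).
#' @param spacing_mm voxel spacing along the motion axis, mm (> 0).
#' @return numeric vector of odd length, centred on zero displacement.
#' @export
motion_kernel <- function(extent_mm, spacing_mm) {
  if (!is.finite(extent_mm) || extent_mm < 0)
    stop("motion extent must be >= 0", call. = FALSE)
  if (!is.finite(spacing_mm) || spacing_mm <= 0)
    stop("spacing must be > 0", call. = FALSE)
  A <- extent_mm / 2
  if (A < spacing_mm * 1e-9) return(1)
  half <- ceiling(A / spacing_mm - 0.5 + 1e-12)
  offs <- (-half):half
  cdf <- function(u) {
    u <- pmin(A, pmax(-A, u))
    0.5 + asin(u / A) / pi
  }
  k <- cdf(offs * spacing_mm + spacing_mm / 2) -
       cdf(offs * spacing_mm - spacing_mm / 2)
  ## symmetrize against floating-point asymmetry and renormalize
  k <- (k + rev(k)) / 2
  k / sum(k)
}

## integrated (bin-averaged) Gaussian kernel, unit sum
gaussian_kernel <- function(fwhm_mm, spacing_mm) {
  if (fwhm_mm <= 0) return(1)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(4 * sigma / spacing_mm))
  offs <- (-half):half
  k <- stats::pnorm((offs + 0.5) * spacing_mm, sd = sigma) -
       stats::pnorm((offs - 0.5) * spacing_mm, sd = sigma)
  k / sum(k)
}

## convolve a 3D array along one axis with a centred kernel (zero padding)
convolve_axis <- function(arr, kernel, axis) {
  if (length(kernel) == 1L) return(arr * kernel)
  d <- dim(arr)
  n <- d[axis]
  half <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (j in seq_along(kernel)) {
    off <- j - 1L - half
    idx <- seq_len(n)
    src <- idx - off
    ok <- src >= 1L & src <= n
    K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + kernel[j]
  }
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = n)
  out <- K %*% m
  aperm(array(out, d[perm]), order(perm))
}

## fractional occupancy of a union of spheres on the grid, via supersampling
sphere_occupancy <- function(shape, spacing, origin, centers, radii,
                             supersample = 3L) {
  occ <- array(0, shape)
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(shape[a]) - 1) * spacing[a])
  ss <- max(1L, as.integer(supersample))
  sub <- (seq_len(ss) - (ss + 1) / 2) / ss  # offsets in voxel fractions
  for (si in seq_along(radii)) {
    ctr <- centers[si, ]
    r <- radii[si]
    ## bounding indices (with a one-voxel skirt)
    rng <- lapply(1:3, function(a) {
      which(ax[[a]] >= ctr[a] - r - spacing[a] & ax[[a]] <= ctr[a] + r + spacing[a])
    })
    if (any(lengths(rng) == 0L)) next
    dx2 <- outer(ax[[1]][rng[[1]]], sub * spacing[1], "+") - ctr[1]
    dy2 <- outer(ax[[2]][rng[[2]]], sub * spacing[2], "+") - ctr[2]
    dz2 <- outer(ax[[3]][rng[[3]]], sub * spacing[3], "+") - ctr[3]
    ## accumulate counts of subsamples inside the sphere
    nx <- length(rng[[1]]); ny <- length(rng[[2]]); nz <- length(rng[[3]])
    cnt <- array(0, c(nx, ny, nz))
    r2 <- r * r
    for (a in seq_len(ss)) for (b in seq_len(ss)) {
      ## vector over x-subsample collapsed below
      dyz2 <- outer(dy2[, a]^2, dz2[, b]^2, "+")  # ny x nz
      for (cxs in seq_len(ss)) {
        x2 <- dx2[, cxs]^2
        inside <- outer(x2, dyz2, "+") <= r2     # nx x ny x nz
        cnt <- cnt + array(inside, c(nx, ny, nz))
      }
    }
    frac <- cnt / ss^3
    occ[rng[[1]], rng[[2]], rng[[3]]] <-
      pmax(occ[rng[[1]], rng[[2]], rng[[3]]], frac)
  }
  occ
}

## binary voxelization (center-in-sphere), optionally with axis displacement
sphere_mask_at <- function(shape, spacing, origin, centers, radii,
                           shift = c(0, 0, 0)) {
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(shape[a]) - 1) * spacing[a])
  m <- array(FALSE, shape)
  for (si in seq_along(radii)) {
    ctr <- centers[si, ] + shift
    r2 <- radii[si]^2
    dx2 <- (ax[[1]] - ctr[1])^2
    dy2 <- (ax[[2]] - ctr[2])^2
    dz2 <- (ax[[3]] - ctr[3])^2
    m <- m | (outer(dx2, outer(dy2, dz2, "+"), "+") <= r2)
  }
  m
}

#' Simulate a PET scan of the phantom
#'
#' Produces the blurred, motion-time-averaged activity map together with
#' ground-truth masks.  The ideal object (fractional sphere occupancy,
#' supersampled to reduce staircase bias) is convolved along the motion
#' axis with the arcsine dwell-time kernel, then with the Gaussian PSF;
#' the image is `background_ac + (source_ac - background_ac) * blurred
#' occupancy`, plus optional noise.  A constant background is invariant
#' under the normalized blurs, so total activity is conserved whenever the
#' spheres sit at least `3 * FWHM` inside the grid (guaranteed by the
#' default grid).
#'
#' @param spec a [phantom_spec()].
#' @param supersample sub-voxel sampling factor for partial-volume
#'   occupancy (default 3; 1 disables).
#' @param n_phases number of uniformly spaced phase samples whose union
#'   forms the motion-envelope truth mask (default 64).
#' @return list with `pet` ([image_volume()]), `static_truth` and
#'   `envelope_truth` ([binary_mask()]): the sphere voxelized at the motion
#'   midpoint, and the union of sphere positions over one period (the ITV
#'   ground truth).
#' @export
simulate_pet <- function(spec, supersample = 3L, n_phases = 64L) {
  stopifnot(inherits(spec, "phantom_spec"))
  centers <- do.call(rbind, lapply(spec$spheres, `[[`, "center"))
  radii <- vapply(spec$spheres, function(s) s$diameter / 2, 0)

  occ <- sphere_occupancy(spec$shape, spec$spacing_mm, spec$origin,
                          centers, radii, supersample)
  mk <- motion_kernel(spec$motion_extent_mm, spec$spacing_mm[spec$motion_axis])
  blurred <- convolve_axis(occ, mk, spec$motion_axis)
  for (a in 1:3) {
    gk <- gaussian_kernel(spec$psf_fwhm_mm, spec$spacing_mm[a])
    blurred <- convolve_axis(blurred, gk, a)
  }
  pet_data <- spec$background_ac +
    (spec$source_ac - spec$background_ac) * blurred
  if (spec$noise_sd > 0) {
    if (is.null(spec$seed))
      stop("a seed is required when noise_sd > 0", call. = FALSE)
    set.seed(spec$seed)
    pet_data <- pet_data + array(stats::rnorm(length(pet_data), 0, spec$noise_sd),
                                 dim(pet_data))
  }
  static <- sphere_mask_at(spec$shape, spec$spacing_mm, spec$origin,
                           centers, radii)
  env <- static
  if (spec$motion_extent_mm > 0) {
    A <- spec$motion_extent_mm / 2
    phases <- seq(0, 2 * pi, length.out = n_phases + 1L)[-(n_phases + 1L)]
    for (ph in phases) {
      shift <- c(0, 0, 0); shift[spec$motion_axis] <- A * sin(ph)
      env <- env | sphere_mask_at(spec$shape, spec$spacing_mm, spec$origin,
                                  centers, radii, shift)
    }
  }
  list(
    pet = image_volume(pet_data, spec$spacing_mm, spec$origin),
    static_truth = binary_mask(static, spec$spacing_mm, spec$origin),
    envelope_truth = binary_mask(env, spec$spacing_mm, spec$origin)
  )
}

#' Simulate a CT-like maximum-intensity-projection volume
#'
#' Emulates the cine-CT MIP used for reference ITV contouring: every voxel
#' of the motion envelope gets tumor HU, everything else lung HU, followed
#' by a small Gaussian blur.  Region growing on this volume at -425 HU
#' recovers the motion envelope.
#'
#' @param spec a [phantom_spec()].
#' @param tumor_hu,lung_hu Hounsfield values (defaults 0 and -800).
#' @param ct_blur_fwhm_mm CT blur FWHM, mm (default 1).
#' @param spacing_mm CT grid spacing; default `c(0.98, 0.98, 2.5)` mm
#'   (50 cm field of view on a 512 matrix, 2.5 mm slices).
#' @param n_phases phase samples for the envelope, as in [simulate_pet()].
#' @return list with `mip` ([image_volume()], HU) and `envelope_truth`
#'   ([binary_mask()]) on the CT grid.
#' @export
simulate_ct_mip <- function(spec, tumor_hu = 0, lung_hu = -800,
                            ct_blur_fwhm_mm = 1,
                            spacing_mm = c(0.98, 0.98, 2.5),
                            n_phases = 64L) {
  stopifnot(inherits(spec, "phantom_spec"))
  centers <- do.call(rbind, lapply(spec$spheres, `[[`, "center"))
  radii <- vapply(spec$spheres, function(s) s$diameter / 2, 0)
  ## CT grid covering the same world extent as the PET grid
  extent <- (spec$shape - 1) * spec$spacing_mm
  shape <- as.integer(ceiling(extent / spacing_mm)) + 1L
  origin <- spec$origin

  env <- sphere_mask_at(shape, spacing_mm, origin, centers, radii)
  if (spec$motion_extent_mm > 0) {
    A <- spec$motion_extent_mm / 2
    phases <- seq(0, 2 * pi, length.out = n_phases + 1L)[-(n_phases + 1L)]
    for (ph in phases) {
      shift <- c(0, 0, 0); shift[spec$motion_axis] <- A * sin(ph)
      env <- env | sphere_mask_at(shape, spacing_mm, origin, centers, radii,
                                  shift)
    }
  }
  hu <- array(lung_hu, shape) + (tumor_hu - lung_hu) * env
  if (ct_blur_fwhm_mm > 0) {
    for (a in 1:3) {
      gk <- gaussian_kernel(ct_blur_fwhm_mm, spacing_mm[a])
      hu <- convolve_axis(hu, gk, a)
    }
  }
  list(
    mip = image_volume(hu, spacing_mm, origin),
    envelope_truth = binary_mask(env, spacing_mm, origin)
  )
}

#' Full factorial calibration grid of phantom specs
#'
#' The model-development design: every combination of sphere diameter,
#' motion extent and SBR.  Defaults reproduce the six NEMA IEC sphere
#' diameters, seven motion extents spanning 0-30 mm and six SBR levels up
#' to 50, i.e. 6 x 7 x 6 = 252 configurations.
#'
#' @param sphere_diameters_mm sphere diameters, mm (within 10-37).
#' @param motion_extents_mm peak-to-peak motion extents, mm (0-30).
#' @param sbr_levels source-to-background ratios (> 1, up to 50).
#' @param background_ac background activity, Bq/mL (default 3000,
#'   a typical lung background).
#' @param ... further arguments passed to [phantom_spec()] (e.g.
#'   `spacing_mm`, `psf_fwhm_mm`).
#' @return list of [phantom_spec()] objects, one per combination, each
#'   carrying attributes `diameter_mm`, `motion_mm`, `sbr`.
#' @export
calibration_grid <- function(sphere_diameters_mm = c(10, 13, 17, 22, 28, 37),
                             motion_extents_mm = c(0, 5, 10, 15, 20, 25, 30),
                             sbr_levels = c(2, 4, 8, 16, 32, 50),
                             background_ac = 3000, ...) {
  if (length(sphere_diameters_mm) == 0L || length(motion_extents_mm) == 0L ||
      length(sbr_levels) == 0L)
    stop("all three factor lists must be non-empty", call. = FALSE)
  if (any(sphere_diameters_mm < 10 - 1e-9) || any(sphere_diameters_mm > 37 + 1e-9))
    stop("sphere diameters must lie within the phantom range 10-37 mm",
         call. = FALSE)
  if (any(motion_extents_mm < 0) || any(motion_extents_mm > 30 + 1e-9))
    stop("motion extents must lie within 0-30 mm", call. = FALSE)
  if (any(sbr_levels <= 1) || any(sbr_levels > 50 + 1e-9))
    stop("SBR levels must lie in (1, 50]", call. = FALSE)
  combos <- expand.grid(d = sphere_diameters_mm, y = motion_extents_mm,
                        z = sbr_levels, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(combos)), function(i) {
    sp <- phantom_spec(
      spheres = list(center = c(0, 0, 0), diameter = combos$d[i]),
      motion_extent_mm = combos$y[i],
      source_ac = background_ac * combos$z[i],
      background_ac = background_ac, ...)
    attr(sp, "diameter_mm") <- combos$d[i]
    attr(sp, "motion_mm") <- combos$y[i]
    attr(sp, "sbr") <- combos$z[i]
    sp
  })
}

#' Single-lesion phantom spec from cohort-style scalars
#'
#' Builds a one-sphere [phantom_spec()] whose sphere volume, motion and
#' true SBR match a lesion description, for synthetic-cohort experiments.
#'
#' @param volume_cm3 sphere volume, cm^3.
#' @param motion_mm peak-to-peak motion, mm.
#' @param sbr true source-to-background ratio (> 1).
#' @param background_ac background activity, Bq/mL.
#' @param ... passed to [phantom_spec()].
#' @return a [phantom_spec()].
#' @export
lesion_phantom <- function(volume_cm3, motion_mm, sbr, background_ac = 3000,
                           ...) {
  stopifnot(volume_cm3 > 0, sbr > 1)
  d <- 2 * (3 * volume_cm3 * 1000 / (4 * pi))^(1 / 3)
  phantom_spec(spheres = list(center = c(0, 0, 0), diameter = d),
               motion_extent_mm = motion_mm,
               source_ac = background_ac * sbr,
               background_ac = background_ac, ...)
}
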