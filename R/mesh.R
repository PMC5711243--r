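#' Triangle mesh in world coordinates
#'
#' @param vertices n x 3 numeric matrix of world-mm points.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("vertices and faces must have 3 columns", call. = FALSE)
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range", call. = FALSE)
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces, area %.4g mm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

#' Extract the surface of a binary mask as a triangle mesh
#'
#' Isosurface of the binary field at level 0.5, extracted with a marching
#' tetrahedra scheme (six tetrahedra per grid cell, shared interpolated
#' edge vertices), so the surface of a bounded region is watertight.  By
#' default the binary field is first anti-aliased with a small Gaussian
#' (`smooth_sigma_vox` voxels): the 0.5 level set of the smoothed field
#' tracks the underlying smooth boundary much more faithfully than the
#' blocky midpoint surface of the raw 0/1 field, which matters for surface
#' areas and sub-voxel surface distances.  Smoothing is skipped
#' automatically when it would erase the object (very small masks).
#' The grid is zero-padded so masks touching the array boundary still
#' produce closed surfaces.  Zero-area faces are dropped.
#'
#' @param mask a non-empty [binary_mask()].
#' @param smooth_sigma_vox Gaussian sigma in voxels for anti-aliasing
#'   (default 1; 0 disables).
#' @return a `tri_mesh` with vertices in world mm.
#' @export
mask_to_mesh <- function(mask, smooth_sigma_vox = 1) {
  stopifnot(inherits(mask, "binary_mask"))
  if (sum(mask$data) == 0L)
    stop("cannot mesh an empty mask", call. = FALSE)
  pad <- as.integer(max(2, ceiling(3 * smooth_sigma_vox) + 1))
  d <- dim(mask$data)
  field <- array(0, d + 2L * pad)
  field[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.numeric(mask$data)
  if (smooth_sigma_vox > 0) {
    sm <- field
    for (a in 1:3) {
      gk <- gaussian_kernel(2.3548 * smooth_sigma_vox, 1)
      sm <- convolve_axis(sm, gk, a)
    }
    ## keep the smoothed field only if the object survives the 0.5 level
    if (max(sm) > 0.55) field <- sm
  }
  iso <- 0.5
  field[field == iso] <- iso + 1e-9
  raw <- .marching_tetrahedra_cpp(as.numeric(field), dim(field), iso)
  v_idx <- raw$vertices  # continuous 0-based padded indices
  ## padded index -> original 1-based index -> world mm
  v1 <- sweep(v_idx, 2, pad - 1, "-")  # 1-based fractional index in mask grid
  world <- sweep(sweep(v1 - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")
  m <- tri_mesh(world, raw$faces)
  drop_degenerate_faces(m)
}

drop_degenerate_faces <- function(mesh, tol = 1e-12) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  cc <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  areas <- 0.5 * sqrt(rowSums(cross3(b - a, cc - a)^2))
  keep <- areas > tol
  if (all(keep)) return(mesh)
  tri_mesh(mesh$vertices, mesh$faces[keep, , drop = FALSE])
}

#' Total surface area of a mesh
#' @param mesh a `tri_mesh`.
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (nrow(mesh$faces) == 0L) return(0)
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  cc <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  sum(0.5 * sqrt(rowSums(cross3(b - a, cc - a)^2)))
}

#' Check mesh watertightness
#'
#' A closed surface has every undirected edge shared by exactly two faces.
#'
#' @param mesh a `tri_mesh`.
#' @return logical.
#' @export
mesh_is_watertight <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  f <- mesh$faces
  if (nrow(f) == 0L) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Mean surface separation between two meshes
#'
#' From each sampling point on the `reference` mesh, the distance to the
#' closest point anywhere on the surface of `other` (exact point-to-
#' triangle distances) is computed; the mean of these distances is the
#' surface separation.  One-sided by default — the reference (CT-derived)
#' surface is the yardstick; `symmetric = TRUE` averages both directions.
#' Sampling points are all reference vertices, supplemented with face
#' centroids when the mesh has fewer than `centroid_below` vertices.
#'
#' @param reference,other `tri_mesh` objects.
#' @param symmetric also sample `other` against `reference` and average.
#' @param centroid_below add face-centroid samples when the vertex count is
#'   below this (default 500).
#' @return mean separation in mm.
#' @export
surface_separation <- function(reference, other, symmetric = FALSE,
                               centroid_below = 500L) {
  stopifnot(inherits(reference, "tri_mesh"), inherits(other, "tri_mesh"))
  if (nrow(reference$faces) == 0L || nrow(other$faces) == 0L)
    stop("cannot compare empty meshes", call. = FALSE)
  one_sided <- function(src, dst) {
    pts <- mesh_sample_points(src, centroid_below)
    mean(.point_mesh_distance_cpp(pts, dst$vertices, dst$faces))
  }
  if (symmetric) {
    (one_sided(reference, other) + one_sided(other, reference)) / 2
  } else {
    one_sided(reference, other)
  }
}

mesh_sample_points <- function(mesh, centroid_below = 500L) {
  pts <- mesh$vertices
  if (nrow(pts) < centroid_below) {
    cen <- (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
            mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
            mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
    pts <- rbind(pts, cen)
  }
  pts
}
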