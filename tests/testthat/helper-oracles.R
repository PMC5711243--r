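# Independent oracles and shared fixtures, built in code at test time.

# Brute-force flood fill over a thresholded boolean array: breadth-first
# frontier expansion in plain R, independent of the package's compiled path.
bfs_flood_fill <- function(pass, seed, connectivity = 6) {
  d <- dim(pass)
  visited <- array(FALSE, d)
  if (!pass[seed[1], seed[2], seed[3]]) return(visited)
  offsets <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  manh <- abs(offsets$di) + abs(offsets$dj) + abs(offsets$dk)
  offsets <- offsets[if (connectivity == 6) manh == 1 else manh > 0, ]
  frontier <- matrix(seed, ncol = 3)
  visited[seed[1], seed[2], seed[3]] <- TRUE
  while (nrow(frontier) > 0) {
    nxt <- do.call(rbind, lapply(seq_len(nrow(offsets)), function(o)
      sweep(frontier, 2, as.numeric(offsets[o, ]), "+")))
    keep <- nxt[, 1] >= 1 & nxt[, 2] >= 1 & nxt[, 3] >= 1 &
      nxt[, 1] <= d[1] & nxt[, 2] <= d[2] & nxt[, 3] <= d[3]
    nxt <- nxt[keep, , drop = FALSE]
    if (nrow(nxt) == 0) break
    ok <- pass[nxt] & !visited[nxt]
    nxt <- unique(nxt[ok, , drop = FALSE])
    if (nrow(nxt) == 0) break
    visited[nxt] <- TRUE
    frontier <- nxt
  }
  visited
}

# Exact point-to-triangle distance by an independent construction: project
# onto the triangle's plane; if the projection's barycentric coordinates are
# all non-negative the planar distance is the answer, otherwise the minimum
# over the three edge segments.
oracle_point_triangle <- function(p, a, b, c) {
  seg_dist <- function(p, u, v) {
    w <- v - u
    t <- sum((p - u) * w) / sum(w * w)
    t <- min(1, max(0, t))
    sqrt(sum((p - (u + t * w))^2))
  }
  n <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
         (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
         (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
  nn <- sum(n * n)
  if (nn < 1e-300) return(min(seg_dist(p, a, b), seg_dist(p, b, c),
                              seg_dist(p, c, a)))
  dist_plane <- sum((p - a) * n) / sqrt(nn)
  q <- p - dist_plane * n / sqrt(nn)
  # barycentric coordinates of q
  v0 <- b - a; v1 <- c - a; v2 <- q - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  if (v >= 0 && w >= 0 && v + w <= 1) return(abs(dist_plane))
  min(seg_dist(p, a, b), seg_dist(p, b, c), seg_dist(p, c, a))
}

oracle_mesh_distance <- function(points, mesh) {
  vapply(seq_len(nrow(points)), function(i) {
    p <- points[i, ]
    min(vapply(seq_len(nrow(mesh$faces)), function(f) {
      oracle_point_triangle(p, mesh$vertices[mesh$faces[f, 1], ],
                            mesh$vertices[mesh$faces[f, 2], ],
                            mesh$vertices[mesh$faces[f, 3], ])
    }, 0))
  }, 0)
}

# voxelized sphere mask centred in a cube grid
sphere_mask <- function(radius_mm, spacing = 1, margin_mm = 5) {
  half <- radius_mm + margin_mm
  ax <- seq(-half, half, by = spacing)
  n <- length(ax)
  binary_mask(array(outer(ax^2, outer(ax^2, ax^2, "+"), "+") <= radius_mm^2,
                    c(n, n, n)),
              spacing = rep(spacing, 3), origin = rep(-half, 3))
}

# one shared simulated lesion reused by several test files (built lazily)
.shared_cache <- new.env(parent = emptyenv())
shared_lesion_sim <- function() {
  if (is.null(.shared_cache$sim)) {
    spec <- lesion_phantom(8, 8, 15, spacing_mm = c(2, 2, 2))
    sim <- simulate_pet(spec)
    sim$spec <- spec
    sim$seed <- round(world_to_index(sim$pet, c(0, 0, 0)))
    sim$lung <- phantom_background_mask(sim$envelope_truth, 13)
    .shared_cache$sim <- sim
  }
  .shared_cache$sim
}
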