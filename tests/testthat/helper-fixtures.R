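# Shared fixtures and independent brute-force oracles. Everything is built
# in code at test time; oracles deliberately avoid the package's fast paths.

# Small phantom spec used by most integration tests: same organ geometry as
# the default, coarser grid for speed.
small_spec <- function(...) {
  phantom_spec(shape = c(48, 48, 40), spacing = c(4, 4, 3.2), ...)
}

# Mid-resolution spec used by registration/cohort tests.
demo_spec_args <- function() list(shape = c(64, 64, 48), spacing = c(3, 3, 3))

# Cube mask occupying voxel index ranges (inclusive, 1-based).
cube_mask <- function(shape, ix, iy, iz, spacing = c(1, 1, 1),
                      label = "CTV") {
  arr <- array(FALSE, shape)
  arr[ix, iy, iz] <- TRUE
  structure_mask(arr, spacing, label = label)
}

# Sphere/ellipsoid mask from analytic geometry (world mm).
ball_mask <- function(shape, spacing, center, radii, label = "CTV") {
  proto <- image_volume(array(0, shape), spacing)
  pts <- sweep(dirval:::lattice_world(proto), 2, center, "-")
  xi <- sweep(pts, 2, rep(radii, length.out = 3), "/")
  structure_mask(array(rowSums(xi^2) <= 1, shape), spacing, label = label)
}

# Oracle: directed and symmetric surface distances by exhaustive
# nearest-neighbour search over boundary voxel centres (mm).
bf_surface_stats <- function(a, b) {
  pa <- which(dirval:::boundary_voxels(a$array), arr.ind = TRUE) - 1
  pb <- which(dirval:::boundary_voxels(b$array), arr.ind = TRUE) - 1
  wa <- sweep(pa, 2, a$spacing, "*")
  wb <- sweep(pb, 2, b$spacing, "*")
  d2 <- outer(rowSums(wa^2), rowSums(wb^2), "+") - 2 * wa %*% t(wb)
  d2[d2 < 0] <- 0
  d_ab <- sqrt(apply(d2, 1, min))
  d_ba <- sqrt(apply(d2, 2, min))
  list(dta_mean = (mean(d_ab) + mean(d_ba)) / 2 / 10,
       dta_max = max(d_ab, d_ba) / 10)
}

# Oracle: single-source shortest paths over the mesh edge graph by iterated
# full edge relaxation (Bellman-Ford). Per round, candidate distances over
# all directed edges are aggregated with min per head vertex (plain vector
# assignment would silently keep only the last duplicate).
bf_shortest_paths <- function(mesh, source) {
  e <- dirval:::mesh_edges(mesh)
  w <- sqrt(rowSums((mesh$vertices[e[, 1], ] - mesh$vertices[e[, 2], ])^2))
  heads <- c(e[, 1], e[, 2])
  tails <- c(e[, 2], e[, 1])
  ww <- c(w, w)
  n <- nrow(mesh$vertices)
  dist <- rep(Inf, n)
  dist[source] <- 0
  for (it in seq_len(n)) {
    cand <- tapply(dist[tails] + ww, heads, min)
    nd <- dist
    idx <- as.integer(names(cand))
    nd[idx] <- pmin(nd[idx], cand)
    if (identical(nd, dist)) break
    dist <- nd
  }
  dist
}

# Shared small session cache (generated once per test run).
cached_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_phantom(small_spec(bladder_fill_factor = 2,
                                            seed = 42))
    cache
  }
})
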