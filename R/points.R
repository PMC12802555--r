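# Controlling points: geodesically separated vertex subsets on the reference
# mesh, mapped by shared topology to the corresponding vertices on a session
# mesh. The points coincide with a random subset of mesh vertices and carry no
# anatomical-landmark meaning.

#' Select controlling-point vertices under a minimum geodesic separation
#'
#' Greedy selection over a seeded uniform random permutation of the mesh
#' vertices: a candidate is accepted iff its geodesic distance (shortest path
#' over the edge graph, Euclidean weights) to every already accepted vertex is
#' at least `d_min`. The result is maximal: every remaining vertex lies within
#' `d_min` of an accepted one, which also makes the selection a geodesic
#' covering of the surface.
#'
#' @param mesh A [surface_mesh()].
#' @param d_min Minimum geodesic separation in mm (default 10).
#' @param seed Integer seed fixing the permutation (the first element plays
#'   the role of the random starting vertex).
#' @return Integer vector of selected vertex indices, in acceptance order.
#' @export
select_control_vertices <- function(mesh, d_min = 10, seed = 1L) {
  assert_that(d_min > 0, "d_min must be positive")
  n <- nrow(mesh$vertices)
  g <- mesh_graph(mesh)
  order <- with_seed(seed, sample.int(n))
  accepted <- integer(0)
  for (v in order) {
    if (length(accepted) == 0) {
      accepted <- v
      next
    }
    d <- igraph::distances(g, v = v, to = accepted)[1, ]
    if (all(d >= d_min)) accepted <- c(accepted, v)
  }
  accepted
}

#' Map selected vertices to corresponding coordinates on two meshes
#'
#' Uses the shared mesh topology to read the world coordinates of the selected
#' vertex indices on the reference and target meshes, order preserved.
#' Correspondence is undefined across different topologies, so mismatched
#' `topology_id`s are rejected.
#'
#' @param vertex_ids Integer vertex indices (e.g. from
#'   [select_control_vertices()]).
#' @param ref_mesh,target_mesh [surface_mesh()] objects with equal
#'   `topology_id`.
#' @param d_min,seed Provenance of the selection, stored with the set.
#' @return An object of class `control_point_set` with fields `vertex_ids`,
#'   `ref_points`, `target_points`, `organ`, `d_min`, `seed`.
#' @export
map_points <- function(vertex_ids, ref_mesh, target_mesh,
                       d_min = 10, seed = NA_integer_) {
  assert_that(identical(ref_mesh$topology_id, target_mesh$topology_id),
              "map_points: meshes have different topology_id ('%s' vs '%s')",
              ref_mesh$topology_id, target_mesh$topology_id)
  n <- nrow(ref_mesh$vertices)
  assert_that(all(vertex_ids >= 1) && all(vertex_ids <= n),
              "vertex_ids out of range")
  structure(list(vertex_ids = as.integer(vertex_ids),
                 ref_points = ref_mesh$vertices[vertex_ids, , drop = FALSE],
                 target_points = target_mesh$vertices[vertex_ids, , drop = FALSE],
                 organ = ref_mesh$label %||% target_mesh$label,
                 d_min = d_min, seed = seed),
            class = "control_point_set")
}

#' @export
print.control_point_set <- function(x, ...) {
  res <- sqrt(rowSums((x$ref_points - x$target_points)^2))
  cat(sprintf("<control_point_set> %s: %d points, d_min %.1f mm, mean |ref-target| %.2f mm\n",
              x$organ %||% "unlabelled", length(x$vertex_ids), x$d_min,
              mean(res)))
  invisible(x)
}

#' Read and write controlling-point sets as JSON
#'
#' @param points A [map_points()] control point set.
#' @param path File path.
#' @export
write_points <- function(points, path) {
  jsonlite::write_json(
    list(vertex_ids = points$vertex_ids,
         ref_points = unname(apply(points$ref_points, 1, as.numeric,
                                   simplify = FALSE)),
         target_points = unname(apply(points$target_points, 1, as.numeric,
                                      simplify = FALSE)),
         organ = points$organ, d_min = points$d_min, seed = points$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_points
#' @export
read_points <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(p) {
    if (is.matrix(p)) p else matrix(unlist(p), ncol = 3, byrow = TRUE)
  }
  structure(list(vertex_ids = as.integer(x$vertex_ids),
                 ref_points = as_mat(x$ref_points),
                 target_points = as_mat(x$target_points),
                 organ = x$organ, d_min = x$d_min,
                 seed = x$seed %||% NA_integer_),
            class = "control_point_set")
}
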