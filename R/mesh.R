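# Fixed-topology surface meshes. Every organ surface in every session is
# fitted from the same subdivided-icosahedron template, so vertex index i
# corresponds across images (the vertex-to-vertex mapping is initialised by
# projection along the centroid ray shared by all fits of the same template).

#' Triangulated organ surface with a shared topology
#'
#' @param vertices N x 3 matrix of world coordinates (mm).
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @param topology_id Identifier shared by all meshes fitted from the same
#'   template; equal ids guarantee identical vertex counts and face lists.
#' @param label Optional organ label.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, topology_id, label = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  assert_that(ncol(vertices) == 3, "vertices must be N x 3")
  assert_that(min(faces) >= 1 && max(faces) <= nrow(vertices),
              "face indices out of range")
  structure(list(vertices = vertices, faces = faces,
                 topology_id = topology_id, label = label),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %s: %d vertices, %d faces (topology %s)\n",
              x$label %||% "unlabelled", nrow(x$vertices), nrow(x$faces),
              x$topology_id))
  invisible(x)
}

#' Icosphere template mesh
#'
#' Unit icosphere obtained by subdividing an icosahedron `level` times and
#' reprojecting onto the unit sphere; vertex count follows
#' `N = 10 * 4^level + 2`. Level 3 (642 vertices) gives inter-vertex spacing
#' of a few mm on organ-sized surfaces, dense enough for the 10 mm
#' controlling-point separation rule to be meaningful.
#'
#' @param level Subdivision level (>= 0); level 0 is the icosahedron.
#' @return A unit-radius [surface_mesh()] centred at the origin, with
#'   `topology_id = "icosphere-L<level>"`.
#' @export
build_template_mesh <- function(level = 3) {
  assert_that(level >= 0, "subdivision level must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lv in seq_len(level)) {
    mid <- new.env(parent = emptyenv())
    verts <- v
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      idx <- mid[[key]]
      if (is.null(idx)) {
        p <- (verts[a, ] + verts[b, ]) / 2
        p <- p / sqrt(sum(p^2))
        verts <<- rbind(verts, p)
        idx <- nrow(verts)
        mid[[key]] <- idx
      }
      idx
    }
    nf <- matrix(0L, nrow(f) * 4, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[(t - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                       c(c, ca, bc), c(ab, bc, ca))
    }
    v <- verts
    f <- nf
  }
  surface_mesh(v, f, topology_id = sprintf("icosphere-L%d", level))
}

# Unique undirected edges of a mesh (E x 2, sorted pairs).
mesh_edges <- function(mesh) {
  e <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)],
             mesh$faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# Edge graph with Euclidean edge weights (mm), as an igraph object.
mesh_graph <- function(mesh) {
  e <- mesh_edges(mesh)
  w <- sqrt(rowSums((mesh$vertices[e[, 1], ] - mesh$vertices[e[, 2], ])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::E(g)$weight <- w
  g
}

#' Geodesic distance over the mesh edge graph
#'
#' Shortest-path length between two vertices over the triangulation's edge
#' graph with Euclidean edge weights, in mm.
#'
#' @param mesh A [surface_mesh()].
#' @param i,j Vertex indices (1-based).
#' @return Distance in mm.
#' @export
geodesic_distance <- function(mesh, i, j) {
  n <- nrow(mesh$vertices)
  assert_that(all(c(i, j) >= 1) && all(c(i, j) <= n),
              "vertex index out of range")
  if (i == j) return(0)
  d <- igraph::distances(mesh_graph(mesh), v = i, to = j)[1, 1]
  assert_that(is.finite(d), "mesh edge graph is disconnected")
  d
}

#' Fit the template mesh to a binary organ mask
#'
#' Each template vertex is mapped along the ray from the mask centroid through
#' the vertex direction to the subvoxel zero crossing of the mask's signed
#' distance transform (trilinear interpolation). The template's faces and
#' `topology_id` are kept, so all fits of one template are in vertex-to-vertex
#' correspondence. Rays without a crossing (non-star-shaped spots) fall back
#' to a closest-point projection onto the zero level set, with a warning.
#'
#' @param template A [build_template_mesh()] mesh.
#' @param mask A nonempty, single-component [structure_mask()].
#' @return A fitted [surface_mesh()] carrying the mask's organ label.
#' @export
fit_mesh_to_mask <- function(template, mask) {
  assert_that(any(mask$array), "cannot fit a mesh to an empty mask")
  sd_arr <- signed_distance(mask$array, mask$spacing)
  sd_vol <- image_volume(sd_arr, mask$spacing, mask$origin)
  idx <- which(mask$array, arr.ind = TRUE) - 1
  centroid <- mask$origin + colMeans(idx) * mask$spacing
  out_fill <- max(sd_arr)

  dirs <- template$vertices / sqrt(rowSums(template$vertices^2))
  nv <- nrow(dirs)
  t_max <- sqrt(sum(((dim(mask$array) - 1) * mask$spacing)^2))
  step <- min(mask$spacing) / 2
  ts <- seq(0, t_max, by = step)

  # march all rays at once: nv x length(ts) signed-distance samples
  sdm <- matrix(0, nv, length(ts))
  for (q in seq_along(ts))
    sdm[, q] <- sample_volume(sd_vol, sweep(ts[q] * dirs, 2, centroid, "+"),
                              fill = out_fill)
  first_exit <- apply(sdm[, -ncol(sdm), drop = FALSE] < 0 &
                      sdm[, -1, drop = FALSE] >= 0, 1,
                      function(r) if (any(r)) which(r)[1] else NA_integer_)
  hit <- !is.na(first_exit)

  lo <- ifelse(hit, ts[pmax(first_exit, 1)], 0)
  hi <- ifelse(hit, ts[pmax(first_exit, 1) + 1], 0)
  for (it in 1:30) {               # vectorised bisection to subvoxel accuracy
    mid <- (lo + hi) / 2
    sm <- sample_volume(sd_vol, sweep(mid * dirs, 2, centroid, "+"),
                        fill = out_fill)
    neg <- sm < 0
    lo <- ifelse(neg, mid, lo)
    hi <- ifelse(neg, hi, mid)
  }
  verts <- sweep(((lo + hi) / 2) * dirs, 2, centroid, "+")

  if (any(!hit)) {
    # closest-point projection onto the zero level set for rays that never
    # cross the surface (non-star-shaped spots)
    warning(sprintf("fit_mesh_to_mask: %d vertex ray(s) had no surface crossing; used closest-point projection", sum(!hit)))
    idx_nf <- which(!hit)
    p <- dirs[idx_nf, , drop = FALSE] *
      ts[apply(abs(sdm[idx_nf, , drop = FALSE]), 1, which.min)]
    p <- sweep(p, 2, centroid, "+")
    h <- min(mask$spacing) / 2
    for (it in 1:15) {
      s <- sample_volume(sd_vol, p, fill = out_fill)
      g <- matrix(0, nrow(p), 3)
      for (c in 1:3) {
        dp <- p; dp[, c] <- dp[, c] + h
        dm <- p; dm[, c] <- dm[, c] - h
        g[, c] <- (sample_volume(sd_vol, dp, fill = out_fill) -
                   sample_volume(sd_vol, dm, fill = out_fill)) / (2 * h)
      }
      gn <- pmax(rowSums(g^2), 1e-12)
      p <- p - g * (s / gn)
    }
    verts[idx_nf, ] <- p
  }
  surface_mesh(verts, template$faces, template$topology_id, mask$label)
}

#' Enclosed volume of a closed mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes over triangles, mm^3.
#'
#' @param mesh A closed, consistently oriented [surface_mesh()].
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  a <- v[mesh$faces[, 1], , drop = FALSE]
  b <- v[mesh$faces[, 2], , drop = FALSE]
  c <- v[mesh$faces[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c[, 3] - b[, 3] * c[, 2],
              b[, 3] * c[, 1] - b[, 1] * c[, 3],
              b[, 1] * c[, 2] - b[, 2] * c[, 1])
  abs(sum(rowSums(a * cr))) / 6
}

# PLY IO ----------------------------------------------------------------------

#' Read and write surface meshes as ASCII PLY
#'
#' The topology identifier and organ label are stored in header comments and
#' restored on read.
#'
#' @param mesh A [surface_mesh()].
#' @param path File path.
#' @export
write_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("comment topology_id", mesh$topology_id),
               paste("comment organ", mesh$label %||% "none"),
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(apply(mesh$vertices, 1,
                   function(r) paste(format(r, digits = 17), collapse = " ")),
             con)
  writeLines(apply(mesh$faces - 1L, 1,
                   function(r) paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  lines <- readLines(path)
  hdr_end <- which(lines == "end_header")[1]
  hdr <- lines[seq_len(hdr_end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr,
                                                   value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr,
                                                 value = TRUE)))
  topo <- sub("comment topology_id ", "",
              grep("^comment topology_id", hdr, value = TRUE))
  organ <- sub("comment organ ", "", grep("^comment organ", hdr, value = TRUE))
  verts <- matrix(scan(text = lines[hdr_end + seq_len(nv)], quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  fl <- matrix(scan(text = lines[hdr_end + nv + seq_len(nf)], quiet = TRUE),
               ncol = 4, byrow = TRUE)
  surface_mesh(verts, fl[, 2:4] + 1L, topology_id = topo,
               label = if (identical(organ, "none")) NULL else organ)
}
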