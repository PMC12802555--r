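# Fixed-topology surface meshes: template construction, mask fitting,
# geodesics, PLY IO, cross-session correspondence.

test_that("icosphere template follows the subdivision recurrence", {
  m0 <- build_template_mesh(0)
  expect_equal(nrow(m0$vertices), 12)
  expect_equal(nrow(m0$faces), 20)
  m2 <- build_template_mesh(2)
  expect_equal(nrow(m2$vertices), 162)
  expect_equal(nrow(m2$faces), 320)
  for (m in list(m0, m2)) {
    E <- nrow(dirval:::mesh_edges(m))
    expect_equal(nrow(m$vertices) - E + nrow(m$faces), 2)  # sphere topology
    expect_equal(unname(sqrt(rowSums(m$vertices^2))), rep(1, nrow(m$vertices)))
  }
})

test_that("fitting a spherical mask recovers the radius within a voxel", {
  sphere <- ball_mask(c(40, 40, 40), c(2, 2, 2), c(39, 39, 39), 30)
  fit <- fit_mesh_to_mask(build_template_mesh(2), sphere)
  r <- sqrt(rowSums(sweep(fit$vertices, 2, c(39, 39, 39))^2))
  expect_true(all(abs(r - 30) <= 2))
  fit2 <- fit_mesh_to_mask(build_template_mesh(2), sphere)
  expect_identical(fit$vertices, fit2$vertices)   # deterministic
  expect_identical(fit$topology_id, "icosphere-L2")
  expect_error(fit_mesh_to_mask(build_template_mesh(1),
                                cube_mask(c(8, 8, 8), 0, 0, 0)), "empty")
})

test_that("fitted mesh volume matches the analytic ellipsoid volume", {
  ell <- ball_mask(c(50, 50, 50), c(2, 2, 2), c(49, 49, 49), c(20, 30, 40))
  fit <- fit_mesh_to_mask(build_template_mesh(3), ell)
  va <- 4 / 3 * pi * 20 * 30 * 40
  expect_lt(abs(mesh_volume(fit) - va) / va, 0.05)
})

test_that("geodesic distances match an independent Bellman-Ford oracle", {
  mesh <- build_template_mesh(2)
  mesh$vertices <- mesh$vertices * 40
  expect_equal(geodesic_distance(mesh, 5, 5), 0)
  e <- dirval:::mesh_edges(mesh)[3, ]
  expect_equal(geodesic_distance(mesh, e[1], e[2]),
               sqrt(sum((mesh$vertices[e[1], ] - mesh$vertices[e[2], ])^2)))
  set.seed(4)
  for (src in sample(nrow(mesh$vertices), 3)) {
    bf <- bf_shortest_paths(mesh, src)
    for (dst in sample(nrow(mesh$vertices), 5)) {
      g <- geodesic_distance(mesh, src, dst)
      expect_equal(g, bf[dst], tolerance = 1e-10)
      # geodesic is at least the Euclidean chord
      chord <- sqrt(sum((mesh$vertices[src, ] - mesh$vertices[dst, ])^2))
      expect_gte(g + 1e-12, chord)
    }
  }
})

test_that("fits of the same template are topology-compatible across sessions", {
  ses <- cached_session()
  tmpl <- build_template_mesh(3)
  m_ref <- fit_mesh_to_mask(tmpl, ses$masks$reference$bladder)
  m_bo <- fit_mesh_to_mask(tmpl, ses$masks$beam_on$bladder)
  expect_identical(m_ref$faces, m_bo$faces)
  expect_identical(m_ref$topology_id, m_bo$topology_id)
  # correspondence plausibility: ground-truth-mapped session vertices land
  # near the same-index reference vertices, within the mean edge length
  mapped <- warp_point(m_bo$vertices, ses$gt_field$beam_on)
  err <- mean(sqrt(rowSums((mapped - m_ref$vertices)^2)))
  e <- dirval:::mesh_edges(m_ref)
  mean_edge <- mean(sqrt(rowSums((m_ref$vertices[e[, 1], ] -
                                  m_ref$vertices[e[, 2], ])^2)))
  expect_lt(err, mean_edge)
})

test_that("meshes round-trip through ASCII PLY with metadata", {
  tmp <- withr::local_tempdir()
  ell <- ball_mask(c(30, 30, 30), c(2, 2, 2), c(29, 29, 29), c(14, 18, 11),
                   label = "rectum")
  fit <- fit_mesh_to_mask(build_template_mesh(2), ell)
  f <- file.path(tmp, "m.ply")
  write_mesh(fit, f)
  back <- read_mesh(f)
  expect_equal(back$vertices, fit$vertices, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(back$faces, fit$faces)
  expect_identical(back$topology_id, fit$topology_id)
  expect_identical(back$label, "rectum")
})
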