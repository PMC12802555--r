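# Hybrid deformable registration: configuration contracts, identity and
# known-deformation recovery, strategy nesting, objective monotonicity,
# point-term efficacy.

reg_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_phantom(small_spec(bladder_fill_factor = 2.1,
                                            seed = 17))
    cache
  }
})

reg_structures <- function(ses, to = "beam_on") {
  orgs <- c("CTV", "bladder", "rectum")
  lapply(setNames(orgs, orgs), function(o)
    list(fixed = ses$masks[[to]][[o]], moving = ses$masks$reference[[o]]))
}

test_that("configuration invariants are enforced", {
  expect_error(registration_config(lambda_img = -1), "non-negative")
  cfg <- registration_config("intensity", lambda_struct = 99,
                             lambda_point = 99)
  expect_equal(cfg$lambda_struct, 0)
  expect_equal(cfg$lambda_point, 0)
  cfg2 <- registration_config("cs", lambda_point = 99)
  expect_equal(cfg2$lambda_point, 0)
  expect_gt(cfg2$lambda_struct, 0)

  ses <- reg_session()
  other <- image_volume(array(0, c(10, 10, 10)), c(2, 2, 2))
  expect_error(register(ses$images$reference, other,
                        registration_config("intensity")), "lattice")
  expect_error(register(ses$images$reference, ses$images$beam_on,
                        registration_config("cs")), "controlling structures")
  expect_error(register(ses$images$reference, ses$images$beam_on,
                        registration_config("cs_p"),
                        structures = reg_structures(ses)),
               "controlling points")
})

test_that("identity registration stays below a quarter voxel for all strategies", {
  ses <- reg_session()
  img <- ses$images$reference
  structures <- lapply(reg_structures(ses), function(s)
    list(fixed = s$moving, moving = s$moving))
  tmpl <- build_template_mesh(2)
  mesh <- fit_mesh_to_mask(tmpl, ses$masks$reference$bladder)
  pts <- map_points(select_control_vertices(mesh, 10, seed = 1), mesh, mesh)
  for (strategy in c("intensity", "cs", "cs_p")) {
    cfg <- registration_config(strategy, iterations = c(15, 10, 5))
    r <- register(img, img, cfg, structures = structures, points = list(pts))
    expect_lt(max(abs(r$field$vectors)), 0.25 * min(img$spacing))
  }
})

test_that("a known 5 mm translation is recovered within 1 mm over the CTV", {
  ses <- reg_session()
  fx <- ses$images$reference
  tvec <- c(5, 0, 0)
  mv <- image_volume(
    array(sample_volume(fx, sweep(dirval:::lattice_world(fx), 2, tvec, "-")),
          dim(fx$array)), fx$spacing, fx$origin)
  r <- register(fx, mv,
                registration_config("intensity", iterations = c(100, 60, 30)))
  ctv <- ses$masks$reference$CTV$array
  u_mean <- vapply(1:3, function(c) mean(r$field$vectors[, , , c][ctv]),
                   numeric(1))
  expect_lt(sqrt(sum((u_mean - tvec)^2)), 1)
  # objective trace is non-increasing within every resolution level
  for (lv in unique(r$trace$level)) {
    tr <- r$trace$objective[r$trace$level == lv]
    expect_true(all(diff(tr) <= 1e-10))
  }
})

test_that("cs_p with zero structure and point weights reduces to intensity-only", {
  ses <- reg_session()
  fx <- ses$images$adapt
  mv <- ses$images$reference
  it <- c(10, 6, 3)
  r_int <- register(fx, mv, registration_config("intensity", iterations = it))
  tmpl <- build_template_mesh(2)
  mesh <- fit_mesh_to_mask(tmpl, ses$masks$reference$bladder)
  pts <- map_points(select_control_vertices(mesh, 10, seed = 1), mesh, mesh)
  r_nested <- register(fx, mv,
                       registration_config("cs_p", lambda_struct = 0,
                                           lambda_point = 0, iterations = it),
                       structures = reg_structures(ses, "adapt"),
                       points = list(pts))
  expect_identical(r_nested$field$vectors, r_int$field$vectors)
})

test_that("the point term halves its residual on a large-deformation pair", {
  ses <- reg_session()
  orgs <- c("CTV", "bladder", "rectum")
  tmpl <- build_template_mesh(3)
  points <- lapply(setNames(orgs, orgs), function(o) {
    mf <- fit_mesh_to_mask(tmpl, ses$masks$reference[[o]])
    mt <- fit_mesh_to_mask(tmpl, ses$masks$beam_on[[o]])
    map_points(select_control_vertices(mf, 10, seed = derive_seed(17, o)),
               mf, mt)
  })
  r <- register(ses$images$beam_on, ses$images$reference,
                registration_config("cs_p"),
                structures = reg_structures(ses), points = points)
  expect_lt(r$point_residual_mm["final"], 0.5 * r$point_residual_mm["initial"])
  # and the propagated bladder beats the intensity-only result
  r_int <- register(ses$images$beam_on, ses$images$reference,
                    registration_config("intensity"))
  d_csp <- dice(warp_mask(ses$masks$reference$bladder, r$field),
                ses$masks$beam_on$bladder)
  d_int <- dice(warp_mask(ses$masks$reference$bladder, r_int$field),
                ses$masks$beam_on$bladder)
  expect_gt(d_csp, d_int)
})

test_that("tidy and glance expose the optimisation record", {
  ses <- reg_session()
  r <- register(ses$images$reference, ses$images$reference,
                registration_config("intensity", iterations = c(5, 3, 2)))
  tr <- tidy(r)
  expect_true(all(c("level", "iteration", "objective") %in% names(tr)))
  g <- glance(r)
  expect_equal(nrow(g), 1)
  expect_identical(g$strategy, "intensity")
  expect_true(is.finite(g$objective))
})
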