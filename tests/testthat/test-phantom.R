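# Synthetic pelvic phantom: deformation bookkeeping, volume targeting,
# ground-truth consistency, dose shape, contour noise.

test_that("identity spec produces identical session and reference anatomy", {
  spec <- small_spec(bladder_fill_factor = 1, rigid_offset = c(0, 0, 0),
                     perturb_amplitude = 0, noise_sigma = 0, seed = 1)
  ses <- generate_phantom(spec)
  for (org in c("CTV", "bladder", "rectum"))
    expect_identical(ses$masks$beam_on[[org]]$array,
                     ses$masks$reference[[org]]$array)
  # noiseless intensities take exactly the tissue-class means
  expect_setequal(unique(as.numeric(ses$images$reference$array)),
                  unname(spec$intensity_means))
})

test_that("bladder fill factor is realised within 10%", {
  ses <- generate_phantom(small_spec(bladder_fill_factor = 2, seed = 3))
  ratio <- sum(ses$masks$beam_on$bladder$array) /
    sum(ses$masks$reference$bladder$array)
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("volume targeting holds across random specs while CTV and rectum stay stable", {
  set.seed(11)
  for (i in 1:20) {
    fill <- runif(1, 1, 2.5)
    jit <- runif(2, 0.9, 1.1)
    ses <- generate_phantom(small_spec(
      bladder_fill_factor = fill, seed = 100 + i,
      bladder_axes = c(30, 26, 26) * jit[1],
      ctv_axes = c(21, 19, 17) * jit[2]))
    ratio <- volume_cc(ses$masks$beam_on$bladder) /
      volume_cc(ses$masks$reference$bladder)
    expect_lt(abs(ratio / fill - 1), 0.1)
    for (org in c("CTV", "rectum")) for (role in c("adapt", "verify", "beam_on"))
      expect_lt(abs(volume_cc(ses$masks[[role]][[org]]) /
                    volume_cc(ses$masks$reference[[org]]) - 1), 0.1)
  }
})

test_that("sessions are bit-identical for a fixed spec and seed", {
  s1 <- generate_phantom(small_spec(bladder_fill_factor = 1.7, seed = 9))
  s2 <- generate_phantom(small_spec(bladder_fill_factor = 1.7, seed = 9))
  expect_identical(s1$images$beam_on$array, s2$images$beam_on$array)
  expect_identical(s1$masks$verify$bladder$array, s2$masks$verify$bladder$array)
  expect_identical(s1$gt_field$adapt$vectors, s2$gt_field$adapt$vectors)
})

test_that("warping reference masks through the ground-truth field reproduces session masks", {
  ses <- cached_session()
  for (role in c("adapt", "verify", "beam_on"))
    for (org in c("CTV", "bladder", "rectum")) {
      w <- warp_mask(ses$masks$reference[[org]], ses$gt_field[[role]])
      expect_gte(dice(w, ses$masks[[role]][[org]]), 0.98)
    }
})

test_that("organ geometry exceeding the grid is rejected with a clear message", {
  expect_error(generate_phantom(small_spec(bladder_axes = c(90, 90, 60))),
               "exceeds the grid extent")
  expect_error(generate_phantom(small_spec(bladder_fill_factor = -1)),
               "bladder_fill_factor")
})

test_that("dose has a prescription plateau over the CTV and monotone fall-off", {
  ses <- cached_session()
  dose <- ses$dose$beam_on
  img_dose <- resample_volume(dose, ses$images$beam_on)
  ctv <- ses$masks$beam_on$CTV
  idx <- which(ctv$array, arr.ind = TRUE) - 1
  centroid <- ctv$origin + colMeans(idx) * ctv$spacing
  expect_lt(abs(sample_volume(dose, rbind(centroid)) - 600), 0.02 * 600)
  # brute-force voxel average over the CTV
  expect_gt(mean(img_dose$array[ctv$array]), 588)
  expect_lt(mean(img_dose$array[ctv$array]), 612)
  # dose along a ray leaving the CTV is non-increasing
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0.6, 0.8))
  for (k in 1:3) {
    ts <- seq(0, 60, by = 1)
    ray <- sweep(outer(ts, dirs[k, ]), 2, centroid, "+")
    dd <- sample_volume(dose, ray, fill = 0)
    expect_true(all(diff(dd) <= 0.5))  # small slack for grid interpolation
  }
  expect_true(all(dose$array > 0))
  expect_error(generate_dose(ses, "beam_on", prescription = -5), "positive")
})

test_that("contour noise perturbs surfaces by about the requested amplitude", {
  sphere <- ball_mask(c(40, 40, 40), c(2, 2, 2), c(39, 39, 39), 30,
                      label = "bladder")
  expect_identical(simulate_contour_noise(sphere, 0, seed = 1), sphere)
  noisy <- simulate_contour_noise(sphere, 1, seed = 1)
  sds <- surface_distance_stats(noisy, sphere)
  expect_gt(sds$dta_mean * 10, 0.3)   # mm
  expect_lt(sds$dta_mean * 10, 2)
  n2 <- simulate_contour_noise(sphere, 2, seed = 1)
  n3 <- simulate_contour_noise(sphere, 2, seed = 2)
  expect_lt(dice(n2, n3), 1)
})

test_that("a session writes to disk with a complete manifest", {
  tmp <- withr::local_tempdir()
  ses <- generate_phantom(small_spec(bladder_fill_factor = 1.3, seed = 2))
  write_session(ses, tmp)
  man <- jsonlite::read_json(file.path(tmp, "session.json"),
                             simplifyVector = TRUE)
  expect_equal(man$seed, 2)
  expect_true(all(file.exists(file.path(tmp, unlist(man$files)))))
  img <- read_volume(file.path(tmp, man$files$image_beam_on))
  expect_equal(img$array, ses$images$beam_on$array, tolerance = 1e-6)
})
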