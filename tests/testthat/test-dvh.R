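# DVH extraction, point metrics, Delta-DVH, course scaling, cohort bands.

# A cube with a linear dose ramp 0..600 cGy along the first axis.
ramp_fixture <- function(n = 30, sp = 2) {
  shape <- c(n, n, n)
  dosev <- array(rep(seq(0, 600, length.out = n), times = n * n), shape)
  dose <- image_volume(dosev, rep(sp, 3))
  mask <- structure_mask(array(TRUE, shape), rep(sp, 3), label = "CTV")
  list(dose = dose, mask = mask)
}

test_that("uniform and two-level doses yield the textbook DVH values", {
  shape <- c(10, 10, 10)
  mask <- structure_mask(array(TRUE, shape), c(2, 2, 2), label = "CTV")
  uni <- image_volume(array(600, shape), c(2, 2, 2))
  cv <- compute_dvh(uni, mask)
  expect_equal(cv$rel_volume[1], 100)
  expect_equal(cv$rel_volume[cv$dose_edges <= 600], rep(100, 61))
  expect_equal(cv$rel_volume[cv$dose_edges > 600], rep(0, sum(cv$dose_edges > 600)))
  expect_true(all(diff(cv$rel_volume) <= 0))
  expect_lt(abs(dose_at_relative_volume(cv, 98) - 600), 10)  # within one bin
  expect_equal(dose_at_absolute_volume(uni, mask, 3), 600)

  two <- image_volume(array(rep(c(600, 300), each = 500), shape), c(2, 2, 2))
  cv2 <- compute_dvh(two, mask)
  expect_equal(cv2$rel_volume[cv2$dose_edges == 450], 50)
  expect_equal(dose_at_relative_volume(cv2, 100), 300, tolerance = 10)
})

test_that("the hottest-subvolume metric follows the sorted-voxel oracle", {
  shape <- c(10, 10, 10)
  mask <- structure_mask(array(TRUE, shape), c(2, 2, 2), label = "bladder")
  # 2 cc at 700 + rest at 100; 1 cc sits entirely in the hot region
  nhot <- round(2 / (8 / 1000))
  dosev <- array(100, shape); dosev[seq_len(nhot)] <- 700
  dose <- image_volume(dosev, c(2, 2, 2))
  expect_equal(dose_at_absolute_volume(dose, mask, 1), 700)
  expect_error(dose_at_absolute_volume(dose, mask, 99), "not inside")

  rf <- ramp_fixture()
  vox_cc <- prod(rf$mask$spacing) / 1000
  d_sorted <- sort(rf$dose$array[rf$mask$array], decreasing = TRUE)
  oracle <- d_sorted[round(5 / vox_cc)]
  got <- dose_at_absolute_volume(rf$dose, rf$mask, 5)
  expect_lt(abs(got - oracle), max(diff(sort(unique(d_sorted)))) + 1e-9)
})

test_that("a linear ramp matches its closed-form DVH within one bin", {
  rf <- ramp_fixture()
  cv <- compute_dvh(rf$dose, rf$mask, bin_width = 10)
  inside <- cv$dose_edges <= 600
  analytic <- 100 * (1 - cv$dose_edges[inside] / 600)
  expect_lt(max(abs(cv$rel_volume[inside] - analytic)), 100 / 30 + 1e-9)
  expect_lt(abs(dose_at_relative_volume(cv, 50) - 300), 25)
  # metric consistency with a direct voxel quantile
  q <- as.numeric(quantile(rf$dose$array[rf$mask$array], 1 - 0.98))
  expect_lt(abs(dose_at_relative_volume(cv, 98) - q), 25)
})

test_that("delta-DVH is zero for identical curves, antisymmetric, and course-scaled", {
  rf <- ramp_fixture()
  c1 <- compute_dvh(rf$dose, rf$mask, dose_max = 700)
  dd0 <- delta_dvh(c1, c1)
  expect_true(all(dd0$delta_rel_volume == 0))
  shifted <- image_volume(rf$dose$array + 30, rf$dose$spacing)
  c2 <- compute_dvh(shifted, rf$mask, dose_max = 700)
  d12 <- delta_dvh(c1, c2)
  d21 <- delta_dvh(c2, c1)
  expect_equal(d12$delta_rel_volume, -d21$delta_rel_volume)
  expect_true(all(abs(d12$delta_rel_volume) <= 100))
  # course scaling multiplies per-fraction metric differences by exactly 5
  m <- dvh_metric_set(rf$dose, rf$mask, rf$mask)
  expect_equal(m$delta_course_cgy, 5 * m$delta_cgy)
  mask2 <- structure_mask(rf$mask$array, rf$mask$spacing, label = "CTV")
  p <- dvh_metric_set(shifted, mask2, mask2)
  expect_equal(p$delta_cgy, 0)
  # a +10 cGy per-fraction D98% difference scales to +50 cGy over the course
  d98_m <- dose_at_relative_volume(compute_dvh(rf$dose, rf$mask), 98)
  shifted10 <- image_volume(rf$dose$array + 10, rf$dose$spacing)
  d98_p <- dose_at_relative_volume(compute_dvh(shifted10, rf$mask), 98)
  expect_equal(5 * (d98_p - d98_m), 50, tolerance = 1e-9)
})

test_that("cohort bands are central percentile envelopes with nesting", {
  mk <- function(const) {
    structure(list(dose_edges = seq(0, 100, 10),
                   delta_rel_volume = rep(const, 11), scale_factor = 5),
              class = "delta_dvh")
  }
  same <- cohort_bands(list(mk(2), mk(2), mk(2)))
  expect_true(all(same$bands$lo_95 == 2 & same$bands$hi_95 == 2 &
                  same$bands$mean == 2))
  tri <- cohort_bands(list(mk(-1), mk(0), mk(1)))
  expect_equal(unique(tri$bands$lo_95), -0.95)
  expect_equal(unique(tri$bands$hi_95), 0.95)
  expect_equal(unique(tri$bands$mean), 0)
  set.seed(5)
  for (i in 1:20) {
    curves <- lapply(1:7, function(j) mk(rnorm(1, 0, 3)))
    cb <- cohort_bands(curves)$bands
    expect_true(all(cb$lo_95 <= cb$lo_50 & cb$lo_50 <= cb$lo_25 &
                    cb$hi_25 <= cb$hi_50 & cb$hi_50 <= cb$hi_95))
  }
  expect_error(cohort_bands(list(mk(1))), "at least 2")
  bad <- mk(1); bad$dose_edges <- seq(0, 50, 5)
  expect_error(cohort_bands(list(mk(1), bad)), "mismatched")
})

test_that("DVH rejects invalid inputs", {
  shape <- c(6, 6, 6)
  dose <- image_volume(array(100, shape), c(2, 2, 2))
  empty <- structure_mask(array(FALSE, shape), c(2, 2, 2), label = "CTV")
  expect_error(compute_dvh(dose, empty), "empty")
  c1 <- compute_dvh(dose, structure_mask(array(TRUE, shape), c(2, 2, 2),
                                         label = "CTV"))
  c2 <- c1; c2$dose_edges <- c1$dose_edges + 5
  expect_error(delta_dvh(c1, c2), "mismatched")
})
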