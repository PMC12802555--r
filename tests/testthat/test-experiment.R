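# Cohort orchestration: row contracts, determinism, zero channel, failure
# isolation, summaries.

fast_reg <- function(strategy, mode = "symmetric") {
  registration_config(strategy, struct_mode = mode, iterations = c(15, 8, 4))
}

tiny_config <- function(...) {
  experiment_config(
    n_patients = 1, n_fractions = 1, pairs = "A2B", strategies = "intensity",
    phantom = list(shape = c(48, 48, 40), spacing = c(4, 4, 3.2)),
    reg_configs = list(intensity = fast_reg("intensity"),
                       cs = fast_reg("cs"), cs_p = fast_reg("cs_p")),
    seed = 5, ...)
}

test_that("the long-form table has one row per patient/fraction/pair/strategy/organ", {
  rep1 <- run_experiment(tiny_config())
  expect_equal(nrow(rep1$metrics), 1 * 1 * 1 * 1 * 3)
  expect_setequal(rep1$metrics$organ, c("CTV", "bladder", "rectum"))
  expect_true(all(c("dsc", "dta_mean_cm", "dta_max_cm", "metric",
                    "delta_cgy", "delta_course_cgy") %in%
                  names(rep1$metrics)))
  expect_equal(nrow(rep1$curves), 3)
})

test_that("identical configs give bit-identical tables and resumable outputs", {
  r1 <- run_experiment(tiny_config())
  r2 <- run_experiment(tiny_config())
  expect_identical(r1$metrics, r2$metrics)

  tmp <- withr::local_tempdir()
  r3 <- run_experiment(tiny_config(output_dir = tmp))
  expect_true(file.exists(file.path(tmp, "patient_001_metrics.csv")))
  r4 <- run_experiment(tiny_config(output_dir = tmp))   # resumed from disk
  expect_equal(r4$metrics$dsc, r3$metrics$dsc, tolerance = 1e-9)
})

test_that("the zero-deformation channel is exactly clean through the whole pipeline", {
  cfg <- experiment_config(
    n_patients = 1, n_fractions = 1, pairs = c("R2B", "A2B"),
    strategies = c("intensity", "cs", "cs_p"),
    fill_range = c(1, 1), geometry_jitter = 0, contour_noise_mm = 0,
    phantom = list(shape = c(48, 48, 40), spacing = c(4, 4, 3.2),
                   rigid_offset = c(0, 0, 0), perturb_amplitude = 0,
                   noise_sigma = 0),
    reg_configs = list(intensity = fast_reg("intensity"),
                       cs = fast_reg("cs"), cs_p = fast_reg("cs_p")),
    seed = 2)
  rep0 <- run_experiment(cfg)
  expect_equal(nrow(rep0$metrics), 2 * 3 * 3)
  expect_true(all(rep0$metrics$dsc == 1))
  expect_true(all(rep0$metrics$dta_mean_cm == 0))
  expect_true(all(rep0$metrics$dta_max_cm == 0))
  expect_true(all(rep0$metrics$delta_cgy == 0))
  expect_true(all(rep0$metrics$delta_course_cgy == 0))
  expect_true(all(vapply(rep0$curves$curve,
                         function(c) all(c$delta_rel_volume == 0),
                         logical(1))))
})

test_that("a failing fraction is recorded and does not abort the cohort", {
  cfg <- tiny_config()
  cfg$phantom$shape <- c(20, 20, 16)   # organs cannot fit this grid
  rep_f <- run_experiment(cfg)
  expect_equal(nrow(rep_f$metrics), 0)
  expect_length(rep_f$manifest$failures, 1)
  expect_match(rep_f$manifest$failures[[1]]$message, "grid extent")
})

test_that("summaries match hand arithmetic and a brute-force recomputation", {
  df <- tibble::tibble(
    pair = "A2B", strategy = rep(c("a", "b"), c(1, 3)),
    organ = "CTV",
    dsc = c(0.5, 1, 2, 3), dta_mean_cm = 1, dta_max_cm = 2,
    delta_cgy = 0, delta_course_cgy = 0)
  s <- summarize_experiment(df)
  one <- s[s$strategy == "a", ]
  expect_equal(one$dsc_mean, 0.5)
  expect_equal(one$dsc_disp, 0)
  three <- s[s$strategy == "b", ]
  expect_equal(three$dsc_mean, 2)
  expect_equal(three$dsc_disp, 1)          # sample SD of {1,2,3}
  se <- summarize_experiment(df, dispersion = "se")
  expect_equal(se[se$strategy == "b", ]$dsc_disp, 1 / sqrt(3))

  rep1 <- run_experiment(tiny_config())
  s2 <- summarize_experiment(rep1)
  bf <- aggregate(dsc ~ pair + strategy + organ, rep1$metrics, mean)
  merged <- merge(bf, s2, by = c("pair", "strategy", "organ"))
  expect_equal(merged$dsc, merged$dsc_mean, tolerance = 1e-12)
})

test_that("report accessors expose tidy data and bands", {
  cfg <- tiny_config()
  cfg$n_patients <- 2L
  rep2 <- run_experiment(cfg)
  expect_identical(tidy(rep2), rep2$metrics)
  g <- glance(rep2)
  expect_equal(g$n_rows, nrow(rep2$metrics))
  b <- experiment_bands(rep2, "A2B", "intensity", "bladder")
  expect_s3_class(b, "cohort_bands")
  expect_equal(b$n_curves, 2)
  p <- autoplot(b)
  expect_s3_class(p, "ggplot")
  p2 <- plot_geometry_metrics(rep2, "A2B", "dsc")
  expect_s3_class(p2, "ggplot")
  p3 <- plot_dta_vs_fill(rep2, "A2B")
  expect_s3_class(p3, "ggplot")
})
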