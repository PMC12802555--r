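# Dose-volume-histogram analysis: cumulative relative-volume DVH extraction,
# DVH differences between propagated and manual contours (the dosimetric DIR
# error measure), clinical point metrics (CTV D98%, bladder D5cc, rectum
# D1cc), five-fraction course scaling, and cohort percentile bands.

#' Cumulative dose-volume histogram of a structure
#'
#' `rel_volume(d)` is the percentage of the structure volume receiving at
#' least dose `d`, evaluated at regularly spaced dose edges. The dose grid
#' must already live on the mask lattice (see [resample_volume()]).
#'
#' @param dose Dose [image_volume()] (cGy) on the mask lattice.
#' @param mask Nonempty [structure_mask()].
#' @param bin_width Dose bin width in cGy (default 10).
#' @param dose_max Upper edge of the histogram (cGy); defaults to just above
#'   the maximum in-mask dose. Fix it when curves from different structures
#'   must share edges (e.g. for [delta_dvh()]).
#' @return An object of class `dvh_curve` with `dose_edges` (cGy),
#'   `rel_volume` (%), and `abs_volume_cc`.
#' @export
compute_dvh <- function(dose, mask, bin_width = 10, dose_max = NULL) {
  assert_that(same_lattice(dose, mask),
              "compute_dvh: dose must be resampled to the mask lattice")
  assert_that(any(mask$array), "compute_dvh: empty mask")
  d <- dose$array[mask$array]
  edges <- seq(0, (dose_max %||% max(d)) + 2 * bin_width, by = bin_width)
  rel <- 100 * (1 - stats::ecdf(d)(edges - 1e-9))  # P(dose >= edge)
  structure(list(dose_edges = edges, rel_volume = rel,
                 abs_volume_cc = volume_cc(mask),
                 doses = sort(d, decreasing = TRUE),
                 voxel_cc = prod(mask$spacing) / 1000),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %.1f cc, dose 0..%.0f cGy in %d edges\n",
              x$abs_volume_cc, max(x$dose_edges), length(x$dose_edges)))
  invisible(x)
}

#' Dose received by the hottest x% of a structure (Dx%)
#'
#' Largest dose `d` whose relative volume is still at least `x`, linearly
#' interpolated between the DVH edges. `x = 100` returns the minimum in-mask
#' dose.
#'
#' @param curve A [compute_dvh()] curve.
#' @param x Relative volume in percent, `0 < x <= 100`.
#' @return Dose in cGy.
#' @export
dose_at_relative_volume <- function(curve, x) {
  assert_that(x > 0 && x <= 100, "relative volume must be in (0, 100]")
  e <- curve$dose_edges; v <- curve$rel_volume
  if (v[1] < x) return(e[1])
  k <- max(which(v >= x))
  if (k == length(v) || v[k] == x) return(e[k])
  # interpolate within the edge interval where rel_volume crosses x
  e[k] + (v[k] - x) / (v[k] - v[k + 1]) * (e[k + 1] - e[k])
}

#' Minimum dose to the hottest v cc of a structure (Dvcc)
#'
#' Sorted-voxel partial sum with fractional-voxel interpolation: the dose at
#' which the cumulative hottest volume reaches `v` cm^3.
#'
#' @param dose Dose [image_volume()] on the mask lattice.
#' @param mask Nonempty [structure_mask()].
#' @param v Absolute volume in cc, strictly less than the structure volume.
#' @return Dose in cGy.
#' @export
dose_at_absolute_volume <- function(dose, mask, v) {
  assert_that(same_lattice(dose, mask), "dose must be on the mask lattice")
  vol <- volume_cc(mask)
  assert_that(v > 0 && v < vol,
              "requested volume %.2f cc not inside (0, %.2f) cc", v, vol)
  d <- sort(dose$array[mask$array], decreasing = TRUE)
  vox_cc <- prod(mask$spacing) / 1000
  n_frac <- v / vox_cc
  k <- floor(n_frac)
  if (k < 1) return(d[1])
  if (k >= length(d)) return(d[length(d)])
  d[k] + (n_frac - k) * (d[k + 1] - d[k])
}

#' Difference of two relative-volume DVHs
#'
#' Pointwise `propagated - manual` difference in percentage points of relative
#' volume. Per-fraction dose-metric differences scale linearly by
#' `scale_factor` (default 5) to represent the full five-fraction course.
#'
#' @param propagated,manual [compute_dvh()] curves on identical dose edges.
#' @param scale_factor Course scaling factor (default 5).
#' @return An object of class `delta_dvh`.
#' @export
delta_dvh <- function(propagated, manual, scale_factor = 5) {
  n <- min(length(propagated$dose_edges), length(manual$dose_edges))
  assert_that(isTRUE(all.equal(propagated$dose_edges[1:n],
                               manual$dose_edges[1:n])),
              "delta_dvh: DVH curves have mismatched dose edges")
  pad <- function(v) c(v, rep(0, n - min(n, length(v))))[1:n]
  structure(list(dose_edges = propagated$dose_edges[1:n],
                 delta_rel_volume = pad(propagated$rel_volume) -
                   pad(manual$rel_volume),
                 scale_factor = scale_factor),
            class = "delta_dvh")
}

#' @export
print.delta_dvh <- function(x, ...) {
  cat(sprintf("<delta_dvh> max |delta| %.2f pp over %d edges (course scale %g)\n",
              max(abs(x$delta_rel_volume)), length(x$dose_edges),
              x$scale_factor))
  invisible(x)
}

#' Clinical DVH metric set for one propagated/manual contour pair
#'
#' Computes the paper-style point metrics for the organ at hand: CTV D98%
#' (relative), bladder D5cc, rectum D1cc (absolute), for both contours, with
#' per-fraction and course-scaled differences (propagated minus manual).
#'
#' @param dose Dose [image_volume()] on the mask lattice.
#' @param propagated,manual [structure_mask()]s of the same organ.
#' @param scale_factor Course scaling (default 5 fractions).
#' @param bin_width DVH bin width in cGy.
#' @return One-row tibble: `organ`, `metric`, `manual_cgy`, `propagated_cgy`,
#'   `delta_cgy`, `delta_course_cgy`.
#' @export
dvh_metric_set <- function(dose, propagated, manual, scale_factor = 5,
                           bin_width = 10) {
  organ <- manual$label
  value <- function(mask) {
    switch(organ,
           CTV = dose_at_relative_volume(compute_dvh(dose, mask, bin_width), 98),
           bladder = dose_at_absolute_volume(dose, mask, 5),
           rectum = dose_at_absolute_volume(dose, mask, 1))
  }
  metric <- switch(organ, CTV = "D98%", bladder = "D5cc", rectum = "D1cc")
  m <- value(manual); p <- value(propagated)
  tibble::tibble(organ = organ, metric = metric, manual_cgy = m,
                 propagated_cgy = p, delta_cgy = p - m,
                 delta_course_cgy = scale_factor * (p - m))
}

#' Cohort percentile bands of delta-DVH curves
#'
#' Per-edge central percentile envelopes (for level L, the `(100-L)/2` to
#' `(100+L)/2` percentiles, linearly interpolated between order statistics)
#' and the pointwise mean across curves.
#'
#' @param curves List of at least two [delta_dvh()] curves on identical edges.
#' @param levels Band levels in percent (default `c(95, 50, 25)`).
#' @return An object of class `cohort_bands`: tibble `bands` with columns
#'   `dose_cgy`, `mean`, and `lo_<level>`/`hi_<level>` pairs.
#' @export
cohort_bands <- function(curves, levels = c(95, 50, 25)) {
  assert_that(length(curves) >= 2, "cohort_bands needs at least 2 curves")
  edges <- curves[[1]]$dose_edges
  for (c in curves)
    assert_that(isTRUE(all.equal(c$dose_edges, edges)),
                "cohort_bands: curves on mismatched dose edges")
  mat <- vapply(curves, function(c) c$delta_rel_volume,
                numeric(length(edges)))
  out <- tibble::tibble(dose_cgy = edges, mean = rowMeans(mat))
  for (L in levels) {
    pr <- c((100 - L) / 2, (100 + L) / 2) / 100
    q <- apply(mat, 1, quantile, probs = pr, names = FALSE)
    out[[sprintf("lo_%g", L)]] <- q[1, ]
    out[[sprintf("hi_%g", L)]] <- q[2, ]
  }
  structure(list(bands = out, levels = sort(levels, decreasing = TRUE),
                 n_curves = length(curves)),
            class = "cohort_bands")
}

#' @export
print.cohort_bands <- function(x, ...) {
  cat(sprintf("<cohort_bands> %d curves, levels %s%%\n", x$n_curves,
              paste(x$levels, collapse = "/")))
  invisible(x)
}

#' Write a DVH or delta-DVH curve as CSV
#'
#' @param curve A `dvh_curve` or `delta_dvh`.
#' @param path File path.
#' @export
write_dvh_csv <- function(curve, path) {
  df <- if (inherits(curve, "delta_dvh"))
    data.frame(dose_cgy = curve$dose_edges,
               delta_rel_volume_pp = curve$delta_rel_volume)
  else
    data.frame(dose_cgy = curve$dose_edges, rel_volume_pct = curve$rel_volume)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
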