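# Geometric agreement between propagated and manual contours. Surfaces are
# the voxel-face boundaries at native spacing; distances are exact Euclidean
# distances between boundary voxel centres (distance transform based, which
# for centre-to-centre distances is identical to exhaustive nearest-neighbour
# search). DTA values are reported in cm to match clinical convention.

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)` over voxel sets; symmetric in its arguments.
#'
#' @param a,b [structure_mask()]s on congruent lattices.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  assert_that(same_lattice(a, b), "dice: masks on different lattices")
  na <- sum(a$array); nb <- sum(b$array)
  assert_that(na + nb > 0, "dice undefined for two empty masks")
  2 * sum(a$array & b$array) / (na + nb)
}

#' Mean and maximum distance to agreement between two contours
#'
#' Boundary point sets are the centres of voxel-face boundary voxels of each
#' mask. Directed distances are computed with an exact Euclidean distance
#' transform of the opposite boundary; `dta_mean` averages the two directed
#' mean distances and `dta_max` is the symmetric Hausdorff distance (maximum
#' over both directed maxima). One-sided variants measure only a -> b.
#'
#' @param a,b Nonempty [structure_mask()]s on congruent lattices.
#' @param symmetric If `FALSE`, return the one-sided (a to b) statistics.
#' @return Named list with `dta_mean` and `dta_max`, in cm.
#' @export
surface_distance_stats <- function(a, b, symmetric = TRUE) {
  assert_that(same_lattice(a, b), "masks on different lattices")
  assert_that(any(a$array) && any(b$array),
              "surface distance undefined for an empty mask")
  ba <- boundary_voxels(a$array)
  bb <- boundary_voxels(b$array)
  dt_b <- distance_to(bb, b$spacing)
  d_ab <- dt_b[ba]
  if (!symmetric)
    return(list(dta_mean = mean(d_ab) / 10, dta_max = max(d_ab) / 10))
  dt_a <- distance_to(ba, a$spacing)
  d_ba <- dt_a[bb]
  list(dta_mean = (mean(d_ab) + mean(d_ba)) / 2 / 10,
       dta_max = max(max(d_ab), max(d_ba)) / 10)
}

#' Full geometric comparison record for one propagated contour
#'
#' @param propagated,manual [structure_mask()]s to compare.
#' @param organ Organ label recorded in the row (defaults to the mask label).
#' @param pair Image-pair tag, one of `"R2A"`, `"R2V"`, `"R2B"`, `"A2V"`,
#'   `"A2B"`.
#' @param strategy Optional DIR strategy tag.
#' @return One-row tibble with `dsc`, `dta_mean_cm`, `dta_max_cm`.
#' @export
contour_comparison <- function(propagated, manual, organ = NULL,
                               pair = NA_character_,
                               strategy = NA_character_) {
  if (!is.na(pair))
    assert_that(pair %in% c("R2A", "R2V", "R2B", "A2V", "A2B"),
                "unknown image-pair tag '%s'", pair)
  sds <- surface_distance_stats(propagated, manual)
  tibble::tibble(pair = pair, strategy = strategy,
                 organ = organ %||% manual$label %||% propagated$label,
                 dsc = dice(propagated, manual),
                 dta_mean_cm = sds$dta_mean, dta_max_cm = sds$dta_max)
}
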