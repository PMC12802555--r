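#' Binary organ mask on an image lattice
#'
#' A binary structure mask tied to the lattice of a parent [image_volume()].
#' Only the three organs evaluated in the pelvic workflow are valid labels:
#' `"CTV"` (prostate clinical target volume), `"bladder"`, and `"rectum"`.
#'
#' @param array Logical (or 0/1) 3D array.
#' @param spacing,origin Lattice geometry, as for [image_volume()].
#' @param label Organ label, one of `"CTV"`, `"bladder"`, `"rectum"`.
#' @return An object of class `structure_mask` (also an `image_volume`).
#' @export
structure_mask <- function(array, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                           label = c("CTV", "bladder", "rectum")) {
  label <- match.arg(label)
  arr <- array(as.logical(array), dim(array))
  vol <- image_volume(arr, spacing, origin)
  vol$label <- label
  class(vol) <- c("structure_mask", class(vol))
  vol
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> %s: %d voxels (%.2f cc) on %s grid @ %s mm\n",
              x$label, sum(x$array), volume_cc(x),
              paste(dim(x$array), collapse = "x"),
              paste(format(x$spacing, trim = TRUE), collapse = "x")))
  invisible(x)
}

#' Absolute structure volume in cubic centimetres
#'
#' Voxel count times voxel volume.
#'
#' @param mask A [structure_mask()].
#' @return Volume in cc.
#' @export
volume_cc <- function(mask) {
  sum(mask$array) * prod(mask$spacing) / 1000
}

#' @rdname write_volume
#' @param mask A [structure_mask()].
#' @param label Organ label used when reading a mask.
#' @export
write_mask <- function(mask, path) {
  write_volume(image_volume(array(as.numeric(mask$array), dim(mask$array)),
                            mask$spacing, mask$origin), path)
}

#' @rdname write_volume
#' @export
read_mask <- function(path, label) {
  vol <- read_volume(path)
  structure_mask(vol$array > 0.5, vol$spacing, vol$origin, label)
}

# Boundary voxels: foreground voxels with at least one 6-connected background
# neighbour (grid faces are the surface definition used by the metrics).
boundary_voxels <- function(arr) {
  d <- dim(arr)
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
        pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
        pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  core & !nb
}
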