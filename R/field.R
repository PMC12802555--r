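#' Dense displacement field
#'
#' Vector field on the fixed-image lattice. The convention throughout the
#' package is the pull-back one: a fixed-image world point `x` corresponds to
#' the moving-image point `x + u(x)`, with `u` in mm. Contours and images are
#' propagated from moving to fixed by reading the moving data at `x + u(x)`.
#'
#' @param vectors 4D numeric array `nx x ny x nz x 3` of displacements (mm).
#' @param spacing,origin Fixed-lattice geometry, as for [image_volume()].
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(vectors, spacing = c(1, 1, 1),
                               origin = c(0, 0, 0)) {
  d <- dim(vectors)
  assert_that(length(d) == 4 && d[4] == 3,
              "displacement_field: vectors must be nx x ny x nz x 3")
  assert_that(all(is.finite(vectors)),
              "displacement_field: vectors must be finite everywhere")
  structure(list(vectors = vectors, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  m <- sqrt(rowSums(matrix(x$vectors, ncol = 3)^2))
  cat(sprintf("<displacement_field> %s @ %s mm; |u| mean %.2f, max %.2f mm\n",
              paste(dim(x$vectors)[1:3], collapse = "x"),
              paste(format(x$spacing, trim = TRUE), collapse = "x"),
              mean(m), max(m)))
  invisible(x)
}

# All-zero field on the lattice of `like` (an image_volume).
zero_field <- function(like) {
  displacement_field(array(0, c(dim(like$array), 3)), like$spacing, like$origin)
}

field_component <- function(field, c) {
  image_volume(field$vectors[, , , c], field$spacing, field$origin)
}

# Interpolate the field at world points; N x 3 matrix of u(p) in mm.
sample_field <- function(field, pts) {
  cbind(sample_volume(field_component(field, 1), pts),
        sample_volume(field_component(field, 2), pts),
        sample_volume(field_component(field, 3), pts))
}

#' Map a world point through a displacement field
#'
#' Returns `p + u(p)` with trilinear interpolation of the field. Points must
#' lie inside the fixed grid.
#'
#' @param p N x 3 matrix (or length-3 vector) of world coordinates in mm.
#' @param field A [displacement_field()].
#' @return N x 3 matrix of mapped world coordinates (mm).
#' @export
warp_point <- function(p, field) {
  p <- rbind(p)
  idx <- world_to_index(field, p)
  d <- dim(field$vectors)[1:3]
  inside <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
            idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
            idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
  assert_that(all(inside), "warp_point: %d point(s) outside the fixed grid",
              sum(!inside))
  p + sample_field(field, p)
}

#' Warp a moving image onto the fixed lattice
#'
#' Pull-back warping: the output voxel at fixed world position `x` takes the
#' trilinearly interpolated moving value at `x + u(x)`. Points mapped outside
#' the moving grid read `fill`.
#'
#' @param vol Moving [image_volume()].
#' @param field A [displacement_field()] on the fixed lattice.
#' @param fill Background fill value.
#' @return An [image_volume()] on the fixed lattice.
#' @export
warp_volume <- function(vol, field, fill = 0) {
  pts <- lattice_world(field_component(field, 1)) +
    matrix(field$vectors, ncol = 3)
  vals <- sample_volume(vol, pts, fill = fill)
  image_volume(array(vals, dim(field$vectors)[1:3]), field$spacing,
               field$origin)
}

#' Propagate a contour through a displacement field
#'
#' Pull-back mask warping: the binary moving mask is interpolated trilinearly
#' at `x + u(x)` and thresholded at 0.5. Points mapped outside the moving grid
#' read as background.
#'
#' @param mask Moving [structure_mask()].
#' @param field A [displacement_field()] on the fixed lattice.
#' @return A [structure_mask()] on the fixed lattice.
#' @export
warp_mask <- function(mask, field) {
  vol <- image_volume(array(as.numeric(mask$array), dim(mask$array)),
                      mask$spacing, mask$origin)
  w <- warp_volume(vol, field, fill = 0)
  structure_mask(w$array >= 0.5, field$spacing, field$origin, mask$label)
}

#' Read and write displacement fields as 3-component NIfTI
#'
#' @param field A [displacement_field()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @export
write_field <- function(field, path) {
  img <- RNifti::asNifti(field$vectors)
  RNifti::pixdim(img) <- c(field$spacing, 1)
  aff <- diag(c(field$spacing, 1))
  aff[1:3, 4] <- field$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  displacement_field(array(as.numeric(img), dim(img)),
                     spacing = abs(diag(aff)[1:3]),
                     origin = as.numeric(aff[1:3, 4]))
}
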