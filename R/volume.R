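#' 3D scalar image volume
#'
#' Lightweight carrier for a 3D scalar grid with physical geometry: per-axis
#' voxel spacing and the world coordinate of the centre of voxel `(0, 0, 0)`.
#' World coordinates follow the voxel-centred convention: voxel index `i`
#' (0-based) sits at `origin + i * spacing` (mm). Used both for MR-like
#' intensity images (arbitrary units) and dose grids (cGy).
#'
#' @param array Numeric 3D array.
#' @param spacing Length-3 positive numeric, voxel size in mm.
#' @param origin Length-3 numeric, world position (mm) of voxel (0,0,0).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(array, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  assert_that(length(dim(array)) == 3, "image_volume: array must be 3D")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  assert_that(length(spacing) == 3 && all(spacing > 0),
              "image_volume: spacing must be 3 strictly positive values")
  assert_that(length(origin) == 3, "image_volume: origin must have length 3")
  structure(list(array = array, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels @ %s mm, origin (%s) mm\n",
              paste(dim(x$array), collapse = "x"),
              paste(format(x$spacing, trim = TRUE), collapse = "x"),
              paste(format(x$origin, trim = TRUE), collapse = ", ")))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$array)

# TRUE if two volumes live on the same lattice.
same_lattice <- function(a, b, tol = 1e-6) {
  all(dim(a$array) == dim(b$array)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Convert between world (mm) and continuous voxel-index coordinates
#'
#' @param vol An [image_volume()].
#' @param pts N x 3 matrix of points.
#' @return N x 3 matrix in the other coordinate system (0-based indices).
#' @export
world_to_index <- function(vol, pts) {
  pts <- rbind(pts)
  sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/")
}

#' @rdname world_to_index
#' @export
index_to_world <- function(vol, pts) {
  pts <- rbind(pts)
  sweep(sweep(pts, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

# World coordinates (mm) of every voxel centre, as an N x 3 matrix in
# column-major voxel order.
lattice_world <- function(vol) {
  d <- dim(vol$array)
  i <- seq_len(d[1]) - 1; j <- seq_len(d[2]) - 1; k <- seq_len(d[3]) - 1
  cbind(rep(vol$origin[1] + i * vol$spacing[1], times = d[2] * d[3]),
        rep(rep(vol$origin[2] + j * vol$spacing[2], each = d[1]), times = d[3]),
        rep(vol$origin[3] + k * vol$spacing[3], each = d[1] * d[2]))
}

#' Sample a volume at arbitrary world points by trilinear interpolation
#'
#' @param vol An [image_volume()].
#' @param pts N x 3 matrix of world coordinates (mm).
#' @param fill Value returned for points outside the grid.
#' @return Numeric vector of length N.
#' @export
sample_volume <- function(vol, pts, fill = 0) {
  idx <- world_to_index(vol, pts)
  cpp_trilinear(as.numeric(vol$array), dim(vol$array), idx, fill)
}

#' Resample a volume onto another lattice
#'
#' Trilinear resampling of `vol` onto the lattice of `like` (an
#' [image_volume()]); values outside `vol` read `fill`.
#'
#' @param vol Volume to resample.
#' @param like Volume whose lattice defines the output grid.
#' @param fill Out-of-grid fill value.
#' @return An [image_volume()] on the lattice of `like`.
#' @export
resample_volume <- function(vol, like, fill = 0) {
  vals <- sample_volume(vol, lattice_world(like), fill = fill)
  image_volume(array(vals, dim(like$array)), like$spacing, like$origin)
}

# Euclidean distance transform helpers ---------------------------------------

# Distance (mm) from every voxel centre to the nearest TRUE voxel centre.
distance_to <- function(mask_array, spacing) {
  assert_that(any(mask_array), "distance transform of an empty mask")
  array(cpp_edt3d(as.logical(mask_array), dim(mask_array), spacing),
        dim(mask_array))
}

# Signed distance: negative inside the mask, positive outside (mm).
signed_distance <- function(mask_array, spacing) {
  assert_that(any(mask_array) && !all(mask_array),
              "signed distance needs both foreground and background")
  distance_to(mask_array, spacing) - distance_to(!mask_array, spacing)
}

# Separable Gaussian smoothing with sigma given in mm.
gauss_smooth <- function(arr, sigma_mm, spacing) {
  sig <- rep(sigma_mm, length.out = 3) / spacing
  array(cpp_gauss_smooth(as.numeric(arr), dim(arr), sig), dim(arr))
}

# NIfTI IO --------------------------------------------------------------------

#' Read and write image volumes as NIfTI
#'
#' Round-trips the voxel array, spacing, and origin through a NIfTI-1 file
#' (`.nii` or `.nii.gz`) using an axis-aligned affine.
#'
#' @param vol An [image_volume()].
#' @param path File path.
#' @return `read_volume` returns an [image_volume()]; `write_volume` returns
#'   `path` invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$array)
  RNifti::pixdim(img) <- vol$spacing   # before the forms: scales live here
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  image_volume(array(as.numeric(img), dim(img)[1:3]),
               spacing = abs(diag(aff)[1:3]),
               origin = as.numeric(aff[1:3, 4]))
}
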