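# Synthetic pelvic phantom: seeded sessions (reference + adapt/verify/beam-on)
# with ground-truth deformation fields, organ masks, MR-like intensities, and
# a conformal per-fraction dose. The dominant deformation mode is bladder
# filling, modelled as a radial expansion about the bladder centre with smooth
# compact-support falloff, composed with a low-frequency random perturbation
# and a small rigid setup offset.

SESSION_ROLES <- c("reference", "adapt", "verify", "beam_on")

# Fraction of the requested bladder fill reached at each session role:
# a small inter-fraction change at adapt, continued filling at verify, and
# the largest bladder at beam-on (filling over the adaptive session).
ROLE_FILL_WEIGHT <- c(reference = 0, adapt = 0.25, verify = 0.5, beam_on = 1)

#' Phantom specification
#'
#' Parameters of the synthetic pelvic scene: grid geometry, organ shapes and
#' placement, the target bladder fill, deformation nuisance terms, MR-like
#' tissue intensities, and the RNG seed. All lengths in mm, intensities in
#' arbitrary units, dose in cGy.
#'
#' @param shape Grid size in voxels (length 3).
#' @param spacing Voxel size in mm (length 3).
#' @param ctv_axes,bladder_axes Ellipsoid semi-axes (mm) of the prostate-analog
#'   CTV and the bladder at reference.
#' @param rectum_radius,rectum_length Rectum tube radius and length (mm); the
#'   tube runs along the third (superior-inferior) axis with rounded caps.
#' @param ctv_offset,bladder_offset,rectum_offset Organ centre offsets (mm)
#'   from the grid centre.
#' @param bladder_fill_factor Target beam-on/reference bladder volume ratio.
#' @param rigid_offset Rigid setup offset (mm) applied to all fraction images.
#' @param perturb_amplitude RMS amplitude (mm) of the smooth random
#'   deformation added on top of bladder filling.
#' @param perturb_corr_len Correlation length (mm) of that perturbation.
#' @param intensity_means Named tissue-class means (background, CTV, bladder,
#'   rectum).
#' @param noise_sigma Additive Gaussian intensity noise SD.
#' @param prescription Per-fraction prescription dose (cGy); the default 600
#'   corresponds to 30 Gy in five fractions.
#' @param dose_spacing Dose-grid voxel size in mm (isotropic).
#' @param seed Integer seed; the whole session is deterministic given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96, 96, 64),
                         spacing = c(2, 2, 2),
                         ctv_axes = c(21, 19, 17),
                         bladder_axes = c(30, 26, 26),
                         rectum_radius = 11,
                         rectum_length = 100,
                         ctv_offset = c(0, 11, -29),
                         bladder_offset = c(0, -25, 15),
                         rectum_offset = c(0, 43, -3),
                         bladder_fill_factor = 1.5,
                         rigid_offset = c(1.5, 1.5, 1),
                         perturb_amplitude = 1.5,
                         perturb_corr_len = 40,
                         intensity_means = c(background = 100, CTV = 170,
                                             bladder = 230, rectum = 60),
                         noise_sigma = 8,
                         prescription = 600,
                         dose_spacing = 3,
                         seed = 1L) {
  assert_that(bladder_fill_factor > 0, "bladder_fill_factor must be > 0")
  assert_that(noise_sigma >= 0, "noise_sigma must be >= 0")
  assert_that(perturb_amplitude >= 0, "perturb_amplitude must be >= 0")
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               ctv_axes = ctv_axes, bladder_axes = bladder_axes,
               rectum_radius = rectum_radius, rectum_length = rectum_length,
               ctv_offset = ctv_offset, bladder_offset = bladder_offset,
               rectum_offset = rectum_offset,
               bladder_fill_factor = bladder_fill_factor,
               rigid_offset = as.numeric(rigid_offset),
               perturb_amplitude = perturb_amplitude,
               perturb_corr_len = perturb_corr_len,
               intensity_means = intensity_means,
               noise_sigma = noise_sigma,
               prescription = prescription,
               dose_spacing = dose_spacing,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

# Geometry helpers ------------------------------------------------------------

grid_center <- function(spec) (spec$shape - 1) / 2 * spec$spacing

organ_centers <- function(spec) {
  gc <- grid_center(spec)
  list(CTV = gc + spec$ctv_offset,
       bladder = gc + spec$bladder_offset,
       rectum = gc + spec$rectum_offset)
}

# Analytic inside tests at reference anatomy; pts is an N x 3 world matrix.
inside_organ <- function(spec, organ, pts) {
  ctr <- organ_centers(spec)[[organ]]
  if (organ == "CTV" || organ == "bladder") {
    ax <- if (organ == "CTV") spec$ctv_axes else spec$bladder_axes
    xi <- sweep(sweep(pts, 2, ctr, "-"), 2, ax, "/")
    rowSums(xi^2) <= 1
  } else {
    d <- sweep(pts, 2, ctr, "-")
    half <- spec$rectum_length / 2 - spec$rectum_radius
    dz <- pmax(abs(d[, 3]) - half, 0)  # rounded tube caps
    d[, 1]^2 + d[, 2]^2 + dz^2 <= spec$rectum_radius^2
  }
}

# Smooth band-limited random vector field with vector RMS `amp_rms` (mm) and
# correlation length `corr_len` (mm). Each sinusoidal mode's direction is
# perpendicular to its wave vector, so the field is divergence-free and
# (to first order) volume preserving: deformation noise moves organs without
# inflating or deflating them. Returns function(pts N x 3) -> N x 3 (mm).
smooth_vector_field <- function(amp_rms, corr_len, seed, n_modes = 6) {
  if (amp_rms <= 0) return(function(pts) matrix(0, nrow(pts), 3))
  par <- with_seed(seed, {
    k <- matrix(rnorm(n_modes * 3), ncol = 3)
    k <- k / sqrt(rowSums(k^2)) / corr_len      # |k| = 1/corr_len
    e <- matrix(rnorm(n_modes * 3), ncol = 3)
    e <- e - k * (rowSums(e * k) / rowSums(k * k))   # project e perp k
    e <- e / sqrt(rowSums(e^2))
    list(k = k, e = e, phase = runif(n_modes, 0, 2 * pi))
  })
  a <- amp_rms * sqrt(2 / n_modes)              # sin has RMS 1/sqrt(2)
  function(pts) {
    out <- matrix(0, nrow(pts), 3)
    for (m in 1:n_modes) {
      s <- a * sin(2 * pi * (pts %*% par$k[m, ]) + par$phase[m])
      out <- out + s %*% t(par$e[m, , drop = TRUE])
    }
    out
  }
}

# Radial bladder-filling pull-back: maps session points to reference points.
# In normalised coordinates (bladder = unit ellipsoid at reference) the
# session bladder occupies rho <= s with s = fill^(1/3); interior points scale
# uniformly (g = rho/s), and exterior points follow g(rho)^3 = rho^3 + 1 - s^3,
# the unique radial profile whose deformation is exactly volume preserving:
# the surroundings are displaced, not inflated or deflated, like the
# incompressible tissue around a filling bladder. Displacement decays as
# 1/rho^2; the map is continuous, radially monotone, and invertible.
bladder_pullback <- function(spec, fill) {
  s <- fill^(1 / 3)
  ctr <- organ_centers(spec)$bladder
  a <- spec$bladder_axes
  # Filling is base-sparing: the expansion centre sits toward the bladder base
  # (anchored at the trigone next to the prostate) inside a metric elongated
  # along the superior-inferior axis, so the dome rises about 2.3x more than
  # the base descends -- the dominant clinical filling pattern. The radial
  # profile is linear (uniform scaling by s) over a zone covering the whole
  # bladder and exactly volume preserving outside it (g^3 = rho^3 + const).
  b <- c(a[1], a[2], 1.4 * a[3])          # expansion metric semi-axes
  c_exp <- ctr - c(0, 0, 0.4 * a[3])      # base-ward expansion centre
  rho_lin <- 1.1                          # linear zone: reference rho <= 1.1
  function(pts) {
    xi <- sweep(sweep(pts, 2, c_exp, "-"), 2, b, "/")
    rho <- pmax(sqrt(rowSums(xi^2)), 1e-12)
    g <- ifelse(rho <= s * rho_lin, rho / s,
                (rho^3 + rho_lin^3 * (1 - s^3))^(1 / 3))
    ref <- sweep(xi * (g / rho), 2, b, "*")
    sweep(ref, 2, c_exp, "+")
  }
}

# Pull-back map for a session role: T(x) = session point x -> reference point.
role_pullback <- function(spec, role) {
  wfill <- ROLE_FILL_WEIGHT[[role]]
  fill <- 1 + wfill * (spec$bladder_fill_factor - 1)
  bl <- bladder_pullback(spec, fill)
  pert <- if (role == "reference") NULL else
    smooth_vector_field(spec$perturb_amplitude, spec$perturb_corr_len,
                        derive_seed(spec$seed, "perturb", role))
  rigid <- if (role == "reference") c(0, 0, 0) else spec$rigid_offset
  function(pts) {
    ref <- bl(pts)
    if (!is.null(pert)) ref <- ref + pert(pts)
    sweep(ref, 2, rigid, "+")
  }
}

check_spec_fits_grid <- function(spec) {
  extent <- (spec$shape - 1) * spec$spacing
  margin <- 3 * spec$perturb_amplitude + max(abs(spec$rigid_offset))
  s <- max(1, spec$bladder_fill_factor)^(1 / 3)
  ctrs <- organ_centers(spec)
  reach <- list(CTV = spec$ctv_axes,
                bladder = c(1.05 * s * spec$bladder_axes[1:2],
                            spec$bladder_axes[3] * (1.4 * s - 0.4)),
                rectum = c(spec$rectum_radius, spec$rectum_radius,
                           spec$rectum_length / 2))
  for (org in names(ctrs)) {
    lo <- ctrs[[org]] - reach[[org]] - margin
    hi <- ctrs[[org]] + reach[[org]] + margin
    if (any(lo < 0) || any(hi > extent))
      stopf("phantom organ '%s' exceeds the grid extent (reach %s..%s mm vs 0..%s); enlarge the grid or shrink the organ",
            org, paste(round(lo), collapse = "/"),
            paste(round(hi), collapse = "/"),
            paste(round(extent), collapse = "/"))
  }
  invisible(TRUE)
}

# Session generation ----------------------------------------------------------

#' Generate a synthetic pelvic session
#'
#' Builds the four session images (reference, adapt, verify, beam-on) with
#' organ masks, per-role ground-truth displacement fields (session lattice to
#' reference, the package's pull-back convention), and a per-fraction dose
#' grid for each role. Fully deterministic given the spec (including its
#' seed). Bladder volume grows along the session according to
#' `bladder_fill_factor`; the CTV and rectum only move and deform mildly.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_session` with elements `spec`,
#'   `images`, `masks` (per role, per organ), `dose` (per role, 3 mm grid),
#'   and `gt_field` (per role).
#' @export
generate_phantom <- function(spec) {
  assert_that(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  check_spec_fits_grid(spec)
  proto <- image_volume(array(0, spec$shape), spec$spacing, c(0, 0, 0))
  pts <- lattice_world(proto)

  session <- list(spec = spec, images = list(), masks = list(),
                  dose = list(), gt_field = list())
  class(session) <- "phantom_session"

  for (role in SESSION_ROLES) {
    Tmap <- role_pullback(spec, role)
    ref_pts <- Tmap(pts)
    gt <- displacement_field(array(ref_pts - pts, c(spec$shape, 3)),
                             spec$spacing, c(0, 0, 0))
    masks <- list()
    for (org in c("CTV", "bladder", "rectum")) {
      if (role == "reference") {
        # analytic reference segmentation, discretised at voxel centres
        inside <- inside_organ(spec, org, ref_pts)
        masks[[org]] <- structure_mask(array(inside, spec$shape), spec$spacing,
                                       c(0, 0, 0), org)
      } else {
        # session contours are the reference segmentation propagated through
        # the ground-truth field, so field and contours are exactly consistent
        masks[[org]] <- warp_mask(session$masks$reference[[org]], gt)
      }
    }
    if (role == "reference") {
      overlap <- (masks$CTV$array & masks$bladder$array) |
                 (masks$CTV$array & masks$rectum$array) |
                 (masks$bladder$array & masks$rectum$array)
      assert_that(!any(overlap), "phantom organs overlap at generation")
    }
    mu <- spec$intensity_means
    img <- array(mu[["background"]], spec$shape)
    img[masks$rectum$array] <- mu[["rectum"]]
    img[masks$CTV$array] <- mu[["CTV"]]
    img[masks$bladder$array] <- mu[["bladder"]]
    if (spec$noise_sigma > 0) {
      noise <- with_seed(derive_seed(spec$seed, "noise", role),
                         rnorm(length(img), 0, spec$noise_sigma))
      img <- img + array(noise, spec$shape)
    }
    session$images[[role]] <- image_volume(img, spec$spacing, c(0, 0, 0))
    session$masks[[role]] <- masks
    session$gt_field[[role]] <- gt
  }
  for (role in SESSION_ROLES)
    session$dose[[role]] <- generate_dose(session, role, spec$prescription)
  session
}

#' @export
print.phantom_session <- function(x, ...) {
  cat(sprintf("<phantom_session> seed %d, bladder fill factor %.2f\n",
              x$spec$seed, x$spec$bladder_fill_factor))
  for (role in SESSION_ROLES)
    cat(sprintf("  %-9s CTV %5.1f cc  bladder %5.1f cc  rectum %5.1f cc\n",
                role, volume_cc(x$masks[[role]]$CTV),
                volume_cc(x$masks[[role]]$bladder),
                volume_cc(x$masks[[role]]$rectum)))
  invisible(x)
}

#' Generate a conformal per-fraction dose grid
#'
#' A prescription-level plateau covering the CTV plus margin with a monotone
#' sigmoidal fall-off outside, computed on an isotropic dose grid (3 mm by
#' default) from the signed distance to the role's CTV surface. Dose is
#' strictly positive everywhere; resample to the image lattice (see
#' [resample_volume()]) before DVH extraction.
#'
#' @param session A [generate_phantom()] session.
#' @param role Session role, one of `"reference"`, `"adapt"`, `"verify"`,
#'   `"beam_on"`.
#' @param prescription Per-fraction prescription (cGy); must be positive.
#' @param margin Plateau margin beyond the CTV surface (mm).
#' @param falloff Sigmoid fall-off scale (mm).
#' @return An [image_volume()] dose grid in cGy.
#' @export
generate_dose <- function(session, role, prescription = 600,
                          margin = 8, falloff = 2.5) {
  assert_that(prescription > 0, "prescription must be positive")
  assert_that(role %in% names(session$masks), "unknown session role '%s'", role)
  ctv <- session$masks[[role]]$CTV
  spec <- session$spec
  extent <- (spec$shape - 1) * spec$spacing
  nd <- pmax(floor(extent / spec$dose_spacing) + 1L, 2L)
  proto <- image_volume(array(0, nd), rep(spec$dose_spacing, 3), c(0, 0, 0))
  ctv_d <- resample_volume(
    image_volume(array(as.numeric(ctv$array), dim(ctv$array)), ctv$spacing,
                 ctv$origin), proto)
  sd_mm <- signed_distance(ctv_d$array >= 0.5, proto$spacing)
  dose <- prescription * plogis((margin - sd_mm) / falloff)
  image_volume(dose, proto$spacing, proto$origin)
}

#' Perturb a mask by a smooth random surface displacement
#'
#' Emulates manual-contouring variability: the mask is warped by a smooth
#' random displacement field whose surface-normal component has RMS about
#' `amplitude_mm`. Amplitude zero returns the input unchanged.
#'
#' @param mask A [structure_mask()].
#' @param amplitude_mm Displacement RMS in mm (>= 0).
#' @param seed Integer seed.
#' @param corr_len Correlation length of the noise field (mm).
#' @return A [structure_mask()] on the same lattice.
#' @export
simulate_contour_noise <- function(mask, amplitude_mm, seed, corr_len = 15) {
  assert_that(amplitude_mm >= 0, "amplitude_mm must be >= 0")
  if (amplitude_mm == 0) return(mask)
  f <- smooth_vector_field(amplitude_mm, corr_len,
                           derive_seed(seed, "contour_noise"))
  pts <- lattice_world(mask)
  u <- f(pts)
  field <- displacement_field(array(u, c(dim(mask$array), 3)), mask$spacing,
                              mask$origin)
  warp_mask(mask, field)
}

# Session IO ------------------------------------------------------------------

#' Write a phantom session to disk
#'
#' One NIfTI per role image, role+organ mask, dose grid, and ground-truth
#' field, plus a JSON manifest recording the file names, the seed, and the
#' generating spec.
#'
#' @param session A [generate_phantom()] session.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = session$spec$seed,
                   spec = unclass(session$spec), files = list())
  for (role in SESSION_ROLES) {
    f <- sprintf("image_%s.nii.gz", role)
    write_volume(session$images[[role]], file.path(dir, f))
    manifest$files[[paste0("image_", role)]] <- f
    for (org in c("CTV", "bladder", "rectum")) {
      f <- sprintf("mask_%s_%s.nii.gz", role, org)
      write_mask(session$masks[[role]][[org]], file.path(dir, f))
      manifest$files[[paste0("mask_", role, "_", org)]] <- f
    }
    f <- sprintf("dose_%s.nii.gz", role)
    write_volume(session$dose[[role]], file.path(dir, f))
    manifest$files[[paste0("dose_", role)]] <- f
    f <- sprintf("gt_field_%s.nii.gz", role)
    write_field(session$gt_field[[role]], file.path(dir, f))
    manifest$files[[paste0("gt_field_", role)]] <- f
  }
  path <- file.path(dir, "session.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
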