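# Hybrid deformable registration. A dense displacement field on the fixed
# lattice (pull-back convention: fixed x corresponds to moving x + u(x)) is
# optimised by multi-resolution first-order descent with backtracking line
# search on the composite objective
#
#   lambda_img    * (1 - windowed local correlation of fixed vs warped moving)
# + lambda_reg    * squared-spatial-gradient (strain) energy of u
# + lambda_struct * surface-distance-transform matching of controlling
#                   structures (symmetric signed-distance-map form by default;
#                   a one-sided chamfer form is kept to study its failure mode
#                   under large deformations)
# + lambda_point  * mean squared controlling-point residual
#                   ||p_fixed + u(p_fixed) - p_moving||^2.
#
# Distances inside the structure and point terms are normalised by the clamp
# scale (10 mm) so the default weights act on comparable magnitudes.

#' Registration configuration
#'
#' @param strategy `"intensity"` (image + regularity only), `"cs"` (adds the
#'   controlling-structure term), or `"cs_p"` (adds controlling points too).
#' @param lambda_img,lambda_reg,lambda_struct,lambda_point Non-negative term
#'   weights. `lambda_struct` is forced to 0 for the intensity strategy and
#'   `lambda_point` to 0 unless the strategy is `cs_p`.
#' @param levels Multi-resolution downsampling factors, coarse to fine.
#' @param iterations Iteration cap per level (recycled to `length(levels)`).
#' @param tol Relative objective-decrease convergence tolerance per level.
#' @param lcc_sigma Gaussian window (mm) of the local correlation metric.
#' @param update_sigma Gaussian smoothing of each gradient step, in voxels of
#'   the current resolution level (resolution-relative: coarse levels smooth
#'   over proportionally larger distances, which is what lets flat image
#'   regions inherit the motion of their surroundings).
#' @param clamp Distance clamp / normalisation scale (mm) of the structure and
#'   point terms.
#' @param struct_mode `"symmetric"` (default) or `"one_sided"` structure term.
#' @param seed Integer seed (the solver is deterministic; the seed is recorded
#'   for provenance).
#' @return An object of class `registration_config`.
#' @export
registration_config <- function(strategy = c("intensity", "cs", "cs_p"),
                                lambda_img = 1, lambda_reg = 6,
                                lambda_struct = 10, lambda_point = 10,
                                levels = c(4, 2, 1),
                                iterations = c(60, 40, 20),
                                tol = 1e-4,
                                lcc_sigma = 6, update_sigma = 1, clamp = 10,
                                struct_mode = c("symmetric", "one_sided"),
                                seed = 1L) {
  strategy <- match.arg(strategy)
  struct_mode <- match.arg(struct_mode)
  assert_that(all(c(lambda_img, lambda_reg, lambda_struct, lambda_point) >= 0),
              "registration weights must be non-negative")
  if (strategy == "intensity") lambda_struct <- 0
  if (strategy != "cs_p") lambda_point <- 0
  structure(list(strategy = strategy, lambda_img = lambda_img,
                 lambda_reg = lambda_reg, lambda_struct = lambda_struct,
                 lambda_point = lambda_point, levels = levels,
                 iterations = rep(iterations, length.out = length(levels)),
                 tol = tol, lcc_sigma = lcc_sigma,
                 update_sigma = update_sigma, clamp = clamp,
                 struct_mode = struct_mode, seed = as.integer(seed)),
            class = "registration_config")
}

#' Write a registration configuration as YAML
#'
#' @param config A [registration_config()].
#' @param path File path.
#' @export
write_registration_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_registration_config
#' @export
read_registration_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(registration_config, x)
}

# Internal: downsampled copy of a volume (presmoothed, lattice-aligned).
level_volume <- function(vol, factor, presmooth = TRUE) {
  if (factor == 1) return(vol)
  arr <- vol$array
  if (presmooth)
    arr <- gauss_smooth(arr, 0.5 * factor * min(vol$spacing), vol$spacing)
  sm <- image_volume(arr, vol$spacing, vol$origin)
  shape <- pmax(floor((dim(vol$array) - 1) / factor) + 1, 4L)
  proto <- image_volume(array(0, shape), vol$spacing * factor, vol$origin)
  resample_volume(sm, proto, fill = 0)
}

# Central-difference gradient arrays of a 3D array (per-axis, units/mm).
grad_arrays <- function(arr, spacing) {
  d <- dim(arr)
  out <- vector("list", 3)
  for (ax in 1:3) {
    idx_hi <- lapply(1:3, function(a) seq_len(d[a]))
    idx_lo <- idx_hi
    idx_hi[[ax]] <- pmin(idx_hi[[ax]] + 1, d[ax])
    idx_lo[[ax]] <- pmax(idx_lo[[ax]] - 1, 1)
    hi <- arr[idx_hi[[1]], idx_hi[[2]], idx_hi[[3]], drop = FALSE]
    lo <- arr[idx_lo[[1]], idx_lo[[2]], idx_lo[[3]], drop = FALSE]
    denom <- (pmin(seq_len(d[ax]) + 1, d[ax]) -
              pmax(seq_len(d[ax]) - 1, 1)) * spacing[ax]
    den_arr <- switch(ax,
                      array(rep(denom, times = d[2] * d[3]), d),
                      array(rep(rep(denom, each = d[1]), times = d[3]), d),
                      array(rep(denom, each = d[1] * d[2]), d))
    out[[ax]] <- (hi - lo) / den_arr
  }
  out
}

# Strain energy of u (4D array, mm) and its gradient: mean squared
# dimensionless strain over voxels and components (forward differences).
strain_energy <- function(u, spacing) {
  n <- prod(dim(u))
  res <- cpp_strain(as.numeric(u), dim(u)[1:3], spacing)
  list(E = res$E / n, G = array(res$G, dim(u)) / n)
}

# Sample several same-lattice arrays at shared world points (N x k matrix).
sample_multi <- function(arrs, spacing, origin, pts, fill = 0) {
  idx <- sweep(sweep(pts, 2, origin, "-"), 2, spacing, "/")
  cpp_trilinear_multi(lapply(arrs, as.numeric), dim(arrs[[1]]), idx, fill)
}

#' Hybrid deformable image registration
#'
#' Estimates a dense [displacement_field()] mapping fixed-image points into
#' the moving image under one of three strategies: intensity-only, intensity
#' plus controlling structures (CS), or intensity plus structures and
#' controlling points (CS+P). Optimisation is multi-resolution gradient
#' descent with a monotone backtracking line search, so the per-level
#' objective trace is non-increasing.
#'
#' @param fixed,moving [image_volume()]s on congruent lattices.
#' @param config A [registration_config()].
#' @param structures For `cs`/`cs_p`: named list per organ, each element a
#'   list with `fixed` and `moving` [structure_mask()]s on the corresponding
#'   lattices.
#' @param points For `cs_p`: list of [map_points()] sets (one per organ).
#'   Within each set, `target_points` must lie on the fixed image and
#'   `ref_points` at the corresponding positions on the moving image; the
#'   penalty is the mean squared residual `||p_t + u(p_t) - p_r||^2`.
#' @return An object of class `registration_result`: `field`
#'   (full-resolution), `trace` (per level/iteration objective values),
#'   `terms` (final per-term values), `point_residual_mm` (initial and final
#'   mean control-point residual), and the `config`.
#' @export
register <- function(fixed, moving, config, structures = NULL, points = NULL) {
  assert_that(inherits(config, "registration_config"),
              "config must be a registration_config")
  assert_that(same_lattice(fixed, moving),
              "register: fixed and moving lattices differ")
  if (config$strategy %in% c("cs", "cs_p") && config$lambda_struct > 0)
    assert_that(!is.null(structures) && length(structures) > 0,
                "strategy '%s' requires controlling structures", config$strategy)
  if (config$strategy == "cs_p" && config$lambda_point > 0)
    assert_that(!is.null(points) && length(points) > 0,
                "strategy 'cs_p' requires controlling points")
  if (!is.null(points) && inherits(points, "control_point_set"))
    points <- list(points)

  use_struct <- config$lambda_struct > 0 && !is.null(structures)
  use_point <- config$lambda_point > 0 && !is.null(points)
  tau <- config$clamp

  pt_fixed <- NULL; pt_moving <- NULL
  if (use_point) {
    pt_fixed <- do.call(rbind, lapply(points, `[[`, "target_points"))
    pt_moving <- do.call(rbind, lapply(points, `[[`, "ref_points"))
  }

  u <- NULL
  trace <- list()
  final_terms <- NULL
  init_res <- NA_real_; final_res <- NA_real_

  for (li in seq_along(config$levels)) {
    fac <- config$levels[li]
    fx <- level_volume(fixed, fac)
    mv <- level_volume(moving, fac)
    d <- dim(fx$array)
    sp <- fx$spacing
    n_vox <- prod(d)
    proto <- image_volume(array(0, d), sp, fx$origin)
    base_pts <- lattice_world(proto)

    # image-term precomputations
    sig <- config$lcc_sigma
    f_arr <- fx$array
    mu_f <- gauss_smooth(f_arr, sig, sp)
    P_ff <- gauss_smooth(f_arr^2, sig, sp)
    B <- pmax(P_ff - mu_f^2, 0)
    eps_v <- (1e-3 * stats::var(as.numeric(f_arr)) + 1e-9)
    mv_grad <- grad_arrays(mv$array, sp)

    # structure-term precomputations
    st <- NULL
    if (use_struct) {
      st <- lapply(structures, function(s) {
        fmask <- resample_volume(
          image_volume(array(as.numeric(s$fixed$array), dim(s$fixed$array)),
                       s$fixed$spacing, s$fixed$origin), proto)$array >= 0.5
        mmask <- resample_volume(
          image_volume(array(as.numeric(s$moving$array), dim(s$moving$array)),
                       s$moving$spacing, s$moving$origin), proto)$array >= 0.5
        if (!any(fmask) || !any(mmask) || all(fmask) || all(mmask))
          return(NULL)
        out <- list()
        if (config$struct_mode == "symmetric") {
          S_f <- pmin(pmax(signed_distance(fmask, sp), -tau), tau)
          S_m <- pmin(pmax(signed_distance(mmask, sp), -tau), tau)
          out$S_f <- S_f
          # stored shifted by -tau so an out-of-grid fill of 0 reads as "far
          # outside" (+tau) after the shift is undone
          out$S_m_shift <- S_m - tau
          out$S_m_grad <- grad_arrays(S_m, sp)
        } else {
          # one-sided chamfer: fixed-surface distance map sampled at the
          # warped moving-structure surface. Minimised by putting the
          # propagated surface anywhere ON the fixed surface, with nothing
          # enforcing coverage -- the collapse-prone formulation.
          fsurf <- boundary_voxels(fmask)
          D_f <- pmin(distance_to(fsurf, sp), 2 * tau)
          out$D2 <- (D_f / tau)^2
          out$m_soft <- array(as.numeric(mmask), dim(mmask))
          out$m_grad <- grad_arrays(out$m_soft, sp)
        }
        out
      })
      st <- Filter(Negate(is.null), st)
      if (length(st) == 0) use_struct <- FALSE
    }

    # initial field at this level
    if (is.null(u)) {
      u <- array(0, c(d, 3))
    } else {
      up <- array(0, c(d, 3))
      for (c in 1:3) {
        comp <- image_volume(u[, , , c], prev_sp, fixed$origin)
        idx <- world_to_index(comp, base_pts)
        dp <- dim(comp$array)
        idx[, 1] <- pmin(pmax(idx[, 1], 0), dp[1] - 1)
        idx[, 2] <- pmin(pmax(idx[, 2], 0), dp[2] - 1)
        idx[, 3] <- pmin(pmax(idx[, 3], 0), dp[3] - 1)
        up[, , , c] <- array(cpp_trilinear(as.numeric(comp$array), dp, idx, 0), d)
      }
      u <- up
    }
    prev_sp <- sp

    eval_obj <- function(u, want_grad = FALSE) {
      pts <- base_pts + matrix(u, ncol = 3)
      terms <- list(image = 0, regularity = 0, structure = 0, point = 0)
      G <- if (want_grad) array(0, c(d, 3)) else NULL

      if (config$lambda_img > 0) {
        if (want_grad) {
          sm <- sample_multi(c(list(mv$array), mv_grad), sp, mv$origin, pts,
                             fill = 0)
          w <- array(sm[, 1], d)
        } else {
          w <- array(sample_volume(mv, pts, fill = 0), d)
        }
        mu_w <- gauss_smooth(w, sig, sp)
        P_fw <- gauss_smooth(f_arr * w, sig, sp)
        P_ww <- gauss_smooth(w^2, sig, sp)
        A <- P_fw - mu_f * mu_w
        C <- pmax(P_ww - mu_w^2, 0)
        cc <- A^2 / (B * C + eps_v^2)
        terms$image <- config$lambda_img * mean(1 - cc)
        if (want_grad) {
          dccdw <- 2 * A / (B * C + eps_v^2) *
            ((f_arr - mu_f) - A / (C + eps_v) * (w - mu_w))
          coef <- -config$lambda_img / n_vox * dccdw
          for (c in 1:3)
            G[, , , c] <- G[, , , c] + coef * array(sm[, c + 1], d)
        }
      }

      if (config$lambda_reg > 0) {
        se <- strain_energy(u, sp)
        terms$regularity <- config$lambda_reg * se$E
        if (want_grad) G <- G + config$lambda_reg * se$G
      }

      if (use_struct) {
        lam <- config$lambda_struct / length(st)
        for (s in st) {
          if (config$struct_mode == "symmetric") {
            if (want_grad) {
              sm <- sample_multi(c(list(s$S_m_shift), s$S_m_grad), sp,
                                 proto$origin, pts, fill = 0)
              Sm_w <- array(sm[, 1], d) + tau
            } else {
              Sm_w <- array(sample_multi(list(s$S_m_shift), sp, proto$origin,
                                         pts, fill = 0)[, 1], d) + tau
            }
            diff <- (Sm_w - s$S_f) / tau
            terms$structure <- terms$structure + lam * mean(diff^2)
            if (want_grad) {
              coef <- lam * 2 / (n_vox * tau^2) * (Sm_w - s$S_f)
              for (c in 1:3)
                G[, , , c] <- G[, , , c] + coef * array(sm[, c + 1], d)
            }
          } else {
            # fixed-surface distance weighted by the warped surface density
            # psi = phi(1-phi): exactly differentiable, and minimisable by
            # concentrating the propagated surface on nearby fixed-surface
            # patches -- the coverage-free chamfer behaviour
            if (want_grad) {
              sm <- sample_multi(c(list(s$m_soft), s$m_grad), sp,
                                 proto$origin, pts, fill = 0)
              phi <- array(sm[, 1], d)
            } else {
              phi <- array(sample_multi(list(s$m_soft), sp, proto$origin,
                                        pts, fill = 0)[, 1], d)
            }
            psi <- phi * (1 - phi)
            W <- sum(psi) + 1e-8
            Ebar <- sum(psi * s$D2) / W
            terms$structure <- terms$structure + lam * Ebar
            if (want_grad) {
              coef <- lam * (1 - 2 * phi) * (s$D2 - Ebar) / W
              for (c in 1:3)
                G[, , , c] <- G[, , , c] + coef * array(sm[, c + 1], d)
            }
          }
        }
      }

      if (use_point) {
        np <- nrow(pt_fixed)
        uf <- displacement_field(u, sp, proto$origin)
        q <- pt_fixed + sample_field(uf, pt_fixed)
        res <- q - pt_moving
        terms$point <- config$lambda_point * mean(rowSums(res^2)) / tau^2
        if (want_grad) {
          idx <- world_to_index(proto, pt_fixed)
          coef <- config$lambda_point * 2 / (np * tau^2)
          for (j in seq_len(np)) {
            i0 <- pmin(pmax(floor(idx[j, ]), 0), d - 2)
            fr <- idx[j, ] - i0
            for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
              wgt <- (if (dx) fr[1] else 1 - fr[1]) *
                     (if (dy) fr[2] else 1 - fr[2]) *
                     (if (dz) fr[3] else 1 - fr[3])
              if (wgt == 0) next
              ii <- i0 + c(dx, dy, dz) + 1
              for (c in 1:3)
                G[ii[1], ii[2], ii[3], c] <- G[ii[1], ii[2], ii[3], c] +
                  coef * wgt * res[j, c]
            }
          }
        }
      }

      list(E = terms$image + terms$regularity + terms$structure + terms$point,
           terms = terms, G = G)
    }

    if (li == 1 && use_point) {
      r0 <- pt_fixed +
        sample_field(displacement_field(u, sp, proto$origin), pt_fixed) -
        pt_moving
      init_res <- mean(sqrt(rowSums(r0^2)))
    }

    cur <- eval_obj(u, want_grad = TRUE)
    lvl_trace <- cur$E
    step <- NA_real_
    n_fail <- 0L
    n_small <- 0L
    for (it in seq_len(config$iterations[li])) {
      dir <- cur$G
      for (c in 1:3)
        dir[, , , c] <- gauss_smooth(dir[, , , c],
                                     config$update_sigma * min(sp), sp)
      gmax <- max(abs(dir))
      if (gmax < 1e-14) break
      if (is.na(step)) step <- 0.5 * min(sp) / gmax
      accepted <- FALSE
      for (bt in 1:12) {
        u_try <- u - step * dir
        trial <- eval_obj(u_try, want_grad = FALSE)
        if (trial$E <= cur$E) { accepted <- TRUE; break }
        step <- step / 2
      }
      if (!accepted) {          # direction momentarily bad; retry smaller
        n_fail <- n_fail + 1L
        if (n_fail >= 3L) break
        step <- step / 4
        next
      }
      n_fail <- 0L
      rel_dec <- (cur$E - trial$E) / max(abs(cur$E), 1e-12)
      u <- u_try
      cur <- eval_obj(u, want_grad = TRUE)
      lvl_trace <- c(lvl_trace, cur$E)
      step <- step * 1.5
      if (step * gmax > 2 * min(sp)) step <- 2 * min(sp) / gmax
      n_small <- if (rel_dec < config$tol) n_small + 1L else 0L
      if (n_small >= 2L) break
    }
    trace[[li]] <- lvl_trace
    final_terms <- cur$terms
    if (li == length(config$levels) && use_point) {
      rf <- pt_fixed +
        sample_field(displacement_field(u, sp, proto$origin), pt_fixed) -
        pt_moving
      final_res <- mean(sqrt(rowSums(rf^2)))
    }
  }

  # lift to the full-resolution fixed lattice if the last level was coarse
  if (config$levels[length(config$levels)] != 1) {
    dful <- dim(fixed$array)
    base_full <- lattice_world(fixed)
    uf <- array(0, c(dful, 3))
    for (c in 1:3) {
      comp <- image_volume(u[, , , c], prev_sp, fixed$origin)
      idx <- world_to_index(comp, base_full)
      dp <- dim(comp$array)
      idx[, 1] <- pmin(pmax(idx[, 1], 0), dp[1] - 1)
      idx[, 2] <- pmin(pmax(idx[, 2], 0), dp[2] - 1)
      idx[, 3] <- pmin(pmax(idx[, 3], 0), dp[3] - 1)
      uf[, , , c] <- array(cpp_trilinear(as.numeric(comp$array), dp, idx, 0),
                           dful)
    }
    u <- uf
  }

  tr <- dplyr::bind_rows(lapply(seq_along(trace), function(li)
    tibble::tibble(level = config$levels[li],
                   iteration = seq_along(trace[[li]]) - 1L,
                   objective = trace[[li]])))
  structure(list(field = displacement_field(u, fixed$spacing, fixed$origin),
                 trace = tr, terms = final_terms,
                 point_residual_mm = c(initial = init_res, final = final_res),
                 config = config),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  m <- sqrt(rowSums(matrix(x$field$vectors, ncol = 3)^2))
  cat(sprintf("<registration_result> strategy %s: objective %.5f after %d evaluations; |u| mean %.2f / max %.2f mm\n",
              x$config$strategy, tail(x$trace$objective, 1), nrow(x$trace),
              mean(m), max(m)))
  invisible(x)
}

#' Write per-iteration objective traces as CSV
#'
#' @param result A [register()] result.
#' @param path File path.
#' @export
write_trace_csv <- function(result, path) {
  write.csv(result$trace, path, row.names = FALSE)
  invisible(path)
}

#' @export
tidy.registration_result <- function(x, ...) x$trace

#' @export
glance.registration_result <- function(x, ...) {
  m <- sqrt(rowSums(matrix(x$field$vectors, ncol = 3)^2))
  tibble::tibble(strategy = x$config$strategy,
                 objective = tail(x$trace$objective, 1),
                 term_image = x$terms$image,
                 term_regularity = x$terms$regularity,
                 term_structure = x$terms$structure,
                 term_point = x$terms$point,
                 n_evaluations = nrow(x$trace),
                 max_displacement_mm = max(m),
                 point_residual_final_mm = unname(x$point_residual_mm["final"]))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
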