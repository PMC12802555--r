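# Cohort experiment orchestration: synthetic patients x fractions, the five
# image-pair registrations under the requested DIR strategies, geometric and
# DVH metric collection, and summary tables.

PAIR_ROLES <- list(R2A = c("reference", "adapt"),
                   R2V = c("reference", "verify"),
                   R2B = c("reference", "beam_on"),
                   A2V = c("adapt", "verify"),
                   A2B = c("adapt", "beam_on"))

STRATEGY_TAGS <- c("intensity", "cs", "cs_p", "cs_one_sided")

#' Experiment configuration
#'
#' Describes a full validation experiment: cohort size, the phantom parameter
#' ranges, the image pairs and DIR strategies to evaluate, per-strategy
#' registration configurations, and the master seed from which every
#' patient/fraction/stage seed is derived deterministically.
#'
#' @param n_patients Number of synthetic patients (>= 1).
#' @param n_fractions Fractions per patient (default 5).
#' @param pairs Image pairs to evaluate, subset of
#'   `c("R2A","R2V","R2B","A2V","A2B")`; `"X2Y"` propagates the contours of
#'   session image X onto session image Y.
#' @param strategies DIR strategies to run, subset of
#'   `c("intensity","cs","cs_p","cs_one_sided")` (the last is the
#'   collapse-prone one-sided structure-term variant of `cs`).
#' @param fill_range Range of the bladder fill factor sampled uniformly per
#'   patient/fraction (default spans 1 to 2.5, i.e. up to well beyond volume
#'   doubling).
#' @param geometry_jitter Relative half-width of the per-patient organ size
#'   jitter (default 0.08).
#' @param contour_noise_mm RMS amplitude of manual-contouring noise applied to
#'   the evaluation contours (0 = use the ground-truth contours).
#' @param phantom Base [phantom_spec()] arguments as a named list (grid shape,
#'   spacing, ...), merged over the defaults.
#' @param reg_configs Named list of [registration_config()]s per strategy tag;
#'   missing entries get defaults.
#' @param d_min Controlling-point minimum geodesic separation (mm).
#' @param mesh_level Icosphere subdivision level for organ meshes.
#' @param dvh_bin_width DVH bin width (cGy).
#' @param dose_max DVH upper edge (cGy).
#' @param scale_factor Course scaling for Delta-DVH metrics (default 5).
#' @param seed Master seed.
#' @param output_dir Optional directory for per-patient result CSVs; when set,
#'   a rerun resumes past completed patients.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_patients = 10, n_fractions = 5,
                              pairs = c("R2A", "R2V", "R2B", "A2V", "A2B"),
                              strategies = c("intensity", "cs", "cs_p"),
                              fill_range = c(1.0, 2.5),
                              geometry_jitter = 0.08,
                              contour_noise_mm = 0,
                              phantom = list(),
                              reg_configs = list(),
                              d_min = 10, mesh_level = 3,
                              dvh_bin_width = 10, dose_max = 700,
                              scale_factor = 5,
                              seed = 1L, output_dir = NULL) {
  assert_that(n_patients >= 1, "n_patients must be >= 1")
  assert_that(length(pairs) > 0 && all(pairs %in% names(PAIR_ROLES)),
              "pairs must be a nonempty subset of R2A/R2V/R2B/A2V/A2B")
  assert_that(all(strategies %in% STRATEGY_TAGS),
              "unknown strategy tag(s): %s",
              paste(setdiff(strategies, STRATEGY_TAGS), collapse = ", "))
  for (tag in strategies)
    if (is.null(reg_configs[[tag]]))
      reg_configs[[tag]] <- switch(tag,
        intensity = registration_config("intensity"),
        cs = registration_config("cs"),
        cs_p = registration_config("cs_p"),
        cs_one_sided = registration_config("cs", struct_mode = "one_sided"))
  structure(list(n_patients = as.integer(n_patients),
                 n_fractions = as.integer(n_fractions),
                 pairs = pairs, strategies = strategies,
                 fill_range = fill_range, geometry_jitter = geometry_jitter,
                 contour_noise_mm = contour_noise_mm,
                 phantom = phantom, reg_configs = reg_configs,
                 d_min = d_min, mesh_level = mesh_level,
                 dvh_bin_width = dvh_bin_width, dose_max = dose_max,
                 scale_factor = scale_factor,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "experiment_config")
}

# Phantom spec for one patient/fraction: patient-level geometry jitter,
# fraction-level fill factor and deformation seeds.
patient_fraction_spec <- function(config, patient, fraction) {
  gj <- config$geometry_jitter
  geo <- with_seed(derive_seed(config$seed, "patient", patient),
                   runif(4, 1 - gj, 1 + gj))
  fill <- with_seed(derive_seed(config$seed, "fill", patient, fraction),
                    runif(1, config$fill_range[1], config$fill_range[2]))
  base <- phantom_spec()
  args <- utils::modifyList(list(
    ctv_axes = base$ctv_axes * geo[1],
    bladder_axes = base$bladder_axes * geo[2],
    rectum_radius = base$rectum_radius * geo[3],
    rectum_length = base$rectum_length * geo[4],
    bladder_fill_factor = fill,
    seed = derive_seed(config$seed, "phantom", patient, fraction)),
    config$phantom)
  args$bladder_fill_factor <- fill
  args$seed <- derive_seed(config$seed, "phantom", patient, fraction)
  do.call(phantom_spec, args)
}

# Manual (evaluation) contours for a session: ground-truth masks, optionally
# perturbed by simulated contouring noise.
manual_contours <- function(session, config, patient, fraction) {
  out <- session$masks
  if (config$contour_noise_mm > 0)
    for (role in names(out))
      for (org in names(out[[role]]))
        out[[role]][[org]] <- simulate_contour_noise(
          out[[role]][[org]], config$contour_noise_mm,
          derive_seed(config$seed, "contour", patient, fraction, role, org))
  out
}

run_one_fraction <- function(config, patient, fraction) {
  spec <- patient_fraction_spec(config, patient, fraction)
  session <- generate_phantom(spec)
  manual <- manual_contours(session, config, patient, fraction)
  orgs <- c("CTV", "bladder", "rectum")
  fill_real <- volume_cc(session$masks$beam_on$bladder) /
    volume_cc(session$masks$reference$bladder)

  need_points <- any(config$strategies == "cs_p")
  roles_used <- unique(unlist(PAIR_ROLES[config$pairs]))
  meshes <- NULL
  if (need_points) {
    tmpl <- build_template_mesh(config$mesh_level)
    meshes <- lapply(setNames(roles_used, roles_used), function(role)
      lapply(setNames(orgs, orgs), function(org)
        fit_mesh_to_mask(tmpl, manual[[role]][[org]])))
  }

  dose_on_img <- lapply(setNames(roles_used, roles_used), function(role)
    resample_volume(session$dose[[role]], session$images[[role]]))

  metrics <- list()
  curves <- list()
  for (pair in config$pairs) {
    from <- PAIR_ROLES[[pair]][1]
    to <- PAIR_ROLES[[pair]][2]
    fixed <- session$images[[to]]
    moving <- session$images[[from]]
    structures <- lapply(setNames(orgs, orgs), function(org)
      list(fixed = manual[[to]][[org]], moving = manual[[from]][[org]]))
    points <- NULL
    if (need_points)
      points <- lapply(setNames(orgs, orgs), function(org) {
        ids <- select_control_vertices(
          meshes[[from]][[org]], config$d_min,
          derive_seed(config$seed, "points", patient, fraction, pair, org))
        map_points(ids, meshes[[from]][[org]], meshes[[to]][[org]],
                   d_min = config$d_min)
      })
    for (strategy in config$strategies) {
      res <- register(fixed, moving, config$reg_configs[[strategy]],
                      structures = structures,
                      points = if (strategy == "cs_p") points else NULL)
      for (org in orgs) {
        prop <- warp_mask(manual[[from]][[org]], res$field)
        man <- manual[[to]][[org]]
        geo <- contour_comparison(prop, man, pair = pair, strategy = strategy)
        dm <- dvh_metric_set(dose_on_img[[to]], prop, man,
                             scale_factor = config$scale_factor,
                             bin_width = config$dvh_bin_width)
        metrics[[length(metrics) + 1]] <- dplyr::bind_cols(
          tibble::tibble(patient = patient, fraction = fraction,
                         fill_factor = spec$bladder_fill_factor,
                         fill_realized = fill_real),
          geo, dm[, setdiff(names(dm), "organ")])
        d_prop <- compute_dvh(dose_on_img[[to]], prop, config$dvh_bin_width,
                              dose_max = config$dose_max)
        d_man <- compute_dvh(dose_on_img[[to]], man, config$dvh_bin_width,
                             dose_max = config$dose_max)
        curves[[length(curves) + 1]] <- tibble::tibble(
          patient = patient, fraction = fraction, pair = pair,
          strategy = strategy, organ = org,
          curve = list(delta_dvh(d_prop, d_man, config$scale_factor)))
      }
    }
  }
  list(metrics = dplyr::bind_rows(metrics), curves = dplyr::bind_rows(curves))
}

#' Run a full validation experiment
#'
#' For every patient and fraction: generate a synthetic session, fit meshes
#' and select controlling points where needed, run every requested strategy on
#' every requested image pair, propagate the three organ contours, and collect
#' geometric (DSC, DTA) and dosimetric (Delta-DVH metric) records. Fully
#' deterministic for a fixed master seed. A failing fraction is recorded in
#' the manifest and skipped, never aborting the cohort; with `output_dir` set,
#' completed patients are written to disk and skipped on rerun.
#'
#' @param config An [experiment_config()].
#' @return An object of class `experiment_report`: `metrics` (long-form
#'   tibble, one row per patient/fraction/pair/strategy/organ), `curves`
#'   (Delta-DVH curves as a list-column tibble), and `manifest` (config echo,
#'   seeds, failures).
#' @export
run_experiment <- function(config) {
  assert_that(inherits(config, "experiment_config"),
              "config must be an experiment_config")
  all_metrics <- list()
  all_curves <- list()
  failures <- list()
  use_disk <- !is.null(config$output_dir)
  if (use_disk)
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  for (p in seq_len(config$n_patients)) {
    p_file <- if (use_disk)
      file.path(config$output_dir, sprintf("patient_%03d_metrics.csv", p))
    p_rows <- list()
    p_curves <- list()
    if (use_disk && file.exists(p_file)) {
      all_metrics[[p]] <- tibble::as_tibble(
        utils::read.csv(p_file, stringsAsFactors = FALSE))
      next
    }
    for (fr in seq_len(config$n_fractions)) {
      out <- tryCatch(run_one_fraction(config, p, fr), error = function(e) e)
      if (inherits(out, "error")) {
        failures[[length(failures) + 1]] <-
          list(patient = p, fraction = fr, message = conditionMessage(out))
        next
      }
      p_rows[[fr]] <- out$metrics
      p_curves[[fr]] <- out$curves
    }
    pm <- dplyr::bind_rows(p_rows)
    all_metrics[[p]] <- pm
    all_curves[[p]] <- dplyr::bind_rows(p_curves)
    if (use_disk && nrow(pm) > 0) write.csv(pm, p_file, row.names = FALSE)
  }

  metrics <- dplyr::bind_rows(all_metrics)
  manifest <- list(seed = config$seed,
                   n_patients = config$n_patients,
                   n_fractions = config$n_fractions,
                   pairs = config$pairs, strategies = config$strategies,
                   failures = failures,
                   package_version = as.character(utils::packageVersion("dirval")))
  structure(list(metrics = metrics,
                 curves = dplyr::bind_rows(all_curves),
                 manifest = manifest, config = config),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d rows (%d patients x %d fractions), pairs %s, strategies %s; %d failure(s)\n",
              nrow(x$metrics), x$manifest$n_patients, x$manifest$n_fractions,
              paste(x$manifest$pairs, collapse = "/"),
              paste(x$manifest$strategies, collapse = "/"),
              length(x$manifest$failures)))
  invisible(x)
}

#' Summarise an experiment report
#'
#' Mean and dispersion of every metric per image pair, strategy, and organ.
#' The dispersion convention is selectable: the standard deviation of the
#' sample (`"sd"`, the convention of cohort summary tables) or the standard
#' error of the mean (`"se"`).
#'
#' @param report An [run_experiment()] report (or its `metrics` tibble).
#' @param dispersion `"sd"` or `"se"`.
#' @return Tibble with one row per pair/strategy/organ.
#' @export
summarize_experiment <- function(report, dispersion = c("sd", "se")) {
  dispersion <- match.arg(dispersion)
  df <- if (inherits(report, "experiment_report")) report$metrics else report
  assert_that(nrow(df) > 0, "empty metric table")
  disp <- function(x) {
    s <- if (length(x) > 1) sd(x) else 0
    if (dispersion == "se") s / sqrt(length(x)) else s
  }
  df |>
    dplyr::group_by(.data$pair, .data$strategy, .data$organ) |>
    dplyr::summarise(dplyr::across(
      c("dsc", "dta_mean_cm", "dta_max_cm", "delta_cgy", "delta_course_cgy"),
      list(mean = mean, disp = disp)), n = dplyr::n(), .groups = "drop")
}

#' Demo validation cohort configuration
#'
#' The package's standard desk-scale validation experiment: ten synthetic
#' patients, one fraction each, the reference-to-beam-on pair (the largest
#' bladder deformations, including doubling), evaluated under the three DIR
#' strategies plus the collapse-prone one-sided structure-term variant, on a
#' 64 x 64 x 48 grid at 3 mm. Bladder fill factors span 1 to 2.5.
#'
#' @param seed Master seed.
#' @param n_patients Cohort size (default 10).
#' @param pairs Image pairs (default `"R2B"`).
#' @param strategies Strategy tags (default all four).
#' @param ... Further [experiment_config()] overrides.
#' @return An [experiment_config()].
#' @export
demo_experiment_config <- function(seed = 1L, n_patients = 10,
                                   pairs = "R2B",
                                   strategies = c("intensity", "cs", "cs_p",
                                                  "cs_one_sided"), ...) {
  experiment_config(n_patients = n_patients, n_fractions = 1,
                    pairs = pairs, strategies = strategies,
                    phantom = list(shape = c(64, 64, 48),
                                   spacing = c(3, 3, 3)),
                    seed = seed, ...)
}

#' Cohort Delta-DVH bands for one pair/strategy/organ cell
#'
#' @param report An [run_experiment()] report.
#' @param pair,strategy,organ Cell selector.
#' @param levels Percentile band levels.
#' @return A [cohort_bands()] object.
#' @export
experiment_bands <- function(report, pair, strategy, organ,
                             levels = c(95, 50, 25)) {
  cur <- report$curves
  sel <- cur$pair == pair & cur$strategy == strategy & cur$organ == organ
  assert_that(sum(sel) >= 2, "need >= 2 curves for %s/%s/%s",
              pair, strategy, organ)
  cohort_bands(cur$curve[sel], levels = levels)
}

#' Write the long-form metric table as CSV
#'
#' @param report An [run_experiment()] report.
#' @param path File path.
#' @export
write_metrics_csv <- function(report, path) {
  write.csv(report$metrics, path, row.names = FALSE)
  invisible(path)
}

#' @export
tidy.experiment_report <- function(x, ...) x$metrics

#' @export
glance.experiment_report <- function(x, ...) {
  tibble::tibble(n_rows = nrow(x$metrics),
                 n_patients = x$manifest$n_patients,
                 n_fractions = x$manifest$n_fractions,
                 n_pairs = length(x$manifest$pairs),
                 n_strategies = length(x$manifest$strategies),
                 n_failures = length(x$manifest$failures),
                 mean_dsc = mean(x$metrics$dsc),
                 mean_dta_mean_cm = mean(x$metrics$dta_mean_cm))
}
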