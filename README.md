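# dirval

Hybrid deformable image registration (DIR) with controlling structures and
points, plus the geometric and dosimetric evaluation framework needed to
validate it — built for the hardest case in MR-guided adaptive prostate
radiotherapy: bladders that double their volume between images.

## Who this is for

Medical-physics and image-analysis researchers who need to (a) reproduce the
mechanism by which intensity-only and contour-guided ("chamfer") DIR fail
under large organ deformations, (b) demonstrate that corresponding surface
points rescue it, and (c) quantify both effects with the field's standard
metrics — all on fully synthetic, seeded data, with no clinical images
required.

## What it implements

* **Synthetic pelvic phantom** (`generate_phantom()`): seeded sessions
  (reference, adapt, verify, beam-on) of a CTV/bladder/rectum scene with a
  smooth ground-truth displacement field per session image. Bladder filling
  is modelled as a base-sparing, exactly volume-preserving radial expansion
  (dome rises, trigone stays put) with a controllable fill factor up to and
  beyond doubling, composed with divergence-free random deformation and a
  rigid setup offset; MR-like piecewise intensities with noise, and a
  conformal 600 cGy/fraction dose grid (3 mm) with a steep sigmoidal edge at
  the CTV boundary.
* **Mesh correspondence** (`build_template_mesh()`, `fit_mesh_to_mask()`):
  every organ surface is fitted from one subdivided icosahedron by centroid
  ray casting onto the signed-distance zero level, so vertex *i* corresponds
  across sessions by construction.
* **Controlling points** (`select_control_vertices()`, `map_points()`):
  seeded greedy selection of mesh vertices under a 10 mm minimum geodesic
  separation (shortest paths over the mesh edge graph), mapped by shared
  topology to the corresponding vertices on any session mesh.
* **Registration** (`register()`): dense multi-resolution field minimising
  local-correlation image mismatch + strain regularisation, optionally with a
  controlling-structure term (symmetric signed-distance matching, or the
  collapse-prone one-sided chamfer variant) and a controlling-point residual
  `||p + u(p) - p'||^2`. Strategies: `intensity`, `cs`, `cs_p`.
* **Metrics** (`dice()`, `surface_distance_stats()`): volume Dice and
  symmetric mean / maximum distance to agreement (cm), exact to the
  brute-force boundary-point computation.
* **DVH analysis** (`compute_dvh()`, `delta_dvh()`, `dvh_metric_set()`,
  `cohort_bands()`): relative-volume DVHs, propagated-minus-manual ΔDVH,
  CTV D98% / bladder D5cc / rectum D1cc, five-fraction course scaling, and
  cohort percentile bands.
* **Pipeline** (`run_experiment()`, `summarize_experiment()`): the full
  cohort experiment — patients × fractions × image pairs × strategies ×
  organs — as one deterministic, resumable call returning tidy tibbles, with
  `autoplot()`/`plot_*()` figures and `tidy()`/`glance()` accessors. A thin
  CLI (`inst/cli/dirval.R`) exposes `generate`, `register`, `evaluate`,
  `run`, and `report` verbs.

## Worked example

Register a reference image to a beam-on image whose bladder has more than
doubled, with and without controlling points:

```r
library(dirval)

ses <- generate_phantom(phantom_spec(shape = c(64, 64, 48), spacing = c(3, 3, 3),
                                     bladder_fill_factor = 2.2, seed = 11))
orgs <- c("CTV", "bladder", "rectum")
structures <- lapply(setNames(orgs, orgs), function(o)
  list(fixed = ses$masks$beam_on[[o]], moving = ses$masks$reference[[o]]))
tmpl <- build_template_mesh(3)
points <- lapply(setNames(orgs, orgs), function(o) {
  m_from <- fit_mesh_to_mask(tmpl, ses$masks$reference[[o]])
  m_to   <- fit_mesh_to_mask(tmpl, ses$masks$beam_on[[o]])
  map_points(select_control_vertices(m_from, d_min = 10, seed = 1),
             m_from, m_to)
})

dplyr::bind_rows(lapply(c("intensity", "cs", "cs_p"), function(strategy) {
  r <- register(ses$images$beam_on, ses$images$reference,
                registration_config(strategy),
                structures = structures, points = points)
  prop <- warp_mask(ses$masks$reference$bladder, r$field)
  contour_comparison(prop, ses$masks$beam_on$bladder,
                     pair = "R2B", strategy = strategy)
}))
```

prints:

```
# A tibble: 3 × 6
  pair  strategy  organ     dsc dta_mean_cm dta_max_cm
  <chr> <chr>     <chr>   <dbl>       <dbl>      <dbl>
1 R2B   intensity bladder 0.791      0.438       1.04
2 R2B   cs        bladder 0.962      0.0954      0.424
3 R2B   cs_p      bladder 0.980      0.0532      0.300
```

Read: with a 2.2× bladder fill, intensity-only DIR leaves a ~4 mm mean
surface error on the propagated bladder contour (Dice 0.79); adding the
organs as controlling structures recovers most of it; adding 10 mm-separated
controlling points brings the mean error to sub-voxel (0.53 mm) and caps the
worst-case error at one voxel. The one-sided chamfer variant
(`registration_config("cs", struct_mode = "one_sided")`) instead collapses
the propagated bladder toward the inferior wall (Dice 0.63, maximum error
1.3 cm) — the failure mode that motivates the points.

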