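---
title: "Validating hybrid deformable registration with controlling structures and points"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating hybrid deformable registration with controlling structures and points}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dirval)
```

## The problem

In MR-guided online-adaptive radiotherapy of the prostate, a plan is
re-optimised at every fraction on the anatomy of the day, and several MR
images are taken per session: an adapt image for replanning, a verify image
before beam-on, and a beam-on image during delivery. Accumulating the
delivered dose over a course requires deformable image registration (DIR)
between these images, and the dominant difficulty is the bladder: it can more
than double its volume within a session, and intensity-driven DIR degrades
badly under such deformations. A hybrid strategy supplies the registration
with organ contours as *controlling structures* (CS) and, on top of those,
with corresponding surface *controlling points* (CS+P) selected on a shared
mesh topology.

`dirval` implements this full strategy stack together with the evaluation
machinery needed to validate it — geometric contour agreement (Dice, mean and
maximum distance to agreement) and dose-volume-histogram (DVH) differences —
and a seeded synthetic pelvic phantom that generates the study conditions,
including bladder volume doubling, so that every claim in the package is
checkable end to end without clinical data.

## The synthetic pelvic phantom

`phantom_spec()` / `generate_phantom()` build a four-image session
(`reference`, `adapt`, `verify`, `beam_on`) of a pelvic scene with three
organs: a prostate-analog CTV (ellipsoid, ~28 cc), a bladder (ellipsoid,
~85 cc at reference), and a rectum (rounded tube, ~35 cc). Defaults: a
96 × 96 × 64 grid at 2 mm isotropic spacing, chosen so every organ spans at
least 15 voxels; tests and the demo cohort use 64 × 64 × 48 at 3 mm and
48 × 48 × 40 at 4 mm variants of the same geometry to keep suite runtimes at
desk scale.

Each non-reference role is related to the reference anatomy by a smooth
ground-truth map composed of three parts, all expressed in the pull-back
convention used throughout the package (a session point `x` corresponds to
the reference point `x + u(x)`):

* **Bladder filling** — the deformation of interest. In normalised
  coordinates where the bladder is a unit ellipsoid, interior points scale
  uniformly by `s = fill^(1/3)`, and exterior points follow
  `g(rho)^3 = rho^3 + const`, the unique radial profile whose exterior
  deformation is exactly volume preserving: surrounding tissue is displaced,
  not inflated. This keeps CTV and rectum volumes stable to ~1–2% while the
  bladder hits its target fill ratio by construction. Filling is
  *base-sparing*: the expansion centre sits toward the bladder base (the
  trigone, anchored against the prostate) inside a metric elongated along the
  superior-inferior axis, so the dome rises about 2.3 times more than the
  base descends — the clinically dominant filling pattern, and the geometry
  that makes nearest-surface ("chamfer") matching genuinely ambiguous. With a
  centroid-symmetric filling model we found that no strategy ever failed;
  the asymmetry is what reproduces the failure regime that motivates
  controlling points.
* **A low-frequency random deformation** (`perturb_amplitude`, default
  1.5 mm RMS; correlation length 40 mm) built from sinusoidal modes whose
  directions are perpendicular to their wave vectors, hence divergence-free:
  organ shapes wobble but volumes are preserved to first order.
* **A small rigid setup offset** (default ~2 mm) shared by all fraction
  images, mimicking residual error after the clinical rigid match.

The fill schedule over a session is 25% of the requested fill change at
`adapt`, 50% at `verify`, and 100% at `beam_on`, emulating continued filling
over an adaptive session, so reference-to-beam-on pairs carry the largest
deformations.

Session contours are the analytic reference segmentation propagated through
the ground-truth field; this makes field/contour consistency exact by
construction (propagating reference masks through the stored field reproduces
the session masks identically), which is the property the evaluation relies
on. Intensities are piecewise constant per tissue class (background 100,
CTV 170, bladder 230, rectum 60 — a T2-like ordering with bright urine) plus
Gaussian noise (sigma 8). The per-fraction dose is a 600 cGy prescription
plateau over the CTV plus an 8 mm margin with a sigmoidal fall-off (scale
2.5 mm), computed on a 3 mm dose grid from the signed distance to the CTV
surface, then resampled to the image lattice for DVH work. 600 cGy is one
fraction of a 30 Gy / 5-fraction course, and differences of per-fraction DVH
metrics are scaled by 5 to course level.

What the phantom deliberately does *not* model: MR physics (bias fields,
distortion, sequence contrast), heterogeneous in-organ texture, sliding
interfaces, content gain/loss (rectal gas), and observer contouring policy
(only `simulate_contour_noise()`'s smooth random surface perturbation).
Passing tests therefore demonstrate correct mechanics and the expected
*relative* behaviour of the strategies under large deformations — not
clinical-grade absolute accuracy on real MR.

## Mesh correspondence and controlling points

`build_template_mesh()` constructs a subdivided icosahedron (level 3 by
default, 642 vertices — inter-vertex spacing of a few mm on organ-sized
surfaces, dense enough that a 10 mm separation rule is meaningful).
`fit_mesh_to_mask()` maps each template vertex along the ray from the mask
centroid to the subvoxel zero crossing of the mask's signed distance
transform (bisection on the trilinearly interpolated field); rays without a
crossing fall back to closest-point projection with a warning. Because every
fit of one template uses the same rays and face list, vertex `i` corresponds
across sessions — a plausible surface correspondence, not an anatomical
landmark match.

`select_control_vertices()` visits vertices in a seeded uniform random
permutation and accepts a candidate iff its geodesic distance (shortest path
over the mesh edge graph with Euclidean weights, via igraph) to every
accepted vertex is at least `d_min` (default 10 mm). The visiting order is
the one place the procedure is underdetermined — only a random *start* is
prescribed — and a full seeded permutation was chosen because it makes the
entire selection reproducible from one integer. Greedy selection makes the
result maximal, hence also a geodesic `d_min`-covering of the surface.

## The registration model

`register()` estimates a dense displacement field `u` on the fixed lattice
minimising

```
lambda_img * (1 - LCC(f, m(x + u)))        local correlation, Gaussian window 6 mm
+ lambda_reg * mean ||grad u||^2           dimensionless strain energy
+ lambda_struct * S(u)                     controlling-structure term
+ lambda_point * mean ||p_f + u(p_f) - p_m||^2 / tau^2
```

by multi-resolution (4x, 2x, 1x) gradient descent with Gaussian-smoothed
steps and a monotone backtracking line search, so per-level objective traces
are non-increasing by construction. The step smoothing is
resolution-relative (1 voxel of the current level): coarse levels smooth
over proportionally larger distances, which is what lets flat image regions
— organ interiors have no intensity gradient — inherit the motion of their
boundaries, while the finest level retains voxel-scale detail. Distances in the structure and
point terms are normalised by the clamp scale `tau = 10 mm` so the default
weights act on comparable magnitudes.

The structure term has two forms:

* **symmetric** (default): clamped signed-distance-map matching,
  `mean((clamp(S_fixed) - clamp(S_moving(x+u)))^2) / tau^2`. This penalises
  mismatch on *both* sides of both surfaces (the difference vanishes wherever
  both signed distances saturate at the clamp), which is the tractable
  realisation of symmetrised surface-distance sampling under a pull-back
  field — the literal moving-to-fixed sampling direction would require the
  inverse field, which a dense pull-back parameterisation does not provide.
* **one-sided** (`struct_mode = "one_sided"`): the fixed-surface distance
  map integrated against the warped moving-surface density
  `psi = phi(1 - phi)` (with `phi` the warped soft mask), normalised by the
  total density. This is the chamfer-matching formulation with no coverage
  constraint: the propagated surface can lower the objective by concentrating
  on whichever fixed-surface patch is nearest — for a small bladder
  registered to a grown one, the inferior wall. It is kept deliberately, as
  the mechanism study of why plain controlling structures fail under volume
  doubling and why corresponding points fix it.

The point term uses exact trilinear-weight gradients of the interpolated
field at each fixed-side point. Points are soft penalties, not hard
constraints — the proprietary system this emulates does not document which;
soft penalties compose cleanly with the other terms and cannot produce
non-diffeomorphic spikes at isolated points.

Default weights are `lambda_img = 1`, `lambda_struct = lambda_point = 10`,
`lambda_reg = 6`. The regularity weight is the one solver constant tuned on
the package's own property suite: with weak regularisation the solver
recovers even bladder doubling from the clean synthetic intensities alone,
which no clinical intensity-only DIR does, and the strategy comparison
degenerates; at `lambda_reg = 6` the intensity-only strategy shows the
classic large-deformation underfit (bladder Dice ~0.8 and mean surface
error ~4 mm on a doubling pair) while the 10x-weighted structure and point
terms still drive CS/CS+P to sub-voxel agreement. Numerical guards: local
correlation uses a variance floor of `1e-3 * var(f)` (flat noiseless regions
score zero correlation with zero gradient); the line search halves up to 12
times, tolerates 3 consecutive failures, and a level stops after two
consecutive relative decreases below `tol = 1e-4`.

## Evaluation metrics

`dice()` is voxel-set Dice. `surface_distance_stats()` defines contour
surfaces as voxel-face boundaries at native spacing and computes exact
Euclidean distances between boundary voxel centres via distance transform
(identical to exhaustive nearest-neighbour search, which the tests verify to
1e-6 cm). Both DTA statistics are symmetrised — the directed means are
averaged, the Hausdorff maximum is two-sided — because symmetry gives the
strongest invariants and matches common validation practice; one-sided
variants remain available (`symmetric = FALSE`). Values are reported in cm.

`compute_dvh()` builds cumulative relative-volume DVHs (default bin 10 cGy —
a 600 cGy fraction spans 60 bins, so interpolation error is far below the
effects of interest). `dose_at_relative_volume()` (D98%) interpolates the
curve linearly between edges; `dose_at_absolute_volume()` (D5cc, D1cc) uses
sorted-voxel partial sums with fractional-voxel interpolation. `delta_dvh()`
is the pointwise propagated-minus-manual difference in percentage points;
per-fraction metric differences scale linearly by 5 to the course level.
`cohort_bands()` summarises curve sets by central percentile envelopes
(2.5–97.5 for the 95% band, etc., linear interpolation between order
statistics) around the pointwise mean; a percentile envelope was chosen over
a parametric interval because the cohort distributions of interest are
heavy-tailed by design (the failure regime), and the dispersion convention in
`summarize_experiment()` is selectable between sample SD and standard error
because published summary tables are ambiguous between the two.

## The experiment pipeline

`run_experiment()` drives the whole study: per patient and fraction it
generates a session (patient-level organ-size jitter ±8%, fraction-level
bladder fill drawn uniformly from 1–2.5), fits meshes and selects points
where needed, registers every requested image pair under every requested
strategy, propagates the three contours, and records geometric and DVH
metrics in a long-form tibble (one row per patient, fraction, pair, strategy
and organ). Every random choice derives its seed deterministically from the
master seed, the unit's indices and a stage tag, so reruns are bit-identical;
a failing fraction is logged in the manifest and skipped. Inter-fraction
pairs (`R2A`, `R2V`, `R2B`) use the reference as the "from" image,
intra-fraction pairs (`A2V`, `A2B`) the adapt image, each with its own meshes
and points.

`demo_experiment_config()` is the package's standard desk-scale experiment:
10 patients, 1 fraction each, the reference-to-beam-on pair (the hardest
one), all three strategies plus the one-sided variant, on the 64 × 64 × 48 /
3 mm phantom. These sizes are the package's validation choice: large enough
that doubling pairs occur and orderings are stable, small enough to run a
full cohort in minutes. `scripts/acceptance.R` runs exactly this experiment
and writes its headline numbers.

## Known limitations

* The mapping between the emulated system's "mesh detail" parameter and a
  vertex count is unknown; the icosphere subdivision level is an uncalibrated
  surrogate, and whether the emulated correspondence refines beyond its
  initial surface projection is likewise unknown — none is applied here.
* The solver is a faithful-in-spirit surrogate of a proprietary optimiser;
  properties are asserted as strategy *orderings* on the phantom, never as
  clinical absolute values.
* Dose is never warped or accumulated; the DVH comparison isolates the
  dosimetric consequence of contour misalignment only.
* Interior (volumetric) registration error is not assessed — controlling
  points live on surfaces, and no interior landmarks exist in the phantom.
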