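---
title: "Modeling tricuspid regurgitation in synthetic HLHS valve cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling tricuspid regurgitation in synthetic HLHS valve cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvsim)
```

## The problem

In hypoplastic left heart syndrome (HLHS), the tricuspid valve becomes
the systemic atrioventricular valve, and tricuspid regurgitation (TR) —
a backward leak through the incompletely closed valve — is a major
driver of mortality through the staged palliation. The clinical
literature has linked TR to annular dilation, annular flattening,
leaflet tethering and prolapse, but mostly through univariate group
comparisons. `tvsim` implements an engineering-style pipeline for
studying these relationships in a controlled setting:

1. generate a *pseudo-population* of valve geometries spanning the
   clinically observed ranges of seven measurements,
2. simulate quasi-static closure of each valve under transvalvular
   pressure,
3. score regurgitation severity as the maximum regurgitant orifice area
   (ROA) over a set of projection viewpoints,
4. grade severity by unsupervised clustering and identify multivariate
   predictors with L1-penalized logistic regression, and
5. estimate tissue stiffness parameters from a segmented point cloud by
   inverse simulation.

Because every stage runs on synthetic valves with known ground truth,
the pipeline's statistical machinery can be validated end to end before
it is pointed at patient data.

## The seven measurements and the pseudo-population

A pseudo-patient is defined by `valve_params()`: the anterior–posterior
and septal–lateral annular diameters (mm), the annular bending angle
(degrees; 180° is a flat annulus, smaller angles fold the annulus about
its AP axis), the three leaflet heights (mm), and the systolic annular
area change (% of the diastolic area lost during closure). The default
sampling intervals (`default_ranges()`) span 100–200% of cohort-average
diameters (emulating annular dilation), ±10% of the average bending
angle, ±50% of the average leaflet heights, and a 5–20% area change.
`sample_cohort()` draws each parameter independently and uniformly
within its interval; a full-factorial grid scheme is available for
sweeps. Draws are a pure function of the seed.

The annulus is realized as a planar ellipse folded about the AP axis so
that each half-loop tilts out of plane by half the bending-angle
deficit; the SL semi-axis is pre-corrected by the fold so the landmark
chord still measures `d_sl` exactly. `annulus_metrics()` recovers
circumference, best-fit-plane projected area, the two landmark
diameters, the dihedral bending angle (from planes fitted to the two
half-loops) and the annular height; the construction round-trips all
generating parameters well within 0.5% / 0.5°.

Leaflets are lofted from the annulus to a constructed free edge. Sector
spans are a fixed convention (septal 120°, anterior 140°, posterior
100°, anterior centered on the +AP landmark; configurable), since
patient-specific sector boundaries are not part of the seven
measurements. Each annulus point maps to a free-edge point displaced
toward the centroid axis and toward the ventricle so that the
straight-line annulus-to-free-edge distance equals the local leaflet
height (70% of the height is spent radially until a floor of 10% of the
local annular radius keeps the reference orifice open). Heights are
smoothed across sector boundaries with a short circular moving average;
sector midlines are unaffected. Two papillary anchor points sit below
the annular plane under the anterior–posterior and septal–posterior
commissures at 0.4 / 0.6 of the mean annular radius (radius / depth);
both are configurable.

## The closure model

`simulate_closure()` implements a deliberately simple structural model —
the point is the *pipeline around it*, not constitutive realism, and
all constants are exposed in `simulation_config()` as calibration knobs:

* **Membrane**: linear springs on mesh edges (`k_membrane`, N/mm),
  at rest in the reference configuration. With `tension_field = TRUE`
  the membrane springs are tension-only: a thin leaflet wrinkles rather
  than supporting compression, and the tension-field idealization drops
  the compressive branch entirely.
* **Bending**: springs between the opposite vertices of adjacent
  triangle pairs (`k_bend`) penalize folding across edges. This is a
  regularization, not a shell model: it selects a smooth configuration
  where the membrane alone would admit many wrinkled ones.
* **Pressure**: the transvalvular pressure (kPa) acts as the exact
  gradient of the enclosed-volume potential, taken relative to the
  annular centroid. At interior vertices this reproduces the usual
  lumped area-weighted-normal load; at the free edge it adds the load
  transmitted through the orifice fluid column. Writing the load as a
  potential makes the whole system conservative, so equilibria can be
  found by energy minimization rather than pseudo-dynamics.
* **Chordae**: unilateral springs (resist elongation only) from every
  free-edge vertex to *both* papillary points, at rest initially;
  papillary points are fixed in space.
* **Contact**: a quadratic penalty (`k_contact`) activates when
  topologically distant vertices (graph distance > 4) approach within
  the contact thickness (0.4 mm default).
* **Annular contraction**: displacement-driven — annulus vertices move
  affinely toward the centroid axis with a radial scale chosen so the
  projected annular area drops by exactly `delta_area` percent at full
  load. This is why the achieved area change tracks the prescription to
  numerical precision.

Loads are ramped linearly over `n_steps` increments; at each increment
the interior is settled by L-BFGS-B on the total energy with the exact
analytic gradient, refreshing the contact candidate set between solves;
a short damped-relaxation burst (the `damping` knob) is used if the
minimizer stalls on a flapping contact set. Convergence is declared
when the maximum nodal residual force falls below `tol` (default
1e-4 N over a 50-step ramp); non-convergence is reported in-state, and
non-finite forces are a hard error naming the ramp step.

Two numerical behaviors are worth knowing. First, with bilateral
membrane springs the contracted, pressurized valve is *multi-stable*:
wrinkling admits many nearby equilibria, and which one the solver finds
can flip under tiny parameter changes. This does not affect the cohort
pipeline (each run is deterministic, and severity is graded within one
consistent configuration), but it matters for inverse analysis — see
below. Second, the ramp-size insensitivity that holds for smooth
tension-dominated states degrades in strongly wrinkled regimes; the
vignette's recommended configurations keep the demonstration in the
well-behaved region.

## ROA scoring

`max_roa()` projects the deformed valve orthographically onto the
top-down viewpoint (the annular normal) and eight offset viewpoints
tilted 20° from it with azimuths 45° apart (both configurable), and
measures, per view, the area inside the projected annulus loop not
covered by any projected leaflet triangle. Areas are measured by pixel
counting at 0.05 mm/pixel by default (0.1 mm in the cohort pipeline),
with pixel-center-in-polygon assignment; a raster on which the annulus
subtends fewer than 100 pixels is rejected with advice to refine.
Orthographic projection keeps areas in mm² and removes camera-distance
effects. The severity score is the maximum over the nine views. On
analytic fixtures the rasterizer reproduces closed forms within 2% and
is invariant under rigid motions within 1%. Near-contacting leaflets
that overlap in projection count as covered — coverage is a 2D
criterion, deliberately matching the projection procedure rather than a
3D gap test. For the log transform downstream, areas below 1e-3 mm²
are floored at 1e-3 mm².

## Severity grading and prediction

`label_severity()` clusters `ln(max ROA)` into two groups. In one
dimension the optimal two-cluster partition is contiguous in sorted
order, so the within-cluster sum of squares can be minimized *exactly*
by scanning the n−1 split points with prefix sums; seeded k-means with
restarts is used only beyond 10,000 cases. The cluster with the larger
center is labeled severe.

`split_cohort()` makes a stratified 70/30 train/test split.
`fit_lasso_logistic()` standardizes features on training statistics,
walks an L1 penalty path of 100 log-spaced values from the strongest
penalty, and returns the model at the smallest penalty whose nonzero
coefficient count stays within the requested budget (3, 5, and 7 in the
pipeline report). Penalized coefficients are reported as-is, in both
standardized and raw-scale form — no post-selection refit.
`evaluate_model()` builds the ROC sweep, computes the c statistic by
the trapezoid rule (validated against the Mann–Whitney normalization to
1e-10), picks the threshold maximizing Youden's J = TPR − FPR (ties
toward the higher threshold), reports sensitivity, specificity and
precision at that threshold, and the precision–recall curve over the
same thresholds. AUC is reported for the test split (primary) and the
full cohort (secondary), since either convention appears in practice.
`compare_features()` runs pooled-variance Student's t per measurement
with raw two-sided p-values (Holm adjustment available but off by
default, matching common reporting practice).

## Inverse material estimation

`fit_material()` estimates `(k_membrane, k_chordae)` by matching the
simulated closed surface to a target point cloud: the residual is the
sum over target points of the orthogonal distance to the closest point
on the triangulated surface, and the optimizer is gradient descent in
log-parameter space with forward-difference gradients and a
backtracking (Armijo) line search, with Barzilai–Borwein step
initialization and a per-iteration move cap of 0.3 log units.

Three further choices make this work reliably on a multi-stable
forward model:

* **Parameter continuation.** Each forward solve warm-starts from the
  equilibrium of the current iterate (or, if supplied, from the
  observed closed configuration), so successive solves track one
  equilibrium branch and the residual landscape stays smooth. Cold
  restarts are attempted when the descent stalls, and kept only if they
  genuinely lower the residual.
* **Axis probes.** When the gradient line search stalls, or the
  relative-change stopping rule (1e-4 over 3 iterations) would fire,
  the two coordinate axes are probed at three step scales and the best
  improving move is taken; the fit stops only when no probe improves.
  Residual valleys here are strongly anisotropic — the chordae
  direction is much shallower than the membrane direction — and pure
  gradient steps under-resolve the shallow direction.
* **Demonstration conditions.** The recommended inverse configuration
  is a pressurized valve with no annular contraction, tension-field
  membrane and `k_bend = 0.5`. Annular contraction induces compressive
  wrinkling and with it genuine non-uniqueness of the closed shape; in
  that regime the same parameters can map to visibly different
  equilibria and no point-cloud residual can identify them. This is
  the practical face of the uniqueness caveat that inverse valve
  modeling carries in general, and `residual_landscape()` exposes it:
  it maps the residual over a stiffness grid, fits a local quadratic in
  log-parameters and warns when the Hessian condition number exceeds
  1e3 (a flat valley).

Under those conditions, synthetic-truth recovery succeeds in 10/10
runs with truths drawn from [0.5, 5] N/mm and inits within a factor of
two (noiseless targets sampled at the mesh vertices), with errors well
under 5%.

## Problem sizes and runtimes

The package's demonstration sizes, chosen to keep a full study
interactive on a single CPU: cohort n = 200; mesh of 32 annulus points
× 2 radial layers (96 vertices, 128 triangles); 4-step ramp at 5e-4 N
tolerance and 0.1 mm/px rasters in the pipeline (~1.5 s per
pseudo-patient, ~6 min end to end); 96-point annuli for geometry
round-trips; the inverse demonstration uses a 3-step ramp at 1e-4 N
with ~100–250 forward solves per fit (~20–40 s). The default
`simulation_config()` (50-step ramp, 1e-4 N) is tighter and
correspondingly slower; use it when individual closed states, rather
than cohort statistics, are the object of study.

## What the synthetic generator does and does not emulate

The generator covers the *geometric* axes implicated in TR — annular
dilation (diameters), annular flattening (bending angle), leaflet size
(heights) and annular dynamics (area change) — sampled independently
and uniformly. Real valves correlate these measurements, have
non-elliptic annuli and regionally varying leaflet geometry, move their
papillary muscles, and carry measurement noise from echo segmentation;
none of that is emulated. Passing tests therefore validate the
*machinery* (geometry construction, solver contracts, scoring
arithmetic, estimator implementations), not clinical conclusions. The
structural model is a calibrated toy: its stiffnesses are not tissue
moduli, its pressure is a single static load, and quantitative
agreement with published patient-cohort coefficients is out of reach by
design. What transfers to real data is the pipeline: segmentation in,
severity scores, predictor rankings and fitted parameters out.

## Known limitations

* Multi-stability of wrinkled states makes position-level ramp
  consistency and inverse identifiability conditional on the
  configuration; the tools warn (`residual_landscape()`) but cannot
  remove the physics.
* The rasterized ROA is resolution-limited; areas below ~100 pixels
  are refused rather than silently under-resolved.
* The 1D exact clustering guarantees the optimal split, but a binary
  severe/non-severe grading is itself a simplification of the clinical
  multi-grade scale.
* Chordae are straight springs to two fixed points; papillary motion,
  chordal branching and leaflet thickness variation are not modeled.
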