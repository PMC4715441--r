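---
title: "Convex-hull body-mass estimation: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convex-hull body-mass estimation: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chullmass)
```

## The method in one page

A fossil's body mass is estimated in three stages.

**Geometry.** The articulated skeleton is partitioned into functional units
— skull, a subdivided cervical series (`neck_1`, `neck_2`, ... so the hulls
track the curve of the neck), trunk, individual limb elements, feet. Each
unit's minimum convex hull is computed and the whole-body predictor is the
sum of segment hull volumes. Totals are reported both with and without the
foot segments: hulls around feet are dominated by the (taphonomically
arbitrary) adduction of the toes, and the method handles that by exclusion
rather than by correction.

**Calibration.** On extant carcasses of known mass, ordinary least squares
is fitted to

$$\log_{10} M_b = a + b\,\log_{10} \mathrm{CH_{vol}},$$

masses in grams, volumes in mm³ (the intercept is unit-bound; convert
first). A type-I regression is the right tool because the line is used for
prediction, not for describing a bivariate scaling law. Residual
non-independence due to shared ancestry can be modelled by generalized
least squares with covariance proportional to shared branch length under
Brownian motion on a user-supplied tree; OLS and PGLS fits on the same data
are compared by AIC.

**Prediction.** At a fossil volume $V_0$ with $x_0 = \log_{10} V_0$:

* point estimate $10^{\,a + b x_0}$, multiplied by the smearing factor
  $e^{\mathrm{MSE}/2}$ to undo the downward bias of back-transforming a
  log-linear mean;
* a 95% prediction interval
  $10^{\,\hat y \pm t_{0.975,\,n-2}\sqrt{\mathrm{MSE}\,(1 + 1/n + (x_0-\bar x)^2/S_{xx})}}$,
  also carrying the smearing factor;
* a hard lower bound $V_0 \times \rho$ with $\rho = 648$ kg/m³, the one
  published whole-carcass density for an intact feathered pigeon — a bound,
  not an estimate, because body volume cannot be smaller than hull volume;
* for calibrations built on eviscerated carcasses, a ×1.33 viscera
  correction approximating live mass from organ-mass fractions measured in
  extant rock doves.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `predictor_variant` | `minus_feet` | — | foot hulls are posture-noise; pigeon-calibrated models predict from minus-feet totals, while externally published ground-dwelling coefficients expect with-feet totals. The variant is stored in the model and enforced when a fossil table is scored. |
| PI `level` | 0.95 | — | convention for reporting uncertainty of a single new observation |
| `density` | 648 | kg/m³ | sole literature value for intact feathered pigeon density; used only for the lower bound |
| `viscera_factor` | 1.33 | — | organ mass ≈ 33% of eviscerated mass in extant rock doves; there are no data on how this scales across body size, so it is a flat factor and should be read cautiously |
| tree branch lengths | all 1 | — | topology-only covariance when no calibrated tree exists; any Newick with lengths is accepted |
| `tau_planar` | 1e-8 × bbox diagonal | mm | scale-free containment/degeneracy tolerance |
| `tau_vol` | 1e-9 | relative | volume comparison tolerance |

## Statistical conventions

* **MSE** is the residual mean square $\mathrm{SSE}/(n-2)$ of the
  log10-scale fit. Under this convention the back-transformed prediction
  intervals reproduce the published dodo intervals to printed precision,
  which is how the convention was pinned down.
* **AIC** uses the full Gaussian log-likelihood (2π constants included) at
  the maximum-likelihood variance $\mathrm{SSE}/n$, with $k = 3$ (intercept,
  slope, variance). For PGLS the likelihood includes $\log\det C$ with the
  Brownian covariance $C$. This reproduces the published AIC magnitudes to
  about 0.1; since the source never states its convention, AIC agreement is
  treated as a soft check, and only OLS-vs-PGLS *comparisons* on the same
  data should be interpreted.
* **Smearing.** The correction is implemented literally as $e^{\mathrm{MSE}/2}$
  with MSE on the log10 scale, the form stated alongside the published
  predictions. The fully consistent log10-normal factor would be
  $10^{\ln(10)\,\mathrm{MSE}/2} = e^{\ln(10)^2 \mathrm{MSE}/2}$; at
  MSE ≈ 0.0045 the two differ by ~0.5%, below reporting precision. We keep
  the literal form for fidelity and note the inconsistency here.
* The correction multiplies the PI bounds as well as the point estimate,
  preserving log-scale symmetry of the interval; whether the original
  analysis did the same is not stated, and at printed precision both
  choices agree.
* **PGLS r²** is the GLS analogue $1 - \mathrm{SSE}_{C}/S_{yy,C}$ with both
  quadratic forms taken in the $C^{-1}$ metric about the GLS-weighted mean.
* **Perfect fits** (SSE numerically zero, as with noiseless synthetic data)
  are snapped to SSE = 0: MSE = 0, zero-width intervals, AIC reported as
  −Inf. The snap threshold is $10^{-12}\max(1, S_{yy})$.

## Geometric choices

The hull is built by incremental insertion with horizon patching
(a Quickhull-family construction): an initial extreme-point tetrahedron,
then each remaining point (farthest first) either falls inside the current
hull or replaces its visible facets with a fan to its horizon loop. The
contract is the output — a closed, outward-oriented triangular surface
containing every input point within `tau_planar`, with every hull vertex an
input point — not the algorithm. Volume is the signed-tetrahedron sum over
oriented facets, origin-independent on a closed surface.

Points are deduplicated before hulling (repeated coordinates create
degenerate simplices). Fewer than four distinct points, or an affine rank
below 3 (collinear/coplanar sets), is a hard `DegenerateGeometry` error and
never a silent zero volume: a zero-volume segment would corrupt the
whole-body total, and a segment too sparse to hull is a data problem the
user must see. Mesh readers consume vertex records only — faces, normals
and non-manifold defects are irrelevant to a hull — so imperfect scan
meshes are acceptable input. Strict visibility during construction uses a
threshold well inside `tau_planar`; a point that is outside by less than
that is treated as on the surface, which keeps the containment guarantee
within tolerance even for exactly coplanar inputs such as box faces.

Mirroring (for bilaterally incomplete material, e.g. a ribcage missing one
side's ribs) is an exact reflection: an involution that preserves hull
volume to floating-point accuracy.

Segment boundaries at joints are taken as given input: how bone surfaces
are apportioned between adjacent functional units is an upstream
segmentation decision the toolkit deliberately does not automate, and the
segment vocabulary is open — any label is accepted, with feet flagged
explicitly rather than inferred from names.

## What the synthetic generators emulate

`make_synthetic_skeleton` produces point clouds on convex polytopes with
closed-form volumes — cuboids, regular tetrahedra, and octahedral
"ellipsoid" approximations whose ground truth is the octahedron's own
volume $\tfrac{4}{3}abc$ (deliberately the polyhedron's, so truth is exact
rather than a converging approximation). Every polytope vertex is included
in the cloud and interior points are strictly-interior convex combinations,
so the generated hull volume is exactly the analytic value and recovery can
be tested at `tau_vol` rather than at a loose approximation band. Poses are
random rigid motions, which the volume must ignore.

`make_calibration_dataset` draws $x \sim U(4.6, 6.2)$ — the extant pigeon
span of log10 hull volume — and masses $10^{a + bx + \varepsilon}$ with
$\varepsilon \sim N(0, \sigma^2)$; recovery tests use $n = 13$,
$a = -2.31$, $b = 0.90$, $\sigma = 0.07$, matching the eviscerated
calibration's size and residual scale. `make_brownian_dataset` draws the
residual vector from $N(0, \sigma^2 C(\text{tree}))$, the regime PGLS
assumes. Generators are pure functions of spec + seed.

What passing these tests does **not** show about real data: synthetic
segments are convex and exactly sampled, whereas real skeletons have
concavities the hull deliberately overestimates; real calibration error is
not exactly lognormal; and composite museum mounts introduce articulation
and completeness error that no statistical interval captures. The packaged
dodo volumes are from composite skeletons — the estimates describe each
mounted hypothetical individual, and damage to hull-defining extremities
(e.g. a lost pubis tip) propagates directly into the trunk hull.

## Problem sizes in the test suite

Monte-Carlo containment checks use 50–500-point hulls with 2–4 × 10⁵
samples (hull-volume agreement to 1%); PI coverage uses 1,000 fresh
calibration-plus-new-draw replicates; coefficient recovery uses 500
datasets of n = 13; the self-consistency sweep covers 100 random segment
specs. These sizes give Monte-Carlo standard errors several times smaller
than the asserted bands while keeping the full suite under a minute.

## Known limitations

* Convex hulls cannot represent concavities; the method is calibrated, not
  corrected, for that bias — which is why the calibration and fossil
  geometry must come from the same hulling protocol.
* Predicting a dodo from pigeons extrapolates roughly an order of magnitude
  beyond the calibration's mass range; the widening prediction interval
  reports this honestly, but the linearity assumption itself is untestable
  out of range. Applying externally published ground-dwelling coefficients
  (`apply_external_model`, with-feet volumes) is the complementary check.
* The viscera factor is a single-species flat correction.
* PGLS assumes plain Brownian residuals (no Pagel's λ or other
  transformations) with, by default, unit branch lengths.
* Centre-of-mass and inertial properties are out of scope: hulls carry no
  mass distribution.
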