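---
title: "Deriving tumor-tracking margins from 4D-CT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving tumor-tracking margins from 4D-CT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tle4d)
```

## The problem

Dynamic tumor tracking (DTT) steers the treatment beam after implanted
fiducial markers, because the tumor itself is hard to see on fluoroscopy.
The method is only as good as the surrogate: across the breathing cycle the
tumor and the markers do not move in perfect synchrony, so even a tracking
system that follows the marker centroid flawlessly leaves a residual tumor
position error.  `tle4d` quantifies that residual — the *target
localization error* (TLE) — from 4D-CT data, and turns it into anisotropic
margins whose geometric adequacy can be checked.

## The statistic

A 4D-CT study provides, for each of 10 respiratory phases, a binary GTV
mask and the 3-D coordinates of $m \in \{2,\dots,5\}$ fiducial markers.
One phase (by default the 30% phase, mid-exhale, usually the most
reproducible) is the *reference*.

For a subset $S$ of markers with per-phase centroid $M_p$, aligning phase
$p$ on the marker centroid translates its structures by
$s_p = M_{\mathrm{ref}} - M_p$.  The GTV centroid $G_p$ then lands at
$G_p + s_p$, and its deviation from the reference GTV centroid
$\hat G = G_{\mathrm{ref}}$ is the localization residual.  Per direction
$d \in \{\mathrm{LR}, \mathrm{AP}, \mathrm{SI}\}$:

$$
\mathrm{RMSE}_d(S) \;=\;
\sqrt{\frac{1}{N}\sum_{p \ne \mathrm{ref}}
\bigl[(G_{p,d} - M_{p,d}) - (\hat G_d - M_{\mathrm{ref},d})\bigr]^2},
\qquad N = 9,
$$

where the bracketed form is the algebraic shortcut used by default:
translating a rigid mask moves its centroid by exactly the shift, so no
mask needs to be resampled.  A mask-shifting mode
(`rmse_per_direction(..., method = "mask")`) exists for end-to-end
validation; because shifts are snapped to whole voxels there, it agrees
with the shortcut only to within half a voxel per axis.

Because marker count and placement vary between operators and
institutions, *every* subset of $\ge 2$ markers is evaluated
(`enumerate_combinations()`), and the per-direction RMSEs are pooled
across all combinations of all patients.  The TLE is the 95th percentile
of the pooled RMSE values; the upper percentile (rather than the maximum)
keeps occasional artifact-driven outlier contours from dictating the
margin.  Grouped by subset size, this yields the familiar report layout
(rows Two, Three, Four, Five, All; per direction the RMSE range, its SD,
and the TLE).

### Conventions the percentile and SD leave open

The source procedure fixes neither the percentile interpolation nor the
SD divisor.  `pool_tle()` defaults to:

* **Percentile**: linear interpolation between closest order statistics,
  rank $h = 0.95\,(n-1)$ zero-based (`stats::quantile` type 7).  This is
  the most widespread convention; it makes the worked check
  "pooled values $1..20 \mapsto P_{95} = 19.05$" exact, and that value is
  pinned by a test.
* **SD**: population divisor $n$, since the pooled combinations are the
  entire population of subsets for the cohort, not a sample from a larger
  one.  `sd_divisor = "n-1"` switches to the sample convention.

Both choices shift the TLE by far less than a voxel for realistic pool
sizes, but they are exposed so a user can match another installation's
convention.

## Margin validation geometry

The alternative, more laborious target construction unions the per-phase
GTVs after marker-centroid alignment (`build_gtv_union_shift()`): shift
the phase-$p$ mask by $s_p$, then OR the 10 masks.  Validation compares
this union target against the reference GTV expanded anisotropically by
the per-direction TLE (`expand_mask()`, an ellipsoidal morphological
dilation with mm semi-axes), with a further 5 mm isotropic expansion to
the PTV:

* `r_v_union_ref` — volume ratio of the TLE-expanded GTV to the union
  target (≈ 1 when the margin recipe reproduces the union construction);
* `centroid_distance_mm` — 3-D Euclidean distance between their
  centroids;
* `coverage_fraction_geometric` — the fraction of the union target's
  volume contained in the PTV.  This is a deliberate geometric proxy for
  dosimetric coverage: a conformal plan prescribes full dose to the PTV,
  so union-target voxels outside the PTV are exactly the ones at risk of
  underdose.  No dose calculation is performed, and the column name says
  so.

Numerical choices: mask shifts are snapped to the nearest whole voxel
(round-half-away-from-zero per axis) with the sub-voxel remainder
recorded, which conserves volume exactly and avoids interpolation
pseudo-volumes on binary masks at the cost of a bounded half-voxel error;
grids are padded (`pad_mask()`, automatic inside `make_target_set()`) by
the largest shift plus both margins so nothing falls off the edge; an
expansion margin of zero on an axis admits no displacement along that
axis; empty masks are rejected before any centroid is taken.

## The synthetic phantom

No patient 4D-CT can be redistributed, so the package generates studies
with *known* asynchrony.  Each object (tumor, each marker) follows

$$x_d(p) = b_d + A_d\, w\!\left(\tfrac{p}{n} + \varphi\right)
  + \delta_d\, p + \varepsilon, \qquad p = 0,\dots,n-1,$$

with per-axis amplitude $A$, phase lag $\varphi$ (cycles), baseline $b$,
linear drift $\delta$, and iid Gaussian noise $\varepsilon$.  Waveforms:
a pure sinusoid (closed-form oracles) and a Lujan-type $\cos^4$ that
dwells at exhale (realism).  The tumor is rasterized as a digitized
sphere — a voxel is occupied iff its center lies inside the sphere — and
markers stay mathematical points, since only their centroids enter the
computation.

`analytic_residual_rmse()` evaluates the residual formula directly on the
continuous, noise-free trajectories and is the independent ground truth
the pipeline is tested against: agreement is exact in centroid mode and
within rasterization tolerance in mask mode.

### Cohort defaults and what they represent

`random_phantom_spec()` fixes the study conditions for the simulated
cohorts, chosen once as a plausible lung-SBRT scenario:

| parameter | default | why |
|---|---|---|
| SI tumor amplitude | 5–15 mm | dominant breathing direction; lower-lobe lung tumors commonly move ~5–15 mm |
| AP / LR amplitudes | 1–5 / 0.5–3 mm | secondary directions, typically a few mm |
| marker phase lags | ≤ 0.1 cycle | small tumor–marker asynchrony; no published distribution exists, so a modest bound was set a priori |
| marker amplitude mismatch | ±15 % per axis | markers ride nearby but not identical anatomy |
| marker distance from tumor | 10–30 mm | "implanted near the tumor" |
| positional noise | 0.3 mm SD per axis | delineation / localization jitter |
| waveform | $\cos^4$ | exhale dwell of real breathing |
| grid | 1 × 1 × 2.5 mm | in-plane CT resolution with a coarse slice thickness, the harder case for voxel snapping |
| tumor radius | 5–12 mm | 10–24 mm diameter lesions |

With these settings the simulated cohort (11 patients, marker counts
2/3/4/5 in proportions 1/2/4/4, hence 71 + 58 + 24 + 4 = 157
combinations) produces SI-dominant TLEs of a few millimetres and
validation ratios near 1 — the qualitative regime the method was designed
for.  The phantom emulates rigid, periodic, slightly asynchronous motion
with optional drift and noise; it does **not** emulate deformable
anatomy, hysteresis beyond a phase lag, CT reconstruction artifacts
(which in practice smear markers to ~10 mm streaks and are the main
real-world confounder of the union target), inter-observer contour
variability, or marker migration.  Green tests on phantoms therefore
certify the *computational chain*, not the clinical magnitudes: the
patient-derived TLE values cannot be reproduced without the clinical
data.

## Correlation analysis

Two covariates are attached to every combination: the per-direction
distance from the marker-subset centroid to the GTV centroid at the
reference phase (*marker–GTV distance*), and the subset centroid's
maximum per-direction displacement from the reference phase across the
cycle (*respiratory marker motion*; a peak-to-peak alternative is a
flag).  `correlate_tle()` reports Pearson r and two-sided p per group ×
direction × covariate.

Two readings had to be fixed here.  First, the error variable: a group's
TLE is a single percentile and admits no correlation, so the
per-combination RMSE is correlated instead — the only reading that
produces the advertised analysis.  Second, the covariates of a multi-
marker subset are computed for the subset *centroid* (not per member),
matching the quantity the alignment actually uses.  No multiplicity
correction is applied by default, mirroring the plain Pearson analysis;
groups smaller than 3 or with degenerate covariates are skipped with a
warning rather than silently dropped.

## Problem sizes

The bundled tests and the acceptance script run entirely on generated
phantoms: 11 + 10 study cohorts on ~50³ voxel grids, 50 random phantoms
for oracle equivalence, a 3 × 3 amplitude × lag recovery grid, and 200
seeds for the marker-averaging trend — sizes picked so the whole suite
completes in well under a minute while keeping every Monte-Carlo
assertion far from its decision boundary.

## Known limitations

* Alignment is pure translation of the marker centroid; rotational or
  deformable alignment and distance-weighted marker pooling are out of
  scope.
* Voxel-snapped shifting bounds, but does not remove, a half-voxel error
  in mask mode; the centroid shortcut is exact and is the default.
* The geometric coverage fraction is a containment proxy, not dosimetry;
  beam models, dose grids and plan optimization are explicitly not
  modeled.
* NIfTI is the only raster interchange format; marker tracks travel as
  CSV, studies as YAML manifests.
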