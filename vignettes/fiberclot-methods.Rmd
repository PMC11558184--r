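---
title: "Models and methods behind fiberclot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fiberclot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberclot)
```

`fiberclot` analyses clot formation in rod-array flow chambers that mimic
the hollow-fiber bundle of an artificial lung. This vignette records the
models the package implements, the parameter choices that matter and why
they were made, and what the synthetic-data generator does and does not
emulate.

## Chamber geometry and hemodynamic quantities

A chamber is a rectangular duct, width `W` = 7.3 mm (x), height `H` = 3 mm
(y), path length `L` = 20 or 40 mm (z, the flow axis), filled with vertical
rods of diameter `d_f` = 380 μm standing in for gas-exchange fibers. The
packing density `PD` is the areal fraction of the plan region covered by
rod cross-sections.

**Lattice.** The rods are "evenly spaced"; the package defaults to a
square lattice aligned with the flow axis — the simplest layout consistent
with an even array — with spacing `s = d_f * sqrt(pi / (4 PD))` so that one
circle per cell produces exactly the requested areal fraction. A hexagonal
option is provided (`s = d_f * sqrt(pi / (2 sqrt(3) PD))`, alternate rows
offset). Packing densities at or above the square circle-packing bound
`pi/4 ≈ 0.785` are rejected as infeasible. Rods whose circles cross the
chamber boundary are kept and clipped at voxelization; realized packing
density is therefore measured over an interior window spanning whole
lattice cells, where it converges to `PD` as the voxel size shrinks
(within 1% at 10 μm voxels).

**Velocity convention.** Stated velocities are treated as superficial —
flow rate over the full frontal area, `Q = u_s · W · H` — because
20 cm/min × 7.3 mm × 3 mm reproduces the device flow rate of 4.38 mL/min
exactly. The companion rates printed for 16 cm/min (3.65 mL/min) are not
internally consistent with this convention (16 × 0.219 = 3.504); the
package treats velocity as primary. Interstitial velocity follows as
`u_i = u_s / (1 − PD)`.

**Hydraulic diameter and Reynolds number.** For an infinite rod bundle,
`D_h = 4 × void volume / wetted rod surface = d_f (1 − PD)/PD`, chamber
walls excluded. The Reynolds number is evaluated strictly in SI units:
`Re = ρ u D_h / μ`. For the 50% chamber at the baseline condition
(ρ = 1.09 g/mL, interstitial u = 40 cm/min, D_h = 0.38 mm, μ = 3.4 cP)
this gives `Re ≈ 0.81`, i.e. deeply laminar creeping flow. Reported
Reynolds numbers for such devices are sometimes two orders of magnitude
larger (consistent with a unit slip of about 96× in one of the
conversions); `fiberclot` reports the SI value and makes no attempt to
reproduce figures that cannot be derived from the stated formula.

**Units.** Lengths are stored in mm, time in minutes, pressure in mmHg,
viscosity in cP, with conversions localized in the functions that need SI
(`reynolds()`). This makes the measured baseline fixtures exact.

**Equivalent distances.** To compare clot across conditions at matched
cumulative fiber surface exposure, the package ships the published lookup
(6.8 / 5.7 / 4.5 mm for 16 / 20 / 25 cm/min; 10.0 / 5.7 / 3.2 mm for
40 / 50 / 60% packing), which is the default. An analytic criterion is
also provided: cumulative surface per unit flow, `S(d)/Q`, matched to the
(20 cm/min, 50%, 5.7 mm) reference, giving `d = 5.7 (0.5/PD)(Q/Q_ref)`.
The analytic rule reproduces neither the published packing-density
distances (it gives 7.1 and 4.75 mm where 10.0 and 3.2 mm are published)
nor the direction of the velocity adjustment; the exact matching rule
behind the published values is not stated, so the lookup table is kept
authoritative and the analytic mode is clearly subordinate.

## The synthetic-data generator

No scan data are distributed with the package; every downstream stage is
validated against phantoms whose ground truth is known exactly.

**Voxel phantoms.** `voxelize_chamber()` rasterises the rod array (rods
span the full height) plus 1-voxel walls on the x/y faces onto an
isotropic grid; axis 1 is width, axis 2 the rod axis, axis 3 the flow
axis with the inlet at index 1. The default voxel size is 20 μm — not the
scanner's 3 μm — so a full 2 cm chamber fits comfortably in memory
(365 × 150 × 1000 voxels); it is configurable down to 5 μm for
convergence studies, and cohort-scale simulations in the tests and the
acceptance script use 50 μm, a deliberate problem-size choice that
preserves every qualitative feature (gaps between rods remain 2–3 voxels
wide at 50 μm).

**Clot accretion.** Clot growth is a phenomenological stochastic surface
accretion, not a coagulation model. At each step every fluid voxel
face-adjacent (6-connectivity) to solid or existing clot converts with
probability `1 − exp(−λ)`, where

```
λ = β0 · exp(β_z · z/L) · (1 + β_in · 1[z < z_in]) ·
    exp(−gap/δ) · (u_ref/u_i)^α
```

The factors encode, in order: a base deposition intensity; an exponential
rise toward the outlet (clot accumulates preferentially near the outlet
where activated factors have accumulated and the outlet housing captures
emboli); an inlet-capture boost over the first `z_in` of the chamber
(emboli arriving from upstream); gap bridging — `gap` is the distance to
the surface of the *second*-nearest rod, so deposition concentrates in
narrow inter-fiber gaps where fibrin strands bridge adjacent fibers; and
an inverse dependence on interstitial velocity normalized to
`u_ref = 40 cm/min`, the interstitial velocity of the baseline (20 cm/min,
50%) condition. Face connectivity guarantees clot that is connected to and
nucleated on surfaces, matching the observation that deposition begins
directly on fiber surfaces.

Defaults, chosen once as a realistic operating point and not revisited:
`β0 = 0.006` (a baseline run clots roughly 8% of its void volume over a
15-minute experiment — visible but far from occlusive), `β_z = 2` (about a
sevenfold inlet-to-outlet intensity ratio), `β_in = 0.5` over `z_in = 1 mm`
(mirroring the 1 mm inlet region that is cropped from analysis),
`δ = 0.15 mm` (commensurate with the 55–153 μm surface-to-surface gaps of
the studied lattices, so tighter packing deposits distinctly faster),
`α = 1`, and `T = 15` steps — one per experimental minute. With these
defaults the generator reproduces the qualitative regularities the
analysis is meant to detect — more clot at higher packing density, less at
higher velocity, outlet-dominant spatial distribution with secondary inlet
capture — but makes no claim to reproduce absolute clot volumes in mm³
from any real experiment.

Determinism: the accretion kernel (compiled, Rcpp) draws from R's RNG in a
fixed voxel order, so a fixed seed yields bit-identical volumes across
runs and platforms. The grayscale renderer and cohort generator likewise
take seeds; in `generate_cohort()` and `run_pipeline()` every per-run seed
derives from the single design seed and is recorded.

**Scan rendering.** `render_grayscale()` assigns fluid 0.2, clot 0.6,
solid 1.0, applies an isotropic Gaussian PSF, adds Gaussian noise and
clips to [0, 1]. The default PSF of 5 μm matches the emulated instrument
(about two native 3 μm voxels) and is therefore sub-voxel at the package's
emulation voxel sizes; it becomes material only when rendering fine grids.
The default noise (sd 0.05) leaves the three intensity classes separated
by 4 sd, which is deliberately benign: the package's purpose is to
validate the quantification chain against known truth, not to benchmark
segmentation robustness.

**Donor-paired cohorts.** Each donor receives a single multiplicative
factor on `β0`, log-normal with log-sd `donor_effect_sd = 0.15` (mean 1),
shared across all of that donor's runs — the structure implied by a paired
design in which one donor's blood perfuses every chamber configuration.
aPTT covariates are drawn uniform over the 20–50 s inclusion range; they
are carried as metadata and not used by the simulator (the donor
multiplier already subsumes donor-level procoagulant variation).

**Resistance.** The simulator maps an occlusion trajectory φ(t) to
resistance with a Kozeny–Carman-style porosity law,
`R(t) = R0 ((1 − PD)/(1 − PD − φ(t)))^2`. No quantitative occlusion law is
available for these chambers — only monotone trends — so the exponent is
configurable; the square is the simplest porous-media-flavoured choice
that is convex and diverges at full occlusion. Baselines `R0` are shipped
measured constants (0.333 / 0.365 / 0.379 mmHg·min/mL at 2 cm for
40/50/60% packing, 0.615 at 4 cm and 50%); for non-studied geometries the
fixture table is interpolated linearly in packing density and in path
length through the measured 2 cm and 4 cm points. Real devices show
transient resistance *decreases* at medium and high velocity before the
rise; the simulator is monotone by construction and does not reproduce
such transients.

## The quantification chain

`segment_volume()` implements the two-stage segmentation: stage one
thresholds fluid against everything denser using two-threshold
(three-class) Otsu on the global 256-bin histogram, keeping voxels above
the lower threshold — a clotted scan is inherently three-class (fluid,
clot, solid), and a single global Otsu threshold tends to land on the
clot mode itself; stage two removes the chamber by clean-mask subtraction
(`subtract_mask()`), leaving clot only. A flat (zero-variance) image is
rejected rather than segmented.

`crop_volume()` removes 0.4 mm from top and bottom, 1.3 mm from each
side, and 1 mm from the inlet (outlet untouched) to exclude wall- and
inlet-activation artifacts. Margins snap to whole voxels toward the
interior, and the volume's physical origin is advanced so that all
downstream distances — slice centres, equivalent-distance slabs — remain
measured from the true inlet face. This matters: published equivalent
distances (e.g. 3.2 mm) fall inside the cropped first millimetre's
coordinate frame if one forgets the offset.

`slice_profile()` interprets "five locations summed for 2 mm segments" as
2-mm segments centred at 5%, 25%, 50%, 75% and 95% of the cropped length
(entrance, first quarter, middle, third quarter, downstream end), clipped
inward at the ends; whether the five published segments overlap or tile
only part of the chamber is not stated, so a contiguous `tiling` mode is
also provided and is the one used for conservation tests (its segment
volumes sum exactly to the total clot volume). Normalization divides clot
volume by the void volume available for clot, `V_region (1 − PD)` — the
printed formula's typography is ambiguous between multiplying and
dividing by `(1 − PD)`, and division is what "normalized based on the
available volume for clot to form" means. Because cropped windows near
walls contain slightly more void than `1 − PD` (boundary rods are
clipped), normalized fractions may exceed 1 by a few percent for
saturated phantoms; values beyond 5% over the available volume raise an
error as physically impossible.

`probability_map()` is the voxelwise mean of replicate binary masks — an
estimate of per-voxel clot probability under a condition — and
`project_axis()` averages along the rod axis by default, producing the
inlet-to-outlet plan view used for display. The projection axis
terminology in imaging protocols is inconsistent ("Z-axis" vs
"longitudinal"); the rod-axis projection is the one that yields the plan
view shown in such figures, and the flow-axis alternative is exposed
explicitly.

## Statistics

Mixed models with aPTT covariates (as fitted in proprietary software for
the original benchtop data) are deliberately not re-implemented: the
claims exercised by synthetic cohorts are paired effect *directions*, and
a donor-paired sign-flip permutation test addresses exactly that
exchangeability without fragile covariance-structure assumptions. The
statistic is the mean within-donor difference; the null flips each
donor's difference sign independently. With n ≤ 15 donors all 2^n
patterns are enumerated and the p-value is exact (identity included, so
never zero; the smallest attainable two-sided p with 6 donors is
2/64 ≈ 0.031). Sampled mode uses the add-one rule
`(1 + #{|T*| ≥ |T|})/(n_perm + 1)`. Bonferroni adjustment wraps
`stats::p.adjust`; trend direction across ordered condition levels is a
Spearman rank correlation. Published p-values from the original donor
experiments derive from real blood and a different model family and are
not reproduction targets.

## Numerical choices and degenerate inputs

- Voxel membership is by voxel-centre-in-circle; physical extents match
  the spec within one voxel per axis.
- The accretion update is synchronous (all conversions in a step are
  decided against the pre-step state) — growth is order-independent
  within a step, and the per-step clot count is nondecreasing by
  construction.
- Gaussian blur is separable, implemented as banded sparse-matrix
  products per axis with edge-renormalized kernels.
- Otsu histograms use 256 bins; ties in the between-class variance
  resolve to the lowest threshold bin, so a noiseless image thresholds at
  the upper edge of the fluid mode.
- Zero flow, non-positive resistances, occlusion `PD + φ ≥ 1`, margins
  exceeding extents, mismatched grids, unpaired donors and infeasible
  packings all raise immediate, specific errors.
- `excess_over_baseline()` uses strict inequality: the baseline itself is
  clot-free by definition.

## Problem sizes used by the tests

Unit tests run on 6-mm chambers at 40–60 μm voxels; the end-to-end oracle
check uses the full 2 cm chamber at 20 μm voxels; effect-recovery runs
ten 6-donor cohorts (four conditions each) at 50 μm voxels. These sizes
were chosen so the whole suite completes in minutes on a laptop while
keeping every geometric feature resolved (the narrowest inter-rod gap
spans at least two voxels in all configurations).

## Known limitations

- The generator is phenomenological: no coagulation biochemistry,
  platelet mechanics, or flow-coupled transport; parameters were chosen
  for qualitative realism, so passing tests demonstrate that the
  *analysis chain* is correct, not that the generator predicts real clot
  volumes.
- No registration: synthetic volumes share a frame by construction; real
  scan alignment is out of scope.
- No reconstruction artifacts (beam hardening, rings) are simulated, and
  no shear-stress computation is provided.
- The resistance law is monotone; observed transient resistance dips are
  outside the model family.
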