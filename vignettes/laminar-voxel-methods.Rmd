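---
title: "Methods: voxel-lattice layering, columns, smoothing, QA, VASO and deveining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-lattice layering, columns, smoothing, QA, VASO and deveining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminae)
```

This vignette documents the models behind `laminae`, the parameters that
matter, the numerical choices made where the design was genuinely open,
and what the synthetic phantoms do and do not establish about real data.

## The lattice stance

Everything operates on the voxel index lattice. The only geometric
information used anywhere is the voxel size (header `pixdim`), which
scales step costs; the NIfTI affine is carried through to outputs
untouched. This is a deliberate trade: native-EPI-space processing with
no topology or anatomical-reference requirements, at the cost of
discretization effects that each algorithm must handle explicitly
(metrication error in distances, jagged unit columns, Pythagorean error
in step counting). Single-slice volumes (`nz = 1`) are first-class: all
neighborhoods degenerate from 26/6-connectivity to their 8/4-connected 2D
forms automatically.

## Layering

**Depth growing.** `grow_geodesic_depths()` computes multi-source
shortest paths on the 26-connected lattice with true Euclidean
center-to-center step costs (`1, √2, √3` scaled per-axis by the voxel
size). Euclidean costs remove the metrication (Pythagorean) error at the
source rather than patching it afterwards, and anisotropic voxels need no
special casing. Growth from the inner border (code 1) may traverse only
codes `{1, 3}`, growth from the outer border (code 2) only `{2, 3}`: a
path can never shortcut across the CSF gap between kissing gyri, which is
the failure mode voxel-space layering must avoid. Metrication error on
the 26-neighborhood is bounded (worst case about 3–8% for directions
between lattice axes in 2D/3D); the annulus test shows the residual
largely cancels in the *normalized* depth because numerator and
denominator are distorted alike. Ties for the nearest border voxel
resolve to the smallest linear voxel index, making streamline assignment
deterministic. Gray-matter voxels unreachable from either border carry
`Inf`, are reported once via a warning, and are excluded downstream;
`validate_rim()` flags them before any computation if asked.

**Unit columns.** Voxels are grouped by their nearest outer-border voxel.
This is the thinnest exhaustive partition anchored on one surface, but by
construction each initial column touches exactly one outer voxel, so a
repair pass makes the partition depth-spanning: a column with no member
26-adjacent to a code-1 voxel is merged into the column of the
steepest-descent gray-matter neighbor of its least-deep member, iterated
to a fixed point. After merging, every column touches at least one inner
and one outer border voxel, and curvature is classified by comparing the
counts of unique inner vs. outer border voxels its streamlines touch
(more outer = gyrus, more inner = sulcus, equal = straight). On discrete
rings the per-column classification is noisy at one-voxel scale — thin
columns can touch two inner voxels through near-ties — but the
member-weighted majority flips correctly between convex and concave
geometries, which is what the tests assert.

**Equi-volume metric.** Per column, the balancing depth `m*` is the
median of member `equidist` values: the median is exactly the point that
splits the member count in half, which is the discrete equi-volume
criterion. The factor pair `(a, b) = (1 − m*, m*)` then drives the
simplex perturbation
`equivol = equidist·a / (equidist·a + (1 − equidist)·b)`, a strictly
increasing bijection of `[0, 1]` for `0 < m* < 1` that is the identity at
`m* = 0.5`. Consequences that the tests pin down: flat slabs (zero
curvature) give `equivol ≡ equidist` to machine precision, and on a 2D
ring the `equivol = 0.5` contour lands on the equal-area radius
`√((r₁² + r₂²)/2)` within a voxel — in 2D, equi-volume is equi-area.
Columns with fewer than 2 members cannot balance anything; they get
`(0.5, 0.5)` (no push) and are flagged. The factor fields can be smoothed
across gray matter by `smooth_iters` iterations (default 3) of a
26-neighborhood mean restricted to code-3 voxels — restriction makes the
smoothing kissing-gyri safe, and 3 iterations of the one-voxel kernel
soften inter-column steps without erasing curvature structure. Set
`smooth_iters = 0` to reproduce the per-column analytic behavior exactly.

**Quantization.** `layer_id = 1 + floor(metric · N)` with the last bin
closed, so bins are half-open `[k/N, (k+1)/N)` and a metric of exactly 1
stays in layer `N`. Both continuous metrics are always available
alongside the labels so users can re-bin without recomputation.

## Columnar distances

Lateral distances grow from a user landmark with **unit steps on the
face-connected neighborhood** (6 in 3D, 4 in 2D): a diagonal neighbor
counts two steps. This deliberately differs from the Euclidean-cost
choice in layering: columnar growth is defined by iteration counts, and
the resulting Pythagorean error is removed by the prescribed within-layer
smoothing passes instead. The growth is confined to a middle-depth band
(`equidist ∈ 0.5 ± band_halfwidth`, default half-width 0.15) so the
coordinate is defined where the ribbon is best sampled; distances then
extrapolate to all depths by inheritance from the nearest assigned voxel,
again confined to gray matter. Both smoothing passes use the
layer-restricted smoother with FWHM of one voxel (scaled by the smallest
voxel size) — enough to cancel the step-count bias (the straight-strip
test recovers arc length within 5%) without shifting the coordinate.
Curved columns acquire a frustum shape across depth purely through the
extrapolation; no geometric construction is imposed. A caveat the smoke
tests exercise: with a thin band, a fold steeper than one voxel of rise
per voxel of run can disconnect the band under face-connectivity; growth
then covers only the landmark's component (with a warning) and the
extrapolation fills the rest by inheritance. Widen `band_halfwidth` for
steep geometry. Without `n_columns`, bins are one voxel wide
(`round(distance) + 1`); with it, bin edges are equal-width over the
middle-band distance range, so column widths are equal in the middle
layer, as the definition requires.

## Anatomically constrained smoothing

Both smoothers are normalized kernel means, hence exact partitions of
unity: constant input is reproduced to machine precision, and `fwhm → 0`
recovers the input. `sigma = fwhm / (2√(2 ln 2))` in mm; kernels truncate
at `truncation_radius` sigmas (default 3).

`layer_smooth()` restricts the Gaussian to voxels with the same layer
label — isotropic smoothing inside each depth bin with hard boundaries
between bins. More layers means narrower depth bins and less
cross-depth leakage. `no_kissing` additionally requires a 26-connected
same-layer path from the center within the truncation window, computed by
a per-voxel breadth-first search; this is a connectivity constraint, not
a geodesic reweighting, which matches the "blocked, not attenuated"
semantics the kissing-gyri problem calls for.

`grad_smooth()` multiplies the distance Gaussian by
`exp(−ΔI² / (2 (selectivity · s_local)²))`, where `I` is an independent
anatomical-contrast image and `s_local` its standard deviation in the
truncation window. Two open choices are documented rather than hidden:
"local signal variance" is operationalized as the windowed *SD* (keeping
the penalty in intensity units; a variance convention would square the
scale), and the "entropy-weighted" difference penalty is implemented as
this Gaussian-in-intensity form, the standard edge-preserving kernel,
since no entropy formula is fixed by the description. The kernel is
always built from the `gradfile`, never from the data being smoothed —
with single-digit tSNR a data-driven kernel would chase noise. Where the
window is intensity-flat (`s_local = 0`) the penalty is disabled and the
voxel flagged. With `selectivity = 0.08` the step-edge test shows
cross-edge contamination below `10⁻³` of the step height.

## QA metrics

In the thermal-noise regime, artifacts hide below the noise floor of
tSNR; they surface as non-Gaussianity (skew, excess kurtosis) or as
spatiotemporal coupling (lag-1 autocorrelation, global-signal
correlation, noise kernel). Conventions: kurtosis is excess (Gaussian =
0); the global signal is the mask-mean time course; correlations use
per-voxel linear detrending by default (drift trivially inflates them)
while moment maps are computed raw by default — both switchable. The
noise kernel averages, over all in-mask voxel pairs at each offset up to
`radius` (default 5, an 11³ window), the Pearson correlation of their
time courses, and returns the full `(2r+1)³` volume rather than an FWHM
summary, preserving negative sidelobes and diagonal structure. The tests
calibrate all of this against generators with known truth: white noise
(moment sampling bounds `3√(6/nt)`, `3√(24/nt)`; kernel off-center bound
`2/√nt`), temporal AR(1) (lag-1 = φ), x-axis-coupled AR(1) noise
(kernel(±1,0,0) = φ, other offsets 0), and Gaussian-filtered noise
(kernel follows the analytic `σ√2` autocorrelation within 15%).

## VASO

The acquisition interleaves blood-nulled and not-nulled volumes; T1 and
T2* relaxation are independent multiplicative factors, so BOLD
contamination divides out: `vaso = nulled / bold` after aligning the two
series. Alignment linearly interpolates BOLD onto the nulled timestamps
(the nulled series is the contrast of interest and is never resampled),
holding endpoints. Linear interpolation is exact on affine signals and
second-order accurate otherwise; the block-design generator uses
raised-cosine ramps (8 s) over 20 s blocks at `tr_pair = 2 s`, values in
the range of typical laminar VASO protocols, which puts the recovery
error at the interpolation limit (below 0.3% relative) rather than at a
transition artifact. Division guards: denominators at or below `1e-9` of
the series mean yield `NA` plus a flag; clipping to
`[0, clip_max · voxel-mean]` exists for vessel blow-ups but is off by
default so it can never silently alter data. Explicit timestamp vectors
cover variable-TR acquisitions.

## Model-based deveining

Profiles are ordered deep → superficial, asserted everywhere — silent
ordering bugs are the dominant failure mode in this family of methods.
The three corrections:

* **linear**: subtract the least-squares trend across depth (needs
  `K ≥ 3`); idempotent, annihilates affine profiles.
* **scaling**: divide by `s = c / mean(c)` where `c` is the CBVv depth
  profile; a pure gain profile flattens exactly.
* **leakage**: solve `S = A m` by forward substitution with
  `A[i,j] = c_j / c_i (i > j)`, unit diagonal. The published leakage
  models share this triangular-mixing formalism and differ only in how
  the weights are estimated; the CBVv-ratio rule is the package default
  and any weight matrix can be substituted by editing the model object.
  Uniform CBVv reduces `A` to a cumulative sum, a useful sanity limit.

Because `A` is unit-triangular the inversion is exact (round-trip error
at machine precision in the tests), but noise amplifies: corrected-layer
variances follow `‖A⁻¹ rows‖² σ²`, which the Monte-Carlo test reproduces
within 10%. `devein_voxelwise()` applies the 1D corrections per region
(unit column or user ROI) and broadcasts ratios/offsets back to voxels,
so corrected maps remain inspectable across layers and columns. CBVv can
be estimated as per-layer GLM-residual SD normalized to mean 1 — a
convention, stated as such.

## What the phantoms do and do not show

The generators produce exactly the structures each algorithm is designed
to detect or preserve: analytic rim geometries (slab, ring, folded wall,
kissing gyri) with closed-form depth truths; seeded noise with known
moments, temporal or spatial coupling; forward-simulated VASO runs and
leaky laminar profiles. Passing tests therefore establish algorithmic
correctness — distances match an independent shortest-path oracle to
`1e-9` mm on random geometries, smoothers match literal brute-force
kernels to `1e-12`, inversions are exact — under ideal segmentation and
stationary noise. They do not establish robustness to segmentation
error, partial-volume effects at real border voxels, motion, distortion,
or physiological noise, none of which the phantoms model. Problem sizes
in the tests (chosen as comfortable desk-scale checks): 20 random rims up
to 20³ for the distance oracle, 16³ volumes for brute-force kernel
equivalence, 1000-voxel / 1000-timepoint noise fields for moment bounds,
and one 64³ folded-wall phantom driven end-to-end through the CLI.

## Known limitations

* Curvature classification is per-unit-column and noisy at one-voxel
  scale; treat the member-weighted aggregate, not single columns.
* The equi-volume construction assumes columns sample the full depth;
  heavily under-resolved cortex (thickness near 1–2 voxels) degrades
  `m*` toward the flagged no-push default.
* Columnar distances depend on a manually placed landmark and a
  connected middle-depth band; disconnected slabs map only the
  landmark's component.
* No sub-voxel machinery: users wanting finer layers should upsample the
  rim before layering, not the outputs after.
* Deveining inherits its weights' physiology; the package implements the
  formalism exactly but takes no position on which published CBVv
  profile is correct.
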