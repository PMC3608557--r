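---
title: "Methods: caliber classification and volumetric dispersion of microvessel networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: caliber classification and volumetric dispersion of microvessel networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halovasc)
```

## The measurement problem

Fluorescent staining of vessel walls in thick tumor sections yields 3D
confocal stacks in which microvessels appear as bright hollow tubes on a
dark background. Three properties of the network carry treatment
information: the amount of vessel wall (percent volume, V%), the caliber
spectrum of the vessels, and their spatial arrangement (evenly distributed
versus clustered). `halovasc` computes all three per sample and compares
them across treatment cohorts. This vignette documents the model behind
each stage, the tunable parameters, the numerical conventions, and what the
synthetic validation does and does not establish.

## Preprocessing

**Isotropic resampling.** Confocal stacks are anisotropic (default
0.54 µm in-plane, 1 µm between slices). All later morphology — Cartesian
cross-sections, structuring elements, thinning — assumes cubic voxels, so
stacks are resampled along z by linear interpolation to
`round(n_z * axial/lateral)` slices. Linear interpolation is the right
order here: higher orders can overshoot and manufacture intensities, while
nearest-neighbor quantizes tube walls. The operation is the identity once
the pitches are equal, hence idempotent. Intensities are rounded back to
integers and clamped to [0, 255].

**Conditional contrast normalization.** Each z-slice whose dynamic range
exceeds 30 grey levels is linearly rescaled so min maps to 0 and max to 255
(rounded to nearest; the map is monotone, so within-slice intensity order
is preserved). The strict `> 30` gate protects slices that contain no
structure: stretching a noise-only slice would amplify noise into the
signal range. The gate value is the package default and is exposed as
`min_dynamic_range` in `run_config()`.

**Rényi-entropy binarization.** The binarization threshold is computed
from the pooled 256-bin histogram by the Rényi-entropy criterion: the
maximum-entropy thresholds at Rényi orders 1/2, 1 and 2 are combined with
weights that depend on their mutual agreement (within 5 grey levels), and
the result is truncated to an integer; voxels strictly above the threshold
are foreground. Entropy-based thresholds are well suited to sparse bright
structures because they are driven by the shape of the histogram rather
than by the (dominant) background mode, and in practice they sit just
above the background tail, which keeps faint specks out while the
subsequent particle filter removes the rest. One threshold is computed for
the whole stack, not per slice: per-slice thresholds flicker between
adjacent slices and modulate vessel thickness along z. A per-slice variant
(`threshold_method = "renyi_per_slice"`) exists for comparison.

## Caliber classification

**Particle filter.** 26-connected components whose *maximal* 2D
cross-section over all slices of all three Cartesian orientations is below
`min_particle_px` (default 4 px ≈ 1 µm² at 0.54 µm) are deleted. Using the
maximum over orientations is what lets 1-voxel-thick but long filaments
survive (their longitudinal section is large) while isolated specks die.
The exact particle criterion of the original ImageJ tooling is not fully
specified anywhere; "maximal cross-section over the three orientations,
strict inequality" is this package's fixed, documented interpretation, and
the threshold is configurable.

**Vessel fill.** Since only walls are stained, calibers must be measured
on filled vessels. Holes are filled in 2D, slice-wise, in each of the
three orientations, and the three fills are unioned with the input. A pure
3D fill cannot fill tubes open at the stack faces (their lumen connects to
the outside), and any single orientation misses tubes whose profile in
that orientation is an open "C" (e.g. tilted tubes); the three-orientation
union handles both, at the cost of slightly over-filling blind-ended
concavities. The fill is extensive and idempotent, and in-plane foreground
uses 8-connectivity (hence background 4-connectivity for hole detection).

**Minimal Cartesian cross-section.** Every filled voxel receives the
smallest area (pixel count, 8-connected) of the 2D component containing it
among its xy, xz and yz slices. For a tube roughly aligned with an axis,
the transverse slice is by far the smallest of the three, so the minimum
tracks the tube's cross-section. Two systematic effects are inherent and
documented rather than corrected:

* *Tilt inflation.* A Cartesian slice of a cylinder tilted by θ from the
  slicing axis cuts an ellipse of area A/cos θ; within 45° of the nearest
  axis the worst factor is √2 ≈ 1.41. Calibers are therefore indicative,
  and bin edges grow geometrically so that a √2 error rarely crosses more
  than one bin.
* *Short-tube slivers.* The longitudinal sections of a tube of length L
  include width-1 slivers of area ≈ L; if L is smaller than the transverse
  area, edge voxels report the sliver instead. This matters only for
  stubby fragments, and for test fixtures, which use tubes long enough
  that the transverse disc is the minimum.

**Bins.** The default bin set is the doubling sequence
4–8–16–32–64–128–256 px, i.e. 1–2, 2–5, 5–9, 9–19, 19–37, 37–75 µm² at the
reference 0.54 µm pitch (µm² labels are `round(px * pitch^2)`). Areas
below 4 px or at/above 256 px get label 0 and are excluded — removal of
large vessels is a feature: the method targets microvessels under ~10 µm
diameter. Three interleaved presets (`set2`–`set4`) provide redundant
classifications for sensitivity checks; the paper-style analysis uses
`set1` alone. Bins are half-open `[lower, upper)`. Because the redundant
presets overlap each other, `classify_voxels()` accepts one preset at a
time. Finally the per-class maps are intersected with the pre-fill volume:
reported wall stacks contain only originally stained voxels, each labeled
by the caliber of its whole vessel rather than of its own 1-px wall, and
lumen counts are filled-minus-wall. Exclusion of out-of-range calibers
happens before the intersection; the order does not affect the wall
stacks.

## Skeletonization

Filled vessels are thinned to 1-voxel centerlines by directional border
thinning in the decision-tree family: in each pass, border voxels of the
six face directions are examined in turn; a voxel is deletable when it is
*simple* in the (26, 6) digital topology — exactly one 26-connected
foreground component among its 26 neighbors and exactly one 6-connected
background component in its 18-neighborhood touching a face — and not a
curve endpoint (more than one foreground neighbor). Candidates are
collected per direction and then deleted sequentially with the simplicity
test re-evaluated at deletion time, which makes topology preservation
exact rather than approximate: component counts and loops provably cannot
change. Consequences verified in the tests: the skeleton is a subset of
the input, a solid cylinder thins to its axis (length ≈ tube length, so
skeleton counts are a length proxy independent of wall thickness), a
torus keeps exactly its loop, and the operation is idempotent. Voxel-level
output may differ from other thinning implementations; all downstream use
is through counts and topology, which are implementation-stable.

Skeleton voxels are classified by looking up the caliber map of the same
sample — the whole volume is skeletonized once and split afterwards, so
vessels are not cut at class boundaries. Two artifact-control ratios
follow: wall/skeleton (staining per unit length; inflated by intracellular
staining) and lumen/wall (patent-lumen content). Zero denominators yield
`NA`, never a silent division.

## Volumetric Halo index

Spatial dispersion is measured by growth: binary dilation is applied
repeatedly — the 6-neighbor 3D cross on odd cycles, the 3×3×3 cube on even
cycles — and the foreground fraction is recorded after each cycle. The
alternation approximates spherical growth on the grid (the two-cycle
composite structuring element is rhombicuboctahedral); cross-first parity
is the default and is recorded with every fill curve, since Hv depends on
it. Growth clips at the stack faces (no padding, no wraparound). The Halo
index Hv is the fractional cycle count at which the curve crosses the
target fraction (default 0.90), linearly interpolated between the two
encompassing cycles; a volume already at target has Hv = 0.

Hv confounds amount with arrangement — more initial foreground fills the
stack sooner regardless of layout. The cohort normalization removes the
amount effect: the largest initial foreground count among all volumes
analyzed together is the normalization count, and each sample's
`norm_cycles` — the fractional cycles at which its absolute count curve
reaches that value, interpolated by the same rule — is subtracted:
nHv = Hv − norm_cycles. Fractional (rather than integer) norm_cycles was
chosen deliberately: truncation would inject up to one cycle of
quantization noise into every nHv; an `integer_norm` flag preserves the
alternative. Within `run_pipeline()` the normalization pools the entire
analysis set (every sample × class volume co-analyzed), so nHv values are
comparable across the whole plot; nHv is only meaningful among stacks of
identical dimensions, which `cohort_normalization_count()` enforces.
Classes with no voxels in a sample propagate `NA` ("missing by design"),
matching cohorts where a treatment empties a caliber class. Precondition:
the normalization count must not exceed the target fraction of the stack,
otherwise nHv is undefined for the cohort.

Higher nHv means poorer volume filling, i.e. a more clustered layout. The
test suite verifies the primitive against a brute-force set-union dilation
oracle voxel-exactly, checks the hand-enumerable center-voxel case
(Hv = 1 + (0.9 − 7/27)/(1 − 7/27) ≈ 1.865 on a 3×3×3 stack), and confirms
the discriminative property on matched phantom pairs — where the ordering
claim is about cohort medians: a single uniform draw can itself be clumpy,
so per-pair ordering is not guaranteed and not asserted.

## Cohort statistics

Per class and sample: V% = 100 × foreground/total voxels, nHv, counts and
ratios. Across samples: medians with 25–75% interquartile ranges
(linear-interpolation percentiles, `quantile` type 7), chosen over means
because nHv distributions are typically non-normal. Pairwise treatment
comparisons use Welch's unequal-variance t-test on V% and the unpaired
Wilcoxon rank-sum test on nHv (exact distribution when the pooled n ≤ 20
without ties, otherwise the tie-corrected normal approximation; the choice
is recorded). Stars use strict thresholds (`*` p < 0.05, `**` p < 0.01,
`***` p < 0.001; p = 0.05 is "ns"). No multiple-testing correction is
applied by default, mirroring per-cell reporting conventions for this kind
of grid; `adjust = "BH"` is available. Within each sample the per-class
(V%, nHv) points are fitted with nHv = a·V%² + b·V% + c by least squares,
with R² = 1 − SS_res/SS_tot; dispersion is fitted as a function of amount
(the inverse orientation would model amount as caused by arrangement,
which is the less natural reading, and the fit is a descriptive summary
either way).

## The phantom generator

`generate_phantom()` rasterizes digital cylinders (a voxel belongs to a
tube iff its center lies within the radius of the centerline segment;
documented because bin boundaries depend on it) with wall-only brightness
when `wall < radius`, Gaussian intensity noise clamped to [0, 255],
homogeneous or Thomas-cluster (parents + Gaussian offspring) layouts, and
optional dim "stained cell body" spheres. Anchors snap to voxel centers so
axis-aligned tubes have exactly the lattice digital-disc cross-section
(13 px at radius 2, 29 at 3, 49 at 4), making count oracles exact. Tube
overlap is allowed by default, as in real networks; `overlap = FALSE`
enables rejection sampling with one voxel of clearance for clean unit
tests, and a fixed `anchors` matrix pins geometry entirely. Each pipeline
stage draws from its own seeded RNG stream, so adding artifact blobs to a
spec changes neither the tubes nor the noise field.

What the phantoms emulate: mixed calibers in the 1–75 µm² range, hollow
walls, layout contrast, sub-threshold intracellular staining. What they do
not: the confocal point-spread function and depth attenuation, tissue
deformation, curved and branching vessels, intensity inhomogeneity along
walls. Passing phantom tests therefore validates the *computational*
contract of every stage (exact geometry, topology, statistics), not the
biological accuracy of segmentation on real tissue — on real stacks the
threshold step is the main sensitivity, which is why the threshold
criterion is pinned and validated bin-exactly against an independent
implementation of the same criterion.

On noise-free synthetic stacks the intensity histogram collapses to a few
delta masses, where entropy thresholds behave degenerately (the optimum can
sit at the background bin). Tests of the artifact-exclusion invariant
("blobs below the binarization threshold leave all class counts
unchanged") therefore fix a mid-gap threshold explicitly, which is exactly
the regime the invariant describes; the auto-threshold itself is tested on
continuous histograms.

## Numerical conventions and edge cases

* Arrays are `(y, x, z)`; slices along z. Binary TIFFs are 0/255-coded
  8-bit, round-tripping voxel-exactly.
* In-plane connectivity 8 (foreground) / 4 (background holes); 3D
  particle labeling 26-connected. These match common ImageJ defaults and
  are fixed and documented.
* Interpolations (isotropic resampling, Hv, norm_cycles) are linear;
  contrast rescaling rounds to nearest.
* Degenerate inputs fail loudly: empty volumes cannot produce fill
  curves, constant stacks have no threshold, mismatched shapes or
  normalization counts below a sample's own volume are errors, and
  non-monotone fill curves (impossible for dilation) signal an upstream
  bug rather than being silently interpolated.
* Test and validation problem sizes were chosen as the smallest volumes
  on which every geometric property is non-trivial: 20³ random volumes
  for oracle equivalence, 48³–72³ phantom stacks, cohorts of 2 × 8
  samples; the full suite and the acceptance script each run in about a
  minute on one core.

## Known limitations

Calibers are projections, not local diameters — a distance-transform
granulometry would measure true radii but is a different method with
different failure modes, and is deliberately out of scope. The dispersion
index depends on stack dimensions and on the dilation parity, so nHv is
comparable only within a cohort processed identically. The quadratic
V%–nHv fit is a descriptive summary, not a mechanistic model. And the
per-slice contrast normalization, while faithful to the acquisition-era
workflow, is non-local: a single bright or dark voxel can shift a whole
slice's mapping, which is why it is gated and why thresholds are computed
after it on the pooled histogram.
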