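# halovasc

Quantification of tumor microvasculature in 3D: caliber-resolved vessel
maps and a volumetric spatial-dispersion statistic (the normalized Halo
index, nHv) computed from confocal z-stacks of stained vessel walls.

Classical mean vessel density counts vessels per area and is blind to both
vessel caliber and spatial arrangement. Vascular-targeted drugs differ in
exactly those dimensions: antiangiogenic agents prune thin microvessels and
leave a sparser, more clustered network, while vascular-disrupting agents
collapse existing vessels with different caliber signatures. `halovasc`
measures, per caliber class, how much vessel there is (V%), how it is
arranged in space (nHv), and how much of it is patent lumen — so treated
and untreated vascular beds can be compared quantitatively.

## Method

Starting from an 8-bit greyscale z-stack (typically 0.54 µm lateral pitch,
1 µm slice spacing):

1. **Preprocess** — resample to isotropic voxels (linear interpolation
   along z), rescale each slice to the full 8-bit range when its dynamic
   range exceeds 30 grey levels, and binarize with a Rényi-entropy
   auto-threshold (Sahoo's three-order combination on the pooled stack
   histogram).
2. **Caliber classification** — remove sub-resolution particles (maximal
   Cartesian cross-section < 4 px ≈ 1 µm²), fill hollow vessels slice-wise
   in all three orientations, and label every voxel by the *minimal
   Cartesian cross-section* of its filled vessel: the smallest area of the
   2D connected component containing the voxel among its xy, xz and yz
   slices. Pixel-area bins (4–8–16–32–64–128–256 px, i.e. 1–2, 2–5, 5–9,
   9–19, 19–37, 37–75 µm² at 0.54 µm) define six caliber classes; larger
   vessels are excluded. The class maps are intersected with the pre-fill
   volume so wall voxels inherit the caliber of their vessel, and lumen
   volume is the filled-minus-wall difference. For tubes tilted up to 45°
   from a Cartesian axis the measured section differs from the true one by
   at most √2 ≈ 1.41, so calibers are indicative values.
3. **Skeletonization** — topology-preserving 3D thinning reduces filled
   vessels to 1-voxel centerlines; skeleton voxel counts are a
   wall-thickness-free length proxy, giving artifact-control ratios
   (wall/skeleton = staining per unit length, lumen/wall = patent-lumen
   fraction).
4. **Dispersion** — the volumetric Halo index Hv is the (linearly
   interpolated) number of alternating cross/cube ("rhombicuboctahedral")
   dilation cycles needed for the foreground to occupy 90% of the stack.
   Subtracting the cycles needed to grow each sample to the cohort's
   largest initial volume gives nHv, comparable across samples: low nHv =
   space-filling, high nHv = clustered.
5. **Cohort statistics** — per-class medians and 25–75% IQRs, Welch's
   t-test on V%, Wilcoxon rank-sum on nHv (with significance stars), and
   per-sample quadratic fits of nHv against V% with R².

A seeded phantom generator (`phantom_spec()` / `generate_phantom()`)
produces hollow digital-cylinder vascular beds with known ground truth —
calibers, layouts (homogeneous vs Thomas-cluster), wall-only staining,
optional stained-cell-body artifacts — so every stage is testable without
imaging data.

## Worked example

```r
library(halovasc)
# a homogeneous and a clustered synthetic vascular bed, same vessel amount
hom <- generate_phantom(phantom_spec(dims = c(64, 64, 48), n_tubes = 8, radii = 2L,
                                     wall = 1L, layout = "homogeneous", seed = 1))
clu <- generate_phantom(phantom_spec(dims = c(64, 64, 48), n_tubes = 8, radii = 2L,
                                     wall = 1L, layout = "clustered", seed = 1))

cfg <- run_config(lateral_pitch = 0.54, axial_pitch = 0.54)
vol <- preprocess_stack(hom$stack, cfg)   # isotropic -> contrast -> Renyi threshold
a <- analyze_sample(vol, cfg)             # particle filter, fill, classify, skeletonize
print(a$classification)
#> caliber_classification (set1): 6 classes
#>   class     label filled_count wall_count lumen_count
#> 1     1   1-2 um2          721        721           0
#> 2     2   2-5 um2         4326       2675        1651
#> 3     3   5-9 um2            0          0           0
#> 4     4  9-19 um2           63         48          15
#> 5     5 19-37 um2          108         87          21
#> 6     6 37-75 um2          127         64          63

# spatial dispersion of the dominant caliber class, cohort-normalized
b  <- analyze_sample(preprocess_stack(clu$stack, cfg), cfg)
vh <- a$class_masks[["2-5 um2"]]; vc <- b$class_masks[["2-5 um2"]]
nc <- cohort_normalization_count(list(vh, vc))
normalized_halo(vh, nc)
#> dispersion_result: Hv = 14.841, norm_cycles = 0.112, nHv = 14.729 (initial 2675 voxels, ...)
normalized_halo(vc, nc)
#> dispersion_result: Hv = 18.410, norm_cycles = 0.000, nHv = 18.410 (initial 3288 voxels, ...)
```

The radius-2 hollow tubes land in the 2–5 µm² class with their lumina
recovered (walls 2675, lumen 1651 voxels), and the clustered bed needs
~3.7 more dilation cycles to fill the stack than the homogeneous one
(nHv 18.4 vs 14.7) — the dispersion signal the method is built around.

A full cohort (manifest of samples × treatments) runs through
`run_pipeline()`, which writes per-sample metrics, the class × treatment
significance grid, cohort summaries and quadratic fits as CSV. The same
pipeline is scriptable from the shell via `inst/cli/halovasc.R` with
subcommands `simulate`, `preprocess`, `classify`, `skeletonize`,
`dispersion`, `cohort`.

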