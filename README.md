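# cytoshell

3D volumetric analysis of how punctate fluorescent signal — a tagged
receptor, endosomal Rab markers — is distributed within single dividing
cells imaged as confocal z-stacks. The package was built for the kind of
question asked of precardiac founder cells in ascidian embryos (does
receptor signal sit at the plasma membrane, in the peripheral cytoplasm, or
deep in the cell, and how does that change across mitosis?), but the
machinery is generic: any cropped single-cell multi-channel stack with
known voxel spacing.

## What it computes

For each cell, after single-cell segmentation and an exact anisotropic
Euclidean distance transform to the mask surface, the cell is partitioned
into three concentric shells — membrane-associated (0–1 µm), peripheral
cytoplasm (1–3 µm), deep cytoplasm (>3 µm) — and puncta are thresholded at
the 95th percentile of smoothed intensity within the mask. The statistics
are:

- **Regional fold enrichment** of thresholded signal, per shell:

  E_region = (V_signal∩region / V_region) / (V_signal / V_cell)

  E = 1 means the shell holds signal in proportion to its volume.

- **Object-based Manders' overlap** between two thresholded channels,
  whole-cell and per shell (asymmetric in its arguments):

  MOC = V(A ∩ B) / V(A)

- **Ventral/dorsal enrichment ratio**: thresholded signal volume in the
  ventral half over the dorsal half, after bisecting the cell into two
  equal-volume halves along an annotated dorsal–ventral axis.

- **Group statistics**: one-way ANOVA with Tukey HSD, Fisher exact +
  Pearson chi-squared (no continuity correction), t-tests on arcsine
  square-root transformed proportions, and mean ± SEM summaries.

Everything is validated against ground truth: a synthetic-stack generator
renders ellipsoidal cells with region-controlled puncta, Gaussian PSF blur
and sensor noise, and records the exact statistics its masks imply.

## Worked example

```r
library(cytoshell)

# a simulated founder-cell-sized cell with known ground truth
sim <- simulate_cell(simulation_spec(seed = 7))
cfg <- default_config()
cfg$spacing <- c(0.3, 0.25, 0.25)   # (dz, dy, dx) of the simulated stack

row <- quantify_cell(sim$channels, sim$record, cfg)
t(round(row[, c("V_cell_um3", "E_membrane", "E_peripheral", "E_deep",
                "moc_cell", "vd_ratio")], 3))
#> V_cell_um3   1264.406
#> E_membrane      1.621
#> E_peripheral    0.621
#> E_deep          0.576
#> moc_cell        0.271
#> vd_ratio        1.028

sim$truth$E          # generator truth: 1.721 0.583 0.575
sim$truth$moc_cell   # 0.3 (overlap fraction by construction)
```

The recovered membrane enrichment (1.62 vs 1.72 true; the membrane shell
holds ~1.7× its volume-proportional share of receptor signal) and
whole-cell overlap (0.27 vs 0.30) come from the full pipeline —
segmentation, distance shells, percentile thresholding — run on the
rendered noisy image, not on the truth masks.

Group comparison across stages:

```r
anova_tukey(c(1, 2, 3, 2, 3, 4, 3, 4, 5), rep(c("pre", "meta", "post"), each = 3))
#> $F
#> [1] 3        # SSB = 6 on 2 df, SSW = 6 on 6 df
#> $p
#> [1] 0.125
```

Batch runs (`run_pipeline()`, or the CLI in `inst/cli/cytoshell`:
`cytoshell run --n 20 --out results/ --seed 7`) write a per-cell CSV plus
QC overlay PNGs of the mask contour for manual review.

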