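---
title: "Distance-shell volumetric analysis: model, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-shell volumetric analysis: model, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoshell)
```

## The measurement model

The package answers a spatial question about a single cell imaged as a
multi-channel confocal z-stack: what fraction of a punctate signal
(receptor, endosome marker) lies near the plasma membrane versus deeper in
the cytoplasm, and how strongly do two such channels overlap, region by
region. The pipeline is:

1. **Segmentation.** Each z-plane is smoothed with a 2D Gaussian, the
   whole stack is binarized at Otsu's threshold times a configurable scale,
   gaps are closed plane-wise (dilate, fill holes, erode, with a 2-pixel
   disk), a 3D erosion detaches minimally connected debris, objects smaller
   than 10 µm³ are deleted, and a symmetric 3D redilation restores the
   eroded margin. The result must be a single 26-connected component; if
   several survive the volume filter, the largest is kept and the event
   logged for manual review (QC overlays render the mask contour on the
   mid-plane and the max projection).
2. **Distance shells.** An exact Euclidean distance transform — the
   separable lower-envelope algorithm, equivalent to Maurer's linear-time
   transform — is computed with the physical voxel spacing applied per
   axis, so anisotropic sampling (e.g. 0.3 µm z-steps against ~0.1–0.25 µm
   pixels) is handled exactly rather than approximately. In-mask voxels are
   then labeled membrane-associated `[0, b1)`, peripheral `[b1, b2)` or
   deep `[b2, ∞)` by their distance to the surface, with b1 = 1 µm and
   b2 = 3 µm by default.
3. **Puncta.** Each channel is smoothed per plane (σ = 0.1 µm) and
   binarized at the nearest-rank 95th percentile of in-mask intensity, so
   the thresholded volume is by construction ~5% of the cell and comparable
   across cells of different brightness.
4. **Statistics.** Regional fold enrichment
   `E = (V_in_region/V_region) / (V_in_cell/V_cell)`; object-based
   Manders' overlap `V(A∩B)/V(A)` whole-cell and per shell; and the
   ventral/dorsal ratio of puncta volumes after bisecting the mask into
   equal-volume halves along an annotated axis. Two algebraic identities
   follow from the definitions and are enforced as tests: enrichment
   conservation, `Σ E·V_region = V_cell`, and the overlap decomposition,
   `MOC_cell = Σ (V_A,region/V_A,cell)·MOC_region`.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| spacing (dz, dy, dx) | (0.3, 0.1, 0.1) µm | physical voxel size; must always be supplied — stack files alone cannot be trusted to carry it |
| shell boundaries (b1, b2) | (1, 3) µm | membrane/peripheral/deep cuts |
| puncta percentile | 95 | thresholded volume ≈ 5% of the cell |
| quantification σ | 0.1 µm | pre-threshold smoothing, per plane |
| segmentation σ | 0.5 µm | suppresses shot noise without erasing the cell boundary |
| Otsu scale | 1.0 | multiplier on the Otsu level |
| minimum volume | 10 µm³ | object pruning during segmentation |

## Numerical conventions

Several cut-point and tie conventions are deliberate and tested:

- **Half-open shells.** The printed region definitions are ambiguous at
  exactly 1 and 3 µm; `[0,b1), [b1,b2), [b2,∞)` makes the shells an exact
  disjoint cover, so the conservation identity holds at machine precision.
- **Voxel-center distances.** Distance is measured between voxel centers,
  so a boundary voxel carries the one-step distance, never 0, and the
  domain outside the crop counts as background one step away (cells are
  assumed fully contained in the crop).
- **Nearest-rank percentile, strict binarization.** No interpolation; ties
  at the threshold fall *below* it. With 12-bit integer data this is the
  conservative choice, and a constant channel yields an empty puncta mask
  with a warning rather than an error.
- **Otsu on the exact value distribution.** Every distinct intensity is a
  candidate cut; the returned threshold is the midpoint between the levels
  it separates, with ties averaged. Consequence (tested): the segmentation
  mask is invariant under multiplying all intensities by a positive
  constant. "Scaled by the threshold level" is read as
  `threshold = otsu × scale` with scale = 1 by default — the scale is the
  only free knob such a phrasing can denote.
- **Undefined statistics are flagged, never dropped.** Thin cells
  legitimately have empty deep shells; regional denominators of zero yield
  `NA` with the volume terms still reported.
- **Equal-volume bisection.** "Divided in half" is implemented as the cut
  plane that best balances in-mask voxel counts (whole planes assigned to
  one side, first minimum on ties), not the bounding-box midpoint.

## The synthetic world, and what a green test establishes

The generator (`simulation_spec()`, `simulate_cell()`) states a world with
the structure the analysis assumes: one ellipsoidal cell (semi-axes
~6.4–7 µm, founder-cell scale; analytic membership doubles as the
segmentation oracle), puncta drawn voxelwise by region-conditional
Bernoulli sampling with occupancies (0.15, 0.05, 0.05), a second channel
that shares exactly a fraction f = 0.3 of the first channel's puncta
voxels (so the true overlap is f by construction), a Gaussian PSF of
σ = 0.1 µm, a dim cytoplasmic fill (300 on the 12-bit scale over a
background of 100) so segmentation has something to segment, and additive
Gaussian noise at SNR 10 (noise sd = median puncta amplitude / 10).

Two generator choices deserve explanation because they were forced by an
identifiability analysis, not by taste:

- **Vesicle-scale voxels (xy 0.25 µm).** A punctum occupies one voxel, so
  the lattice constant *is* the punctum size. At 0.1 µm pixels a one-voxel
  punctum is a sub-resolution object: after PSF blur its peak is small
  against the intensity texture created by neighboring puncta, and the
  95th-percentile mask then selects voxels by regional crowding (local
  mean) rather than punctum identity. In that regime membrane enrichment
  is overestimated ~40% by *any* intensity-ranking estimator — the truth
  is unrecoverable in principle, which makes the world useless for
  validation. With 0.25 µm voxels (a realistic endosome diameter and a
  realistic modest-zoom confocal pixel) puncta are resolvable and the
  pipeline's error is attributable to the pipeline.
- **Heterogeneous punctum brightness.** Per-punctum amplitudes are iid
  lognormal (median 1500, log-sd 0.8), as vesicle cargo loads genuinely
  vary severalfold. Statistically this gives the rank threshold an
  intrinsic, region-independent brightness axis, so the ~56% of true
  puncta it keeps are a near-uniform subsample across shells — exactly the
  condition under which density ratios (and hence E) survive thresholding
  unbiased. The B-only occupancy default (0.025) likewise makes channel
  B's true puncta volume ≈ 5%, matching the threshold convention so that
  recovered overlap is limited by noise, not by threshold truncation.

What the synthetic world does **not** emulate: image-derived cell shapes
(no invaginations or mitotic furrowing), realistic PSF anisotropy or depth
dependence, spectral bleed-through, chromatic shifts, and touching
neighbor cells. A green recovery test therefore establishes that the
*computational* pipeline is correct and stable under blur and noise at the
stated levels — not that segmentation or thresholding choices are optimal
for any particular microscope or tissue.

Recovery has two tiers. In the mask tier the truth masks short-circuit
segmentation and thresholding, and recovery must be *exact* — this pins
down the bookkeeping (partition, counting, ratios). In the image tier the
full pipeline runs from rendered intensities; over 20 cells the median
relative error of E per shell stays under 15% (observed ~2–6%) and the
recovered whole-cell MOC is within ±0.05 of f = 0.3 (observed ~0.27;
the small deficit is the noise-driven exchange of true threshold mask
voxels for bright-halo voxels, which overlap across channels only at
shared puncta).

## Group statistics

Stage and condition comparisons use R's reference implementations behind a
thin, tested interface: one-way ANOVA with Tukey HSD (`aov`/`TukeyHSD`),
two-sided Fisher exact plus Pearson chi-squared *without* continuity
correction (the exact test is reported alongside, so the corrected
approximation would add nothing), and Student t-tests on
arcsine-square-root transformed proportions (the classic
variance-stabilizing analysis for per-trial induction rates; pooled
variance, matching the transform's equal-variance rationale). Tests verify
the ANOVA against hand-computed sums of squares, Fisher against full
hypergeometric enumeration, and the two-group identity F = t².

## Known limitations

- Single-cell only: no watershed splitting of touching cells; crops must
  isolate one cell.
- The dorsal–ventral axis is consumed as annotation; nothing infers it.
- Distances are Euclidean, not geodesic: for strongly non-convex masks a
  "deep" voxel can be close to the surface through a path outside the
  mask. At founder-cell roundness this is immaterial.
- The TIFF codec covers uncompressed grayscale multi-page stacks
  (ImageJ-style metadata, 8/16-bit, either byte order); compressed or
  multi-sample files must be converted first.
- Whether the original analysis computed Otsu per plane or per stack, and
  smoothing in 2D or 3D, is not derivable from its description; per-stack
  Otsu and per-plane smoothing are implemented, and both are configurable
  at the operation level.
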