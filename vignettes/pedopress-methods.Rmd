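---
title: "Plantar pressure image analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plantar pressure image analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedopress)
```

## The measurement model

Pedobarographic platforms export pressure as a false-color raster in which
deeper red encodes higher pressure. `pedopress` treats the red band intensity
itself as the pressure proxy: a region's "pressure" is the sum of 8-bit red
values over its pixels. This is a deliberate simplification — platform
colormaps are proprietary and unpublished, so decoding color to physical
pressure (kPa) is not attempted. Consequences to keep in mind:

* pressures are in arbitrary intensity units; only *ratios* and *relative*
  comparisons between regions of the same image are meaningful;
* orange/yellow colormap zones (moderate pressure in many colormaps) are
  excluded by design via the red-dominance rule below. The forefoot–hindfoot
  ratio is therefore a ratio of *high-pressure* content, which is exactly
  what the foot-type classification wants.

## Segmentation pipeline

Order is fixed: threshold → area opening → closing → hole filling. Each step
is monotone in the right direction (opening only removes pixels, closing and
filling only add them), which gives the pipeline predictable behavior and
makes the conservation property below exact.

**Thresholding.** A pixel is pressure iff `red ≥ T` and
`red − max(green, blue) ≥ margin`. `T` defaults to the Otsu threshold of the
red-band histogram — the canonical histogram-based choice when the source
describes thresholding only as histogram-driven — with a fixed threshold
available for strict reproducibility. Ties in the between-class variance are
broken toward the lower intensity, so the result is deterministic. A
constant red band has no histogram structure; the Otsu path refuses it and
asks for a fixed threshold rather than guessing.

**Parameters.** All defaults are free parameters, echoed into every report:

| parameter | default | units | why |
|---|---|---|---|
| `red_dominance_margin` | 30 | intensity | excludes orange/yellow (red ≈ green) while tolerating sensor noise of a few intensity units |
| `min_blob_area` | 20 | px | below ~20 px a component is speckle at typical export resolutions |
| `closing_radius` | 2 | px | smooths 1–2 px boundary roughness without bridging distinct pressure centers |
| `connectivity` | 8 | — | diagonal contact joins blobs, the common blob-analysis convention |

**Morphology details that matter numerically.**

* Closing is computed on a canvas padded by the structuring-element radius,
  so the operation is extensive (its output is a superset of its input) even
  at image borders; unpadded erosion would eat border pixels.
* Hole filling marks every background region not connected to the image
  border. Background connectivity is the complement of the foreground
  connectivity (8-connected foreground ⇒ 4-connected background), the
  standard digital-topology duality that prevents a diagonal "crack" from
  draining a hole.
* Connected components are labeled by vectorized minimum-label propagation to
  a fixed point; labels are canonicalized to first-pixel order so results are
  reproducible across runs.

## Region split and classification

The forefoot/hindfoot boundary is the midpoint row of the bounding box of
all detected pressure, `split_row = floor((row_min + row_max + 1)/2)`; pixels
strictly above it are forefoot when toes point up (`orientation` flips this,
since image orientation is a property of the export, not of the foot). The
split is **per pixel**, not per component: a component straddling the
boundary contributes to both regions. We chose this over assigning whole
components by centroid because it guarantees exact conservation —
`forefoot + hindfoot = whole-mask pressure` as integer arithmetic, for every
input — which in turn makes the ratio well-defined even for degenerate
masks. A per-component mode would also be anatomically cruder whenever a
midfoot component spans the boundary. The flat 50% rule is an operational
definition, not an anatomical one: no landmark detection is attempted.

Foot type follows the ratio thresholds: Type 0 below 0.8, Type 2 above 1.2,
and the *closed* interval [0.8, 1.2] is Type 1, so the boundary values count
as balanced and the two outer classes are strict inequalities. A zero
hindfoot with positive forefoot reports an infinite ratio and Type 2; a
completely empty foot is an error, not a report.

## The synthetic generator

`generate_pressure_image()` renders red-dominant disks with a linear radial
decay from the peak (center) to a rim intensity of 140, on a non-red
background (default blue, `(0, 0, 120)`); green/blue inside blobs are held
at 20, far below red, so the default margin always passes. The ground-truth
manifest (pixel set, per-region sums, ratio, foot type) is computed from the
noise-free rendering; seeded Gaussian noise is added afterwards and clipped
to [0, 255]. Default peaks stay ≤ 245 so clipping cannot bias noisy sums.

`synthetic_foot_spec()` lays out two forefoot disks and one hindfoot disk
with a wide gap so the bounding-box midpoint falls between the regions, and
solves the two peak intensities jointly against the exact rendered pixel
sums (which are affine in the peak), hitting a requested ground-truth ratio
to well under 1% — accurate enough that recovery tests can demand 5%
relative agreement without the generator itself being the bottleneck.

What the generator does *not* emulate: anatomical foot outlines, partial
footprints, the full platform colormap (graded red→yellow→green→blue),
spatial noise correlation, and calibration drift. Passing tests therefore
demonstrate that the algorithm implements its stated rules exactly and is
robust to i.i.d. pixel noise — not that it handles every artifact of real
clinical exports.

Test and demonstration scales were chosen to exercise the properties at
realistic sizes while keeping the suite fast: 64×64 masks for the morphology
oracle comparisons (200 of them), 120×80 images for pipeline runs (100–300
per property), point sets of n ≤ 150 for clustering.

## Clustering and validity indices

Points are standardized column-wise to mean 0 and **population** standard
deviation 1 (divisor n, recorded in the output), the convention matching
"assign the attribute a standard deviation of one"; a constant column is an
error naming the column rather than a silent division by zero.

**k-means** is Lloyd's algorithm from seeded k-means++ starts. Deterministic
details: assignment ties break toward the lowest centroid index; an empty
cluster is re-seeded to the point farthest from its current centroid; the
final inertia is recomputed from residuals (not the expanded quadratic form,
which loses precision through cancellation). The inertia trace is recorded
per iteration and is non-increasing by construction. The elbow curve runs
best-of-5 restarts per k and adds one warm start per k — the previous k's
best centroids plus the farthest point — which guarantees the curve is
monotone non-increasing in k (Lloyd never increases inertia from its
initialization, and the augmented initialization already beats the previous
k). **Agglomerative clustering** delegates the merge bookkeeping to
`stats::hclust` (Ward as `ward.D2`, which requires euclidean input) behind a
tidy interface, with the merge list exposed for export; an O(n³)
recompute-from-members reference implementation cross-checks the merge
heights in the test suite.

**Indices.** Silhouette uses the `(b − a)/max(a, b)` contrast; members of a
singleton cluster score 0 (the common convention; the alternatives ±1 would
reward or punish singletons arbitrarily), and `0/0` (all-coincident points)
also scores 0. Davies–Bouldin uses centroid means and mean member-to-centroid
radii; coincident centroids are an error, since the index divides by their
distance. The Dunn index ships in **two variants** because its common prose
definition (minimum between-cluster distance over maximum intra-cluster
diameter) and a frequently printed summation formula — which is structurally
the Davies–Bouldin expression — disagree. `variant = "standard"` is the
default; `cluster_quality()` always reports both, so the reader can see when
a published "Dunn" value is actually the DBI-like quantity. An all-singleton
labeling makes the standard Dunn infinite; it is reported as `Inf` with a
warning rather than silently clamped.

Distance support: euclidean and manhattan (via `stats::dist`), cosine
(`1 − similarity`; undefined and an error for two zero vectors), and Jaccard
on binarized vectors (`dist(method = "binary")`, with the both-empty pair
defined as distance 0).

## Scoring metrics

Classification metrics are confusion-matrix based. Macro averaging is the
default — appropriate for near-balanced classes, and the averaging mode is
recorded in every report rather than left implicit. Per-class ratios with a
zero denominator (a class never predicted, or never present) are set to 0
with a warning, keeping reports total instead of propagating NaN. The
Jaccard score is implemented as intersection-over-union. Matthews
correlation uses the multiclass confusion-matrix form. Hamming loss is the
fraction of misclassified samples, so it equals 1 − micro-averaged accuracy
— an identity the tests assert.

Regression metrics follow their definitions; RMSLE requires all values
> −1; SMAPE is the symmetric 0–200% form reported in percent, with `0/0`
terms defined as 0. R² needs at least two pairs and non-constant truth; for
a single pair it is `NA` with a warning so the other five metrics of the
report remain available.

## Known limitations

* Red-intensity sums are a colormap-dependent proxy, not physical pressure.
* The 50% split knows no anatomy; severe deformity or partial prints can put
  metatarsal pressure below the midline.
* Left/right feet are not distinguished; midfoot is folded into hindfoot.
* The generator's disks are geometrically idealized; robustness claims
  extend only to the noise model it implements.
* Divisive (top-down) hierarchical clustering is not implemented; the
  agglomerative dendrogram with cutting covers the supported analyses.
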