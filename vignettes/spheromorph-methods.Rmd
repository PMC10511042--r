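---
title: "Methods: quantifying spheroid rounding, cell motion coordination, and junction morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying spheroid rounding, cell motion coordination, and junction morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the measurement models behind `spheromorph`, the
choices that were genuinely open when they were made, and what the
synthetic validation does and does not establish about real microscopy
data.

## Circularity and its phases

The silhouette of a rounding cell mass is summarized per frame by the
form factor

$$c = \frac{4\pi A}{P^2},$$

which is 1 for a circle and decreases with elongation (a square gives
$\pi/4$, a 3:1 rectangle $3\pi/16$). $A$ and $P$ are taken from a
*subpixel iso-contour polygon*: the largest connected component is kept,
holes are filled, the mask is smoothed with a small Gaussian
(`smooth_sigma`, default 1.5 px), and the 0.5 level set is traced by
marching squares with linear interpolation. The perimeter of that
polygon, not a pixel-edge count, enters the formula: pixel-edge
perimeters of digitized discs are biased high by up to ~27%, which
would bias circularity low by a factor of ~0.6 and break the
circle-measures-1 property. With the smoothed iso-contour a radius-50
disc measures $c = 0.997$ (checked in the test suite). Manual freehand
tracing of outlines is replaced by this automated contour; the synthetic
oracle validates the substitution but no claim is made that it
reproduces hand tracings on real images.

Phase segmentation uses a slope criterion on a moving-median-smoothed
series (window 3 h): the **latent** phase is the initial maximal run
with |slope| < `slope_eps` (default 0.005 h⁻¹), the **static** phase is
the final such run whose values also sit within 5% of the terminal
plateau, and the **rising** phase is what lies between. The boundaries
of the underlying biology are qualitative; the slope threshold is our
operationalization, and on programmed kinetics (latent to 5 h, static
from 18 h, sampled hourly) it recovers both boundaries within one
sample. The median filter is used because it preserves step edges;
missing frames propagate as `NA` rather than being interpolated, so a
gap can never manufacture a phase boundary.

Discrete fusion events — two sub-masses merging — appear as upward jumps
in circularity. `detect_jumps()` flags forward differences that exceed
both an absolute floor (`min_step`) and `k_mad` (default 5) times the
median absolute deviation of all frame-to-frame differences, then merges
consecutive hits into a single event at the largest step.

## Synthetic rounding movies

The generator renders a constant-area rounded rectangle whose aspect
ratio and corner radius morph toward a disc. Both the area and perimeter
of that family are closed-form, so the *programmed* circularity curve is
analytic: each frame solves (by `uniroot` on the monotone shape path)
for the silhouette whose analytic circularity equals the kinetics curve
at that time. The kinetics curve itself is flat at the analytic initial
circularity until `t_latent`, rises along a smoothstep to `c_inf` at
`t_static`, and is flat after; programmed jumps add instantaneous
increments. A jump is rendered as an instantaneous change to a rounder
single silhouette rather than as a literal two-component merger — for
the projected-contour statistic the two are equivalent, and the single
silhouette keeps the analytic curve exact. The curve is capped at 0.995
because a rasterized silhouette cannot be measured meaningfully closer
to 1 than its own discretization.

## Nucleus detection and linking

Detection uses an anisotropic difference of Gaussians,
$G_{\sigma_\text{small}} - G_{\sigma_\text{large}}$, with default sigma
pairs 1.9/3.8 px in XY and 0.7/1.4 px in Z — the paired small/large
kernel sigmas of a 3D DoG, with the Z pair smaller because confocal
stacks sample Z more coarsely. Borders are mirror-reflected. Candidate
nuclei are strict 26-neighborhood local maxima above a threshold (Otsu
on the positive responses by default, since no published threshold
exists for this assay), greedily suppressed inside an anisotropic
exclusion ellipsoid (default radii 2 px Z, 4 px XY), and refined to
subvoxel coordinates by a per-axis three-point quadratic fit. At SNR 5
this localizes isolated blobs to ~0.15 px laterally and ~0.06 px
axially, which is close to the information-theoretic floor for these
blob sizes; window-based paraboloid and centroid refinements were
evaluated and gave no material improvement.

Linking is the plain nearest-neighbor method: between consecutive
frames, candidate pairs within `max_link_dist` are matched one-to-one in
ascending distance order, ties broken deterministically by detection
index. An exact minimum-total-distance variant (Jonker–Volgenant
shortest augmenting path, with dummy columns so unmatched detections are
allowed) is available behind `method = "optimal"`; the test suite
asserts both agree on well-separated movies. There is no gap closing,
division handling, or re-identification: trajectories end when a link
fails. The frame interval is carried as metadata only — linking is
interval-agnostic.

## Displacement-direction correlation

For each trajectory present in consecutive frames, the displacement is
$v_t = x_t - x_{t-1}$ (anisotropy-corrected to isotropic px). The
correlation of a neighboring pair is the cosine of the angle between
their displacement directions, giving +1 for parallel, −1 for
antiparallel motion; a componentwise Pearson variant is provided for
sensitivity analysis only. "Neighboring" is not defined by the assay, so
the default rule is an adaptive radius — pairs closer than 1.5 times the
frame's median nearest-neighbor distance — with a symmetrized
k-nearest-neighbor rule as the alternative; the rule and its parameters
are recorded on every output. A Delaunay-edge rule was considered and
not shipped: it needs a computational-geometry dependency the package
otherwise does not, and on the near-uniform configurations generated
here the adaptive radius yields essentially the same graph.

Displacements below `eps_motion` (default 0.3 px/frame) have no
well-defined direction; such pair-frames are omitted and counted, and
the exclusion count is reported so the sensitivity of downstream
fractions to this cutoff can be assessed rather than assumed. For
isotropic 3D directions the cosine is uniform on [−1, 1], so an
uncoordinated population contributes a flat background with
$P(r > 0.8) = 0.1$ — the Monte-Carlo baseline used throughout the tests.
The time-resolved density normalizes each time column to a maximum of 1
by default (each slice shows its own modal structure); global
normalization is available because "normalized to 0–1" is ambiguous
between the two readings.

## Synthetic nuclei movies

Nuclei are anisotropic Gaussian blobs (peak amplitude 1) plus additive
Gaussian noise of standard deviation 1/SNR — the simplest noise model
that stresses detection; Poisson noise is deferred. Initial positions
are drawn with pairwise separation at least 4·max(psf σ). Motion modes:
independent random walkers (fixed step length, isotropic direction);
coherent groups sharing a rigid translation plus (1−coherence)-scaled
individual noise, with an optional rigid rotation about the group's
initial centroid to emulate swing-arm folding of cell-mass segments
without simulating mechanics; antiparallel passing pairs; and a mixture
in which a fraction of spatially adjacent pairs move coherently.

Two realism constraints matter for validation. First, nuclei are
excluded-volume objects, so non-rigid modes redraw any step that would
bring two centers closer than `hard_core` (default 3·max(psf σ)) —
without it, long random walks let blobs overlap, and failures of
detection on physically impossible configurations would contaminate the
benchmark. Second, positions reflect at a rendering margin; for coherent
groups the *shared* step bounces as a whole so that perfect coherence
keeps within-group displacements identical. No cell division or death
occurs: over the ~12 h imaging window this assay uses, constant identity
is an acceptable simplification, and the trajectory count is asserted
constant.

The assay gives no distributional parameters for cell speeds, so the
generator defaults are free choices, documented here, not data-derived
values: 1.2 px/frame for the slow coherent benchmark and 3 px/frame for
the correlation-pipeline benchmark. The latter sits comfortably above
the direction-resolvability floor: with ~0.15 px localization noise the
pipeline's pair-r mean absolute error is ≈0.03 at 3 px/frame but would
roughly double at 2 px/frame, scaling inversely with step length. The
distribution of r in the mixture is a sharp coherent mode at +1 over a
flat uncorrelated background — this reproduces the two-population
structure seen in the assay (one peak near +1, broad mass around 0),
though a literal local density peak *at* 0 is not modeled.

## Junction morphometrics

PA spots are threshold-segmented (Otsu by default), size-filtered, and
kept only if their footprint dilated by 2 px overlaps the segmented
actin mask — the operational version of a visual "attached to an F-actin
bundle" criterion. Sizes are reported as the maximum Feret diameter
computed exactly on the convex hull of pixel *corner* points, so a
single pixel has Feret √2 rather than 0; an exhaustive all-pairs oracle
confirms exactness in the tests.

TJ length follows the skeletal recipe: white top-hat with a disc
structuring element at the line scale (radius 5 px by default, against
~2 px lines) to enhance linear structures, threshold segmentation,
morphological thinning to a single-pixel skeleton (Zhang–Suen,
implemented here since the imaging stack provides no thinning
operation), and the skeleton pixel count as the length, normalized per
cell (nuclei counted by blob segmentation) and per field area. The raw
pixel count underestimates diagonal runs by up to √2, so a corrected
length is also emitted: the skeleton is decomposed into branches at
junction pixels and each branch measured by the chain-code estimator
$\sqrt{N_d^2 + (N_d + N_a)^2}$ (axial steps $N_a$, diagonal $N_d$),
which is exact for straight digital lines; branch-to-junction links
contribute their individual step weights. On programmed hexagonal
tessellations the corrected length lands within ~1% of the true edge
length and is invariant to line thickening from 2 to 6 px; the raw
pixel count runs ~10% low, as expected for a network with edges at 60°
to the pixel grid. Segmentation thresholds for this channel are
unpublished in the original assay; the defaults here are validated on
synthetic tessellations only.

## Fusion metrics

The synthetic doublet is two discs whose center distance is programmed
so that the intersection chord — the contact neck — follows a prescribed
growth law; the doublet length is $r_1 + r_2 + d(t)$ and both are stored
as ground truth. Measurement replaces the assay's manual line drawing:
the long-axis length is the maximum Feret diameter of the silhouette
(pixel centers; the sub-pixel corner convention matters only for
few-pixel objects) after a configurable morphological opening (default
radius 5 px) that removes surface protrusions, and the contact length is
the silhouette width at the *waist* — the minimum width perpendicular to
the principal axis, scanned between the centroids of the two lobes. A
convex silhouette has no waist; it is flagged `fully_fused` and the
width at the axis midpoint is reported, which for a coalesced disc is
the diameter. Near-complete necks are geometrically almost convex, so
late frames may carry the flag while still reporting the correct width.
Doublet lengths are normalized to the first frame, and normalization is
idempotent by construction.

## Problem sizes and determinism

The validation suite generates everything it consumes; no external data
or binary fixtures exist. Benchmarks use 30 nuclei over 100 frames in a
20×110×110 volume at SNR 5 for detection/linking, 25–60 frames of
24×130×130 mixtures for the correlation pipeline, 12-cell tessellations
for junctions, and 16-frame doublets for fusion — sizes at which every
property under test is already expressed while a full run of tests plus
acceptance completes in a few minutes. All stochastic steps flow from a
single integer seed per generator call; identical seeds produce
bit-identical movies, and the acceptance script derives every stream
from its `--seed` argument.

## Known limitations

- The pipeline measures projected 2D contours; 3D surface sphericity is
  out of scope.
- The pair-r MAE degrades inversely with displacement magnitude; below
  ~3 px/frame at SNR 5 it exceeds 0.05 because localization noise
  dominates the direction signal.
- The synthetic movies do not model uneven illumination, bleaching,
  blob-shape irregularity, division, or apoptosis; passing tests bound
  algorithmic error under the stated image model, not performance on
  arbitrary real data.
- Skeleton-based TJ length assumes the network is line-like after
  top-hat enhancement; dense honeycomb junctions blur into plateaus at
  line widths well above the structuring-element scale.
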