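# spheromorph

Quantitative image analysis of epithelial **spheroid rounding**. When a
suspension of epithelial cells is seeded as an elongated mass, it rounds
up into a spheroid over hours; how fast and how completely it does so
reports on the mechanics of its cell–cell junctions. `spheromorph`
implements the measurement pipeline for this assay end to end, for
researchers analyzing time-lapse silhouette movies, 3D+t nuclear stacks,
and immunofluorescence junction images:

- **Morphometry** — subpixel contour extraction and circularity (form
  factor) `4π·A/P²` of the projected silhouette; segmentation of the
  circularity time course into *latent*, *rising*, and *static* phases;
  detection of discrete circularity jumps caused by sub-mass fusion.
- **Nuclei tracking** — anisotropic 3D difference-of-Gaussians (DoG)
  band-pass filtering (default sigmas 1.9/3.8 px in XY, 0.7/1.4 px in Z),
  local-maximum detection with subvoxel refinement, and frame-to-frame
  nearest-neighbor linking (greedy by ascending distance, with an exact
  minimum-total-distance variant).
- **Neighbor correlation** — per-frame displacement vectors, an adaptive
  radius neighbor graph, the direction correlation
  `r = (v_a · v_b)/(|v_a||v_b|) ∈ [−1, 1]` of neighboring pairs, its
  time-resolved density, and the coordinated fraction (share of pairs
  with `r > 0.8` in a time window).
- **Junction morphometrics** — punctum adherens (PA) spots segmented and
  filtered by attachment to F-actin bundles, measured by maximum Feret
  diameter; tight-junction (TJ) network length from a single-pixel
  skeleton, normalized per cell and per field area.
- **Fusion metrics** — spheroid-doublet long-axis length (normalized to
  t = 0) and contact-neck length over time.

Because public time-lapse data for this assay are scarce, the package
ships a first-class **synthetic-data generator** that renders all four
input types with exact ground truth (programmed circularity curves,
true 3D positions and identities, exact tessellation edge lengths,
programmed neck widths). Every pipeline stage is validated against it.

## Worked example

```r
library(spheromorph)

# a 3:1 elongated mass rounding with a latent phase to 5 h and a
# plateau from 18 h
kin <- rounding_kinetics(c_inf = 0.95, t_latent = 5, t_static = 18)
sim <- generate_rounding_movie(aspect_ratio = 3, kinetics = kin,
                               frames = 25, interval_h = 1, seed = 1)
ts  <- circularity_timeseries(sim$movie, interval_h = 1)
seg <- segment_phases(ts)

sim$truth$circularity[1]                      # 0.6357137 (analytic c0 of a
                                              # 3:1 rounded rectangle)
max(abs(ts$circularity / sim$truth$circularity - 1))  # 0.0106 (1.1% max error)
seg$t_latent_end                              # 5   (programmed 5 h)
seg$t_static_start                            # 18  (programmed 18 h)
```

The measured form factor follows the programmed curve within ~1% and the
phase boundaries are recovered exactly at the 1 h sampling. The same
pattern holds for the other stages (numbers from `analysis/` runs):
nucleus detection at SNR 5 reaches precision 0.998 / recall 1.000 with
link accuracy 1.000; the full images→r pipeline reproduces ground-truth
pair correlations with MAE 0.030; the TJ skeleton length lands within 1%
of the programmed 1020 px of tessellation edge; PA Feret diameters come
back within 0.8 px of the programmed 10 px; fusion contact length tracks
the programmed neck within 1 px.

## Analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the
whole study on synthetic data, writing tables to `results/`:

| script | writes |
| --- | --- |
| `01_simulate.R` | synthetic movies + ground truth (under `scratch/data/`) |
| `02_rounding_kinetics.R` | `rounding_circularity.csv`, `rounding_phases.json` |
| `03_tracking_correlation.R` | `detections.csv`, `trajectories.csv`, `pairs.csv`, `density.csv`, `correlation_summary.json` |
| `04_junction_morphometrics.R` | `pa_objects.csv`, `tj_summary.csv` |
| `05_fusion.R` | `fusion.csv` |

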