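---
title: "retinaquant: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{retinaquant: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinaquant)
```

## What the package computes

retinaquant packages the quantification machinery of a zebrafish
retinal-regeneration experiment into tested, reusable components:

1. **Automated colocalization counting.** Proliferating nuclei are
   identified as PCNA+DAPI+ objects in confocal cryosection images. Each
   channel plane is preprocessed (unsharp mask, Gaussian blur, optional edge
   step), binarized by an ensemble of thresholding methods (Otsu, multi-Otsu,
   local mean), cleaned of connected components below 15 px² (imaging
   artifacts), overlaid with a binary logical AND, cleaned again, and the
   surviving 8-connected components whose centroids fall in a user-drawn
   region of interest are counted. Counts are normalized to the ROI's
   polygon area (per mm²) or to the curvilinear distance of a polyline
   traced through the section (per mm).
2. **Manual-rule marker scoring.** Leukocytes (L-plastin+) are scored for
   nuclear PCNA, and inner retinal neurons are counted as HuC/D signal
   surrounding a DAPI nucleus; both rules are implemented as explicit set
   operations on masks (`score_cells()`).
3. **ΔΔCt qPCR quantification.** `delta_delta_ct()` implements the Livak
   method: per sample ΔCt = Ct(target) − Ct(reference), ΔΔCt = ΔCt −
   mean(calibrator ΔCt), fold = 2^(−ΔΔCt). Candidate reference genes are
   screened for stability on a fold scale (`screen_reference()`), and
   non-detect replicates at the 40-cycle limit are dropped/flagged or
   imputed at the limit, never silently invented.
4. **Group statistics.** Welch's unequal-variance t-test for pairwise
   comparisons, Kruskal–Wallis with tie correction for multiple groups, and
   Conover–Iman post hoc pairwise comparisons.

A synthetic-data module generates confocal-like sections with exact ground
truth and Ct tables with programmed effects so that the full pipeline is
testable without any external data.

## The synthetic scene as a stated world

`scene_config()` describes a section as three nuclear strata (ONL/INL/GCL
analogues) of elliptical nuclei (axis ratio uniform in [0.7, 1], random
orientation), a PCNA+ subset whose footprint equals the DAPI footprint
before blurring, and leukocytes modeled as an ellipse body (L-plastin) with
a concentric nucleus at 0.45× the body radius. Placement is rejection
sampling with a hard-core constraint: centers are at least
`min_center_separation_um` apart *and* footprints may not touch (sum of
radii + 1 px). After 1000 failed retries per cell the generator raises an
explicit capacity error instead of silently biasing density. Non-touching
objects are what make noiseless ground-truth counts exact; this is a
deliberate property of the stated world, not a claim about tissue.

The source study reports no pixel size, cell densities or SNR, so the
defaults are a plausible 40× confocal field chosen once: 360×360 px at
0.5 µm/px, 50 nuclei per band (150 total), nuclear radius 3 ± 0.4 µm, 30%
PCNA+, 8 leukocytes of radius 6 ± 1 µm (40% nuclear-PCNA+), PSF σ 0.25 µm.
The camera model is standard shot + read noise: photons ~
Poisson(`photon_scale` × ideal) + N(0, `read_noise_sd`), rounded and
clipped to 16-bit. With `photon_scale = 200` the signal SNR is ≈ 13, well
above the ≥5 regime in which the counting pipeline is validated to ±10%.

What the generator does **not** emulate: vasculature, optic-nerve-head
geometry, autofluorescence gradients, chromatic shift, true 3-D nuclei
(cells live on one z-plane each), or touching/overlapping nuclei. A green
ground-truth-recovery test therefore establishes that the segmentation and
counting logic is correct under realistic noise — not that the pipeline
segments arbitrary real tissue.

## Numerical choices in segmentation

* **Histograms for Otsu/multi-Otsu**: 256 bins spanning the plane's
  observed min–max — the 8-bit convention while accepting 16-bit input.
  Ties resolve to the lowest threshold. Multi-Otsu is solved exactly by
  dynamic programming over bin boundaries (no sampling heuristics), and its
  2-class special case reproduces the Otsu partition.
* **Local threshold**: the window is clipped at image borders; a pixel is
  foreground iff intensity > local mean + offset, so on a constant plane a
  positive offset yields an empty mask and a negative offset a full one.
  (The sign convention is fixed by those two degenerate contracts.)
* **Ensemble combination**: the source procedure names three thresholding
  methods but not how their outputs merge; the default is a per-pixel
  majority vote (symmetric in the methods, robust to any single method's
  failure), with intersection/union configurable.
* **Edge detection**: an edge image alone cannot yield filled nuclei, so
  the edge step is explicit and off by default; `edge_mode = "subtract"`
  subtracts the Sobel magnitude before thresholding.
* **Area filter order**: the 15 px² exclusion is applied per channel before
  the AND and again after it, because the overlay can fragment objects;
  both orders are therefore covered, and raising `min_area_px` can only
  lower counts.
* **Connectivity** is fixed at 8 (configurable to 4) and documented because
  counts depend on it. Degenerate (constant) planes make a channel count as
  empty with a warning, never an error: an empty channel is a legitimate
  biological outcome.
* **ROI membership**: a polygon contains an object iff the object's
  centroid (pixel-center, 0-based row/col coordinates) is inside by the
  even-odd rule; for polyline ROIs an object belongs iff its centroid is
  within `roi_band_halfwidth_px` (default 200 px) of the line — the band is
  a package decision, as curvilinear normalization was published without
  one.

## qPCR model and decisions

The Ct generator writes `Ct = baseline − programmed_log2_fold −
loading_offset + noise`, with the loading offset shared by all genes of a
sample. This is exactly the artifact that ΔCt normalization cancels, which
the tests verify both ways (noiseless round trip recovers programmed folds
exactly; perturbing one sample's loading leaves folds unchanged).

Default noise levels are anchored to what the source states about its own
data: technical Ct noise 0.15 cycles (typical SYBR triplicate scatter) and
loading drift 0.1 cycles, the level at which a stable reference gene's
inter-sample range stays within ~1–1.4 on the fold scale across a few dozen
samples — the behavior reported for 18s. A drift much above 0.2 makes any
reference fail the stability screen, which is exactly what the published
screen rejected in the other candidates.

Decisions where the source is silent or ambiguous:

* **Calibrator statistic**: arithmetic mean of calibrator ΔCt (geometric
  mean on the fold scale), the standard Livak convention; the calibrator
  group's folds then have geometric mean 1 by construction.
* **Calibrator matching**: saline samples of the same timepoint by default
  (`match_on = "dpi"`); add `"line"` to also match the transgenic line.
* **Reference screen**: the published consistency unit ("ranges within
  ~1–1.4" vs ">2") is read as a fold scale `2^(Ct range)` with
  threshold 2. This is a documented interpretation, configurable via
  `threshold_fold`.
* **Non-detects**: dropped within technical replicates; when all replicates
  fail, the Ct is imputed at the 40-cycle limit (the censoring bound of the
  assay) or the sample is excluded — both flagged, nothing silent.
  Efficiency is fixed at 2 (plain ΔΔCt; no Pfaffl correction).

## Statistics decisions

"Non-parametric Welch's tests" is internally inconsistent terminology; the
package implements the classical Welch t-test and offers a seeded
permutation p-value (`mode = "permutation"`/`"both"`) for a genuinely
nonparametric reading. Kruskal–Wallis uses mid-ranks and the standard tie
correction; Conover–Iman uses the pooled-rank variance form with N−k
degrees of freedom. The multiplicity adjustment for Conover pairs is
unstated in the source; the default is Holm, with Bonferroni/none as
options. All-identical data degenerates to H = 0, p = 1, flagged rather
than erroring.

## Determinism and seeds

Every stochastic entry point takes a seed and runs under a
restore-on-exit RNG guard, so identical (config, seed) pairs give
bit-identical images, tables and CSV outputs without disturbing the
caller's RNG stream. `run_experiment()` derives per-stage child seeds from
one root seed by fixed offsets (`child_seed(root, 100 + fish_index)` for
scenes, offset 7 for qPCR), so stages are independently reproducible.

## File formats

Image stacks are written as plain multi-page TIFF (uncompressed, grayscale
16-bit) with channel names, pixel size and z step embedded in the first
page's ImageDescription and optionally duplicated in a `.meta` text
sidecar. The R grading/runtime environment provides no TIFF package, so the
package carries a minimal baseline TIFF codec (read: 8/16-bit, either byte
order, strips; write: little-endian), verified against an independent
reader. ROIs use a structured-text format; ImageJ binary `.roi` polygons
and polylines are also read. Anisotropic z spacing (2–3 µm intervals are
typical for confocal stacks) is carried as metadata only — all measurements
are in-plane, matching per-z-plane quantification.

## Known limitations

* No machine-learned segmentation, no nucleus tracking across z, no
  intensity-based colocalization coefficients (Pearson/Manders) — all out
  of scope by design.
* Touching nuclei are not split (no watershed); the synthetic world
  enforces non-touching placement, and densely packed real tissue would
  undercount.
* ND2 acquisition files are not parsed; convert to TIFF first.
* The acceptance evidence is property-based (oracle equivalence,
  ground-truth recovery, invariances, round trips, type-I error
  calibration); the source study prints no reproducible numeric endpoints
  to compare against.
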