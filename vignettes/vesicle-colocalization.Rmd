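---
title: "Object-based vesicle colocalization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Object-based vesicle colocalization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endovesiq)
```

## The question the package answers

Endothelial cells exposed to low laminar shear stress (LSS, ~1 dyn/cm²,
atheroprone) internalize the BMP co-receptor Endoglin into Caveolin-1-positive
early endosomes, where active SMAD1 signaling can be detected; under high
laminar shear stress (HSS, ~30 dyn/cm², atheroprotective) this compartment is
much less prominent. The quantitative readout behind that statement is an
object-based colocalization analysis of multi-channel confocal micrographs:

1. detect vesicles (puncta) in one marker channel (Caveolin-1 or EEA1),
2. decide, per vesicle, whether it is *positive* for a secondary marker
   (Endoglin) by comparing its mean intensity with the image mean,
3. screen the positives for further markers (EEA1, SMAD1),
4. count per field of view and compare the two shear conditions.

`endovesiq` implements that analysis as a reproducible pipeline, plus a
seeded synthetic-micrograph generator with vesicle-level ground truth so
every stage can be validated without access to the original micrographs.

## The positivity rule

For a vesicle $v$ with mean intensity $\bar{I}_v$ in a marker channel and
the whole-image mean $\bar{I}$ of the same channel, the enrichment ratio is
$r_v = \bar{I}_v / \bar{I}$ and the vesicle is marker-positive iff

$$ r_v \ge 1 + f, \qquad f = 0.15 \text{ by default.} $$

Three interpretive choices are deliberately fixed (and overridable):

* **"At least 15% higher" is inclusive** (`>=`); a strict mode exists but is
  not the default.
* **The reference is the mean over *all* pixels** of the channel
  (`reference_scope = "image"`), the literal reading of "mean intensity of
  the image". Means over non-vesicle or vesicle-only pixels are selectable.
* **Intensities are measured on the raw raster** (`measure_on = "raw"`).
  This matters more than it looks: after top-hat background subtraction the
  image mean collapses toward the noise floor, so a *relative* margin like
  15% loses its meaning — almost everything exceeds it. The 15% rule is
  calibrated for images with a substantial intensity baseline, so the
  package measures enrichment on raw intensities and reserves the top-hat
  for detection. A `"subtracted"` mode exists for inspection.

Co-positivity is a gated conjunction: only vesicles positive for every base
marker (e.g. Endoglin) are evaluated against the screen channel (e.g.
SMAD1), with the same rule and optional per-marker `f` overrides; vesicles
failing the base set get `FALSE`, never a missing value. Consequently the
co-positive count can never exceed any component marker's positive count.

## Detection model

Detection mirrors a standard particle-analysis workflow:

Gaussian pre-smoothing (σ = 1 px) → white top-hat background subtraction
(disc radius 15 px) → automatic threshold (Otsu by default) → hole filling
→ connected-component labeling (8-connectivity) → area and circularity
filters → consecutive relabeling.

Parameter notes, all in `detection_params()`:

* `background_radius` (px) should exceed the largest vesicle radius
  severalfold; 15 px suits 2–5 px vesicles. Rasters are normalized to
  [0, 1] internally for the morphology, so 8-bit, 16-bit and float inputs
  behave identically.
* `smoothing_sigma = 1` px suppresses single-pixel shot noise that would
  otherwise survive the top-hat (which preserves *any* feature smaller than
  the structuring element, including noise spikes) and flood the threshold
  stage with speckle.
* Automatic thresholds are clamped from below at median + `noise_floor_k`
  (default 4) MADs of the subtracted raster. Histogram-splitting methods
  such as Otsu always find a "foreground" even in pure noise; the robust
  floor makes an empty field yield zero detections while never binding on
  fields with real puncta (where Otsu sits far above it).
* `min_area = 4` px², `max_area = 400` px², `min_circularity = 0.3`
  (circularity $= 4\pi A / P^2$, clamped at 1) are typical endosome-scale
  choices at confocal sampling, documented as defaults rather than measured
  values; bounds are inclusive.
* Centroids are intensity-weighted on the subtracted raster and reported in
  0-based (row, col) pixel coordinates.
* Touching vesicles are **not** split (no watershed); the generator's
  `min_separation` option exists to produce the non-overlapping regime the
  validation criteria assume.

## The synthetic-data generator

`simulate_field()` draws a Poisson number of vesicles (mean
`vesicle_density` × area / 1000), places them uniformly (optionally with a
minimum separation via rejection sampling), and renders each as an
isotropic 2D Gaussian blob with SD = radius/2 — the standard approximation
of a diffraction-blurred punctum. The background is a Gaussian random field
(white noise blurred at `background_smoothness` = 20 px, standardized to
mean `background_level` and SD `background_sd`), so background subtraction
has real work to do. Noise is shot-then-read: Poisson on the expected
signal, then additive Gaussian (SD 4). Ground truth records ids, centers,
radii, per-channel amplitudes and true positivity labels before noise.

Secondary channels render an enriched copy of each truly positive vesicle
(amplitude × `secondary_enrichment_factor`, default 3) and a small bleed
for negatives (`bleed_fraction` = 0.1 of the vesicle's *primary* amplitude,
i.e. ~3% of an enriched peak). Defining bleed relative to the primary
amplitude keeps negative vesicles dim but visible; tying it to the enriched
amplitude instead would park negatives exactly at the 15% decision boundary
and make the classifier's accuracy undefined by construction.

Photometry defaults were chosen by analysis, once: baseline 100, vesicle
amplitude 60, background SD 6, read noise 4. Two constraints drive them.
First, the 15% rule's absolute margin is 0.15 × baseline; it must dominate
the smooth background variation a vesicle can sit on (15 units vs 6 here),
or marker-free vesicles on background hills cross the threshold regardless
of bleed. Second, peak SNR — amplitude over the total noise SD at signal
level (√(100+60) + read ≈ 11) — lands at ≈5, a realistically hard but
workable detection regime.

Conditional positivity (`conditional_on`) draws a channel's positive label
only among vesicles positive for a parent channel, producing the nested
truth (SMAD1-positive ⊂ Endoglin-positive) that the screening stage is
meant to recover.

`shear_presets()` encodes the qualitative biology as defaults: LSS has
twice the vesicle density of HSS (0.8 vs 0.4 per 1000 px²) and higher
positive fractions (Endoglin 0.6 vs 0.35; EEA1 0.7 vs 0.5; SMAD1 among
Endoglin-positives 0.45 vs 0.3). No public per-field counts exist for the
original experiments, so these magnitudes are order-of-magnitude choices —
the pipeline's validation is against the generator's own ground truth and
the *direction* of the LSS/HSS contrast, not against published axis values.

What the generator deliberately does **not** emulate: 3D optics beyond
Gaussian blur, cell boundaries and per-cell vesicle clustering, chromatic
misregistration, vesicle shape irregularity, and spatially varying noise.
Passing tests therefore demonstrate the pipeline's correctness under its
stated model, not performance on any particular real dataset.

## Statistics

`compare_conditions()` performs an unpaired two-sided two-sample test on a
per-field metric. Welch's t-test is the default — robust to the unequal
variances that Poisson-like counts with unequal means necessarily have —
with the classical pooled Student's test available for fidelity to common
practice, and a permutation test (difference of means, add-one p) as a
distribution-free alternative. With two constant identical groups the test
degenerates gracefully to t = 0, p = 1. Multiple markers are tested without
multiplicity correction by default, matching per-panel testing practice;
apply `p.adjust` downstream if a corrected family is needed.

`match_to_ground_truth()` validates detections by greedy nearest-neighbor
matching in ascending distance order, each side used at most once, pairs
accepted within `max_dist`. For well-separated vesicles this equals optimal
assignment while being simpler to reason about. Precision with zero
detections (and recall with empty truth) is reported absent (`NA`), not 0.

## Reproducibility machinery

A single integer seed determines everything. `simulate_experiment()`
derives per-field sub-seeds by hashing (master seed, condition label, field
index) into [1, 2³¹ − 2], so fields are independent yet exactly
replayable. `run_pipeline()` writes a config snapshot that reproduces the
run bit-identically; per-file read errors are logged and skipped rather
than aborting a batch.

## Problem sizes used by the validation suite

The test suite exercises: detection on 20 fields of 512×512 px with ~200
non-overlapping vesicles each; classification recovery at true positive
fractions 0.1–0.8 on 320×320 fields (~200 vesicles) over 20 seeds per
fraction; nested screening pooled over ~1000 base positives; null
calibration over 100 replicate two-condition experiments (5 fields per
condition, 128×128 px) and power at a 2× density contrast over 40
replicates (10 fields per condition). These sizes give stable estimates
(binomial SEs of 1–3 percentage points) while keeping a full run in a few
minutes on one CPU.

## Known limitations

* Counts are per field of view, not per cell; there is no cell segmenter.
* No watershed splitting of touching vesicles by default; dense fields will
  under-count.
* The 15% rule presumes a meaningful image-wide baseline; on
  background-free (e.g. pre-subtracted) images its reference degenerates,
  and the package raises an error when the reference mean is not positive.
* Channels are assumed co-registered, as in single-pass confocal
  acquisition.
* The permutation test's resolution is limited by group sizes (smallest
  attainable p with 3 + 3 fields is ~0.1).
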