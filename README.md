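# endovesiq

Object-based vesicle colocalization analysis for multi-channel fluorescence
micrographs of endothelial cells under laminar shear stress.

Endothelial cells exposed to *low* laminar shear stress (LSS, atheroprone)
internalize the BMP co-receptor Endoglin into Caveolin-1-positive early
endosomes that also carry SMAD1 — a shear-regulated signaling compartment
that is much less prominent under *high* shear (HSS, atheroprotective).
`endovesiq` implements the image analysis that quantifies this:

1. **Detect** vesicles (puncta) in a detection channel (Caveolin-1 or
   EEA1): Gaussian pre-smoothing, white top-hat background subtraction,
   automatic thresholding (Otsu/triangle/fixed), connected-component
   labeling, area and circularity filters.
2. **Classify** each vesicle as secondary-marker positive by the relative
   enrichment rule: with vesicle mean intensity Ī_v and whole-image mean Ī
   of the same channel, the vesicle is positive iff

   &nbsp;&nbsp;&nbsp;&nbsp; Ī_v ≥ (1 + f) · Ī,&nbsp;&nbsp; f = 0.15 by default

   ("at least 15% above the image mean", inclusive).
3. **Screen** positives for additional markers (EEA1, SMAD1) with the same
   rule, gated on the base markers (nested co-positivity).
4. **Quantify**: per-field counts and fractions, two-condition comparison
   (Welch/Student t-test or permutation test), multi-channel line
   profiles, and precision/recall evaluation against ground truth.

Because the original micrographs are not publicly deposited, the package
ships a seeded synthetic-micrograph generator (`simulate_field()`,
`shear_presets()`) producing Gaussian-blob vesicles on smooth random
backgrounds with Poisson + Gaussian noise and per-vesicle ground truth, so
the entire pipeline is testable end to end.

## Worked example

Simulate one LSS-like field (256×256 px, ~100 non-overlapping vesicles,
half of them truly Endoglin-positive), detect, classify and evaluate:

```r
library(endovesiq)

p <- simulation_params(field_shape = c(256, 256), vesicle_density = 1.5,
                       true_positive_fraction = 0.5, min_separation = 12,
                       condition_label = "LSS", seed = 42)
sim <- simulate_field(p)            # $field (4 rasters), $truth (111 vesicles)

det <- detect_vesicles(sim$field, "cav1")
tb  <- classify_vesicles(det$table, det$mask, sim$field, "endoglin")
head(tb, 4)
#>   label    row    col area mean_endoglin ratio_endoglin pos_endoglin
#> 1     1 131.83 1.2265   21         198.5         1.9266         TRUE
#> 2     2 171.01 0.8347   13         101.6         0.9864        FALSE
#> 3     3  78.30 4.5101   12         105.8         1.0265        FALSE
#> 4     4  48.25 7.4895   14         212.2         2.0595         TRUE
```

Row/col are 0-based intensity-weighted centroids (px); `ratio_endoglin` is
the enrichment ratio Ī_v / Ī; `pos_endoglin` applies the ≥ 1.15 rule.

```r
summarize_field(tb, "LSS")
#>   condition n_vesicles n_pos_endoglin frac_pos_endoglin
#> 1       LSS        111             58         0.5225225

match_to_ground_truth(tb, sim$truth, max_dist = 3)[c("precision", "recall", "rmse")]
#> precision 1.000  recall 1.000  rmse 0.34 px
```

The recovered positive fraction (0.523) equals this field's actual truth
(58/111 = 0.523 of simulated vesicles carry the Endoglin enrichment).

A full two-condition experiment — simulate, detect, classify, screen for
SMAD1, compare — in one call:

```r
cfg <- default_config(seed = 11)
cfg$simulation$field_shape <- c(256L, 256L)
cfg$simulation$n_fields_per_condition <- 5L
res <- run_pipeline(cfg, simulate = TRUE, out_dir = "out")

res$comparisons$n_vesicles
#> n_vesicles: welch test, HSS = 23.400 vs 46.200 (n = 5, 5), stat = -7.321, p = 0.0002055
res$comparisons$n_copos_smad1
#> n_copos_smad1: welch test, HSS = 4.400 vs 13.400 (n = 5, 5), stat = -5.095, p = 0.0009835
```

Under the default presets the simulated LSS condition has significantly
more Caveolin-1 vesicles and more SMAD1-positive Endoglin/Cav-1 vesicles
per field than HSS — the direction the analysis was built to detect.
`out/` contains per-field label masks (16-bit TIFF), vesicle tables (CSV),
the per-field summary, comparison JSON, a config snapshot that replays the
run bit-identically, and a log.

Real micrographs enter through `read_field()` (multi-page TIFF + channel
map) or `run_pipeline(cfg, images = data.frame(path, condition))`. A thin
command-line wrapper with verbs `simulate`, `detect`, `classify`,
`profile`, `summarize`, `compare`, `evaluate`, `run` is installed at
`inst/cli/endovesiq.R`.

## Documentation

The methods vignette (`vignettes/vesicle-colocalization.Rmd`) documents the
detection model, the enrichment rule's interpretive choices, the simulator's
photometric design, the statistics, and known limitations.
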