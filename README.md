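# spermdfi

Single-sperm morphometry, DNA fragmentation index (DFI) and DNA-quality
prediction in R.

In ICSI-style assisted reproduction a clinician picks one sperm under
brightfield optics, but every direct DNA-integrity assay destroys the cell.
`spermdfi` implements the quantitative bridge between the two: it measures
a cell's visible morphology from a brightfield raster, computes its DFI
from paired acridine-orange fluorescence channels

    DFI = I_red / (I_red + I_green),

and fits three predictive models of `Ln(DFI)` on the six morphological
parameters — head circularity `C = 4*pi*A/P^2`, head width `HW`, head
length `L`, midpiece width `MW`, vacuole area `VA` and acrosome area `AA`:

* a centered two-factor-interaction least-squares model
  (`fit_linear()`), with forward selection over the 28-term candidate set
  by cross-validated R² (`forward_select()`);
* a single-hidden-layer neural network (20 tanh nodes, linear output)
  trained by Levenberg–Marquardt with validation early stopping
  (`fit_nn()`);
* a logistic classifier of `Ln(DFI)` rank categories, e.g. best 80% vs
  worst 20% (`fit_logistic()`).

Evaluation follows the field's conventions: Pearson r per split,
percentile rank groups (0–5, 5–10, 10–20, 20–80, 80–90, 90–95, 95–100%)
with Welch tests and enrichment percentiles, ROC/AUC, confusion matrices,
and leave-one-donor-out reports.

Because no per-cell dataset of this kind is publicly deposited, the package
includes a first-class synthetic-data module: `generate_feature_table()`
draws cohorts whose ground truth is the published 14-term
morphology–Ln(DFI) interaction model (`reference_model()`), and
`generate_cell_images()` renders matching brightfield + green/red rasters
(elevated-gray acrosome, darker vacuoles, dim midpiece, noise) so the whole
measurement pipeline is testable end to end.

## Worked example

```r
library(spermdfi)

# a synthetic study cohort: 1056 cells, 6 donors, noise calibrated so a
# refit of the reference model attains held-out r ~ 0.57
cfg   <- synth_config(n_cells = 1056, seed = 1)
tab   <- generate_feature_table(cfg)$table
split <- split_data(nrow(tab), c(0.65, 0.10, 0.25), seed = 1)

# forward selection + OLS on the training split
spec <- forward_select(tab[split == "train", ], seed = 1)
fit  <- fit_linear(tab[split == "train", ], spec)

test <- tab[split == "test", ]
pred <- predict(fit, test)
pearson_r(test$ln_dfi, pred)
#> [1] 0.5637344

# rank the test set by predicted Ln(DFI) and summarize each group
groups <- group_mean_and_test(rank_groups(pred), test$ln_dfi)
groups[, c("lo", "hi", "n", "mean_actual", "p_vs_overall",
           "enrichment_percentile")]
#>   lo  hi   n mean_actual p_vs_overall enrichment_percentile
#> 1  0   5  13   -2.508096  0.001548863              89.20455
#> 2  5  10  13   -2.303467  0.281593921              72.53788
#> 3 10  20  26   -2.311726  0.010403316              63.25758
#> 4 20  80 159   -2.234223  0.657232005              50.18939
#> 5 80  90  26   -2.178833  0.023659366              37.87879
#> 6 90  95  13   -2.143829  0.058159741              23.29545
#> 7 95 100  14   -2.083624  0.001031805              12.87879
```

The mean actual `Ln(DFI)` climbs from the predicted-best to the
predicted-worst groups (the 13-cell extreme groups wobble at this test-set
size), and the predicted-best 10–20% group's median actual `Ln(DFI)` sits
at the 63rd quality percentile of the whole test set — the model enriches
for low-DFI cells well above the 50th-percentile baseline of random
selection.

The image pipeline closes the loop on the feature pipeline:

```r
icfg <- synth_config(n_cells = 12, seed = 5, shape_consistent = TRUE)
ds   <- generate_image_dataset(icfg)          # tables + rendered rasters
m    <- measure_cell(ds$images[[1]])          # segment + measure one cell
round(m[, c("C", "HW", "L", "MW", "VA", "AA", "DFI")], 3)
#>       C   HW     L   MW    VA    AA   DFI
#> 1 0.736 3.15 4.189 1.26 0.765 3.995 0.102
round(unlist(ds$table[1, c("C", "HW", "L", "MW", "VA", "AA", "DFI")]), 3)
#>     C    HW     L    MW    VA    AA   DFI
#> 0.739 3.126 4.158 1.250 0.767 3.989 0.100
```

Measured features land within a few percent of the generating truth; the
morphometry oracles (pixel-count area, sub-pixel marching-squares
perimeter) sit within 0.6% / 0.8% of closed forms on rasterized ellipses.

`run_pipeline(pipeline_config(...))` chains the stages (synthetic table,
rendered images, or a feature CSV via `read_feature_table()`) into a
reproducible bundle: identical config + seed give byte-identical outputs,
each artifact stamped with the seed and config hash.

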