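# panicledyn

Rice yield forms during a short reproductive window that nadir RGB imagery
can watch directly: after heading, the fraction of the canopy occupied by
panicles rises steeply, plateaus, and then declines as grains fill and
panicles droop out of view. `panicledyn` turns that *panicle coverage*
signal into quantitative phenotypes. It is aimed at crop phenotyping and
agronomy researchers who have (or want to simulate) per-plot time series of
segmented canopy images and plot-level yield-component measurements.

The package covers the full analysis chain:

1. **Synthetic data** — canopy images with exact panicle masks, coverage
   time series with controlled noise, and yield-component tables with a
   realistic correlation structure, so every downstream stage is testable
   without field data.
2. **Dataset preparation** — 512-pixel tiling, photometric and scale
   augmentation (brightness/contrast 0.8–1.2, upscale 1.1–2.0, downscale
   0.6–0.9, Gaussian noise), and leakage-guarded 7:2:1
   train/validation/test splits.
3. **Segmentation scoring** — pixel accuracy, precision, recall, F1,
   per-class IoU and mIoU from binary mask pairs, with micro/macro
   aggregation.
4. **Coverage extraction** — images standardised to 1536×1536, split into
   nine 512×512 tiles, segmented by any pluggable segmenter (a baseline
   colour-rule segmenter ships with the package), and scored as
   PC = PA/(PA+BA), averaged over the nine tiles.
5. **Growth–decline modelling** — the core of the package: bounded
   nonlinear least squares fits of the piecewise model

   ```
   f(x) = K / (1 + exp(-g (x - d0)))                      x <= d1
   f(x) = K / (1 + exp(-g (d1 - d0))) - a (x - d1)^2      x >  d1
   ```

   yielding five dynamic parameters per plot: the plateau coverage `K`,
   growth rate `g` (1/day), inflection day `d0`, transition day `d1`, and
   decline curvature `a` (1/day²), plus an R² goodness of fit.
6. **Yield prediction** — Pearson correlation screens of the parameters
   against Yield, GN, PN, GNP, TGW and FGR; leave-one-out cross-validated
   regression with four model families (PLSR with 3 components, random
   forest with 100 trees, gradient boosting and XGBoost with 100 stages at
   learning rate 0.05); and exact Shapley feature attribution for the tree
   ensembles.

## Worked example

Simulate one plot imaged every 4 days after heading with realistic
observation noise, refit the model, then run the yield analysis on 200
simulated plots:

```r
library(panicledyn)

cfg <- scenario_config(
  true_params = reference_params()[1, ],   # treatment 23-F-0N
  sampling_days = seq(0, 56, by = 4), noise_sd = 0.01, seed = 42
)
series <- simulate_coverage_series(cfg)
fit <- piecewise_fit(series[, c("day", "coverage")])
fit
#> Piecewise coverage model fit
#>   n = 15, R^2 = 0.9891, converged: TRUE
#>       K       g      d0       a      d1
#>  0.2593  0.2623  9.9871  0.0003 28.9538
```

With 15 noisy observations the fit recovers the generating parameters
(K = 0.2512, g = 0.2738, d0 = 9.94, a = 0.0003, d1 = 28.07) to within a few
percent; `autoplot(fit)` draws the data and curve, `tidy()`/`glance()`
return the estimates and fit summary as tibbles.

```r
rec <- simulate_plot_records(200, seed = 1)
dplyr::filter(correlation_screen(rec), feature == "K")
#>   feature target        r  p_value stars     n
#> 1 K       Yield   0.871   4.90e-63 ***     200
#> 2 K       GN      0.863   1.24e-60 ***     200
#> 3 K       PN      0.811   5.26e-48 ***     200
#> 5 K       TGW    -0.479   7.26e-13 ***     200
#> ...

loocv(rec, "Yield", "rfr", seed = 2)
#> LOOCV Yield ~ dynamic parameters [rfr]: R^2 = 0.907, RMSE = 282.1 (n = 200)
```

The screen shows the plateau coverage `K` dominating Yield and grain
number, with the timing parameters `d0`/`d1` negatively related to the
filled-grain ratio, and the random forest explains ~91% of the simulated
yield variance out of sample. `shap_attribution(fit_tree_model(rec,
"Yield", "rfr"), rec)` decomposes each prediction into exactly additive
per-parameter contributions.

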