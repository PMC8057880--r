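# eicsmri

Interpolated compressed-sensing reconstruction for multislice MRI with
radial undersampling.

## The problem

Multislice MRI scan time is proportional to the number of k-space samples
acquired per slice. Compressed sensing (CS) reconstructs each slice from a
few percent of the Nyquist budget, but at the most aggressive ratios the
measurements alone no longer support a clean reconstruction. Consecutive
slices of a multislice volume, however, are strongly correlated. If
neighboring slices are undersampled with radial masks that share **no spoke
angles**, each slice can import, verbatim, the k-space samples its two
neighbors acquired at locations it skipped — tripling the effective sample
budget at zero acquisition cost — and then reconstruct from the pooled set.

For a target slice *T* with left/right neighbors *L*, *R* (all undersampled
with pairwise disjoint masks), the interpolated sample set is

    T_int = (L ⊖ T) ⊕ T ⊕ (R ⊖ T)

with ⊖/⊕ set difference/union over quantized k-space locations. The pooled
slice is reconstructed by nonlinear conjugate gradient on the standard
sparse-MRI objective

    min_x ‖F_u x − y‖₂² + λ₁‖Ψx‖₁ + λ₂ TV(x)

where `F_u` is the undersampling NUFFT (built-in Kaiser-Bessel gridding),
`Ψ` an orthogonal Daubechies-4 wavelet, and TV the isotropic total
variation. The three-slice scheme (EiCS), its two-slice predecessor (FiCS),
and plain CS are all available for comparison, along with a seven-metric
evaluation harness (SSIM, FSIM, MSE, PSNR, correlation, sharpness index,
PIQE), a drifting multislice phantom generator, and an experiment pipeline
(method × ratio × interslice-gap grids).

Who it is for: researchers prototyping interpolated-CS sampling strategies,
and anyone needing a self-contained radial-MRI simulation/reconstruction/IQA
stack in R.

## Worked example

```r
library(eicsmri)

# synthetic multislice stack: 9 slices of 64x64 with slow interslice drift
stack <- generate_phantom(phantom_spec(n_slices = 9, matrix_size = 64,
                                       drift = 0.004, noise_sigma = 0.01,
                                       seed = 7))
round(correlation_profile(stack, 4), 4)
#> [1] 1.0000 0.9790 0.9736 0.9685 0.9562
```

Adjacent slices correlate at ~0.98, decaying with slice distance — the
regime interslice interpolation assumes. Undersample at 5 % with a
golden-angle mask triple, interpolate, and inspect where the pooled samples
came from:

```r
triple <- make_mask_triple(spokes_for_ratio(0.05, 64), "golden", 64)
u  <- undersample_stack(stack, triple)
ui <- interpolate_stack(u, "eics")
provenance_table(ui)[c(1, 2, 10), ]
#>      slice pct_T pct_L pct_R n_samples pct_of_grid
#> 1        1 50.08 49.92   0.0       631       15.41
#> 2        2 33.40 33.30  33.3       946       23.10
#> 10 average 37.11 36.99  25.9       876       21.39
```

Interior slices keep ~33 % of their samples from the target itself and ~33 %
from each neighbor, holding almost 3× the acquired budget; boundary slices
fall back to the two-slice rule. Reconstruct and score against the ground
truth:

```r
recs   <- reconstruct_stack(ui, recon_params(max_iter = 30))
report <- evaluate_stack(recs, stack, metrics = c("ssim", "mse", "psnr", "corr"))
report
#> <metrics_report> 9 slices
#>    ssim     mse    psnr    corr
#>  0.6699  0.0057 22.4857  0.9839
```

The three-method comparison in one call — with more interpolated samples,
quality must not degrade:

```r
cfg <- experiment_config(
  phantom = phantom_spec(n_slices = 9, matrix_size = 64, seed = 7),
  scheme = "golden", ratios = 0.05,
  recon = recon_params(max_iter = 30), seed = 7
)
ordering_experiment(cfg)
#> <ordering_verdict> eics >= fics >= cs holds for 4/4 metrics
#>   metric          cs         fics         eics higher_better ordering_holds
#> 1   ssim  0.49367412  0.631807054  0.669942787          TRUE           TRUE
#> 2    mse  0.01390915  0.006975306  0.005681546         FALSE           TRUE
#> 3   psnr 18.57628124 21.589331558 22.485718751          TRUE           TRUE
#> 4   corr  0.95763532  0.980266135  0.983894767          TRUE           TRUE
```

Three-slice interpolation (eics) beats the two-slice baseline (fics), which
beats plain CS, on every metric at the same 5 % acquisition budget. The
methods vignette (`vignettes/eics-methods.Rmd`) documents the models,
parameter choices and limitations; `inst/cli/eics.R` exposes each stage as a
shell subcommand (`simulate`, `masks`, `undersample`, `interpolate`,
`reconstruct`, `evaluate`, `run`).

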