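# samba

Rapid quantitative MRI relaxometry by **S**piral **A**cquisition with a
**M**atching-**B**ased **A**lgorithm — an R toolkit for simulating,
reconstructing and evaluating fast T1/T2 mapping on low-field preclinical
scanners, with gold-standard spin-echo least-squares fitting (SELSF) as the
comparator.

Conventional quantitative T1/T2 mapping with spin-echo protocols takes hours
per slice, which is prohibitive for preclinical contrast-agent studies. The
SAMBA approach combines two accelerations:

- **SA — spiral acquisition.** Interleaved Archimedean spiral k-space
  sampling (5 arms) covers k-space in a few shots instead of one
  phase-encode line per TR, cutting scan time from hours to minutes.
- **MBA — matching-based algorithm.** As in MR fingerprinting, measured
  magnitude time-courses are matched against a dictionary of simulated
  signal evolutions: the atom
  maximizing the normalized inner product
  ⟨s/‖s‖, d(T)⟩ yields the voxel's relaxation time, and the un-normalized
  inner product recovers M0.

The package implements the whole in-silico pipeline for phantom studies:

| layer | contents |
|---|---|
| signal models | inversion-prepared Look-Locker train (recursion `Mz ← M0 + (Mz−M0)e^(−τ/T1)`, sampling `sin α`, depletion `cos α`), T2-preparation decay `M0·e^(−TP/T2)`, IR spin echo `M0(1 − 2ε·e^(−TI/T1) + e^(−TR/T1))` |
| protocols | the four published sequence-parameter presets (`samba-t1`, `samba-t2`, `se-ir-t1`, `se-t2prep`), YAML serialization, nominal scan-time arithmetic |
| spiral engine | trajectory design at the azimuthal Nyquist limit, analytic/Voronoi density compensation, Kaiser-Bessel gridding (2× oversampling, width-4 kernel) with an exact adjoint and a direct-DFT oracle |
| dictionary engine | dictionary generation from any protocol, vectorized voxel-wise matching into parameter maps |
| least-squares fitting | log-linear T2 fit, polarity-restored magnitude IR T1 fit, Look-Locker-corrected train fit, with Rician noise-floor handling |
| digital phantom | multi-tube phantom generator and full forward simulation (spiral and Cartesian) with complex Gaussian k-space noise → Rician magnitude images |
| evaluation | ROI tables, method-agreement regression, Bland-Altman limits of agreement, CV% repeatability and CV%·scan-time efficiency across all four method permutations (SE/SA × LSF/MBA) |

Results come back as tibbles (with `tidy()`/`glance()` methods on fitted
objects) and every result type has an `autoplot()`/`plot_*()` ggplot2
method.

## Worked example

Simulate one tube, estimate its T1 both ways:

```r
library(samba)

p <- protocol_preset("samba-t1")     # TR 14 s, 50 readouts every 265 ms
scan_time(p)
#> <samba_scan_time> 210 s (3min30s)

tube <- tissue_params(t1 = 1000, t2 = 80)
sig  <- ll_ir_signal(tube, p)        # signed 50-point train

dict <- build_dictionary(protocol = p)         # default 50..5000 ms grid
match_signal(abs(sig), dict)
#> <samba_match> 1000 ms (score 1.000000, M0 1)

fit <- fit_t1_looklocker(abs(sig), p)
fit
#> <samba_fit> T1 = 1000 ms (M0 1, residual RMS 3.31e-17)
tidy(fit)
#> # A tibble: 2 × 2
#>   term  estimate
#>   <chr>    <dbl>
#> 1 T1        1000
#> 2 M0           1
```

The dictionary match lands on the 1000 ms grid atom with a perfect score;
the Look-Locker fit recovers the apparent T1* of the flip-angle-driven
recovery and corrects it back to 1000 ms.

A reduced end-to-end phantom study (4 tubes, 48² matrix, 2 repeats —
seconds instead of minutes):

```r
cfg <- experiment_config(
  tube_values = default_tube_values()[c(1, 4, 6, 8), ],
  protocols = list(
    samba_t1 = samba_t1_protocol(matrix_size = 48, n_points_per_interleaf = 600,
                                 n_readouts = 20, tr = 6000),
    samba_t2 = samba_t2_protocol(matrix_size = 48, n_points_per_interleaf = 600),
    se_t1 = se_ir_protocol(matrix_size = 48),
    se_t2 = se_t2_protocol(matrix_size = 48)),
  methods = c("SA-MBA", "SE-LSF"), n_repeats = 2, seed = 1,
  t1_grid = seq(100, 3500, by = 20), t2_grid = seq(10, 450, by = 4))
res <- run_experiment(cfg)
res
#> <samba_experiment> 2 methods x 2 repeats, seed 1
#> -- T1 comparisons --
#>   method_x method_y  slope intercept r_squared     bias loa_low loa_high
#> 1    truth   SA-MBA 0.9911    2.9165         1 -11.3934 -32.254    9.467
#> 2    truth   SE-LSF 0.9980    3.5148         1   0.2851 -12.870   13.440
#> 3   SA-MBA   SE-LSF 1.0070    0.5899         1  11.6785  -9.741   33.098
#> ...
```

Each row is one method pair: the OLS regression of per-tube means (slope,
intercept in ms, R²), the Bland-Altman bias and 95 % limits of agreement in
ms, and a paired t-test across tubes. `plot_method_agreement(res, "T1")`
and `plot_repeatability(res, "T1")` draw the corresponding figures;
`experiment_config(output_dir = ...)` writes ROI tables, the comparison
report and CV tables as CSV, maps as NIfTI, and a provenance record.

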