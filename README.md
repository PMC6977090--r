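# netrate

Single-terminal norepinephrine transporter (NET) reuptake kinetics from
confocal fluorescence time-lapse imaging.

## What this package is for

Sympathetic nerve terminals clear norepinephrine through NET, and a
fluorescent NET substrate (paired with an extracellular masking dye) turns
that transport into an optical signal: terminals pre-labelled with a dilute
substrate solution fluoresce at a stable baseline, and switching to a
concentrated solution drives a linear rise in intra-terminal fluorescence
whose slope is the reuptake rate. netrate is for labs running such
uptake/washout experiments on z-stack time series — and for anyone who wants
a fully testable reference implementation of the analysis. It provides:

* **quantification**: ROI detection (or manual centres), background-subtracted
  trace extraction, ΔF/F normalisation, linear-phase slope fitting, washout
  analysis;
* **statistics**: group summaries over terminals (n_t), the
  normality-screened Student/Welch/Mann-Whitney two-group rule,
  Kruskal-Wallis/Friedman omnibus with Dunn's post-hoc, percent-excess and
  fold-change with root-sum-of-squares error propagation;
* **a synthetic generator**: z-stack series of varicose terminals ("beads on
  a string") with known uptake, washout, per-exposure photobleaching, Q10
  temperature scaling and detector noise, plus a ground-truth sidecar, so the
  whole chain is validated by parameter recovery.

## The core model

For one terminal with background-subtracted ROI intensities `F_t` and
control-phase mean `F_ctrl`:

    ΔF_t = (F_t − F_ctrl) / F_ctrl

The reuptake rate is the gradient `m` of the OLS line `y = mx + c` through
the linear portion of the test-phase `(t, ΔF_t)` points, reported as
`100·m` %·min⁻¹. Washout declines are fitted the same way (negative slopes;
ΔF = −1 is complete loss). Simulated rates obey
`rate = base × multiplier × q10^((T−37)/10)` for temperature and drug
conditions, and photobleaching multiplies intensities by
`(1 − b)^exposures` — per imaging event, not per minute.

## Worked example

Simulate a field of six terminals at a mouse-heart-like rate
(12.7 ± 0.8 %·min⁻¹ over 24 terminals ⇒ per-terminal SD 0.039 min⁻¹), then
quantify it blind:

```r
library(netrate)

cfg <- sim_config(image_shape = c(8, 128, 128), n_terminals = 6,
                  uptake_rate_mean = 0.127, uptake_rate_sd = 0.039,
                  noise_sd = 8, seed = 42)
sim <- simulate_series(cfg)
sim$series
#> <stack_series> 10 timepoints, stacks 8 x 128 x 128 px
#>   phases: control (3), test (7), washout (0)
#>   t = 0 .. 9 min; voxel 1 x 0.41 x 0.41 um

rates <- run_quantify(sim$series)   # auto-detects terminals
round(rates[, c("terminal_id", "row", "col", "slope", "r_squared")], 2)
#>   terminal_id row col slope r_squared
#> 1           1  36  87 15.57      0.99
#> 2           2  86  45 15.88      0.99
#> 3           3  81  18 11.69      0.97
#> 4           4  83  31  8.74      0.98
#> 5           5  28  98  9.24      0.98
#> 6           6  89  59 17.21      1.00
```

Each row is one detected terminal; `slope` is its reuptake rate in %·min⁻¹
(here scattered around the configured 12.7, as the configured between-terminal
spread dictates) and `r_squared` the linearity of the fitted window. A single
fit is a small model object:

```r
roi <- detect_terminals(sim$series$stacks[[1]])[[1]]
fit <- fit_uptake_rate(normalize_trace(measure_trace(sim$series, roi)))
fit
#> <net_rate> uptake slope 15.57 %/min (R^2 0.992, n = 7, window 3-9 min)
coef(fit)
#>  intercept      slope
#> -0.4947657 15.5680750
plot(fit)        # points, fitted line, fitted window
```

Group comparisons follow the protocol's decision rule and print like a
results sentence (`compare_two(control, drug)`), and derived statistics are
one-liners: `percent_excess(6.5, 4.0)` → 62.5 % faster in the heart than the
artery; `fold_change(20.0, 6.5)` → 3.08-fold slowing on 10 °C cooling.

A thin command-line wrapper covers the same pipeline:
`Rscript inst/scripts/netrate.R simulate|quantify|reproduce ...`
(exit codes: 0 ok, 1 usage, 2 data error).

## Series storage

`write_series()`/`read_series()` use multi-page TIFF (one file per timepoint
or one hyperstack) plus a `series.json` sidecar: acquisition times (min),
phase labels (`control`/`test`/`washout`), voxel size, array shape, storage
encoding, and optionally the simulator's ground truth. Integer data in
0–65535 round-trips bit-exactly (16-bit); continuous data is stored as
scaled 32-bit samples accurate to ~1 part in 10⁹ of the dynamic range. ROI
tables import/export as CSV (`terminal_id, row, col, radius,
reference_slice, annulus_inner, annulus_outer`; 0-based pixel coordinates).

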