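---
title: "Quantifying single-terminal NET uptake kinetics from fluorescence time lapses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-terminal NET uptake kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netrate)
```

## The measurement problem

The norepinephrine transporter (NET) clears norepinephrine into sympathetic
nerve terminals; its turnover rate is a functional readout of presynaptic
physiology. A fluorescent NET substrate paired with an extracellular masking
dye makes that rate optically measurable at single varicosities: terminals
are pre-labelled with a dilute (1:100) substrate solution until they are
visible, three control z-stacks are acquired, and a concentrated (1:20)
solution is then superfused while the same field is imaged every one to two
minutes. Intra-terminal fluorescence rises linearly while the transporter
runs; returning the preparation to substrate-free buffer (washout) reverses
the rise. netrate implements the full quantification chain for such
experiments, together with a synthetic data generator that makes every stage
testable by parameter recovery.

## The model

For one terminal, let $F_t$ be the background-subtracted mean ROI intensity
at time $t$ and $F_{\mathrm{ctrl}}$ the mean of its control-phase values.
Every later timepoint is normalised as

$$\Delta F_t \;=\; \frac{F_t - F_{\mathrm{ctrl}}}{F_{\mathrm{ctrl}}},$$

which removes the arbitrary intensity scale set by native labelling,
detector gain and pinhole. The reuptake rate is the gradient $m$ of the
ordinary least-squares line $y = mx + c$ through the linear portion of the
test-phase $(t, \Delta F_t)$ points, reported as $100\,m$ in %·min⁻¹.
Washout is treated symmetrically: the OLS gradient over washout timepoints
(conventionally the first five minutes) is the decline rate; $\Delta F = -1$
is the complete-loss floor, reached when a terminal's fluorescence
disappears entirely.

Assumptions worth stating explicitly:

* uptake is linear over the fitted window — there is no saturation or
  plateau term in the model;
* the ROI is stationary (the protocol restores the same ROI in every stack;
  optional ±3 px re-centring exists for drifting preparations, off by
  default);
* background is estimated locally, as the median of an annulus around the
  ROI disc, on the same reference slice;
* terminals are statistically independent sampling units ($n_t$), matching
  the source protocol. This is deliberate pseudo-replication — terminals
  within an animal are correlated in reality — and is reproduced, not
  "fixed", so that results are comparable with the reference analysis.

## Measurement chain

1. **Detection** (`detect_terminals`). Varicosities are found on the
   per-pixel maximum projection of the first control stack with a
   multi-scale Laplacian-of-Gaussian response (computed as differences of
   Gaussians over four scales between `min_sigma` and `max_sigma`).
   Candidates must be local maxima of the response, at least
   `min_separation` px apart (the brighter wins), clear of the border by the
   annulus radius, and above `threshold`. The default threshold is adaptive,
   10 × MAD of the response image: on blank noise fields the largest response
   peaks reach about 7 MAD, while rendered terminals at SNR ≈ 10 sit at
   15–22 MAD, so the default detects nothing on noise while keeping real
   terminals. Hand-placed centres can be supplied instead (`rois =` a
   data.frame of centres), which mirrors the manual ROI placement of the
   reference protocol.
2. **Reference slice**: for each ROI, the z-slice with maximal disc mean in
   the first control stack ("the terminal at its brightest"). The same slice
   is used at every timepoint by default; per-timepoint re-selection is
   deliberately not done, because picking the maximum of noisy candidates at
   every timepoint would bias intensities upward.
3. **Trace extraction** (`measure_trace`): disc mean minus annulus median,
   per timepoint. The median is robust to a neighbouring terminal intruding
   into the annulus. Defaults: disc radius 3 px, annulus 5–8 px, sized for
   ~1 µm varicosities at the default pixel scale.
4. **Normalisation and fitting** (`normalize_trace`, `fit_uptake_rate`,
   `fit_washout_rate`): as in the model above. Fits return a `net_rate`
   object with `print`, `summary`, `coef`, `predict`, `plot`, `residuals`
   and `fitted` methods.

## The linear window

The source protocol fits "the linear portion" without defining it. The
automatic rule used here is: take the longest prefix of test-phase points
whose OLS fit reaches $R^2 \ge 0.95$, with a minimum of three points, and
fall back to all test points if no prefix qualifies. This is reproducible
and conservative for traces that start linear and then saturate or bleach.

It has a known failure mode, documented rather than hidden: when the true
relationship is linear but per-point noise is large relative to the total
rise (slow transport, low SNR), the full-trace $R^2$ can fall below 0.95,
and the prefix search then selects short sub-windows in which noise happens
to line up — a selection effect that biases the magnitude of the recovered
slope upward. For data known to be linear throughout (all synthetic
validation arms in this package, by construction), an explicit window
spanning the whole test phase is passed instead (`window = c(start, end)`),
which restores the unbiased OLS estimate. For real data the choice is the
analyst's; the object's `r_squared` and `window` fields expose what was
fitted.

Degenerate cases: an exactly flat trace has zero residual variance and is
assigned $R^2 = 1$ (the line fits perfectly); a terminal whose control
baseline is not positive cannot be normalised and is excluded with a logged
reason rather than propagating infinities; fits need at least two points and
error otherwise.

## The synthetic generator

`simulate_series()` renders what the quantification chain expects to see:

* **Geometry**: varicosities placed every `intervaricose_spacing` px along
  smooth random paths (a heading with small cumulative curvature, gentle z
  drift) — the "beads on a string" appearance of terminal axons. Terminals
  keep a margin from the border so every ROI and annulus fits.
* **Kinetics**: per-terminal uptake rates drawn from
  N(`uptake_rate_mean`, `uptake_rate_sd²`), then scaled by the Q10
  temperature model `q10^((T − 37)/10)` (reference 37 °C, the physiological
  upper bound) and a drug `rate_multiplier` (0 = complete transporter
  block). Washout rates are drawn analogously and expressed per
  washout-start value.
* **Rendering**: each terminal is a Gaussian spot (lateral σ =
  `terminal_radius`/2, axial σ = 1 slice) whose peak equals its current
  kinetic intensity; dim diffuse blobs emulate non-neuronal fluorescence.
  The Gaussian PSF is folded analytically into every blob (Gaussian ⊛
  Gaussian = Gaussian with summed variances), which is exact and keeps
  noiseless renders noiseless. Additive Gaussian detector noise (optional
  Poisson resampling) is applied last and the stack clipped at zero.
* **Photobleaching** is per imaging event, not per unit time:
  `(1 − bleach_per_exposure)^exposures`. Skipped imaging events therefore
  cost no signal, which is what makes reduced-illumination schedules
  informative.
* **Determinism**: the config seed drives geometry, kinetic draws and
  per-event noise; identical config + seed gives bit-identical pixels, with
  no global RNG state disturbed.

Default parameters are the acquisition conditions of the reference protocol
(≈15 slices at 1 µm, 512 × 512 px, three control stacks then one-minute test
imaging, baseline 100 a.u.), with the uptake-rate spread implied by the
fastest reported control group (28.4 ± 4.1 %·min⁻¹ at $n_t = 24$ ⇒
per-terminal SD ≈ 0.20 min⁻¹). The brightness of non-neuronal blobs is not
quantified in the reference work; it is a free parameter defaulting to 30 %
of the terminal baseline.

What the generator does **not** emulate: uptake saturation or plateau (the
model is purely linear, so late-phase endpoint statistics under heavy
bleaching are milder than in real traces), optical physics beyond a Gaussian
PSF, tissue movement, and spatially correlated noise. Passing recovery tests
on this generator therefore demonstrates correctness of the measurement
chain, not robustness to every artefact of real tissue.

`standardize_rates = TRUE` additionally rescales the drawn rates so the
realized sample mean and SD equal the configured values exactly (moment
matching). The reproduction harness uses this to emulate cohorts whose
summary statistics are known: recovered group statistics then differ from
the configured ones only by measurement error, not by the resampling noise
of one simulated cohort. The default is plain i.i.d. draws.

## Group statistics

`compare_two` reproduces the reference decision rule: a Kolmogorov–Smirnov
normality screen on each group — the Lilliefors variant, since parameters
are estimated from the sample; it requires n ≥ 5, and smaller groups are
treated as not rejecting normality — then Mann-Whitney if either group
deviates, otherwise an F test of equal variances deciding between Student's
and Welch's t-test. All tests are two-sided (the source does not state
sidedness) and the full decision trail is returned. `compare_multi` runs
Friedman (paired) or Kruskal-Wallis (independent) omnibus tests followed by
Dunn's multiple-comparison z tests on rank sums — tie-corrected pooled ranks
for the independent case, within-block rank sums for the paired case — with
Bonferroni adjustment over the tested pairs, the conventional family for
this post-hoc. Percent differences between groups carry a combined relative
error computed as the root of the sum of squares of the per-group relative
errors (`combine_relative_errors`). Applied to the reference work's own
printed means and SEMs this rule does not reproduce its printed ± values;
the rule is implemented as stated and the discrepancy simply noted.

## Storage format

Series are written as multi-page TIFF (one file per timepoint, or a single
T·Z hyperstack) plus a JSON sidecar holding times, phases, voxel size, shape
and the storage encoding. Integer-valued data in 0–65535 — what a real
detector produces — takes a 16-bit path with bit-exact round trips.
Continuous data is stored as 32-bit samples under a power-of-two scale
recorded in the sidecar; round trips are accurate to one part in ~10⁹ of the
dynamic range (the TIFF writer quantises at 2⁻³² of full scale). All writes
are byte-deterministic.

## Validation scale and the reproduction harness

The test-suite and acceptance arms simulate 6–8 slice stacks of 64–256 px —
large enough for 4–25 well-separated terminals with full annuli — rather
than full 15 × 512 × 512 fields, keeping complete parameter-recovery
experiments (including 100-replicate schedule comparisons and 1000-replicate
null calibrations) fast enough to run routinely.

`run_reproduce()` simulates every experimental family of the reference
study — four control/inhibitor cohort pairs across two species and two
tissues, the separate tissue/species-comparison cohorts, tyramine washout,
10 °C cooling, carbachol with and without atropine, and constant- versus
reduced-illumination photobleaching — with generator means and SDs set from
the reported group summaries, then runs the full pipeline and juxtaposes
recovered against reported values. Two conversions are involved: reported
washout slopes are per control baseline while the generator's washout rate
is per washout-start value, so the generator receives
`printed / (1 + m̄ · T_test)`; and transporter-block arms model the residual
negative slope as pure per-exposure photobleaching at the reported
magnitude. For the illumination comparison, no parameter pair of the linear
bleach-uptake model reproduces both reported endpoint deltas at once (real
traces saturate; this model deliberately does not), so that condition uses a
parameter set chosen for robust sign separation — constant imaging loses
signal between the 6- and 20-minute marks, reduced imaging gains — which is
the level at which that experiment's conclusion operates.

## Known limitations

* Slopes from the automatic window rule are biased upward in magnitude at
  low SNR (see above); prefer explicit windows when linearity is known.
* The annulus median under heavy zero-clipped noise is only approximately
  the local background; at SNR ≈ 10 arm-level recoveries carry a residual
  uncertainty of a few percent.
* Terminals are treated as independent; no mixed-effects modelling of
  animal-level clustering is provided.
* No Michaelis–Menten kinetics: substrate concentration is never varied, so
  only the linear-regime slope is identifiable.
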