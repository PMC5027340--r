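---
title: "Epicardial mapping and cohort endpoint analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epicardial mapping and cohort endpoint analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimapr)
```

## Scope and model

`epimapr` implements the analysis chain of an epicardial multielectrode
mapping experiment in a chronic-hypertension large-animal study: unipolar
electrograms from a planar 128-channel array (16 × 8 grid assumed, 2.7 mm
pitch, 25 kHz, 12-bit ADC, 2 s windows, pacing at 120 bpm from a bipolar
site at the upper-left corner) are reduced to activation maps, conduction
velocity fields, conduction-heterogeneity and repolarization indices; a
parallel cohort module reproduces the endpoint statistics (weekly MAP,
CMR-derived LV mass / EF / SV, postmortem wall thicknesses) of a
two-group longitudinal design.

The true arrangement of the 128 electrodes on the physical device is not
public; the 16 × 8 default is an assumption that matches channel count and
pitch, and every function takes the geometry as a parameter, so other
layouts are a one-line change.

### Activation and repolarization detection

Local activation is the time of the steepest negative slope of the
intrinsic deflection; repolarization is the steepest positive slope of the
repolarization wave regardless of T-wave polarity (the Wyatt convention);
ARI is their difference, a surrogate for action potential duration.
"Slope" is a discrete central difference, endpoints excluded, earliest
sample winning ties.

Two numerical choices matter here:

* **Derivative scale.** Activation uses the 1-sample central difference
  (0.08 ms support): the intrinsic deflection is the fastest feature in
  the signal and a one-sample estimator localizes it to the sample. The
  repolarization wave is 1–2 orders of magnitude slower; a 1-sample
  derivative of a band-limited noisy signal is dominated by noise over a
  320 ms search window, so the repolarization detector uses a wide
  central difference (default half-width 5 ms), i.e. a smoothed slope
  estimator matched to the T-wave time scale. This is the same device as
  the heavy low-pass filtering customary in ARI pipelines, and it is what
  makes the package's stated ARI-recovery property (mean error < 2 ms at
  noise up to 5% of deflection amplitude) attainable. The property-based
  tests compare the detector against a brute-force scan of the *same*
  k-step derivative, so detector and oracle stay equivalent by
  construction of the convention, not by sharing code.
* **Windows and blanking.** 5 ms after each stimulus is blanked. The
  default activation window is the inter-stimulus interval trimmed by the
  blanking interval at both ends — the tail guard matters because the
  next stimulus artifact has negative-slope lobes a few ms before its
  centre. The repolarization window is [80, 400] ms after each channel's
  activation (ventricular defaults at 120 bpm; ~[40, 250] ms suits
  atria), configurable.
* **Validity.** A channel is invalid when its peak slope magnitude falls
  below `min_slope` (default 5 × the channel's median absolute
  derivative, a robust noise floor — flat or disconnected channels fail
  it), when it is listed as a bad channel, or, for ARI, when
  repolarization does not follow activation.

### Conduction velocity and heterogeneity

For each triangle of the grid triangulation with three valid vertices the
plane `t = a x + b y + c` is solved exactly; the gradient `(a, b)` (ms/mm)
points toward later activation, speed is `1/|(a, b)|`, direction its
orientation. Filters: positive area above 1e-6 mm²; time span across the
triangle of at least one sample (0.04 ms); fitted speed inside
[0.1, 5] m/s — triangles nearly parallel to the wavefront otherwise
produce arbitrarily large speeds. WPV is the mean over valid triangle
speeds (median behind a flag; the choice is recorded in the output).
Rejections are counted by reason and logged.

The phase map assigns each channel the largest *absolute* activation-time
difference to its valid Moore neighbors ("largest difference" is treated
as unsigned, making the statistic direction-agnostic), and
`CHI = (P95 − P5)/P50` of these delays. The percentile convention —
linear interpolation with endpoints at the extreme order statistics,
`quantile type 7` — is part of the definition: changing it changes CHI.
CHI is exactly 0 for a uniform planar wave on a regular grid (up to
~1e-15 floating-point residue) and invariant under rescaling all delays.

### Endpoint statistics

Groups are summarized as mean ± sample SD (n − 1). Between-group
comparisons use the pooled-variance Student's t (the study's named test;
Welch is available behind a flag and the variant is recorded).
Baseline-vs-follow-up comparisons within a group are treated as paired —
the same animals are measured twice; the original report does not state
the pairing, so the report metadata records this choice and the unpaired
route remains callable. No multiple-testing correction is applied
(matching the emulated design); p-values are labelled unadjusted and
star-coded at 0.05/0.01/0.001. Percent changes are computed from
unrounded means and reported both unrounded and at 1 decimal. Degenerate
cases are explicit: identical constant groups give t = 0, p = 1;
zero-variance nonzero paired differences are reported as p = 0 with a
`p_floor` flag rather than a spuriously finite p.

The MAP trajectory summary computes weekly group means ± SD and a plateau
week: the first week whose group mean reaches 95% (configurable) of the
mean over the final four observed weeks. Missing weeks are omitted, never
interpolated.

## The synthetic world

### Electrograms

The generator renders exact wavefront ground truth into signals:

* Intrinsic deflection: derivative-of-Gaussian biphasic wave
  `−a·u·exp(−u²/2)`, `u = (t − t_act)/σ` with `a = 10` mV, `σ = 1` ms. Its
  steepest negative slope is analytically at `t_act` (magnitude `a/σ`),
  which is what makes the recovery tests exact rather than approximate.
* Repolarization: the mirrored shape centred at `t_act + ARI`, `b = 4` mV,
  `σ = 8` ms — steepest positive slope exactly at activation + ARI.
* Stimulus artifact: a large biphasic spike (20 mV, σ = 0.5 ms) at each
  pacing stimulus, decaying as `exp(−d/5 mm)` from the stimulation
  corner; it exists to exercise the blanking logic.
* Noise: white Gaussian convolved with a 0.5 ms Gaussian kernel and
  rescaled to the requested SD. Real acquisition chains band-limit;
  white noise at the full 12.5 kHz Nyquist bandwidth would make any
  slope-based repolarization detector fail for reasons that have nothing
  to do with physiology.
* Quantization: 12-bit over ±20 mV applied last. The step, 5/512 mV, is
  an exact binary fraction, so quantized samples are exactly representable
  in 32-bit floats and the binary file dialect round-trips bit-identically.

What this emulates well: pacing geometry, sampling, amplitude scales,
detection-relevant morphology. What it does not: fractionated or
low-amplitude electrograms, motion and contact artifacts, far-field
components, spatially correlated noise, curved or colliding wavefronts,
tissue anisotropy. A green recovery test therefore establishes that the
*estimators* are correct and calibrated, not that the pipeline handles
every pathology of real epicardial signals.

### Cohort

Each endpoint draws a per-animal baseline from `N(mean, SD)` and a
per-animal change `Δ ~ N(δ, SD_δ)`; follow-up = baseline + Δ, so zero
effect and zero SD give exact equality. Baseline means/SDs and the
LV-mass change SDs (13.16 / 8.52 g) are the printed values of the
emulated study; change SDs the study does not print (EF, SV, weight,
creatinine, and the within-animal MAP change SD of 4.4 mmHg ≈
√(6.9² − 5.3²)) were set once to plausible magnitudes consistent with the
printed baseline/follow-up SDs. Weekly MAP follows
`baseline + Δ·L(week) + ε`, where `L` is a logistic normalized to 0 at
week 0 with midpoint 1.5 weeks and rate `ln(19)/1.5` — placing ~95% of
the rise at week 3, the printed plateau time — and `ε` has SD 2 mmHg
(each real reading is already an average of five consecutive
measurements). The generator draws group sizes 9 (treated) and 7
(control) by default and is a pure function of `(params, seed)`.

## Testing strategy and limits

Every detector is property-tested against an independent brute-force scan
on random signals; conduction fitting against analytic planes, rotation
equivariance, and exact recovery of noiseless planar truth at machine
precision; CHI against hand-interpolated percentiles and its null/
monotonicity behaviour; t-tests against hand computations and
`stats::t.test` as an external oracle, plus type-I calibration at
10⁴ null replicates (3 SE Monte-Carlo band). Simulation-based checks use
fixed seeds; bounds were chosen from the error budget (e.g. 3 SE where
many comparisons run jointly), not adjusted to observed outcomes.

Known limitations: single-beat analysis (no beat averaging or alternans),
no re-entry/wavebreak or anisotropy estimation, no mixed-effects
longitudinal modelling, and the published per-animal electrophysiology
values (CV 0.77–1.29 m/s, CHI 2.0–2.9, ARI 154–254 ms) cannot be
reproduced because the underlying recordings were never deposited — the
acceptance suite instead proves the estimators recover known synthetic
ground truth within stated tolerances.
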