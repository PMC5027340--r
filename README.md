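# epimapr

Analysis of epicardial multielectrode array (MEA) recordings and
longitudinal cohort endpoints from large-animal hypertension studies, as an
installable, tested R package.

Open-chest epicardial mapping with a flexible 128-channel MEA (2.7 mm
pitch, 25 kHz sampling, 12-bit digitization, pacing at 120 bpm) yields 2 s
of unipolar electrograms per site. From those this package computes the
standard electrophysiological readouts:

* **Local activation time** — per channel, the time of the maximum negative
  slope of the intrinsic deflection (`min dV/dt`).
* **Repolarization time** — the maximum positive slope of the
  repolarization wave (Wyatt convention, T-wave polarity independent).
* **ARI** (activation recovery interval) — repolarization minus activation
  time, a surrogate for local action potential duration.
* **WPV** (wave propagation velocity) — for every triangle of adjacent
  electrodes the plane `t = a x + b y + c` is fitted through its three
  activation times; the gradient `g = (a, b)` gives local speed `1/|g|`
  (mm/ms = m/s) and direction; WPV summarizes valid triangles (mean by
  default).
* **CHI** (conduction heterogeneity index) — each site's largest absolute
  activation-time difference to its Moore neighbors forms the phase map;
  `CHI = (P95 − P5) / P50` of those delays. CHI is 0 for a perfectly
  uniform planar wave and dimensionless by construction.

Animal recordings of this kind are rarely deposited, so the package ships a
first-class synthetic-data module: exact planar/focal wavefront ground
truth, realistic electrogram synthesis (biphasic intrinsic deflection,
slow repolarization wave, pacing artifact with spatial decay, band-limited
noise, 12-bit quantization), and a cohort generator that emulates an
8-week angiotensin-II hypertension study (treated n = 9 vs control n = 7;
MAP 87.4 ± 5.3 → 111.8 ± 6.9 mmHg with a logistic rise plateauing at week
3; LV mass 111.2 ± 12.6 → 131.5 ± 18.7 g; postmortem wall thicknesses).
Endpoint statistics mirror the study design: group mean ± SD, paired
within-group and pooled-variance unpaired between-group Student's t-tests,
percent changes, and MAP-trajectory plateau detection.

## Worked example

```r
library(epimapr)

g   <- make_geometry(16, 8, 2.7)                  # the 128-channel array
tr  <- simulate_planar_truth(g, speed_mps = 0.9, direction_deg = 30, t0_ms = 10)
rec <- synthesize_recording(tr, ari_ms = 180, noise_sd_mv = 0.05, seed = 42)

amap <- detect_activation_times(rec)
rmap <- detect_repolarization_times(rec, amap)
ari  <- compute_ari(amap, rmap)
wave_propagation_velocity(amap, g)
chi  <- conduction_heterogeneity_index(phase_map(amap, g))
```

prints

```
Conduction field: WPV (mean) = 0.899 m/s (SD 0.017), 210/210 valid triangles
P5 4.04  P50 4.12  P95 4.20 ms,  CHI 0.039
mean ARI 179.9 +/- 0.4 ms over 128 channels
```

i.e. the mapping stages recover the programmed 0.9 m/s wavefront and
180 ms ARI from the noisy, quantized synthetic recording; the residual CHI
of 0.04 reflects the one-sample (0.04 ms) detection granularity plus noise.

The cohort side:

```r
co  <- generate_cohort(cohort_params(), seed = 42)
rep <- endpoint_report(co)
attr(map_trajectory_summary(co), "plateau_week")
```

```
  endpoint                       comparison            group mean_diff pct_change        p stars
1 map_mmhg              paired_within_group            angii     24.86      28.22 3.65e-07   ***
2 map_mmhg              paired_within_group          control      2.72       2.98 1.26e-01
3 map_mmhg unpaired_between_groups_followup angii vs control     18.93         NA 5.16e-05   ***
  angii control
      3       0
```

The treated group's MAP rises ~28% (significant), the control group does
not, and the plateau detector places the treated group's MAP plateau at
week 3 — the qualitative behavior of the emulated study.

## Command line

An executable `epimap` is installed under the package's `exec/` directory
(subcommands `simulate-recording`, `simulate-cohort`, `activation-map`,
`conduction`, `chi`, `ari`, `endpoints`, `run`), e.g.

```sh
Rscript -e 'epimapr::epimap_cli()' run --out out_dir --seed 3
```

Exit codes: 0 success, 2 usage/config error, 3 data/format error,
4 analysis error. All machine outputs embed the effective configuration
and seed; logs go to stderr only, and reruns with the same config + seed
are byte-identical.

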