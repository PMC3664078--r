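---
title: "Extrema-points analysis of beat-to-beat haemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extrema-points analysis of beat-to-beat haemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(extremabeat)
```

## The model

Continuous finger-cuff monitors report one record per heart beat: systolic
(SBP) and diastolic (DBP) blood pressure, heart rate (HR), stroke volume
(SV), and derived quantities — mean arterial pressure (MAP), cardiac output
(CO = SV × HR) and total peripheral resistance (TPR). Healthy circulation
holds perfusion pressure inside a narrow band by continually nudging it up
and down; each beat-indexed parameter therefore oscillates between local
peaks and troughs. The extrema-points model summarises a recording by those
turning points rather than by global dispersion:

1. **Detection.** A beat *n* is a local maximum when its value strictly
   exceeds both neighbouring beats, and a local minimum when strictly below
   both. Equality with either neighbour disqualifies the point, and the
   first and last beats (one neighbour each) never qualify.
2. **Intervals and frequencies.** For consecutive extrema (regardless of
   kind — peak→trough and trough→peak transitions both count) the elapsed
   time *t* between their beat timestamps gives a frequency *F* = 1/*t*
   in true Hz. Real timestamps are used, not beat counts, because beat
   spacing is irregular.
3. **Amplitudes.** The absolute value difference between consecutive
   extrema. The sign is recoverable from the extrema kinds; absolute values
   match how such tables are conventionally reported.
4. **Comparison.** The per-recording frequency and amplitude sequences of
   two subjects (or phases) are compared per parameter: Welch's t-test when
   both samples pass a normality check, the two-sided Mann-Whitney U
   otherwise, at α = 0.05, with no multiple-testing correction (each cell
   is reported as its own test). Correlations (e.g. extrema frequency vs
   heart rate) use Pearson for normal-looking inputs, Spearman otherwise.

MAP, when absent from an input file, is filled with the clinical estimate
MAP = DBP + (SBP − DBP)/3. The companion identity Q = ΔP/R
(`flow_variation()`) states the interpretive point of the model: high
pressure variation combined with low resistance variation implies high
variation in flow, assuming constant venous pressure.

## Numerical choices

* **Ties.** Neighbour comparisons are exact floating-point comparisons with
  no epsilon. A tolerance would silently change extrema counts; the cost is
  that quantised signals (values rounded to few digits) under-detect, which
  is documented rather than patched.
* **Endpoints and short series.** Fewer than 3 beats cannot contain an
  extremum; the detector warns and returns an empty set. Fewer than 2
  extrema yield empty interval/frequency/amplitude vectors, not errors, and
  comparison tables mark such cells "NC" (not computable) and continue.
* **Quantiles.** Quartiles use linear interpolation of order statistics
  (R's default type 7), one documented convention for reproducible IQRs.
* **Normality.** Shapiro–Wilk at α = 0.05 for 3 ≤ n ≤ 5000; Anderson–Darling
  beyond that (Shapiro–Wilk's implementation limit). Degenerate or tiny
  samples (n < 3) are treated as non-normal, which routes comparisons to the
  rank test.
* **Mann-Whitney p.** Exact U distribution when the combined n ≤ 10 with no
  ties; normal approximation with tie correction otherwise. At the
  thousands of extrema pairs a real recording produces, the approximation
  is the appropriate regime.
* **Independence caveat.** Consecutive extrema pairs from one recording are
  compared as if independent observations. No autocorrelation adjustment is
  applied; p-values on real recordings are anti-conservative to the extent
  that successive intervals are correlated. This mirrors how such
  single-subject comparisons are conventionally run and is a known
  limitation, not an oversight.

## The synthetic generator

No public beat-by-beat recordings accompany the model, so the package ships
a generator whose ground truth is analytic:

* **Beat times**: cumulative RR intervals drawn from a normal distribution
  (default mean 1.0 s, SD 0.05 s; profiles require mean > 3 × SD) truncated
  below at 0.25 s (a 240 bpm ceiling). Sub-threshold draws are redrawn,
  deterministically for a given seed.
* **Pressures**: baseline + slow sinusoidal oscillations + Gaussian noise.
  A `map`-targeted oscillation is common mode (added to SBP and DBP alike),
  an `sbp`/`dbp` oscillation shifts pulse pressure. Noise draws that would
  violate SBP > DBP are redrawn (bounded retries), so every emitted record
  satisfies the record invariants by construction.
* **Derived parameters**: MAP from the clinical formula, HR from the
  current RR interval, CO = SV × HR/1000. TPR is MAP/CO by default
  (self-consistent physiology); profiles with an explicit `tpr_baseline`
  instead oscillate TPR independently, which is how the
  resistance-variability dissociation between the two default subjects is
  emulated.

A sinusoid of frequency *f* and amplitude *A* has adjacent extrema half a
period apart, so the designed truth is an extrema frequency of 2*f* and an
amplitude of 2*A* — the generator exists precisely to make that truth
checkable.

**What beat sampling does to the 2f law.** The law holds in the
densely-sampled limit. At realistic beat rates it degrades in a specific,
geometric way: once the oscillation exceeds one third of the beat rate
(phase step > 120° per beat), the sampled sinusoid turns at nearly every
beat and the detector reports one extremum per beat — the measured median
frequency saturates near the beat rate rather than tracking 2*f*. With 1-s
beats, recovery is within ~8% at *f* = 0.2 Hz and ~15% at 0.3 Hz, but a
0.4 Hz design oscillation reads out near 1 Hz (≈22% from 2*f*) with
correspondingly clipped amplitudes. This is a property of strict
neighbour-comparison detection on discretely sampled signals, not of the
implementation; analyses of real recordings inherit it, which is worth
remembering when extrema frequencies approach the beat rate. Mild noise has
a second-order effect: it jitters which beat wins a turning point, wobbling
the quantised median interval by a percent or two before, at high
amplitude, spurious extrema dominate and the median frequency climbs
towards the beat rate.

**Default subject profiles.** `hd_profile()` and `nc_profile()` each return
a rest/stress pair. Durations mirror a realistic protocol: 1500 s
(dialysis-like subject) and 1800 s (control-like) at rest, 10800 s (a
three-hour session) under stress. Baseline pressures are 121/75 and
118/78 mmHg. The dialysis-like subject carries a fast common-mode pressure
oscillation (0.39 Hz rest, 0.38 Hz stress) with a low-amplitude independent
TPR oscillation (0.009–0.011 MU); the control-like subject a slow pressure
oscillation (0.17/0.20 Hz) with five times the stress TPR amplitude
(0.055 MU) — a designed contrast in the direction of impaired vs intact
resistance-mediated buffering. TPR baselines (~1 MU) are plausibility
choices: the device's "medical units" have no published scale, and only
within-file consistency matters for amplitude comparisons. RR means
(0.9/0.8 s) keep every design frequency below 0.45 × beat rate, the
resolvability bound profiles enforce.

These profiles emulate irregular beat times, slow oscillatory structure and
measurement noise. They do **not** emulate artefact beats, baroreflex
feedback, non-stationary drift, or intra-beat waveforms — so passing tests
demonstrate that the pipeline measures designed oscillatory structure
correctly, not that real recordings are this clean.

## Experiment sizes

Validation experiments are sized to be decisive yet quick: recovery
ensembles use 100 seeds of 30-minute recordings; the directional-contrast
ensemble uses 100 seeds of 1200-s recordings (≈900 extrema pairs per
recording, ample power for the designed effect); type-I calibration uses
2000 null comparisons at n = 50 per group. The acceptance script runs the
full default-duration pipeline once plus those ensembles in well under a
minute per block.

## Worked example

```{r example, eval = FALSE}
dir <- tempfile()
paths <- cmd_simulate(dir, seed = 42)          # 4 recordings + manifest
rep <- cmd_compare(paths[["hd_stress"]], paths[["nc_stress"]],
                   parameters = c("map", "tpr"))
rep$table[, c("parameter", "metric", "a_cell", "b_cell", "p_value")]
```

The comparison table mirrors the conventional layout: one frequency row and
one amplitude row per parameter, cells as "median (q1–q3)" to 3 significant
figures, with the raw per-pair values always available via
`metrics_table()` or the `_pairs.csv` companion written by `cmd_analyze()`.

## Known limitations

* Strict-inequality detection under-counts extrema on quantised signals and
  saturates near the beat rate (above).
* Extrema pairs are treated as independent in all tests (above).
* The generator's sinusoid-plus-noise form is a validation instrument, not
  a physiological model: no closed-loop baroreflex, no Windkessel
  waveforms.
* No artefact filtering precedes detection; input hygiene is limited to
  invariant-based row rejection in `read_beats()`.
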