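---
title: "Validating movement-related cortical potentials in a scanning speller: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating movement-related cortical potentials in a scanning speller: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mrcpspeller)
```

## The problem

A movement-related cortical potential (MRCP) is a slow negative EEG
deflection that begins roughly two seconds before a voluntary movement. Its
trace has a shallow early negative ramp (the Bereitschaftspotential, NS1), a
steeper late negative slope (NS2) ending at the peak negativity (PN), and a
positive rebound afterwards. Because the MRCP precedes movement and needs no
external flashing stimulus, it is a candidate control signal for
brain-computer-interface (BCI) spellers used by people who are losing
voluntary motor control.

`mrcpspeller` implements an offline feasibility analysis of exactly this
question for a scanning matrix speller: a selector bar sweeps the columns and
then the rows of a 6 x 6 character matrix; the user performs (or, in future
applications, imagines) a ballistic foot dorsiflexion when the bar reaches
the target column or row. Every column/row passage cues one potential MRCP,
and a 13-character phrase yields 26 cued trials. The pipeline decides, trial
by trial and with fixed formal criteria, whether an MRCP is present; the
fraction of validated trials is the *success rate*.

No public recordings of this paradigm exist, so the package ships a
first-class synthetic-data generator with known ground truth. Every stage of
the analysis is exercised end to end on simulated sessions, and the
generator's planted parameters let the tests measure recovery rather than
merely plausibility.

## The speller simulation

`speller_layout()` fills the 6 x 6 matrix row-major with A-Z, the digits
0-8, and a space in the final cell. The source interface's exact matrix is
not published; this layout is the natural choice that covers the three study
phrases (all letters plus the space).

`simulate_session()` models the selector kinematics as constant 2-s dwell
per cell with a 2-s pause after each selection, columns scanned left to
right and rows bottom to top (column first, then row). The cue (event) time
is the moment the bar *enters* the target column/row; the movement is
expected at the cell midpoint, one second later (`midpoint_offset_s`). A
`lead_in_s` of 5 s precedes the first sweep so that pre-cue epochs fit into
the recording.

**Trial reference time.** The published task description defines the cue as
bar entry but instructs the subject to move at the cell midpoint, while the
validation criteria require the PN and the EMG onset to fall within half a
second of the trial reference. These constraints are only jointly
satisfiable if the reference is the *expected movement time* (cue + midpoint
offset). The pipeline therefore anchors every epoch at `onset_s +
midpoint_offset_s`; the event tables on disk keep the raw bar-entry onsets.

## The synthetic data generator

The generator is the package's definition of the study conditions, not a
tuning knob.

* **MRCP template** (`mrcp_template_params()`): piecewise linear relative to
  the PN - flat until 2 s before the PN, NS1 slope -2 uV/s on [-2, -0.5] s,
  NS2 slope -10 uV/s on [-0.5, 0] s, rebound +8 uV/s back to baseline. The
  PN depth is *derived* from this geometry (-8 uV with the defaults): the
  triangle closes exactly, which is what makes exact slope recovery a
  meaningful test. Corners can be smoothed with a Hann kernel
  (`smoothing_s`, default 0.1 s); recovery tests use `smoothing_s = 0`.
  The published study reports no amplitude figures, so these are
  conventional MRCP magnitudes and fully configurable.
* **Spatial spread**: the planted waveform appears on Cz at gain 1, on the
  six flanking electrodes (FC1, FC2, C3, C4, CP1, CP2) at 0.5, and on the
  outer sites (FP1, Fz, Pz) at 0.25. This makes the large Laplacian act
  nontrivially: it attenuates the planted signal (by the ring-mean gain)
  without cancelling it.
* **Noise** (`noise_params()`): 1/f background with broadband SD 1.5 uV,
  5 uV of 50 Hz line, 10 uV of sub-0.05 Hz drift. The 1/f level was fixed by
  a design simulation before any acceptance test was written: it leaves
  about 1.4 uV of in-band (0.05-3 Hz) background, so the NS1-window slope
  noise SD is about 0.9 uV/s against a true slope of -2 uV/s and the planted
  criteria remain decidable in the large majority of trials. That keeps the
  planted success probability identifiable - the recovered success rate is
  an estimate of the planted probability, not of the noise level. Real
  single-trial EEG is usually noisier and rater-limited; passing these tests
  demonstrates correct recovery under clean-recording conditions, not
  human-level performance on arbitrary data.
* **EMG**: baseline Gaussian noise (SD 10 uV) multiplied by a gain of 10
  during a 2-s burst with a 50 ms raised-cosine onset ramp. The burst is
  *modulated baseline*, which is why "noise off" (`noise_params_off()`)
  keeps the EMG carrier: a silent channel would contain no movement at all.
* **Jitters**: the planted PN and EMG onset are jittered around the expected
  movement time with SDs of 0.15 s and 0.1 s, so the +/- 0.5 s timing
  criterion is satisfiable but not guaranteed.
* **Condition probabilities**: each trial carries an MRCP with probability
  0.67 / 0.67 / 0.63 for the control / phrase / random conditions - the
  study's own mean per-condition success rates.

## Preprocessing

Continuous EEG first passes a 2nd-order Butterworth band-stop at 48-52 Hz
(the 50 Hz notch; the source names the filter and order but not the
bandwidth, and +/- 2 Hz is the conventional choice), then a 2nd-order
Butterworth band-pass at 0.05-3 Hz. Both are applied zero-phase
(forward-backward `filtfilt`), which doubles the effective order and removes
group delay; the analysis is offline, so causality is not required, and
causal application remains available via `zero_phase = FALSE`. Note that the
0.05 Hz corner at 1,200 Hz puts filter poles very close to the unit circle:
linearity and round-trip identities hold to about 1e-7, not machine
precision, and the tests are written against that realistic tolerance.

Epochs are cut from 4 s before to 5 s after the trial reference (half-open
sample window, 10,800 samples at 1,200 Hz), demeaned per epoch, and the
large Laplacian for Cz is computed as `Cz - mean(Fz, C3, C4, Pz)` - the
next-nearest neighbors available in this 10-electrode montage. Both
processing paths (plain Cz and Laplacian Cz) run through the identical
downstream chain.

## EMG onset detection

The envelope is high-pass 20 Hz, full-wave rectification, low-pass 5 Hz (all
zero-phase), clamped at zero. The envelope is binarized at `baseline mean +
3 x baseline SD`; morphological closing then opening with a 50 ms
structuring element removes sub-threshold gaps and supra-threshold blips;
the onset is the first sample of the first supra-threshold run lasting at
least 1.5 s (the movement is sustained for about 2 s). The threshold is
baseline-relative, so the estimate is invariant to overall EMG gain.

Two paradigm-specific choices:

* the default baseline window is [-1.5, -0.5] s before the reference rather
  than an earlier interval, because consecutive selections can be only 4 s
  apart and the previous trial's burst would otherwise sit inside the
  baseline;
* candidate runs must begin after the baseline window - earlier bursts
  belong to the preceding selection.

The zero-phase envelope smearing biases detected onsets about 40 ms early at
the default burst gain; the acceptance budget for the median absolute error
is 50 ms over 500 synthetic bursts.

## Trial validation

`detect_pn()` marks the PN as the global minimum within [-2, +2] s of the
reference (earliest sample on ties). Trials are then re-aligned to their PN
(2 s before to 1.5 s after; 4,200 samples at 1,200 Hz), features are
extracted, and `evaluate_criteria()` applies the four rules:

1. PN and EMG onset both within +/- 0.5 s of the reference (missing EMG
   onset fails);
2. MRCP morphology: NS1 < 0, NS2 < 0, rebound > 0;
3. the PN is a strict local minimum within a 50 ms neighborhood (robust at
   single-sample granularity);
4. exclusion: a PN earlier than 1 s before the reference is rejected - a
   potential peaking that early cannot reflect the cued movement.

The published wording lists rule 4 with an ambiguous "or"; reading it as an
exclusion is the only interpretation that keeps the set coherent, and it is
the one implemented. The study validated trials manually through a GUI; this
module is the codified, deterministic replacement - a declared
methodological substitution, not a model of rater behavior.

The success rate is the number of validated trials as a rounded percentage
of the 26 trials per session, reported separately for the Cz and Laplacian
paths.

## Features

From each PN-aligned trial: PN amplitude (value at time 0), the three slopes
as ordinary least-squares fits over [-2, -0.5], [-0.5, 0] and [0, +1] s, and
the peak-to-peak amplitude over [-2, +2] s clipped to the aligned epoch's
real extent (+1.5 s; the nominal window cannot be covered on the rebound
side, and the clipping is deliberate and logged). The slope windows follow
the conventional MRCP partition (early BP / late negative slope / rebound);
the source figure shows them only graphically, so they are configurable.
Least squares rather than two-point differences: identical on perfect lines,
robust to residual noise otherwise. Subject-condition means over validated
trials feed the statistics.

## Statistics

* **Friedman omnibus** per feature over the subjects x conditions table of
  means, with mid-ranks and Conover's tie correction. For small tables
  (up to 5e5 within-subject arrangements) the p-value is exact by full
  enumeration; otherwise chi-square with k-1 degrees of freedom. The
  13 x 3 study table uses the asymptotic path.
* **Wilcoxon signed-rank post-hoc** for each condition pair when the
  omnibus p < 0.05, at the Bonferroni-adjusted threshold (0.05 / 3 =
  0.0167). Zero differences are dropped and counted; p-values are exact up
  to n = 25 via convolution over the rank generating function (ties
  handled exactly), normal approximation with tie and continuity correction
  beyond. The within-subject design calls for the signed-rank (paired)
  test, which is what is implemented.
* **Grand averages** per condition (pointwise mean +/- SD over trials or
  subject means).
* **Statistical map**: subject-condition mean traces (39 at full scale)
  enter a pointwise one-way repeated-measures ANOVA over time. The
  pointwise threshold is the parametric F quantile at alpha = 0.05; each
  supra-threshold cluster receives a p-value from the permutation
  distribution of the maximum cluster mass (sum of F - threshold) under
  within-subject relabelling of the conditions, with a seeded draw of 199
  permutations by default. This cluster-permutation correction is a
  documented substitute for random-field-theory thresholds, which are out
  of scope; it is exchangeable-valid, and the test suite verifies the
  family-wise error on 1,000 null simulations. A pooled (between-subject)
  F variant is available behind `variant = "pooled"`; repeated-measures is
  the default because the design is within-subject. Significant omnibus
  clusters trigger pointwise paired t curves per condition pair at the
  Bonferroni-adjusted alpha.

## Orchestration, formats, reproducibility

`run_study()` executes simulate - preprocess - detect - validate - features
- stats for every subject-condition recording and both processing paths,
writing tidy CSV tables (assessments, success rates long and wide, features,
subject-condition means, Friedman/post-hoc results, grand averages, the
statistical map and its input manifest, and a planted-versus-detected
report), a YAML config echo with a content hash, and a run log. All
randomness flows from the single master seed through named substreams, so a
rerun is file-for-file identical (the log's timestamp aside).

Continuous signals interchange as EDF (a minimal 16-bit codec written for
this package, since no R EDF reader is available in the target environment;
round trips are exact for labels and rate and within one quantization step
for samples). Events are CSV, ground truth is JSON. When `write_raw = TRUE`,
`run_study()` processes the data it just wrote back from disk, so the
file-based stage functions (`stage_simulate()` through `stage_stats()`,
which the `inst/cli/mrcpspeller` wrapper dispatches to) reproduce the
orchestrated run exactly - the EDF quantization is applied exactly once on
either route.

## Problem sizes used in the checks

The test suite runs the full design - 13 subjects x 3 conditions x 26
trials at 1,200 Hz - once, end to end, and verifies the 39-trace manifest
and the recovery of the planted per-condition success probabilities. The
remaining properties are checked at the smallest sizes that still prove
them: exact-test oracles at n <= 6 (where full enumeration is feasible),
EMG onset recovery over 500 isolated bursts, permutation calibration on
1,000 null simulations of an 8 x 3 x 40 design, and pipeline determinism on
a 2-subject cohort at 600 Hz.

## Known limitations

* The generator's background is stationary 1/f + line + drift; it contains
  no blinks, no movement artifacts, no electrode drift-steps, and no
  between-subject amplitude variability. Passing recovery tests therefore
  bounds algorithmic correctness, not field performance.
* The published study's subject-level tables come from unreleased human
  recordings and manual validation; they are not reproducible from
  synthetic data, and the package does not attempt to match them
  numerically - it reproduces the structural and arithmetic facts and the
  method's behavior under known ground truth.
* The EDF codec writes one fixed layout (uniform rate, 1-s records,
  microvolt units) and is not a general EDF+ implementation.
* Cluster p-values are permutation-based; with 199 permutations the
  smallest attainable p is 1/200, which is adequate at alpha 0.05 but not
  for stricter thresholds - raise `spm_n_perm` if needed.
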