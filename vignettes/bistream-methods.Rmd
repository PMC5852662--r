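---
title: "Linking percept reports to triplet-locked neural responses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking percept reports to triplet-locked neural responses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Repeating HLH- tone triplets (high, low, high, silence; 100 ms tones, 50 ms
gaps within a triplet, 200 ms between triplets, so one triplet every
600 ms) are perceptually bistable: listeners hear them either as one
integrated galloping stream or as two segregated streams, and perception
alternates spontaneously every few seconds after a longer initial
integrated phase. The question this package's pipeline addresses is whether
listeners can *intentionally* steer that organization, and — because button
presses alone could reflect response bias rather than perception — whether
stimulus-locked neural activity in auditory cortex backs up what they
report.

The pipeline has four statistical stages over (simulated) continuous
percept reports and source-level neural waveforms:

1. **Behavior.** Report streams are segmented into initial-integrated,
   subsequent-integrated, and segregated phases. Percentages of time
   reporting segregation are analyzed on the logit scale, phase durations
   on the log scale (means are formed on the transformed scale and
   back-transformed for reporting), with delta-f-by-task repeated-measures
   ANOVAs (Huynh-Feldt-corrected degrees of freedom) and paired t tests.
2. **Univariate neural.** 600 ms triplet-locked epochs, guarded against
   button presses, are averaged per percept (delta-f cells equally
   weighted), and segregated-vs-integrated differences are assessed with a
   cluster-based permutation test plus a window test on the 216-288 ms
   post-triplet-onset mean (66-138 ms after the L tone).
3. **Decoding.** Per participant and delta-f, 5-fold x 100-repeat balanced
   linear SVMs (C = 1) classify single neutral epochs by percept from the
   150 time-point features; weights are Haufe-corrected into activation
   patterns; the trained ensembles classify all epochs from the intention
   conditions.
4. **Bias checks.** Two expected-vs-observed comparisons ask whether the
   neural effects of intention are exactly as large as accurate reporting
   predicts: report-weighted mixtures of the neutral percept means
   (univariate) and accuracy-adjusted report differences (decoding).

## What the generator emulates

`simulate_participant()` draws, per participant, a percept process and a
neural response template, then renders each scheduled sequence:

* **Session structure.** Blocks of five 150 s sequences (250 triplets):
  two neutral (never consecutive), one attempt-integration, one
  attend-high, one attend-low; delta-f alternates between 4 and 6
  semitones from sequence to sequence; the within-block order is reversed
  for the second half of the session. Four blocks give 5000 triplets per
  session.
* **Percept dynamics.** Phase durations are log-normal — the analysis
  log-transforms durations, which presumes approximate log-normality — with
  class- and delta-f-specific log-means and a common `sigma_log = 0.6`.
  Defaults (in seconds, geometric means): initial integrated 15 / 10,
  subsequent integrated 7.5 / 5.4, segregated 5.4 / 7.5 for delta-f 4 / 6.
  These values were chosen once so that (a) larger delta-f yields more
  segregation through shorter integrated and longer segregated phases,
  (b) the press-guard exclusion retains a median near 58% of epochs, and
  (c) intention multipliers of 1.35 (attempt integration) and 1.75
  (attempt segregation, either attended frequency) move the mean reported
  difference between attempt-segregation and attempt-integration to about
  36 percentage points, with the shift toward segregation larger than the
  shift toward integration. A per-participant segregation bias
  (log-scale SD 0.35) lengthens one percept's phases at the expense of the
  other's.
* **Reports.** A press marks each phase transition; the first percept is
  reported 2 s after sequence start. Epochs before the first report are
  labeled integrated downstream.
* **Evoked waveforms.** Each tone evokes a gamma-shaped deflection
  (shape 3, peak 55 ms post tone onset; amplitudes 1 / 0.85 / 0.7
  mimicking adaptation). During segregated phases a raised-cosine
  positivity confined to 216-288 ms post triplet onset is added with peak
  amplitude 0.15 source units. Noise is an equal-variance mixture of white
  and 1/f Gaussian noise with total SD 1 at the 1000 Hz synthesis rate.
* **Between-participant structure.** A common latency shift (SD 5 ms); an
  overall response gain, log-uniform with half-width 1.3 (gains roughly
  0.27-3.7), representing the wide spread of reconstructed source
  amplitudes across heads and dipole fits; an effect gain
  `|1 + N(0, 0.25)|` with a 15% probability of a global sign flip,
  modeling individuals whose percept signature opposes the group
  direction.

**Calibration.** The effect amplitude and noise SD were fixed together so
that a full-session participant's neutral decoding accuracy is near 53%
(measured: 53.3% at 4 blocks x 250 triplets), and the amplitude-gain
spread so that the group window effect size in the average-variance
convention (`d_av`, mean difference divided by the mean of the two
condition SDs) is near 0.32 while the difference-standardized `d_z`
remains near 0.9. The two conventions diverge strongly here by design:
the percept effect is small but consistent within participants, while
overall response amplitudes vary widely between participants. Reported
pairs of t and d values for within-participant contrasts are only jointly
coherent under the average-variance convention, which is why
`paired_t_with_d()` returns both (`d` is `d_z`, with a noncentral-t CI;
`d_av` is provided whenever the condition vectors are available).

**What the generator does not emulate.** Sensor-space fields, head
movement, eye/cardiac artifacts, line noise, SQUID jumps, or any
channel-level structure: the simulation starts where source
reconstruction ends, as a single source waveform per participant. There is
no audio rendering, no attention-related modulation of single-tone
responses outside the percept effect, and no latency drift within a
session. Passing tests therefore certify the statistical machinery —
filtering, epoching, labeling, permutation inference, decoding, bias
logic — under the assumed generative structure, not robustness to the
artifact content of real recordings.

## Preprocessing choices

Filters are linear-phase windowed-sinc FIRs specified by their -6 dB
cutoff and transition bandwidth (low-pass 30 Hz / 6.667 Hz transition;
high-pass 0.278 Hz / 0.556 Hz transition). The window is Hamming — the
conventional default where none is named — giving kernel length
`ceil(3.3 / normalized transition bandwidth)`, rounded up to odd.
Filtering is zero-phase with reflect padding at the edges. Downsampling to
250 Hz is integer decimation after the 30 Hz low-pass (which already
prevents aliasing); the high-pass is applied at the decimated rate, where
its ~1500-tap kernel is cheaper — linear filters commute, and a test
verifies the commutation on band-limited inputs. The 0.278 Hz high-pass
matches the 3.6 s minimum interval between retained epochs of different
percepts implied by the 1.5 s press guard.

Epochs start at triplet onsets (rounded to the nearest sample at 250 Hz;
the grid aligns exactly since 0.6 s x 250 Hz = 150 samples), span the
half-open window [onset, onset + 0.6 s), and receive no baseline
correction: the repeating stimulus leaves no silent baseline, and because
guarded epochs only neighbor epochs of the same reported percept,
carry-over is percept-pure and epoch time can be treated as circular. The
guard uses the strict reading of "< 1500 ms": an epoch is retained only if
it keeps at least the guard distance from every press and sequence
boundary. An epoch whose onset coincided exactly with a press would be
excluded by the guard regardless, so the label attribution of that instant
is moot.

## Statistical choices

* **Cluster test.** Cluster-defining statistic: mass (sum of pointwise
  paired t within a maximal suprathreshold run), two-sided thresholding at
  the alpha = 0.05 critical t with positive and negative clusters tracked
  separately; the null is the distribution of the maximum absolute cluster
  mass under within-participant sign flips of the difference waves (the
  standard family-wise-error-controlling max-statistic reading), with the
  observed statistic included, so the smallest attainable p is
  `1/(n_perm + 1)`. Ties between null and observed masses are counted with
  a small relative tolerance so the p-value is invariant to waveform
  rescaling.
* **Window test.** Samples with latency `216 <= t <= 288` ms inclusive on
  the 4 ms grid (19 samples).
* **Decoding.** Per repeat, the larger class is subsampled without
  replacement to the smaller class's size; folds are class-stratified;
  feature standardization is fit on training folds only and reused for
  test and cross-condition epochs (fold-internal fitting is the
  leakage-safe reading; a whole-set mode was considered and rejected
  because it lets test-fold statistics leak into training). Decision
  values are oriented so positive means segregated. Vote aggregation is
  the mean over models of per-model segregated percentages. Haufe
  patterns use Ledoit-Wolf-shrunk covariances of the standardized training
  folds (guaranteeing well-conditioned estimates on small subsamples) and
  are normalized to unit Euclidean norm per participant before group
  averaging.
* **Effect-size CIs.** Cohen's d CI by noncentral-t pivot inversion;
  partial eta squared CI by participant bootstrap (default 2000
  resamples).
* **Bias tests.** The expected-vs-observed comparisons weight the neutral
  percept means by *percentages of reported percept measured on the
  retained epochs themselves* (`epoch_label_percentages()`), not by the
  behavioral first-press-to-end percentages. The two timebases differ
  systematically: perceptual phases shorter than the 3.6 s guarded span
  contribute report time but no retained epochs, and pre-first-report time
  is epoch-labeled integrated but excluded from behavioral denominators.
  Weighting by the epoched composition makes "accurate reporting" imply
  exact equality of expected and observed values in expectation, so the
  test isolates response bias; with behavioral weights
  (`bias_weights = "behavioral"`, available for comparison) the null is
  systematically violated at realistic switch rates even for a perfectly
  accurate reporter. The decoding-side adjustment multiplies reported
  percentages by `(accuracy - 50) / 50` using each participant's delta-f
  averaged accuracy, the granularity at which performance is assessed.
* **Biased-reporter model.** With `report_bias` set, non-neutral sequences
  carry two independent phase streams: the percept driving the neural
  signal keeps neutral dynamics, while the presses follow the intention
  multipliers raised to the given exponent — a reporter who complies with
  instructions on paper only. Exponent 2-3 corresponds to near-complete
  claimed compliance.

## Problem sizes in tests and calibration experiments

The full study conditions (23 analyzed participants, 4 blocks x 5
sequences x 250 triplets, 100 decoding repeats) are the package defaults,
and behavioral analyses run at that scale (they need no waveforms). The
waveform-based calibration experiments use reduced sizes chosen as the
smallest that preserve the effect structure:

* Null cluster calibration: 200 cohorts of 12 participants, one
  100-triplet sequence each, 100 permutations.
* Calibrated-effect detection: 25 cohorts of 23 participants at full
  session length (4 blocks), 200 permutations. Detection is limited mainly
  by between-participant template variability — cohorts that draw many
  sign-flipped individuals have genuinely attenuated group effects — with
  per-participant estimation noise a secondary factor, so halving the
  session (as the cheaper exploratory default of
  `calibrated_cluster_runs()` does) costs only a few points of detection
  rate.
* Decoder nulls: 20 participants, 2 blocks of 100-triplet sequences.
* Bias-test self-consistency: 12 participants, 2 blocks of 200-triplet
  sequences, 2 decoding repeats. At this reduced scale the SVM learning
  curve keeps neutral accuracy near 51%, which collapses the
  `(accuracy - 50)/50` adjustment and with it any possible bias signal —
  a power property of the test itself, not of the reporter. The
  demonstration cohorts therefore use a stronger percept-effect amplitude
  (0.35, accuracy ~58% at this scale), restoring the sensitivity
  relationship that holds at full scale with the calibrated amplitude,
  and omit sign-reversed individuals: a flipped participant's percept
  signature contributes an *opposing* expected value, capping the
  univariate bias test's group-level effect size at the cohort's sign
  consistency — the same dilution that motivates the per-participant
  decoder. The accurate-reporter arm uses the identical configuration,
  so its null behavior is directly comparable. The test's logic — bias
  appears as expected exceeding observed — depends on neither choice.

## Known limitations

* The generator's percept process is memoryless across phases
  (independent log-normal draws); real phase durations show serial
  dependencies.
* The segregation signature is a single fixed-latency component per
  participant; real percept signatures can involve multiple components
  with participant-specific timing, which the decoder would exploit but
  the univariate window test would miss.
* Phase-duration parameters are calibrated to qualitative orderings and
  aggregate statistics (retention, report differences), not to
  numerically reported per-condition means, which are not available in
  machine-readable form.
* The cluster-detection rate of the calibrated effect is limited by the
  sign-flip rate: cohorts that draw many sign-flipped individuals have a
  genuinely attenuated group effect, and no amount of data per participant
  recovers it. This mirrors the motivation for the per-participant
  decoding analysis, which is insensitive to the group-level sign.
* Pooling across recording settings, hemisphere-specific analyses, and
  artifact-robustness are out of scope; the pipeline begins at clean
  source waveforms.
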