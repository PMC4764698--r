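---
title: "Simulating and analyzing beat-omission oddball ERP studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing beat-omission oddball ERP studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oddbeat)
```

## The paradigm

A two-measure rock drum pattern (hi-hat on all eight isochronous positions,
bass drum and snare on alternating strong positions, 150 ms onset-to-onset)
loops continuously. Occasionally the bass-drum and hi-hat sounds at position
1 — the metrically strongest event — are silenced. In listeners with a sense
of beat, this *deviant omission* violates a temporal expectation and evokes
a characteristic cascade in the EEG difference wave (deviant minus
standard): a frontocentral **mismatch negativity** (MMN, negative,
~100–250 ms), a frontocentral **P3a**, and, when the listener actively
detects omissions, a posterior **P3b**. Comparing a single atypical
listener, such as a beat-deaf individual, against a small control cohort on
these components and on detection accuracy requires single-case statistics;
this package implements the complete chain, with a synthetic-cohort
generator standing in for raw EEG, which is not publicly available for this
paradigm.

Two tasks are modeled:

* **ignore**: 10 blocks × 300 sequences, exactly 5% deviants, at least
  three standard sequences between deviants (enforced also across block
  boundaries, since presentation is gapless), presented while the subject
  ignores the sounds. A deviant-only control block
  (`make_control_schedule()`) verifies that omission responses require
  rarity; the generator injects no deviance components there.
* **attend**: 120 trials of five sequences; 60 trials carry one deviant in
  slot 4 or 5 (uniform), the first three sequences are always standard. The
  subject reports after each trial whether it contained an irregularity;
  keypresses within 6 s count.

## The generative model

`simulate_recording()` produces, per subject and task,

$$x_c(t) \;=\; \sum_k w_c^{(k)}\, \frac{A_k}{g(\sigma_k)}
\exp\!\Big(\!-\tfrac{(t - t_k^{dev} - \ell_k)^2}{2\sigma_k^2}\Big)
\;+\; b\,w_c^{blink}\sum_j \phi_j(t) \;+\; \eta_c(t),$$

i.e. Gaussian component kernels at each deviant target, blink artifacts,
and independent $1/f$ background noise per channel.

* **Kernels.** Each component is a Gaussian bump with peak amplitude $A_k$
  (µV, signed), latency $\ell_k$ (ms) and SD $\sigma_k$. Gaussians are
  smooth, analytically integrable (closed-form window means make exact
  oracles possible) and match the morphology of the empirical deflections.
  Default widths: MMN 30 ms, P3a 60 ms, P3b 80 ms — narrow enough that the
  MMN is a crisp deflection, broad enough that the P3 family spans its
  typical few-hundred-ms extent.
* **Amplitude calibration.** Published component amplitudes are
  *measurements*: ROI-averaged 40-ms window means of 0.5–25 Hz filtered,
  baseline-corrected data. That measurement chain has gain well below one
  on smooth kernels (the window averages over the flanks; the 0.5 Hz
  highpass removes the kernel's net area — `pipeline_gain()` is 0.79–0.86
  for SDs of 20–80 ms), and the highpass rebound of one component leaks
  into its neighbors' windows. The generator therefore defines a
  component's `amplitude` on the measurement scale: for each topography
  group it solves the small linear system `G peaks = amplitudes`, where
  `G[i, j]` is the filtered, baseline-corrected response of a unit kernel
  `j` inside component `i`'s window, and injects the solved peaks. A
  noiseless subject run through the full pipeline then reads back the
  configured amplitudes to better than 1%. `calibrate = FALSE` disables
  this for arithmetic tests on unfiltered data.
* **Topography.** Anterior components peak at FCz, the P3b at Pz, with a
  falloff over neighboring sites. Each map is normalized so the mean weight
  over its own ROI's four electrodes is exactly 1 — the amplitude parameter
  is then on the same ROI-average scale as reported group means. Cross-ROI
  leakage is set to zero: an idealization (real scalp fields overlap) that
  makes each ROI measure only its own components, which is what a
  parameter-recovery instrument needs.
* **Noise.** Independent per-channel Gaussian noise with power ∝ $1/f$
  above 0.5 Hz, default RMS 10 µV — a realistic broadband EEG magnitude.
  This value was calibrated once so that (i) cohort-level parameter
  recovery succeeds (grand means within ±0.5 µV / ±15 ms), and (ii)
  attend-task baseline CI half-widths land near 0.1 µV, the order of
  magnitude of published per-subject noise CIs (±0.20 µV). The generator
  does not model alpha rhythms, line noise, or drifts beyond $1/f$.
* **Blinks.** Poisson events at 3/min, 150 µV Gaussian transients (SD
  50 ms) on the vertical EOG, attenuated to 40% on prefrontal sites. At
  these defaults ≥95% of epochs survive the 75 µV rejection criterion by
  construction, leaving retained deviant-epoch counts on the order of the
  ~114 per subject reported for real recordings.
* **Behavior.** One keypress per trial: "deviant" with probability
  `p_hit` on deviant trials and `p_fa` on standard trials; RT ~ N(1.5 s,
  0.5 s) truncated at zero. Behavior and EEG noise are independent by
  construction, so cohort-level behavior–ERP correlations are null.

Built-in profiles fix the components at the published control-group means
(MMN −2.81 µV @ 159 ms; ignore P3a +1.10 µV @ 297 ms; attend P3a +3.24 µV @
496 ms; P3b +2.90 µV @ 506 ms) and the two case phenotypes: `case_m`
(larger MMN, absent attend P3b, hits 0.57/FA 0.16) and `case_j` (enlarged
ignore P3a +3.11 µV and attend P3b +6.74 µV, conservative responding: hits
0.36/FA 0.03). Controls are homogeneous — every control shares the group
means, so between-subject spread reflects measurement noise only. Real
cohorts vary biologically; consequently, simulated Crawford t values for
the cases are systematically larger in magnitude than published ones, which
is expected and not a target.

A single master seed is split arithmetically into per-subject, per-task,
per-purpose substreams: subjects are independent yet the whole study is
bit-reproducible.

## The analysis pipeline

The preprocessing chain mirrors standard ERP practice for this paradigm:

1. nose re-reference (`rereference()`, a no-op on synthetic data, which is
   generated in the analysis reference);
2. zero-phase 4th-order Butterworth bandpass, 0.5–25 Hz (`bandpass()`;
   the band is conventional, the realization — order, forward–backward
   application — is our choice; hour-scale recordings take an equivalent
   frequency-domain pass, the spectrum multiplied by the squared
   Butterworth magnitude response);
3. epoching around position-1 target onsets: −100..500 ms (ignore),
   −100..900 ms (attend), inclusive endpoints rounded to the nearest
   sample (615/1025 samples at 1024 Hz); epochs that would cross the
   recording edge are dropped and counted;
4. artifact rejection: an epoch is rejected iff any channel's peak-to-peak
   range within any 500-ms sliding window (step one sample, the most
   conservative choice) strictly exceeds 75 µV — "amplitude change" is
   read as peak-to-peak range, and an excursion of exactly 75 µV is
   retained;
5. per-epoch baseline correction over −100..0 ms;
6. selective averaging (`average_condition()`): all retained epochs per
   condition; in the attend task, only trials answered correctly within
   6 s. (Published analyses averaged a subset of ~650 standard epochs per
   subject in the passive task without stating the selection; we average
   all ~2850 retained standard targets, which only tightens the standard
   estimate.)

Quantification operates on ROI-averaged difference waves (anterior AFz,
Fz, FCz, Cz; posterior CPz, Pz, POz, Oz): peak latency within a component
search window (MMN 100–250 ms negative; P3a 250–600 ms positive, capped at
450 ms in the short passive epoch so the 40-ms window fits; P3b 300–800 ms
positive — windows chosen to bracket all published peak latencies,
137–542 ms), then the mean over a 40-ms window. Group mode centers the
window on the control grand-average peak (as done for control groups);
individual mode on the subject's own peak (as done for single cases, to
avoid underestimating their amplitudes). Peak ties break toward the
earlier latency; window endpoints are inclusive; a window truncated by the
epoch edge is an error, never a silent clip.

## The reliability verdict: a deliberate design choice

A component is reported *reliable* when its window mean exceeds a 95%
noise CI. Two CI estimators are implemented:

* `ci_method = "baseline"` — the classical estimate: a Student-t CI of the
  mean over the ~103 baseline samples of the subject's difference wave
  (`baseline_noise_ci()`), half-width $t_{.975}\,s/\sqrt{n}$. This is the
  quantity whose published half-widths are ±0.2 µV, and it is always
  reported (`ci_baseline`).
* `ci_method = "epochs"` (default for the verdict) — a Welch 95% CI of the
  deviant-minus-standard window mean across retained epochs.

The default is the epoch-level CI, and the reason is quantitative, not
stylistic. On stationary synthetic noise, the baseline-sample CI is about
$0.19\,s$ while a 40-ms window mean of the *same* averaged noise
fluctuates at roughly $0.8{-}1.3\,s$ (and is biased upward when the window
is centered on a data-driven peak). The comparison is scale-free: a
zero-amplitude component would be declared "reliable" ~96% of the time at
any noise level. The baseline-sample CI can behave sensibly on real data —
where baseline variance also carries residual evoked context, inflating
$s$ — but on this generator it cannot reproduce the defining phenotype of
an absent P3b. The epoch-level CI measures the actual trial-sampling error
of the quantified amplitude and stays calibrated under peak-centering. It
is an honest per-subject test, not a certainty, on either side: centering
an absent component's window on the noise peak inflates the measured
amplitude, so a pure-noise P3b is still flagged "reliable" in roughly a
fifth of simulated subjects; conversely, at the attend task's epoch counts
(~43 retained deviants, ~100 standards; amplitude SE ≈ 0.8 µV) a genuine
2.9 µV P3b passes with probability ≈ 0.95 per subject, so in a 10-subject
cohort one marginal control occasionally fails the check. In the passive
task (≈ 145/2850 epochs) the same components pass essentially always.

## Inference

* `crawford_t()` — the modified t for one case against n controls,
  $t=(x-\bar c)/(s_c\sqrt{(n+1)/n})$, df $=n-1$; one-tailed by default in
  the direction of poorer case performance (lower hits/A/P3 amplitudes,
  higher false alarms/bias; latencies two-tailed). The reported sign is
  always that of case − control mean; published tables are not fully
  consistent in sign conventions, and those signs are not reproduced. No
  multiple-testing correction is applied, matching field practice; a
  Bonferroni adjustment can be applied to the returned p values by the
  user.
* `loo_control_analysis()` — each control against the remaining n−1
  (df = n−2), flagged two-tailed at α = 0.05. On exchangeable controls
  each subject is flagged with probability α by construction, so "no
  control flagged" events have probability ≈ 0.95^n per measure.
* `rm_anova_2level()` — the deviant-vs-standard repeated-measures ANOVA,
  df (1, n−1); for two levels F = t² of the paired t, which the tests use
  as an independent oracle.
* `sensitivity_A()` / `bias_b()` — the Zhang–Mueller distribution-free
  measures, adopted because the source cites them without printing
  formulas; the piecewise forms here reproduce all four published case
  values at 2 dp from the published hit/false-alarm rates. Below-chance
  operating points use the reflection symmetries A(H,F) = 1 − A(F,H),
  b(H,F) = 1/b(F,H); cohort-level A and b are averages of per-subject
  values (the published control b of 1.16 is inconsistent with b computed
  from mean rates, confirming per-subject averaging). At H = F both
  formulas are taken at their defined limits (A = 0.5, b = 1), including
  the degenerate corners H = F = 0 and 1.

## Problem sizes and determinism

`run_study()` executes the full design above — 12 subjects × (3600 s
ignore + 720 s attend) at 1024 Hz on an 18-channel montage (the midline
sites of both ROIs, representative lateral sites, prefrontals, and both
EOGs; channels outside these carry no information in this generative
model) — in roughly ten minutes on one core, and is deterministic given
its seed. The desk-scale configurations used in the unit tests shrink
block counts and trial numbers, not the sampling rate or epoch geometry.

## What passing tests do and do not show

The generator produces exactly the structure the pipeline assumes:
Gaussian components at known latencies, stationary 1/f noise, stereotyped
blinks, one response per trial. Parameter recovery therefore validates the
*pipeline arithmetic* (filtering, epoching, rejection, averaging,
quantification, statistics), not the model's adequacy for real EEG — real
data add overlapping evoked context, non-stationary noise, alpha
intrusions, drifting electrodes and response slips, none of which are
modeled. Published statistics that depend on the actual recordings (case t
values, epoch counts, grand-average waveforms) are accordingly *not*
reproduction targets; the worked examples that are reproducible from
printed numbers (sensitivity/bias values, Crawford consistency, design
counts) are asserted exactly, and everything else is covered by
property-based tests with analytic oracles.
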