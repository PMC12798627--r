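---
title: "Methods: signal cleaning, feature extraction and statistics in physiopipe"
author: "physiopipe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal cleaning, feature extraction and statistics in physiopipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physiopipe)
```

# Scope

physiopipe processes one-participant multimodal physiological sessions —
ECG, electrodermal activity (EDA), EMG and respiration — recorded around a
10-minute experiential phase, and extracts the windowed dependent
variables used in within/between-subject designs: five 2-minute breath
rates, ten 1-minute heart rates, five 2-minute tonic EDA means, and the
LF/HF heart-rate-variability ratio for the first and last 5 minutes. A
statistical layer supplies Wilcoxon signed-rank and Mann-Whitney U tests
with rank-biserial effect sizes, Benjamini-Hochberg and Holm corrections,
and a mixed repeated-measures ANOVA with Mauchly sphericity testing,
Greenhouse-Geisser correction and generalized eta-squared. A seeded
synthetic-session generator with full ground truth makes every stage
testable end to end.

All windowing is computed on time rebased so that the `experience_start`
marker is t = 0 (`trim_to_experience()`); sessions are assumed analyzed
strictly within the marker window, with no use of pre-experience baseline
samples.

# ECG

Cleaning (`clean_ecg()`) notches powerline interference at 60 Hz
(second-order IIR, quality factor 30) and bandpasses 0.5-45 Hz with a
4th-order Butterworth prototype. Both filters run forward-backward, so the
effective bandpass order is 8 and no phase distortion is introduced —
R-peak timing is preserved by construction, which the tests verify via a
zero cross-correlation lag. Samples whose *filtered* absolute amplitude
exceeds 1500 device units are masked and linearly interpolated rather than
deleted, preserving the uniform grid that all later windowing assumes; a
channel with more than half its samples masked is unacceptable. Note that
because the gate applies after filtering, a one-sample raw excursion is
smeared by the bandpass and must be several times the threshold to
trigger masking; genuine saturation episodes (many samples) gate as
expected.

Baseline wandering (`assess_ecg_acceptability()`) is measured as the
peak-to-peak amplitude of a 0.5 Hz zero-phase low-pass of the sanitized
signal — a low-frequency artifact must be measured on the low-frequency
baseline estimate, not on the raw trace, where QRS amplitude would
dominate the peak-to-peak. The channel is unacceptable above 1700 device
units; a drift sinusoid crosses the rule exactly at amplitude 850.

R peaks (`detect_r_peaks()`) come from a smoothed squared-derivative
energy with a blockwise (2 s) adaptive threshold at half the local
maximum, a 250 ms refractory rule, and removal of the smaller peak in any
physiologically impossible RR interval (< 0.25 s). On simulated sessions
(sharp biphasic template, amplitude 800, noise SD 20) recovery is exact to
a few milliseconds. Per-minute heart rate is 60 over the mean RR interval
whose midpoint falls in the window; windows with fewer than two usable
intervals are missing, and a final partial window shorter than 30 s is
dropped.

# EDA and EMG

Motion artifacts are detected on the EMG (`detect_motion_windows()`): the
signal is globally z-scored, each sample is embedded as a 2-D point
(value, first difference) — scalar LOF misses fast transients of equal
amplitude — and scored with an exact k-nearest-neighbor Local Outlier
Factor (k = 20, outlier when LOF > 1.5). Scores are computed against a
fixed, evenly spaced 400-point reference sample of the whole recording.
This reference is the one methodological subtlety worth spelling out: LOF
is scale-free, so a window computed purely on its own samples cannot flag
a sustained amplitude burst that fills it (an amplified Gaussian looks
locally identical to a quiet one). Scoring against the global reference
keeps "outliers within each window" semantics while making bursts of any
duration outlying. Sliding 4 s windows with 2 s stride are flagged when
more than 10% of their samples are outliers; flagged windows merge into
disjoint intervals. On burst-free simulations under 5% of windows flag;
injected 10x bursts are covered completely.

Cleaning (`clean_eda()`) applies an 8 s median filter, a 5 Hz zero-phase
low-pass (order 4; skipped with a note when the sampling rate cannot
support it), then linear interpolation across the flagged intervals from
the nearest clean boundary samples (edge windows extend the nearest clean
value). Coverage beyond 50% of the channel is unacceptable. The quality
index (`eda_quality_index()`) counts a sample as violating when it lies
outside 0.05-60 microsiemens or when the absolute change between it and
any sample within one second exceeds 10 microsiemens per second of lag
(a symmetric, grid-robust reading of a rate limit "within a 1-second
interval"); qi = 100 (1 - violating fraction), rejected below 50, and the
linear mapping is the simplest one consistent with a 0-100 index. The
order of operations is fixed as clean, then quality, then tonic. The tonic
component is a 0.05 Hz zero-phase low-pass — a conventional tonic/phasic
boundary, exposed in `eda_params()` — averaged over non-overlapping
2-minute windows (a final partial window needs at least 60 s).

# Respiration

`smooth_respiration()` high-passes at 0.1 Hz (order 2, zero-phase) to
remove drift, resamples to a fixed 100 Hz grid, estimates the breathing
period in sliding windows by FFT, smooths with a period-guided moving
average, returns to the original rate and normalizes to unit SD. Several
numerical choices here were forced by the slow-pacing regime and deserve
explanation:

* **Estimation window 45 s, stride 15 s, search band 0.05-1 Hz.** The
  window must hold at least two full 19 s paced cycles (inhale 4 s, hold
  7 s, exhale 8 s; about 3.16 breaths/min); anything shorter cannot
  resolve the fundamental at 0.053 Hz at all.
* **High-pass compensation in the period estimator.** The 0.1 Hz drift
  filter passes only about 7% of a 0.053 Hz fundamental (zero-phase gain
  $1/(1+(f_c/f)^4)$) while passing its second harmonic largely intact, so
  the raw FFT peak of paced breathing is an octave error. The estimator
  divides the window spectrum by the known filter response before peak
  picking (plus Hann taper, 4x zero padding, parabolic peak refinement
  and a subharmonic check).
* **Half-period smoothing kernel.** A moving average of length half the
  local period nulls all even harmonics of the cycle exactly while
  keeping the fundamental (attenuated by sinc(1/2) = 0.64). The
  high-passed paced waveform is bimodal — its suppressed fundamental
  rides under strong harmonics — and a shorter kernel retains the second
  bump as a false breath.
* **Per-sample period from the nearest estimation window.** Each sample
  takes the period of the window whose center is nearest, so at a rate
  transition (the 60 s free-breathing lead-in into pacing) the kernel
  switches essentially at the transition itself instead of blending the
  slow-regime kernel back over the last fast cycles and erasing them.

Breath onsets (`detect_breath_onsets()`) are the crossings between the
smoothed signal and its moving mean over one local period: upward
crossings are inhalation onsets, downward ones exhalation onsets.
Alternation is repaired by dropping the earlier of two same-type onsets;
breaths are inhalation, exhalation, next inhalation; breaths below the
0.25 peak-to-trough amplitude threshold (in unit-SD normalized units; the
threshold is dimensionless by construction and exposed in config) are
deleted with their onsets. Three robustness rules follow: crossings whose
inhale-to-exhale span is under a tenth of the local period are discarded
(mean-crossing wiggles can borrow the genuine trough of the surrounding
cycle and look large); two inhalations closer than half the smaller of
their local periods merge (residual harmonics can split one slow cycle);
and a trailing inhalation whose peak is reached — or whose upstroke has
decayed to under a quarter of its maximum slope — before the record ends
is completed into a breath, since its downward crossing lies beyond the
recording while the zero-phase peak does not. Finally, onset times are
refined from the crossing to the adjacent extremum (the crossing trails
the physiological turn of breath by up to a quarter cycle); the raw
intercepts remain available in the `crossings` element, and `refine =
FALSE` keeps them as the onsets.

`breath_rate_series()` counts a breath in the 2-minute window containing
its inhalation onset (rate = count / 2), also reports first/last 5-minute
counts, and fails the session when the overall mean rate reaches 20
breaths/min (the session-mean reading of the rate gate). On simulated
sessions at default noise, every 2-minute window is recovered within 0.5
breaths/min of ground truth for both protocols.

# Heart rate variability

`lf_hf()` builds the RR tachogram at interval midpoints (intervals gated
to 0.25-3 s), interpolates it to a uniform 4 Hz grid, removes a linear
trend and estimates the PSD by Welch's method: 120 s Hann segments with
50% overlap — at least three averages inside a 5-minute segment while
resolving 0.04 Hz. LF is the trapezoidal integral over 0.04-0.15 Hz, HF
over 0.15-0.4 Hz, with the shared 0.15 Hz boundary assigned to HF (a
deterministic assignment is required; which side it lands on is
empirically negligible). Segments with fewer than 60 RR intervals are
missing; zero HF power flags the ratio undefined. The ratio is computed
for 0-300 s and the final 300 s of the session; a session shorter than
600 s reports only the segments that fit.

Computing "LF and HF components" directly on the ECG waveform rather than
on the tachogram is implemented for comparison (`lf_hf_signal()`), but the
tachogram route is the default analysis surface: waveform band power at
0.04-0.4 Hz reflects baseline residue, not beat-to-beat variability, and
is not a recognized HRV measure.

# Statistics

`wilcoxon_rbc()` drops zero differences, mid-ranks ties, and reports W,
the matched rank-biserial correlation (signed-rank imbalance over the
total rank mass), and a two-sided p — exact by enumeration over all
$2^n$ sign assignments for up to 12 retained pairs, otherwise a
tie-corrected normal approximation with continuity correction (the
convention of the common desktop statistics packages, which the exact
path renders moot for small samples). `mann_whitney_rbc()` mirrors this
for two groups (exact when $n_1 n_2 \le 100$; RBC $= 2U/(n_1 n_2) - 1$).
Benjamini-Hochberg and Holm adjustments are delegated to
`stats::p.adjust` within user-supplied families; the default family
structure groups repeated-measures models per measure and group tests per
comparison.

`rm_anova_gg()` fits the univariate mixed ANOVA by the classical
stratification: between-subject effects on subject means (error: subjects
within groups), within-subject effects on subject-centered deviations
(error: time by subjects within groups), each stratum with sum-to-zero
coded marginal (Type III) sums of squares so unequal group sizes are
handled. Mauchly's W uses the pooled within-group covariance with the
standard chi-square approximation; when its p falls below .05 and there
are more than two timepoints, the Greenhouse-Geisser epsilon — from the
eigenvalues of the orthonormally contrasted covariance — multiplies both
degrees of freedom of every within-stratum test. Both uncorrected and
corrected p-values are reported. Generalized eta-squared uses the
all-manipulated-factors convention: SS of the effect over itself plus
every error-stratum SS, the form comparable across within and between
manipulations in a mixed design. `holm_posthoc_paired()` provides paired
t post-hocs with Holm correction and paired Cohen's d =
mean(difference)/sd(difference).

# The synthetic-data generator

`simulate_session()` emulates the study conditions: a 600 s experiential
phase with markers at its ends, under guided 4-7-8 breathwork (60 s
free-breathing lead-in, then 19 s cycles, rendered as rising
ramp/plateau/falling ramp half-cosines) or free breathing at a constant
base rate (15 breaths/min by default, the center of the normal adult
range). Breath-cycle durations carry multiplicative lognormal jitter (SD
0.05): real breathing is not metronomic, and without within-subject
timing variability windowed counts would have zero residual variance and
degenerate F statistics. ECG places a sharp 80 ms biphasic template
(amplitude 800) at RR-modulated peak times (mean 70 bpm, sinusoidal LF/HF
modulation components plus 10 ms white RR noise); morphological realism
is deliberately out of scope. EDA is a piecewise-linear tonic trajectory
(default drifting 5 to 6 microsiemens) plus Poisson phasic responses
(4/min, 0.5 microsiemens, 1 s rise and exponential decay) and 0.01
microsiemens noise; EMG is white noise whose amplitude multiplies by the
configured gain inside motion-artifact windows, which also add spiky
contamination to the EDA. Noise defaults (ECG 20 units, respiration 0.05
relative, EDA 0.01 microsiemens, EMG 10 units) are set so that clean
simulations pass every quality gate, making configured artifacts the only
contamination.

A simulated breath counts as ground truth only when its exhalation onset
falls strictly inside the session — the same pairing rule the detector
states ("unmatched trailing onsets are not counted") — which also makes
the 4-7-8 arithmetic exact: 600 s at 19 s per cycle gives 31 complete
cycles.

What the generator does *not* emulate: ECG morphology (P/T waves,
ectopy), respiratory sinus arrhythmia beyond the configured RR tones,
skin-conductance deconvolution-grade SCR shapes, electrode drift and
detachment, or clock drift between devices. Passing tests on these
simulations therefore demonstrate correctness of the algorithms under
their stated models, not robustness to every artifact class of field
recordings.

# Validation design and problem sizes

The package's acceptance surface (`scripts/acceptance.R`, mirrored in the
test suite) recomputes, from scratch at fixed seeds: breath-rate recovery
on 20 sessions per protocol (every 2-minute window within 0.5
breaths/min); perfect 15-vs-22 breaths/min gate agreement over 50 seeds;
quality-index linearity within one unit with the verdict cut at 50; full
coverage of injected EMG bursts and post-repair EDA error under 0.2
microsiemens on constant-tonic fixtures; LF/HF at least 5 for a 0.10 Hz
RR tone and at most 0.5 for a 0.30 Hz tone, cross-checked against a
direct periodogram; the baseline-wander gate flipping at drift amplitude
850, at least 20 dB of 60 Hz attenuation, and 600 +/- 1 R peaks on a 60
bpm 10-minute simulation; exact-enumeration and hand-oracle agreement of
the statistical layer; and two cohort-level properties, run on
ground-truth breath events (the signal-level recovery being established
separately above, this keeps the cohort studies about the statistical
layer): with 20 subjects per cell the Timepoint-by-Stimulus interaction
on breath rate is detected at FDR-corrected p < .05 in at least 90% of
100 replicates while the built-in technology null is detected in at most
10%; and under a global null (40 subjects, 5 timepoints, 200 replicates)
the corrected time effect rejects at a rate inside [0.02, 0.09].

# Known limitations

* The CSV session dialect is the only on-disk format read directly;
  binary XDF containers must be exported to it first.
* The LOF reference sample assumes artifacts occupy a minority of the
  recording; a majority-contaminated channel degrades the reference (and
  is rejected by the coverage rule anyway).
* The 0.25 breath-amplitude threshold is interpreted on the unit-SD
  normalized signal; recordings whose variance is dominated by artifacts
  rather than breathing would shift its meaning.
* Very slow paced breathing sits below the 0.1 Hz drift high-pass; the
  pipeline compensates in period estimation and smoothing, but
  breath-onset timing there relies on harmonics and is less precise than
  for free breathing (counts, the analysis-facing quantity, are
  unaffected in simulation).
* `rm_anova_gg()` assumes complete cases (listwise deletion) and one
  within-subject factor.
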