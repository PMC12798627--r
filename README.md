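# physiopipe

Cleaning, quality control, feature extraction and statistics for
multimodal psychophysiological session recordings — ECG, electrodermal
activity (EDA), EMG and respiration — collected around a 10-minute
experiential phase (e.g. guided 4-7-8 breathwork versus ambient-sound
controls, delivered by different technologies). It is written for
researchers who need the windowed dependent variables of such designs and
an auditable, reproducible path from raw channels to test statistics.

## What it computes

Per participant, on time rebased to the `experience_start` marker:

* **Breath rate** — five 2-minute rates from breath onsets detected as
  crossings between the smoothed respiration signal and its moving mean,
  after 0.1 Hz drift removal, resampling to 100 Hz, windowed-FFT breathing
  period estimation and period-guided moving-average smoothing; breaths
  with peak-to-trough amplitude under 0.25 (unit-SD units) are discarded,
  and sessions at ≥ 20 breaths/min fail quality assurance.
* **Heart rate** — ten 1-minute means of 60/RR from R peaks detected on
  ECG cleaned with a 60 Hz notch and a 0.5–45 Hz zero-phase 4th-order
  Butterworth bandpass, amplitude-gated at 1500 device units; channels
  whose low-frequency baseline wanders more than 1700 units peak-to-peak
  are rejected.
* **Tonic EDA** — five 2-minute means of the 0.05 Hz low-passed skin
  conductance, after 8 s median filtering, 5 Hz low-passing and linear
  interpolation across motion-artifact windows found by a Local Outlier
  Factor scan of the EMG; a 0–100 quality index (range 0.05–60 μS, rate
  limit ±10 μS/s) rejects channels scoring below 50.
* **HRV** — the LF/HF ratio (LF 0.04–0.15 Hz, HF 0.15–0.4 Hz; Welch PSD
  of the linearly detrended 4 Hz RR tachogram, 120 s Hann segments, 50%
  overlap) for the first and last 5 minutes:

  $$\mathrm{LF/HF} = \frac{\int_{0.04}^{0.15} S_{RR}(f)\,df}{\int_{0.15}^{0.40} S_{RR}(f)\,df}$$

The statistical layer provides Wilcoxon signed-rank and Mann-Whitney U
tests with rank-biserial correlations (exact small-sample p-values by
enumeration), Benjamini-Hochberg and Holm corrections with family
grouping, mixed repeated-measures ANOVA with Mauchly's test,
Greenhouse-Geisser correction and generalized η², and Holm-corrected
paired post-hocs with Cohen's d.

A seeded synthetic-session generator (`simulate_session()`) produces all
four channels with known ground truth — breath onsets, R-peak times,
artifact windows, tonic trajectories — so the whole pipeline is testable
without any recordings. See `vignette("physiopipe-methods")` for the
models, parameter choices and their rationale.

## Worked example

```r
library(physiopipe)

cfg <- sim_config(seed = 42, protocol = "breathwork_478")
sim <- simulate_session(cfg)
run <- run_pipeline(list(sim$session))
dplyr::select(run$features, participant_id, stim, BR_t1, BR_t5, BR_change,
              HR_t1, HRV_first)
#> # A tibble: 1 × 7
#>   participant_id stim       BR_t1 BR_t5 BR_change HR_t1 HRV_first
#>   <chr>          <chr>      <dbl> <dbl>     <dbl> <dbl>     <dbl>
#> 1 sim0042        Breathwork   9.5   2.5        -7  70.1      2.64
```

The participant breathed at the free rate during the first 2-minute
window (9.5 breaths/min, which includes the 60 s lead-in) and settled to
the 19 s paced cycle by the last window (2.5 breaths/min), a change of
−7 breaths/min; heart rate and the first-5-minute LF/HF ratio come from
the same session's ECG. `run$qc` records, per channel, the verdicts the
rules produced (here: ECG wander 374 units — acceptable; EDA quality
index 100; mean breath rate 4.3 breaths/min — passes the 20 breaths/min
gate).

Cohort-level inference on a simulated study (20 subjects per cell,
Breathwork versus Rain, with a deliberately inert technology factor):

```r
feats <- simulate_breath_cohort(20, seed = 7)
st <- analyze_features(feats, measures = "BR")
subset(st$rm_anova, model == "time_by_stim",
       c(effect, df1_adj, df2_adj, F, p_corrected, p_fdr, eta2_g))
#>      effect df1_adj df2_adj    F p_corrected     p_fdr eta2_g
#> 1      stim     1.0      78  936    3.39e-45  9.49e-45  0.920
#> 2      time     2.1     164 1341   1.11e-103 1.55e-102  0.420
#> 3 time:stim     2.1     164 1084    1.40e-96  6.52e-96  0.369
```

The Timepoint × Stimulus interaction (paced breathing falls over time,
ambient listening does not) is detected with Greenhouse-Geisser-adjusted
degrees of freedom (ε̂ ≈ 0.52 here, hence df1 ≈ 2.1) and an FDR-corrected
p-value; η²G is the mixed-design generalized effect size.

Sessions recorded to disk use a plain-text CSV dialect (one file per
channel with a `# modality / # fs / # units` header plus a marker
sidecar; see `?load_session`), written and read by `write_session_csv()`
/ `load_session()`.

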