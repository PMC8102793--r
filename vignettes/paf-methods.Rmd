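---
title: "Methods: peak alpha frequency modulation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak alpha frequency modulation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pafmod)
```

## What this package computes

`pafmod` analyzes working-memory EEG experiments in which each trial shows a
sample array, imposes a 2 s memory delay, and then presents a test array.
The quantity of interest is the **peak alpha frequency (PAF)** — the
frequency in the 8–14 Hz band at which spectral power is maximal — and its
**modulation**: the change of PAF from a pre-trial baseline window to the
delay (maintenance) window, in Hz. Sex differences in modulation are the
headline contrast: female subjects are modeled with a mean modulation of
+0.30 Hz (SD 1.1) and male subjects with 0.00 Hz (SD 0.7).

Because raw EEG from the original cohort is not shippable, the package pairs
the analysis chain with a synthetic cohort generator so that every stage can
be validated by parameter recovery: inject known frequencies, run the full
pipeline, and compare estimates against ground truth.

## Trial timeline and analysis windows

Each trial runs: cue + sample onset at t = 0, 500 ms sample presentation,
a 2,000 ms delay (0.5–2.5 s), and the test array at 2.5 s. Epochs span
[−2.0, 5.5) s around onset — 7.5 s, i.e. 3,840 samples at 512 Hz — so
consecutive epochs of the 5.5 s trial cycle overlap by 2 s. Analysis
windows are half-open:

* **baseline** `[−0.5, 0)` — the 500 ms of fixation before onset,
* **maintenance** `[1.0, 2.5)` — the last 1,500 ms of the delay,
* **pretest** `[−0.5, 2.5)` — baseline through delay.

`analysis_windows()` and `trial_timeline()` return these constants; the
half-open convention means a TFR time point exactly at a window's right
edge belongs to the next interval.

## Preprocessing

`preprocess_session()` applies, in order:

1. **Band-limiting** (`bandlimit()`): 4th-order Butterworth high-pass at
   0.5 Hz and low-pass at 30 Hz, each applied forward and backward
   (zero-phase, 8th-order effective magnitude response) with odd-reflection
   edge padding.
2. **Segmentation** (`segment_epochs()`) into 7.5 s epochs; trials whose
   epoch would run past the recording edge are dropped with a warning.
3. **EOG screening** (`reject_eog_trials()`): a trial is rejected when the
   peak-to-peak amplitude on any EOG channel strictly exceeds 18.75 µV.
4. **Spike screening** (`reject_spike_trials()`): trials whose absolute
   peak exceeds 10× the median per-trial peak are rejected (a simple
   stand-in for manual artifact inspection; skipped below 3 trials, where
   the median is unstable).
5. **Correct-trial selection** (`split_correct_trials()`): only correct
   trials enter spectral analysis, per task type (2-item/3-item ×
   precise/relative: `2P`, `2R`, `3P`, `3R`).

No ICA is bundled; `preprocess_session(ica_hook =)` accepts a function if
you have one.

## Spectral decomposition

`tfr_transform()` computes induced power on a fixed grid: 2–20 Hz in
0.5 Hz steps, using a 2 s Hann-tapered window slid across the epoch (default
stride 0.05 s). Windows extending past the epoch are zero-padded, never
dropped. Power is normalized so a sinusoid of amplitude A at a grid
frequency yields power ≈ A² at interior time points, and is averaged over
trials after squaring (induced, not evoked, power).

With the defaults (512 Hz, 2 s window), the 0.5 Hz grid coincides with the
window's native DFT bins and an FFT fast path is used; any other
combination falls back to an explicit complex-exponential basis. Both paths
are tested against a brute-force windowed DFT oracle.

## Center-of-gravity PAF

For the 14 posterior channels, at every time point:

1. sum each channel's power over the 8–14 Hz band;
2. convert the sums to proportional weights (`channel_weights()`) — each
   channel's share of the total, so weights are scale-free;
3. multiply each channel's power spectrum by its weight and average over
   channels (`weighted_alpha_power()`).

PAF for a window is then the frequency of the maximum of the time-averaged
weighted spectrum (`extract_paf()`). Exact ties break toward the lowest
frequency and are flagged. Modulation is `maintenance PAF − baseline PAF`
(`paf_modulation()`); `subject_paf()` runs the whole chain per task type
and pooled.

Numerical choices worth knowing:

* Weights are computed from power summed over the 8–14 Hz band (the
  band-restricted reading keeps the weights alpha-specific).
* All-zero band power at a time point degenerates to uniform weights with a
  warning rather than NaN.
* PAF lives on the 0.5 Hz analysis grid; estimates are quantized
  accordingly, and modulation values are multiples of 0.5 Hz per subject.
  Group means are therefore continuous for practical purposes.

## Synthetic cohorts

`sim_config()` holds every generator parameter, with defaults matching the
study design: 77 female / 33 male subjects, 8 blocks × 64 trials, 512 Hz,
47 scalp channels of which 14 are posterior, plus 2 EOG channels.
`simulate_subject()` builds one continuous session:

* a posterior alpha sinusoid (10 µV, random phase per segment, per-channel
  gains U(0.8, 1.2)) at the subject's baseline PAF during fixation and
  sample, stepped to baseline + modulation during the delay, suppressed
  during test/response (event-related desynchronization), and back to
  baseline afterwards;
* an independent 1/f aperiodic background (2 µV RMS, exponent 1) in every
  channel, via FFT spectral shaping;
* Gaussian blink pulses (σ = 0.12 s, 100 µV) in the EOG channels on ~10%
  of trials;
* behavior: Bernoulli accuracy around Table-style task means with
  logit-scale subject effects (SD 0.55), log-normal response times, and —
  for males only — a Gaussian-copula coupling (r = 0.4) between baseline
  PAF and the relative-task accuracy effect.

Subject parameters are drawn once at cohort level
(`simulate_subject_params()`), each with its own seed, so
`recover_cohort_paf()` can stream subjects one at a time with flat memory.
Realism limits: the alpha rhythm is a fixed-frequency sinusoid per segment
(no waveform asymmetry, no amplitude dynamics beyond the ERD step), the
aperiodic background is stationary, and injected PAF values are unbounded
Gaussian draws, so a small fraction fall outside the 8–14 Hz estimation
band; the band-limited estimator cannot (by definition) recover those.

## Statistics

* `hd_quantile()` — Harrell–Davis quantiles (Beta-CDF weighted order
  statistics).
* `shift_function()` — decile differences with simultaneous percentile
  bootstrap intervals. The per-decile level is calibrated by binary search
  so that the joint bootstrap coverage over all nine deciles reaches
  1 − α; this replaces a fixed critical-value table and adapts to sample
  size.
* `ks_2samp()` — two-sample Kolmogorov–Smirnov test; exact p for small
  untied samples, asymptotic otherwise.
* `mixed_anova()` — 2×4 split-plot ANOVA with generalized η², Mauchly's
  test on orthonormalized within contrasts, and Greenhouse–Geisser
  corrected p-values whenever Mauchly rejects at 0.05.
* `tukey_hsd()` — Tukey–Kramer pairwise comparisons with a compact letter
  display.
* `fisher_z_compare()` — independent-correlation comparison; following the
  source analysis, the baseline–maintenance PAF correlation is computed on
  pooled subject × task-type records (n = 4 × subjects per group).
* `hierarchical_compare()` — task-type-only vs task-type × PAF regressions
  with the nested-model F-change test, in both the full-interaction (4
  added parameters) and pooled-interaction (PAF main effect + PAF ×
  relative-task, 2 added parameters) forms.
* `fdr_adjust()` — Benjamini–Hochberg, applied within each sex × window
  family of the correlation table.

`run_pipeline()` chains everything from a `sim_config()` to a `paf_report`;
`report_from_cohort()` is the statistics-only stage and gives identical
results on a saved cohort table. `write_report()` emits TSV/JSON bundles
with a config hash and seed in the manifest.

## Reduced-size validation runs

The validation suite recovers group modulation means on cohorts with the
full 77/33 design but reduced per-subject cost: 1 block × 4 trials, a
posterior-only 14 + 2 channel montage, and a 0.25 s TFR stride. These
choices only trade estimator variance for speed; every scientific parameter
(group sizes, injected means and SDs, SNR, filters, windows) keeps its
default. At these sizes one subject takes ~0.3 s and a 110-subject cohort
about half a minute.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_females = 8, n_males = 4, n_blocks = 1,
                  trials_per_block = 8, n_channels = 14,
                  posterior_channels = sprintf("ch%02d", 1:14), seed = 1)
report <- run_pipeline(cfg, stride = 0.25, n_boot = 500)
report$anova$modulation
tidy(report$shift$modulation)
plot_shift_function(report$shift$modulation)
```
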