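# pafmod

Peak alpha frequency (PAF) modulation analysis for working-memory EEG, with
a matched synthetic-cohort generator for end-to-end validation.

## The science

In visual working-memory tasks, the frequency of the posterior alpha rhythm
(8–14 Hz) shifts between rest and the memory delay. This package measures
that shift: PAF is estimated by a **center-of-gravity** method — at every
time point the 14 posterior channels are weighted by their share of summed
alpha-band power, the weighted spectra are averaged over channels, and PAF
is the frequency of the maximum of the time-averaged weighted spectrum.
**Modulation** is maintenance-window PAF (the last 1.5 s of the 2 s delay)
minus baseline-window PAF (the 0.5 s fixation before the sample), in Hz.
The headline contrast is a sex difference: females are modeled with a mean
modulation of +0.30 Hz (SD 1.1), males 0.00 Hz (SD 0.7).

The analysis chain mirrors a standard EEG pipeline: 0.5–30 Hz zero-phase
band-limiting, 7.5 s epochs around each trial onset, strict > 18.75 µV
EOG peak-to-peak rejection, correct-trial selection per task type, and a
2 s Hann-windowed time-frequency decomposition on a 0.5 Hz grid from 2 to
20 Hz. The statistics layer provides Harrell–Davis shift functions with
simultaneous bootstrap intervals, two-sample Kolmogorov–Smirnov tests,
2×4 mixed ANOVA with generalized η² and Greenhouse–Geisser correction,
Tukey HSD, Fisher r-to-z correlation comparison, two-step hierarchical
regressions with F-change, and Benjamini–Hochberg FDR adjustment.

Because raw EEG is not shippable, `sim_config()` / `simulate_subject()`
generate realistic sessions (alpha sinusoid stepping from baseline to
modulated frequency during the delay, 1/f background, EOG blinks, coupled
behavior) with recorded ground truth, so the whole pipeline is validated by
parameter recovery.

## Worked example

```r
library(pafmod)

cfg <- sim_config(n_females = 8, n_males = 4, n_blocks = 1,
                  trials_per_block = 8, n_channels = 14,
                  posterior_channels = sprintf("ch%02d", 1:14), seed = 1)

ses <- simulate_subject(cfg, "S001", "F", seed = 7)
round(unlist(ses$truth), 2)
#> baseline_paf   modulation
#>        13.14        -1.02

res <- analyze_session(ses, stride = 0.25, by_task = FALSE)
res$paf[res$paf$task_type == "all", ]
#> # A tibble: 3 x 7
#>   subject sex   task_type window        paf modulation n_trials
#>   <chr>   <chr> <chr>     <chr>       <dbl>      <dbl>    <int>
#> 1 S001    F     all       baseline       13         NA        2
#> 2 S001    F     all       maintenance    12         -1        2
#> 3 S001    F     all       pretest        12         NA        2
```

The injected baseline (13.14 Hz) and modulation (−1.02 Hz) come back as
13.0 and −1.0 on the 0.5 Hz grid. Streaming a whole cohort:

```r
rec <- recover_cohort_paf(cfg, stride = 0.25)
tapply(rec$modulation, rec$sex, mean, na.rm = TRUE)
#>     F     M
#> 0.625 0.125
```

Robust statistics:

```r
fisher_z_compare(0.82, 132, 0.58, 308)
#> # A tibble: 1 x 2
#>       z          p
#>   <dbl>      <dbl>
#> 1  4.71 0.00000251

sf <- shift_function(rnorm(120, 0.3, 1.1), rnorm(60, 0, 0.7),
                     n_boot = 1000, seed = 2)
head(as.data.frame(sf), 3)
#>   decile    q_x    q_y difference ci_low ci_high significant
#> 1    0.1 -1.029 -0.657    -0.3722 -0.963   0.565       FALSE
#> 2    0.2 -0.436 -0.287    -0.1491 -0.610   0.318       FALSE
#> 3    0.3 -0.140 -0.119    -0.0207 -0.362   0.382       FALSE
```

`run_pipeline(cfg)` chains simulation, preprocessing, PAF extraction and
the full statistical battery into a `paf_report`; `write_report()` saves
TSV/JSON bundles whose manifest records the config hash and seed.
`tidy()` / `glance()` methods and `plot_shift_function()`,
`plot_group_stripchart()`, `plot_weighted_alpha()` cover tabular and
visual outputs. See the methods vignette
(`vignettes/paf-methods.Rmd`) for the model and every numerical choice.

## Reproduction

Tests (unit + acceptance; the acceptance blocks run parameter-recovery,
type-I-error, bootstrap-coverage and estimator-recovery studies and take
~15 minutes):

```r
R CMD INSTALL --no-docs --no-html --no-help .
Rscript -e 'testthat::test_dir("tests/testthat", package = "pafmod",
                               load_package = "installed")'
```

Headline quantities for one seeded synthetic cohort (JSON out):

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness flows from the supplied seed; the same seed reproduces the
same JSON bit for bit.
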