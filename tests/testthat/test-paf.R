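fs <- 512
t_axis <- -2 + (0:(round(7.5 * fs) - 1)) / fs

test_that("channel weights are proportional power shares", {
  expect_equal(channel_weights(c(3, 1)), c(0.75, 0.25))
  expect_equal(channel_weights(c(2, 6, 2)), c(0.2, 0.6, 0.2))
  expect_equal(channel_weights(rep(7, 14)), rep(1 / 14, 14))
  expect_equal(sum(channel_weights(runif(14))), 1)
  expect_warning(w0 <- channel_weights(rep(0, 5)), "uniform")
  expect_equal(w0, rep(0.2, 5))
  expect_error(channel_weights(c(1, -1)), "non-negative")
})

test_that("weighted alpha power matches the explicit-loop oracle", {
  set.seed(11)
  freqs <- seq(2, 20, by = 0.5)
  n_ch <- 5; n_t <- 9
  power <- array(rexp(n_ch * length(freqs) * n_t), c(n_ch, length(freqs), n_t))
  tfr <- structure(list(power = power, freq_axis = freqs,
                        time_axis = seq(-0.5, by = 0.25, length.out = n_t),
                        channel_labels = sprintf("ch%02d", 1:n_ch),
                        n_trials = 1L),
                   class = "tfr")
  wap <- weighted_alpha_power(tfr, tfr$channel_labels)
  band_idx <- which(freqs >= 8 & freqs <= 14)
  expect_equal(dim(wap), c(13, n_t))
  expect_equal(unclass(wap)[, ], brute_weighted(power, band_idx),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(attr(wap, "freqs"), freqs[band_idx])
})

test_that("weights are scale-free: common gain rescales but never moves the peak", {
  set.seed(12)
  freqs <- seq(2, 20, by = 0.5)
  power <- array(rexp(3 * length(freqs) * 4), c(3, length(freqs), 4))
  mk <- function(p) structure(list(power = p, freq_axis = freqs,
                                   time_axis = c(-0.4, -0.2, 1.2, 1.4),
                                   channel_labels = c("a", "b", "c"),
                                   n_trials = 1L), class = "tfr")
  w1 <- weighted_alpha_power(mk(power), c("a", "b", "c"))
  w2 <- weighted_alpha_power(mk(power * 3.7), c("a", "b", "c"))
  expect_equal(unclass(w2)[, ], 3.7 * unclass(w1)[, ], ignore_attr = TRUE)
})

test_that("PAF extraction uses half-open windows and low-frequency tie-break", {
  freqs <- seq(8, 14, by = 0.5)
  times <- c(-0.5, -0.25, 0, 1.0, 2.25, 2.5)
  wap <- matrix(1, length(freqs), length(times))   # flat spectrum everywhere
  attr(wap, "freqs") <- freqs; attr(wap, "times") <- times
  paf <- extract_paf(wap, c(-0.5, 0))
  expect_equal(as.numeric(paf), 8.0)               # exact tie -> lowest freq
  expect_true(attr(paf, "tie"))
  # peak at 10.5 only at t = 0; baseline [-0.5, 0) must exclude it
  wap2 <- wap
  wap2[freqs == 10.5, times == 0] <- 50
  expect_equal(as.numeric(extract_paf(wap2, c(-0.5, 0))), 8.0)
  # maintenance [1.0, 2.5) includes 1.0 and 2.25, excludes 2.5
  wap3 <- wap
  wap3[freqs == 11, times == 2.5] <- 50
  wap3[freqs == 9.5, times == 1.0] <- 10
  p3 <- extract_paf(wap3, "maintenance")
  expect_equal(as.numeric(p3), 9.5)
  expect_false(attr(p3, "tie"))
  expect_error(extract_paf(wap, c(8, 9)), "no time points")
})

test_that("modulation is maintenance minus baseline", {
  expect_equal(paf_modulation(10.63, 10.30), 0.33)
  expect_equal(paf_modulation(10.53, 10.67), -0.14)
  expect_equal(paf_modulation(9.5, 9.5), 0)
})

test_that("subject_paf recovers injected baseline and maintenance frequencies", {
  cfg <- tiny_config(trials_per_block = 6, noise_amplitude = 0.5)
  ses <- simulate_subject(cfg, "S001", "F", seed = 21)
  ep <- preprocess_session(ses)
  res <- subject_paf(ep, cfg$posterior_channels, stride = 0.15,
                     by_task = FALSE)
  expect_setequal(res$window, c("baseline", "maintenance", "pretest"))
  base <- res$paf[res$window == "baseline"]
  maint <- res$paf[res$window == "maintenance"]
  expect_lt(abs(base - ses$truth$baseline_paf), 0.5 + 1e-9)
  expect_lt(abs(maint - (ses$truth$baseline_paf + ses$truth$modulation)),
            0.5 + 1e-9)
  mod <- res$modulation[res$window == "maintenance"]
  expect_equal(mod, maint - base)
})

test_that("subject_paf handles task types without correct trials", {
  cfg <- tiny_config(trials_per_block = 8, noise_amplitude = 0.5)
  ses <- simulate_subject(cfg, "S001", "M", seed = 2)
  ep <- preprocess_session(ses)
  ep$trial_meta$correct[ep$trial_meta$task_type == "3R"] <- FALSE
  res <- subject_paf(ep, cfg$posterior_channels, stride = 0.25)
  r3 <- res[res$task_type == "3R", ]
  expect_true(all(is.na(r3$paf)))
  expect_true(all(r3$n_trials == 0))
  expect_true(all(!is.na(res$paf[res$task_type == "all"])))
  expect_setequal(unique(res$task_type), c("all", "2P", "2R", "3P", "3R"))
})
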