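fs <- 512

test_that("band-limiting removes DC, keeps the passband, kills the stopband", {
  t <- seq(0, 10, by = 1 / fs)
  x10 <- sin(2 * pi * 10 * t)
  x60 <- sin(2 * pi * 60 * t)
  y <- bandlimit(rbind(5 + 0 * t, x10, x60), fs)
  mid <- 1500:3500
  # constant input -> zero output up to filter transients and the numeric
  # precision of a 0.5 Hz high-pass at fs 512 (residual << 0.5% of the DC)
  expect_lt(max(abs(y[1, mid])) / 5, 0.005)
  expect_lt(abs(mean(y[1, ])), 1e-6)
  # 10 Hz passband amplitude preserved within ripple tolerance
  expect_lt(abs(sd(y[2, mid]) / sd(x10[mid]) - 1), 0.01)
  # 8th-order effective low-pass at 30 Hz: |H(60)| = (1+(60/30)^8)^-1 ~ 1/257
  expect_lt(sd(y[3, mid]) / sd(x60[mid]), 1 / 100)
  expect_error(bandlimit(rbind(x10), fs, hp = 30, lp = 0.5), "hp < lp")
})

make_session <- function(n_ch = 3, dur = 30, onsets = c(5, 10.5, 16)) {
  labels <- c(sprintf("ch%02d", seq_len(n_ch - 1)), "EOG1")
  roles <- setNames(c(rep("posterior", n_ch - 1), "eog"), labels)
  list(signals = matrix(seq_len(n_ch * dur * fs) %% 7, n_ch, dur * fs,
                        dimnames = list(labels, NULL)),
       sampling_rate = fs, channel_labels = labels, channel_roles = roles,
       events = tibble::tibble(trial = seq_along(onsets), onset = onsets,
                               task_type = rep("2P", length(onsets)),
                               correct = TRUE, rt = 500))
}

test_that("segmentation yields exact sample counts and drops edge trials", {
  ses <- make_session()
  ep <- segment_epochs(ses)
  expect_equal(dim(ep$data), c(3, 3, round(7.5 * fs)))
  expect_equal(ep$time_axis[1], -2.0)
  # onset too close to the start is dropped with a warning
  ses$events <- tibble::add_row(ses$events, trial = 4L, onset = 1.0,
                                task_type = "2R", correct = TRUE, rt = 500)
  expect_warning(ep2 <- segment_epochs(ses), "edge")
  expect_equal(dim(ep2$data)[1], 3)
  expect_identical(attr(ep2, "dropped"), 4L)
  # no onsets -> empty epoch set
  ses$events <- ses$events[0, ]
  ep0 <- segment_epochs(ses)
  expect_equal(dim(ep0$data)[1], 0)
})

blank_epochs <- function(n_trials, eog_ptp = rep(0, n_trials)) {
  labels <- c("ch01", "ch02", "EOG1")
  roles <- setNames(c("posterior", "posterior", "eog"), labels)
  dat <- array(0, dim = c(n_trials, 3, 100))
  for (i in seq_len(n_trials)) {
    dat[i, 3, 1] <- -eog_ptp[i] / 2
    dat[i, 3, 2] <- eog_ptp[i] / 2
    dat[i, 1:2, ] <- sin(seq_len(100) / 5)
  }
  epoch_set(dat, 100, labels, roles, time_axis = (0:99) / 100,
            trial_meta = tibble::tibble(trial = seq_len(n_trials),
                                        task_type = "2P", correct = TRUE,
                                        rt = 1))
}

test_that("EOG rejection uses a strict peak-to-peak threshold", {
  ep <- blank_epochs(3, eog_ptp = c(20, 0, 18.75))
  out <- reject_eog_trials(ep, threshold = 18.75)
  log <- attr(out, "rejection_log")
  # 20 uV exceeds 18.75 -> rejected; flat and exactly-at-threshold retained
  expect_identical(log$rejected, c(TRUE, FALSE, FALSE))
  expect_equal(n <- dim(out$data)[1], 2)
  expect_equal(log$eog_ptp, c(20, 0, 18.75))
  # retained voltages are untouched
  expect_identical(out$data[1, , ], ep$data[2, , ])
  # screening cannot run without EOG channels
  labels <- c("ch01", "ch02")
  roles <- setNames(rep("posterior", 2), labels)
  no_eog <- epoch_set(ep$data[, 1:2, , drop = FALSE], 100, labels, roles,
                      ep$time_axis, ep$trial_meta)
  expect_error(reject_eog_trials(no_eog), "EOG")
})

test_that("spike screen removes order-of-magnitude outlier trials only", {
  ep <- blank_epochs(50)
  ep$data[17, 1, ] <- ep$data[17, 1, ] * 20
  out <- reject_spike_trials(ep, factor = 10)
  expect_identical(which(attr(out, "rejection_log")$rejected), 17L)
  # identical trials: nothing removed
  ep2 <- blank_epochs(10)
  out2 <- reject_spike_trials(ep2)
  expect_equal(dim(out2$data)[1], 10)
  # infinite factor disables the screen
  out3 <- reject_spike_trials(ep, factor = Inf)
  expect_equal(dim(out3$data)[1], 50)
  # unstable median with < 3 trials: skipped with warning
  expect_warning(out4 <- reject_spike_trials(blank_epochs(2)), "skipped")
  expect_equal(dim(out4$data)[1], 2)
})

test_that("correct-trial partition matches a hand tally", {
  ep <- blank_epochs(8)
  ep$trial_meta$task_type <- c("2P", "2P", "2R", "3P", "3P", "3P", "3R", "3R")
  ep$trial_meta$correct <- c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  sets <- split_correct_trials(ep)
  expect_equal(unname(attr(sets, "counts")), c(1L, 1L, 2L, 0L))
  expect_identical(attr(sets, "empty"), "3R")
  expect_equal(dim(sets[["3P"]]$data)[1], 2)
  # all incorrect -> four empty sets, all flagged
  ep$trial_meta$correct <- FALSE
  sets0 <- split_correct_trials(ep)
  expect_true(all(attr(sets0, "counts") == 0))
  expect_length(attr(sets0, "empty"), 4)
})
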