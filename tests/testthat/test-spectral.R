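fs <- 512
t_axis <- -2 + (0:(round(7.5 * fs) - 1)) / fs

tone_epochs <- function(freq, amp = 1, n_ch = 1, t0 = -2) {
  mat <- matrix(rep(amp * sin(2 * pi * freq * (t_axis - t0)), n_ch),
                nrow = n_ch, byrow = TRUE)
  signal_epochs(mat, fs = fs, t0 = -2)
}

test_that("zero input gives zero power and the default grid has 37 bins", {
  ep <- signal_epochs(matrix(0, 1, length(t_axis)), fs = fs)
  tfr <- tfr_transform(ep, stride = 0.5)
  expect_true(all(tfr$power == 0))
  expect_length(tfr$freq_axis, 37)
  expect_equal(range(tfr$freq_axis), c(2, 20))
})

test_that("a pure grid-frequency sinusoid peaks at its frequency with power ~ A^2", {
  for (amp in c(1, 2)) {
    tfr <- tfr_transform(tone_epochs(10, amp), stride = 0.25)
    interior <- tfr$time_axis > -0.9 & tfr$time_axis < 4.4
    peak_freq <- tfr$freq_axis[apply(tfr$power[1, , interior], 2, which.max)]
    expect_true(all(peak_freq == 10))
    expect_equal(max(tfr$power[1, , interior]), amp^2, tolerance = 1e-5)
  }
  # doubling the amplitude quadruples power in every bin
  t1 <- tfr_transform(tone_epochs(10, 1), stride = 0.5)
  t2 <- tfr_transform(tone_epochs(10, 2), stride = 0.5)
  expect_equal(t2$power, 4 * t1$power, tolerance = 1e-12)
})

test_that("STFT power matches a brute-force windowed DFT oracle", {
  set.seed(3)
  n_ch <- 3
  mat <- matrix(rnorm(n_ch * length(t_axis)), n_ch)
  mat[1, ] <- mat[1, ] + 4 * sin(2 * pi * 11 * t_axis)
  ep <- signal_epochs(mat, fs = fs)
  tfr <- tfr_transform(ep, stride = 1.0)
  win_n <- round(2 * fs)
  for (ci in 1:n_ch) for (ti in seq_along(tfr$time_axis)) {
    center <- tfr$time_axis[ti]
    start <- round((center - t_axis[1]) * fs) + 1 - floor(win_n / 2)
    idx <- start:(start + win_n - 1)
    x <- ifelse(idx >= 1 & idx <= length(t_axis), mat[ci, pmax(1, pmin(idx, length(t_axis)))], 0)
    x[idx < 1 | idx > length(t_axis)] <- 0
    for (fi in c(1, 17, 19, 37)) {
      expect_equal(unname(tfr$power[ci, fi, ti]),
                   brute_window_power(x, fs, tfr$freq_axis[fi]),
                   tolerance = 1e-10)
    }
  }
})

test_that("FFT fast path and explicit-basis path agree", {
  set.seed(4)
  mat <- matrix(rnorm(2 * length(t_axis)), 2)
  ep <- signal_epochs(mat, fs = fs)
  aligned <- tfr_transform(ep, stride = 0.8)              # 0.5 Hz grid, fast
  off_grid <- tfr_transform(ep, stride = 0.8,
                            freqs = seq(2, 20, by = 0.5) + 1e-7)
  expect_equal(aligned$power, off_grid$power, tolerance = 1e-4)
  # exactly comparable: force the generic path onto the aligned grid via a
  # non-aligned window (1.5 s -> 2/3 Hz native bins), checked by the oracle
  gen <- tfr_transform(ep, window = 1.5, stride = 1.5, freqs = c(8, 10.5, 13))
  win_n <- round(1.5 * fs)
  ti <- which.min(abs(gen$time_axis - 0.25))
  center <- gen$time_axis[ti]
  start <- round((center - t_axis[1]) * fs) + 1 - floor(win_n / 2)
  x <- mat[1, start:(start + win_n - 1)]
  for (fi in 1:3) {
    expect_equal(unname(gen$power[1, fi, ti]),
                 brute_window_power(x, fs, gen$freq_axis[fi]),
                 tolerance = 1e-10)
  }
})

test_that("time-shift covariance holds at interior time points", {
  set.seed(5)
  x <- rnorm(length(t_axis))
  stride <- 0.25
  k <- 4                                    # shift by k * stride seconds
  shift_n <- round(k * stride * fs)
  x2 <- c(rep(0, shift_n), x[1:(length(x) - shift_n)])
  t1 <- tfr_transform(signal_epochs(rbind(x), fs = fs), stride = stride)
  t2 <- tfr_transform(signal_epochs(rbind(x2), fs = fs), stride = stride)
  interior <- which(t1$time_axis > -0.5 & t1$time_axis < 3.0)
  expect_equal(t2$power[1, , interior + k], t1$power[1, , interior],
               tolerance = 1e-8)
})

test_that("2 s window separates 10 and 12 Hz components", {
  x <- sin(2 * pi * 10 * (t_axis + 2)) + 0.8 * sin(2 * pi * 12 * (t_axis + 2))
  tfr <- tfr_transform(signal_epochs(rbind(x), fs = fs), stride = 1)
  ti <- which.min(abs(tfr$time_axis - 1.5))
  spec <- tfr$power[1, , ti]
  i10 <- which(tfr$freq_axis == 10); i12 <- which(tfr$freq_axis == 12)
  # both local maxima present, separated by a dip at 11 Hz
  expect_gt(spec[i10], spec[i10 - 1]); expect_gt(spec[i10], spec[i10 + 1])
  expect_gt(spec[i12], spec[i12 - 1]); expect_gt(spec[i12], spec[i12 + 1])
  expect_lt(spec[which(tfr$freq_axis == 11)], min(spec[i10], spec[i12]))
})

test_that("parameter validation", {
  ep <- signal_epochs(matrix(0, 1, 1000), fs = 100)
  expect_error(tfr_transform(ep, freqs = c(10, 60)), "Nyquist")
  expect_error(tfr_transform(ep, stride = 0), "stride")
  expect_error(tfr_transform(ep, window = 30), "window")
  expect_error(tfr_transform(ep, channels = "nope"), "channel")
})
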