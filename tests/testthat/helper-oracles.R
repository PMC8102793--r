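# Independent brute-force oracles. These deliberately re-derive each
# quantity from its definition with plain loops, so they share no code with
# the package implementations they check.

# Hann-tapered Fourier power at one frequency from an explicit sample sum
brute_window_power <- function(x, fs, freq) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  tt <- (seq_len(n) - 1) / fs
  re <- sum(w * x * cos(2 * pi * freq * tt))
  im <- -sum(w * x * sin(2 * pi * freq * tt))
  (2 / sum(w))^2 * (re^2 + im^2)
}

# Harrell-Davis estimate straight from the Beta-CDF weight definition
brute_hd <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  a <- (n + 1) * q
  b <- (n + 1) * (1 - q)
  total <- 0
  for (i in seq_len(n)) {
    wi <- pbeta(i / n, a, b) - pbeta((i - 1) / n, a, b)
    total <- total + wi * x[i]
  }
  total
}

# sup |ECDF_x - ECDF_y| over the pooled sample, counted by hand
brute_ks_d <- function(x, y) {
  d <- 0
  for (v in c(x, y)) {
    fx <- sum(x <= v) / length(x)
    fy <- sum(y <= v) / length(y)
    d <- max(d, abs(fx - fy))
  }
  d
}

# Benjamini-Hochberg step-up, from the definition
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (k in n:1) {
    running <- min(running, p[o[k]] * n / k)
    adj[o[k]] <- running
  }
  adj
}

# channel-weighted alpha power by explicit loops over time and frequency
brute_weighted <- function(power, band_idx) {
  n_ch <- dim(power)[1]
  n_t <- dim(power)[3]
  out <- matrix(0, length(band_idx), n_t)
  for (t in seq_len(n_t)) {
    sums <- numeric(n_ch)
    for (ch in seq_len(n_ch)) sums[ch] <- sum(power[ch, band_idx, t])
    w <- if (sum(sums) == 0) rep(1 / n_ch, n_ch) else sums / sum(sums)
    for (fi in seq_along(band_idx)) {
      acc <- 0
      for (ch in seq_len(n_ch)) acc <- acc + w[ch] * power[ch, band_idx[fi], t]
      out[fi, t] <- acc / n_ch
    }
  }
  out
}

# small montage config used across tests: all scalp channels posterior
tiny_config <- function(n_females = 2, n_males = 2, trials_per_block = 8,
                        n_blocks = 1, seed = 42, ...) {
  sim_config(n_females = n_females, n_males = n_males,
             trials_per_block = trials_per_block, n_blocks = n_blocks,
             n_channels = 14,
             posterior_channels = sprintf("ch%02d", 1:14),
             seed = seed, ...)
}

# epoch_set wrapping one deterministic signal matrix (channels x samples)
signal_epochs <- function(mat, fs = 512, t0 = -2.0, roles = NULL) {
  labels <- rownames(mat)
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(nrow(mat)))
  if (is.null(roles)) {
    roles <- setNames(rep("posterior", length(labels)), labels)
  }
  epoch_set(array(mat, dim = c(1, nrow(mat), ncol(mat))),
            fs, labels, roles, time_axis = t0 + (seq_len(ncol(mat)) - 1) / fs)
}
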