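#' Trial schedule for one session
#'
#' Lays out `n_blocks x trials_per_block` trials with the four task types
#' (2-/3-sample x precise/relative) pseudorandomized within each block:
#' each block contains as near-equal task-type counts as its length allows,
#' in shuffled order. Uses the current RNG state.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `trial`, `block`, `task_type`.
#' @export
trial_schedule <- function(config) {
  tt <- task_types()
  blocks <- purrr::map(seq_len(config$n_blocks), function(b) {
    base <- rep(tt, length.out = config$trials_per_block)
    tibble::tibble(block = b, task_type = sample(base))
  })
  out <- dplyr::bind_rows(blocks)
  out$trial <- seq_len(nrow(out))
  out[, c("trial", "block", "task_type")]
}

#' Draw subject-level simulation parameters for a cohort
#'
#' Samples, per subject: baseline PAF ~ N(`baseline_paf_mean`,
#' `baseline_paf_sd`); PAF modulation ~ N(group mean, group SD) with
#' sex-specific parameters; accuracy random effects on the logit scale; and
#' a response-time random effect on the log scale. In males the
#' relative-task accuracy effect is coupled to baseline PAF through a
#' Gaussian copula at correlation `paf_accuracy_r_male_relative`; in
#' females the two are independent.
#'
#' Seeds the RNG from `config$seed`, so the same config always yields the
#' same cohort parameters (and the same per-subject seeds used by
#' [simulate_subject()]).
#'
#' @param config A [sim_config()].
#' @return Tibble with one row per subject: `subject`, `sex`,
#'   `baseline_paf`, `modulation`, `acc_shift_precise`,
#'   `acc_shift_relative`, `rt_z`, `subject_seed`.
#' @export
simulate_subject_params <- function(config) {
  if (config$n_females + config$n_males < 2) {
    stop("cohort needs at least 2 subjects", call. = FALSE)
  }
  set.seed(config$seed)
  n <- config$n_females + config$n_males
  sex <- c(rep("F", config$n_females), rep("M", config$n_males))
  z_paf <- stats::rnorm(n)
  w1 <- stats::rnorm(n)
  w2 <- stats::rnorm(n)
  r <- config$paf_accuracy_r_male_relative
  z_rel <- ifelse(sex == "M", r * z_paf + sqrt(1 - r^2) * w2, w2)
  mod_mean <- ifelse(sex == "F", config$modulation_mean_f,
                     config$modulation_mean_m)
  mod_sd <- ifelse(sex == "F", config$modulation_sd_f, config$modulation_sd_m)
  tibble::tibble(
    subject = sprintf("S%03d", seq_len(n)),
    sex = sex,
    baseline_paf = config$baseline_paf_mean + config$baseline_paf_sd * z_paf,
    modulation = stats::rnorm(n, mod_mean, mod_sd),
    acc_shift_precise = config$accuracy_logit_sd * w1,
    acc_shift_relative = config$accuracy_logit_sd * z_rel,
    rt_z = stats::rnorm(n),
    subject_seed = sample.int(.Machine$integer.max - 1L, n)
  )
}

# piecewise alpha frequency over one trial's ownership window, relative to
# cue onset: fixation + sample carry the baseline frequency, the delay the
# modulated frequency, test/response no alpha (event-related
# desynchronization), late inter-trial interval baseline again
trial_alpha_segments <- function(f_base, f_maint) {
  tl <- trial_timeline()
  list(
    list(span = c(-0.5, tl$delay_onset), freq = f_base),
    list(span = c(tl$delay_onset, tl$test_onset), freq = f_maint),
    list(span = c(tl$response_end, 5.0), freq = f_base)
  )
}

# 1/f^chi Gaussian background via spectral shaping, scaled to target RMS
gen_aperiodic <- function(n, fs, chi, rms) {
  if (rms <= 0) return(numeric(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  shape <- ifelse(f > 0, f^(-chi / 2), 0)
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  y * rms / stats::sd(y)
}

#' Simulate one subject's EEG session and behavior
#'
#' Generates a continuous multichannel recording (microvolts) containing,
#' in the posterior channels, an alpha oscillation whose frequency steps
#' from the subject's baseline PAF (during fixation and the sample period)
#' to baseline + modulation during the 2 s memory delay, superimposed on an
#' independent 1/f aperiodic background in every channel; EOG channels
#' additionally carry blink transients in a `blink_rate` fraction of
#' trials. Behavioral accuracy is Bernoulli per trial around the task-type
#' means (logit-scale subject effects) and response times are log-normal.
#'
#' @param config A [sim_config()].
#' @param subject_id Subject label.
#' @param sex `"F"` or `"M"`.
#' @param seed Integer seed for this subject's RNG stream.
#' @param params Optional single row of [simulate_subject_params()]; drawn
#'   internally when `NULL`.
#' @return An `eeg_session`: list with `signals` (channels x samples
#'   matrix), `sampling_rate`, `channel_labels`, `channel_roles`, `events`
#'   (tibble: trial, block, onset s, task_type, correct, rt), `subject`,
#'   `sex`, and `truth` (injected baseline PAF and modulation).
#' @export
simulate_subject <- function(config, subject_id = "S001", sex = c("F", "M"),
                             seed = config$seed, params = NULL) {
  sex <- match.arg(sex)
  set.seed(seed)
  if (is.null(params)) {
    mod_mean <- if (sex == "F") config$modulation_mean_f else config$modulation_mean_m
    mod_sd <- if (sex == "F") config$modulation_sd_f else config$modulation_sd_m
    params <- tibble::tibble(
      baseline_paf = stats::rnorm(1, config$baseline_paf_mean,
                                  config$baseline_paf_sd),
      modulation = stats::rnorm(1, mod_mean, mod_sd),
      acc_shift_precise = config$accuracy_logit_sd * stats::rnorm(1),
      acc_shift_relative = config$accuracy_logit_sd * stats::rnorm(1),
      rt_z = stats::rnorm(1)
    )
  }

  fs <- config$sampling_rate
  sched <- trial_schedule(config)
  n_tr <- nrow(sched)
  onsets <- 4.0 + (seq_len(n_tr) - 1) * trial_timeline()$trial_spacing
  total_s <- max(onsets) + 5.5 + 2.0
  n_samp <- round(total_s * fs)

  # behavior
  acc_shift <- ifelse(grepl("R$", sched$task_type),
                      params$acc_shift_relative, params$acc_shift_precise)
  p_correct <- stats::plogis(stats::qlogis(config$accuracy_means[sched$task_type]) +
                               acc_shift)
  correct <- unname(stats::runif(n_tr) < p_correct)
  # log-normal RT: ~15% between-subject, ~20% within-subject CV
  rt <- exp(log(config$rt_means[sched$task_type]) + 0.15 * params$rt_z +
              stats::rnorm(n_tr, 0, 0.20))

  labels <- c(config$scalp_channels, config$eog_channels)
  roles <- stats::setNames(
    c(ifelse(config$scalp_channels %in% config$posterior_channels,
             "posterior", "scalp"),
      rep("eog", length(config$eog_channels))), labels)

  signals <- matrix(0, nrow = length(labels), ncol = n_samp,
                    dimnames = list(labels, NULL))

  # shared posterior alpha trace with per-channel gain
  post_idx <- which(roles == "posterior")
  gains <- stats::runif(length(post_idx), 0.8, 1.2)
  if (config$alpha_amplitude > 0) {
    alpha <- numeric(n_samp)
    add_tone <- function(alpha, t0, t1, freq) {
      i0 <- max(0L, round(t0 * fs)) + 1L
      i1 <- min(n_samp, round(t1 * fs))
      if (i1 < i0) return(alpha)
      tt <- (seq(i0, i1) - 1) / fs
      phase <- stats::runif(1, 0, 2 * pi)
      alpha[i0:i1] <- alpha[i0:i1] +
        config$alpha_amplitude * sin(2 * pi * freq * (tt - t0) + phase)
      alpha
    }
    jit <- if (config$paf_trial_sd > 0) {
      stats::rnorm(n_tr, 0, config$paf_trial_sd)
    } else rep(0, n_tr)
    # lead-in and tail at baseline frequency
    alpha <- add_tone(alpha, 0, onsets[1] - 0.5, params$baseline_paf)
    for (k in seq_len(n_tr)) {
      fb <- params$baseline_paf + jit[k]
      fm <- fb + params$modulation
      for (seg in trial_alpha_segments(fb, fm)) {
        alpha <- add_tone(alpha, onsets[k] + seg$span[1],
                          onsets[k] + seg$span[2], seg$freq)
      }
    }
    alpha <- add_tone(alpha, max(onsets) + 5.0, total_s, params$baseline_paf)
    for (j in seq_along(post_idx)) {
      signals[post_idx[j], ] <- gains[j] * alpha
    }
  } else {
    # keep the RNG stream structure comparable
    invisible(stats::runif(1))
  }

  # aperiodic background in every channel
  if (config$noise_amplitude > 0) {
    for (i in seq_along(labels)) {
      signals[i, ] <- signals[i, ] +
        gen_aperiodic(n_samp, fs, config$aperiodic_exponent,
                      config$noise_amplitude)
    }
  }

  # blink transients in both EOG channels
  eog_idx <- which(roles == "eog")
  if (config$blink_rate > 0 && config$blink_amplitude > 0) {
    blink_trials <- which(stats::runif(n_tr) < config$blink_rate)
    for (k in blink_trials) {
      t0 <- onsets[k] + stats::runif(1, 0, 4.5)
      idx <- which(abs((seq_len(n_samp) - 1) / fs - t0) < 0.5)
      if (!length(idx)) next
      pulse <- config$blink_amplitude *
        exp(-((seq_len(n_samp)[idx] - 1) / fs - t0)^2 / (2 * 0.12^2))
      for (e in eog_idx) signals[e, idx] <- signals[e, idx] + pulse
    }
  }

  events <- tibble::tibble(
    trial = sched$trial, block = sched$block, onset = onsets,
    task_type = sched$task_type, correct = correct, rt = as.numeric(rt)
  )
  structure(
    list(signals = signals, sampling_rate = fs, channel_labels = labels,
         channel_roles = roles, events = events, subject = subject_id,
         sex = sex,
         truth = list(baseline_paf = params$baseline_paf,
                      modulation = params$modulation)),
    class = "eeg_session"
  )
}

#' @export
print.eeg_session <- function(x, ...) {
  cat(sprintf("<eeg_session> %s (%s): %d channels x %d samples @ %g Hz, %d trials\n",
              x$subject, x$sex, nrow(x$signals), ncol(x$signals),
              x$sampling_rate, nrow(x$events)))
  invisible(x)
}

#' Simulate a full cohort
#'
#' Draws subject parameters with [simulate_subject_params()] and generates
#' one [simulate_subject()] session per subject. With `out_dir` set, each
#' session is written to disk as an EDF recording plus a JSON event
#' sidecar, together with a cohort-level behavior TSV and a plain-text
#' ground-truth parameter log (see [read_ground_truth()]).
#'
#' For large cohorts prefer streaming subjects one at a time from
#' [simulate_subject_params()] + [simulate_subject()] (as
#' [recover_cohort_paf()] does) to avoid holding all sessions in memory.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory.
#' @return List with `sessions` (list of `eeg_session`), `subjects`
#'   (parameter tibble), and `behavior` (per-trial tibble across subjects).
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  params <- simulate_subject_params(config)
  sessions <- purrr::pmap(
    list(params$subject, params$sex, params$subject_seed,
         seq_len(nrow(params))),
    function(id, sex, sd_i, i) {
      simulate_subject(config, id, sex, seed = sd_i,
                       params = params[i, ])
    }
  )
  behavior <- purrr::map2_dfr(sessions, params$subject, function(s, id) {
    dplyr::mutate(s$events, subject = id, sex = s$sex, .before = 1)
  })
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
    for (s in sessions) write_session(s, out_dir)
    utils::write.table(behavior, file.path(out_dir, "behavior.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    truth <- params[, c("subject", "sex", "baseline_paf", "modulation")]
    utils::write.table(truth, file.path(out_dir, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(sessions = sessions, subjects = params, behavior = behavior)
}

#' Read back a cohort ground-truth parameter log
#'
#' @param out_dir Directory written by [simulate_cohort()].
#' @return Tibble with `subject`, `sex`, `baseline_paf`, `modulation`.
#' @export
read_ground_truth <- function(out_dir) {
  tibble::as_tibble(utils::read.delim(file.path(out_dir, "ground_truth.tsv"),
                                      colClasses = c("character", "character",
                                                     "numeric", "numeric")))
}

#' Write one session to disk (EDF + JSON sidecar)
#'
#' @param session An `eeg_session`.
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_session <- function(session, out_dir) {
  edf <- file.path(out_dir, paste0(session$subject, ".edf"))
  write_edf(session$signals, session$sampling_rate, session$channel_labels,
            edf)
  sidecar <- file.path(out_dir, paste0(session$subject, ".json"))
  meta <- list(
    subject = session$subject, sex = session$sex,
    sampling_rate = session$sampling_rate,
    n_samples = ncol(session$signals),
    channel_roles = as.list(session$channel_roles),
    events = session$events
  )
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(edf, sidecar))
}

#' Read a session written by [write_session()]
#'
#' @param subject Subject label. @param dir Directory holding
#'   `<subject>.edf` and `<subject>.json`.
#' @return An `eeg_session` (voltages quantized by EDF's 16-bit encoding).
#' @export
read_session <- function(subject, dir) {
  rec <- read_edf(file.path(dir, paste0(subject, ".edf")))
  meta <- jsonlite::read_json(file.path(dir, paste0(subject, ".json")),
                              simplifyVector = TRUE)
  if (!is.null(meta$n_samples) && meta$n_samples < ncol(rec$signals)) {
    rec$signals <- rec$signals[, seq_len(meta$n_samples), drop = FALSE]
  }
  structure(
    list(signals = rec$signals, sampling_rate = rec$sampling_rate,
         channel_labels = rec$channel_labels,
         channel_roles = unlist(meta$channel_roles),
         events = tibble::as_tibble(meta$events), subject = meta$subject,
         sex = meta$sex, truth = NULL),
    class = "eeg_session"
  )
}
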