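#' Analyze one session into PAF records and behavior summaries
#'
#' Convenience wrapper: preprocess the session (band-limit, segment, EOG
#' and spike screens), then compute channel-weighted PAF per analysis
#' window, pooled over all correct trials and (optionally) per task type.
#' Behavioral summaries (proportion correct, mean correct-trial RT) come
#' from the full event record, independent of EEG trial rejection.
#'
#' @param session An `eeg_session`.
#' @param posterior_channels Posterior channel labels; defaults to the
#'   session's channels flagged `"posterior"`.
#' @param hp,lp,eog_threshold,spike_factor Preprocessing parameters.
#' @param window,stride,freqs,band Spectral/PAF parameters.
#' @param by_task Compute per-task-type PAF (default TRUE).
#' @return List with `paf` (tibble from [subject_paf()] plus subject/sex)
#'   and `behavior` (tibble: subject, sex, task_type, accuracy, rt,
#'   n_trials).
#' @export
analyze_session <- function(session, posterior_channels = NULL,
                            hp = 0.5, lp = 30, eog_threshold = 18.75,
                            spike_factor = 10, window = 2.0, stride = 0.05,
                            freqs = seq(2, 20, by = 0.5), band = c(8, 14),
                            by_task = TRUE) {
  if (is.null(posterior_channels)) {
    posterior_channels <-
      names(session$channel_roles)[session$channel_roles == "posterior"]
  }
  epochs <- preprocess_session(session, hp = hp, lp = lp,
                               eog_threshold = eog_threshold,
                               spike_factor = spike_factor)
  paf <- subject_paf(epochs, posterior_channels, band = band,
                     window = window, stride = stride, freqs = freqs,
                     by_task = by_task)
  paf <- dplyr::mutate(paf, subject = session$subject, sex = session$sex,
                       .before = 1)
  behavior <- session$events |>
    dplyr::group_by(.data$task_type) |>
    dplyr::summarise(
      accuracy = mean(.data$correct),
      rt = mean(.data$rt[.data$correct]),
      n_trials = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(subject = session$subject, sex = session$sex, .before = 1)
  list(paf = paf, behavior = behavior)
}

#' Stream a synthetic cohort through the PAF pipeline
#'
#' Generates each subject with [simulate_subject()] (one at a time, so
#' memory stays flat), runs [analyze_session()], and collects estimated
#' pooled PAF per window alongside the injected ground truth. This is the
#' parameter-recovery harness: the returned table lets you compare
#' recovered group mean modulations against what the generator injected.
#'
#' @param config A [sim_config()].
#' @param stride TFR stride in seconds (coarser strides speed up large
#'   recovery runs). @param by_task Also keep per-task-type PAF records.
#' @param ... Further arguments to [analyze_session()].
#' @return Tibble: one row per subject with `subject`, `sex`,
#'   `true_baseline`, `true_modulation`, `paf_baseline`, `paf_maintenance`,
#'   `paf_pretest`, `modulation`, `n_trials`; per-task records in attribute
#'   `"by_task"` when requested.
#' @export
recover_cohort_paf <- function(config, stride = 0.05, by_task = FALSE, ...) {
  params <- simulate_subject_params(config)
  rows <- vector("list", nrow(params))
  task_rows <- if (by_task) vector("list", nrow(params)) else NULL
  for (i in seq_len(nrow(params))) {
    ses <- simulate_subject(config, params$subject[i], params$sex[i],
                            seed = params$subject_seed[i],
                            params = params[i, ])
    res <- analyze_session(ses, stride = stride, by_task = by_task, ...)
    pooled <- tidyr::pivot_wider(
      dplyr::filter(res$paf, .data$task_type == "all"),
      id_cols = c("subject", "sex"), names_from = "window",
      values_from = "paf", names_prefix = "paf_")
    rows[[i]] <- dplyr::mutate(
      pooled,
      true_baseline = params$baseline_paf[i],
      true_modulation = params$modulation[i],
      modulation = .data$paf_maintenance - .data$paf_baseline,
      n_trials = res$paf$n_trials[res$paf$task_type == "all"][1])
    if (by_task) {
      task_rows[[i]] <- dplyr::filter(res$paf, .data$task_type != "all")
    }
  }
  out <- dplyr::bind_rows(rows)
  if (by_task) attr(out, "by_task") <- dplyr::bind_rows(task_rows)
  out
}

#' Build the long cohort table from per-subject analyses
#'
#' Joins per-task behavioral summaries with per-task and pooled PAF records
#' into the long format (one row per subject x task type) consumed by the
#' inferential layer.
#'
#' @param analyses List of [analyze_session()] results.
#' @return Tibble: `subject`, `sex`, `task_type`, `accuracy`, `rt`,
#'   `paf_baseline`, `paf_maintenance`, `paf_pretest`, `modulation`.
#' @export
build_cohort_table <- function(analyses) {
  beh <- purrr::map_dfr(analyses, "behavior")
  paf <- purrr::map_dfr(analyses, "paf") |>
    dplyr::filter(.data$task_type != "all") |>
    tidyr::pivot_wider(id_cols = c("subject", "sex", "task_type"),
                       names_from = "window", values_from = "paf",
                       names_prefix = "paf_") |>
    dplyr::mutate(modulation = .data$paf_maintenance - .data$paf_baseline)
  dplyr::left_join(beh, paf, by = c("subject", "sex", "task_type")) |>
    dplyr::select(-"n_trials")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' End-to-end, reproducible from `(config, seed)`: simulate each subject,
#' preprocess, decompose, extract PAF, and run the statistical battery.
#' Stages: mixed ANOVAs (accuracy, response time, PAF modulation) with
#' Tukey HSD on task type; Kolmogorov-Smirnov tests and shift functions
#' comparing female vs male subject-level distributions; the
#' baseline-maintenance PAF correlation per sex with a Fisher r-to-z
#' comparison (computed on pooled subject x task-type records); hierarchical
#' regressions of accuracy on task type and baseline PAF per sex; and the
#' accuracy-PAF correlation table with FDR adjustment.
#'
#' @param config A [sim_config()]; its `seed` drives simulation.
#' @param stride TFR stride (s). @param n_boot,alpha Shift-function
#'   bootstrap settings. @param out_dir Optional directory for TSV/JSON
#'   outputs (every file carries the config hash and seed).
#' @param ... Further arguments to [analyze_session()].
#' @return List of class `paf_report`.
#' @export
run_pipeline <- function(config, stride = 0.05, n_boot = 2000, alpha = 0.05,
                         out_dir = NULL, ...) {
  params <- simulate_subject_params(config)
  analyses <- purrr::map(seq_len(nrow(params)), function(i) {
    ses <- simulate_subject(config, params$subject[i], params$sex[i],
                            seed = params$subject_seed[i],
                            params = params[i, ])
    analyze_session(ses, stride = stride, by_task = TRUE, ...)
  })
  cohort <- build_cohort_table(analyses)
  report_from_cohort(cohort, config = config, n_boot = n_boot, alpha = alpha,
                     out_dir = out_dir)
}

#' Statistical battery on a prepared cohort table
#'
#' The statistics-only stage: identical inference whether the cohort table
#' comes fresh from [run_pipeline()] or was saved and reloaded.
#'
#' @param cohort Long cohort table (see [build_cohort_table()]).
#' @param config Optional [sim_config()] recorded in the manifest.
#' @param n_boot,alpha Shift-function settings.
#' @param seed Seed for bootstrap stages (default `config$seed` or 1).
#' @param out_dir Optional output directory.
#' @return List of class `paf_report` with elements `cohort`,
#'   `anova` (accuracy, rt, modulation), `tukey_accuracy`, `ks`,
#'   `shift` (accuracy, rt, modulation), `paf_correlation` (per-sex r,
#'   Fisher comparison), `hierarchical` (per sex), `correlation_table`.
#' @export
report_from_cohort <- function(cohort, config = NULL, n_boot = 2000,
                               alpha = 0.05, seed = NULL, out_dir = NULL) {
  if (is.null(seed)) seed <- if (!is.null(config)) config$seed else 1L
  subj <- cohort |>
    dplyr::group_by(.data$subject, .data$sex) |>
    dplyr::summarise(accuracy = mean(.data$accuracy, na.rm = TRUE),
                     rt = mean(.data$rt[is.finite(.data$rt)]),
                     modulation = mean(.data$modulation, na.rm = TRUE),
                     .groups = "drop")
  f <- function(col) subj[[col]][subj$sex == "F"]
  m <- function(col) subj[[col]][subj$sex == "M"]

  anovas <- list(
    accuracy = mixed_anova(cohort, "accuracy"),
    rt = mixed_anova(cohort, "rt"),
    modulation = mixed_anova(cohort, "modulation")
  )
  ks <- purrr::map(c(accuracy = "accuracy", rt = "rt",
                     modulation = "modulation"),
                   function(col) ks_2samp(f(col), m(col)))
  shifts <- purrr::imap(c(accuracy = "accuracy", rt = "rt",
                          modulation = "modulation"),
                        function(col, nm) {
                          shift_function(f(col), m(col), n_boot = n_boot,
                                         alpha = alpha, seed = seed)
                        })
  # baseline-maintenance PAF correlation per sex on subject x task records
  bm <- cohort |>
    dplyr::group_by(.data$sex) |>
    dplyr::summarise(r = stats::cor(.data$paf_baseline,
                                    .data$paf_maintenance,
                                    use = "complete.obs"),
                     n = dplyr::n(), .groups = "drop")
  rf <- bm$r[bm$sex == "F"]; rm_ <- bm$r[bm$sex == "M"]
  fisher <- fisher_z_compare(rm_, bm$n[bm$sex == "M"],
                             rf, bm$n[bm$sex == "F"])
  hier <- purrr::map(c(F = "F", M = "M"), function(s) {
    hierarchical_compare(dplyr::filter(cohort, .data$sex == s),
                         "accuracy", "paf_baseline")
  })
  report <- structure(list(
    cohort = cohort, anova = anovas,
    tukey_accuracy = tukey_hsd(cohort, "accuracy", "task_type"),
    ks = ks, shift = shifts,
    paf_correlation = list(by_sex = bm, fisher_m_vs_f = fisher),
    hierarchical = hier,
    correlation_table = paf_accuracy_correlations(cohort),
    seed = seed,
    config_hash = if (!is.null(config)) rlang::hash(config) else NA_character_
  ), class = "paf_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.paf_report <- function(x, ...) {
  cat("<paf_report>\n")
  cat(sprintf("  cohort: %d subjects (%d F / %d M), %d rows\n",
              length(unique(x$cohort$subject)),
              sum(table(x$cohort$subject[x$cohort$sex == "F"]) > 0),
              sum(table(x$cohort$subject[x$cohort$sex == "M"]) > 0),
              nrow(x$cohort)))
  cat(sprintf("  modulation ANOVA sex effect: F(%d,%d) = %.2f, p = %.4g\n",
              x$anova$modulation$df_num[1], x$anova$modulation$df_den[1],
              x$anova$modulation$f[1], x$anova$modulation$p[1]))
  cat(sprintf("  modulation KS: D = %.2f, p = %.3g; Fisher z (M vs F) = %.2f\n",
              x$ks$modulation$d, x$ks$modulation$p,
              x$paf_correlation$fisher_m_vs_f$z))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits the cohort table and shift functions as TSV and the inferential
#' results as JSON; `manifest.json` records the config hash and seed.
#'
#' @param report A `paf_report`. @param out_dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wt <- function(d, f) utils::write.table(d, file.path(out_dir, f),
                                          sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(report$cohort, "cohort_table.tsv")
  for (nm in names(report$shift)) {
    wt(report$shift[[nm]], paste0("shift_", nm, ".tsv"))
  }
  wt(report$correlation_table, "correlation_table.tsv")
  stats_out <- list(
    anova = purrr::map(report$anova, ~as.data.frame(.x)),
    ks = purrr::map(report$ks, ~.x[c("d", "p", "n_x", "n_y")]),
    paf_correlation = report$paf_correlation,
    hierarchical = purrr::map(report$hierarchical, ~as.data.frame(.x)),
    tukey = list(pairs = report$tukey_accuracy$pairs,
                 groups = report$tukey_accuracy$groups),
    seed = report$seed, config_hash = report$config_hash
  )
  jsonlite::write_json(stats_out, file.path(out_dir, "statistics.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  jsonlite::write_json(list(config_hash = report$config_hash,
                            seed = report$seed,
                            version = as.character(utils::packageVersion("pafmod"))),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
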