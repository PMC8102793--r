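#' Mixed-design (split-plot) ANOVA
#'
#' Sex-by-task-type decomposition for one outcome: a between-subject factor
#' crossed with a complete within-subject factor. Sums of squares come from
#' the classical two-stratum decomposition (the between effect is tested
#' against subject variation, the within effect and interaction against the
#' subject-by-within residual), effect sizes are generalized eta squared,
#' and sphericity of the within factor is assessed with Mauchly's test with
#' Greenhouse-Geisser corrected degrees of freedom reported whenever the
#' Mauchly p is below 0.05.
#'
#' Rows with missing or non-finite outcomes are removed first; subjects
#' then missing any within-factor cell are dropped listwise with a
#' warning. With g between groups, k within levels and n subjects the
#' design degrees of freedom are `(g-1, n-g)` for the between effect and
#' `(k-1, (k-1)(n-g))` for the within effect and interaction.
#'
#' @param data Long-format data frame: one row per subject x within level.
#' @param outcome,between,within,subject Column names (strings).
#' @param sphericity Run Mauchly/Greenhouse-Geisser machinery (default
#'   TRUE); FALSE skips it (the between-effect test is unaffected by
#'   sphericity).
#' @return Tibble of class `paf_anova`: `effect`, `df_num`, `df_den`, `f`,
#'   `p`, `ges`, `corrected`, `gg_epsilon`, `df_num_gg`, `df_den_gg`,
#'   `p_gg`; attributes `mauchly_w`, `mauchly_p`, `n_subjects`,
#'   `degenerate`.
#' @export
mixed_anova <- function(data, outcome, between = "sex", within = "task_type",
                        subject = "subject", sphericity = TRUE) {
  df <- data.frame(
    y = data[[outcome]],
    g = factor(data[[between]]),
    w = factor(data[[within]]),
    s = factor(data[[subject]])
  )
  if (anyNA(df$y) || any(!is.finite(df$y))) {
    df <- droplevels(df[is.finite(df$y), ])
  }
  k <- nlevels(df$w)
  complete <- names(which(tapply(df$w, df$s, function(x) {
    length(unique(x)) == k
  })))
  if (length(complete) < nlevels(df$s)) {
    warning(sprintf("%d subject(s) dropped: incomplete within-factor cells",
                    nlevels(df$s) - length(complete)), call. = FALSE)
    df <- droplevels(df[df$s %in% complete, ])
  }
  grp_of <- tapply(as.character(df$g), df$s, `[`, 1)
  if (min(table(grp_of)) < 2) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  n <- nlevels(df$s); g <- nlevels(df$g)
  degenerate <- stats::var(df$y) < .Machine$double.eps
  if (degenerate) {
    warning("constant outcome: F statistics undefined", call. = FALSE)
  }

  fit <- stats::aov(y ~ g * w + Error(s), data = df)
  sm <- summary(fit)
  btw <- as.data.frame(sm[["Error: s"]][[1]])
  wth <- as.data.frame(sm[["Error: Within"]][[1]])
  rn <- function(tab) trimws(rownames(tab))
  ss_err_s <- btw[rn(btw) == "Residuals", "Sum Sq"]
  ss_err_w <- wth[rn(wth) == "Residuals", "Sum Sq"]
  ss <- c(btw[rn(btw) == "g", "Sum Sq"],
          wth[rn(wth) == "w", "Sum Sq"],
          wth[rn(wth) == "g:w", "Sum Sq"])
  fstat <- c(btw[rn(btw) == "g", "F value"],
             wth[rn(wth) == "w", "F value"],
             wth[rn(wth) == "g:w", "F value"])
  pval <- c(btw[rn(btw) == "g", "Pr(>F)"],
            wth[rn(wth) == "w", "Pr(>F)"],
            wth[rn(wth) == "g:w", "Pr(>F)"])
  out <- tibble::tibble(
    effect = c(between, within, paste(between, within, sep = ":")),
    df_num = c(g - 1, k - 1, (g - 1) * (k - 1)),
    df_den = c(n - g, (k - 1) * (n - g), (k - 1) * (n - g)),
    f = if (degenerate) rep(NA_real_, 3) else fstat,
    p = if (degenerate) rep(NA_real_, 3) else pval,
    ges = if (degenerate) rep(NA_real_, 3) else {
      ss / (ss + ss_err_s + ss_err_w)
    },
    corrected = FALSE,
    gg_epsilon = NA_real_, df_num_gg = NA_real_, df_den_gg = NA_real_,
    p_gg = NA_real_
  )
  mw <- mp <- NA_real_
  if (sphericity && k > 2 && !degenerate) {
    wide <- stats::reshape(df[, c("s", "w", "y")], idvar = "s",
                           timevar = "w", direction = "wide")
    Y <- as.matrix(wide[, paste0("y.", levels(df$w))])
    grp <- grp_of[as.character(wide$s)]
    # pooled covariance of orthonormal within contrasts
    M <- stats::contr.helmert(k)
    M <- sweep(M, 2, sqrt(colSums(M^2)), "/")
    D <- Y %*% M
    resid <- D - apply(D, 2, function(col) {
      stats::ave(col, grp)
    })
    S <- crossprod(resid) / (n - g)
    eps <- sum(diag(S))^2 / ((k - 1) * sum(S^2))
    lW <- determinant(S)$modulus - (k - 1) * log(sum(diag(S)) / (k - 1))
    dfm <- k * (k - 1) / 2 - 1
    cc <- (n - g) - (2 * (k - 1)^2 + (k - 1) + 2) / (6 * (k - 1))
    chi <- -cc * as.numeric(lW)
    mw <- exp(as.numeric(lW))
    mp <- stats::pchisq(chi, dfm, lower.tail = FALSE)
    if (is.finite(mp) && mp < 0.05) {
      wrows <- 2:3
      out$corrected[wrows] <- TRUE
      out$gg_epsilon[wrows] <- eps
      out$df_num_gg[wrows] <- out$df_num[wrows] * eps
      out$df_den_gg[wrows] <- out$df_den[wrows] * eps
      out$p_gg[wrows] <- stats::pf(out$f[wrows], out$df_num_gg[wrows],
                                   out$df_den_gg[wrows], lower.tail = FALSE)
    } else {
      out$gg_epsilon[2:3] <- eps
    }
  }
  attr(out, "mauchly_w") <- mw
  attr(out, "mauchly_p") <- mp
  attr(out, "n_subjects") <- n
  attr(out, "degenerate") <- degenerate
  class(out) <- c("paf_anova", class(out))
  out
}

#' Tukey HSD pairwise comparisons with compact letter display
#'
#' All pairwise comparisons between cell means of a single factor using the
#' studentized range distribution, in the Tukey-Kramer form for unequal
#' cell sizes, with a compact letter display (cells sharing a letter are
#' not separated at the given alpha).
#'
#' @param data Data frame. @param outcome Outcome column name.
#' @param cell Factor column name defining the cells (>= 2 cells).
#' @param alpha Family-wise level (default 0.05).
#' @return List of class `tukey_result`: `pairs` (tibble: comparison,
#'   difference, q, p_adj) and `groups` (tibble: cell, mean, n, letters).
#' @export
tukey_hsd <- function(data, outcome, cell, alpha = 0.05) {
  y <- data[[outcome]]
  f <- factor(data[[cell]])
  kk <- nlevels(f)
  if (kk < 2) stop("need at least 2 cells", call. = FALSE)
  m <- tapply(y, f, mean)
  nn <- tapply(y, f, length)
  fit <- stats::lm(y ~ f)
  mse <- sum(stats::resid(fit)^2) / fit$df.residual
  dfres <- fit$df.residual
  cmb <- utils::combn(levels(f), 2)
  diffs <- m[cmb[2, ]] - m[cmb[1, ]]
  se <- sqrt(mse / 2 * (1 / nn[cmb[1, ]] + 1 / nn[cmb[2, ]]))
  qstat <- abs(diffs) / se
  padj <- stats::ptukey(qstat, kk, dfres, lower.tail = FALSE)
  pairs <- tibble::tibble(
    comparison = paste(cmb[2, ], cmb[1, ], sep = "-"),
    difference = as.numeric(diffs), q = as.numeric(qstat),
    p_adj = as.numeric(padj)
  )
  # greedy compact letter display over the "not separated" relation
  ord <- order(m)
  sep <- matrix(FALSE, kk, kk, dimnames = list(levels(f), levels(f)))
  for (i in seq_len(ncol(cmb))) {
    sep[cmb[1, i], cmb[2, i]] <- sep[cmb[2, i], cmb[1, i]] <- padj[i] < alpha
  }
  classes <- list()
  for (lv in levels(f)[ord]) {
    placed <- FALSE
    for (ci in seq_along(classes)) {
      if (!any(sep[lv, classes[[ci]]])) {
        classes[[ci]] <- c(classes[[ci]], lv)
        placed <- TRUE
      }
    }
    if (!placed) classes[[length(classes) + 1]] <- lv
  }
  letter_of <- vapply(levels(f), function(lv) {
    paste0(letters[which(vapply(classes, function(cl) lv %in% cl, TRUE))],
           collapse = "")
  }, "")
  groups <- tibble::tibble(cell = levels(f), mean = as.numeric(m),
                           n = as.integer(nn), letters = letter_of)
  structure(list(pairs = pairs, groups = groups, alpha = alpha),
            class = "tukey_result")
}

#' @export
print.tukey_result <- function(x, ...) {
  cat("Tukey HSD (alpha =", x$alpha, ")\n")
  print(x$groups)
  invisible(x)
}

#' Two-step hierarchical regression with F-change test
#'
#' Step 1 models the outcome by task type alone; step 2 adds PAF as an
#' interacting predictor. Two step-2 parameterizations are fitted: the full
#' interaction (PAF main effect plus PAF-by-task-type interactions, 4 added
#' parameters with 4 task types) and a pooled variant adding only a PAF
#' main effect and a single PAF-by-relative-task interaction (2 added
#' parameters). Each is compared to step 1 by a nested-model F test.
#'
#' Rows with missing or non-finite outcome or PAF values are dropped before
#' fitting.
#'
#' @param data Data frame of subject-by-task-type records for one group.
#' @param outcome Outcome column (e.g. accuracy). @param paf_col PAF
#'   predictor column. @param task_col Task-type factor column.
#' @return Tibble of class `paf_hreg`: one row per step-2 variant with
#'   `model`, `f_change`, `df_change_1`, `df_change_2`, `p_change`,
#'   `r_sq_step1`, `r_sq_step2`, `f_full`, `df_full_1`, `df_full_2`,
#'   `p_full`; fitted models in attribute `"fits"`.
#' @export
hierarchical_compare <- function(data, outcome, paf_col,
                                 task_col = "task_type") {
  df <- data.frame(y = data[[outcome]], task = factor(data[[task_col]]),
                   paf = data[[paf_col]])
  df <- df[is.finite(df$y) & is.finite(df$paf), ]
  if (any(table(df$task) < 2)) {
    stop("need at least 2 observations per task type", call. = FALSE)
  }
  if (stats::var(df$paf) < .Machine$double.eps) {
    stop("PAF predictor is constant: step-2 fit is singular", call. = FALSE)
  }
  df$relative <- grepl("R$", as.character(df$task))
  m1 <- stats::lm(y ~ task, data = df)
  m2_full <- stats::lm(y ~ task * paf, data = df)
  m2_pooled <- stats::lm(y ~ task + paf + paf:relative, data = df)
  row_for <- function(m2, label) {
    cmp <- stats::anova(m1, m2)
    s1 <- summary(m1); s2 <- summary(m2)
    tibble::tibble(
      model = label,
      f_change = cmp$F[2], df_change_1 = cmp$Df[2],
      df_change_2 = cmp$Res.Df[2], p_change = cmp$`Pr(>F)`[2],
      r_sq_step1 = s1$r.squared, r_sq_step2 = s2$r.squared,
      f_full = s2$fstatistic[1], df_full_1 = s2$fstatistic[2],
      df_full_2 = s2$fstatistic[3],
      p_full = stats::pf(s2$fstatistic[1], s2$fstatistic[2],
                         s2$fstatistic[3], lower.tail = FALSE)
    )
  }
  out <- dplyr::bind_rows(row_for(m2_full, "full_interaction"),
                          row_for(m2_pooled, "pooled_interaction"))
  attr(out, "fits") <- list(step1 = m1, full_interaction = m2_full,
                            pooled_interaction = m2_pooled)
  class(out) <- c("paf_hreg", class(out))
  out
}

#' Accuracy-PAF correlation table by sex, task type and window
#'
#' Pearson correlations between accuracy and PAF for each sex x task-type
#' cell and PAF window, with uncorrected p-values and FDR-adjusted
#' p-values (adjusted across task types within each sex x window family)
#' reported side by side.
#'
#' @param cohort Long cohort table with columns `sex`, `task_type`,
#'   `accuracy`, and one PAF column per window.
#' @param paf_cols Named character vector: window label -> column name.
#' @return Tibble: `window`, `sex`, `task_type`, `r`, `n`, `p`, `p_fdr`.
#' @export
paf_accuracy_correlations <- function(cohort,
                                      paf_cols = c(pretest = "paf_pretest",
                                                   baseline = "paf_baseline",
                                                   maintenance = "paf_maintenance")) {
  out <- purrr::imap_dfr(paf_cols, function(col, win) {
    cohort |>
      dplyr::group_by(.data$sex, .data$task_type) |>
      dplyr::summarise(
        r = stats::cor(.data$accuracy, .data[[col]],
                       use = "complete.obs"),
        n = sum(stats::complete.cases(.data$accuracy, .data[[col]])),
        .groups = "drop"
      ) |>
      dplyr::mutate(window = win,
                    p = 2 * stats::pt(-abs(.data$r) *
                                        sqrt((.data$n - 2) / (1 - .data$r^2)),
                                      .data$n - 2))
  })
  out |>
    dplyr::group_by(.data$window, .data$sex) |>
    dplyr::mutate(p_fdr = fdr_adjust(.data$p)) |>
    dplyr::ungroup() |>
    dplyr::select("window", "sex", "task_type", "r", "n", "p", "p_fdr")
}
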