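# long-format cohort table with k = 4 task types per subject
make_long <- function(n_f = 77, n_m = 33, seed = 1,
                      sex_effect = 0, task_effect = c(0, 0, 0, 0)) {
  set.seed(seed)
  subj <- sprintf("S%03d", seq_len(n_f + n_m))
  sex <- c(rep("F", n_f), rep("M", n_m))
  tasks <- c("2P", "2R", "3P", "3R")
  re <- rnorm(length(subj), sd = 0.5)
  tidyr::expand_grid(subject = subj, task_type = tasks) |>
    dplyr::mutate(
      sex = sex[match(subject, subj)],
      accuracy = 0.8 + (sex == "F") * sex_effect +
        task_effect[match(task_type, tasks)] +
        re[match(subject, subj)] * 0.1 + rnorm(dplyr::n(), sd = 0.05)
    )
}

test_that("mixed ANOVA reports the design degrees of freedom for 77F/33M", {
  res <- mixed_anova(make_long(), "accuracy")
  expect_equal(res$df_num, c(1, 3, 3))
  expect_equal(res$df_den, c(108, 324, 324))
  expect_equal(res$effect, c("sex", "task_type", "sex:task_type"))
  expect_true(all(res$ges >= 0 & res$ges <= 1))
  expect_equal(attr(res, "n_subjects"), 110)
})

test_that("mixed ANOVA F and p match aov on the same data", {
  d <- make_long(n_f = 20, n_m = 15, seed = 3, sex_effect = 0.05,
                 task_effect = c(0, 0.02, -0.05, 0.01))
  res <- mixed_anova(d, "accuracy", sphericity = FALSE)
  fit <- stats::aov(accuracy ~ sex * task_type + Error(factor(subject)),
                    data = d)
  sm <- summary(fit)
  btw <- as.data.frame(sm[["Error: factor(subject)"]][[1]])
  wth <- as.data.frame(sm[["Error: Within"]][[1]])
  expect_equal(res$f[1], btw["sex", "F value"][1], ignore_attr = TRUE)
  expect_equal(res$f[2:3], wth[1:2, "F value"], ignore_attr = TRUE)
  expect_equal(res$p, c(btw[1, "Pr(>F)"], wth[1:2, "Pr(>F)"]),
               ignore_attr = TRUE)
})

test_that("mixed ANOVA detects a pure between-group effect", {
  res <- mixed_anova(make_long(seed = 5, sex_effect = 0.15), "accuracy")
  expect_lt(res$p[res$effect == "sex"], 1e-6)
  expect_gt(res$p[res$effect == "task_type"], 0.01)
})

test_that("mixed ANOVA degenerate and incomplete inputs are handled", {
  d <- make_long(n_f = 6, n_m = 6)
  d$accuracy <- 0.5
  expect_warning(res <- mixed_anova(d, "accuracy"), "constant outcome")
  expect_true(all(is.na(res$f)))
  expect_true(attr(res, "degenerate"))
  # subject with a missing cell is dropped listwise
  d2 <- make_long(n_f = 6, n_m = 6, seed = 2)
  d2 <- d2[!(d2$subject == "S001" & d2$task_type == "3R"), ]
  expect_warning(res2 <- mixed_anova(d2, "accuracy"), "dropped")
  expect_equal(attr(res2, "n_subjects"), 11)
  expect_equal(res2$df_den[1], 9)
  # one subject per group is refused
  d3 <- make_long(n_f = 1, n_m = 1)
  expect_error(mixed_anova(d3, "accuracy"), "at least 2 subjects")
})

test_that("Greenhouse-Geisser machinery engages only when Mauchly rejects", {
  # strongly non-spherical: one task type has far larger variance
  set.seed(7)
  d <- make_long(n_f = 30, n_m = 20, seed = 7)
  bump <- rnorm(50, sd = 1.5)
  d$accuracy[d$task_type == "3R"] <-
    d$accuracy[d$task_type == "3R"] + bump[match(d$subject[d$task_type == "3R"],
                                                 unique(d$subject))]
  res <- mixed_anova(d, "accuracy")
  expect_lt(attr(res, "mauchly_p"), 0.05)
  expect_true(all(res$corrected[2:3]))
  eps <- res$gg_epsilon[2]
  expect_gte(eps, 1 / 3)          # lower bound 1/(k-1)
  expect_lte(eps, 1 + 1e-9)
  expect_equal(res$df_num_gg[2], 3 * eps)
  expect_equal(res$df_den_gg[2], res$df_den[2] * eps)
  # spherical data (compound symmetric): no correction applied
  res2 <- mixed_anova(make_long(n_f = 40, n_m = 30, seed = 8), "accuracy")
  expect_false(any(res2$corrected))
})

test_that("Tukey HSD matches TukeyHSD and separates only distinct cells", {
  set.seed(9)
  d <- data.frame(task = rep(c("2P", "2R", "3P", "3R"), each = 25),
                  y = rnorm(100, sd = 0.04))
  d$y[d$task == "3P"] <- d$y[d$task == "3P"] - 0.2   # clearly lower cell
  res <- tukey_hsd(d, "y", "task")
  base <- stats::TukeyHSD(stats::aov(y ~ task, data = d))$task
  key <- rownames(base)
  expect_equal(res$pairs$p_adj[match(key, res$pairs$comparison)],
               unname(base[, "p adj"]), tolerance = 1e-10)
  expect_equal(res$pairs$difference[match(key, res$pairs$comparison)],
               unname(base[, "diff"]), tolerance = 1e-12)
  g <- res$groups
  l3p <- g$letters[g$cell == "3P"]
  others <- g$letters[g$cell != "3P"]
  # 3P shares no letter with any other cell; the rest share one
  expect_true(all(!vapply(strsplit(others, ""), function(ch) {
    any(ch %in% strsplit(l3p, "")[[1]])
  }, TRUE)))
  shared <- Reduce(intersect, strsplit(others, ""))
  expect_gte(length(shared), 1)
  # identical cells are never separated
  d0 <- data.frame(task = rep(c("a", "b", "c"), each = 20),
                   y = rnorm(60))
  g0 <- tukey_hsd(d0, "y", "task")$groups
  expect_length(unique(g0$letters), 1)
  expect_error(tukey_hsd(data.frame(task = "a", y = 1), "y", "task"),
               "at least 2 cells")
})

test_that("hierarchical regression has the published degrees of freedom", {
  set.seed(10)
  n <- 33                                   # male-group size
  d <- tidyr::expand_grid(subject = seq_len(n),
                          task_type = c("2P", "2R", "3P", "3R"))
  paf <- rnorm(n, 10.4, 1.2)
  d$paf <- paf[d$subject]
  d$accuracy <- 0.8 + 0.02 * (d$paf - 10.4) * grepl("R$", d$task_type) +
    rnorm(nrow(d), sd = 0.05)
  res <- hierarchical_compare(d, "accuracy", "paf")
  full <- res[res$model == "full_interaction", ]
  pooled <- res[res$model == "pooled_interaction", ]
  # full step-2 model: F(7, 124); change test F(4, 124)
  expect_equal(unname(full$df_full_1), 7)
  expect_equal(unname(full$df_full_2), 124)
  expect_equal(full$df_change_1, 4)
  expect_equal(full$df_change_2, 124)
  # pooled variant adds 2 parameters: change test F(2, 126)... no:
  # y ~ task + paf + paf:relative has 6 parameters -> residual df 126
  expect_equal(pooled$df_change_1, 2)
  expect_equal(pooled$df_change_2, 126)
  # step 2 never explains less variance than step 1
  expect_gte(full$r_sq_step2, full$r_sq_step1)
  expect_gte(pooled$r_sq_step2, pooled$r_sq_step1)
  # F-change agrees with the direct nested-model computation
  fits <- attr(res, "fits")
  rss1 <- sum(resid(fits$step1)^2)
  rss2 <- sum(resid(fits$full_interaction)^2)
  expect_equal(full$f_change, ((rss1 - rss2) / 4) / (rss2 / 124),
               tolerance = 1e-12)
  # constant predictor is refused
  d$paf <- 10
  expect_error(hierarchical_compare(d, "accuracy", "paf"), "constant")
})

test_that("correlation table computes r, p and within-family FDR", {
  set.seed(11)
  n <- 40
  coh <- tidyr::expand_grid(subject = seq_len(n),
                            task_type = c("2P", "2R", "3P", "3R")) |>
    dplyr::mutate(sex = ifelse(subject <= 28, "F", "M"),
                  paf_baseline = rnorm(dplyr::n(), 10.4),
                  paf_maintenance = rnorm(dplyr::n(), 10.6),
                  paf_pretest = rnorm(dplyr::n(), 10.5),
                  accuracy = 0.8 + 0.05 * paf_baseline + rnorm(dplyr::n(), 0, 0.2))
  tab <- paf_accuracy_correlations(coh)
  expect_equal(nrow(tab), 3 * 2 * 4)       # windows x sex x task types
  one <- tab[tab$window == "baseline" & tab$sex == "F" & tab$task_type == "2P", ]
  sub <- coh[coh$sex == "F" & coh$task_type == "2P", ]
  ct <- stats::cor.test(sub$accuracy, sub$paf_baseline)
  expect_equal(one$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(one$p, ct$p.value, tolerance = 1e-12)
  # FDR adjusted within each sex-by-window family of 4 task types
  fam <- tab[tab$window == "baseline" & tab$sex == "F", ]
  expect_equal(fam$p_fdr, fdr_adjust(fam$p))
})
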