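#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a mixed ANOVA table
#'
#' @param x A `paf_anova`. @param ... Unused.
#' @return The effect table as a plain tibble (`term` naming the effect).
#' @export
tidy.paf_anova <- function(x, ...) {
  out <- tibble::as_tibble(x)
  dplyr::rename(out, term = "effect", statistic = "f", p.value = "p")
}

#' One-line summary of a mixed ANOVA
#'
#' @param x A `paf_anova`. @param ... Unused.
#' @return Tibble with subject count, Mauchly statistics and degeneracy
#'   flag.
#' @export
glance.paf_anova <- function(x, ...) {
  tibble::tibble(
    n_subjects = attr(x, "n_subjects"),
    mauchly_w = attr(x, "mauchly_w"),
    mauchly_p = attr(x, "mauchly_p"),
    degenerate = attr(x, "degenerate")
  )
}

#' Tidy a shift function
#'
#' @param x A `shift_result`. @param ... Unused.
#' @return Plain tibble of deciles, differences and simultaneous CIs.
#' @export
tidy.shift_result <- function(x, ...) tibble::as_tibble(x)

#' One-line summary of a shift function
#'
#' @param x A `shift_result`. @param ... Unused.
#' @return Tibble with bootstrap settings, calibrated per-decile level, and
#'   number of significant deciles.
#' @export
glance.shift_result <- function(x, ...) {
  tibble::tibble(
    n_boot = attr(x, "n_boot"), alpha = attr(x, "alpha"),
    gamma = attr(x, "gamma"), seed = attr(x, "seed"),
    n_significant = sum(x$significant)
  )
}

#' Tidy a two-sample KS test
#'
#' @param x A `ks_result`. @param ... Unused.
#' @return Tibble with `statistic`, `p.value`, sample sizes and method.
#' @export
tidy.ks_result <- function(x, ...) {
  tibble::tibble(statistic = x$d, p.value = x$p, n_x = x$n_x, n_y = x$n_y,
                 method = x$method)
}

#' Tidy a hierarchical regression comparison
#'
#' @param x A `paf_hreg`. @param ... Unused.
#' @return Plain tibble, one row per step-2 variant.
#' @export
tidy.paf_hreg <- function(x, ...) tibble::as_tibble(x)

#' One-line-per-variant summary of a hierarchical regression
#'
#' @param x A `paf_hreg`. @param ... Unused.
#' @return Tibble with the step-1 and step-2 R-squared and the F-change
#'   test per variant.
#' @export
glance.paf_hreg <- function(x, ...) {
  tibble::as_tibble(x)[, c("model", "r_sq_step1", "r_sq_step2",
                           "f_change", "p_change")]
}
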