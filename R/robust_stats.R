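#' Harrell-Davis quantile estimator
#'
#' Estimates the `q`-th quantile as a weighted sum of all order statistics,
#' with weights given by successive increments of the Beta((n+1)q,
#' (n+1)(1-q)) distribution function evaluated at i/n. Smooth in the data,
#' which makes bootstrap inference on quantile differences well behaved.
#'
#' @param x Numeric vector (n >= 2). @param q Quantile level in (0, 1);
#'   may be a vector.
#' @return Estimate(s), one per level.
#' @export
hd_quantile <- function(x, q) {
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
  if (any(q <= 0 | q >= 1)) stop("q must lie in (0, 1)", call. = FALSE)
  drop(hd_weight_matrix(length(x), q) %*% sort(x))
}

# rows = levels, cols = order statistics
hd_weight_matrix <- function(n, q) {
  grid <- (0:n) / n
  t(vapply(q, function(qq) {
    diff(stats::pbeta(grid, (n + 1) * qq, (n + 1) * (1 - qq)))
  }, numeric(n)))
}

#' Shift function between two independent samples
#'
#' Compares the Harrell-Davis deciles of `x` and `y`: the shift at each
#' decile is `hd(x, d) - hd(y, d)`. Simultaneous (1 - alpha) confidence
#' intervals come from a seeded percentile bootstrap (independent
#' resampling of the two groups) whose per-decile coverage level is
#' calibrated so that the joint bootstrap coverage across all deciles
#' reaches the nominal level. A decile is flagged significant when its
#' adjusted interval excludes zero.
#'
#' The difference orientation is first sample minus second; in a
#' female-vs-male comparison pass the female sample as `x` so positive
#' shifts mean larger female quantiles.
#'
#' @param x,y Numeric samples (each n >= 10 recommended; smaller samples
#'   trigger a warning and deciles outside the data support are refused).
#' @param deciles Quantile levels (default 0.1 ... 0.9).
#' @param n_boot Bootstrap replicates (default 2000; < 200 warns).
#' @param alpha Joint type-I level (default 0.05).
#' @param seed Integer seed for the bootstrap.
#' @return A tibble of class `shift_result`: `decile`, `q_x`, `q_y`,
#'   `difference`, `ci_low`, `ci_high`, `significant`; attributes `n_boot`,
#'   `seed`, `alpha`, `gamma` (calibrated per-decile level) and
#'   `orientation`.
#' @export
shift_function <- function(x, y, deciles = seq(0.1, 0.9, by = 0.1),
                           n_boot = 2000, alpha = 0.05, seed = 1L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (min(nx, ny) < 10) {
    warning("fewer than 10 observations in a group: restricting deciles to the data support",
            call. = FALSE)
    lim <- 1 / (min(nx, ny) + 1)
    deciles <- deciles[deciles > lim & deciles < 1 - lim]
    if (!length(deciles)) stop("no estimable deciles", call. = FALSE)
  }
  if (n_boot < 200) {
    warning("n_boot < 200 gives unstable simultaneous bounds", call. = FALSE)
  }
  Wx <- hd_weight_matrix(nx, deciles)
  Wy <- hd_weight_matrix(ny, deciles)
  qx <- drop(Wx %*% sort(x)); qy <- drop(Wy %*% sort(y))
  diff_hat <- qx - qy

  set.seed(seed)
  bx <- matrix(sample(x, nx * n_boot, replace = TRUE), nx)
  by <- matrix(sample(y, ny * n_boot, replace = TRUE), ny)
  bx <- apply(bx, 2, sort); by <- apply(by, 2, sort)
  dboot <- Wx %*% bx - Wy %*% by              # deciles x n_boot

  cover <- function(gam) {
    lo <- apply(dboot, 1, stats::quantile, probs = gam / 2)
    hi <- apply(dboot, 1, stats::quantile, probs = 1 - gam / 2)
    inside <- dboot >= lo & dboot <= hi
    mean(colSums(inside) == nrow(dboot))
  }
  # calibrate the per-decile level so the joint bootstrap coverage is 1-alpha
  lo_g <- alpha / (10 * length(deciles)); hi_g <- alpha
  gam <- alpha
  if (cover(hi_g) < 1 - alpha) {
    for (it in 1:25) {
      gam <- (lo_g + hi_g) / 2
      if (cover(gam) >= 1 - alpha) lo_g <- gam else hi_g <- gam
    }
    gam <- lo_g
  }
  ci_low <- apply(dboot, 1, stats::quantile, probs = gam / 2)
  ci_high <- apply(dboot, 1, stats::quantile, probs = 1 - gam / 2)

  out <- tibble::tibble(
    decile = deciles, q_x = qx, q_y = qy, difference = diff_hat,
    ci_low = ci_low, ci_high = ci_high,
    significant = ci_low > 0 | ci_high < 0
  )
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- seed
  attr(out, "alpha") <- alpha
  attr(out, "gamma") <- gam
  attr(out, "orientation") <- "x - y at matching deciles"
  class(out) <- c("shift_result", class(out))
  out
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum over the pooled support of the absolute difference of
#' the two empirical distribution functions. The p-value uses the two-sided
#' asymptotic KS distribution with effective size `n_x n_y / (n_x + n_y)`;
#' for small untied samples (both n <= 25) the exact distribution is used
#' instead.
#'
#' @param x,y Numeric samples (non-empty).
#' @return List of class `ks_result`: `d`, `p`, `n_x`, `n_y`, `method`.
#' @export
ks_2samp <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  v <- sort(unique(c(x, y)))
  d <- max(abs(stats::ecdf(x)(v) - stats::ecdf(y)(v)))
  ties <- any(duplicated(c(x, y)))
  if (max(length(x), length(y)) <= 25 && !ties) {
    p <- stats::ks.test(x, y, exact = TRUE)$p.value
    method <- "exact"
  } else {
    ne <- length(x) * length(y) / (length(x) + length(y))
    lambda <- sqrt(ne) * d
    k <- 1:100
    p <- min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))))
    method <- "asymptotic"
  }
  structure(list(d = d, p = p, n_x = length(x), n_y = length(y),
                 method = method), class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Two-sample KS test: D = %.3f, p = %.4g (%s; n = %d, %d)\n",
              x$d, x$p, x$method, x$n_x, x$n_y))
  invisible(x)
}

#' Compare two independent Pearson correlations (Fisher r-to-z)
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided normal p-value. Antisymmetric in the two groups.
#'
#' @param r1,r2 Correlations with `|r| < 1`. @param n1,n2 Sample sizes
#'   (> 3).
#' @return Tibble with `z` and `p`.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) stop("need n > 3 in both groups", call. = FALSE)
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("|r| = 1: Fisher transform is infinite", call. = FALSE)
  }
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble::tibble(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1), via
#' [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order.
#' @export
fdr_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}
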