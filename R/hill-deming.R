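# Hill (sigmoidal) fits of phosphorylation versus kinase activity, and
# Deming errors-in-variables regression.

#' Hill fit of phospho fraction versus kinase activity
#'
#' Least squares of
#'   phospho = baseline + amplitude * a^n / (K^n + a^n)
#' on single cells, or on binned medians of the activity axis (robust to the
#' heavy single-cell scatter of immunofluorescence). The Hill coefficient n
#' measures the ultrasensitivity of site phosphorylation with respect to
#' kinase activity; K is the half-maximal activity.
#'
#' @param activity per-cell kinase (CDK2) activity, dimensionless ratio.
#' @param phospho per-cell normalized phospho fraction.
#' @param binned if `TRUE`, fit on medians of `n_bins` equal-count activity
#'   bins instead of single cells.
#' @param n_bins number of bins when `binned = TRUE`.
#' @param n_max upper bound for the Hill coefficient (default 20).
#' @return object of class `hill_fit`: `n`, `K`, `baseline`, `amplitude`,
#'   standard errors, and the underlying `nls` fit.
#' @export
fit_hill <- function(activity, phospho, binned = FALSE, n_bins = 25,
                     n_max = 20) {
  stopifnot(length(activity) == length(phospho))
  ok <- is.finite(activity) & is.finite(phospho)
  a <- activity[ok]; p <- phospho[ok]
  if (length(a) < 10) stop("too few cells for a Hill fit")
  if (diff(range(a)) <= 0) stop("degenerate activity range")
  if (binned) {
    br <- stats::quantile(a, probs = seq(0, 1, length.out = n_bins + 1))
    br <- unique(br)
    grp <- cut(a, br, include.lowest = TRUE)
    am <- tapply(a, grp, stats::median)
    pm <- tapply(p, grp, stats::median)
    a <- as.numeric(am); p <- as.numeric(pm)
  }
  base0 <- unname(stats::quantile(p, 0.05))
  amp0 <- unname(stats::quantile(p, 0.95)) - base0
  if (amp0 <= 0) amp0 <- diff(range(p)) + 1e-6
  K0 <- stats::median(a)
  # the RSS surface in n has local minima; multi-start over n and keep the
  # best fit
  fit <- NULL
  best_rss <- Inf
  for (n0 in c(1, 2, 4, 8, 14)) {
    f <- try(minpack.lm::nlsLM(
      p ~ b + A * a^n / (K^n + a^n),
      start = list(b = base0, A = amp0, K = K0, n = min(n0, n_max)),
      lower = c(-Inf, 0, min(a[a > 0]), 1e-3),
      upper = c(Inf, Inf, max(a), n_max),
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    if (inherits(f, "try-error")) next
    rss <- sum(stats::resid(f)^2)
    if (rss < best_rss) { best_rss <- rss; fit <- f }
  }
  if (is.null(fit)) stop("Hill fit failed from all starting values")
  sm <- summary(fit)$coefficients
  structure(list(n = unname(sm["n", "Estimate"]),
                 K = unname(sm["K", "Estimate"]),
                 baseline = unname(sm["b", "Estimate"]),
                 amplitude = unname(sm["A", "Estimate"]),
                 n_se = unname(sm["n", "Std. Error"]),
                 K_se = unname(sm["K", "Std. Error"]),
                 n_cells = sum(ok), binned = binned, fit = fit),
            class = "hill_fit")
}

#' Deming errors-in-variables regression
#'
#' Orthogonal-type regression for the case where both axes carry
#' measurement error, with error-variance ratio delta = var(err_y) /
#' var(err_x) (delta = 1 for two equally noisy fluorescence axes). Slope:
#'   slope = (s_yy - delta s_xx + sqrt((s_yy - delta s_xx)^2
#'            + 4 delta s_xy^2)) / (2 s_xy)
#' intercept through the means; slope standard error by leave-one-out
#' jackknife.
#'
#' @param x,y paired measurements.
#' @param delta error-variance ratio (default 1).
#' @param jackknife if `TRUE` (default) estimate the slope s.e. by
#'   leave-one-out jackknife.
#' @return object of class `deming_fit`: `slope`, `intercept`, `slope_se`,
#'   `delta`, `n`.
#' @export
deming_fit <- function(x, y, delta = 1, jackknife = TRUE) {
  stopifnot(length(x) == length(y), delta > 0)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 points")
  slope_of <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sxx <- mean((x - mx)^2); syy <- mean((y - my)^2)
    sxy <- mean((x - mx) * (y - my))
    if (sxy == 0) stop("s_xy = 0: regression orientation undefined")
    (syy - delta * sxx + sqrt((syy - delta * sxx)^2 + 4 * delta * sxy^2)) /
      (2 * sxy)
  }
  slope <- slope_of(x, y)
  intercept <- mean(y) - slope * mean(x)
  slope_se <- NA_real_
  if (jackknife && n > 3) {
    loo <- vapply(seq_len(n),
                  function(i) slope_of(x[-i], y[-i]), numeric(1))
    # jackknife variance of the slope estimator
    slope_se <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  }
  structure(list(slope = slope, intercept = intercept, slope_se = slope_se,
                 delta = delta, n = n), class = "deming_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "Hill fit%s: n = %.3g +/- %.2g, K = %.3g +/- %.2g, baseline = %.3g, amplitude = %.3g (%d cells)\n",
    if (x$binned) " (binned medians)" else "",
    x$n, x$n_se, x$K, x$K_se, x$baseline, x$amplitude, x$n_cells))
  invisible(x)
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf(
    "Deming regression (delta = %g): slope = %.4g +/- %.2g, intercept = %.4g, n = %d\n",
    x$delta, x$slope, x$slope_se, x$intercept, x$n))
  invisible(x)
}
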