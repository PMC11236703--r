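# Normalization of phospho-site immunofluorescence signals and the PSP fit.

#' Normalize phospho signals to per-cell fractions
#'
#' Each cell's phospho-site signal is divided by its total-Rb signal in the
#' same cell, and the resulting ratio is scaled so that the mean ratio over
#' S-phase cells (where Rb is hyperphosphorylated, i.e. the site is fully
#' occupied) equals 1. The result is interpretable as a phosphorylated
#' fraction.
#'
#' @param phospho phospho-site signal per cell (a.u.), non-negative.
#' @param total total-Rb signal per cell (a.u.); cells with non-positive
#'   total are flagged `NA` and excluded from the S-phase mean.
#' @param s_phase logical flag per cell; at least one `TRUE` with a valid
#'   total is required.
#' @return numeric vector of normalized fractions (S-phase mean = 1);
#'   attribute `"s_phase_mean"` records the raw S-phase mean ratio.
#' @export
normalize_phospho <- function(phospho, total, s_phase) {
  stopifnot(length(phospho) == length(total),
            length(phospho) == length(s_phase))
  bad <- !is.finite(total) | total <= 0
  ratio <- phospho / total
  ratio[bad] <- NA_real_
  s_ok <- s_phase & !bad
  if (!any(s_ok)) stop("no S-phase cells with valid total-Rb signal")
  s_mean <- mean(ratio[s_ok])
  if (!is.finite(s_mean) || s_mean <= 0)
    stop("S-phase mean ratio is not positive; cannot normalize")
  out <- ratio / s_mean
  attr(out, "s_phase_mean") <- s_mean
  out
}

#' Fit the PSP coefficient to paired phosphorylated fractions
#'
#' Nonlinear least squares of y on [psp_curve()] over cell pairs whose
#' normalized fractions fall inside the fit window on both axes
#' (default 0.1 <= x <= 0.9 and 0.1 <= y <= 0.9, excluding the saturated
#' tails where the curve carries no information about the coefficient).
#'
#' @param x,y paired normalized phosphorylated fractions (site x is the
#'   preferentially phosphorylated site, y the reference site).
#' @param window length-2 numeric, fit window applied to both axes.
#' @param min_n minimum number of in-window pairs required (default 10).
#' @return an object of class `psp_fit`: list with `coeff`, `se`, `n`,
#'   `window` and the underlying `nls` fit.
#' @export
fit_psp <- function(x, y, window = c(0.1, 0.9), min_n = 10) {
  stopifnot(length(x) == length(y), length(window) == 2, window[1] < window[2])
  keep <- is.finite(x) & is.finite(y) &
    x >= window[1] & x <= window[2] &
    y >= window[1] & y <= window[2]
  n <- sum(keep)
  if (n < min_n)
    stop(sprintf("only %d pairs inside the fit window (need >= %d)", n, min_n))
  dat <- data.frame(x = x[keep], y = y[keep])
  fit <- minpack.lm::nlsLM(
    y ~ x / (coeff + (1 - coeff) * x),
    data = dat, start = list(coeff = 1),
    lower = 1e-6, control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- summary(fit)$coefficients
  structure(list(coeff = unname(est["coeff", "Estimate"]),
                 se = unname(est["coeff", "Std. Error"]),
                 n = n, window = window, fit = fit),
            class = "psp_fit")
}

#' @export
print.psp_fit <- function(x, ...) {
  cat(sprintf("PSP fit: coeff = %.4g +/- %.2g (s.e.), n = %d in window [%g, %g]\n",
              x$coeff, x$se, x$n, x$window[1], x$window[2]))
  invisible(x)
}
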