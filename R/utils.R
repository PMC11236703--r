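# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Micrometre-to-pixel conversions use commercial rounding (half away from
#' zero) rather than banker's rounding, so that e.g. 2.5 px -> 3 px.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Convert a length in micrometres to pixels
#'
#' @param um length in micrometres.
#' @param pixel_size pixel size in micrometres per pixel; must be > 0.
#' @param integer if `TRUE` (default) round half away from zero to an
#'   integer pixel count, otherwise return the continuous value.
#' @return pixels (integer or numeric).
#' @export
um_to_px <- function(um, pixel_size, integer = TRUE) {
  stopifnot(is.numeric(um), is.numeric(pixel_size), pixel_size > 0)
  px <- um / pixel_size
  if (integer) round_half_up(px) else px
}

# Running 3-point median used to denoise single-cell traces before event
# detection; endpoints are kept as-is (runmed "keep" rule).
smooth3 <- function(x) {
  if (length(x) < 3) return(x)
  as.numeric(stats::runmed(x, k = 3, endrule = "keep"))
}

# Multiplicative log-normal noise with a given coefficient of variation.
# Mean of the factor is 1 for any cv; cv = 0 returns exact 1s.
lnorm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Standard error of the mean, NA-safe.
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# Bilinear interpolation of a coarse grid (values at centres cx, cy) onto
# the full pixel grid of size nr x nc. Edges are extended (constant).
interp_grid <- function(vals, cy, cx, nr, nc) {
  # interpolate along rows first, then columns
  rows <- matrix(0, nrow = nr, ncol = length(cx))
  for (j in seq_along(cx)) {
    rows[, j] <- stats::approx(cy, vals[, j], xout = seq_len(nr),
                               rule = 2)$y
  }
  out <- matrix(0, nrow = nr, ncol = nc)
  for (i in seq_len(nr)) {
    out[i, ] <- stats::approx(cx, rows[i, ], xout = seq_len(nc),
                              rule = 2)$y
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
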