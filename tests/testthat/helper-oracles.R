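# Independent oracles used across tests; deliberately naive implementations
# that do not share code with the package.

# Brute-force grayscale morphology with a Euclidean-ball structuring
# element: erosion (min), dilation (max), white top-hat (img - opening).
ref_white_tophat <- function(img, r) {
  off <- -r:r
  sel <- which(outer(off^2, off^2, "+") <= r^2, arr.ind = TRUE)
  dy <- off[sel[, 1]]; dx <- off[sel[, 2]]
  nr <- nrow(img); nc <- ncol(img)
  apply_se <- function(x, fun, pad) {
    out <- matrix(pad, nr, nc)
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        ys <- i + dy; xs <- j + dx
        ok <- ys >= 1 & ys <= nr & xs >= 1 & xs <= nc
        out[i, j] <- fun(x[cbind(ys[ok], xs[ok])])
      }
    }
    out
  }
  er <- apply_se(img, min, Inf)
  op <- apply_se(er, max, -Inf)
  img - op
}

# Suprathreshold footprint (pixel count) of a single Gaussian spot centred
# on a pixel, after reference top-hat filtering.
ref_spot_footprint <- function(amplitude, sigma_px, kernel_r, threshold,
                               half = 15) {
  off <- -half:half
  g <- amplitude * exp(-outer(off^2, off^2, "+") / (2 * sigma_px^2))
  th <- ref_white_tophat(g, kernel_r)
  sum(th > threshold)
}

# Exact single-site relaxation used to cross-check trajectory code.
ref_relax <- function(alpha, beta, z0, t) {
  zeq <- alpha / (alpha + beta)
  zeq + (z0 - zeq) * exp(-(alpha + beta) * t)
}

# Reshape a long decay table (site filtered) to time x replicate matrix.
decay_wide <- function(d) {
  w <- stats::reshape(d[, c("time", "replicate", "value")],
                      direction = "wide", idvar = "time",
                      timevar = "replicate")
  list(time = w$time, values = as.matrix(w[, -1, drop = FALSE]))
}

# Fit one site of a decay table with the package fitter.
fit_decay_site <- function(tab, site, ...) {
  w <- decay_wide(tab[tab$site == site, ])
  fit_exp_decay(w$time, w$values, ...)
}
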