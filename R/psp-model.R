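# Two-site phosphorylation-dephosphorylation kinetics and the equilibrium
# phosphorylation-site-preference (PSP) curve.
#
# Each Rb site is modelled as a two-state (phospho / dephospho) species:
#   dx/dt = alpha1 (1 - x) - beta1 x     (site x, e.g. T373)
#   dy/dt = alpha2 (1 - y) - beta2 y     (site y, e.g. S807/S811)
# with alpha the per-site phosphorylation rate and beta the per-site
# dephosphorylation rate (min^-1). Under kinase non-selectivity
# (alpha1 == alpha2) the equilibrium fractions of the two sites trace a
# one-parameter curve whose coefficient is the dephosphorylation-rate ratio
# beta2 / beta1 ("PSP coefficient").

#' Kinetic parameters of the two-site model
#'
#' @param alpha1,alpha2 phosphorylation rates (min^-1), >= 0.
#' @param beta1,beta2 dephosphorylation rates (min^-1), >= 0.
#' @return an object of class `kinetic_params`.
#' @export
kinetic_params <- function(alpha1, alpha2 = alpha1, beta1, beta2) {
  rates <- c(alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1, beta2 = beta2)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and >= 0")
  structure(as.list(rates), class = "kinetic_params")
}

#' Equilibrium phosphorylated fraction of a single site
#'
#' Setting dx/dt = 0 in `alpha (1 - x) - beta x` gives x = alpha/(alpha+beta).
#'
#' @param alpha phosphorylation rate (min^-1).
#' @param beta dephosphorylation rate (min^-1).
#' @return equilibrium fraction in \[0, 1\]. Vectorized over both arguments.
#' @export
equilibrium_fraction <- function(alpha, beta) {
  stopifnot(all(alpha >= 0), all(beta >= 0))
  tot <- alpha + beta
  if (any(tot == 0)) stop("equilibrium undefined when alpha + beta == 0")
  alpha / tot
}

#' Simulate the two-site kinetic model
#'
#' Each site relaxes independently and linearly, so the exact solution
#' x(t) = x_eq + (x0 - x_eq) exp(-(alpha + beta) t) is used (no integrator
#' error). When a rate pair is all-zero the site stays at its initial value.
#'
#' @param params a [kinetic_params()] object.
#' @param x0,y0 initial phosphorylated fractions in \[0, 1\].
#' @param times numeric vector of times (min), non-negative.
#' @return data.frame with columns `time`, `x`, `y`.
#' @export
simulate_two_site <- function(params, x0 = 0, y0 = 0, times) {
  stopifnot(inherits(params, "kinetic_params"),
            x0 >= 0, x0 <= 1, y0 >= 0, y0 <= 1,
            is.numeric(times), all(times >= 0))
  relax <- function(a, b, z0) {
    k <- a + b
    if (k == 0) return(rep(z0, length(times)))
    zeq <- a / k
    zeq + (z0 - zeq) * exp(-k * times)
  }
  data.frame(time = times,
             x = relax(params$alpha1, params$beta1, x0),
             y = relax(params$alpha2, params$beta2, y0))
}

#' Equilibrium preference curve between two phosphorylation sites
#'
#' Under equal phosphorylation rates at the two sites, the equilibrium
#' fractions satisfy
#'   y = x / (coeff + (1 - coeff) x),   coeff = beta2 / beta1,
#' i.e. the coefficient is the relative dephosphorylation rate of the
#' reference site y over site x. coeff = 1 is the identity; coeff > 1 bends
#' the curve below the diagonal (site x phosphorylated first).
#'
#' @param x phosphorylated fraction of the preferred site, in \[0, 1\].
#' @param coeff PSP coefficient, > 0.
#' @return phosphorylated fraction of the reference site, in \[0, 1\].
#' @export
psp_curve <- function(x, coeff) {
  if (!is.numeric(coeff) || length(coeff) != 1 || !is.finite(coeff) ||
      coeff <= 0)
    stop("coeff must be a single positive number")
  stopifnot(all(x >= 0 & x <= 1, na.rm = TRUE))
  x / (coeff + (1 - coeff) * x)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "Two-site kinetic parameters (min^-1):\n  alpha1 = %g, alpha2 = %g, beta1 = %g, beta2 = %g\n  beta2/beta1 = %s\n",
    x$alpha1, x$alpha2, x$beta1, x$beta2,
    if (x$beta1 > 0) format(x$beta2 / x$beta1) else "undefined"))
  invisible(x)
}
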