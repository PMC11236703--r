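# Exponential-decay fitting of dephosphorylation time courses and the
# dephosphorylation rate ratio with first-order error propagation.

#' Fit an exponential decay to replicate time courses
#'
#' Fits value = plateau + amplitude * exp(-k t) to each replicate by
#' nonlinear least squares, then summarizes parameters as mean +/- s.e.
#' across replicates (the replicate, not the timepoint, is the unit of
#' biological variation). With a single replicate the per-fit asymptotic
#' standard errors are reported instead.
#'
#' @param time timepoints (min), length >= 3.
#' @param values numeric vector (one replicate) or matrix / data.frame with
#'   one column per replicate, rows matching `time`.
#' @param fix_plateau_zero if `TRUE`, pin the plateau at 0.
#' @return an object of class `decay_fit`: `k` (min^-1), `half_life`
#'   (ln 2 / k, min), `plateau`, `amplitude`, standard errors `k_se`,
#'   `half_life_se`, per-replicate table `replicates`, and `flags`.
#' @export
fit_exp_decay <- function(time, values, fix_plateau_zero = FALSE) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  stopifnot(is.numeric(time), nrow(values) == length(time))
  if (length(unique(time)) < 3)
    stop("need >= 3 distinct timepoints to identify an exponential decay")
  n_rep <- ncol(values)

  fit_one <- function(v) {
    ok <- is.finite(v) & is.finite(time)
    t1 <- time[ok]; v1 <- v[ok]
    plateau0 <- if (fix_plateau_zero) 0 else min(v1)
    amp0 <- max(v1) - plateau0
    flag <- NULL
    if (amp0 <= 0 || stats::sd(v1) == 0) {
      # constant (or rising-to-flat) data: no decay component
      return(list(k = 0, plateau = mean(v1), amplitude = 0,
                  flag = "no_decay"))
    }
    # crude rate from the log-linear early segment for a starting value
    pos <- v1 - plateau0 > amp0 * 0.05
    k0 <- if (sum(pos) >= 2) {
      sl <- stats::coef(stats::lm(log(v1[pos] - plateau0 + amp0 * 1e-3) ~
                                    t1[pos]))[2]
      max(-sl, 1e-4)
    } else 1e-2
    fit <- try({
      if (fix_plateau_zero) {
        minpack.lm::nlsLM(v1 ~ A * exp(-k * t1),
                          start = list(A = amp0, k = k0),
                          lower = c(0, 0),
                          control = minpack.lm::nls.lm.control(maxiter = 300))
      } else {
        minpack.lm::nlsLM(v1 ~ p + A * exp(-k * t1),
                          start = list(p = plateau0, A = amp0, k = k0),
                          lower = c(-Inf, 0, 0),
                          control = minpack.lm::nls.lm.control(maxiter = 300))
      }
    }, silent = TRUE)
    if (inherits(fit, "try-error"))
      return(list(k = NA_real_, plateau = NA_real_, amplitude = NA_real_,
                  flag = "fit_failed"))
    cf <- stats::coef(fit)
    k <- unname(cf["k"])
    if (k <= 0) flag <- "nondecaying"
    list(k = max(k, 0),
         plateau = if (fix_plateau_zero) 0 else unname(cf["p"]),
         amplitude = unname(cf["A"]), flag = flag, fit = fit)
  }

  per <- lapply(seq_len(n_rep), function(j) fit_one(values[, j]))
  reps <- data.frame(
    replicate = seq_len(n_rep),
    k = vapply(per, `[[`, numeric(1), "k"),
    plateau = vapply(per, `[[`, numeric(1), "plateau"),
    amplitude = vapply(per, `[[`, numeric(1), "amplitude"))
  reps$half_life <- ifelse(reps$k > 0, log(2) / reps$k, Inf)
  flags <- unlist(lapply(per, `[[`, "flag"))

  k_mean <- mean(reps$k, na.rm = TRUE)
  if (n_rep > 1) {
    k_se <- sem(reps$k)
    hl_se <- sem(reps$half_life[is.finite(reps$half_life)])
  } else {
    # single replicate: asymptotic s.e. from the fit, if available
    k_se <- hl_se <- NA_real_
    if (!is.null(per[[1]]$fit)) {
      sm <- summary(per[[1]]$fit)$coefficients
      if ("k" %in% rownames(sm)) {
        k_se <- sm["k", "Std. Error"]
        if (reps$k[1] > 0) hl_se <- log(2) / reps$k[1]^2 * k_se
      }
    }
  }
  structure(list(
    k = k_mean, k_se = k_se,
    half_life = if (k_mean > 0) log(2) / k_mean else Inf,
    half_life_se = hl_se,
    plateau = mean(reps$plateau, na.rm = TRUE),
    amplitude = mean(reps$amplitude, na.rm = TRUE),
    n_replicates = n_rep, replicates = reps,
    flags = flags), class = "decay_fit")
}

#' Dephosphorylation rate ratio between a fast and a slow site
#'
#' ratio = k_fast / k_slow, with standard error by first-order propagation:
#' se = ratio * sqrt((se_fast/k_fast)^2 + (se_slow/k_slow)^2). Equivalently
#' the ratio of half-lives t1/2(slow) / t1/2(fast).
#'
#' @param fit_fast,fit_slow [fit_exp_decay()] results for the faster- and
#'   slower-dephosphorylated site.
#' @return list with `ratio` and `se`.
#' @export
rate_ratio <- function(fit_fast, fit_slow) {
  stopifnot(inherits(fit_fast, "decay_fit"), inherits(fit_slow, "decay_fit"))
  if (!is.finite(fit_slow$k) || fit_slow$k <= 0)
    stop("slow-site rate is zero or undefined; ratio undefined")
  if (!is.finite(fit_fast$k) || fit_fast$k < 0)
    stop("fast-site rate undefined")
  ratio <- fit_fast$k / fit_slow$k
  rel2 <- function(se, k) if (is.finite(se)) (se / k)^2 else 0
  se <- ratio * sqrt(rel2(fit_fast$k_se, fit_fast$k) +
                     rel2(fit_slow$k_se, fit_slow$k))
  list(ratio = ratio, se = se)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential decay fit (%d replicate%s):\n  k = %.4g +/- %.2g min^-1, half-life = %.3g min\n  plateau = %.3g, amplitude = %.3g\n",
    x$n_replicates, if (x$n_replicates == 1) "" else "s",
    x$k, x$k_se, x$half_life, x$plateau, x$amplitude))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
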