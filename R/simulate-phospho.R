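# Synthetic phospho-site snapshot tables and dephosphorylation time courses
# with planted ground truth.

#' Simulate paired phospho-site snapshots from the two-site model
#'
#' Each G1 cell draws a shared phosphorylation rate alpha from the
#' cell-to-cell kinase-activity distribution (the two Rb-targeting kinases
#' are assumed non-selective between sites, so one alpha serves both). True
#' phosphorylated fractions are the equilibrium solutions
#' x = alpha/(alpha + beta1), y = alpha/(alpha + beta2) with
#' beta2/beta1 = `beta_ratio`. Observed signals are fraction x total-Rb x
#' multiplicative log-normal noise. A separate S-phase subpopulation is
#' generated in the saturating-kinase limit (fractions = 1, Rb
#' hyperphosphorylated) to anchor the normalization.
#'
#' @param n_cells number of G1 cells.
#' @param beta_ratio planted PSP coefficient beta2/beta1 (> 0).
#' @param kinase_dist list with `meanlog`, `sdlog` of the log-normal
#'   kinase-activity (alpha) distribution; `beta1` optionally sets the
#'   absolute scale (default 1).
#' @param noise_cv multiplicative measurement noise CV applied to phospho
#'   and total signals.
#' @param seed integer seed.
#' @param n_s_phase number of S-phase (saturated) cells (default
#'   `max(50, n_cells %/% 10)`).
#' @return list with `snapshots` (data.frame: `cell`, `s_phase`,
#'   `phospho_x`, `phospho_y`, `total_rb`) and `truth` (data.frame:
#'   `cell`, `alpha`, `x_true`, `y_true`).
#' @export
simulate_phospho_snapshots <- function(n_cells, beta_ratio,
                                       kinase_dist = list(meanlog = 0,
                                                          sdlog = 1),
                                       noise_cv = 0.1, seed = 1L,
                                       n_s_phase = NULL) {
  if (!is.numeric(beta_ratio) || beta_ratio <= 0)
    stop("beta_ratio must be > 0")
  if (!all(c("meanlog", "sdlog") %in% names(kinase_dist)) ||
      !is.finite(kinase_dist$sdlog) || kinase_dist$sdlog < 0)
    stop("kinase_dist must give finite meanlog and sdlog >= 0")
  set.seed(seed)
  n_s <- n_s_phase %||% max(50L, n_cells %/% 10L)
  beta1 <- kinase_dist$beta1 %||% 1
  alpha <- stats::rlnorm(n_cells, kinase_dist$meanlog, kinase_dist$sdlog)
  x_true <- equilibrium_fraction(alpha, beta1)
  y_true <- equilibrium_fraction(alpha, beta1 * beta_ratio)
  # S phase: hyperphosphorylated, saturating-kinase limit
  x_all <- c(x_true, rep(1, n_s))
  y_all <- c(y_true, rep(1, n_s))
  n_tot <- n_cells + n_s
  total <- 1000 * lnorm_noise(n_tot, 0.2)   # cell-to-cell total-Rb spread
  snapshots <- data.frame(
    cell = seq_len(n_tot),
    s_phase = rep(c(FALSE, TRUE), c(n_cells, n_s)),
    phospho_x = x_all * total * lnorm_noise(n_tot, noise_cv),
    phospho_y = y_all * total * lnorm_noise(n_tot, noise_cv),
    total_rb = total)
  truth <- data.frame(cell = seq_len(n_cells), alpha = alpha,
                      x_true = x_true, y_true = y_true)
  list(snapshots = snapshots, truth = truth)
}

#' Simulate a dephosphorylation decay experiment
#'
#' Generates replicate time courses value = plateau + amplitude *
#' 2^(-t / half_life) x multiplicative noise, one curve per site. Default
#' half-lives follow the ordering observed for Rb sites after acute CDK2
#' inhibition: slow T373 (~40 min), intermediate S608 (~15 min) and fast
#' C-terminal S807/S811 (~6 min).
#'
#' @param half_lives named numeric vector of half-lives (min), all > 0.
#' @param timepoints sampling times (min), non-negative increasing,
#'   length >= 3.
#' @param n_replicates biological replicates per site (default 3).
#' @param noise_cv multiplicative noise CV (default 0.05).
#' @param seed integer seed.
#' @param plateau,amplitude curve plateau and amplitude (defaults 0.1, 0.9).
#' @param shared_noise if `TRUE` (default) one noise realization is drawn
#'   per replicate and timepoint and applied to every site: the sites are
#'   measured in the same cells and imaging session (iterative
#'   immunofluorescence), so experiment-level fluctuations are shared
#'   across sites within a replicate. `FALSE` draws independent noise per
#'   site.
#' @return data.frame: `site`, `replicate`, `time`, `value`, `true_value`.
#' @export
simulate_decay_experiment <- function(half_lives = c(T373 = 40, S608 = 15,
                                                     `S807/S811` = 6),
                                      timepoints = seq(0, 60, by = 5),
                                      n_replicates = 3, noise_cv = 0.05,
                                      seed = 1L, plateau = 0.1,
                                      amplitude = 0.9, shared_noise = TRUE) {
  if (any(half_lives <= 0)) stop("half_lives must be > 0")
  if (length(timepoints) < 3)
    stop("need >= 3 timepoints for an identifiable decay fit")
  if (any(timepoints < 0) || is.unsorted(timepoints, strictly = TRUE))
    stop("timepoints must be non-negative and strictly increasing")
  set.seed(seed)
  sites <- names(half_lives) %||% paste0("site", seq_along(half_lives))
  nt <- length(timepoints)
  shared <- if (shared_noise)
    matrix(lnorm_noise(nt * n_replicates, noise_cv), nt, n_replicates)
  else NULL
  out <- list()
  for (s in seq_along(half_lives)) {
    true_v <- plateau + amplitude * 2^(-timepoints / half_lives[s])
    for (r in seq_len(n_replicates)) {
      noise <- if (shared_noise) shared[, r] else lnorm_noise(nt, noise_cv)
      out[[length(out) + 1L]] <- data.frame(
        site = sites[s], replicate = r, time = timepoints,
        value = true_v * noise, true_value = true_v)
    }
  }
  do.call(rbind, out)
}
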