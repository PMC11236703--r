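# Synthetic single-cell reporter traces with planted ground truth.
#
# The trace model is deliberately phenomenological scaffolding, not a
# mechanistic claim: committed cells show a CDK2 rise, an intermediate E2F
# plateau of variable duration, a joint late rise of both activities, and a
# sharp degron-reporter drop at S entry; reversing cells decay from the
# plateau below half of their peak with no degron drop; undecided cells
# hold the plateau through the imaging horizon. Activities are reported on
# a normalized 0-1 convention (CDK2 slightly above 1 at S entry).

# smooth 0->1 ramp (cubic smoothstep) starting at t0, duration dur
.ramp <- function(t, t0, dur) {
  u <- pmin(pmax((t - t0) / dur, 0), 1)
  u * u * (3 - 2 * u)
}

#' Simulate single-cell reporter traces
#'
#' Generates per-cell time series of E2F-reporter activity, CDK2 activity
#' (cytoplasm/nucleus ratio convention) and a CRL4^Cdt2-degron reporter,
#' sampled every `frame_interval_min`, together with a ground-truth table.
#'
#' Fate structure: each cell is drawn from the configured multinomial over
#' committed (S entry), reversing and undecided. Committed cells get a
#' G1 length (E2F activation to S entry) from the configured log-normal;
#' the degron reporter decays exponentially at S entry with a 15 min
#' half-life (CRL4^Cdt2-mediated degradation is fast relative to the frame
#' interval).
#' Measurement noise is multiplicative log-normal per frame.
#'
#' @param config a [sim_config()] object.
#' @return list with `traces` (data.frame: `cell`, `time` in hours, `e2f`,
#'   `cdk2`, `degron`) and `truth` (data.frame: `cell`, `fate`,
#'   `t_cdk2_onset`, `t_e2f_onset`, `t_s_entry`, `g1_length`, `stratum`).
#' @export
simulate_traces <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cells
  dt <- config$frame_interval_min / 60
  times <- seq(0, config$horizon_h, by = dt)
  nt <- length(times)
  pop <- config$population
  cv <- pop$noise_cv

  fates <- sample(c("S_enter", "E2F_reverse", "undecided"), n, replace = TRUE,
                  prob = c(pop$fraction_committed, pop$fraction_reversing,
                           pop$fraction_undecided))
  # trace shape constants (normalized activity units)
  cdk2_base <- 0.2; cdk2_plateau <- 0.55; cdk2_hi <- 1.05
  e2f_base <- 0.02; e2f_plateau <- 0.35; e2f_hi <- 1.0
  onset_rise_h <- 1.0     # CDK2 baseline -> plateau
  e2f_rise_h <- 1.0       # E2F baseline -> plateau
  late_rise_h <- 3.0      # joint late rise ending at S entry
  # CRL4^Cdt2-mediated degradation is fast relative to the frame interval
  degron_half_life_h <- 0.25

  t_cdk2 <- stats::runif(n, 3, 9)
  t_e2f <- t_cdk2 + pmax(stats::rnorm(n, 1, 0.2), 0.2)
  g1 <- stats::rlnorm(n, pop$g1_meanlog, pop$g1_sdlog)
  t_s <- ifelse(fates == "S_enter", t_e2f + g1, NA_real_)
  # keep committed S entries observable inside the horizon
  over <- fates == "S_enter" & t_s > config$horizon_h - 2
  t_s[over] <- config$horizon_h - 2
  g1[fates == "S_enter"] <- t_s[fates == "S_enter"] - t_e2f[fates == "S_enter"]
  # reversal time: plateau duration before E2F decays back down
  t_rev <- ifelse(fates == "E2F_reverse",
                  pmin(t_e2f + stats::rlnorm(n, log(8), 0.4),
                       config$horizon_h - 8), NA_real_)

  traces <- vector("list", n)
  for (i in seq_len(n)) {
    fate <- fates[i]
    cdk2 <- cdk2_base +
      (cdk2_plateau - cdk2_base) * .ramp(times, t_cdk2[i], onset_rise_h)
    e2f <- e2f_base +
      (e2f_plateau - e2f_base) * .ramp(times, t_e2f[i], e2f_rise_h)
    degron <- 0.15 + 0.6 * (1 - exp(-times / 8))
    if (fate == "S_enter") {
      cdk2 <- cdk2 + (cdk2_hi - cdk2_plateau) *
        .ramp(times, t_s[i] - late_rise_h, late_rise_h)
      e2f <- e2f + (e2f_hi - e2f_plateau) *
        .ramp(times, t_s[i] - late_rise_h, late_rise_h)
      post <- times >= t_s[i]
      degron[post] <- degron[post] *
        2^(-(times[post] - t_s[i]) / degron_half_life_h)
    } else if (fate == "E2F_reverse") {
      dec <- times >= t_rev[i]
      e2f[dec] <- e2f_base + (e2f[dec] - e2f_base) *
        2^(-(times[dec] - t_rev[i]) / 2.5)
      cdk2[dec] <- cdk2_base + (cdk2[dec] - cdk2_base) *
        2^(-(times[dec] - t_rev[i]) / 2.5)
    }
    if (cv > 0) {
      e2f <- e2f * lnorm_noise(nt, cv)
      cdk2 <- cdk2 * lnorm_noise(nt, cv)
      degron <- degron * lnorm_noise(nt, cv)
    }
    traces[[i]] <- data.frame(cell = i, time = times, e2f = e2f,
                              cdk2 = cdk2, degron = degron)
  }

  strata <- cut(g1, breaks = c(5, 10, 15, 20, 25),
                labels = c("5-10", "10-15", "15-20", "20-25"), right = FALSE)
  strata[fates != "S_enter"] <- NA
  truth <- data.frame(cell = seq_len(n), fate = fates,
                      t_cdk2_onset = t_cdk2, t_e2f_onset = t_e2f,
                      t_s_entry = t_s, t_reversal = t_rev,
                      g1_length = ifelse(fates == "S_enter", g1, NA_real_),
                      stratum = as.character(strata),
                      stringsAsFactors = FALSE)
  list(traces = do.call(rbind, traces), truth = truth)
}
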