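# Configuration object for the synthetic-data generators.

#' Configuration for the synthetic single-cell experiment
#'
#' Bundles every knob of the synthetic imaging experiment: acquisition
#' (frame interval, pixel size), optics (nucleus size, point-spread-function
#' width, vignetting, camera noise) and population structure (fate
#' fractions, G1-length distribution, kinase-activity distribution,
#' measurement noise). Defaults mirror the acquisition settings of the
#' study design this package models: frames every 12 min, 0.65 um/px, and
#' fate strata populated over 5-25 h of G1 length.
#'
#' @param seed integer seed fixing all generator output bit-for-bit.
#' @param n_cells number of cells to simulate.
#' @param frame_interval_min time between frames (min).
#' @param horizon_h duration of the time-lapse (h).
#' @param pixel_size_um pixel size (um/px).
#' @param optics list: `nucleus_radius_um`, `psf_sigma_um`,
#'   `vignetting_amplitude` (relative falloff at the frame corner),
#'   `read_noise_sd` (a.u.), `photon_gain` (photons per a.u.; 0 disables
#'   shot noise).
#' @param population list: `fraction_committed`, `fraction_reversing`,
#'   `fraction_undecided` (must sum to 1); `g1_meanlog`, `g1_sdlog`
#'   (log-normal G1 length, h); `kinase_meanlog`, `kinase_sdlog`
#'   (log-normal cell-to-cell kinase activity); `noise_cv` (multiplicative
#'   measurement noise, coefficient of variation).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_cells = 200L,
                       frame_interval_min = 12,
                       horizon_h = 40,
                       pixel_size_um = 0.65,
                       optics = list(),
                       population = list()) {
  opt_def <- list(nucleus_radius_um = 5.2, psf_sigma_um = 0.5,
                  vignetting_amplitude = 0.25, read_noise_sd = 2,
                  photon_gain = 0.5)
  pop_def <- list(fraction_committed = 0.6, fraction_reversing = 0.25,
                  fraction_undecided = 0.15,
                  g1_meanlog = log(12), g1_sdlog = 0.4,
                  kinase_meanlog = 0, kinase_sdlog = 1,
                  noise_cv = 0.05)
  optics <- utils::modifyList(opt_def, optics)
  population <- utils::modifyList(pop_def, population)
  if (frame_interval_min <= 0) stop("frame_interval_min must be > 0")
  if (horizon_h <= 0) stop("horizon_h must be > 0")
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  fr <- with(population,
             c(fraction_committed, fraction_reversing, fraction_undecided))
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8)
    stop("fate fractions must be non-negative and sum to 1")
  sc <- with(optics, c(nucleus_radius_um, psf_sigma_um))
  if (any(sc <= 0)) stop("optics scale parameters must be > 0")
  if (population$noise_cv < 0) stop("noise_cv must be >= 0")
  structure(list(seed = as.integer(seed), n_cells = as.integer(n_cells),
                 frame_interval_min = frame_interval_min,
                 horizon_h = horizon_h, pixel_size_um = pixel_size_um,
                 optics = optics, population = population),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d cells, %g min frames over %g h, %g um/px, seed %d\n",
    x$n_cells, x$frame_interval_min, x$horizon_h, x$pixel_size_um, x$seed))
  cat(sprintf("  fates: committed %.2f / reversing %.2f / undecided %.2f, noise CV %.2g\n",
              x$population$fraction_committed, x$population$fraction_reversing,
              x$population$fraction_undecided, x$population$noise_cv))
  invisible(x)
}
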