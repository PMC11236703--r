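# Trace alignment, G1-length stratification, phase-plane trajectories and
# cumulative event frequencies.

#' Align traces at an anchor event and stratify by G1 length
#'
#' Each anchored trace is re-indexed to time-before-anchor (offset 0 = the
#' anchor, negative offsets = before it) and grouped into G1-length strata;
#' per stratum and offset the pointwise mean and standard error over the
#' cells contributing at that offset are returned.
#'
#' @param traces data.frame with `cell`, `time` and the signal columns in
#'   `signals`.
#' @param anchors data.frame with `cell`, `anchor` (hours) and `g1_length`
#'   (hours); cells without a finite anchor are skipped.
#' @param signals character vector of trace columns to align.
#' @param strata numeric break points of G1-length strata (hours), default
#'   `c(5, 10, 15, 20, 25)` giving 5-10, 10-15, 15-20 and 20-25 h.
#' @return data.frame: `stratum`, `offset` (hours), then per signal
#'   `<signal>_mean`, `<signal>_sem`, and `n` cells contributing. Empty
#'   strata are omitted with a warning.
#' @export
align_and_stratify <- function(traces, anchors,
                               signals = c("cdk2", "e2f"),
                               strata = c(5, 10, 15, 20, 25)) {
  stopifnot(all(c("cell", "anchor") %in% names(anchors)))
  anchors <- anchors[is.finite(anchors$anchor), ]
  if (!nrow(anchors)) stop("no anchored traces")
  lab <- paste(utils::head(strata, -1), strata[-1], sep = "-")
  anchors$stratum <- as.character(cut(anchors$g1_length, breaks = strata,
                                      labels = lab, right = FALSE))
  empty <- setdiff(lab, unique(stats::na.omit(anchors$stratum)))
  if (length(empty))
    warning("empty strata omitted: ", paste(empty, collapse = ", "))
  anchors <- anchors[!is.na(anchors$stratum), ]

  dt <- min(diff(sort(unique(traces$time))))
  sub <- merge(traces, anchors[, c("cell", "anchor", "stratum")], by = "cell")
  sub$offset <- round((sub$time - sub$anchor) / dt) * dt
  out <- list()
  for (st in unique(anchors$stratum)) {
    ss <- sub[sub$stratum == st, ]
    offs <- sort(unique(ss$offset))
    res <- data.frame(stratum = st, offset = offs)
    grp <- factor(ss$offset, levels = offs)
    for (sig in signals) {
      res[[paste0(sig, "_mean")]] <- as.numeric(tapply(ss[[sig]], grp, mean))
      res[[paste0(sig, "_sem")]] <- as.numeric(tapply(ss[[sig]], grp, sem))
    }
    res$n <- as.integer(tapply(ss$cell, grp, function(z) length(unique(z))))
    out[[st]] <- res
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Phase-plane trajectory of aligned ensemble means
#'
#' Pairs the aligned mean CDK2 and mean E2F activities pointwise in time
#' order, per stratum.
#'
#' @param ensembles output of [align_and_stratify()] containing
#'   `cdk2_mean` and `e2f_mean`.
#' @return data.frame: `stratum`, `offset`, `cdk2`, `e2f`, ordered by
#'   offset within stratum.
#' @export
phase_plane <- function(ensembles) {
  need <- c("stratum", "offset", "cdk2_mean", "e2f_mean")
  if (!all(need %in% names(ensembles)))
    stop("ensembles must carry aligned cdk2 and e2f means")
  ord <- order(ensembles$stratum, ensembles$offset)
  data.frame(stratum = ensembles$stratum[ord],
             offset = ensembles$offset[ord],
             cdk2 = ensembles$cdk2_mean[ord],
             e2f = ensembles$e2f_mean[ord])
}

#' Cumulative frequency of an event over the cell population
#'
#' Fraction of all cells (missing events never count) whose event time is
#' <= t, evaluated on a step grid.
#'
#' @param event_times numeric vector, `NA` for cells without the event.
#' @param horizon maximal time (hours).
#' @param times evaluation grid; default a fine grid over \[0, horizon\].
#' @return data.frame: `time`, `frequency` (in \[0, 1\], denominator = all
#'   cells).
#' @export
cumulative_frequency <- function(event_times, horizon = 40, times = NULL) {
  n <- length(event_times)
  if (is.null(times)) times <- seq(0, horizon, length.out = 201)
  ev <- event_times[is.finite(event_times)]
  freq <- if (n == 0) rep(0, length(times))
          else vapply(times, function(t) sum(ev <= t) / n, numeric(1))
  data.frame(time = times, frequency = freq)
}

#' Bin snapshot signals by time since anaphase
#'
#' For mitotic-exit dephosphorylation analysis: each fixed cell carries a
#' time since its (annotated) anaphase; signals are binned on that clock
#' and per-bin means +/- sem are returned, ready for [fit_exp_decay()].
#'
#' @param snapshot data.frame with `time_since_anaphase` (min) and the
#'   signal column `value`.
#' @param bin_width bin width (min, default 6).
#' @return data.frame: `time` (bin centre, min), `mean`, `sem`, `n`;
#'   empty bins dropped.
#' @export
align_at_anaphase <- function(snapshot, bin_width = 6) {
  stopifnot(all(c("time_since_anaphase", "value") %in% names(snapshot)))
  t <- snapshot$time_since_anaphase
  b <- floor(t / bin_width)
  grp <- factor(b)
  out <- data.frame(
    time = (as.numeric(levels(grp)) + 0.5) * bin_width,
    mean = as.numeric(tapply(snapshot$value, grp, mean)),
    sem = as.numeric(tapply(snapshot$value, grp, sem)),
    n = as.integer(table(grp)))
  out[out$n > 0, ]
}
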