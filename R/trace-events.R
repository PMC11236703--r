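# Event detection on single-cell traces and cell-fate classification.

#' Link per-frame cell records into tracks
#'
#' Greedy nearest-centroid linking frame to frame with a maximum
#' displacement gate; a cell with no candidate within the gate terminates
#' its track, and new detections start new tracks. Ties are resolved by
#' distance, then by lower label id.
#'
#' @param records data.frame with columns `frame`, `cell`, `x`, `y` (px)
#'   and any measurement columns; frames must be in time order.
#' @param max_displacement gate per frame (px, default 15 um at the
#'   configured pixel size is typical; supply in px).
#' @param min_length tracks shorter than this many frames are dropped
#'   (default 1 keeps all).
#' @return the input with a `track` column; dropped rows removed.
#' @export
link_tracks <- function(records, max_displacement = 23, min_length = 1) {
  stopifnot(all(c("frame", "cell", "x", "y") %in% names(records)))
  frames <- sort(unique(records$frame))
  records$track <- NA_integer_
  next_id <- 1L
  prev <- NULL
  for (f in frames) {
    idx <- which(records$frame == f)
    cur <- records[idx, ]
    assigned <- rep(NA_integer_, nrow(cur))
    if (!is.null(prev)) {
      # candidate pairs within the gate, closest first; label id breaks ties
      d <- outer(prev$y, cur$y, function(a, b) (a - b)^2) +
           outer(prev$x, cur$x, function(a, b) (a - b)^2)
      d <- sqrt(d)
      ord <- order(d, rep(prev$cell, ncol(d)))
      used_prev <- rep(FALSE, nrow(prev))
      used_cur <- rep(FALSE, nrow(cur))
      for (o in ord) {
        if (d[o] > max_displacement) break
        i <- (o - 1) %% nrow(prev) + 1
        j <- (o - 1) %/% nrow(prev) + 1
        if (used_prev[i] || used_cur[j]) next
        assigned[j] <- prev$track[i]
        used_prev[i] <- TRUE; used_cur[j] <- TRUE
      }
    }
    new <- is.na(assigned)
    if (any(new)) {
      assigned[new] <- seq.int(next_id, length.out = sum(new))
      next_id <- next_id + sum(new)
    }
    records$track[idx] <- assigned
    cur$track <- assigned
    prev <- cur
  }
  if (min_length > 1) {
    len <- table(records$track)
    keep <- as.integer(names(len)[len >= min_length])
    records <- records[records$track %in% keep, ]
  }
  records
}

#' Detect signal-activation onset
#'
#' Onset is the first time the 3-frame-median-smoothed signal exceeds the
#' baseline median + k x MAD and stays above for at least `sustain`
#' frames. The baseline is the first `baseline_window` frames.
#'
#' @param time time grid (hours).
#' @param signal numeric vector.
#' @param baseline_window frames used for the baseline (default 10).
#' @param k_sigma MAD multiplier (default 3).
#' @param sustain consecutive frames required above threshold (default 3).
#' @return onset time, or `NA` if the signal never activates.
#' @export
detect_onset <- function(time, signal, baseline_window = 10, k_sigma = 3,
                         sustain = 3) {
  ok <- is.finite(signal)
  if (!any(ok)) return(NA_real_)
  if (length(signal) < baseline_window) return(NA_real_)
  s <- smooth3(signal)
  base <- signal[seq_len(baseline_window)]
  thr <- stats::median(base, na.rm = TRUE) +
    k_sigma * stats::mad(base, na.rm = TRUE)
  above <- s > thr
  above[!is.finite(above)] <- FALSE
  run <- 0L
  for (i in seq_along(above)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= sustain) return(time[i - sustain + 1L])
  }
  NA_real_
}

#' Detect S-phase entry from a degron-reporter trace
#'
#' S entry is marked by CRL4^Cdt2-mediated degradation of the reporter: the
#' first local maximum from which the smoothed signal falls by at least
#' `drop_fraction` within `window` frames. The returned time is the time of
#' that maximum (degradation start).
#'
#' @param time time grid (hours).
#' @param degron degron-reporter intensity; `NULL`/all-NA returns `NA`.
#' @param drop_fraction required fractional drop (default 0.5).
#' @param window frames within which the drop must complete (default 5).
#' @param min_level floor on the pre-drop maximum, as a fraction of the
#'   trace maximum, guarding against drops inside noise-level signal
#'   (default 0.2).
#' @return S-entry time, or `NA`.
#' @export
detect_s_entry <- function(time, degron, drop_fraction = 0.5, window = 5,
                           min_level = 0.2) {
  if (is.null(degron) || !any(is.finite(degron))) return(NA_real_)
  if (length(degron) < 10) return(NA_real_)
  s <- smooth3(degron)
  floor_v <- min_level * max(s, na.rm = TRUE)
  n <- length(s)
  for (i in seq_len(n - 1)) {
    if (!is.finite(s[i]) || s[i] < floor_v) next
    jmax <- min(n, i + window)
    ahead <- s[(i + 1):jmax]
    if (any(ahead <= (1 - drop_fraction) * s[i], na.rm = TRUE))
      return(time[i])
  }
  NA_real_
}

#' Classify the fate of a single cell
#'
#' Applies the categorization rules in order: `S_enter` if S entry occurs
#' by the horizon; otherwise `E2F_reverse` if the cell activated E2F and
#' the post-peak minimum of the smoothed E2F signal fell strictly below
#' half of its peak; otherwise `undecided` if E2F activated; otherwise
#' `never_activated`. A minimum at exactly half of the peak is read
#' strictly ("more than half") and stays `undecided`.
#'
#' @param time time grid (hours).
#' @param e2f E2F-reporter signal.
#' @param cdk2 CDK2 activity (used for onset and time-to-level summaries).
#' @param degron degron-reporter signal (may be `NULL`).
#' @param horizon classification horizon (hours, default 40).
#' @param ... passed to [detect_onset()].
#' @return a one-row data.frame (`fate_call`): `fate`, `e2f_onset`,
#'   `cdk2_onset`, `s_entry`, `g1_length`, `time_to_level_065`.
#' @export
classify_fate <- function(time, e2f, cdk2 = NULL, degron = NULL,
                          horizon = 40, ...) {
  in_h <- time <= horizon
  e2f_on <- detect_onset(time[in_h], e2f[in_h], ...)
  cdk2_on <- if (!is.null(cdk2)) detect_onset(time[in_h], cdk2[in_h], ...)
             else NA_real_
  s_t <- detect_s_entry(time, degron)
  if (is.finite(s_t) && s_t > horizon) s_t <- NA_real_
  fate <- if (is.finite(s_t)) {
    "S_enter"
  } else if (is.finite(e2f_on)) {
    s <- smooth3(e2f[in_h])
    pk_i <- which.max(s)
    pk <- s[pk_i]
    post_min <- if (pk_i < length(s)) min(s[pk_i:length(s)]) else pk
    if (is.finite(pk) && pk > 0 && post_min < 0.5 * pk) "E2F_reverse"
    else "undecided"
  } else "never_activated"
  ttl <- if (is.finite(cdk2_on) && !is.null(cdk2))
    time_to_level(time, cdk2, level = 0.65, from = cdk2_on)$duration
  else NA_real_
  data.frame(fate = fate, e2f_onset = e2f_on, cdk2_onset = cdk2_on,
             s_entry = s_t,
             g1_length = if (is.finite(s_t) && is.finite(e2f_on))
               s_t - e2f_on else NA_real_,
             time_to_level_065 = ttl)
}

#' Time from onset to a signal level, and the split at that level
#'
#' First crossing of `level` after `from`, with linear interpolation
#' between frames. If the signal already meets the level at onset the
#' duration is 0.
#'
#' @param time time grid (hours).
#' @param signal numeric vector.
#' @param level threshold (default 0.65, the CDK2 intermediate level).
#' @param from start time (e.g. CDK2 onset); must be finite.
#' @param until optional event time (e.g. S entry) for the second leg.
#' @return list with `duration` (onset to level; `NA` with `reason` if the
#'   level is never crossed), `crossing_time`, and `level_to_event` when
#'   `until` is given.
#' @export
time_to_level <- function(time, signal, level = 0.65, from, until = NULL) {
  if (!is.finite(from)) stop("'from' must be a finite time")
  sel <- which(time >= from)
  if (!length(sel))
    return(list(duration = NA_real_, crossing_time = NA_real_,
                reason = "empty_window"))
  t <- time[sel]; v <- signal[sel]
  if (v[1] >= level) {
    cross <- t[1]
  } else {
    idx <- which(v >= level)[1]
    if (is.na(idx))
      return(list(duration = NA_real_, crossing_time = NA_real_,
                  reason = "never_crosses"))
    # linear interpolation between the flanking frames
    t0 <- t[idx - 1]; t1 <- t[idx]; v0 <- v[idx - 1]; v1 <- v[idx]
    cross <- t0 + (level - v0) / (v1 - v0) * (t1 - t0)
  }
  out <- list(duration = cross - from, crossing_time = cross)
  if (!is.null(until)) out$level_to_event <- until - cross
  out
}

#' Classify every track in a trace table
#'
#' @param traces data.frame with `cell`, `time`, `e2f`, `cdk2`, `degron`.
#' @param horizon hours (default 40).
#' @param ... passed to [classify_fate()].
#' @return data.frame of fate calls, one row per cell.
#' @export
classify_fates <- function(traces, horizon = 40, ...) {
  cells <- unique(traces$cell)
  calls <- lapply(cells, function(id) {
    tr <- traces[traces$cell == id, ]
    cbind(cell = id,
          classify_fate(tr$time, tr$e2f, tr$cdk2, tr$degron,
                        horizon = horizon, ...))
  })
  do.call(rbind, calls)
}
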