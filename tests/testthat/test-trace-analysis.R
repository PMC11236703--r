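# Track linking, event detection, fate classification, alignment and
# ensemble summaries.

make_trace <- function(time, e2f = NULL, cdk2 = NULL, degron = NULL) {
  list(time = time, e2f = e2f, cdk2 = cdk2, degron = degron)
}

test_that("linking keeps stationary and uniformly moving cells intact", {
  # stationary: identity linking across 5 frames
  rec <- do.call(rbind, lapply(1:5, function(f)
    data.frame(frame = f, cell = 1:3, x = c(10, 50, 90), y = c(10, 50, 90))))
  lk <- link_tracks(rec)
  expect_equal(length(unique(lk$track)), 3)
  for (tr in unique(lk$track))
    expect_equal(length(unique(lk$x[lk$track == tr])), 1)

  # linear motion below the gate: one track, ordered positions
  rec2 <- do.call(rbind, lapply(1:6, function(f)
    data.frame(frame = f, cell = 1, x = 10 + 7.7 * (f - 1), y = 20)))
  lk2 <- link_tracks(rec2)
  expect_equal(length(unique(lk2$track)), 1)
})

test_that("displacement beyond the gate terminates rather than swaps tracks", {
  # two cells jump across each other by more than the gate
  rec <- rbind(
    data.frame(frame = 1, cell = 1:2, x = c(10, 100), y = 10),
    data.frame(frame = 2, cell = 1:2, x = c(100, 10), y = 60))
  lk <- link_tracks(rec, max_displacement = 23)
  expect_equal(length(unique(lk$track)), 4)   # both tracks end, two start
})

test_that("onset detection matches steps exactly and ignores flat noise", {
  t <- seq(0, 40, by = 0.2)
  step <- ifelse(t >= 10, 1, 0)
  expect_equal(detect_onset(t, step), 10)
  set.seed(30)
  flat <- rnorm(length(t), 1, 0.05)
  expect_true(is.na(detect_onset(t, flat)))
  expect_true(is.na(detect_onset(t, rep(NA_real_, length(t)))))
})

test_that("onsets on simulated populations land within two frames of truth", {
  sim <- simulate_traces(sim_config(seed = 17, n_cells = 120))
  err <- vapply(sim$truth$cell, function(id) {
    tr <- sim$traces[sim$traces$cell == id, ]
    abs(detect_onset(tr$time, tr$e2f) - sim$truth$t_e2f_onset[id])
  }, numeric(1))
  expect_gte(mean(err <= 0.4 + 1e-9, na.rm = TRUE), 0.95)
  expect_lte(median(err, na.rm = TRUE), 0.2 + 1e-9)  # median within 1 frame
})

test_that("S-entry detection finds the first sustained degron drop", {
  t <- seq(0, 40, by = 0.2)
  expect_true(is.na(detect_s_entry(t, 0.2 + 0.02 * t)))   # monotone rise
  # planted drop at frame 101 (t = 20 h), half-life 1 h
  deg <- 0.8 * ifelse(t < 20, 1, 2^(-(t - 20) / 1))
  expect_lt(abs(detect_s_entry(t, deg) - 20), 0.2 + 1e-9)
  # two-cycle trace: the first drop wins
  deg2 <- 0.8 * ifelse(t < 10, 1, ifelse(t < 20, 2^(-(t - 10) / 1),
                                         pmin(1, (t - 20) / 5)))
  expect_lt(abs(detect_s_entry(t, deg2) - 10), 0.2 + 1e-9)
  expect_true(is.na(detect_s_entry(t, NULL)))
})

test_that("fate rules match rule-by-rule evaluation on an edge-case suite", {
  t <- seq(0, 44, by = 0.2)
  horizon <- 40
  base_deg <- 0.2 + 0.6 * (1 - exp(-t / 8))
  drop_at <- function(ts) base_deg * ifelse(t < ts, 1, 2^(-(t - ts) / 0.25))
  plateau_e2f <- function(onset, level = 0.8)
    ifelse(t < onset, 0.01, level)
  reverse_e2f <- function(onset, peak, ratio) {
    # rises to peak then settles at ratio * peak
    ifelse(t < onset, 0.01, ifelse(t < onset + 5, peak,
                                   pmax(ratio * peak,
                                        peak * 2^(-(t - onset - 5) / 2))))
  }
  cases <- list()
  add <- function(e2f, degron, expected)
    cases[[length(cases) + 1]] <<- list(e2f = e2f, degron = degron,
                                        expected = expected)
  # S entry at various times, including exactly at the horizon
  for (ts in c(10, 20, 30, 39.8, 40)) {
    add(plateau_e2f(5), drop_at(ts), "S_enter")
  }
  # degron drop after the horizon: not an S-phase call; flat E2F stays
  # undecided
  add(plateau_e2f(5), drop_at(42), "undecided")
  # reversal depth sweep around the strict one-half rule
  for (ratio in c(0.1, 0.3, 0.45, 0.49)) {
    add(reverse_e2f(5, 1, ratio), base_deg, "E2F_reverse")
  }
  add(reverse_e2f(5, 1, 0.5), base_deg, "undecided")   # exactly half: strict
  for (ratio in c(0.51, 0.7, 0.9)) {
    add(reverse_e2f(5, 1, ratio), base_deg, "undecided")
  }
  # plateau (no decrease) at several onsets and levels
  for (onset in c(3, 10, 25)) add(plateau_e2f(onset), base_deg, "undecided")
  for (level in c(0.3, 0.6, 1.2)) add(plateau_e2f(8, level), base_deg,
                                      "undecided")
  # never-activated: flat baseline, with and without late tiny wiggles
  add(rep(0.01, length(t)), base_deg, "never_activated")
  add(0.01 + 0.001 * sin(t), base_deg, "never_activated")
  # reversal combined with a degron drop: S entry takes precedence
  add(reverse_e2f(5, 1, 0.2), drop_at(15), "S_enter")
  # reversal that also re-activates later still counts as reversed
  re <- reverse_e2f(5, 1, 0.1); re[t > 35] <- 1
  add(re, base_deg, "E2F_reverse")
  # late activation without decrease near the horizon
  add(plateau_e2f(38), base_deg, "undecided")
  # step down then full drop to baseline with no degron drop
  add(ifelse(t < 5, 0.01, ifelse(t < 15, 1, 0.01)), base_deg, "E2F_reverse")
  # very low activation that still clears baseline + 3 MAD (noiseless)
  add(plateau_e2f(5, 0.05), base_deg, "undecided")
  # S entry with late onset and short G1
  add(plateau_e2f(30), drop_at(35), "S_enter")
  add(plateau_e2f(2), drop_at(4), "S_enter")
  # S entry without any E2F activation still counts as S entry
  add(rep(0.01, length(t)), drop_at(22), "S_enter")
  expect_gte(length(cases), 30)
  got <- vapply(cases, function(cs)
    classify_fate(t, cs$e2f, degron = cs$degron, horizon = horizon)$fate,
    character(1))
  expect_identical(got, vapply(cases, `[[`, character(1), "expected"))
})

test_that("fates on simulated populations agree with planted truth", {
  sim <- simulate_traces(sim_config(seed = 23, n_cells = 150))
  fates <- classify_fates(sim$traces)
  expect_gte(mean(fates$fate == sim$truth$fate), 0.99)
})

test_that("alignment collapses shifted copies of one template", {
  t <- seq(0, 40, by = 0.2)
  template_c <- pmin(1, 0.2 + 0.02 * t)
  template_e <- pmin(1, 0.01 * t)
  shifts <- c(0, 1, 2.4, 5, 7.2)
  traces <- do.call(rbind, lapply(seq_along(shifts), function(i) {
    data.frame(cell = i, time = t,
               cdk2 = approx(t + shifts[i], template_c, xout = t,
                             rule = 2)$y,
               e2f = approx(t + shifts[i], template_e, xout = t,
                            rule = 2)$y)
  }))
  anchors <- data.frame(cell = seq_along(shifts), anchor = 20 + shifts,
                        g1_length = 12)
  ens <- suppressWarnings(
    align_and_stratify(traces, anchors, strata = c(5, 10, 15, 20, 25)))
  # all cells in one stratum; where every cell contributes, variance is 0
  full <- ens[ens$n == length(shifts), ]
  expect_gt(nrow(full), 50)
  expect_true(all(full$cdk2_sem < 1e-12))
  expect_true(all(full$e2f_sem < 1e-12))
  # the aligned mean reproduces the template on the common support
  mid <- full[abs(full$offset - (-5)) < 1e-9, ]
  expect_equal(mid$cdk2_mean,
               approx(t, template_c, xout = 20 - 5, rule = 2)$y,
               tolerance = 1e-12)
})

test_that("alignment is invariant to a global clock shift", {
  sim <- simulate_traces(sim_config(seed = 29, n_cells = 60))
  fates <- classify_fates(sim$traces)
  anch <- data.frame(cell = fates$cell, anchor = fates$s_entry,
                     g1_length = fates$g1_length)
  e1 <- suppressWarnings(align_and_stratify(sim$traces, anch))
  shifted <- sim$traces; shifted$time <- shifted$time + 3.4
  anch2 <- anch; anch2$anchor <- anch2$anchor + 3.4
  e2 <- suppressWarnings(align_and_stratify(shifted, anch2))
  expect_equal(e1, e2, tolerance = 1e-9)
  # ensemble bookkeeping: the per-stratum cell count equals the number of
  # anchored cells whose G1 length falls in that stratum
  anchored <- anch[is.finite(anch$anchor), ]
  by_stratum <- table(cut(anchored$g1_length, c(5, 10, 15, 20, 25),
                          labels = c("5-10", "10-15", "15-20", "20-25"),
                          right = FALSE))
  for (st in names(by_stratum)) {
    if (by_stratum[[st]] == 0) next
    expect_equal(max(e1$n[e1$stratum == st]), by_stratum[[st]])
  }
})

test_that("time-to-level interpolates crossings and handles edge cases", {
  t <- seq(0, 20, by = 0.5)
  ramp <- pmin(pmax((t - 5) / 10, 0), 1)      # 0 -> 1 over t = 5..15
  res <- time_to_level(t, ramp, level = 0.65, from = 5)
  expect_equal(res$duration, 6.5)
  # already above the level at onset
  expect_equal(time_to_level(t, rep(0.9, length(t)), 0.65, from = 2)$duration,
               0)
  never <- time_to_level(t, rep(0.1, length(t)), 0.65, from = 2)
  expect_true(is.na(never$duration))
  expect_equal(never$reason, "never_crosses")
  res2 <- time_to_level(t, ramp, 0.65, from = 5, until = 18)
  expect_equal(res2$level_to_event, 18 - 11.5)
})

test_that("commitment timing variance concentrates before the 0.65 level", {
  sim <- simulate_traces(sim_config(seed = 31, n_cells = 150))
  fates <- classify_fates(sim$traces)
  sf <- fates[fates$fate == "S_enter" & is.finite(fates$time_to_level_065), ]
  leg1 <- sf$time_to_level_065
  cross <- sf$cdk2_onset + sf$time_to_level_065
  leg2 <- sf$s_entry - cross
  expect_gt(var(leg1), var(leg2))
})

test_that("phase-plane pairing follows the aligned means", {
  ens <- data.frame(stratum = "5-10", offset = c(-2, -1, 0),
                    cdk2_mean = c(0.5, 0.5, 0.5),
                    e2f_mean = c(0.2, 0.5, 0.9))
  pp <- phase_plane(ens)
  expect_equal(pp$cdk2, rep(0.5, 3))        # vertical segment
  expect_equal(pp$e2f, c(0.2, 0.5, 0.9))
  ens$e2f_mean <- ens$cdk2_mean
  expect_equal(with(phase_plane(ens), cdk2 - e2f), rep(0, 3))  # diagonal
  expect_error(phase_plane(data.frame(a = 1)), "aligned")
})

test_that("cumulative frequency equals the empirical CDF over all cells", {
  expect_true(all(cumulative_frequency(rep(NA_real_, 5))$frequency == 0))
  expect_true(all(cumulative_frequency(rep(0, 4))$frequency == 1))
  set.seed(3)
  ev <- c(runif(60, 0, 35), rep(NA, 40))
  cf <- cumulative_frequency(ev, horizon = 40)
  ref <- ecdf(ev[is.finite(ev)])
  expect_equal(cf$frequency, ref(cf$time) * 0.6, tolerance = 1e-12)
})

test_that("anaphase-aligned binning reproduces planted decay means", {
  set.seed(8)
  t <- runif(600, 0, 60)
  v <- 0.9 * 2^(-t / 10)
  snap <- data.frame(time_since_anaphase = t, value = v)
  bins <- align_at_anaphase(snap, bin_width = 6)
  # noiseless values: bin means lie on the curve evaluated inside the bin
  expect_true(all(abs(bins$mean - (0.9 * 2^(-bins$time / 10))) <
                    0.9 * (2^(3 / 10) - 1)))
  # all cells at one offset collapse to a single bin
  one <- align_at_anaphase(data.frame(time_since_anaphase = rep(7, 5),
                                      value = 1:5))
  expect_equal(nrow(one), 1)
  expect_equal(one$mean, 3)
  # shuffling offsets removes the decay trend
  sh <- snap; sh$time_since_anaphase <- sample(sh$time_since_anaphase)
  bsh <- align_at_anaphase(sh, bin_width = 6)
  expect_lt(diff(range(bsh$mean)), diff(range(bins$mean)) / 2)
})
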