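# Build a bare trajectory data frame from donor/acceptor vectors.
make_traj <- function(i_d, i_a, dt = 0.3, id = 1L) {
  n <- length(i_d)
  data.frame(traj_id = id, frame = seq_len(n), time_s = (seq_len(n) - 1) * dt,
             intensity_donor = i_d, intensity_acceptor = i_a)
}

test_that("FRET efficiency is the acceptor fraction of total emission", {
  expect_equal(fret_efficiency(500, 500), 0.5)
  expect_equal(fret_efficiency(300 * 0.3, 300 * 0.7), 0.7)
  expect_equal(fret_efficiency(100, 0), 0)
  expect_true(is.na(fret_efficiency(0, 0)))
  expect_true(is.na(fret_efficiency(50, -50)))
  # clipped to [0, 1] when background subtraction overshoots a channel
  expect_equal(fret_efficiency(-10, 100), 1)
})

test_that("threshold-run detection finds a constructed bound block with exact dwell", {
  i_d <- rep(150, 60); i_a <- rep(0, 60)
  i_d[10:29] <- 150; i_a[10:29] <- 350   # E = 0.7 for frames 10..29
  es <- detect_events(make_traj(i_d, i_a), threshold = 0.2, min_frames = 2)
  expect_equal(nrow(es$events), 1L)
  expect_equal(es$events$dwell_s, 6.0)
  expect_equal(es$events$start_s, 9 * 0.3)
  expect_equal(es$events$mean_E, 0.7)
  expect_false(es$events$left_censored)
  expect_false(es$events$right_censored)
  # all-unbound trajectory gives a valid empty event set
  es0 <- detect_events(make_traj(rep(500, 40), rep(0, 40)))
  expect_equal(nrow(es0$events), 0L)
  expect_length(dwell_times(es0), 0)
})

test_that("runs touching trajectory edges are censored and excluded from dwells", {
  i_d <- rep(150, 30); i_a <- rep(0, 30)
  i_a[1:5] <- 350     # touches start
  i_a[26:30] <- 350   # touches end
  i_a[12:15] <- 350   # interior
  es <- detect_events(make_traj(i_d, i_a))
  expect_equal(nrow(es$events), 3L)
  expect_equal(sum(es$events$left_censored), 1L)
  expect_equal(sum(es$events$right_censored), 1L)
  expect_length(dwell_times(es), 1L)
  expect_length(dwell_times(es, include_censored = TRUE), 3L)
})

test_that("rebinding gaps are event-to-event intervals within a trajectory", {
  i_d <- rep(150, 50); i_a <- rep(0, 50)
  # events at frames 2-8 and 35-41 (interior, uncensored)
  i_a[2:8] <- 350; i_a[35:41] <- 350
  es <- detect_events(make_traj(i_d, i_a, dt = 1))
  expect_equal(nrow(es$events), 2L)
  # gap = start of second - end of first
  expect_equal(rebind_times(es), es$events$start_s[2] - es$events$end_s[1])
  # single-event trajectory yields no gaps
  i_a2 <- rep(0, 50); i_a2[10:20] <- 350
  expect_length(rebind_times(detect_events(make_traj(rep(150, 50), i_a2, dt = 1))), 0)
})

test_that("detection is deterministic, threshold-monotone, and conserves trajectory time", {
  sim <- sim_fret(30, tau_bound = 6.1, tau_unbound = 17, noise_sd = 50, seed = 21)
  es1 <- detect_events(sim$trajectories)
  es2 <- detect_events(sim$trajectories)
  expect_identical(es1$events, es2$events)
  bound_frames <- function(th) sum(detect_events(sim$trajectories, threshold = th)$frames$in_event)
  bf <- vapply(c(0.1, 0.2, 0.3, 0.5, 0.8), bound_frames, numeric(1))
  expect_true(all(diff(bf) <= 0))
  # per trajectory: leading span + dwells + gaps + trailing span == duration
  for (id in unique(es1$events$traj_id)) {
    ev <- es1$events[es1$events$traj_id == id, ]
    ev <- ev[order(ev$start_s), ]
    dur <- es1$meta$duration[es1$meta$traj_id == id]
    lead <- ev$start_s[1]
    trail <- dur - ev$end_s[nrow(ev)]
    gaps <- if (nrow(ev) > 1) sum(ev$start_s[-1] - ev$end_s[-nrow(ev)]) else 0
    total <- lead + sum(ev$dwell_s) + gaps + trail
    expect_equal(total, dur, tolerance = 1e-9)
    expect_true(all(ev$start_s[-1] >= ev$end_s[-nrow(ev)])) # non-overlap, ordered
  }
})

test_that("on noiseless input detection equals the frame projection of ground truth", {
  # oracle: project the true continuous-time state path onto frame midpoints
  # and extract runs >= min_frames; on noiseless data the detector must
  # reproduce this exactly (dwells shorter than the frame sampling are
  # invisible by construction and excluded by the projection too)
  project_events <- function(truth_tr, n_frames, dt, min_frames) {
    mid <- (seq_len(n_frames) - 0.5) * dt
    seg <- findInterval(mid, truth_tr$start_s)
    bound <- truth_tr$state[seg] == "bound"
    r <- rle(bound)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_frames
    data.frame(start_s = (starts[keep] - 1L) * dt,
               dwell_s = r$lengths[keep] * dt,
               left = starts[keep] == 1L, right = ends[keep] == n_frames)
  }
  sim <- sim_fret(40, tau_bound = 6.1, tau_unbound = 17, noise_sd = 0, seed = 31)
  es <- detect_events(sim$trajectories, threshold = 0.2, min_frames = 2)
  dt <- sim$frame_dt
  for (id in unique(sim$trajectories$traj_id)) {
    n_frames <- sum(sim$trajectories$traj_id == id)
    oracle <- project_events(sim$truth[sim$truth$traj_id == id, ], n_frames, dt, 2)
    ev <- es$events[es$events$traj_id == id, ]
    expect_equal(ev$start_s, oracle$start_s)
    expect_equal(ev$dwell_s, oracle$dwell_s)
    expect_equal(ev$left_censored, oracle$left)
    expect_equal(ev$right_censored, oracle$right)
  }
})

test_that("seeded noisy ensemble recovers >= 90% of resolvable events within one frame", {
  sim <- sim_fret(200, tau_bound = 6.1, tau_unbound = 17, E_bound = 0.7,
                  frame_dt = 0.3, duration = 180, I_total = 500,
                  noise_sd = 50, seed = 42)
  es <- detect_events(sim$trajectories, threshold = 0.2, min_frames = 2)
  dt <- sim$frame_dt
  tb <- sim$truth[sim$truth$state == "bound", ]
  tb <- tb[tb$end_s - tb$start_s >= 2 * dt, ]
  hits <- 0
  for (i in seq_len(nrow(tb))) {
    ev <- es$events[es$events$traj_id == tb$traj_id[i], ]
    m <- abs(ev$start_s - tb$start_s[i]) <= dt & abs(ev$end_s - tb$end_s[i]) <= dt
    if (any(m)) hits <- hits + 1
  }
  expect_gte(hits / nrow(tb), 0.90)
})

test_that("median background subtraction restores efficiencies under acceptor offset", {
  i_d <- rep(150, 80); i_a <- rep(25, 80)          # constant acceptor background
  i_a[20:39] <- 25 + 350                           # bound block on top of it
  es <- detect_events(make_traj(i_d, i_a), background = "median")
  expect_equal(nrow(es$events), 1L)
  expect_equal(es$events$mean_E, 0.7, tolerance = 1e-9)
  # without subtraction the unbound frames already show apparent FRET
  es_raw <- detect_events(make_traj(i_d, i_a), background = "none")
  expect_gt(es_raw$events$mean_E[1], 0.7)
})

test_that("hysteresis bridges single-frame dropouts only when enabled", {
  i_d <- rep(150, 40); i_a <- rep(0, 40)
  i_a[10:25] <- 350
  i_a[17] <- 0                                      # one-frame dropout
  es_off <- detect_events(make_traj(i_d, i_a), hysteresis = FALSE)
  es_on <- detect_events(make_traj(i_d, i_a), hysteresis = TRUE)
  expect_equal(nrow(es_off$events), 2L)
  expect_equal(nrow(es_on$events), 1L)
  expect_equal(es_on$events$dwell_s, 16 * 0.3)
})

test_that("efficiency histogram centers bins on multiples of the bin width", {
  i_d <- rep(150, 30); i_a <- rep(0, 30)
  i_a[5:24] <- 350
  es <- detect_events(make_traj(i_d, i_a))
  h <- efficiency_histogram(es, bin_width = 0.05)
  expect_equal(h$mode, 0.70)
  expect_equal(sum(h$counts > 0), 1L)
  expect_equal(h$n, 20L)
  # noisy ensemble: modal bin still contains the generating efficiency
  sim <- sim_fret(100, tau_bound = 6.1, tau_unbound = 17, noise_sd = 50, seed = 13)
  hh <- efficiency_histogram(detect_events(sim$trajectories), bin_width = 0.05)
  expect_lte(abs(hh$mode - 0.7), 0.025)
  es0 <- detect_events(make_traj(rep(500, 10), rep(0, 10)))
  expect_error(efficiency_histogram(es0), "no bound frames")
})
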