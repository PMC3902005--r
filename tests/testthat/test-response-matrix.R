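test_that("window specs enforce their ordering invariant", {
  w <- window_spec(100, 10)
  expect_equal(w$window_ms, 100)
  expect_error(window_spec(-5), "positive")
  expect_error(window_spec(50, 50), "artifact_blank_ms")
})

test_that("count_evoked places single spikes in the right cell", {
  # one spike at electrode "34", 10 ms after trial 0 of stimulation at "12"
  pulses <- make_pulses()
  t_k <- pulses$pulse_time_s[pulses$stim_electrode_id == "12" &
                               pulses$trial_index == 0]
  ev <- make_stim_events(make_spikes("34", t_k + 0.010))
  counts <- count_evoked(ev, std_map, window_spec(50))
  expect_equal(sum(counts), 1)
  expect_equal(counts["12", "34", "0"], 1L)

  # artifact blanking: spike at +10 ms survives a 15 ms window start? no —
  # blank 15 excludes it, blank 5 keeps it, blank 12 excludes it
  c5 <- count_evoked(ev, std_map, window_spec(50, 5))
  expect_equal(sum(c5), 1)
  c12 <- count_evoked(ev, std_map, window_spec(50, 12))
  expect_equal(sum(c12), 0)
})

test_that("count_evoked validates its inputs", {
  ev <- make_stim_events()
  expect_equal(sum(count_evoked(ev, std_map, window_spec(100))), 0)
  expect_warning(count_evoked(ev, std_map, window_spec(400)),
                 "inter-pulse")
  # a missing trial is reported
  p <- make_pulses()
  p <- p[-5, ]
  ev2 <- spike_events(make_spikes("12", 1), p)
  expect_error(count_evoked(ev2, std_map, window_spec(100)),
               "missing trials")
  expect_error(count_evoked(simulate_spontaneous(std_map, 1, duration_s = 1,
                                                 seed = 1),
                            std_map, window_spec(100)),
               "no pulse table")
})

test_that("total counts equal spikes falling in non-overlapping windows", {
  traj <- generate_latent_trajectory(std_map, growth_schedule(), seed = 31)
  ev <- simulate_stimulation_session(std_map, traj, day_in_vitro = 25,
                                     seed = 32)
  win <- window_spec(100)
  counts <- count_evoked(ev, std_map, win)
  # windows (t, t+0.1] with 0.3 s spacing never overlap; count directly
  n_direct <- 0
  starts <- sort(ev$pulses$pulse_time_s)
  hits <- findInterval(ev$spikes$time_s - 1e-12, starts)
  in_win <- hits > 0 & (ev$spikes$time_s - starts[pmax(hits, 1)]) <= 0.1 &
    (ev$spikes$time_s - starts[pmax(hits, 1)]) > 0
  expect_equal(sum(counts), sum(in_win))
})

test_that("spontaneous baseline is exact for periodic trains and scales with window", {
  # 2 Hz periodic train on every electrode, offset to avoid boundaries
  times <- rep(seq(0.25, 99.75, by = 0.5), times = 59)
  ids <- rep(std_ids, each = 200)
  ev <- spike_events(make_spikes(ids, times, session_kind = "spontaneous"),
                     duration_s = 100)
  b100 <- spontaneous_baseline(ev, std_map, window_spec(100),
                               burst_exclude = FALSE)
  expect_true(all(abs(b100 - 0.2) < 1e-12))
  b50 <- spontaneous_baseline(ev, std_map, window_spec(50),
                              burst_exclude = FALSE)
  expect_equal(as.numeric(b100), as.numeric(2 * b50))

  # empty session of valid duration has zero baseline
  e0 <- spike_events(make_spikes(character(), numeric(),
                                 session_kind = "spontaneous"),
                     duration_s = 10)
  expect_true(all(spontaneous_baseline(e0, std_map, window_spec(100)) == 0))
  # shorter than one window is an error
  e1 <- spike_events(make_spikes("12", 0.01, session_kind = "spontaneous"),
                     duration_s = 0.05)
  expect_error(spontaneous_baseline(e1, std_map, window_spec(100)),
               "shorter than one")
})

test_that("build_z subtracts the baseline from the trial mean", {
  counts <- array(3L, dim = c(59, 59, 50),
                  dimnames = list(std_ids, std_ids, 0:49))
  z <- build_z(counts, rep(1.2, 59), std_map, diagonal = "include")
  expect_true(all(abs(z - 1.8) < 1e-12))

  z0 <- build_z(counts, rep(3, 59), std_map, diagonal = "include")
  expect_true(all(z0 == 0))

  # evoked mean 0, baseline 0.4: negative Z is legal
  zneg <- build_z(array(0L, dim = c(59, 59, 50)), rep(0.4, 59), std_map,
                  diagonal = "include")
  expect_true(all(zneg == -0.4))

  zd <- build_z(counts, rep(1.2, 59), std_map, diagonal = "zero")
  expect_true(all(diag(zd) == 0))
  expect_equal(attr(zd, "diagonal"), "zero")

  counts_na <- counts
  counts_na[1] <- NA
  expect_error(build_z(counts_na, rep(0, 59), std_map), "NaN/NA")
})

test_that("Z is invariant to trial relabeling", {
  traj <- generate_latent_trajectory(std_map, growth_schedule(), seed = 41)
  ev <- simulate_stimulation_session(std_map, traj, day_in_vitro = 20,
                                     seed = 42)
  win <- window_spec(100)
  z1 <- build_z(count_evoked(ev, std_map, win), rep(0, 59), std_map)
  # permute trial indices within each stimulated electrode
  set.seed(1)
  perm <- ev
  perm$pulses$trial_index <- ave(perm$pulses$trial_index,
                                 perm$pulses$stim_electrode_id,
                                 FUN = function(x) sample(x))
  perm <- spike_events(perm$spikes, perm$pulses,
                       duration_s = perm$duration_s)
  z2 <- build_z(count_evoked(perm, std_map, win), rep(0, 59), std_map)
  expect_equal(unclass(z1), unclass(z2))
})

test_that("Z has mean zero under stationary background and no network", {
  zs <- lapply(1:4, function(s) {
    stim <- simulate_stimulation_session(
      std_map, network_on_day(generate_latent_trajectory(
        std_map, growth_schedule(plateau_density = 0), seed = s), 1),
      firing = firing_params(baseline_hz = 1, burst_rate_hz = 0),
      day_in_vitro = 1, seed = s)
    spont <- simulate_spontaneous(std_map, 1,
                                  firing_params(baseline_hz = 1,
                                                burst_rate_hz = 0),
                                  duration_s = 120, seed = s + 100)
    session_response_matrix(stim, spont, std_map, window_spec(100),
                            burst_exclusion = FALSE, diagonal = "include")
  })
  vals <- unlist(lapply(zs, as.numeric))
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)))
})

test_that("burst-contaminated trials are flagged and excluded", {
  counts <- array(0L, dim = c(59, 59, 50))
  counts[] <- rpois(length(counts), 0.1)
  # a network-wide burst in trial 7 of stimulated electrode 3
  counts[3, , 7] <- counts[3, , 7] + 30L
  keep <- flag_burst_trials(counts)
  expect_false(keep[3, 7])
  expect_gt(mean(keep), 0.99)
  z <- build_z(counts, rep(0, 59), std_map, trial_keep = keep,
               diagonal = "include")
  # the burst trial no longer inflates row 3
  expect_lt(max(z[3, ]) - max(z[4, ]), 1)
})
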