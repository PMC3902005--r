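test_that("plating classes reproduce the nominal cell arithmetic", {
  info <- plating_info()
  expect_equal(info$nominal_cells,
               info$plating_volume_ul * info$suspension_density_per_ul)
  expect_equal(plating_info("dense")$nominal_cells, 50000)
  expect_equal(plating_info("small")$nominal_cells, 12500)
  expect_equal(plating_info("sparse")$nominal_cells, 12500)
  expect_error(plating_info("medium"), "unknown")
})

test_that("latent trajectories are deterministic and grow in two phases", {
  sched <- growth_schedule()
  t1 <- generate_latent_trajectory(std_map, sched, seed = 5)
  t2 <- generate_latent_trajectory(std_map, sched, seed = 5)
  expect_identical(t1$edges, t2$edges)

  m <- latent_daily_metrics(t1)
  q <- sched$quiescent_days
  expect_true(all(m$n_edges[1:q] == 0))
  growth <- (q + 1):(q + sched$growth_days)
  expect_true(all(diff(m$n_edges[growth]) > 0))
  plateau <- (q + sched$growth_days + 1):sched$total_days
  expect_equal(length(unique(m$n_edges[plateau])), 1)
  # zero plateau density = zero edges forever
  t0 <- generate_latent_trajectory(std_map,
                                   growth_schedule(plateau_density = 0),
                                   seed = 5)
  expect_equal(nrow(t0$edges), 0)
})

test_that("edge count and edge length increase over growth in expectation", {
  counts <- t(sapply(1:100, function(s) {
    tr <- generate_latent_trajectory(std_map, growth_schedule(), seed = s)
    m <- latent_daily_metrics(tr)
    c(e3 = m$n_edges[3], e30 = m$n_edges[30],
      l8 = m$mean_edge_length_um[8], l17 = m$mean_edge_length_um[17])
  }))
  expect_lt(mean(counts[, "e3"]), mean(counts[, "e30"]))
  expect_lt(mean(counts[, "l8"]), mean(counts[, "l17"]))
})

test_that("supernode-grade hubs emerge by plateau", {
  m <- latent_daily_metrics(generate_latent_trajectory(std_map,
                                                       growth_schedule(),
                                                       seed = 3))
  expect_gt(m$n_incoming_supernodes[40], 0)
  expect_gt(m$n_outgoing_supernodes[40], 0)
})

test_that("spontaneous simulation matches its Poisson rate and seed contract", {
  ev <- simulate_spontaneous(std_map, 10,
                             firing_params(baseline_hz = 1, burst_rate_hz = 0),
                             duration_s = 100, seed = 21)
  n <- nrow(ev$spikes)
  expect_lt(abs(n - 5900), 3 * sqrt(5900))
  ev2 <- simulate_spontaneous(std_map, 10,
                              firing_params(baseline_hz = 1, burst_rate_hz = 0),
                              duration_s = 100, seed = 21)
  expect_identical(ev$spikes, ev2$spikes)
  # zero rates give an empty session
  e0 <- simulate_spontaneous(std_map, 10, firing_params(0, 0, 0, 0),
                             duration_s = 10, seed = 1)
  expect_equal(nrow(e0$spikes), 0)
  expect_error(firing_params(baseline_hz = -1), "non-negative")
})

test_that("stimulation sessions follow the pulse protocol", {
  net <- data.frame(from = character(), to = character(),
                    length_um = numeric(), weight = numeric(),
                    latency_class = character(), day_added = integer())
  ev <- simulate_stimulation_session(std_map, net,
                                     firing = firing_params(0, 0, 0, 0),
                                     day_in_vitro = 1, seed = 2)
  expect_equal(nrow(ev$pulses), 59 * 50)
  expect_equal(nrow(ev$spikes), 0)
  expect_equal(sort(unique(ev$pulses$trial_index)), 0:49)
  expect_equal(min(diff(sort(ev$pulses$pulse_time_s))), 0.3)
})

test_that("a deterministic single edge evokes exactly one spike per pulse", {
  net <- data.frame(from = "12", to = "87", length_um = 100, weight = 1,
                    latency_class = "direct", day_added = 1,
                    stringsAsFactors = FALSE)
  ev <- simulate_stimulation_session(
    std_map, net, firing = firing_params(0, 0, 0, 0), day_in_vitro = 1,
    seed = 4, latency_bands_ms = list(direct = c(10, 10)))
  expect_equal(nrow(ev$spikes), 50)
  expect_true(all(ev$spikes$electrode_id == "87"))
  k_pulses <- ev$pulses$pulse_time_s[ev$pulses$stim_electrode_id == "12"]
  expect_equal(sort(ev$spikes$time_s), sort(k_pulses + 0.010))
})

test_that("evoked spikes never precede their pulse", {
  traj <- generate_latent_trajectory(std_map, growth_schedule(), seed = 7)
  ev <- simulate_stimulation_session(std_map, traj, day_in_vitro = 30,
                                     firing = firing_params(0, 0, 0, 0),
                                     seed = 8)
  # with zero background every spike is evoked; assign each spike to the
  # most recent pulse at its source-capable electrodes: all must be after
  # some pulse by at least 0 and within the maximal latency band
  expect_true(all(ev$spikes$time_s >= min(ev$pulses$pulse_time_s)))
  net <- network_on_day(traj, 30)
  for (i in sample(nrow(ev$spikes), min(50, nrow(ev$spikes)))) {
    j <- ev$spikes$electrode_id[i]
    srcs <- net$from[net$to == j]
    pt <- ev$pulses$pulse_time_s[ev$pulses$stim_electrode_id %in% srcs]
    lag <- ev$spikes$time_s[i] - pt
    expect_true(any(lag > 0 & lag <= 0.25 + 1e-9))
  }
})

test_that("evoked latency classes follow the configured mixture", {
  sched <- growth_schedule()
  traj <- generate_latent_trajectory(std_map, sched, seed = 12)
  cls <- table(traj$edges$latency_class) / nrow(traj$edges)
  for (k in names(sched$latency_fractions)) {
    expect_lt(abs(cls[[k]] - sched$latency_fractions[[k]]),
              4 * sqrt(0.5 * 0.5 / nrow(traj$edges)) + 0.05)
  }
})

test_that("z-mixture sampler honors epsilon, f1 and the seed contract", {
  zm0 <- generate_z_mixture(mixture_spec(epsilon = 0, seed = 1))
  expect_false(any(zm0$truth))

  zm1 <- generate_z_mixture(mixture_spec(epsilon = 1, f1_mean = 5,
                                         f1_sd = 0, seed = 1))
  expect_true(all(zm1$truth))
  expect_true(all(zm1$z == 5))

  zma <- generate_z_mixture(mixture_spec(epsilon = 0.05, seed = 9))
  zmb <- generate_z_mixture(mixture_spec(epsilon = 0.05, seed = 9))
  expect_identical(zma$z, zmb$z)

  # non-null count is binomial(p, 0.05): check the mean over 100 seeds
  n1 <- sapply(1:100, function(s) {
    sum(generate_z_mixture(mixture_spec(epsilon = 0.05, seed = s))$truth)
  })
  p <- 59 * 59
  expect_lt(abs(mean(n1) - p * 0.05),
            3 * sqrt(p * 0.05 * 0.95 / 100))
})

test_that("null entries of the z mixture are N(0, sigma^2)", {
  zm <- generate_z_mixture(mixture_spec(epsilon = 0.05, sigma = 1.5,
                                        dim = c(120, 120), seed = 2))
  ks <- suppressWarnings(stats::ks.test(zm$z[!zm$truth], "pnorm", 0, 1.5))
  expect_gt(ks$p.value, 0.01)
})

test_that("a generated study writes two sessions per culture-day plus truth", {
  mf <- study_manifest(data.frame(culture_id = "c1", batch_id = "b1",
                                  density_class = "dense"))
  dir <- withr::local_tempdir()
  idx <- generate_study(mf, growth_schedule(), seed = 3, out_dir = dir,
                        days = c(10, 20), spont_duration_s = 30)
  expect_equal(nrow(idx), 2)
  session_files <- list.files(dir, pattern = "_(stim|spont)\\.csv$")
  expect_equal(length(session_files), 4) # 2 days x 2 session kinds
  expect_true(all(file.exists(idx$truth_file)))
  # determinism: regenerating gives byte-identical session files
  dir2 <- withr::local_tempdir()
  generate_study(mf, growth_schedule(), seed = 3, out_dir = dir2,
                 days = c(10, 20), spont_duration_s = 30)
  f1 <- file.path(dir, "c1_d10_stim.csv")
  f2 <- file.path(dir2, "c1_d10_stim.csv")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("same-batch cultures are more similar than cross-batch ones", {
  mf <- study_manifest(data.frame(
    culture_id = paste0("c", 1:4),
    batch_id = c("b1", "b1", "b2", "b2"),
    density_class = "dense"))
  diffs <- t(sapply(1:50, function(s) {
    st <- generate_latent_study(mf, seed = s)
    e30 <- sapply(st$trajectories, function(tr) {
      nrow(network_on_day(tr, 30))
    })
    c(within = as.numeric(abs(e30[1] - e30[2])),
      across = as.numeric(abs(e30[1] - e30[3])))
  }))
  expect_lt(mean(diffs[, "within"]), mean(diffs[, "across"]))
})
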