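#' Table of plating density classes
#'
#' The three plating conditions of the study design: dense (20 uL of
#' suspension at 2500 cells/uL), small (5 uL at 2500 cells/uL) and sparse
#' (20 uL at 625 cells/uL). The nominal number of plated cells is plating
#' volume times suspension density.
#'
#' @param class optional class name (`"dense"`, `"small"`, `"sparse"`) to
#'   select one row.
#' @return data.frame with columns `density_class`, `plating_volume_ul`,
#'   `suspension_density_per_ul`, `nominal_cells`, `n_cultures`,
#'   `n_batches`.
#' @export
plating_info <- function(class = NULL) {
  info <- data.frame(
    density_class = c("dense", "small", "sparse"),
    plating_volume_ul = c(20, 5, 20),
    suspension_density_per_ul = c(2500, 2500, 625),
    n_cultures = c(15L, 7L, 6L),
    n_batches = c(6L, 2L, 2L),
    stringsAsFactors = FALSE
  )
  info$nominal_cells <- info$plating_volume_ul * info$suspension_density_per_ul
  if (!is.null(class)) {
    if (!class %in% info$density_class) {
      stop("unknown density class '", class, "'", call. = FALSE)
    }
    info <- info[info$density_class == class, , drop = FALSE]
    rownames(info) <- NULL
  }
  info
}

#' Study manifest
#'
#' Declares the cultures of a (synthetic) study: which batch each culture
#' belongs to and its plating density class. Recorded days default to
#' every day of the growth schedule.
#'
#' @param cultures data.frame with columns `culture_id`, `batch_id`,
#'   `density_class`.
#' @return a `study_manifest` data.frame.
#' @export
study_manifest <- function(cultures) {
  need <- c("culture_id", "batch_id", "density_class")
  miss <- setdiff(need, names(cultures))
  if (length(miss)) {
    stop("manifest is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(cultures$culture_id)) {
    stop("duplicate culture ids in manifest", call. = FALSE)
  }
  bad <- setdiff(unique(cultures$density_class), plating_info()$density_class)
  if (length(bad)) {
    stop("unknown density class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(as.data.frame(cultures), class = c("study_manifest", "data.frame"))
}

#' Network growth schedule
#'
#' Parameters of the two-phase developmental trajectory the generator
#' emulates: a quiescent phase of about five days with essentially no
#' significant connectivity, a rapid-growth phase of 10-15 days during
#' which both the number and the physical reach of connections increase,
#' and a plateau thereafter, over a horizon of about 40 days in vitro.
#'
#' @param quiescent_days days with no connectivity, default 5.
#' @param growth_days duration of the rapid-growth phase, default 12.
#' @param total_days simulated horizon, default 40.
#' @param plateau_density fraction of ordered electrode pairs connected at
#'   plateau, default 0.07 (about 240 of the 3422 ordered pairs).
#' @param length_scale_start_um,length_scale_end_um spatial scale of the
#'   exponential distance kernel from which new edges are drawn, at the
#'   start and end of the growth phase; the increase makes later
#'   connections physically longer.
#' @param hub_fraction fraction of electrodes biased to accumulate edges
#'   (so in/out-degree >= 4 hubs emerge by plateau), default 0.15.
#' @param hub_bias multiplicative sampling weight for hub endpoints,
#'   default 4.
#' @param response_prob range of per-edge evoked-response probabilities.
#' @param latency_fractions mixture over evoked latency classes: direct
#'   (0-20 ms), early post-synaptic (within the 100 ms window) and
#'   culture-wide barrage (beyond 100 ms).
#' @param latency_bands_ms list of `c(min, max)` latency bands (ms) per
#'   class; the early band is exposed as a parameter since its upper edge
#'   is convention, not biology.
#' @param density_scale multiplier on `plateau_density` for sparser
#'   platings (the per-class default is the square root of the nominal
#'   cell count relative to a dense plating).
#' @return a `growth_schedule` list.
#' @export
growth_schedule <- function(quiescent_days = 5, growth_days = 12,
                            total_days = 40, plateau_density = 0.07,
                            length_scale_start_um = 250,
                            length_scale_end_um = 800,
                            hub_fraction = 0.15, hub_bias = 4,
                            response_prob = c(0.4, 0.9),
                            latency_fractions = c(direct = 0.5,
                                                  early = 0.35,
                                                  barrage = 0.15),
                            latency_bands_ms = list(direct = c(0, 20),
                                                    early = c(5, 100),
                                                    barrage = c(100, 250)),
                            density_scale = 1) {
  if (quiescent_days < 0 || growth_days <= 0) {
    stop("phase durations must be positive", call. = FALSE)
  }
  if (quiescent_days + growth_days > total_days) {
    stop("schedule phases exceed the simulated horizon of ", total_days,
         " days", call. = FALSE)
  }
  if (plateau_density < 0 || plateau_density > 1) {
    stop("`plateau_density` must be in [0, 1]", call. = FALSE)
  }
  fr <- latency_fractions / sum(latency_fractions)
  structure(list(quiescent_days = quiescent_days, growth_days = growth_days,
                 total_days = total_days, plateau_density = plateau_density,
                 length_scale_start_um = length_scale_start_um,
                 length_scale_end_um = length_scale_end_um,
                 hub_fraction = hub_fraction, hub_bias = hub_bias,
                 response_prob = response_prob, latency_fractions = fr,
                 latency_bands_ms = latency_bands_ms,
                 density_scale = density_scale),
            class = "growth_schedule")
}

#' Spontaneous firing parameters
#'
#' Dissociated cortical cultures fire spontaneously at a baseline rate
#' punctuated by network-wide bursts; the generator models each electrode
#' as Poisson at `baseline_hz` outside bursts and `burst_multiplier *
#' baseline_hz` inside them, with burst onsets arriving as a Poisson
#' process shared by all electrodes.
#'
#' @param baseline_hz per-electrode baseline firing rate, default 1 Hz.
#' @param burst_rate_hz network burst onset rate, default 0.05 Hz (one
#'   burst per ~20 s).
#' @param burst_duration_s burst length, default 0.3 s.
#' @param burst_multiplier within-burst rate multiplier, default 20.
#' @return a `firing_params` list.
#' @export
firing_params <- function(baseline_hz = 1, burst_rate_hz = 0.05,
                          burst_duration_s = 0.3, burst_multiplier = 20) {
  vals <- c(baseline_hz, burst_rate_hz, burst_duration_s, burst_multiplier)
  if (any(vals < 0)) stop("firing rates must be non-negative", call. = FALSE)
  structure(list(baseline_hz = baseline_hz, burst_rate_hz = burst_rate_hz,
                 burst_duration_s = burst_duration_s,
                 burst_multiplier = burst_multiplier),
            class = "firing_params")
}

#' Stimulation protocol
#'
#' The study protocol: 50 pulses delivered to each of the 59 electrodes,
#' sequentially, once every 300 ms.
#'
#' @param n_pulses pulses per electrode, default 50.
#' @param ipi_s inter-pulse interval in seconds, default 0.3.
#' @return a `stim_protocol` list.
#' @export
stim_protocol <- function(n_pulses = 50, ipi_s = 0.3) {
  if (n_pulses < 1 || ipi_s <= 0) stop("invalid protocol", call. = FALSE)
  structure(list(n_pulses = n_pulses, ipi_s = ipi_s),
            class = "stim_protocol")
}

#' Generate a latent connectivity trajectory
#'
#' Simulates the day-by-day growth of the hidden directed network that
#' drives evoked responses. Edges accumulate (never disappear) toward the
#' plateau count; each day's new edges are drawn over unconnected ordered
#' pairs with probability proportional to
#' `exp(-distance / length_scale(day))` times a hub bias, with the length
#' scale widening over the growth phase — so both the expected edge count
#' and the expected edge length increase during growth and flatten at
#' plateau. Each edge carries a response probability and an evoked-latency
#' class.
#'
#' @param map an `electrode_map`.
#' @param schedule a [growth_schedule].
#' @param seed RNG seed; the trajectory is a pure function of
#'   `(map, schedule, seed)`.
#' @return a `latent_trajectory` list: `edges` (data.frame `from`, `to`,
#'   `length_um`, `weight`, `latency_class`, `day_added`), `days`,
#'   `schedule`, `seed`. Use [network_on_day()] to extract one day's
#'   network.
#' @export
generate_latent_trajectory <- function(map, schedule = growth_schedule(),
                                       seed = NULL) {
  el <- analysis_electrodes(map)
  ids <- el$electrode_id
  n <- length(ids)
  dmat <- electrode_distances(map)
  pair <- expand.grid(from = seq_len(n), to = seq_len(n))
  pair <- pair[pair$from != pair$to, , drop = FALSE]
  pair$dist <- dmat[cbind(pair$from, pair$to)]
  n_pairs <- nrow(pair)
  n_plateau <- round(schedule$plateau_density * schedule$density_scale *
                       n_pairs)
  n_plateau <- min(n_plateau, n_pairs)
  q <- schedule$quiescent_days
  g <- schedule$growth_days
  target <- function(d) {
    if (d <= q) return(0L)
    if (d <= q + g) return(as.integer(round(n_plateau * (d - q) / g)))
    as.integer(n_plateau)
  }
  lscale <- function(d) {
    frac <- min(1, max(0, (d - q) / g))
    schedule$length_scale_start_um +
      frac * (schedule$length_scale_end_um - schedule$length_scale_start_um)
  }
  classes <- names(schedule$latency_fractions)
  with_seed(seed, {
    n_hub <- round(schedule$hub_fraction * n)
    hubs_out <- sample(n, n_hub)
    hubs_in <- sample(n, n_hub)
    hub_w_from <- ifelse(pair$from %in% hubs_out, schedule$hub_bias, 1)
    hub_w_to <- ifelse(pair$to %in% hubs_in, schedule$hub_bias, 1)
    available <- rep(TRUE, n_pairs)
    picked <- integer(0)
    day_added <- integer(0)
    for (d in seq_len(schedule$total_days)) {
      n_new <- target(d) - length(picked)
      if (n_new <= 0) next
      w <- exp(-pair$dist / lscale(d)) * hub_w_from * hub_w_to
      avail <- which(available)
      sel <- if (length(avail) == 1) avail else {
        avail[sample.int(length(avail), n_new, prob = w[avail])]
      }
      available[sel] <- FALSE
      picked <- c(picked, sel)
      day_added <- c(day_added, rep(d, length(sel)))
    }
    edges <- data.frame(
      from = ids[pair$from[picked]],
      to = ids[pair$to[picked]],
      length_um = pair$dist[picked],
      weight = runif(length(picked), schedule$response_prob[1],
                     schedule$response_prob[2]),
      latency_class = if (length(picked)) {
        sample(classes, length(picked), replace = TRUE,
               prob = schedule$latency_fractions)
      } else character(0),
      day_added = day_added,
      stringsAsFactors = FALSE
    )
    structure(list(edges = edges, days = seq_len(schedule$total_days),
                   schedule = schedule, seed = seed,
                   electrode_ids = ids),
              class = "latent_trajectory")
  })
}

#' Extract one day's latent network
#'
#' @param trajectory a `latent_trajectory`.
#' @param day day in vitro.
#' @return data.frame of the edges present on that day.
#' @export
network_on_day <- function(trajectory, day) {
  trajectory$edges[trajectory$edges$day_added <= day, , drop = FALSE]
}

#' Per-day metrics of the latent network
#'
#' Ground-truth counterparts of the pipeline metrics, computed directly on
#' the hidden network: edge count, mean edge length, and supernode counts
#' (in/out degree >= `threshold`). Used to validate what the pipeline
#' recovers.
#'
#' @param trajectory a `latent_trajectory`.
#' @param threshold supernode degree threshold, default 4.
#' @return data.frame with one row per day.
#' @export
latent_daily_metrics <- function(trajectory, threshold = 4) {
  do.call(rbind, lapply(trajectory$days, function(d) {
    net <- network_on_day(trajectory, d)
    data.frame(
      day_in_vitro = d,
      n_edges = nrow(net),
      mean_edge_length_um = if (nrow(net)) mean(net$length_um) else NA_real_,
      n_incoming_supernodes = sum(table(net$to) >= threshold),
      n_outgoing_supernodes = sum(table(net$from) >= threshold)
    )
  }))
}

# attach session metadata to a (possibly empty) electrode/time table
spike_metadata <- function(spk, session_id, kind, day, culture, batch) {
  if (is.null(spk) || nrow(spk) == 0) return(empty_spike_table())
  data.frame(electrode_id = spk$electrode_id, time_s = spk$time_s,
             session_id = session_id, session_kind = kind,
             day_in_vitro = day, culture_id = culture, batch_id = batch,
             stringsAsFactors = FALSE)
}

# spontaneous spike times for all electrodes; caller manages the RNG
r_spontaneous_spikes <- function(ids, firing, duration_s) {
  n_bursts <- rpois(1, firing$burst_rate_hz * duration_s)
  bursts <- NULL
  burst_time <- 0
  if (n_bursts > 0 && firing$burst_duration_s > 0) {
    on <- sort(runif(n_bursts, 0, duration_s))
    off <- pmin(on + firing$burst_duration_s, duration_s)
    # merge overlaps so within-burst time is not double-counted
    keep_on <- on[1]; keep_off <- off[1]
    if (n_bursts > 1) {
      for (i in 2:n_bursts) {
        if (on[i] <= keep_off[length(keep_off)]) {
          keep_off[length(keep_off)] <- max(keep_off[length(keep_off)], off[i])
        } else {
          keep_on <- c(keep_on, on[i]); keep_off <- c(keep_off, off[i])
        }
      }
    }
    bursts <- cbind(keep_on, keep_off)
    burst_time <- sum(keep_off - keep_on)
  }
  extra_rate <- (firing$burst_multiplier - 1) * firing$baseline_hz
  n_el <- length(ids)
  n0 <- rpois(n_el, firing$baseline_hz * duration_s)
  el0 <- rep.int(seq_len(n_el), n0)
  t0 <- runif(sum(n0), 0, duration_s)
  el1 <- integer(0)
  t1 <- numeric(0)
  if (burst_time > 0 && extra_rate > 0) {
    n1 <- rpois(n_el, extra_rate * burst_time)
    if (sum(n1) > 0) {
      el1 <- rep.int(seq_len(n_el), n1)
      len <- bursts[, 2] - bursts[, 1]
      which_b <- sample.int(nrow(bursts), sum(n1), replace = TRUE,
                            prob = len)
      t1 <- bursts[which_b, 1] + runif(sum(n1)) * len[which_b]
    }
  }
  el <- c(el0, el1)
  tt <- c(t0, t1)
  if (!length(tt)) return(NULL)
  data.frame(electrode_id = ids[el], time_s = tt, stringsAsFactors = FALSE)
}

#' Simulate a spontaneous recording session
#'
#' Per-electrode spikes from an inhomogeneous Poisson process: a baseline
#' rate plus network-wide burst epochs shared by all electrodes (see
#' [firing_params()]).
#'
#' @param map an `electrode_map`.
#' @param day_in_vitro day label for the session metadata.
#' @param firing a [firing_params].
#' @param duration_s recording length in seconds.
#' @param seed RNG seed.
#' @param culture_id,batch_id,session_id session metadata; `session_id`
#'   defaults to `"<culture>_d<day>_spont"`.
#' @return a [spike_events] object (no pulse table).
#' @export
simulate_spontaneous <- function(map, day_in_vitro = NA_integer_,
                                 firing = firing_params(), duration_s = 300,
                                 seed = NULL, culture_id = "c1",
                                 batch_id = "b1", session_id = NULL) {
  if (duration_s <= 0) stop("`duration_s` must be positive", call. = FALSE)
  ids <- analysis_electrodes(map)$electrode_id
  if (is.null(session_id)) {
    session_id <- paste0(culture_id, "_d", day_in_vitro, "_spont")
  }
  spk <- with_seed(seed, r_spontaneous_spikes(ids, firing, duration_s))
  spikes <- spike_metadata(spk, session_id, "spontaneous", day_in_vitro,
                           culture_id, batch_id)
  spike_events(spikes, duration_s = duration_s, map = map)
}

#' Simulate a stimulation session
#'
#' Delivers the full protocol (by default 50 pulses to each electrode in
#' sequence, one pulse every 300 ms) against a latent network: each pulse
#' at electrode `k` evokes, independently for every edge `k -> j`, a spike
#' at `j` with the edge's response probability, at a latency drawn
#' uniformly from the edge's latency-class band. Evoked spikes are
#' superimposed on spontaneous background activity covering the whole
#' session.
#'
#' @param map an `electrode_map`.
#' @param network one day's latent network (data.frame from
#'   [network_on_day()], or a whole `latent_trajectory` plus
#'   `day_in_vitro`).
#' @param protocol a [stim_protocol].
#' @param firing background [firing_params] (use
#'   `firing_params(0, 0, 0, 0)` for a noiseless session).
#' @param day_in_vitro,culture_id,batch_id,session_id session metadata.
#' @param seed RNG seed.
#' @param latency_bands_ms latency bands per class; defaults to the bands
#'   of [growth_schedule()].
#' @return a [spike_events] object with a pulse table of
#'   `n_electrodes * n_pulses` rows.
#' @export
simulate_stimulation_session <- function(map, network,
                                         protocol = stim_protocol(),
                                         firing = firing_params(),
                                         day_in_vitro = NA_integer_,
                                         culture_id = "c1", batch_id = "b1",
                                         session_id = NULL, seed = NULL,
                                         latency_bands_ms = NULL) {
  if (inherits(network, "latent_trajectory")) {
    if (is.na(day_in_vitro)) {
      stop("give `day_in_vitro` to pick a day from a trajectory",
           call. = FALSE)
    }
    if (is.null(latency_bands_ms)) {
      latency_bands_ms <- network$schedule$latency_bands_ms
    }
    network <- network_on_day(network, day_in_vitro)
  }
  if (is.null(latency_bands_ms)) {
    latency_bands_ms <- growth_schedule()$latency_bands_ms
  }
  ids <- analysis_electrodes(map)$electrode_id
  if (nrow(network)) {
    unknown <- setdiff(unique(c(network$from, network$to)), ids)
    if (length(unknown)) {
      stop("network electrodes not in map: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  if (is.null(session_id)) {
    session_id <- paste0(culture_id, "_d", day_in_vitro, "_stim")
  }
  n <- length(ids)
  duration_s <- n * protocol$n_pulses * protocol$ipi_s
  pulses <- data.frame(
    stim_electrode_id = rep(ids, each = protocol$n_pulses),
    pulse_time_s = (seq_len(n * protocol$n_pulses) - 1) * protocol$ipi_s,
    trial_index = rep(0:(protocol$n_pulses - 1), times = n),
    session_id = session_id,
    stringsAsFactors = FALSE
  )
  with_seed(seed, {
    spont <- r_spontaneous_spikes(ids, firing, duration_s)
    evoked <- NULL
    if (nrow(network)) {
      # one Bernoulli per (edge, pulse at its source electrode)
      e_idx <- rep(seq_len(nrow(network)), each = protocol$n_pulses)
      src <- network$from[e_idx]
      trial <- rep(0:(protocol$n_pulses - 1), times = nrow(network))
      p_time <- ((match(src, ids) - 1) * protocol$n_pulses + trial) *
        protocol$ipi_s
      hit <- runif(length(e_idx)) < network$weight[e_idx]
      if (any(hit)) {
        band <- do.call(rbind, latency_bands_ms[network$latency_class[e_idx[hit]]])
        lat_s <- (band[, 1] + runif(sum(hit)) * (band[, 2] - band[, 1])) / 1000
        evoked <- data.frame(electrode_id = network$to[e_idx[hit]],
                             time_s = p_time[hit] + lat_s,
                             stringsAsFactors = FALSE)
      }
    }
    spk <- rbind(spont, evoked)
    spikes <- spike_metadata(spk, session_id, "stimulation", day_in_vitro,
                             culture_id, batch_id)
    spike_events(spikes, pulses,
                 duration_s = max(duration_s, spikes$time_s),
                 n_trials = protocol$n_pulses, map = map)
  })
}

#' Generate a complete synthetic study on disk
#'
#' For every culture and recorded day, simulates one stimulation session
#' and one spontaneous session and writes them in the package's file
#' formats, together with the ground-truth edge list of the latent network
#' for that culture-day. Cultures in the same batch share batch-level
#' multipliers on the growth schedule (plateau density and the length
#' scales) with only small per-culture jitter, and also share the latent
#' network template (the realization seed of the trajectory) — emulating
#' the structural similarity of cultures dissociated from the same brain
#' tissue — so batches differ far more than cultures within a batch.
#' Everything is a deterministic function of
#' `seed` via [derive_seed()]; any single session can be re-simulated
#' without regenerating the study.
#'
#' @param manifest a [study_manifest].
#' @param schedule a [growth_schedule]; per-culture schedules are derived
#'   from it.
#' @param seed master seed.
#' @param out_dir output directory (created if needed); `NULL` returns the
#'   simulated objects without writing files.
#' @param days recorded days in vitro, default `1:total_days`.
#' @param firing background [firing_params].
#' @param protocol a [stim_protocol].
#' @param spont_duration_s length of each spontaneous session, default
#'   120 s.
#' @param batch_sd,culture_sd standard deviations of the log-normal
#'   batch-level and culture-level multipliers (defaults 0.25 and 0.05:
#'   strong batch offsets, small within-batch jitter).
#' @return invisibly, a data.frame index of the written sessions (columns
#'   `culture_id`, `batch_id`, `day_in_vitro`, `stim_file`, `spont_file`,
#'   `truth_file`) with the per-culture trajectories attached as attribute
#'   `"trajectories"`.
#' @export
generate_study <- function(manifest, schedule = growth_schedule(), seed = 1,
                           out_dir = NULL, days = NULL,
                           firing = firing_params(),
                           protocol = stim_protocol(),
                           spont_duration_s = 120,
                           batch_sd = 0.25, culture_sd = 0.05) {
  map <- standard_mea_layout()
  if (is.null(days)) days <- seq_len(schedule$total_days)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  scheds <- culture_schedules(manifest, schedule, seed, batch_sd, culture_sd)
  batches <- unique(manifest$batch_id)

  index <- list()
  trajectories <- list()
  for (ci in seq_len(nrow(manifest))) {
    cid <- manifest$culture_id[ci]
    bid <- manifest$batch_id[ci]
    traj <- generate_latent_trajectory(
      map, scheds[[cid]],
      seed = derive_seed(seed, 3, match(bid, batches)))
    trajectories[[cid]] <- traj
    for (d in days) {
      stim <- simulate_stimulation_session(
        map, traj, protocol = protocol, firing = firing,
        day_in_vitro = d, culture_id = cid, batch_id = bid,
        seed = derive_seed(seed, 4, ci, d))
      spont <- simulate_spontaneous(
        map, day_in_vitro = d, firing = firing,
        duration_s = spont_duration_s, culture_id = cid, batch_id = bid,
        seed = derive_seed(seed, 5, ci, d))
      stim_file <- spont_file <- truth_file <- NA_character_
      if (!is.null(out_dir)) {
        stim_file <- file.path(out_dir, paste0(cid, "_d", d, "_stim.csv"))
        spont_file <- file.path(out_dir, paste0(cid, "_d", d, "_spont.csv"))
        truth_file <- file.path(out_dir, paste0("truth_", cid, "_d", d,
                                                ".csv"))
        write_spike_events(stim, stim_file)
        write_spike_events(spont, spont_file)
        write_precise_csv(network_on_day(traj, d), truth_file)
      }
      index[[length(index) + 1]] <- data.frame(
        culture_id = cid, batch_id = bid, day_in_vitro = d,
        stim_file = stim_file, spont_file = spont_file,
        truth_file = truth_file, stringsAsFactors = FALSE)
    }
  }
  idx <- do.call(rbind, index)
  if (!is.null(out_dir)) {
    write.csv(as.data.frame(manifest),
              file.path(out_dir, "manifest.csv"), row.names = FALSE,
              quote = FALSE)
  }
  attr(idx, "trajectories") <- trajectories
  invisible(idx)
}

# batch-level multipliers shared by cultures of a batch, small per-culture
# jitter on top; pure function of (manifest, schedule, seed)
culture_schedules <- function(manifest, schedule, seed, batch_sd = 0.25,
                              culture_sd = 0.05) {
  batches <- unique(manifest$batch_id)
  batch_mult <- lapply(seq_along(batches), function(bi) {
    with_seed(derive_seed(seed, 1, bi), {
      list(density = exp(rnorm(1, 0, batch_sd)),
           length = exp(rnorm(1, 0, batch_sd)))
    })
  })
  names(batch_mult) <- batches
  out <- list()
  for (ci in seq_len(nrow(manifest))) {
    cid <- manifest$culture_id[ci]
    dclass <- manifest$density_class[ci]
    dscale <- sqrt(plating_info(dclass)$nominal_cells /
                     plating_info("dense")$nominal_cells)
    cmult <- with_seed(derive_seed(seed, 2, ci), {
      list(density = exp(rnorm(1, 0, culture_sd)),
           length = exp(rnorm(1, 0, culture_sd)))
    })
    bm <- batch_mult[[manifest$batch_id[ci]]]
    sched_c <- schedule
    sched_c$plateau_density <- min(1, schedule$plateau_density *
                                     bm$density * cmult$density)
    sched_c$length_scale_start_um <- schedule$length_scale_start_um *
      bm$length * cmult$length
    sched_c$length_scale_end_um <- schedule$length_scale_end_um *
      bm$length * cmult$length
    sched_c$density_scale <- schedule$density_scale * dscale
    out[[cid]] <- sched_c
  }
  out
}

#' Generate a latent-only study (no spike simulation)
#'
#' Same batch/culture parameter structure as [generate_study()] — shared
#' batch-level multipliers, small per-culture jitter, density-class
#' scaling — but returns only the hidden networks and their ground-truth
#' daily metrics, in the pipeline's metrics-table format. Useful for
#' validating the longitudinal statistics stage over many replicate
#' studies where spike-level simulation would be wasteful.
#'
#' @inheritParams generate_study
#' @return list with `trajectories` (named list of `latent_trajectory`)
#'   and `metrics` (wide metrics table with ground-truth values; the
#'   latent mean edge length fills the `mean_connection_length_um`
#'   column, `window_ms` is `NA`).
#' @export
generate_latent_study <- function(manifest, schedule = growth_schedule(),
                                  seed = 1, days = NULL,
                                  batch_sd = 0.25, culture_sd = 0.05) {
  map <- standard_mea_layout()
  if (is.null(days)) days <- seq_len(schedule$total_days)
  scheds <- culture_schedules(manifest, schedule, seed, batch_sd, culture_sd)
  batches <- unique(manifest$batch_id)
  trajectories <- list()
  rows <- list()
  for (ci in seq_len(nrow(manifest))) {
    cid <- manifest$culture_id[ci]
    traj <- generate_latent_trajectory(
      map, scheds[[cid]],
      seed = derive_seed(seed, 3, match(manifest$batch_id[ci], batches)))
    trajectories[[cid]] <- traj
    lm <- latent_daily_metrics(traj)
    lm <- lm[lm$day_in_vitro %in% days, , drop = FALSE]
    rows[[ci]] <- data.frame(
      culture_id = cid, batch_id = manifest$batch_id[ci],
      day_in_vitro = lm$day_in_vitro, window_ms = NA_real_,
      n_edges = lm$n_edges,
      mean_connection_length_um = lm$mean_edge_length_um,
      n_incoming_supernodes = lm$n_incoming_supernodes,
      n_outgoing_supernodes = lm$n_outgoing_supernodes,
      stringsAsFactors = FALSE)
  }
  list(trajectories = trajectories, metrics = do.call(rbind, rows))
}

#' Two-group mixture specification for Z matrices
#'
#' The hypothesis-testing model for the entries of the response matrix:
#' with probability `1 - epsilon` an entry is null, drawn from
#' `N(0, sigma^2)`; with probability `epsilon` it is a true connection,
#' drawn from the non-null distribution `f1` (by default
#' `N(f1_mean, f1_sd^2)`).
#'
#' @param epsilon non-null proportion in `[0, 1]`.
#' @param sigma null standard deviation.
#' @param f1_mean,f1_sd location and scale of the Gaussian non-null
#'   component (`f1_sd = 0` gives a point mass).
#' @param f1_sampler optional function `n -> numeric(n)` replacing the
#'   Gaussian non-null sampler.
#' @param dim matrix dimensions, default `c(59, 59)`.
#' @param seed RNG seed.
#' @return a `mixture_spec` list.
#' @export
mixture_spec <- function(epsilon = 0.05, sigma = 1, f1_mean = 4, f1_sd = 1,
                         f1_sampler = NULL, dim = c(59, 59), seed = NULL) {
  if (epsilon < 0 || epsilon > 1) stop("`epsilon` must be in [0, 1]",
                                       call. = FALSE)
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  structure(list(epsilon = epsilon, sigma = sigma, f1_mean = f1_mean,
                 f1_sd = f1_sd, f1_sampler = f1_sampler, dim = dim,
                 seed = seed),
            class = "mixture_spec")
}

#' Draw a Z matrix from the two-group mixture
#'
#' Samples a response matrix directly from the mixture model together with
#' its ground-truth non-null mask, for fast validation of the local FDR
#' stage (false discovery proportion, power, parameter recovery) without
#' simulating spikes.
#'
#' @param spec a [mixture_spec].
#' @return list with `z` (numeric matrix) and `truth` (logical matrix,
#'   `TRUE` = genuinely non-null).
#' @examples
#' zm <- generate_z_mixture(mixture_spec(epsilon = 0.05, seed = 1))
#' mean(zm$truth) # about 0.05
#' @export
generate_z_mixture <- function(spec) {
  p <- prod(spec$dim)
  with_seed(spec$seed, {
    truth <- matrix(runif(p) < spec$epsilon, spec$dim[1], spec$dim[2])
    z <- matrix(rnorm(p, 0, spec$sigma), spec$dim[1], spec$dim[2])
    n1 <- sum(truth)
    if (n1 > 0) {
      z[truth] <- if (is.null(spec$f1_sampler)) {
        rnorm(n1, spec$f1_mean, spec$f1_sd)
      } else {
        spec$f1_sampler(n1)
      }
    }
    list(z = z, truth = truth)
  })
}
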