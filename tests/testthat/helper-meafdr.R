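# shared fixtures and independent oracles

std_map <- standard_mea_layout()
std_ids <- analysis_electrodes(std_map)$electrode_id

# minimal spike table with required metadata
make_spikes <- function(electrode_id, time_s, session_id = "s1",
                        session_kind = "stimulation", day = 10,
                        culture = "c1", batch = "b1") {
  if (length(electrode_id) == 0) {
    return(data.frame(electrode_id = character(), time_s = numeric(),
                      session_id = character(), session_kind = character(),
                      day_in_vitro = integer(), culture_id = character(),
                      batch_id = character(), stringsAsFactors = FALSE))
  }
  data.frame(electrode_id = electrode_id, time_s = time_s,
             session_id = session_id, session_kind = session_kind,
             day_in_vitro = day, culture_id = culture, batch_id = batch,
             stringsAsFactors = FALSE)
}

# full pulse table: every analysis electrode x n_trials, 300 ms spacing
make_pulses <- function(ids = std_ids, n_trials = 50, ipi = 0.3,
                        session_id = "s1") {
  data.frame(stim_electrode_id = rep(ids, each = n_trials),
             pulse_time_s = (seq_len(length(ids) * n_trials) - 1) * ipi,
             trial_index = rep(0:(n_trials - 1), times = length(ids)),
             session_id = session_id, stringsAsFactors = FALSE)
}

# stimulation-session spike_events with given spikes and a full pulse table
make_stim_events <- function(spikes = make_spikes(character(), numeric()),
                             ids = std_ids, n_trials = 50) {
  spike_events(spikes, make_pulses(ids, n_trials), n_trials = n_trials)
}

# independent oracle for the ranked local-FDR cut: explicit running-sum scan
# over every prefix of the ascending-sorted statistics
oracle_cut_index <- function(t_vals, level) {
  ts <- sort(t_vals)
  s <- 0
  best <- 0L
  for (i in seq_along(ts)) {
    s <- s + ts[i]
    if (s / i <= level) best <- i
  }
  best
}

# brute-force one-way ANOVA F from explicit sums of squares
oracle_anova_f <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  (ssb / dfb) / (ssw / dfw)
}

# empirical false discovery proportion with the V/max(R,1) convention
fdp_of <- function(mask, truth) {
  R <- sum(mask)
  sum(mask & !truth) / max(R, 1)
}
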