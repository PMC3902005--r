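#' Post-stimulus counting window
#'
#' Spikes are counted in the interval `(pulse + blank, pulse + window]`
#' after each stimulus pulse. The study windows are 50, 100 and 150 ms,
#' chosen to capture three latency classes of evoked activity: direct
#' responses (0-20 ms), early post-synaptic spikes (within ~100 ms) and
#' culture-wide barrages (beyond 100 ms). Any positive window is accepted.
#'
#' @param window_ms window length in milliseconds.
#' @param artifact_blank_ms dead time after the pulse during which spikes
#'   are ignored (stimulus-artifact suppression; default 0, i.e. count from
#'   stimulus onset).
#' @return a `window_spec` list.
#' @export
window_spec <- function(window_ms = 100, artifact_blank_ms = 0) {
  if (!is.numeric(window_ms) || window_ms <= 0) {
    stop("`window_ms` must be positive", call. = FALSE)
  }
  if (artifact_blank_ms < 0 || artifact_blank_ms >= window_ms) {
    stop("need 0 <= artifact_blank_ms < window_ms", call. = FALSE)
  }
  structure(list(window_ms = window_ms, artifact_blank_ms = artifact_blank_ms),
            class = "window_spec")
}

#' Count evoked spikes per stimulated electrode, recording electrode, trial
#'
#' Builds the per-day count array: entry `(k, j, t)` is the number of
#' spikes recorded at electrode `j` during
#' `(pulse + blank, pulse + window]` for trial `t` of stimulation at
#' electrode `k`. With 59 electrodes and 50 trials this is the
#' 59 x 59 x 50 array that one stimulation session yields.
#'
#' @param events a [spike_events] object from a stimulation session, with
#'   its pulse table.
#' @param map an `electrode_map`.
#' @param window a [window_spec].
#' @return integer array `n_electrodes x n_electrodes x n_trials` with
#'   dimnames (stimulated id, recording id, trial).
#' @export
count_evoked <- function(events, map, window = window_spec()) {
  if (is.null(events$pulses) || nrow(events$pulses) == 0) {
    stop("stimulation session has no pulse table", call. = FALSE)
  }
  ids <- analysis_electrodes(map)$electrode_id
  n <- length(ids)
  n_trials <- events$n_trials
  pulses <- events$pulses
  if (length(unique(pulses$session_id)) > 1) {
    stop("count_evoked() expects a single stimulation session; got ",
         length(unique(pulses$session_id)), call. = FALSE)
  }

  expected <- expand.grid(stim_electrode_id = ids,
                          trial_index = 0:(n_trials - 1),
                          stringsAsFactors = FALSE)
  have <- paste(pulses$stim_electrode_id, pulses$trial_index)
  missing <- setdiff(paste(expected$stim_electrode_id, expected$trial_index),
                     have)
  if (length(missing)) {
    stop("missing trials (stim_electrode trial): ",
         paste(head(missing, 10), collapse = "; "),
         if (length(missing) > 10) " ...", call. = FALSE)
  }

  ipi <- suppressWarnings(min(diff(sort(pulses$pulse_time_s))))
  if (is.finite(ipi) && window$window_ms / 1000 > ipi) {
    warning("counting window (", window$window_ms,
            " ms) exceeds the inter-pulse interval (", round(ipi * 1000),
            " ms): windows overlap the next pulse's responses",
            call. = FALSE)
  }

  blank_s <- window$artifact_blank_ms / 1000
  win_s <- window$window_ms / 1000
  counts <- array(0L, dim = c(n, n, n_trials),
                  dimnames = list(stim = ids, rec = ids,
                                  trial = 0:(n_trials - 1)))
  k_idx <- match(pulses$stim_electrode_id, ids)
  t_idx <- pulses$trial_index + 1L
  spk <- events$spikes[events$spikes$session_kind == "stimulation", ,
                       drop = FALSE]
  by_el <- split(spk$time_s, factor(spk$electrode_id, levels = ids))
  for (j in seq_len(n)) {
    times <- sort(by_el[[j]])
    if (!length(times)) next
    cnt <- findInterval(pulses$pulse_time_s + win_s, times) -
      findInterval(pulses$pulse_time_s + blank_s, times)
    counts[cbind(k_idx, j, t_idx)] <- as.integer(cnt)
  }
  counts
}

#' Flag stimulation trials contaminated by network-wide bursts
#'
#' Dissociated cultures produce spontaneous network-wide bursts; a burst
#' that happens to fall inside one trial's counting window inflates that
#' trial's count at every electrode at once, which the per-pair mixture
#' model then mistakes for a broadly connected stimulation site. Standard
#' MEA practice is to detect and exclude such epochs before averaging.
#' A trial is flagged when its network-wide spike total (summed over all
#' recording electrodes) exceeds `multiplier * median + offset`, the
#' median taken over all trials of the session — a robust threshold that
#' separates bursts (tens of times the background total) from genuine
#' evoked responses (a few times background at most).
#'
#' @param counts array from [count_evoked()].
#' @param multiplier,offset threshold parameters, defaults 5 and 10.
#' @return logical matrix (stimulated electrode x trial), `TRUE` = keep.
#'   If every trial of a stimulated electrode were flagged, all its
#'   trials are kept instead (degenerate case).
#' @export
flag_burst_trials <- function(counts, multiplier = 5, offset = 10) {
  total <- apply(counts, c(1, 3), sum)
  thr <- multiplier * median(total) + offset
  keep <- total <= thr
  dead <- rowSums(keep) == 0
  keep[dead, ] <- TRUE
  keep
}

#' Spontaneous baseline spike count per electrode
#'
#' Mean spike count per counting window in a spontaneous recording from
#' the same culture and day, used to normalize evoked counts. The default
#' places windows as a contiguous tiling of the whole recording (the
#' lowest-variance deterministic estimate); `placement = "random"` draws
#' window starts uniformly instead. The counted interval has length
#' `window_ms - artifact_blank_ms`, matching the effective evoked counting
#' interval, so a stationary process yields an unbiased zero-mean `Z`.
#'
#' @param events a [spike_events] object from a spontaneous session.
#' @param map an `electrode_map`.
#' @param window a [window_spec].
#' @param duration_s recording duration; defaults to the duration recorded
#'   on `events`.
#' @param n_windows number of windows (default: as many as tile the
#'   recording).
#' @param placement `"tile"` (default) or `"random"`.
#' @param seed RNG seed for random placement.
#' @param burst_exclude drop windows whose network-wide spike total
#'   exceeds `burst_multiplier * median + burst_offset` (the same
#'   rule [flag_burst_trials()] applies to stimulation trials, so
#'   evoked and baseline counts are filtered symmetrically). Default
#'   `TRUE`.
#' @param burst_multiplier,burst_offset threshold parameters.
#' @return named numeric vector, mean spikes per window, one per analysis
#'   electrode; attribute `n_windows`.
#' @export
spontaneous_baseline <- function(events, map, window = window_spec(),
                                 duration_s = NULL, n_windows = NULL,
                                 placement = c("tile", "random"),
                                 seed = NULL, burst_exclude = TRUE,
                                 burst_multiplier = 5, burst_offset = 10) {
  placement <- match.arg(placement)
  if (is.null(duration_s)) duration_s <- events$duration_s
  len_s <- (window$window_ms - window$artifact_blank_ms) / 1000
  if (duration_s < len_s) {
    stop("spontaneous recording (", duration_s,
         " s) is shorter than one counting window", call. = FALSE)
  }
  max_tiles <- floor(duration_s / len_s)
  if (is.null(n_windows)) n_windows <- max_tiles
  if (n_windows < 1) stop("`n_windows` must be >= 1", call. = FALSE)
  starts <- switch(placement,
    tile = (seq_len(min(n_windows, max_tiles)) - 1) * len_s,
    random = with_seed(seed, runif(n_windows, 0, duration_s - len_s))
  )
  ids <- analysis_electrodes(map)$electrode_id
  spk <- events$spikes[events$spikes$session_kind == "spontaneous", ,
                       drop = FALSE]
  by_el <- split(spk$time_s, factor(spk$electrode_id, levels = ids))
  win_counts <- vapply(by_el, function(times) {
    if (!length(times)) return(numeric(length(starts)))
    times <- sort(times)
    findInterval(starts + len_s, times) - findInterval(starts, times)
  }, numeric(length(starts)))
  win_counts <- matrix(win_counts, nrow = length(starts))
  keep <- rep(TRUE, length(starts))
  if (burst_exclude && length(starts) > 1) {
    total <- rowSums(win_counts)
    keep <- total <= burst_multiplier * median(total) + burst_offset
    if (!any(keep)) keep <- rep(TRUE, length(starts))
  }
  base <- colMeans(win_counts[keep, , drop = FALSE])
  names(base) <- ids
  attr(base, "n_windows") <- sum(keep)
  base
}

#' Response matrix for one recording day
#'
#' Convenience composition of the whole response-matrix stage: evoked
#' counting, burst-trial exclusion, spontaneous baseline and
#' normalization, for one stimulation session and its matched spontaneous
#' session.
#'
#' @param stim stimulation-session [spike_events] (with pulse table).
#' @param spont matched spontaneous-session [spike_events].
#' @param map an `electrode_map`.
#' @param window a [window_spec].
#' @param burst_exclusion exclude burst-contaminated trials and baseline
#'   windows, default `TRUE`.
#' @param diagonal diagonal policy, see [build_z()].
#' @return a `response_matrix`.
#' @export
session_response_matrix <- function(stim, spont, map,
                                    window = window_spec(),
                                    burst_exclusion = TRUE,
                                    diagonal = "zero") {
  counts <- count_evoked(stim, map, window)
  keep <- if (burst_exclusion) flag_burst_trials(counts) else NULL
  base <- spontaneous_baseline(spont, map, window,
                               burst_exclude = burst_exclusion)
  meta <- stim$spikes
  build_z(counts, base, map, diagonal = diagonal, trial_keep = keep,
          window_ms = window$window_ms,
          day_in_vitro = if (nrow(meta)) meta$day_in_vitro[1] else NA,
          culture_id = if (nrow(meta)) meta$culture_id[1] else NA)
}

#' Build the normalized stimulus-response matrix Z
#'
#' `Z[k, j]` is the trial-averaged evoked spike count at recording
#' electrode `j` after stimulation at electrode `k`, minus electrode `j`'s
#' spontaneous baseline for the same window. Negative entries are legal
#' (evoked activity below the spontaneous rate).
#'
#' @param counts array from [count_evoked()].
#' @param baseline vector from [spontaneous_baseline()] (recycled scalar
#'   accepted).
#' @param map an `electrode_map`.
#' @param diagonal `"zero"` (default) sets `Z[k, k] = 0` and marks the
#'   diagonal as untested downstream (a stimulated electrode's own channel
#'   is artifact-dominated); `"include"` keeps it, matching the literal
#'   59 x 59 test count.
#' @param trial_keep optional logical matrix (stimulated electrode x
#'   trial) from [flag_burst_trials()]; flagged trials are excluded from
#'   the trial average.
#' @param window_ms,day_in_vitro,culture_id metadata stored as attributes.
#' @return a `response_matrix`: numeric matrix with attributes `window_ms`,
#'   `day_in_vitro`, `culture_id`, `diagonal`.
#' @export
build_z <- function(counts, baseline, map, diagonal = c("zero", "include"),
                    trial_keep = NULL, window_ms = NA_real_,
                    day_in_vitro = NA_integer_,
                    culture_id = NA_character_) {
  diagonal <- match.arg(diagonal)
  if (anyNA(counts) || anyNA(baseline)) {
    stop("NaN/NA in counts or baseline", call. = FALSE)
  }
  ids <- analysis_electrodes(map)$electrode_id
  if (is.null(trial_keep)) {
    z <- rowMeans(counts, dims = 2)
  } else {
    if (!all(dim(trial_keep) == dim(counts)[c(1, 3)])) {
      stop("`trial_keep` must be n_stim x n_trials", call. = FALSE)
    }
    w <- array(rep(trial_keep, each = dim(counts)[2]), dim = dim(counts)[c(2, 1, 3)])
    w <- aperm(w, c(2, 1, 3))
    z <- rowSums(counts * w, dims = 2) / rowSums(w, dims = 2)
  }
  if (length(baseline) == 1) baseline <- rep(baseline, ncol(z))
  z <- sweep(z, 2, baseline, "-")
  dimnames(z) <- list(ids, ids)
  if (diagonal == "zero") diag(z) <- 0
  structure(z, window_ms = window_ms, day_in_vitro = day_in_vitro,
            culture_id = culture_id, diagonal = diagonal,
            class = c("response_matrix", class(z)))
}
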