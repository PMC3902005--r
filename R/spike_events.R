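#' Spike event set
#'
#' Container for timestamped spikes from one or more recording sessions,
#' with, for stimulation sessions, the parallel table of stimulus pulses.
#' Times are seconds from session start.
#'
#' @param spikes data.frame with columns `electrode_id`, `time_s`,
#'   `session_id`, `session_kind` (`"spontaneous"` or `"stimulation"`),
#'   `day_in_vitro`, `culture_id`, `batch_id`. May have zero rows.
#' @param pulses for stimulation sessions, a data.frame with columns
#'   `stim_electrode_id`, `pulse_time_s`, `trial_index` (0-based),
#'   `session_id`; otherwise `NULL`.
#' @param duration_s recording duration in seconds; if `NULL`, inferred as
#'   the latest spike or pulse time.
#' @param n_trials number of pulses delivered per stimulated electrode
#'   (default 50); `trial_index` must lie in `[0, n_trials - 1]`.
#' @param map optional `electrode_map`; when given, all electrode ids are
#'   checked against it.
#' @return a `spike_events` object (list with elements `spikes`, `pulses`,
#'   `duration_s`, `n_trials`).
#' @export
spike_events <- function(spikes, pulses = NULL, duration_s = NULL,
                         n_trials = 50, map = NULL) {
  spike_cols <- c("electrode_id", "time_s", "session_id", "session_kind",
                  "day_in_vitro", "culture_id", "batch_id")
  if (nrow(spikes) == 0 && !all(spike_cols %in% names(spikes))) {
    spikes <- empty_spike_table()
  }
  miss <- setdiff(spike_cols, names(spikes))
  if (length(miss)) {
    stop("spike table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  spikes <- spikes[, spike_cols, drop = FALSE]
  if (nrow(spikes)) {
    if (any(!is.finite(spikes$time_s)) || any(spikes$time_s < 0)) {
      bad <- which(!is.finite(spikes$time_s) | spikes$time_s < 0)[1]
      stop("spike record ", bad, ": time must be finite and non-negative",
           call. = FALSE)
    }
    if (!all(spikes$session_kind %in% c("spontaneous", "stimulation"))) {
      stop("session_kind must be 'spontaneous' or 'stimulation'",
           call. = FALSE)
    }
    spikes <- spikes[order(spikes$session_id, spikes$time_s), , drop = FALSE]
    rownames(spikes) <- NULL
  }
  if (!is.null(pulses)) {
    pulse_cols <- c("stim_electrode_id", "pulse_time_s", "trial_index",
                    "session_id")
    miss <- setdiff(pulse_cols, names(pulses))
    if (length(miss)) {
      stop("pulse table is missing columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    pulses <- pulses[, pulse_cols, drop = FALSE]
    bad <- which(pulses$trial_index < 0 | pulses$trial_index >= n_trials)
    if (length(bad)) {
      stop("pulse record ", bad[1], ": trial_index ", pulses$trial_index[bad[1]],
           " outside [0, ", n_trials - 1, "]", call. = FALSE)
    }
    if (any(!is.finite(pulses$pulse_time_s)) || any(pulses$pulse_time_s < 0)) {
      stop("pulse times must be finite and non-negative", call. = FALSE)
    }
    pulses <- pulses[order(pulses$session_id, pulses$pulse_time_s), ,
                     drop = FALSE]
    rownames(pulses) <- NULL
  }
  if (!is.null(map)) {
    ids <- analysis_electrodes(map)$electrode_id
    unknown <- setdiff(unique(c(spikes$electrode_id,
                                if (!is.null(pulses)) pulses$stim_electrode_id)),
                       ids)
    if (length(unknown)) {
      stop("electrode ids not in map: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  if (is.null(duration_s)) {
    duration_s <- max(0, spikes$time_s,
                      if (!is.null(pulses)) pulses$pulse_time_s)
  }
  structure(list(spikes = spikes, pulses = pulses,
                 duration_s = duration_s, n_trials = n_trials),
            class = "spike_events")
}

empty_spike_table <- function() {
  data.frame(electrode_id = character(), time_s = numeric(),
             session_id = character(), session_kind = character(),
             day_in_vitro = integer(), culture_id = character(),
             batch_id = character(), stringsAsFactors = FALSE)
}

#' @export
print.spike_events <- function(x, ...) {
  cat("<spike_events> ", nrow(x$spikes), " spikes, ",
      if (is.null(x$pulses)) 0 else nrow(x$pulses), " pulses, ",
      format(x$duration_s), " s\n", sep = "")
  invisible(x)
}

#' Read / write spike-event tables
#'
#' Spike and pulse tables are plain CSV in the documented column layouts
#' (`read_spike_events()` reverses `write_spike_events()` exactly, to the
#' printed precision of 17 significant digits, i.e. bit-exact for doubles).
#'
#' @param path path of the spike CSV; the pulse table, when present, lives
#'   alongside it with suffix `"_pulses.csv"` in place of `".csv"` (or pass
#'   `pulse_path`).
#' @param pulse_path optional explicit pulse-table path.
#' @param map optional `electrode_map` used to validate electrode ids.
#' @param n_trials pulses per electrode for trial-index validation.
#' @return `read_spike_events()` returns a [spike_events] object;
#'   `write_spike_events()` returns `path` invisibly.
#' @rdname spike_events_io
#' @export
read_spike_events <- function(path, pulse_path = NULL, map = NULL,
                              n_trials = 50) {
  spikes <- read.csv(path, colClasses = c(electrode_id = "character",
                                          session_id = "character",
                                          culture_id = "character",
                                          batch_id = "character"))
  if (nrow(spikes)) {
    for (s in split(seq_len(nrow(spikes)), spikes$session_id)) {
      tdiff <- diff(spikes$time_s[s])
      if (length(tdiff) && any(tdiff < 0)) {
        line <- s[which(tdiff < 0)[1] + 1] + 1 # +1 for the header row
        stop("'", path, "' line ", line, ": spike times not sorted within session",
             call. = FALSE)
      }
    }
  }
  if (is.null(pulse_path)) {
    pulse_path <- sub("\\.csv$", "_pulses.csv", path)
  }
  pulses <- NULL
  if (file.exists(pulse_path)) {
    pulses <- read.csv(pulse_path,
                       colClasses = c(stim_electrode_id = "character",
                                      session_id = "character"))
  }
  spike_events(spikes, pulses, n_trials = n_trials, map = map)
}

#' @param events a [spike_events] object.
#' @rdname spike_events_io
#' @export
write_spike_events <- function(events, path, pulse_path = NULL) {
  write_precise_csv(events$spikes, path)
  if (!is.null(events$pulses)) {
    if (is.null(pulse_path)) pulse_path <- sub("\\.csv$", "_pulses.csv", path)
    write_precise_csv(events$pulses, pulse_path)
  }
  invisible(path)
}

# CSV writer that prints doubles with 17 significant digits so that
# write -> read round-trips bit-exactly
write_precise_csv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      out[[nm]] <- trimws(formatC(out[[nm]], digits = 17, format = "g"))
    }
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
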