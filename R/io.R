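#' Read / write a response matrix
#'
#' Matrices are stored as CSV with a header row and a leading column of
#' electrode ids (rows = stimulated electrode, columns = recording
#' electrode). Values are printed with 17 significant digits, so a
#' write/read round trip is exact. Matrix metadata (window, day, culture,
#' diagonal policy) travels in a JSON sidecar written next to the matrix.
#'
#' @param path CSV path; the sidecar is `path` with extension `.json`.
#' @param map optional `electrode_map`; dimensions and ids are checked
#'   against its analysis electrodes.
#' @return `read_matrix()` returns a numeric matrix with `window_ms`,
#'   `day_in_vitro`, `culture_id` and `diagonal` attributes when a sidecar
#'   is present.
#' @rdname matrix_io
#' @export
read_matrix <- function(path, map = NULL) {
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (nrow(m) != ncol(m)) {
    stop("matrix in '", path, "' is not square: ", nrow(m), " x ", ncol(m),
         call. = FALSE)
  }
  if (!identical(rownames(m), colnames(m))) {
    stop("row and column electrode ids differ in '", path, "'", call. = FALSE)
  }
  if (!is.null(map)) {
    ids_map <- analysis_electrodes(map)$electrode_id
    if (!identical(sort(rownames(m)), sort(ids_map))) {
      stop("matrix electrode ids do not match the electrode map",
           call. = FALSE)
    }
  }
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    for (nm in intersect(names(meta),
                         c("window_ms", "day_in_vitro", "culture_id",
                           "diagonal"))) {
      attr(m, nm) <- meta[[nm]]
    }
  }
  m
}

#' @param m numeric square matrix with electrode-id dimnames.
#' @rdname matrix_io
#' @export
write_matrix <- function(m, path, map = NULL) {
  if (nrow(m) != ncol(m)) {
    stop("matrix must be square", call. = FALSE)
  }
  if (!is.null(map)) {
    ids_map <- analysis_electrodes(map)$electrode_id
    if (nrow(m) != length(ids_map)) {
      stop("matrix dimension ", nrow(m), " does not match the ",
           length(ids_map), " analysis electrodes", call. = FALSE)
    }
  }
  fm <- formatC(m, digits = 17, format = "g")
  fm[] <- trimws(fm)
  df <- data.frame(electrode_id = rownames(m), fm,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("electrode_id", colnames(m))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(window_ms = attr(m, "window_ms"),
               day_in_vitro = attr(m, "day_in_vitro"),
               culture_id = attr(m, "culture_id"),
               diagonal = attr(m, "diagonal"))
  meta <- meta[!vapply(meta, is.null, logical(1))]
  if (length(meta)) {
    jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read / write tidy metric tables
#'
#' Long-format CSV with columns `culture_id`, `batch_id`, `day_in_vitro`,
#' `window_ms`, `metric_name`, `value`. [daily_metrics_long()] and
#' [daily_metrics_wide()] convert between this format and the wide
#' per-culture-day table produced by [metrics_for_day()].
#'
#' @param path CSV path.
#' @rdname metrics_io
#' @export
read_metrics <- function(path) {
  read.csv(path, colClasses = c(culture_id = "character",
                                batch_id = "character",
                                metric_name = "character"))
}

#' @param metrics a long-format metrics data.frame.
#' @rdname metrics_io
#' @export
write_metrics <- function(metrics, path) {
  need <- c("culture_id", "batch_id", "day_in_vitro", "window_ms",
            "metric_name", "value")
  miss <- setdiff(need, names(metrics))
  if (length(miss)) {
    stop("metrics table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  write_precise_csv(metrics[, need, drop = FALSE], path)
}

#' @param wide a wide per-culture-day metrics table (one row per
#'   culture/day/window, metric columns as produced by [metrics_for_day()]).
#' @rdname metrics_io
#' @export
daily_metrics_long <- function(wide) {
  keys <- c("culture_id", "batch_id", "day_in_vitro", "window_ms")
  vals <- setdiff(names(wide), keys)
  out <- do.call(rbind, lapply(vals, function(v) {
    data.frame(wide[, keys, drop = FALSE], metric_name = v,
               value = as.numeric(wide[[v]]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @param long a long-format metrics data.frame.
#' @rdname metrics_io
#' @export
daily_metrics_wide <- function(long) {
  keys <- c("culture_id", "batch_id", "day_in_vitro", "window_ms")
  wide <- stats::reshape(long, idvar = keys, timevar = "metric_name",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  attr(wide, "reshapeWide") <- NULL
  rownames(wide) <- NULL
  wide
}
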