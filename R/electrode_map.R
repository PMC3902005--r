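#' Standard MEA electrode layout
#'
#' Builds the conventional 60-electrode MEA grid: an 8 x 8 lattice minus the
#' four corners, with one position designated as the ground/reference
#' electrode, leaving 59 analysis electrodes. Electrode ids follow the
#' column-row convention used by commercial arrays (`"12"` = column 1,
#' row 2, ... `"87"`); corners `11`, `18`, `81`, `88` do not exist.
#'
#' @param pitch_um center-to-center electrode spacing in micrometers
#'   (default 200, the common commercial pitch).
#' @param ground_electrode id of the grid position wired as ground; it is
#'   kept in the map with `ground_flag = TRUE` and excluded from analysis.
#' @return an `electrode_map`: a data.frame with columns `electrode_id`,
#'   `x_um`, `y_um`, `ground_flag`, 60 rows of which 59 are analysis
#'   electrodes.
#' @examples
#' map <- standard_mea_layout()
#' sum(!map$ground_flag) # 59
#' @export
standard_mea_layout <- function(pitch_um = 200, ground_electrode = "15") {
  if (!is.numeric(pitch_um) || length(pitch_um) != 1 || pitch_um <= 0) {
    stop("`pitch_um` must be a single positive number", call. = FALSE)
  }
  grid <- expand.grid(col = 1:8, row = 1:8)
  corner <- (grid$col %in% c(1, 8)) & (grid$row %in% c(1, 8))
  grid <- grid[!corner, , drop = FALSE]
  id <- paste0(grid$col, grid$row)
  if (!ground_electrode %in% id) {
    stop("ground electrode '", ground_electrode,
         "' is not a valid grid position", call. = FALSE)
  }
  map <- data.frame(
    electrode_id = id,
    x_um = grid$col * pitch_um,
    y_um = grid$row * pitch_um,
    ground_flag = id == ground_electrode,
    stringsAsFactors = FALSE
  )
  map <- map[order(map$electrode_id), , drop = FALSE]
  rownames(map) <- NULL
  map <- structure(map, class = c("electrode_map", "data.frame"))
  validate_electrode_map(map)
  map
}

#' Validate an electrode map
#'
#' Checks the invariants every analysis stage relies on: distinct ids,
#' distinct non-negative coordinates, and (by default) exactly 59 analysis
#' electrodes.
#'
#' @param map a data.frame with columns `electrode_id`, `x_um`, `y_um`,
#'   `ground_flag`.
#' @param n_analysis expected number of analysis electrodes (default 59);
#'   `NULL` skips the count check.
#' @return the map, invisibly classed as `electrode_map`.
#' @export
validate_electrode_map <- function(map, n_analysis = 59) {
  need <- c("electrode_id", "x_um", "y_um", "ground_flag")
  miss <- setdiff(need, names(map))
  if (length(miss)) {
    stop("electrode map is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(map$electrode_id)) {
    stop("duplicate electrode ids in map", call. = FALSE)
  }
  if (anyDuplicated(map[, c("x_um", "y_um")])) {
    stop("duplicate electrode coordinates in map", call. = FALSE)
  }
  if (any(map$x_um < 0) || any(map$y_um < 0)) {
    stop("electrode coordinates must be non-negative", call. = FALSE)
  }
  n <- sum(!map$ground_flag)
  if (!is.null(n_analysis) && n != n_analysis) {
    stop("expected ", n_analysis, " analysis electrodes, found ", n,
         call. = FALSE)
  }
  if (!inherits(map, "electrode_map")) {
    class(map) <- c("electrode_map", class(map))
  }
  invisible(map)
}

#' Analysis electrodes of a map
#'
#' @param map an `electrode_map`.
#' @return the map rows with `ground_flag = FALSE`, in id order.
#' @export
analysis_electrodes <- function(map) {
  out <- map[!map$ground_flag, , drop = FALSE]
  out[order(out$electrode_id), , drop = FALSE]
}

#' Pairwise Euclidean distances between analysis electrodes
#'
#' @param map an `electrode_map`.
#' @return a symmetric matrix (micrometers) with electrode ids as dimnames.
#' @export
electrode_distances <- function(map) {
  el <- analysis_electrodes(map)
  d <- as.matrix(dist(el[, c("x_um", "y_um")]))
  dimnames(d) <- list(el$electrode_id, el$electrode_id)
  d
}

#' Read / write an electrode map
#'
#' Plain CSV with columns `electrode_id`, `x_um`, `y_um`, `ground_flag`.
#'
#' @param path file path.
#' @rdname electrode_map_io
#' @export
read_electrode_map <- function(path) {
  map <- read.csv(path, colClasses = c(electrode_id = "character"))
  map$ground_flag <- as.logical(map$ground_flag)
  validate_electrode_map(map, n_analysis = NULL)
  structure(map, class = c("electrode_map", "data.frame"))
}

#' @param map an `electrode_map`.
#' @rdname electrode_map_io
#' @export
write_electrode_map <- function(map, path) {
  write.csv(as.data.frame(map), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
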