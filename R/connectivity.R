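#' Build the directed connectivity graph of significant pairs
#'
#' Each significant stimulus-response pair (stimulated electrode k,
#' recording electrode j) becomes a directed edge k -> j. The edge carries
#' the straight-line Euclidean distance between the two electrodes in
#' micrometers — the only geometric information the grid provides; a
#' significant pair may of course hide multi-synaptic paths through
#' intermediate neurons.
#'
#' @param mask logical matrix (stimulated x recording) with electrode-id
#'   dimnames, e.g. `significant_mask` from [run_fdr()].
#' @param map an `electrode_map`.
#' @return an [igraph::igraph] directed graph whose vertices are all
#'   analysis electrodes (with `x_um`, `y_um` attributes) and whose edges
#'   carry `length_um`.
#' @export
build_graph <- function(mask, map) {
  el <- analysis_electrodes(map)
  ids <- el$electrode_id
  if (is.null(dimnames(mask)) || is.null(rownames(mask))) {
    if (!all(dim(mask) == length(ids))) {
      stop("mask dimensions do not match the electrode map", call. = FALSE)
    }
    dimnames(mask) <- list(ids, ids)
  }
  if (!all(rownames(mask) %in% ids)) {
    stop("mask electrode ids not in electrode map", call. = FALSE)
  }
  hits <- which(mask & !is.na(mask), arr.ind = TRUE)
  edges <- data.frame(from = rownames(mask)[hits[, 1]],
                      to = colnames(mask)[hits[, 2]],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(
                                       name = ids,
                                       x_um = el$x_um, y_um = el$y_um,
                                       stringsAsFactors = FALSE))
  if (igraph::ecount(g)) {
    co <- cbind(el$x_um, el$y_um)[match(igraph::V(g)$name, ids), ,
                                  drop = FALSE]
    ends <- igraph::ends(g, igraph::E(g), names = FALSE)
    dx <- co[ends[, 1], 1] - co[ends[, 2], 1]
    dy <- co[ends[, 1], 2] - co[ends[, 2], 2]
    igraph::E(g)$length_um <- sqrt(dx^2 + dy^2)
  }
  g
}

#' Mean connection length
#'
#' Arithmetic mean of the edge lengths of a connectivity graph — a measure
#' of how physically far significant functional connections reach across
#' the dish.
#'
#' @param graph a connectivity graph from [build_graph()].
#' @return mean edge length in micrometers; `NA` for an empty graph.
#' @export
mean_connection_length <- function(graph) {
  if (igraph::ecount(graph) == 0) return(NA_real_)
  mean(igraph::E(graph)$length_um)
}

#' Supernode counts
#'
#' A supernode is an electrode with at least `threshold` significant
#' connections in one direction: at least 4 incoming edges makes an
#' incoming supernode, at least 4 outgoing edges an outgoing supernode (a
#' node can be both). These hubs are the network's functional integration
#' points. `mode = "total"` applies the threshold to total degree instead.
#'
#' @param graph a connectivity graph from [build_graph()].
#' @param threshold minimum degree, default 4.
#' @param mode `"each"` (default, per-direction counts) or `"total"`.
#' @return named integer vector `c(incoming = , outgoing = )` (for
#'   `"total"`, `c(total = )`).
#' @export
supernode_counts <- function(graph, threshold = 4, mode = c("each", "total")) {
  mode <- match.arg(mode)
  if (mode == "total") {
    deg <- igraph::degree(graph, mode = "all")
    return(c(total = sum(deg >= threshold)))
  }
  c(incoming = sum(igraph::degree(graph, mode = "in") >= threshold),
    outgoing = sum(igraph::degree(graph, mode = "out") >= threshold))
}

#' Daily connectivity metrics for one culture
#'
#' Composes graph construction and the two study metrics into one tidy row
#' per culture, day and counting window.
#'
#' @param fdr_result a `local_fdr_result` from [run_fdr()] (or a bare
#'   logical mask).
#' @param map an `electrode_map`.
#' @param culture_id,batch_id,day_in_vitro,window_ms identifying metadata.
#' @param threshold supernode degree threshold, default 4.
#' @return one-row data.frame: `culture_id`, `batch_id`, `day_in_vitro`,
#'   `window_ms`, `n_edges`, `mean_connection_length_um` (`NA` when there
#'   are no edges), `n_incoming_supernodes`, `n_outgoing_supernodes`.
#' @export
metrics_for_day <- function(fdr_result, map, culture_id, batch_id,
                            day_in_vitro, window_ms, threshold = 4) {
  mask <- if (inherits(fdr_result, "local_fdr_result")) {
    fdr_result$significant_mask
  } else {
    fdr_result
  }
  g <- build_graph(mask, map)
  sn <- supernode_counts(g, threshold = threshold)
  data.frame(culture_id = culture_id, batch_id = batch_id,
             day_in_vitro = day_in_vitro, window_ms = window_ms,
             n_edges = igraph::ecount(g),
             mean_connection_length_um = mean_connection_length(g),
             n_incoming_supernodes = unname(sn["incoming"]),
             n_outgoing_supernodes = unname(sn["outgoing"]),
             stringsAsFactors = FALSE)
}
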