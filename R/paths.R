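# Shortest non-covalent communication paths over PSN edges.  "Shortest" is
# counted in hops (all edge costs 1, so Dijkstra reduces to breadth-first
# search); all tied shortest paths are enumerated.  Paths are then filtered
# by motion correlation (at least one internal residue correlated with one
# of the two extremities) and ranked by the fraction of frames in which
# they occur.

#' All shortest paths between two nodes of a PSN
#'
#' @param graph a `psn_graph`
#' @param source,target node indices (rows of `graph$nodes`)
#' @param weighted if `TRUE`, edges cost `1 / I_ij` instead of 1 hop
#'   (extension; off by default)
#' @return list of integer node vectors (possibly empty when the endpoints
#'   are disconnected); every path starts at `source` and ends at `target`
#' @export
psn_shortest_paths <- function(graph, source, target, weighted = FALSE) {
  nn <- nrow(graph$nodes)
  if (source < 1 || source > nn || target < 1 || target > nn)
    stop("endpoint is not a node of the graph")
  if (source == target) stop("source and target must differ")
  if (nrow(graph$edges) == 0) return(list())
  ig <- igraph::graph_from_edgelist(cbind(graph$edges$i, graph$edges$j),
                                    directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0, nn - igraph::vcount(ig)))
  w <- if (weighted) 1 / graph$edges$strength else NULL
  res <- suppressWarnings(igraph::all_shortest_paths(
    ig, from = source, to = target, weights = w))
  lapply(res$vpaths %||% res$res, function(p) as.integer(p))
}

#' Correlation filter for communication paths
#'
#' Keeps a path when at least one *internal* residue has motion correlation
#' `>= cutoff` with the first or the last node of the path.  Two-node paths
#' have no interior and are dropped unless `keep_direct = TRUE`.
#'
#' @param paths list of integer node vectors
#' @param corr_matrix symmetric correlation matrix over the PSN nodes
#'   (DCC or LMI; see [corr_dcc()], [corr_lmi()])
#' @param cutoff correlation cutoff
#' @param keep_direct keep 2-node paths (no interior) regardless
#' @return filtered list of paths
#' @export
path_correlation_filter <- function(paths, corr_matrix, cutoff,
                                    keep_direct = FALSE) {
  keep <- vapply(paths, function(p) {
    if (any(p > nrow(corr_matrix)))
      stop("correlation matrix missing path node ", max(p))
    if (length(p) <= 2) return(keep_direct)
    interior <- p[-c(1, length(p))]
    any(corr_matrix[interior, p[1]] >= cutoff |
          corr_matrix[interior, p[length(p)]] >= cutoff)
  }, logical(1))
  paths[keep]
}

path_key <- function(p) {
  # identity up to reversal
  a <- paste(p, collapse = ",")
  b <- paste(rev(p), collapse = ",")
  if (a <= b) a else b
}

#' Communication-path frequencies over a trajectory
#'
#' Builds one PSN per frame, enumerates all shortest paths between the two
#' endpoints in each frame, applies the correlation filter (the correlation
#' matrix is a single trajectory-level statistic), and reports each unique
#' path (up to reversal) with its frequency: the number of frames whose
#' shortest-path set contains it, divided by the total frame count.
#'
#' @param traj a `trj_trajectory`
#' @param structure companion `trj_structure`
#' @param source,target endpoint node indices
#' @param corr_matrix trajectory-level residue correlation matrix
#' @param selection selection string for the PSN
#' @param imin interaction-strength cutoff (percent)
#' @param corr_cutoff correlation cutoff for the filter
#' @param min_length minimum path length in nodes (default 2)
#' @param min_freq minimum reported frequency (default 0)
#' @param keep_direct keep 2-node paths through the correlation filter
#' @param cutoff,n_exclusion,nf as in [build_psn()]
#' @return data.frame of unique paths ranked by descending frequency:
#'   columns `path` (comma-joined nodes), `length`, `frequency`
#' @export
path_frequencies <- function(traj, structure, source, target, corr_matrix,
                             selection = "/*/*/*", imin = 3,
                             corr_cutoff = 0, min_length = 2, min_freq = 0,
                             keep_direct = FALSE, cutoff = 4.5,
                             n_exclusion = 2, nf = nf_table()) {
  if (traj$nframes < 1) stop("empty trajectory")
  F <- traj$nframes
  counts <- list()
  store <- list()
  for (f in seq_len(F)) {
    st <- set_coords(structure, frame_coords(traj, f))
    g <- build_psn(st, selection, imin, cutoff, n_exclusion, nf)
    paths <- psn_shortest_paths(g, source, target)
    paths <- path_correlation_filter(paths, corr_matrix, corr_cutoff,
                                     keep_direct)
    for (p in paths) {
      k <- path_key(p)
      counts[[k]] <- (counts[[k]] %||% 0L) + 1L
      store[[k]] <- p
    }
  }
  if (length(counts) == 0)
    return(data.frame(path = character(), length = integer(),
                      frequency = numeric()))
  out <- data.frame(
    path = vapply(store, function(p) paste(p, collapse = ","), character(1)),
    length = vapply(store, length, integer(1)),
    frequency = unlist(counts) / F,
    stringsAsFactors = FALSE)
  out <- out[out$length >= min_length & out$frequency >= min_freq, ,
             drop = FALSE]
  out <- out[order(-out$frequency, out$length, out$path), , drop = FALSE]
  rownames(out) <- NULL
  out
}
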