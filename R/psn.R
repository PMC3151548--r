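# Protein structure networks: residues (and allowed hetero nodes) are graph
# nodes; two nodes are joined when their interaction strength
# I_ij = 100 * n_ij / sqrt(N_i N_j) reaches the I_min cutoff, where n_ij is
# the number of side-chain atom pairs within a distance cutoff (4.5 A
# default) and N_i, N_j are per-residue normalization factors expressing
# each node's capacity for contacts.

# Amino-acid normalization factors (Kannan & Vishveshwara contact-capacity
# table) plus ligand factors for retinal, GDP, GTP and Mg2+ (GDP- and
# GTP-state GTPases).
.default_nf <- c(
  ALA = 55.7576, ARG = 93.7891, ASN = 73.4097, ASP = 75.1507,
  CYS = 54.9528, GLN = 78.1301, GLU = 78.8288, GLY = 47.3129,
  HIS = 83.7357, ILE = 67.9452, LEU = 72.2517, LYS = 69.6096,
  MET = 69.2569, PHE = 93.3082, PRO = 51.3310, SER = 61.3946,
  THR = 63.7075, TRP = 106.7030, TYR = 100.7190, VAL = 62.3673,
  RET = 170.13, GDP = 220.19, GTP = 274.78,
  MG_GDP = 14.65, MG = 22.01
)

#' Normalization-factor table for PSN nodes
#'
#' Returns the built-in table (20 amino acids plus retinal, GDP, GTP and
#' Mg2+ — the magnesium factor is state-dependent: 22.01 in GTP-bound and
#' 14.65 in GDP-bound GTPases, the latter available under key `MG_GDP`),
#' optionally extended/overridden by user entries.
#'
#' @param extra named numeric vector of additional factors (`name = NF`)
#' @return named numeric vector, all entries `> 0`
#' @export
nf_table <- function(extra = NULL) {
  tab <- .default_nf
  if (!is.null(extra)) {
    if (is.null(names(extra)) || any(names(extra) == ""))
      stop("extra NF entries must be named")
    if (any(extra <= 0)) stop("normalization factors must be positive")
    tab[toupper(names(extra))] <- extra
  }
  tab
}

.backbone_atoms <- c("N", "CA", "C", "O", "OXT", "H", "HN", "HA",
                     "HA1", "HA2", "H1", "H2", "H3")
.amino3 <- names(.default_nf)[1:20]

# Per-node atom indices used for contact counting: side-chain heavy atoms
# for amino acids (glycine therefore has none and cannot form edges);
# hetero nodes contribute all their atoms.  Hydrogens excluded by default.
psn_node_atoms <- function(structure, idx, include_h = FALSE) {
  a <- structure$atoms
  rgrp <- structure$residue_of[idx]
  ures <- sort(unique(rgrp))
  lapply(ures, function(g) {
    members <- idx[rgrp == g]
    nm <- a$name[members]
    if (toupper(a$resname[members[1]]) %in% .amino3)
      members <- members[!(nm %in% .backbone_atoms)]
    if (!include_h) {
      nm2 <- a$name[members]
      members <- members[!grepl("^[0-9]*H", nm2)]
    }
    members
  })
}

psn_nodes <- function(structure, selection = "/*/*/*", nf = nf_table(),
                      include_h = FALSE) {
  idx <- resolve_indices(structure, selection)
  if (length(idx) == 0) stop("empty selection")
  rgrp <- structure$residue_of[idx]
  ures <- sort(unique(rgrp))
  res <- structure$residues[ures, , drop = FALSE]
  nfv <- nf[toupper(res$resname)]
  if (any(is.na(nfv))) {
    missing <- unique(res$resname[is.na(nfv)])
    stop("no normalization factor for node type(s) ",
         paste(missing, collapse = ", "),
         "; supply one via nf_table(extra = c(NAME = value))")
  }
  list(res = res, ures = ures, nf = unname(nfv),
       atoms = psn_node_atoms(structure, idx, include_h))
}

# Count side-chain atom pairs within `cutoff` for all node pairs of one
# frame.  `coords_m` is the full N_atoms x 3 coordinate matrix of the frame.
psn_contact_counts <- function(nodes, coords_m, cutoff = 4.5) {
  nn <- length(nodes$atoms)
  cnt <- matrix(0L, nn, nn)
  pts <- lapply(nodes$atoms, function(ix) coords_m[ix, , drop = FALSE])
  for (i in seq_len(nn)) {
    pi <- pts[[i]]
    if (nrow(pi) == 0) next
    for (j in seq_len(nn)) {
      if (j <= i) next
      pj <- pts[[j]]
      if (nrow(pj) == 0) next
      # cheap bounding check before the pair count
      if (min(pj[, 1]) - max(pi[, 1]) > cutoff ||
          min(pi[, 1]) - max(pj[, 1]) > cutoff) next
      d2 <- outer(rowSums(pi^2), rowSums(pj^2), "+") -
        2 * pi %*% t(pj)
      cnt[i, j] <- cnt[j, i] <- sum(d2 <= cutoff^2 + 1e-12)
    }
  }
  cnt
}

#' Interaction strength between two nodes in one frame
#'
#' `I_ij = 100 * n_ij / sqrt(N_i N_j)` (percent).
#'
#' @param structure a `trj_structure` holding the frame's coordinates
#' @param node_i,node_j residue indices (rows of `structure$residues`)
#' @param cutoff side-chain contact distance cutoff, Angstrom
#' @param nf normalization-factor table (see [nf_table()])
#' @param include_h count hydrogens (off by default)
#' @return interaction strength in percent (symmetric in i, j)
#' @export
interaction_strength <- function(structure, node_i, node_j, cutoff = 4.5,
                                 nf = nf_table(), include_h = FALSE) {
  nodes <- psn_nodes(structure, nf = nf, include_h = include_h)
  pi <- match(node_i, nodes$ures); pj <- match(node_j, nodes$ures)
  if (is.na(pi) || is.na(pj)) stop("node index out of range")
  cnt <- psn_pair_count(nodes, coords(structure), pi, pj, cutoff)
  100 * cnt / sqrt(nodes$nf[pi] * nodes$nf[pj])
}

psn_pair_count <- function(nodes, coords_m, pi, pj, cutoff) {
  ai <- nodes$atoms[[pi]]; aj <- nodes$atoms[[pj]]
  if (length(ai) == 0 || length(aj) == 0) return(0L)
  mi <- coords_m[ai, , drop = FALSE]; mj <- coords_m[aj, , drop = FALSE]
  d2 <- outer(rowSums(mi^2), rowSums(mj^2), "+") - 2 * mi %*% t(mj)
  sum(d2 <= cutoff^2 + 1e-12)
}

#' Build a protein structure network for one frame
#'
#' @param structure a `trj_structure` (frame coordinates in the atom table)
#' @param selection selection string or `trj_selection`
#' @param imin interaction-strength cutoff, percent (edges need
#'   `I_ij >= imin`)
#' @param cutoff contact distance cutoff, Angstrom (default 4.5)
#' @param n_exclusion sequence-neighbour exclusion `j = i +/- n` within a
#'   chain (default 2); inter-chain pairs are always eligible
#' @param nf normalization-factor table
#' @param include_h count hydrogens in contacts
#' @return a `psn_graph`: node table, edge table `(i, j, strength)`,
#'   parameters
#' @export
build_psn <- function(structure, selection = "/*/*/*", imin = 0,
                      cutoff = 4.5, n_exclusion = 2, nf = nf_table(),
                      include_h = FALSE) {
  if (imin < 0) stop("imin must be >= 0")
  nodes <- psn_nodes(structure, selection, nf, include_h)
  cnt <- psn_contact_counts(nodes, coords(structure), cutoff)
  nn <- nrow(cnt)
  S <- 100 * cnt / sqrt(tcrossprod(nodes$nf))
  res <- nodes$res
  same_chain <- outer(res$segid, res$segid, "==") &
    outer(res$chain, res$chain, "==")
  near <- abs(outer(res$resid, res$resid, "-")) <= n_exclusion
  excluded <- same_chain & near
  eligible <- upper.tri(S) & !excluded
  sel_e <- which(eligible & S >= imin & cnt > 0, arr.ind = TRUE)
  edges <- data.frame(i = sel_e[, 1], j = sel_e[, 2],
                      strength = S[sel_e], n_contacts = cnt[sel_e])
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  g <- list(nodes = res, nf = nodes$nf, edges = edges,
            strengths = S, counts = cnt, excluded = excluded,
            imin = imin, cutoff = cutoff, n_exclusion = n_exclusion)
  class(g) <- "psn_graph"
  g
}

#' @export
print.psn_graph <- function(x, ...) {
  cat(sprintf("<psn_graph> %d nodes, %d edges (I_min = %g%%)\n",
              nrow(x$nodes), nrow(x$edges), x$imin))
  invisible(x)
}

#' Re-threshold an existing PSN at a higher I_min without recomputing
#' contacts
#' @param graph a `psn_graph`
#' @param imin new interaction-strength cutoff (percent)
#' @return a `psn_graph`
#' @export
psn_at_imin <- function(graph, imin) {
  keep <- graph$edges$strength >= imin
  g <- graph
  g$edges <- graph$edges[keep, , drop = FALSE]
  rownames(g$edges) <- NULL
  g$imin <- imin
  g
}

#' Hub detection
#'
#' A node is a hub when its degree reaches `hub_cutoff` (inclusive rule,
#' `degree >= cutoff`, by default; `strict = TRUE` requires
#' `degree > cutoff`).  The hub interaction percentage is
#' `I_i = 100 * sum_j n_ij / N_i` over the node's edges.
#'
#' @param graph a `psn_graph`
#' @param hub_cutoff degree threshold, default 4
#' @param strict require strictly more than `hub_cutoff` edges
#' @return data.frame with node, degree, hub flag, hub interaction
#'   percentage
#' @export
find_hubs <- function(graph, hub_cutoff = 4, strict = FALSE) {
  nn <- nrow(graph$nodes)
  deg <- integer(nn)
  isum <- numeric(nn)
  e <- graph$edges
  for (r in seq_len(nrow(e))) {
    deg[e$i[r]] <- deg[e$i[r]] + 1L
    deg[e$j[r]] <- deg[e$j[r]] + 1L
    isum[e$i[r]] <- isum[e$i[r]] + e$n_contacts[r]
    isum[e$j[r]] <- isum[e$j[r]] + e$n_contacts[r]
  }
  hub <- if (strict) deg > hub_cutoff else deg >= hub_cutoff
  data.frame(node = seq_len(nn), key = graph$nodes$key,
             resname = graph$nodes$resname, degree = deg, hub = hub,
             hub_interaction = 100 * isum / graph$nf)
}

#' Node clusterization (connected components)
#'
#' Nodes joined directly or indirectly by edges form one cluster; clusters
#' are numbered deterministically by their smallest member node.
#'
#' @param graph a `psn_graph`
#' @return a `psn_clusters`: per-node cluster id, cluster sizes, largest
#'   size
#' @export
psn_clusterize <- function(graph) {
  nn <- nrow(graph$nodes)
  if (nrow(graph$edges) == 0) {
    memb <- seq_len(nn)
  } else {
    ig <- igraph::graph_from_edgelist(
      cbind(graph$edges$i, graph$edges$j), directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0, nn - igraph::vcount(ig)))
    comp <- igraph::components(ig)$membership
    # renumber by smallest member node
    first <- tapply(seq_len(nn), comp, min)
    memb <- as.integer(match(comp, comp[sort(first)]))
  }
  sizes <- as.integer(table(memb))
  out <- list(membership = memb, sizes = sizes, largest = max(sizes))
  class(out) <- "psn_clusters"
  out
}

#' @export
print.psn_clusters <- function(x, ...) {
  cat(sprintf("<psn_clusters> %d clusters, largest %d\n",
              length(x$sizes), x$largest))
  invisible(x)
}

#' Largest-cluster size across an I_min grid and the critical I_min
#'
#' `I_critic` is the `I_min` at which the largest cluster reaches half its
#' size at `I_min = 0`, by linear interpolation between the bracketing grid
#' points.  When the half size is never reached on the grid the result is
#' flagged unreached and reported as `> max(grid)`.
#'
#' @param graph a `psn_graph` built at `imin = 0` (contacts retained)
#' @param imin_grid grid of I_min values; must include 0
#' @return list with `table` (imin, largest-cluster size), `icritic`,
#'   `reached`
#' @export
psn_icritic <- function(graph, imin_grid = seq(0, 5, by = 0.5)) {
  if (!any(imin_grid == 0)) stop("imin grid must include 0.0")
  imin_grid <- sort(imin_grid)
  largest <- vapply(imin_grid, function(v)
    psn_clusterize(psn_at_imin(graph, v))$largest, integer(1))
  half <- largest[imin_grid == 0][1] / 2
  tab <- data.frame(imin = imin_grid, largest = largest)
  below <- which(largest <= half)
  if (length(below) == 0)
    return(list(table = tab, icritic = max(imin_grid), reached = FALSE,
                message = sprintf("I_critic > %g", max(imin_grid))))
  b <- below[1]
  if (b == 1 || largest[b] == half || largest[b - 1] == largest[b]) {
    ic <- imin_grid[b]
  } else {
    x0 <- imin_grid[b - 1]; x1 <- imin_grid[b]
    y0 <- largest[b - 1]; y1 <- largest[b]
    ic <- x0 + (y0 - half) * (x1 - x0) / (y0 - y1)
  }
  list(table = tab, icritic = ic, reached = TRUE)
}

#' Trajectory-level PSN statistics
#'
#' Builds one PSN per frame and reports per-edge frame frequencies, stable
#' hubs (hub in more than `stability` of frames), and hub-correlation
#' pairs: node pairs that are simultaneously hubs in more than `stability`
#' of the frames.
#'
#' @param traj a `trj_trajectory`
#' @param structure companion `trj_structure`
#' @param selection selection string
#' @param imin interaction-strength cutoff (percent)
#' @param cutoff,n_exclusion,nf,include_h as in [build_psn()]
#' @param hub_cutoff,strict as in [find_hubs()]
#' @param stability frame-fraction threshold, default 0.5
#' @param hub_corr_mode `"joint"` (fraction of frames both are hubs,
#'   default) or `"matching"` (fraction of frames the two hub indicators
#'   agree)
#' @return a `psn_ensemble`: edge frequency table, per-node hub frequency,
#'   stable hubs, hub-correlation pairs
#' @export
psn_ensemble <- function(traj, structure, selection = "/*/*/*", imin = 3,
                         cutoff = 4.5, n_exclusion = 2, nf = nf_table(),
                         include_h = FALSE, hub_cutoff = 4, strict = FALSE,
                         stability = 0.5,
                         hub_corr_mode = c("joint", "matching")) {
  hub_corr_mode <- match.arg(hub_corr_mode)
  if (traj$nframes < 1) stop("empty trajectory")
  F <- traj$nframes
  edge_count <- list()
  hub_ind <- NULL
  nn <- NULL
  for (f in seq_len(F)) {
    st <- set_coords(structure, frame_coords(traj, f))
    g <- build_psn(st, selection, imin, cutoff, n_exclusion, nf, include_h)
    if (is.null(nn)) {
      nn <- nrow(g$nodes)
      hub_ind <- matrix(FALSE, F, nn)
    }
    hubs <- find_hubs(g, hub_cutoff, strict)
    hub_ind[f, ] <- hubs$hub
    if (nrow(g$edges) > 0) {
      keys <- paste(g$edges$i, g$edges$j, sep = "-")
      for (k in keys)
        edge_count[[k]] <- (edge_count[[k]] %||% 0L) + 1L
    }
  }
  ek <- names(edge_count)
  edge_freq <- if (length(ek) > 0) {
    ij <- do.call(rbind, strsplit(ek, "-"))
    data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
               frequency = unlist(edge_count) / F)
  } else data.frame(i = integer(), j = integer(), frequency = numeric())
  hub_freq <- colMeans(hub_ind)
  stable_hubs <- which(hub_freq > stability)
  pairs <- hub_correlation_pairs(hub_ind, stability, hub_corr_mode)
  out <- list(edge_freq = edge_freq[order(-edge_freq$frequency), ,
                                    drop = FALSE],
              hub_freq = hub_freq, stable_hubs = stable_hubs,
              hub_pairs = pairs, stability = stability, imin = imin,
              nframes = F)
  class(out) <- "psn_ensemble"
  out
}

# Pairs whose per-frame hub indicators coincide above the threshold.
hub_correlation_pairs <- function(hub_ind, stability = 0.5,
                                  mode = c("joint", "matching")) {
  mode <- match.arg(mode)
  F <- nrow(hub_ind); nn <- ncol(hub_ind)
  res <- list()
  for (i in seq_len(nn - 1)) for (j in (i + 1):nn) {
    frac <- if (mode == "joint") mean(hub_ind[, i] & hub_ind[, j])
    else mean(hub_ind[, i] == hub_ind[, j])
    if (frac > stability && any(hub_ind[, i]) && any(hub_ind[, j]))
      res[[length(res) + 1L]] <- data.frame(i = i, j = j, fraction = frac)
  }
  if (length(res) == 0)
    return(data.frame(i = integer(), j = integer(), fraction = numeric()))
  do.call(rbind, res)
}

#' @export
print.psn_ensemble <- function(x, ...) {
  cat(sprintf(
    "<psn_ensemble> %d frames, %d stable hubs, %d hub-correlation pairs\n",
    x$nframes, length(x$stable_hubs), nrow(x$hub_pairs)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
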