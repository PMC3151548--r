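# Fixtures built in code at test time.

# Calpha-only structure from explicit coordinates (one residue per node);
# resid/segid controllable so adjacency and exclusion rules can be probed.
ca_structure <- function(xyz, resid = seq_len(nrow(xyz)), segid = "A",
                         bfactor = 10) {
  n <- nrow(xyz)
  atoms <- data.frame(
    serial = seq_len(n), name = "CA", resname = "ALA", resid = resid,
    segid = rep_len(segid, n), chain = rep_len(segid, n), insert = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    mass = 12.011, bfactor = rep_len(bfactor, n),
    stringsAsFactors = FALSE)
  trajan:::new_structure(atoms)
}

# minimal hand-made PSN graph (nodes in one chain unless segid given)
toy_psn_graph <- function(n, edges, strengths = NULL, counts = NULL) {
  nodes <- data.frame(key = paste0("A|", seq_len(n), "|"),
                      segid = "A", chain = "A", resid = seq_len(n),
                      insert = "", resname = "ALA",
                      stringsAsFactors = FALSE)
  ed <- if (length(edges) > 0) {
    data.frame(i = vapply(edges, `[`, integer(1), 1),
               j = vapply(edges, `[`, integer(1), 2),
               strength = strengths %||% rep(1, length(edges)),
               n_contacts = counts %||% rep(1L, length(edges)))
  } else data.frame(i = integer(), j = integer(), strength = numeric(),
                    n_contacts = integer())
  g <- list(nodes = nodes, nf = rep(55.7576, n), edges = ed,
            imin = 0, cutoff = 4.5, n_exclusion = 2)
  class(g) <- "psn_graph"
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# multi-chain structure where every residue sits in its own segment (no
# neighbour exclusion applies); one CA + one CB per residue, CB at the
# given coordinates so contacts are dictated directly
chain_of_segments <- function(cb_xyz) {
  n <- nrow(cb_xyz)
  rows <- list()
  s <- 0L
  for (i in seq_len(n)) {
    for (nm in c("CA", "CB")) {
      s <- s + 1L
      off <- if (nm == "CA") c(0, 0, 3) else c(0, 0, 0)
      rows[[s]] <- data.frame(
        serial = s, name = nm, resname = "ALA", resid = 1L,
        segid = LETTERS[i], chain = LETTERS[i], insert = "",
        x = cb_xyz[i, 1] + off[1], y = cb_xyz[i, 2] + off[2],
        z = cb_xyz[i, 3] + off[3],
        mass = 12.011, bfactor = 10, stringsAsFactors = FALSE)
    }
  }
  trajan:::new_structure(do.call(rbind, rows))
}

# trajectory of frames drawn around well centres; returns the trajectory
# and the ground-truth well of every frame
well_trajectory <- function(centers, wells_of_frames, noise = 0.05,
                            seed = 42) {
  set.seed(seed)
  frames <- lapply(wells_of_frames, function(w) {
    c0 <- centers[[w]]
    c0 + matrix(rnorm(length(c0), sd = noise), nrow = nrow(c0))
  })
  list(traj = trajan::trajectory_from_frames(frames),
       wells = wells_of_frames)
}

# symmetric two-well transition network built from exact expected counts
# (no sampling noise): states 1..n, first half = well A, second = well B
two_well_network <- function(n = 8, intra = 0.2, inter = 0.005,
                             scale = 1e4) {
  wells <- rep(1:2, each = n / 2)
  T <- matrix(inter, n, n)
  same <- outer(wells, wells, "==")
  T[same] <- intra
  diag(T) <- 0
  diag(T) <- 1 - rowSums(T)
  pi0 <- rep(1 / n, n)               # symmetric chain: uniform stationary
  counts <- scale * pi0 * T          # expected transition counts
  weights <- scale * pi0
  net <- list(states = seq_len(n), weights = weights, counts = counts,
              T = counts / rowSums(counts), lag = 1L,
              nframes = as.integer(scale))
  class(net) <- "transition_network"
  list(net = net, wells = wells, T = T)
}
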