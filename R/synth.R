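# Seeded synthetic-fixture generators.  Every generator takes an explicit
# seed, uses one local RNG stream, and returns a machine-readable ground
# truth next to the data, so validation never needs external downloads.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed",
                                          envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a toy polypeptide structure
#'
#' Chemically naive but format-valid chain: backbone N, CA, C, O plus a CB
#' side-chain pseudo-atom per residue (alanine-like), with CA positions on
#' a helix-like or zig-zag curve at 3.8 A spacing.  Side-chain contact
#' geometry is controlled, so interaction-strength contacts are
#' hand-countable; the returned ground truth records every side-chain
#' atom-pair contact count at the 4.5 A cutoff.
#'
#' @param n_res number of residues (`>= 2`)
#' @param geometry `"helix"` or `"zigzag"`
#' @param seed RNG seed (used for the small coordinate jitter)
#' @param jitter uniform coordinate jitter amplitude, Angstrom (default
#'   0.05)
#' @return list with `structure` (a `trj_structure`) and `ground_truth`
#'   (list: CA count, per-pair side-chain contact counts at 4.5 A)
#' @export
gen_toy_structure <- function(n_res, geometry = c("helix", "zigzag"),
                              seed = 1, jitter = 0.05) {
  geometry <- match.arg(geometry)
  if (n_res < 2) stop("need at least 2 residues")
  with_seed(seed, {
    t <- seq_len(n_res)
    helix <- geometry == "helix"
    if (helix) {
      # helix-like: 100 deg turn, 0.9 A rise, radius set for 3.8 A CA-CA;
      # CB points toward the axis, giving side-chain contacts at i+/-3 and
      # i+/-4 (within the 4.5 A default) and none farther
      ang <- (t - 1) * 100 * pi / 180
      rise <- 0.9
      r <- sqrt(3.8^2 - rise^2) / (2 * sin(50 * pi / 180))
      ca <- cbind(r * cos(ang), r * sin(ang), rise * (t - 1))
      cb <- cbind((r - 1.5) * cos(ang), (r - 1.5) * sin(ang),
                  rise * (t - 1) + 0.3)
    } else {
      ca <- cbind(3.4 * (t - 1), rep(c(0, 1.7), length.out = n_res), 0)
      cb <- ca + matrix(rep(c(0, -1.5, 0.4), each = n_res), ncol = 3)
    }
    atoms_list <- list()
    serial <- 0L
    for (i in t) {
      p <- ca[i, ]
      offs <- list(N = c(-0.9, 0.9, 0), CA = c(0, 0, 0),
                   C = c(0.9, 0.9, 0), O = c(1.0, 2.0, 0))
      pos <- c(lapply(offs, function(o) p + o), list(CB = cb[i, ]))
      for (nm in names(pos)) {
        serial <- serial + 1L
        q <- pos[[nm]] + stats::runif(3, -jitter, jitter)
        atoms_list[[serial]] <- data.frame(
          serial = serial, name = nm, resname = "ALA", resid = i,
          segid = "A", chain = "A", insert = "",
          x = q[1], y = q[2], z = q[3], mass = 12.011,
          bfactor = round(stats::runif(1, 5, 30), 2),
          stringsAsFactors = FALSE)
      }
    }
    atoms <- do.call(rbind, atoms_list)
    atoms$mass <- atom_masses(atoms$name, atoms$resname)
    st <- new_structure(atoms)
    # ground truth: side-chain (CB) contact counts at 4.5 A by direct
    # double loop
    cb <- atoms[atoms$name == "CB", ]
    contacts <- list()
    for (i in seq_len(n_res - 1)) for (j in (i + 1):n_res) {
      d <- sqrt(sum((c(cb$x[i], cb$y[i], cb$z[i]) -
                       c(cb$x[j], cb$y[j], cb$z[j]))^2))
      contacts[[length(contacts) + 1L]] <-
        data.frame(i = i, j = j, n_contacts = as.integer(d <= 4.5))
    }
    gt <- list(n_res = n_res, n_ca = n_res, geometry = geometry,
               seed = seed, contacts = do.call(rbind, contacts))
    list(structure = st, ground_truth = gt)
  })
}

#' Generate a Gaussian trajectory with a prescribed covariance
#'
#' Frames are drawn from a multivariate normal centred on the structure's
#' coordinates with the given 3N x 3N covariance (Angstrom^2); the sample
#' covariance converges to the specification as the frame count grows, so
#' analytic correlation values are available as ground truth.
#'
#' @param structure a `trj_structure` providing the mean coordinates
#' @param covariance 3N x 3N positive-semidefinite matrix, or a scalar
#'   (isotropic independent fluctuations of that variance)
#' @param n_frames number of frames
#' @param seed RNG seed
#' @return list with `trajectory` (a `trj_trajectory`) and `ground_truth`
#'   (the covariance and the analytic DCC matrix over atoms)
#' @export
gen_gaussian_traj <- function(structure, covariance, n_frames, seed = 1) {
  n3 <- 3 * natoms(structure)
  if (length(covariance) == 1)
    covariance <- diag(as.numeric(covariance), n3)
  if (!all(dim(covariance) == c(n3, n3)))
    stop("covariance must be 3N x 3N")
  ev <- eigen(covariance, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values)))
    stop("covariance is not positive semidefinite")
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), n3)
  mu <- as.vector(t(coords(structure)))
  with_seed(seed, {
    Zm <- matrix(stats::rnorm(n_frames * n3), n_frames, n3)
    xyz <- sweep(Zm %*% t(L), 2, mu, "+")
    traj <- new_trajectory(xyz)
    gt <- list(covariance = covariance, seed = seed,
               dcc = analytic_dcc(covariance))
    list(trajectory = traj, ground_truth = gt)
  })
}

# Analytic DCC implied by a 3N x 3N covariance
analytic_dcc <- function(covariance) {
  n <- nrow(covariance) %/% 3L
  ip <- matrix(0, n, n)
  for (k in 1:3) {
    idx <- seq(k, 3 * n, by = 3)
    ip <- ip + covariance[idx, idx]
  }
  ip / sqrt(tcrossprod(diag(ip)))
}

#' Generate a Markov microstate trajectory with block (well) structure
#'
#' States are partitioned into wells; within a well each off-diagonal
#' transition has probability `intra_p`, between wells `inter_p`, with the
#' remainder on the diagonal.  The generating transition matrix and the
#' well labels are returned as ground truth.
#'
#' @param n_states number of microstates
#' @param well_assignment integer well label per state (e.g.
#'   `rep(1:2, each = 5)`)
#' @param intra_p per-pair intra-well transition probability
#' @param inter_p per-pair inter-well transition probability
#' @param n_steps trajectory length (frames)
#' @param seed RNG seed
#' @param start starting state (default 1)
#' @return list with `labels` (integer timeseries), `ground_truth`
#'   (transition matrix `T`, `wells`)
#' @export
gen_markov_traj <- function(n_states, well_assignment, intra_p, inter_p,
                            n_steps, seed = 1, start = 1) {
  if (length(well_assignment) != n_states)
    stop("well_assignment must have one label per state")
  T <- matrix(inter_p, n_states, n_states)
  same <- outer(well_assignment, well_assignment, "==")
  T[same] <- intra_p
  diag(T) <- 0
  diag(T) <- 1 - rowSums(T)
  if (any(diag(T) < 0) || any(abs(rowSums(T) - 1) > 1e-12))
    stop("transition probabilities do not sum to 1 (rates too large)")
  labels <- with_seed(seed, {
    s <- integer(n_steps)
    s[1] <- start
    for (t in 2:n_steps)
      s[t] <- sample.int(n_states, 1, prob = T[s[t - 1], ])
    s
  })
  list(labels = labels,
       ground_truth = list(T = T, wells = well_assignment, seed = seed,
                           intra_p = intra_p, inter_p = inter_p))
}

#' Simulate a trajectory from an explicit transition matrix
#'
#' @param T row-stochastic transition matrix
#' @param n_steps number of steps
#' @param seed RNG seed
#' @param start starting state
#' @return integer label timeseries
#' @export
simulate_chain <- function(T, n_steps, seed = 1, start = 1) {
  if (any(abs(rowSums(T) - 1) > 1e-9))
    stop("transition probabilities do not sum to 1")
  with_seed(seed, {
    s <- integer(n_steps)
    s[1] <- start
    for (t in 2:n_steps)
      s[t] <- sample.int(nrow(T), 1, prob = T[s[t - 1], ])
    s
  })
}

#' Write a generator's ground truth as a JSON sidecar
#' @param ground_truth list from a generator
#' @param path output path (`.json`)
#' @return `path`, invisibly
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "rowmajor")
  invisible(path)
}
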