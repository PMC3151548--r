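# Motion cross-correlation along a trajectory: dynamic cross-correlation
# (DCC, normalized covariance of displacement vectors, range [-1, 1]) and
# linear mutual information (LMI, Gaussian mutual information of the
# position vectors, mapped to [0, 1]; sensitive to correlated motions that
# are perpendicular and therefore invisible to DCC).

#' Per-node fluctuation timeseries from a trajectory
#'
#' Nodes are individual atoms (`group_by = "atom"`) or residues
#' (`group_by = "residue"`, coordinates collapsed to the per-frame centroid,
#' mass-weighted when `mass_weighted = TRUE`).  Deviations are taken about
#' the trajectory mean of each node.
#'
#' @param traj a `trj_trajectory`
#' @param structure companion `trj_structure`
#' @param selection selection string or `trj_selection`
#' @param group_by `"atom"` or `"residue"`
#' @param mass_weighted use atomic masses for residue centroids
#' @return a `fluctuation_set`: list with `dev` (F x 3N matrix of mean-free
#'   deviations), `n_nodes`, `node_labels`
#' @export
build_fluctuations <- function(traj, structure, selection = "/*/*/*",
                               group_by = c("atom", "residue"),
                               mass_weighted = FALSE) {
  group_by <- match.arg(group_by)
  if (traj$nframes < 2) stop("need at least 2 frames")
  idx <- resolve_indices(structure, selection)
  if (length(idx) == 0) stop("empty selection")
  F <- traj$nframes
  if (group_by == "atom") {
    cols <- as.vector(t(outer(idx, 1:3, function(a, k) 3 * (a - 1) + k)))
    pos <- traj$xyz[, cols, drop = FALSE]
    labels <- paste0(structure$atoms$name[idx], "@",
                     residue_key(structure$atoms)[idx])
  } else {
    rgrp <- structure$residue_of[idx]
    ures <- unique(rgrp)
    w <- if (mass_weighted) structure$atoms$mass[idx] else
      rep(1, length(idx))
    pos <- matrix(0, F, 3 * length(ures))
    for (g in seq_along(ures)) {
      members <- idx[rgrp == ures[g]]
      wm <- w[rgrp == ures[g]]
      wm <- wm / sum(wm)
      for (k in 1:3) {
        cols <- 3 * (members - 1) + k
        pos[, 3 * (g - 1) + k] <-
          traj$xyz[, cols, drop = FALSE] %*% wm
      }
    }
    labels <- structure$residues$key[ures]
  }
  dev <- sweep(pos, 2, colMeans(pos))
  f <- list(dev = dev, n_nodes = ncol(dev) %/% 3L, nframes = F,
            node_labels = labels, group_by = group_by,
            mass_weighted = mass_weighted)
  class(f) <- "fluctuation_set"
  f
}

#' @export
print.fluctuation_set <- function(x, ...) {
  cat(sprintf("<fluctuation_set> %d nodes x %d frames (%s)\n",
              x$n_nodes, x$nframes, x$group_by))
  invisible(x)
}

node_dev <- function(fluct, i) {
  fluct$dev[, 3 * (i - 1) + 1:3, drop = FALSE]
}

#' Dynamic cross-correlation matrix
#'
#' `DCC_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)` with population
#' (1/F) averaging over frames; +1 for identical, -1 for anti-phase motion.
#'
#' @param fluct a `fluctuation_set`
#' @return a `corr_matrix` (symmetric, unit diagonal, values in `[-1, 1]`,
#'   method tag `"DCC"`)
#' @export
corr_dcc <- function(fluct) {
  n <- fluct$n_nodes
  dev <- fluct$dev
  F <- nrow(dev)
  # <dr_i . dr_j> for all pairs = sum over the three component blocks
  ip <- matrix(0, n, n)
  for (k in 1:3) {
    Dk <- dev[, seq(k, 3 * n, by = 3), drop = FALSE]
    ip <- ip + crossprod(Dk) / F
  }
  v <- diag(ip)
  if (any(v <= 0)) {
    bad <- fluct$node_labels[which(v <= 0)[1]]
    stop("zero-variance node: ", bad)
  }
  C <- ip / sqrt(tcrossprod(v))
  C <- pmin(pmax(C, -1), 1)
  diag(C) <- 1
  new_corr_matrix(C, "DCC", fluct$node_labels)
}

#' Linear mutual information matrix
#'
#' Gaussian mutual information of node position vectors:
#' `I_ij = 1/2 (ln det C_i + ln det C_j - ln det C_ij)` with `C_i` the 3x3
#' marginal and `C_ij` the 6x6 pair covariance (population normalization).
#' Values are mapped to `[0, 1]` by the Gaussian-channel normalization
#' `r = sqrt(1 - exp(-2 I / 3))` (dimension 3), which gives 0 for
#' independent and 1 for identical motions.
#'
#' @param fluct a `fluctuation_set` with more than 6 frames
#' @return a `corr_matrix` (method tag `"LMI"`, values in `[0, 1]`)
#' @export
corr_lmi <- function(fluct) {
  if (fluct$nframes <= 6)
    stop("LMI needs more than 6 frames to estimate 6x6 pair covariances")
  n <- fluct$n_nodes
  F <- fluct$nframes
  Cfull <- crossprod(fluct$dev) / F
  logdet3 <- numeric(n)
  for (i in seq_len(n)) {
    bi <- 3 * (i - 1) + 1:3
    di <- determinant(Cfull[bi, bi], logarithm = TRUE)
    if (di$sign <= 0 || !is.finite(di$modulus))
      stop("singular marginal covariance for node ", fluct$node_labels[i],
           "; consider adding noise or removing frozen atoms (regularize)")
    logdet3[i] <- as.numeric(di$modulus)
  }
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    bi <- 3 * (i - 1) + 1:3
    for (j in seq_len(n)) {
      if (j <= i) next
      bj <- 3 * (j - 1) + 1:3
      dij <- determinant(Cfull[c(bi, bj), c(bi, bj)], logarithm = TRUE)
      ld <- if (dij$sign <= 0) -Inf else as.numeric(dij$modulus)
      I <- max(0, 0.5 * (logdet3[i] + logdet3[j] - ld))
      M[i, j] <- M[j, i] <- lmi_to_correlation(I)
    }
  }
  diag(M) <- 1
  new_corr_matrix(M, "LMI", fluct$node_labels)
}

#' Map a mutual information value to a `[0, 1]` correlation
#'
#' `r = sqrt(1 - exp(-2 I / d))` with dimension `d = 3`; the Gaussian-
#' channel normalization, 0 at independence and 1 for identical variables.
#' @param I mutual information (nats), `I >= 0`
#' @return correlation in `[0, 1]`
#' @export
lmi_to_correlation <- function(I) {
  sqrt(pmax(0, 1 - exp(-2 * I / 3)))
}

new_corr_matrix <- function(C, method, labels = NULL) {
  dimnames(C) <- if (!is.null(labels)) list(labels, labels) else NULL
  attr(C, "method") <- method
  class(C) <- c("corr_matrix", "matrix")
  C
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat(sprintf("<corr_matrix> %s, %d x %d\n", attr(x, "method"),
              nrow(x), ncol(x)))
  invisible(x)
}

#' Least-squares fit of every frame onto a reference frame
#'
#' Optional pre-processing before correlation analysis; off by default in
#' [build_fluctuations()] so raw and fitted analyses stay explicit.
#'
#' @param traj a `trj_trajectory`
#' @param ref reference frame index (default 1)
#' @return fitted `trj_trajectory`
#' @export
superpose_trajectory <- function(traj, ref = 1) {
  fixed <- traj$xyz[ref, ]
  out <- traj$xyz
  for (i in seq_len(traj$nframes)) {
    out[i, ] <- bio3d::fit.xyz(fixed = fixed, mobile = traj$xyz[i, ])
  }
  new_trajectory(out, traj$stride)
}
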