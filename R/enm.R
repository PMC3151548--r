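# Calpha elastic network models and derived analyses.
#
# The network energy is a sum of Hookean springs, E = 1/2 sum_ij k_ij
# (d_ij - d0_ij)^2, over the spring list.  Two force-constant models are
# provided: "cutoff" (linear-cutoff: k = 10 for sequence-adjacent node
# pairs, k = 1 for any other pair within the distance cutoff) and "kovacs"
# (k_ij = C * (d0 / d_ij)^6 with d0 = 3.8 A, every pair interacting, so
# adjacent Calpha pairs feel ~C and the constant decays with the inverse
# sixth power of distance).

KOVACS_D0 <- 3.8        # mean adjacent Calpha-Calpha distance, Angstrom
BOLTZ_KCAL <- 0.0019872041  # kcal / (mol K)

#' Build a Calpha elastic network
#'
#' @param structure a `trj_structure`
#' @param selection selection string or `trj_selection`; default all CA atoms
#' @param model `"cutoff"` (linear cutoff) or `"kovacs"`
#' @param cutoff distance cutoff in Angstrom for the cutoff model (default 12)
#' @param C Kovacs force-constant scale, kcal/(mol A^2), default 40
#' @return an `elastic_network`: node coordinates, masses, and the spring
#'   list (i, j, k, d0)
#' @export
build_enm <- function(structure, selection = "/*/*/CA",
                      model = c("cutoff", "kovacs"), cutoff = 12, C = 40) {
  model <- match.arg(model)
  idx <- resolve_indices(structure, selection)
  if (length(idx) < 2) stop("elastic network needs at least 2 nodes")
  xyz <- coords(structure, idx)
  mass <- structure$atoms$mass[idx]
  seg <- atom_seg(structure$atoms)[idx]
  resid <- structure$atoms$resid[idx]
  n <- nrow(xyz)
  dm <- as.matrix(stats::dist(xyz))
  pairs <- which(upper.tri(dm), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]; d0 <- dm[pairs]
  adjacent <- seg[i] == seg[j] & abs(resid[i] - resid[j]) == 1L
  if (model == "cutoff") {
    keep <- d0 <= cutoff | adjacent
    k <- ifelse(adjacent, 10, 1)[keep]
    i <- i[keep]; j <- j[keep]; d0 <- d0[keep]
  } else {
    k <- C * (KOVACS_D0 / d0)^6
  }
  if (length(i) == 0) stop("disconnected network: no pairs within cutoff")
  net <- list(xyz = xyz, mass = mass, segid = seg, resid = resid,
              springs = data.frame(i = i, j = j, k = k, d0 = d0),
              model = model, cutoff = cutoff, C = C)
  class(net) <- "elastic_network"
  net
}

#' @export
print.elastic_network <- function(x, ...) {
  cat(sprintf("<elastic_network> %d nodes, %d springs (%s model)\n",
              nrow(x$xyz), nrow(x$springs), x$model))
  invisible(x)
}

# Assemble the 3N x 3N Hessian of the spring energy at the equilibrium
# geometry: for each spring the off-diagonal 3x3 block is -k u u^T with u
# the unit bond vector, and the diagonal blocks accumulate +k u u^T.
enm_hessian <- function(network, mass_weighted = FALSE) {
  xyz <- network$xyz
  n <- nrow(xyz)
  H <- matrix(0, 3 * n, 3 * n)
  sp <- network$springs
  for (s in seq_len(nrow(sp))) {
    i <- sp$i[s]; j <- sp$j[s]; k <- sp$k[s]
    u <- xyz[j, ] - xyz[i, ]
    u <- u / sqrt(sum(u^2))
    blk <- k * tcrossprod(u)
    bi <- 3 * (i - 1) + 1:3; bj <- 3 * (j - 1) + 1:3
    H[bi, bj] <- H[bi, bj] - blk
    H[bj, bi] <- H[bj, bi] - blk
    H[bi, bi] <- H[bi, bi] + blk
    H[bj, bj] <- H[bj, bj] + blk
  }
  if (mass_weighted) {
    w <- rep(1 / sqrt(network$mass), each = 3)
    H <- H * tcrossprod(w)
  }
  H
}

#' Diagonalize an elastic network Hessian
#'
#' @param network an `elastic_network`
#' @param mass_weighted apply M^(-1/2) H M^(-1/2) weighting (off by default)
#' @param zero_tol relative tolerance identifying near-zero (rigid-body)
#'   modes: `|lambda| < zero_tol * max(lambda)`
#' @return a `mode_set`: eigenvalues ascending, orthonormal eigenvectors in
#'   columns, and the count/index of near-zero modes
#' @export
enm_modes <- function(network, mass_weighted = FALSE, zero_tol = 1e-8) {
  H <- enm_hessian(network, mass_weighted)
  e <- eigen(H, symmetric = TRUE)
  ord <- order(e$values)
  lambda <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  lmax <- max(abs(lambda))
  zero <- abs(lambda) < zero_tol * lmax
  if (sum(zero) > 6)
    warning("internally disconnected or collinear network: ",
            sum(zero), " near-zero modes")
  m <- list(values = lambda, vectors = vectors, n_zero = sum(zero),
            zero = zero, n_nodes = nrow(network$xyz),
            mass_weighted = mass_weighted)
  class(m) <- "mode_set"
  m
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("<mode_set> %d modes (%d near-zero), %d nodes\n",
              length(x$values), x$n_zero, x$n_nodes))
  invisible(x)
}

#' Structural perturbation analysis for one mode
#'
#' Every spring touching residue `i` is stiffened by `magnitude`; the
#' response is the elastic energy of the perturbation along the chosen
#' mode, `delta_omega_i = v_m' dH_i v_m`, with `dH_i` the Hessian of the
#' perturbed springs.  Large responses mark residues critical to the mode.
#'
#' @param modes a `mode_set`
#' @param network the `elastic_network` the modes came from
#' @param mode_index index of a non-rigid-body mode (1 = softest overall,
#'   so internal modes start at `n_zero + 1` in the default numbering)
#' @param magnitude spring-constant perturbation, default 0.1
#' @return numeric vector of per-residue responses (all `>= 0`)
#' @export
enm_spm <- function(modes, network, mode_index, magnitude = 0.1) {
  if (mode_index < 1 || mode_index > length(modes$values))
    stop("mode index out of range")
  if (modes$zero[mode_index])
    stop("mode ", mode_index, " is a rigid-body mode; pick an internal mode")
  v <- modes$vectors[, mode_index]
  xyz <- network$xyz
  sp <- network$springs
  n <- nrow(xyz)
  # per-spring elastic energy of a unit stiffening along the mode
  du <- numeric(nrow(sp))
  for (s in seq_len(nrow(sp))) {
    i <- sp$i[s]; j <- sp$j[s]
    u <- xyz[j, ] - xyz[i, ]
    u <- u / sqrt(sum(u^2))
    rel <- v[3 * (j - 1) + 1:3] - v[3 * (i - 1) + 1:3]
    du[s] <- magnitude * sum(u * rel)^2
  }
  resp <- numeric(n)
  for (s in seq_len(nrow(sp))) {
    resp[sp$i[s]] <- resp[sp$i[s]] + du[s]
    resp[sp$j[s]] <- resp[sp$j[s]] + du[s]
  }
  resp
}

#' Theoretical B-factors from the normal modes
#'
#' `B_i = (8 pi^2 / 3) * kT * sum_m |v_m,i|^2 / lambda_m` over the
#' `n_modes` lowest-frequency internal modes, in Angstrom^2 (with spring
#' constants in kcal/(mol A^2) and T in Kelvin).  When experimental
#' B-factors are supplied, their Pearson cross-correlation with the
#' theoretical values is reported.
#'
#' @param modes a `mode_set`
#' @param n_modes number of internal modes to use (1 .. 3N-6)
#' @param temperature Kelvin, default 300
#' @param bexp optional experimental B-factors (one per node)
#' @return list with `b_theo`, `b_exp`, `correlation`, `n_modes`
#' @export
enm_beta_factors <- function(modes, n_modes = NULL, temperature = 300,
                             bexp = NULL) {
  internal <- which(!modes$zero)
  if (is.null(n_modes)) n_modes <- length(internal)
  if (n_modes < 1 || n_modes > length(internal))
    stop("n_modes must be between 1 and ", length(internal))
  use <- internal[seq_len(n_modes)]
  n <- modes$n_nodes
  kT <- BOLTZ_KCAL * temperature
  b <- numeric(n)
  for (m in use) {
    v2 <- matrix(modes$vectors[, m]^2, ncol = 3, byrow = TRUE)
    b <- b + rowSums(v2) / modes$values[m]
  }
  b <- (8 * pi^2 / 3) * kT * b
  corr <- NULL
  if (!is.null(bexp)) {
    if (length(bexp) != n)
      stop("experimental B-factors must have one value per node")
    corr <- beta_correlation(b, bexp)
  }
  list(b_theo = b, b_exp = bexp, correlation = corr, n_modes = n_modes,
       temperature = temperature)
}

#' Pearson cross-correlation of theoretical and experimental B-factors
#' @param b_theo,b_exp numeric vectors of equal length
#' @return correlation in `[-1, 1]`
#' @export
beta_correlation <- function(b_theo, b_exp) {
  if (is.null(b_exp)) stop("experimental B-factors required for correlation")
  dt <- b_theo - mean(b_theo); de <- b_exp - mean(b_exp)
  sum(dt * de) / sqrt(sum(dt^2) * sum(de^2))
}

#' Involvement coefficients and cumulative square overlap
#'
#' Projects the displacement between a conformer `T` and the reference `R`
#' onto each internal mode: `I_m = |v_m . dr| / |dr|`.  The cumulative
#' square overlap `CSO = sum_m I_m^2` over all internal modes equals 1 for
#' any displacement orthogonal to the rigid-body space.
#'
#' @param modes a `mode_set`
#' @param conf_t N x 3 coordinates of the displaced conformer
#' @param conf_r N x 3 reference coordinates
#' @param threshold report only `I_m >= threshold` (default 0.2)
#' @return list with per-internal-mode `I`, `cso`, `reported` (filtered
#'   table), and the raw displacement vector
#' @export
enm_involvement <- function(modes, conf_t, conf_r, threshold = 0.2) {
  if (!all(dim(conf_t) == dim(conf_r)) || nrow(conf_t) != modes$n_nodes)
    stop("conformers must match the network's node set")
  disp <- as.vector(t(conf_t - conf_r))
  nrm <- sqrt(sum(disp^2))
  if (nrm == 0) stop("identical conformers: zero displacement")
  dhat <- disp / nrm
  internal <- which(!modes$zero)
  I <- abs(as.vector(crossprod(modes$vectors[, internal, drop = FALSE],
                               dhat)))
  cso <- sum(I^2)
  rep_tab <- data.frame(mode = internal, I = I)[I >= threshold, ]
  list(I = I, modes = internal, cso = cso, reported = rep_tab,
       displacement = disp, threshold = threshold)
}

#' Residue cross-correlations from the normal modes
#'
#' Builds the mode covariance `Cov = sum_m v_m v_m' / lambda_m` over the
#' `n_modes` lowest internal modes and normalizes its 3x3 block traces:
#' `C_ij = tr(Cov_ij) / sqrt(tr(Cov_ii) tr(Cov_jj))`.
#'
#' @param modes a `mode_set`
#' @param n_modes number of internal modes (default all)
#' @return symmetric N x N matrix with unit diagonal, values in `[-1, 1]`
#' @export
enm_mode_correlation <- function(modes, n_modes = NULL) {
  internal <- which(!modes$zero)
  if (is.null(n_modes)) n_modes <- length(internal)
  if (n_modes < 1) stop("n_modes must be >= 1")
  use <- internal[seq_len(min(n_modes, length(internal)))]
  V <- modes$vectors[, use, drop = FALSE]
  w <- 1 / modes$values[use]
  Cov <- V %*% (t(V) * w)
  n <- modes$n_nodes
  tr <- matrix(0, n, n)
  for (k in 1:3) {
    idx <- seq(k, 3 * n, by = 3)
    tr <- tr + Cov[idx, idx]
  }
  d <- sqrt(diag(tr))
  C <- tr / tcrossprod(d)
  C <- pmin(pmax(C, -1), 1)
  diag(C) <- 1
  C
}
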