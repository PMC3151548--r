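# Free-energy-surface analysis of microstate timeseries.
#
# A finely clusterized trajectory (one integer microstate label per frame)
# defines a transition network: nodes are microstates weighted by their
# visit counts, directed links carry the transition counts observed at a
# chosen lag.  Kinetic coordinates (committor probability p_fold and mean
# first passage time) are solved analytically from the row-normalized
# transition matrix; the cut-based free-energy profile ranks microstates by
# kinetic proximity to a reference and reports, for each cut along the
# cumulative partition function, the barrier -ln(Z_AB/Z) from the
# transition flux crossing the cut.  Kinetic grouping assigns microstates
# to basins via pairwise commitment probabilities within a commitment time.

#' Read a microstate label timeseries
#'
#' Plain text, one integer label per line (the per-frame assignment table
#' written by the clustering module is accepted directly).
#'
#' @param path file path
#' @return integer vector of labels
#' @export
read_microstates <- function(path) {
  v <- scan(path, what = integer(), comment.char = "#", quiet = TRUE)
  if (length(v) == 0) stop("no microstate labels in ", path)
  v
}

#' Build a transition network from a label timeseries
#'
#' @param labels integer microstate labels, one per frame
#' @param lag lag in frames (default 1)
#' @param symmetrize enforce detailed balance by symmetrizing the counts
#'   (off by default; the profile construction is defined on sampled
#'   transitions)
#' @return a `transition_network`: `states` (original labels), `weights`
#'   (visit counts), `counts` (directed transition count matrix at `lag`),
#'   `T` (row-normalized transition matrix)
#' @export
transition_network <- function(labels, lag = 1, symmetrize = FALSE) {
  if (lag < 1) stop("lag must be >= 1")
  F <- length(labels)
  if (F <= lag) stop("need more frames than the lag")
  states <- sort(unique(labels))
  if (length(states) < 2) stop("degenerate network: single microstate")
  s <- match(labels, states)      # dense relabeling
  n <- length(states)
  from <- s[seq_len(F - lag)]
  to <- s[seq_len(F - lag) + lag]
  counts <- matrix(0, n, n)
  for (k in seq_along(from))
    counts[from[k], to[k]] <- counts[from[k], to[k]] + 1
  if (symmetrize) counts <- (counts + t(counts)) / 2
  weights <- tabulate(s, nbins = n)
  rs <- rowSums(counts)
  T <- counts / ifelse(rs > 0, rs, 1)
  net <- list(states = states, weights = weights, counts = counts, T = T,
              lag = lag, nframes = F)
  class(net) <- "transition_network"
  net
}

#' @export
print.transition_network <- function(x, ...) {
  cat(sprintf("<transition_network> %d microstates, %d frames, lag %d\n",
              length(x$states), x$nframes, x$lag))
  invisible(x)
}

state_index <- function(net, label) {
  i <- match(label, net$states)
  if (is.na(i)) stop("state ", label, " not in the network")
  i
}

#' Committor probability (p_fold)
#'
#' Probability of reaching `folded` before `unfolded`, solved from the
#' linear system `p_i = sum_j T_ij p_j` for interior nodes with boundary
#' conditions `p(folded) = 1`, `p(unfolded) = 0`.
#'
#' @param net a `transition_network`
#' @param folded,unfolded microstate labels of the two boundary nodes
#' @return a `kinetic_coordinate` with `value` per state in `[0, 1]`
#' @export
pfold <- function(net, folded, unfolded) {
  fi <- state_index(net, folded); ui <- state_index(net, unfolded)
  if (fi == ui) stop("boundary nodes must differ")
  n <- length(net$states)
  reach <- reachable_to(net$T, c(fi, ui))
  if (!all(reach))
    stop("boundary nodes unreachable from state(s) ",
         paste(net$states[!reach], collapse = ", "))
  interior <- setdiff(seq_len(n), c(fi, ui))
  p <- numeric(n)
  p[fi] <- 1; p[ui] <- 0
  if (length(interior) > 0) {
    Tm <- net$T
    A <- diag(length(interior)) - Tm[interior, interior, drop = FALSE]
    b <- Tm[interior, fi]
    p[interior] <- solve(A, b)
  }
  p <- pmin(pmax(p, 0), 1)
  out <- list(kind = "pfold", value = p, states = net$states,
              boundary = c(folded = folded, unfolded = unfolded))
  class(out) <- "kinetic_coordinate"
  out
}

# states from which at least one of `targets` is reachable along T > 0
reachable_to <- function(T, targets) {
  n <- nrow(T)
  reach <- rep(FALSE, n)
  reach[targets] <- TRUE
  repeat {
    new <- reach | (T %*% reach > 0)
    if (all(new == reach)) break
    reach <- as.vector(new)
  }
  reach
}

#' Mean first passage time to a target microstate
#'
#' Solves `m = 1 + T m` with `m(target) = 0`; units of lag steps.  States
#' from which the target is unreachable are flagged `Inf`.
#'
#' @param net a `transition_network`
#' @param target microstate label
#' @return a `kinetic_coordinate` with `value >= 0` per state
#' @export
mfpt <- function(net, target) {
  ti <- state_index(net, target)
  n <- length(net$states)
  reach <- reachable_to(net$T, ti)
  m <- rep(Inf, n)
  m[ti] <- 0
  interior <- setdiff(which(reach), ti)
  if (length(interior) > 0) {
    A <- diag(length(interior)) -
      net$T[interior, interior, drop = FALSE]
    m[interior] <- solve(A, rep(1, length(interior)))
  }
  out <- list(kind = "mfpt", value = m, states = net$states,
              boundary = c(target = target))
  class(out) <- "kinetic_coordinate"
  out
}

#' @export
print.kinetic_coordinate <- function(x, ...) {
  cat(sprintf("<kinetic_coordinate> %s over %d states\n", x$kind,
              length(x$value)))
  invisible(x)
}

#' Cut-based free-energy profile
#'
#' Microstates are ranked by kinetic proximity to the reference (descending
#' committor, or ascending mean first passage time).  Each cut after the
#' k-th ranked state splits the network into a reference side A and the
#' rest B; the profile point is `x = Z_A / Z` (cumulative statistical
#' weight) against `dG = -ln(Z_AB / Z_tot)` where `Z_AB` is the total
#' transition count crossing the cut (both directions) and `Z_tot` the
#' total transition count.  Ties in the coordinate are broken by state
#' weight, then by state id, and cuts fall between consecutive ranked
#' states.
#'
#' @param net a `transition_network`
#' @param coord a `kinetic_coordinate` from [pfold()] or [mfpt()]
#' @return a `fep_profile`: data.frame `profile` with columns `cut`, `x`,
#'   `dG`, `z_ab`, plus the ranking used; the barrier (maximum `dG` over
#'   interior cuts) and its location
#' @export
cfep <- function(net, coord) {
  n <- length(net$states)
  v <- coord$value
  if (any(!is.finite(v)))
    stop("kinetic coordinate must be finite for all visited states")
  proximity <- if (coord$kind == "pfold") -v else v
  ord <- order(proximity, -net$weights, seq_len(n))
  Z <- sum(net$weights)
  Ctot <- sum(net$counts)
  cw <- cumsum(net$weights[ord])
  xs <- numeric(n - 1); dg <- numeric(n - 1); zab <- numeric(n - 1)
  disconnected <- logical(n - 1)
  Cord <- net$counts[ord, ord, drop = FALSE]
  for (k in seq_len(n - 1)) {
    A <- seq_len(k); B <- (k + 1):n
    flux <- sum(Cord[A, B]) + sum(Cord[B, A])
    xs[k] <- cw[k] / Z
    zab[k] <- flux
    dg[k] <- if (flux > 0) -log(flux / Ctot) else Inf
    disconnected[k] <- flux == 0
  }
  prof <- data.frame(cut = seq_len(n - 1), x = xs, dG = dg, z_ab = zab,
                     disconnected = disconnected)
  finite <- which(is.finite(prof$dG))
  bar <- if (length(finite) > 0) finite[which.max(prof$dG[finite])] else NA
  out <- list(profile = prof, order = ord, states = net$states[ord],
              barrier_x = if (is.na(bar)) NA_real_ else prof$x[bar],
              barrier_dG = if (is.na(bar)) NA_real_ else prof$dG[bar],
              barrier_cut = bar, coord_kind = coord$kind)
  class(out) <- "fep_profile"
  out
}

#' @export
print.fep_profile <- function(x, ...) {
  cat(sprintf(
    "<fep_profile> %d cuts (%s-ranked); barrier %.3f kT at x = %.3f\n",
    nrow(x$profile), x$coord_kind, x$barrier_dG, x$barrier_x))
  invisible(x)
}

#' Commitment probability matrix
#'
#' `p_commit(i -> j)` is the fraction of visits to microstate `i` from
#' which the trajectory reaches `j` within `tau_commit` frames.  Every
#' occurrence of `i` is a start (sliding, overlapping windows).
#'
#' @param labels integer microstate label timeseries
#' @param subset microstate labels forming the rows/columns (default: all)
#' @param tau_commit commitment time, frames (`< length(labels)`)
#' @return square matrix of commitment probabilities in `[0, 1]` with
#'   `dimnames` the subset labels; `p(i -> i) = 1`
#' @export
commitment_matrix <- function(labels, subset = NULL, tau_commit) {
  F <- length(labels)
  if (tau_commit >= F) stop("tau_commit must be smaller than the number ",
                            "of frames")
  if (is.null(subset)) subset <- sort(unique(labels))
  ns <- length(subset)
  P <- matrix(0, ns, ns, dimnames = list(subset, subset))
  pos_of <- lapply(subset, function(s) which(labels == s))
  for (a in seq_len(ns)) {
    starts <- pos_of[[a]]
    if (length(starts) == 0) { P[a, ] <- NA; next }
    for (b in seq_len(ns)) {
      if (b == a) { P[a, b] <- 1; next }
      hits <- 0L
      tb <- pos_of[[b]]
      if (length(tb) > 0) {
        # for each start, is there a visit to b within (t, t + tau]?
        nxt <- findInterval(starts, tb) + 1L
        ok <- nxt <= length(tb) & (tb[pmin(nxt, length(tb))] - starts) <=
          tau_commit
        hits <- sum(ok)
      }
      P[a, b] <- hits / length(starts)
    }
  }
  P
}

#' Kinetic grouping analysis
#'
#' The `n_heavy` most populated microstates are grouped into basins by the
#' commitment rule: states `i`, `j` fall in one basin when
#' `max(p_commit(i->j), p_commit(j->i)) >= 0.5` (set `mutual = TRUE` to
#' require both directions), closed transitively.  Every remaining state is
#' then assigned to the basin it commits to with probability `>= 0.5`
#' (largest such basin probability wins), else left unassigned.
#'
#' @param labels integer microstate label timeseries
#' @param tau_commit commitment time, frames
#' @param n_heavy size of the heavy (most populated) subset, default 500
#' @param mutual require `>= 0.5` in both directions for grouping
#' @param representative optional single microstate label: single-basin
#'   mode, returning the basin of all states committing to it with
#'   `p >= 0.5`
#' @return a `basin_partition`: per-state basin id (`NA` = unassigned),
#'   the commitment matrix of the heavy subset, basin representative
#'   states
#' @export
kga <- function(labels, tau_commit, n_heavy = 500, mutual = FALSE,
                representative = NULL) {
  states <- sort(unique(labels))
  pop <- tabulate(match(labels, states), nbins = length(states))
  if (!is.null(representative)) {
    P <- commitment_matrix(labels, states, tau_commit)
    ri <- match(representative, states)
    if (is.na(ri)) stop("representative state not present")
    basin <- ifelse(P[, ri] >= 0.5, 1L, NA_integer_)
    reps <- representative
    heavyP <- P
  } else {
    if (n_heavy > length(states)) {
      warning("n_heavy larger than the number of states; clamped")
      n_heavy <- length(states)
    }
    heavy <- states[order(-pop, states)][seq_len(n_heavy)]
    heavy <- sort(heavy)
    P <- commitment_matrix(labels, heavy, tau_commit)
    nh <- length(heavy)
    rel <- if (mutual) (P >= 0.5) & (t(P) >= 0.5) else
      (P >= 0.5) | (t(P) >= 0.5)
    diag(rel) <- TRUE
    ig <- igraph::graph_from_adjacency_matrix(rel, mode = "max")
    comp <- igraph::components(ig)$membership
    # deterministic numbering by smallest member state
    first <- tapply(heavy, comp, min)
    comp <- match(comp, comp[match(sort(first), heavy)])
    basin <- rep(NA_integer_, length(states))
    basin[match(heavy, states)] <- comp
    nb <- max(comp)
    reps <- vapply(seq_len(nb), function(k) {
      m <- heavy[comp == k]
      m[which.max(pop[match(m, states)])]
    }, states[1])
    # post-processing: commit the light states to the isolated basins
    light <- setdiff(states, heavy)
    if (length(light) > 0) {
      Pl <- commitment_matrix(labels, states, tau_commit)
      for (s in light) {
        si <- match(s, states)
        pb <- vapply(seq_len(nb), function(k) {
          members <- states[which(basin == k)]
          members <- setdiff(members, s)
          if (length(members) == 0) return(0)
          # probability of reaching the basin = max member commitment
          max(Pl[si, match(members, states)])
        }, numeric(1))
        if (max(pb) >= 0.5) basin[si] <- which.max(pb)
      }
    }
    heavyP <- P
  }
  out <- list(states = states, basin = basin, population = pop,
              p_commit = heavyP, representatives = reps,
              tau_commit = tau_commit)
  class(out) <- "basin_partition"
  out
}

#' @export
print.basin_partition <- function(x, ...) {
  nb <- length(unique(stats::na.omit(x$basin)))
  cat(sprintf(
    "<basin_partition> %d states -> %d basins (%d unassigned), tau = %d\n",
    length(x$states), nb, sum(is.na(x$basin)), x$tau_commit))
  invisible(x)
}

#' First-passage-time distribution
#'
#' First passage times to `target`, one per qualifying start.  Starts are
#' every visit to the `from` state (default: the target itself, giving the
#' distribution of return/first-passage times); a start qualifies when the
#' target is visited again later in the trajectory.  The log-log histogram
#' of this distribution typically separates intra- from inter-basin
#' relaxation and guides the choice of the commitment time.
#'
#' @param labels integer microstate label timeseries
#' @param target microstate label
#' @param from start state (default `target`)
#' @return list with `fpt` (vector of first passage times, frames),
#'   `histogram` (time, count), `n_starts`
#' @export
fpt_distribution <- function(labels, target, from = target) {
  if (!target %in% labels) stop("target state never visited")
  starts <- which(labels == from)
  tpos <- which(labels == target)
  fpt <- integer(0)
  for (t0 in starts) {
    nxt <- tpos[tpos > t0]
    if (length(nxt) > 0) fpt <- c(fpt, nxt[1] - t0)
  }
  h <- table(fpt)
  list(fpt = fpt,
       histogram = data.frame(time = as.integer(names(h)),
                              count = as.integer(h)),
       n_starts = length(fpt))
}
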