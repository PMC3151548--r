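# Independent reference implementations used as oracles.  These are kept
# deliberately naive (double loops, dense algebra, explicit recursion) and
# share no code with the package internals they check.

# -- graph oracles -----------------------------------------------------------

# union-find connected components over an edge list
uf_components <- function(n, edges_i, edges_j) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (k in seq_along(edges_i)) {
    a <- find(edges_i[k]); b <- find(edges_j[k])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, sort(unique(roots)))
}

# all shortest paths between s and t by breadth-first search layering
bfs_all_shortest_paths <- function(n, edges_i, edges_j, s, t) {
  adj <- vector("list", n)
  for (k in seq_along(edges_i)) {
    adj[[edges_i[k]]] <- c(adj[[edges_i[k]]], edges_j[k])
    adj[[edges_j[k]]] <- c(adj[[edges_j[k]]], edges_i[k])
  }
  dist <- rep(Inf, n); dist[s] <- 0
  queue <- s
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (dist[w] == Inf) {
      dist[w] <- dist[v] + 1
      queue <- c(queue, w)
    }
  }
  if (!is.finite(dist[t])) return(list())
  extend <- function(path) {
    v <- path[length(path)]
    if (v == t) return(list(path))
    out <- list()
    for (w in adj[[v]]) if (dist[w] == dist[v] + 1 && dist[w] <= dist[t])
      out <- c(out, extend(c(path, w)))
    out
  }
  extend(s)
}

# -- correlation oracles -----------------------------------------------------

# naive double-loop DCC from a fluctuation set
naive_dcc <- function(dev, n_nodes) {
  F <- nrow(dev)
  C <- matrix(0, n_nodes, n_nodes)
  for (i in seq_len(n_nodes)) for (j in seq_len(n_nodes)) {
    num <- 0; vi <- 0; vj <- 0
    for (f in seq_len(F)) {
      di <- dev[f, 3 * (i - 1) + 1:3]
      dj <- dev[f, 3 * (j - 1) + 1:3]
      num <- num + sum(di * dj)
      vi <- vi + sum(di^2)
      vj <- vj + sum(dj^2)
    }
    C[i, j] <- num / sqrt(vi * vj)
  }
  C
}

# closed-form Gaussian mutual information from a 6x6 covariance
gaussian_mi <- function(C6) {
  0.5 * (log(det(C6[1:3, 1:3])) + log(det(C6[4:6, 4:6])) -
           log(det(C6)))
}

# -- clustering oracles ------------------------------------------------------

# straightforward sequential leader scan, nearest modality
naive_leader_nearest <- function(D, threshold) {
  F <- nrow(D)
  centers <- integer(0)
  assign <- integer(F)
  for (f in seq_len(F)) {
    if (length(centers) > 0) {
      d <- D[f, centers]
      if (min(d) <= threshold) {
        assign[f] <- which.min(d)
        next
      }
    }
    centers <- c(centers, f)
    assign[f] <- length(centers)
  }
  list(assign = assign, centers = centers)
}

# brute-force QT-like: repeatedly take the largest candidate cluster
# (ties: lowest centre frame)
naive_qt <- function(D, threshold) {
  F <- nrow(D)
  remaining <- seq_len(F)
  assign <- integer(F)
  centers <- integer(0)
  while (length(remaining) > 0) {
    best_c <- NA; best_m <- integer(0)
    for (c in remaining) {
      m <- remaining[D[c, remaining] <= threshold]
      if (length(m) > length(best_m)) { best_c <- c; best_m <- m }
    }
    centers <- c(centers, best_c)
    assign[best_m] <- length(centers)
    remaining <- setdiff(remaining, best_m)
  }
  list(assign = assign, centers = centers)
}

# naive average-linkage agglomeration, merging while the closest pair of
# clusters is within the threshold
naive_average_linkage <- function(D, threshold) {
  F <- nrow(D)
  clusters <- as.list(seq_len(F))
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (b <= a) next
      d <- mean(D[clusters[[a]], clusters[[b]]])
      if (d < best_d) { best_d <- d; best <- c(a, b) }
    }
    if (best_d > threshold) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  assign <- integer(F)
  ord <- order(vapply(clusters, min, integer(1)))
  for (k in seq_along(ord)) assign[clusters[[ord[k]]]] <- k
  assign
}

# partition agreement: fraction of frame pairs on whose co-membership two
# partitions agree (label-permutation invariant)
partition_agreement <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  mean(same_a[upper.tri(same_a)] == same_b[upper.tri(same_b)])
}

# -- Markov-chain oracles ----------------------------------------------------

# Monte-Carlo committor: probability of hitting `folded` before `unfolded`
mc_pfold <- function(T, start, folded, unfolded, n_walkers, seed) {
  set.seed(seed)
  state <- rep(start, n_walkers)
  done <- logical(n_walkers)
  hit <- logical(n_walkers)
  done[state == folded] <- hit[state == folded] <- TRUE
  done[state == unfolded] <- TRUE
  for (step in 1:10000) {
    if (all(done)) break
    active <- which(!done)
    old <- state[active]
    for (s in unique(old)) {
      sel <- active[old == s]
      state[sel] <- sample.int(nrow(T), length(sel), replace = TRUE,
                               prob = T[s, ])
    }
    newly_f <- !done & state == folded
    newly_u <- !done & state == unfolded
    hit[newly_f] <- TRUE
    done[newly_f | newly_u] <- TRUE
  }
  mean(hit)
}

# Monte-Carlo mean hitting time of `target`
mc_mfpt <- function(T, start, target, n_walkers, seed) {
  set.seed(seed)
  state <- rep(start, n_walkers)
  steps <- integer(n_walkers)
  done <- state == target
  for (step in 1:100000) {
    if (all(done)) break
    active <- which(!done)
    old <- state[active]
    for (s in unique(old)) {
      sel <- active[old == s]
      state[sel] <- sample.int(nrow(T), length(sel), replace = TRUE,
                               prob = T[s, ])
    }
    steps[active] <- steps[active] + 1L
    done[active[state[active] == target]] <- TRUE
  }
  mean(steps)
}

# exhaustive minimum-cut flux over all bipartitions containing `ref`
exhaustive_min_cut <- function(counts, ref) {
  n <- nrow(counts)
  others <- setdiff(seq_len(n), ref)
  best_flux <- Inf; best_set <- NULL
  for (mask in 0:(2^length(others) - 1)) {
    A <- c(ref, others[bitwAnd(mask, 2^(seq_along(others) - 1)) > 0])
    B <- setdiff(seq_len(n), A)
    if (length(B) == 0) next
    flux <- sum(counts[A, B]) + sum(counts[B, A])
    if (flux < best_flux) { best_flux <- flux; best_set <- sort(A) }
  }
  list(flux = best_flux, A = best_set)
}
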