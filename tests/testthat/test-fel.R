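# Transition networks, kinetic coordinates, cut-based profiles, kinetic
# grouping.

test_that("transition counts follow the lagged pair definition", {
  # alternating two-state series: T is the swap matrix
  lab <- rep(c(1L, 2L), 50)
  net <- transition_network(lab, lag = 1)
  expect_equal(net$T, rbind(c(0, 1), c(1, 0)), ignore_attr = TRUE)
  expect_equal(net$weights, c(50, 50))
  # lag 2 sees only self-transitions
  net2 <- transition_network(lab, lag = 2)
  expect_equal(net2$T, diag(2), ignore_attr = TRUE)
  expect_error(transition_network(rep(1L, 10)), "degenerate")
  expect_error(transition_network(lab, lag = 100), "more frames")
  # symmetrization averages the directed counts
  lab3 <- c(1L, 1L, 2L, 1L, 1L, 1L, 2L, 2L)
  nets <- transition_network(lab3, symmetrize = TRUE)
  expect_equal(nets$counts, t(nets$counts))
})

test_that("the estimated matrix converges to the generating chain", {
  gen <- gen_markov_traj(10, rep(1:2, each = 5), intra_p = 0.08,
                         inter_p = 0.004, n_steps = 1e5, seed = 501)
  net <- transition_network(gen$labels)
  T0 <- gen$ground_truth$T
  # every sampled transition probability within 3 standard errors
  for (i in 1:10) {
    n_i <- sum(net$counts[i, ])
    se <- sqrt(T0[i, ] * (1 - T0[i, ]) / n_i)
    expect_true(all(abs(net$T[i, ] - T0[i, ]) <= 3 * se + 1e-12))
  }
})

test_that("the committor is 1/2 at the midpoint of a symmetric chain", {
  # A-B-C random walk: from B both ends are equally likely
  T <- rbind(c(0.5, 0.5, 0), c(0.25, 0.5, 0.25), c(0, 0.5, 0.5))
  lab <- simulate_chain(T, 2000, seed = 502)
  net <- transition_network(lab)
  net$T <- T; net$counts <- T * 100   # exact chain, sampled weights
  p <- pfold(net, folded = 3, unfolded = 1)
  expect_equal(p$value[2], 0.5, tolerance = 1e-12)
  expect_equal(p$value[3], 1)
  expect_equal(p$value[1], 0)
})

test_that("committor and mean first passage solve their linear systems", {
  set.seed(503)
  n <- 8
  T <- matrix(rexp(n * n), n); T <- T / rowSums(T)
  net <- list(states = 1:n, weights = rep(10, n), counts = T * 1000,
              T = T, lag = 1L, nframes = 1000L)
  class(net) <- "transition_network"
  p <- pfold(net, folded = n, unfolded = 1)
  # harmonicity at interior nodes
  interior <- 2:(n - 1)
  expect_equal(p$value[interior],
               as.vector(T %*% p$value)[interior], tolerance = 1e-10)
  # first-step-analysis brute-force solve (independent assembly)
  A <- diag(n); b <- numeric(n)
  for (i in interior) { A[i, ] <- -T[i, ]; A[i, i] <- A[i, i] + 1 }
  b[n] <- 1
  A[n, ] <- 0; A[n, n] <- 1
  A[1, ] <- 0; A[1, 1] <- 1
  expect_equal(p$value, solve(A, b), tolerance = 1e-10)
  # Monte-Carlo hitting probability from a mid state
  expect_equal(p$value[4], mc_pfold(T, 4, n, 1, 1e5, seed = 504),
               tolerance = 0.02)
  m <- mfpt(net, target = n)
  expect_equal(m$value[n], 0)
  resid <- m$value - (1 + as.vector(T %*% m$value))
  expect_true(max(abs(resid[-n])) < 1e-10)
  mc <- mc_mfpt(T, 3, n, 1e5, seed = 505)
  expect_equal(m$value[3], mc, tolerance = 0.02 * mc)
})

test_that("a two-state escape process has mfpt equal to 1/p", {
  for (p_esc in c(0.2, 0.05)) {
    T <- rbind(c(1 - p_esc, p_esc), c(0.5, 0.5))
    net <- list(states = 1:2, weights = c(10, 10), counts = T * 100,
                T = T, lag = 1L, nframes = 100L)
    class(net) <- "transition_network"
    expect_equal(mfpt(net, 2)$value[1], 1 / p_esc, tolerance = 1e-12)
  }
})

test_that("unreachable targets are flagged infinite", {
  T <- rbind(c(1, 0, 0), c(0.5, 0.25, 0.25), c(0, 0.5, 0.5))
  net <- list(states = 1:3, weights = c(5, 5, 5), counts = T * 100,
              T = T, lag = 1L, nframes = 100L)
  class(net) <- "transition_network"
  m <- mfpt(net, 3)
  expect_true(is.infinite(m$value[1]))
  expect_true(is.finite(m$value[2]))
  expect_error(pfold(net, 3, 2), "unreachable")
})

test_that("the profile barrier of a symmetric two-well chain sits at 1/2", {
  tw <- two_well_network(n = 8, intra = 0.2, inter = 0.004)
  p <- pfold(tw$net, folded = 8, unfolded = 1)
  # committor splits the wells
  expect_true(all(p$value[tw$wells == 1] < 0.5))
  expect_true(all(p$value[tw$wells == 2] > 0.5))
  prof <- cfep(tw$net, p)
  # barrier at the midpoint, within one cut position
  expect_equal(prof$barrier_cut, 4)
  expect_equal(prof$barrier_x, 0.5, tolerance = 1 / 8 + 1e-9)
  # the barrier cut separates exactly the two wells (the reference side
  # holds the folded well)
  A <- prof$order[seq_len(prof$barrier_cut)]
  expect_setequal(tw$wells[A], 2)
  # mfpt ranking finds the same barrier
  m <- mfpt(tw$net, 8)
  prof_m <- cfep(tw$net, m)
  expect_equal(prof_m$barrier_cut, 4)
})

test_that("deeper barriers raise the profile maximum", {
  shallow <- two_well_network(n = 8, intra = 0.2, inter = 0.02)
  deep <- two_well_network(n = 8, intra = 0.2, inter = 0.002)
  bs <- cfep(shallow$net, pfold(shallow$net, 8, 1))$barrier_dG
  bd <- cfep(deep$net, pfold(deep$net, 8, 1))$barrier_dG
  expect_gt(bd, bs)
})

test_that("the minimal-flux cut equals exhaustive cut enumeration", {
  tw <- two_well_network(n = 10, intra = 0.15, inter = 0.003)
  prof <- cfep(tw$net, pfold(tw$net, 10, 1))
  k_min <- which.min(prof$profile$z_ab)
  A_prof <- sort(prof$order[seq_len(k_min)])
  brute <- exhaustive_min_cut(tw$net$counts, ref = 10)
  expect_equal(A_prof, brute$A)
  expect_equal(min(prof$profile$z_ab), brute$flux, tolerance = 1e-9)
})

test_that("profiles are invariant under microstate relabelling", {
  tw <- two_well_network(n = 8, intra = 0.2, inter = 0.004)
  lab <- simulate_chain(tw$T, 40000, seed = 506)
  net1 <- transition_network(lab)
  perm <- c(5L, 3L, 8L, 1L, 7L, 2L, 6L, 4L)
  net2 <- transition_network(perm[lab])
  p1 <- cfep(net1, pfold(net1, 8, 1))
  p2 <- cfep(net2, pfold(net2, perm[8], perm[1]))
  expect_equal(p2$barrier_dG, p1$barrier_dG, tolerance = 1e-9)
  expect_equal(p2$barrier_x, p1$barrier_x, tolerance = 1e-9)
})

test_that("commitment probabilities follow the sliding-window definition", {
  lab <- rep(c(1L, 2L), 20)
  P <- commitment_matrix(lab, tau_commit = 1)
  expect_equal(P["1", "2"], 1)
  expect_equal(P["1", "1"], 1)    # zero-time commitment to itself
  # hand evaluation on a short scripted series
  lab2 <- c(1L, 3L, 1L, 2L, 1L, 1L, 3L, 2L, 3L, 1L)
  tau <- 2
  P2 <- commitment_matrix(lab2, tau_commit = tau)
  for (a in 1:3) for (b in 1:3) {
    if (a == b) next
    starts <- which(lab2 == a)
    hit <- vapply(starts, function(t0) {
      if (t0 >= 10) return(FALSE)
      any(lab2[(t0 + 1):min(t0 + tau, 10)] == b)
    }, logical(1))
    expect_equal(P2[as.character(a), as.character(b)], mean(hit))
  }
  expect_error(commitment_matrix(lab2, tau_commit = 10), "smaller")
})

test_that("two-well chains separate cleanly in commitment probability", {
  gen <- gen_markov_traj(10, rep(1:2, each = 5), intra_p = 0.1,
                         inter_p = 2e-4, n_steps = 2e5, seed = 507)
  P <- commitment_matrix(gen$labels, tau_commit = 100)
  wells <- gen$ground_truth$wells
  for (a in 1:10) for (b in 1:10) {
    if (a == b) next
    if (wells[a] == wells[b]) expect_gte(P[a, b], 0.5)
    else expect_lt(P[a, b], 0.5)
  }
})

test_that("kinetic grouping recovers the generating wells exactly", {
  gen2 <- gen_markov_traj(10, rep(1:2, each = 5), intra_p = 0.1,
                          inter_p = 2e-4, n_steps = 2e5, seed = 508)
  part2 <- kga(gen2$labels, tau_commit = 100, n_heavy = 10)
  expect_equal(partition_agreement(part2$basin,
                                   gen2$ground_truth$wells), 1)
  gen3 <- gen_markov_traj(12, rep(1:3, each = 4), intra_p = 0.1,
                          inter_p = 1e-4, n_steps = 4e5, seed = 509)
  part3 <- kga(gen3$labels, tau_commit = 100, n_heavy = 12)
  expect_equal(partition_agreement(part3$basin,
                                   gen3$ground_truth$wells), 1)
  # a long commitment time merges everything into one basin
  part_all <- kga(gen2$labels, tau_commit = 5e4, n_heavy = 10)
  expect_equal(length(unique(part_all$basin)), 1)
})

test_that("light and isolated states are assigned by the 0.5 rule", {
  gen <- gen_markov_traj(10, rep(1:2, each = 5), intra_p = 0.1,
                         inter_p = 2e-4, n_steps = 2e5, seed = 510)
  # heavy subset of 6: the remaining 4 states join via post-processing
  part <- kga(gen$labels, tau_commit = 100, n_heavy = 6)
  expect_equal(partition_agreement(part$basin,
                                   gen$ground_truth$wells), 1)
  expect_warning(kga(gen$labels, tau_commit = 100, n_heavy = 50),
                 "clamped")
  # a state visited once at the very end has no commitment statistics
  lab <- c(gen$labels[1:10000], 99L)
  part2 <- kga(lab, tau_commit = 100, n_heavy = 10)
  expect_true(is.na(part2$basin[part2$states == 99]))
  # single-basin mode around a representative state
  rep_part <- kga(gen$labels, tau_commit = 100,
                  representative = 1)
  in_basin <- which(!is.na(rep_part$basin))
  expect_setequal(rep_part$states[in_basin], 1:5)
})

test_that("first-passage-time distributions capture the timescales", {
  # deterministic period-4 cycle: a single spike at 4
  lab <- rep(1:4, 25)
  fp <- fpt_distribution(lab, target = 1)
  expect_equal(unique(fp$fpt), 4L)
  expect_equal(fp$n_starts, length(fp$fpt))
  expect_equal(sum(fp$histogram$count), fp$n_starts)
  expect_error(fpt_distribution(lab, target = 9), "never visited")
  # two-well chain: intra-basin returns are fast, inter-basin passages slow
  gen <- gen_markov_traj(10, rep(1:2, each = 5), intra_p = 0.1,
                         inter_p = 2e-4, n_steps = 2e5, seed = 511)
  fp1 <- fpt_distribution(gen$labels, target = 1)
  expect_lt(stats::median(fp1$fpt), 50)        # intra-well relaxation
  cross <- fpt_distribution(gen$labels, target = 6, from = 1)
  expect_gt(stats::median(cross$fpt), 500)     # inter-well passage
})
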