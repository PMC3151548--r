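# Protein structure networks: interaction strengths, hubs, clusters,
# critical interaction strength, trajectory statistics.

test_that("the ligand normalization factors are available verbatim", {
  nf <- nf_table()
  expect_equal(nf[["GTP"]], 274.78)
  expect_equal(nf[["GDP"]], 220.19)
  expect_equal(nf[["RET"]], 170.13)
  expect_equal(nf[["MG"]], 22.01)
  expect_equal(nf[["MG_GDP"]], 14.65)
  expect_length(nf[nf > 0], length(nf))
  # user extension and override
  nf2 <- nf_table(extra = c(XYZ = 100, GTP = 300))
  expect_equal(nf2[["XYZ"]], 100)
  expect_equal(nf2[["GTP"]], 300)
  expect_error(nf_table(extra = c(BAD = -1)), "positive")
  expect_error(nf_table(extra = 5), "named")
})

# two custom residues whose side chains have controlled contacts
two_node_structure <- function(n_pairs_within, sep = 30) {
  rows <- list(); s <- 0L
  add <- function(name, resname, resid, segid, p) {
    s <<- s + 1L
    rows[[s]] <<- data.frame(serial = s, name = name, resname = resname,
                             resid = resid, segid = segid, chain = segid,
                             insert = "", x = p[1], y = p[2], z = p[3],
                             mass = 12.011, bfactor = 10,
                             stringsAsFactors = FALSE)
  }
  # residue 1 (segment A): backbone + 3 side-chain atoms at the origin area
  add("CA", "XXX", 1L, "A", c(0, 0, 10))
  for (k in 1:3) add(paste0("C", k), "XXX", 1L, "A", c(k, 0, 0))
  # residue 2 (segment B): n_pairs_within of its atoms within 4.5 A of
  # residue 1 side-chain atom C1; the rest far away
  add("CA", "XXX", 1L, "B", c(0, 0, -10))
  stopifnot(n_pairs_within <= 3)
  for (k in seq_len(n_pairs_within)) add(paste0("D", k), "XXX", 1L, "B",
                                         c(1, 2, 0))
  for (k in seq_len(3 - n_pairs_within))
    add(paste0("E", k), "XXX", 1L, "B", c(sep, 0, 0))
  trajan:::new_structure(do.call(rbind, rows))
}

test_that("interaction strength matches hand evaluation and symmetry", {
  nf <- nf_table(extra = c(XXX = 100))
  st <- two_node_structure(3)
  # each of the 3 close atoms of B is within 4.5 A of all 3 side-chain
  # atoms of A at distance <= sqrt(2^2+2^2) -> count pairs by hand
  d <- function(p, q) sqrt(sum((p - q)^2))
  hand <- 0L
  for (k in 1:3) for (l in 1:3)
    hand <- hand + (d(c(k, 0, 0), c(1, 2, 0)) <= 4.5)
  I <- interaction_strength(st, 1, 2, nf = nf)
  expect_equal(I, 100 * hand / sqrt(100 * 100))
  expect_equal(interaction_strength(st, 2, 1, nf = nf), I)
  # residues far apart: zero contacts, zero strength
  st0 <- two_node_structure(0)
  expect_equal(interaction_strength(st0, 1, 2, nf = nf), 0)
  # unknown NF instructs the user how to supply one
  expect_error(interaction_strength(st, 1, 2), "nf_table")
})

test_that("hetero nodes use their printed normalization factors", {
  nf <- nf_table()
  st <- two_node_structure(3)
  st$atoms$resname[st$atoms$segid == "A"] <- "GTP"
  st$atoms$resname[st$atoms$segid == "B"] <- "ALA"
  st <- trajan:::new_structure(st$atoms)
  # GTP is a hetero node: all its atoms count (including CA);
  # check the NF entering the denominator is 274.78
  g <- build_psn(st, imin = 0, nf = nf)
  expect_equal(g$nf[1], 274.78)
  I <- interaction_strength(st, 1, 2, nf = nf)
  n_pairs <- g$counts[1, 2]
  expect_equal(I, 100 * n_pairs / sqrt(274.78 * nf[["ALA"]]))
})

test_that("PSN edges equal the exhaustive all-pairs oracle", {
  g <- gen_toy_structure(12, "helix", seed = 201)
  st <- g$structure
  for (imin in c(0, 1.0, 3.0)) {
    psn <- build_psn(st, imin = imin)
    # oracle: direct double loop over residues and side-chain atoms
    a <- st$atoms
    nf <- nf_table()
    expected <- list()
    for (i in 1:11) for (j in (i + 1):12) {
      if (abs(i - j) <= 2) next                 # same chain, excluded
      ai <- a[a$resid == i & a$name == "CB", ]
      aj <- a[a$resid == j & a$name == "CB", ]
      n_ij <- 0L
      for (p in seq_len(nrow(ai))) for (q in seq_len(nrow(aj))) {
        d <- sqrt((ai$x[p] - aj$x[q])^2 + (ai$y[p] - aj$y[q])^2 +
                    (ai$z[p] - aj$z[q])^2)
        if (d <= 4.5) n_ij <- n_ij + 1L
      }
      I <- 100 * n_ij / sqrt(nf[["ALA"]]^2)
      if (n_ij > 0 && I >= imin)
        expected[[length(expected) + 1]] <- c(i, j)
    }
    got <- unname(as.matrix(psn$edges[, c("i", "j")]))
    if (length(expected) == 0) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got, do.call(rbind, expected), ignore_attr = TRUE)
    }
  }
})

test_that("neighbour exclusion suppresses i +/- n within a chain only", {
  # residues 1 and 3 overlap: excluded at n = 2, present at n = 1
  cb <- rbind(c(0, 0, 0), c(50, 0, 0), c(1, 0, 0))
  st <- ca_structure(rbind(c(0, 0, 3), c(50, 0, 3), c(1, 0, 3)))
  st$atoms <- rbind(st$atoms,
                    transform(st$atoms, name = "CB", serial = serial + 3,
                              x = cb[, 1], y = cb[, 2], z = cb[, 3]))
  st <- trajan:::new_structure(st$atoms)
  g2 <- build_psn(st, imin = 0, n_exclusion = 2)
  expect_equal(nrow(g2$edges), 0)
  g1 <- build_psn(st, imin = 0, n_exclusion = 1)
  expect_equal(unname(as.matrix(g1$edges[, c("i", "j")])),
               matrix(c(1L, 3L), 1), ignore_attr = TRUE)
  # the same pair split across chains is always eligible
  st_b <- chain_of_segments(rbind(c(0, 0, 0), c(1, 0, 0)))
  gb <- build_psn(st_b, imin = 0)
  expect_equal(nrow(gb$edges), 1)
})

test_that("raising I_min is a monotone filtration", {
  g <- gen_toy_structure(15, "helix", seed = 202)
  psn0 <- build_psn(g$structure, imin = 0)
  grid <- seq(0, 5, by = 0.5)
  prev_edges <- NULL
  prev_largest <- Inf
  for (v in grid) {
    gv <- psn_at_imin(psn0, v)
    keys <- paste(gv$edges$i, gv$edges$j)
    if (!is.null(prev_edges)) expect_true(all(keys %in% prev_edges))
    prev_edges <- keys
    largest <- psn_clusterize(gv)$largest
    expect_lte(largest, prev_largest)
    prev_largest <- largest
  }
})

test_that("interaction strengths are invariant under rigid motion", {
  g <- gen_toy_structure(10, "helix", seed = 203)
  st <- g$structure
  xyz <- coords(st)
  th <- 0.9
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  st2 <- set_coords(st, xyz %*% t(R) + 5)
  p1 <- build_psn(st, imin = 0)
  p2 <- build_psn(st2, imin = 0)
  expect_equal(p1$strengths, p2$strengths, tolerance = 1e-9)
})

test_that("hubs follow the degree rule on star and ring graphs", {
  star <- toy_psn_graph(6, lapply(2:6, function(j) c(1L, j)))
  h <- find_hubs(star, hub_cutoff = 4)
  expect_true(h$hub[1])
  expect_false(any(h$hub[-1]))
  ring <- toy_psn_graph(6, lapply(1:6, function(i)
    c(i, if (i == 6) 1L else i + 1L)))
  expect_false(any(find_hubs(ring, hub_cutoff = 4)$hub))
  # inclusive vs strict threshold; hub set shrinks as the cutoff grows
  deg4 <- toy_psn_graph(5, lapply(2:5, function(j) c(1L, j)))
  expect_true(find_hubs(deg4, 4)$hub[1])
  expect_false(find_hubs(deg4, 4, strict = TRUE)$hub[1])
  h4 <- find_hubs(star, 4)$hub
  h5 <- find_hubs(star, 5)$hub
  expect_true(all(which(h5) %in% which(h4)))
})

test_that("hub interaction percentage matches hand evaluation", {
  g <- toy_psn_graph(4, list(c(1L, 2L), c(1L, 3L), c(1L, 4L)),
                     counts = c(2L, 3L, 1L))
  g$nf <- c(50, 100, 100, 100)
  h <- find_hubs(g, hub_cutoff = 2)
  expect_equal(h$hub_interaction[1], 100 * (2 + 3 + 1) / 50)
  expect_equal(h$hub_interaction[2], 100 * 2 / 100)
})

test_that("clusterization equals the union-find oracle", {
  expect_equal(psn_clusterize(toy_psn_graph(5, list()))$membership, 1:5)
  full <- toy_psn_graph(4, combn(4, 2, simplify = FALSE))
  expect_equal(psn_clusterize(full)$membership, rep(1L, 4))
  set.seed(204)
  for (rep in 1:5) {
    n <- 20
    m <- 15
    ij <- t(replicate(m, sort(sample.int(n, 2))))
    g <- toy_psn_graph(n, lapply(seq_len(m), function(r) as.integer(ij[r, ])))
    got <- psn_clusterize(g)$membership
    expect_equal(got, uf_components(n, ij[, 1], ij[, 2]))
  }
})

test_that("I_critic is recovered from a scripted halving fixture", {
  # chain 1-...-10; the bridge edge 5-6 has strength 2.2, all others 5.0:
  # the largest cluster is 10 up to I_min 2.0 and exactly 5 from 2.5 on
  edges <- lapply(1:9, function(i) c(i, i + 1L))
  strengths <- ifelse(seq_len(9) == 5, 2.2, 5.0)
  g <- toy_psn_graph(10, edges, strengths = strengths)
  res <- psn_icritic(g, seq(0, 5, by = 0.5))
  expect_equal(nrow(res$table), 11)   # the standard 11-value grid
  expect_true(res$reached)
  expect_equal(res$icritic, 2.5)
  # interpolation between bracketing grid points
  g2 <- toy_psn_graph(10, edges,
                      strengths = ifelse(seq_len(9) == 5, 2.25, 5.0))
  res2 <- psn_icritic(g2, seq(0, 5, by = 0.5))
  expect_equal(res2$icritic, 2.5)
  # never halving: flagged unreached at the grid end
  g3 <- toy_psn_graph(10, edges, strengths = rep(50, 9))
  res3 <- psn_icritic(g3, seq(0, 5, by = 0.5))
  expect_false(res3$reached)
  expect_match(res3$message, "I_critic > 5")
  expect_error(psn_icritic(g, c(1, 2)), "include 0")
})

test_that("ensemble statistics follow the frame-frequency definitions", {
  g <- gen_toy_structure(10, "helix", seed = 205)
  st <- g$structure
  m <- coords(st)
  # 4 frames: identical geometry -> every edge frequency is 1.0
  traj <- trajectory_from_frames(list(m, m, m, m))
  ens <- psn_ensemble(traj, st, imin = 0, hub_cutoff = 3)
  expect_true(all(ens$edge_freq$frequency == 1.0))
  single <- build_psn(st, imin = 0)
  expect_equal(nrow(ens$edge_freq), nrow(single$edges))
  hubs1 <- find_hubs(single, 3)$hub
  expect_equal(sort(ens$stable_hubs), which(hubs1))
})

test_that("hub stability and hub correlation follow the indicator rules", {
  # scripted indicator matrix: 10 frames x 4 nodes
  ind <- cbind(rep(c(TRUE, FALSE), 5),        # hub in 5/10 -> not stable
               rep(TRUE, 10),                 # always hub  -> stable
               c(rep(TRUE, 6), rep(FALSE, 4)),# 6/10        -> stable
               rep(FALSE, 10))
  freq <- colMeans(ind)
  expect_equal(which(freq > 0.5), c(2L, 3L), ignore_attr = TRUE)
  pairs <- trajan:::hub_correlation_pairs(ind, 0.5, "joint")
  # brute-force pair scan
  expected <- list()
  for (i in 1:3) for (j in (i + 1):4) {
    frac <- mean(ind[, i] & ind[, j])
    if (frac > 0.5) expected[[length(expected) + 1]] <- c(i, j, frac)
  }
  expected <- do.call(rbind, expected)
  expect_equal(unname(as.matrix(pairs)), expected, ignore_attr = TRUE)
  # matching-state mode counts agreements instead
  pairs_m <- trajan:::hub_correlation_pairs(ind, 0.5, "matching")
  expect_true(all(pairs_m$fraction ==
                    vapply(seq_len(nrow(pairs_m)), function(r)
                      mean(ind[, pairs_m$i[r]] == ind[, pairs_m$j[r]]),
                      numeric(1))))
})
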