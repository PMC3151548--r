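# Conformational clustering of trajectory frames.
#
# Metrics: RMSD (optionally after optimal least-squares superposition) and
# DRMS (root-mean-square difference of the intra-frame pairwise distance
# matrices; superposition-free).  Algorithms: leader-like (fast,
# order-dependent, three comparison modalities), hierarchical
# (average-linkage agglomerative, cut at the threshold), and QT-like
# (threshold = cluster radius around the centre frame).  A two-pass scheme
# refines a subset clustering over all frames, and the frame-frame distance
# matrix can be saved for reuse.

#' Distance between two conformations
#'
#' @param a,b N x 3 coordinate matrices (equal N)
#' @param metric `"rmsd"` or `"drms"`
#' @param superpose superpose `b` onto `a` before RMSD (default `TRUE`;
#'   ignored for DRMS, which needs none)
#' @return distance in Angstrom
#' @export
frame_distance <- function(a, b, metric = c("rmsd", "drms"),
                           superpose = TRUE) {
  metric <- match.arg(metric)
  if (!all(dim(a) == dim(b)))
    stop("selections of unequal size: ", nrow(a), " vs ", nrow(b), " atoms")
  if (metric == "rmsd") {
    va <- as.vector(t(a)); vb <- as.vector(t(b))
    if (superpose)
      as.numeric(bio3d::rmsd(va, vb, fit = TRUE))
    else
      sqrt(mean(rowSums((a - b)^2)))
  } else {
    da <- stats::dist(a); db <- stats::dist(b)
    sqrt(mean((da - db)^2))
  }
}

traj_frame <- function(traj, i, sel = NULL) frame_coords(traj, i, sel)

#' Frame-frame distance matrix of a trajectory
#'
#' @param traj a `trj_trajectory`
#' @param metric,superpose see [frame_distance()]
#' @param sel optional atom indices
#' @return a `frame_dmat`: symmetric F x F matrix with metric metadata
#' @export
distance_matrix <- function(traj, metric = c("rmsd", "drms"),
                            superpose = TRUE, sel = NULL) {
  metric <- match.arg(metric)
  F <- traj$nframes
  frames <- lapply(seq_len(F), function(i) traj_frame(traj, i, sel))
  if (metric == "drms")
    dms <- lapply(frames, function(m) as.vector(stats::dist(m)))
  D <- matrix(0, F, F)
  for (i in seq_len(F - 1)) for (j in (i + 1):F) {
    D[i, j] <- D[j, i] <- if (metric == "drms")
      sqrt(mean((dms[[i]] - dms[[j]])^2))
    else frame_distance(frames[[i]], frames[[j]], "rmsd", superpose)
  }
  attr(D, "metric") <- metric
  attr(D, "superpose") <- superpose && metric == "rmsd"
  attr(D, "selection") <- if (is.null(sel)) "all" else
    paste(sel, collapse = ",")
  class(D) <- c("frame_dmat", "matrix")
  D
}

new_assignment <- function(cluster, centers, algorithm, parameters) {
  stopifnot(all(cluster >= 1 | is.na(cluster)))
  out <- list(cluster = cluster, centers = centers,
              n_clusters = length(centers), algorithm = algorithm,
              parameters = parameters)
  class(out) <- "cluster_assignment"
  out
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %s: %d frames -> %d clusters\n",
              x$algorithm, length(x$cluster), x$n_clusters))
  invisible(x)
}

#' Summary table of a clustering
#' @param object a `cluster_assignment`
#' @param ... unused
#' @return data.frame with cluster id, size, center frame
#' @export
summary.cluster_assignment <- function(object, ...) {
  ids <- seq_len(object$n_clusters)
  data.frame(cluster = ids,
             size = vapply(ids, function(k)
               sum(object$cluster == k, na.rm = TRUE), integer(1)),
             center = object$centers)
}

# Distance of frame i to frame j under a closure built once per run.
make_fdist <- function(traj, metric, superpose, sel) {
  frames <- lapply(seq_len(traj$nframes),
                   function(i) traj_frame(traj, i, sel))
  if (metric == "drms") {
    dms <- lapply(frames, function(m) as.vector(stats::dist(m)))
    function(i, j) sqrt(mean((dms[[i]] - dms[[j]])^2))
  } else {
    function(i, j) frame_distance(frames[[i]], frames[[j]], "rmsd",
                                  superpose)
  }
}

#' Leader-like clustering
#'
#' Frames are scanned in order; a frame joins an existing cluster when its
#' centre lies within the threshold, else it founds a new cluster (and
#' becomes its centre).  Modalities: `"nearest"` (compare with all centres,
#' join the closest within threshold; default), `"first"` (join the first
#' centre within threshold), `"backward"` (scan clusters starting from the
#' one holding frame n-1, then n-2, ..., stop at the first centre within
#' threshold — fast on time-correlated, non-Markovian frame sets).
#'
#' @param traj a `trj_trajectory`
#' @param threshold cluster radius, Angstrom (`>= 0`)
#' @param modality `"nearest"`, `"first"` or `"backward"`
#' @param metric,superpose,sel see [frame_distance()]
#' @return a `cluster_assignment`
#' @export
cluster_leader <- function(traj, threshold,
                           modality = c("nearest", "first", "backward"),
                           metric = c("rmsd", "drms"), superpose = TRUE,
                           sel = NULL) {
  modality <- match.arg(modality)
  metric <- match.arg(metric)
  if (threshold < 0) stop("threshold must be >= 0")
  F <- traj$nframes
  fd <- make_fdist(traj, metric, superpose, sel)
  centers <- integer(0)
  assign <- integer(F)
  for (f in seq_len(F)) {
    hit <- NA_integer_
    if (length(centers) > 0) {
      if (modality == "nearest") {
        d <- vapply(centers, function(c) fd(f, c), numeric(1))
        if (min(d) <= threshold) hit <- which.min(d)
      } else if (modality == "first") {
        for (k in seq_along(centers)) {
          if (fd(f, centers[k]) <= threshold) { hit <- k; break }
        }
      } else {
        # backward: visit clusters in order of most recent occupancy
        order_k <- unique(rev(assign[seq_len(f - 1)]))
        order_k <- c(order_k, setdiff(seq_along(centers), order_k))
        for (k in order_k) {
          if (fd(f, centers[k]) <= threshold) { hit <- k; break }
        }
      }
    }
    if (is.na(hit)) {
      centers <- c(centers, f)
      assign[f] <- length(centers)
    } else {
      assign[f] <- hit
    }
  }
  new_assignment(assign, centers, paste0("leader-", modality),
                 list(threshold = threshold, metric = metric,
                      superpose = superpose))
}

#' QT-like clustering
#'
#' For every unassigned frame a candidate cluster is formed from all
#' unassigned frames within the threshold of it (the threshold is the
#' cluster *radius*, measured to the centre frame).  The largest candidate
#' is taken (ties: the candidate with the lowest centre frame index), its
#' members removed, and the procedure repeats until all frames are
#' assigned.
#'
#' @inheritParams cluster_leader
#' @param dmat optional precomputed `frame_dmat` (overrides `traj` metric
#'   arguments)
#' @return a `cluster_assignment`
#' @export
cluster_qt <- function(traj = NULL, threshold, metric = c("rmsd", "drms"),
                       superpose = TRUE, sel = NULL, dmat = NULL) {
  metric <- match.arg(metric)
  D <- if (!is.null(dmat)) unclass(dmat) else
    unclass(distance_matrix(traj, metric, superpose, sel))
  F <- nrow(D)
  remaining <- rep(TRUE, F)
  assign <- integer(F)
  centers <- integer(0)
  while (any(remaining)) {
    cand_sizes <- integer(F)
    idx <- which(remaining)
    for (c in idx)
      cand_sizes[c] <- sum(D[c, idx] <= threshold)
    best <- idx[which.max(cand_sizes[idx])]  # which.max: lowest index wins
    members <- idx[D[best, idx] <= threshold]
    centers <- c(centers, best)
    assign[members] <- length(centers)
    remaining[members] <- FALSE
  }
  new_assignment(assign, centers, "qt-like",
                 list(threshold = threshold,
                      metric = attr(dmat, "metric") %||% metric))
}

#' Hierarchical (average-linkage) clustering
#'
#' Agglomerative merging continues while the average inter-cluster distance
#' stays within the threshold; the dendrogram is cut at the threshold
#' height.  Cluster centres are the medoid frames.  The result does not
#' depend on the frame order.
#'
#' @param dmat a `frame_dmat` (or plain symmetric matrix)
#' @param threshold cut height, Angstrom
#' @return a `cluster_assignment`
#' @export
cluster_hierarchical <- function(dmat, threshold) {
  D <- unclass(dmat)
  if (!is.matrix(D) || nrow(D) != ncol(D) ||
      !isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix must be square and symmetric")
  F <- nrow(D)
  if (F == 1) return(new_assignment(1L, 1L, "hierarchical",
                                    list(threshold = threshold,
                                         linkage = "average")))
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  memb <- stats::cutree(hc, h = threshold)
  # renumber clusters by smallest member frame; medoid centres
  first <- tapply(seq_len(F), memb, min)
  relab <- match(memb, memb[sort(first)])
  centers <- vapply(seq_len(max(relab)), function(k) {
    m <- which(relab == k)
    m[which.min(colSums(D[m, m, drop = FALSE]))]
  }, integer(1))
  new_assignment(as.integer(relab), centers, "hierarchical",
                 list(threshold = threshold, linkage = "average"))
}

#' Two-pass clustering
#'
#' Pass 1 clusters the frame subset `seq(1, F, by = subset_stride)` with the
#' chosen algorithm.  Pass 2 scans every frame in order and assigns it to
#' the nearest pass-1 centre within the threshold; a frame farther than the
#' threshold from every existing centre founds a new cluster whose centre is
#' immediately available to later frames.
#'
#' @param traj a `trj_trajectory`
#' @param subset_stride stride for the pass-1 subset (must be `< F`)
#' @param algorithm `"leader"`, `"qt"` or `"hierarchical"`
#' @param threshold cluster radius, Angstrom
#' @param metric,superpose,sel see [frame_distance()]
#' @param modality leader modality for pass 1
#' @return a `cluster_assignment` over all frames
#' @export
cluster_two_pass <- function(traj, subset_stride, algorithm = "qt",
                             threshold, metric = c("rmsd", "drms"),
                             superpose = TRUE, sel = NULL,
                             modality = "nearest") {
  metric <- match.arg(metric)
  F <- traj$nframes
  if (subset_stride >= F) stop("subset stride must be smaller than the ",
                               "frame count")
  sub <- seq(1, F, by = subset_stride)
  sub_xyz <- traj$xyz[sub, , drop = FALSE]
  sub_traj <- new_trajectory(sub_xyz, traj$stride)
  pass1 <- switch(algorithm,
    leader = cluster_leader(sub_traj, threshold, modality, metric,
                            superpose, sel),
    qt = cluster_qt(sub_traj, threshold, metric, superpose, sel),
    hierarchical = cluster_hierarchical(
      distance_matrix(sub_traj, metric, superpose, sel), threshold),
    stop("unknown algorithm: ", algorithm))
  centers <- sub[pass1$centers]   # centre frames in full-trajectory indices
  fd <- make_fdist(traj, metric, superpose, sel)
  assign <- integer(F)
  for (f in seq_len(F)) {
    d <- vapply(centers, function(c) fd(f, c), numeric(1))
    if (min(d) <= threshold) {
      assign[f] <- which.min(d)
    } else {
      centers <- c(centers, f)    # isolated frame founds a new cluster
      assign[f] <- length(centers)
    }
  }
  new_assignment(assign, centers, paste0("two-pass-", algorithm),
                 list(threshold = threshold, metric = metric,
                      subset_stride = subset_stride))
}

#' Save a frame distance matrix
#'
#' Plain-text header (metric, superposition, selection, frame count)
#' followed by the upper triangle as binary doubles; the round trip is
#' bit-stable.
#'
#' @param dmat a `frame_dmat`
#' @param path output path
#' @return `path`, invisibly
#' @export
save_distance_matrix <- function(dmat, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- sprintf("TRAJAN-DMAT v1 metric=%s superpose=%s selection=%s n=%d\n",
                 attr(dmat, "metric"),
                 tolower(as.character(attr(dmat, "superpose"))),
                 attr(dmat, "selection"), nrow(dmat))
  writeChar(hdr, con, eos = NULL)
  writeBin(unclass(dmat)[upper.tri(dmat)], con, size = 8,
           endian = "little")
  invisible(path)
}

#' Load a saved frame distance matrix
#'
#' @param path file written by [save_distance_matrix()]
#' @param expect_metric,expect_superpose,expect_selection optional checks;
#'   a mismatch with the stored header is an error (refusing silent reuse
#'   of a matrix computed under different settings)
#' @return a `frame_dmat`
#' @export
load_distance_matrix <- function(path, expect_metric = NULL,
                                 expect_superpose = NULL,
                                 expect_selection = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (length(ch) == 0) stop("distance-matrix file truncated in header")
    if (ch == "\n") break
    hdr <- c(hdr, ch)
  }
  hdr <- paste(hdr, collapse = "")
  m <- regexec(
    "^TRAJAN-DMAT v1 metric=(\\S+) superpose=(\\S+) selection=(\\S+) n=(\\d+)$",
    hdr)
  parts <- regmatches(hdr, m)[[1]]
  if (length(parts) != 5) stop("bad distance-matrix header: ", hdr)
  metric <- parts[2]; superpose <- parts[3] == "true"
  selection <- parts[4]; F <- as.integer(parts[5])
  if (!metric %in% c("rmsd", "drms"))
    stop("bad distance-matrix header: unknown metric '", metric, "'")
  if (!is.null(expect_metric) && expect_metric != metric)
    stop("distance-matrix header mismatch: file holds metric '", metric,
         "', expected '", expect_metric, "'")
  if (!is.null(expect_superpose) && expect_superpose != superpose)
    stop("distance-matrix header mismatch: superposition flag differs")
  if (!is.null(expect_selection) && expect_selection != selection)
    stop("distance-matrix header mismatch: selection differs")
  ntri <- F * (F - 1) / 2
  v <- readBin(con, "numeric", ntri, size = 8, endian = "little")
  if (length(v) != ntri) stop("distance-matrix file truncated")
  D <- matrix(0, F, F)
  D[upper.tri(D)] <- v
  D <- D + t(D)
  attr(D, "metric") <- metric
  attr(D, "superpose") <- superpose
  attr(D, "selection") <- selection
  class(D) <- c("frame_dmat", "matrix")
  D
}
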