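#' @keywords internal
"_PACKAGE"

# Internal constructor for the structure container.  Atoms are stored as a
# data.frame in file order; the residue table is built from the ordered
# unique (segid, resid, insert) keys.  Chain ID falls back to segid when
# segid is blank and vice versa, so either PDB dialect resolves.
new_structure <- function(atoms, trajectory = NULL) {
  stopifnot(is.data.frame(atoms))
  needed <- c("serial", "name", "resname", "resid", "segid", "chain",
              "insert", "x", "y", "z", "mass", "bfactor")
  miss <- setdiff(needed, names(atoms))
  if (length(miss) > 0) stop("atom table missing columns: ",
                             paste(miss, collapse = ", "))
  if (any(!is.finite(atoms$x)) || any(!is.finite(atoms$y)) ||
      any(!is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop("atom masses must be positive")
  key <- residue_key(atoms)
  ukey <- unique(key)
  res_first <- match(ukey, key)
  res <- data.frame(
    key     = ukey,
    segid   = atoms$segid[res_first],
    chain   = atoms$chain[res_first],
    resid   = atoms$resid[res_first],
    insert  = atoms$insert[res_first],
    resname = atoms$resname[res_first],
    stringsAsFactors = FALSE
  )
  res$ca <- vapply(seq_len(nrow(res)), function(i) {
    idx <- which(key == ukey[i] & atoms$name == "CA")
    if (length(idx) >= 1) idx[1] else NA_integer_
  }, integer(1))
  x <- list(atoms = atoms, residues = res, residue_of = match(key, ukey),
            trajectory = trajectory)
  class(x) <- "trj_structure"
  x
}

# Residue identity key: (segid, resid, insertion code); blank segid falls
# back to chain so PDB files without SEGID still separate their chains.
residue_key <- function(atoms) {
  seg <- ifelse(is.na(atoms$segid) | atoms$segid == "",
                ifelse(is.na(atoms$chain) | atoms$chain == "", "_",
                       atoms$chain),
                atoms$segid)
  paste(seg, atoms$resid, ifelse(is.na(atoms$insert), "", atoms$insert),
        sep = "|")
}

# Effective segment label per atom (chain fallback applied).
atom_seg <- function(atoms) {
  ifelse(is.na(atoms$segid) | atoms$segid == "",
         ifelse(is.na(atoms$chain) | atoms$chain == "", "_", atoms$chain),
         atoms$segid)
}

#' Number of atoms in a structure
#' @param x a `trj_structure`
#' @return integer atom count
#' @export
natoms <- function(x) nrow(x$atoms)

#' Number of residues in a structure
#' @param x a `trj_structure`
#' @return integer residue count
#' @export
nresidues <- function(x) nrow(x$residues)

#' Coordinates of a structure as an N x 3 matrix (Angstrom)
#' @param x a `trj_structure`
#' @param sel optional [select_atoms()] result or integer atom indices
#' @return numeric matrix with columns x, y, z
#' @export
coords <- function(x, sel = NULL) {
  idx <- resolve_indices(x, sel)
  m <- cbind(x = x$atoms$x[idx], y = x$atoms$y[idx], z = x$atoms$z[idx])
  m
}

resolve_indices <- function(x, sel) {
  if (is.null(sel)) return(seq_len(natoms(x)))
  if (inherits(sel, "trj_selection")) return(sel$indices)
  if (is.character(sel)) return(select_atoms(x, sel)$indices)
  as.integer(sel)
}

#' @export
print.trj_structure <- function(x, ...) {
  cat(sprintf("<trj_structure> %d atoms, %d residues", natoms(x),
              nresidues(x)))
  if (!is.null(x$trajectory))
    cat(sprintf(", %d models", x$trajectory$nframes))
  cat("\n")
  invisible(x)
}

# --- trajectory container ---------------------------------------------------

# Coordinates are stored bio3d-style: one row per frame, 3N columns ordered
# (x1, y1, z1, x2, ...).  Angstrom throughout.
new_trajectory <- function(xyz, stride = 1L) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 1) stop("trajectory needs at least one frame")
  if (ncol(xyz) %% 3 != 0) stop("coordinate matrix must have 3N columns")
  t <- list(xyz = xyz, nframes = nrow(xyz), natoms = ncol(xyz) %/% 3L,
            stride = stride)
  class(t) <- "trj_trajectory"
  t
}

#' Extract one frame of a trajectory as an N x 3 coordinate matrix
#' @param traj a `trj_trajectory`
#' @param i frame index (1-based)
#' @param sel optional atom indices
#' @return N x 3 numeric matrix
#' @export
frame_coords <- function(traj, i, sel = NULL) {
  if (i < 1 || i > traj$nframes) stop("frame index out of range")
  v <- traj$xyz[i, ]
  m <- matrix(v, ncol = 3, byrow = TRUE)
  colnames(m) <- c("x", "y", "z")
  if (!is.null(sel)) {
    if (inherits(sel, "trj_selection")) sel <- sel$indices
    m <- m[sel, , drop = FALSE]
  }
  m
}

#' Build a trajectory from a stack of coordinate matrices
#' @param frames list of N x 3 matrices (equal N)
#' @param stride frame saving stride metadata
#' @return a `trj_trajectory`
#' @export
trajectory_from_frames <- function(frames, stride = 1L) {
  n <- unique(vapply(frames, nrow, integer(1)))
  if (length(n) != 1) stop("all frames must have the same atom count")
  xyz <- do.call(rbind, lapply(frames, function(m) as.vector(t(m))))
  new_trajectory(xyz, stride)
}

#' Replace the coordinates of a structure
#' @param x a `trj_structure`
#' @param m N x 3 matrix
#' @return modified structure
#' @export
set_coords <- function(x, m) {
  stopifnot(nrow(m) == natoms(x))
  x$atoms$x <- m[, 1]; x$atoms$y <- m[, 2]; x$atoms$z <- m[, 3]
  x
}

#' @export
print.trj_trajectory <- function(x, ...) {
  cat(sprintf("<trj_trajectory> %d frames x %d atoms (stride %d)\n",
              x$nframes, x$natoms, x$stride))
  invisible(x)
}
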