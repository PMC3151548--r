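# PDB reading/writing.  Parsing and formatting of the fixed-width records is
# delegated to bio3d; a pre-scan validates the coordinate fields so that a
# malformed line is reported with its line number instead of surfacing as an
# obscure downstream NA.

#' Read a PDB file
#'
#' Reads ATOM/HETATM records into a structure container.  Multi-model files
#' additionally yield a trajectory (one frame per MODEL) attached as
#' `$trajectory`; the atom table holds the first model's coordinates.
#' B-factors are retained (column `bfactor`).  Masses missing from the file
#' (always, for PDB) are inferred from the element implied by the atom name.
#'
#' @param path path to a PDB file
#' @return a `trj_structure`
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  for (ln in which(is_atom)) {
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      s <- substr(lines[ln], fld[1], fld[2])
      if (is.na(suppressWarnings(as.numeric(s))))
        stop(sprintf("malformed coordinate field at line %d: '%s'", ln, s))
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  atoms <- data.frame(
    serial  = as.integer(a$eleno),
    name    = a$elety,
    resname = a$resid,
    resid   = as.integer(a$resno),
    segid   = ifelse(is.na(a$segid), "", a$segid),
    chain   = ifelse(is.na(a$chain), "", a$chain),
    insert  = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    mass    = atom_masses(a$elety, a$resid),
    bfactor = ifelse(is.na(a$b), 0, a$b),
    stringsAsFactors = FALSE
  )
  traj <- NULL
  if (is.matrix(pdb$xyz) && nrow(pdb$xyz) > 1)
    traj <- new_trajectory(unclass(pdb$xyz))
  new_structure(atoms, trajectory = traj)
}

#' Write a structure (or trajectory) to a PDB file
#'
#' @param x a `trj_structure`
#' @param path output path
#' @param traj optional `trj_trajectory`; when given, one MODEL per frame
#' @param bfactor optional numeric vector overriding the B-factor column
#'   (e.g. perturbation responses)
#' @return `path`, invisibly
#' @export
write_pdb <- function(x, path, traj = NULL, bfactor = NULL) {
  a <- x$atoms
  b <- if (is.null(bfactor)) a$bfactor else rep_len(bfactor, nrow(a))
  xyz <- if (is.null(traj)) as.vector(t(cbind(a$x, a$y, a$z))) else traj$xyz
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = a$resid, resid = a$resname, eleno = a$serial,
                   elety = a$name, chain = ifelse(a$chain == "", " ", a$chain),
                   insert = ifelse(a$insert == "", "", a$insert),
                   o = rep(1, nrow(a)), b = b, segid = a$segid)
  invisible(path)
}

# Mass lookup: element inferred from the atom name per PDB convention
# (strip digits/primes; two-letter element names only for common hetero
# species), standard atomic weights.
.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06, P = 30.974, F = 18.998, MG = 24.305,
                     FE = 55.845, ZN = 65.38, MN = 54.938, NA. = 22.99,
                     K = 39.098, CL = 35.45, BR = 79.904, I = 126.9,
                     CU = 63.546)

atom_masses <- function(name, resname) {
  nm <- toupper(gsub("[0-9'\"*]", "", name))
  vapply(seq_along(nm), function(i) {
    n <- nm[i]
    # Monatomic ions / metals keep their full name (MG, ZN, FE, NA, CL ...)
    two <- if (n == "NA") "NA." else n
    if (nchar(n) >= 2 && two %in% names(.element_masses) &&
        toupper(resname[i]) %in% c(n, "HOH", "ION"))
      return(unname(.element_masses[two]))
    first <- substr(n, 1, 1)
    if (first %in% names(.element_masses))
      return(unname(.element_masses[first]))
    12.011
  }, numeric(1))
}
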