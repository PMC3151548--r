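# CHARMM/X-PLOR binary DCD trajectories.
#
# Layout: Fortran unformatted records, each bracketed by 4-byte length
# markers.  Record 1: "CORD" + 20 int32 control words (ICNTRL); record 2:
# title lines; record 3: atom count; then per frame an optional 56-byte
# unit-cell record followed by the x, y and z coordinate records (float32
# each).  Endianness is auto-detected from the first length marker, which
# must read 84 in the file's native byte order.  Fixed-atom files
# (ICNTRL[9] > 0) store partial frames and are rejected explicitly.

#' Read a CHARMM/X-PLOR binary DCD trajectory
#'
#' Both little- and big-endian files are accepted transparently.  Files
#' written with a fixed-atom list are not supported and raise an error.
#'
#' @param path path to a DCD file
#' @return a `trj_trajectory`
#' @export
read_dcd <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (length(first) == 0) stop("DCD format error: empty file")
  endian <- if (first == 84L) "little" else {
    swapped <- readBin(writeBin(first, raw(), size = 4, endian = "little"),
                       "integer", 1, size = 4, endian = "big")
    if (swapped == 84L) "big" else
      stop("DCD format error: bad header record length (not a DCD file?)")
  }
  rint <- function(n) readBin(con, "integer", n, size = 4, endian = endian)
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (hdr != "CORD") stop("DCD format error: missing CORD magic")
  icntrl <- rint(20)
  if (rint(1) != 84L) stop("DCD format error: unbalanced header record")
  nframes_hdr <- icntrl[1]
  nfixed <- icntrl[9]
  has_cell <- icntrl[11] == 1L
  if (nfixed > 0)
    stop("unsupported feature: DCD with fixed atoms (", nfixed, " fixed)")
  # title record
  tlen <- rint(1)
  readBin(con, "raw", tlen)
  if (rint(1) != tlen) stop("DCD format error: unbalanced title record")
  # natom record
  if (rint(1) != 4L) stop("DCD format error: bad natom record")
  natom <- rint(1)
  if (rint(1) != 4L) stop("DCD format error: unbalanced natom record")
  frames <- list()
  repeat {
    if (has_cell) {
      m <- rint(1)
      if (length(m) == 0) break
      if (m != 48L) stop("DCD format error: bad unit-cell record")
      readBin(con, "raw", 48)
      if (rint(1) != 48L) stop("DCD format error: unbalanced cell record")
    }
    xyz <- matrix(NA_real_, natom, 3)
    started <- FALSE
    ok <- TRUE
    for (k in 1:3) {
      m <- rint(1)
      if (length(m) == 0) { ok <- FALSE; break }
      started <- TRUE
      if (m != 4L * natom)
        stop("DCD format error: frame record size mismatch (",
             m, " bytes, expected ", 4L * natom, ")")
      v <- readBin(con, "numeric", natom, size = 4, endian = endian)
      if (length(v) < natom)
        stop("DCD format error: truncated frame (file ends mid-record)")
      if (length(rint(1)) == 0)
        stop("DCD format error: truncated frame (missing record marker)")
      xyz[, k] <- v
    }
    if (!ok) {
      if (started) stop("DCD format error: truncated frame")
      break
    }
    frames[[length(frames) + 1L]] <- xyz
  }
  if (length(frames) == 0) stop("DCD format error: no frames")
  if (nframes_hdr > 0 && length(frames) != nframes_hdr)
    stop("DCD format error: header promises ", nframes_hdr,
         " frames, file holds ", length(frames))
  trajectory_from_frames(frames, stride = max(1L, icntrl[3]))
}

#' Write a trajectory as a CHARMM binary DCD file
#'
#' @param traj a `trj_trajectory`
#' @param path output path
#' @param endian byte order to write, `"little"` (default) or `"big"`
#' @return `path`, invisibly
#' @export
write_dcd <- function(traj, path, endian = c("little", "big")) {
  endian <- match.arg(endian)
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4, endian = endian)
  icntrl <- integer(20)
  icntrl[1] <- traj$nframes
  icntrl[2] <- 1L                      # first step
  icntrl[3] <- traj$stride             # save frequency
  icntrl[4] <- traj$nframes * traj$stride
  icntrl[20] <- 24L                    # CHARMM version stamp
  wint(84L)
  writeChar("CORD", con, 4, eos = NULL)
  wint(icntrl)
  wint(84L)
  title <- sprintf("%-80s", "Created by trajan write_dcd")
  wint(4L + 80L)
  wint(1L)
  writeChar(title, con, 80, eos = NULL)
  wint(4L + 80L)
  wint(4L); wint(traj$natoms); wint(4L)
  nb <- 4L * traj$natoms
  for (i in seq_len(traj$nframes)) {
    m <- frame_coords(traj, i)
    for (k in 1:3) {
      wint(nb)
      writeBin(as.numeric(m[, k]), con, size = 4, endian = endian)
      wint(nb)
    }
  }
  invisible(path)
}
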