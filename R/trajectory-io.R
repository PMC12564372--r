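# Structures and trajectories.
#
# Interchange format is (multi-model) PDB: desk-scale, text, readable by any
# structural-biology toolchain. Reading goes through bio3d; the multi-model
# writer is implemented here and round-trips through bio3d in the tests.
# Internal container: atoms (shared topology) + an n_frames x 3N coordinate
# matrix, Angstrom, plus a time stamp per frame in ns.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Construct a trajectory object
#'
#' @param atoms data frame with columns `elety` (atom name), `resid`
#'   (three-letter residue name), `chain`, `resno` (1-based residue index)
#'   and optionally `elesy` (element, inferred from the atom name when
#'   absent).
#' @param xyz numeric matrix, `n_frames` x `3 * n_atoms`, coordinates in
#'   Angstrom ordered x1,y1,z1,x2,...; a plain vector is taken as one frame.
#' @param time numeric vector of frame times in ns (default `0, 1, 2, ...`).
#' @return object of class `md_traj`.
#' @export
md_traj <- function(atoms, xyz, time = NULL) {
  stopifnot(is.data.frame(atoms),
            all(c("elety", "resid", "chain", "resno") %in% names(atoms)))
  if (is.null(atoms$elesy)) {
    atoms$elesy <- substr(gsub("[0-9]", "", atoms$elety), 1L, 1L)
  }
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  stopifnot(ncol(xyz) == 3L * nrow(atoms), nrow(xyz) >= 1L,
            all(is.finite(xyz)))
  if (is.null(time)) time <- seq_len(nrow(xyz)) - 1
  stopifnot(length(time) == nrow(xyz))
  structure(list(atoms = atoms, xyz = xyz, time = as.numeric(time)),
            class = "md_traj")
}

#' @export
print.md_traj <- function(x, ...) {
  cat("<md_traj> ", n_frames(x), " frame(s), ", nrow(x$atoms), " atoms, ",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), " residues\n",
      sep = "")
  invisible(x)
}

#' Trajectory accessors
#'
#' `n_frames` counts frames; `get_frame` extracts one frame as a one-frame
#' `md_traj`; `frame_coords` returns a frame's coordinates as an
#' `n_atoms` x 3 matrix.
#'
#' @param traj an `md_traj`.
#' @param i frame index.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' @rdname n_frames
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  md_traj(traj$atoms, traj$xyz[i, , drop = FALSE], traj$time[i])
}

#' @rdname n_frames
#' @export
frame_coords <- function(traj, i = 1L) {
  matrix(traj$xyz[i, ], ncol = 3L, byrow = TRUE)
}

set_frame_coords <- function(traj, i, coords) {
  traj$xyz[i, ] <- as.numeric(t(coords))
  traj
}

#' Select atom indices
#'
#' @param traj an `md_traj`.
#' @param selection `"backbone"` (N, CA, C, O), `"calpha"`, `"heavy"`
#'   (non-hydrogen), `"all"`, or a character vector of atom names.
#' @param resno optional residue indices to restrict to.
#' @param chain optional chain to restrict to.
#' @return integer atom indices.
#' @export
select_atoms <- function(traj, selection = "backbone", resno = NULL,
                         chain = NULL) {
  a <- traj$atoms
  idx <- switch(selection[1L],
    backbone = which(a$elety %in% BACKBONE_ATOMS),
    calpha = which(a$elety == "CA"),
    heavy = which(a$elesy != "H"),
    all = seq_len(nrow(a)),
    which(a$elety %in% selection)
  )
  if (!is.null(resno)) idx <- idx[a$resno[idx] %in% resno]
  if (!is.null(chain)) idx <- idx[a$chain[idx] %in% chain]
  idx
}

xyz_index <- function(atom_idx) {
  as.vector(rbind(3L * atom_idx - 2L, 3L * atom_idx - 1L, 3L * atom_idx))
}

#' Read a (multi-model) PDB file as a trajectory
#'
#' Wraps `bio3d::read.pdb(multi = TRUE)`: every MODEL becomes a frame.
#' Insertion codes are not supported and are rejected.
#'
#' @param path PDB file path.
#' @param time optional frame times in ns.
#' @return an `md_traj`.
#' @export
read_pdb_traj <- function(path, time = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (any(!is.na(at$insert) & nzchar(at$insert))) {
    stop("insertion codes are not supported: ", path, call. = FALSE)
  }
  atoms <- data.frame(elety = at$elety, resid = at$resid,
                      chain = ifelse(is.na(at$chain), "A", at$chain),
                      resno = at$resno, elesy = at$elesy,
                      stringsAsFactors = FALSE)
  blank <- is.na(atoms$elesy) | !nzchar(atoms$elesy)
  atoms$elesy[blank] <- substr(gsub("[0-9]", "", atoms$elety[blank]), 1L, 1L)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  md_traj(atoms, xyz, time)
}

#' Write a trajectory as a (multi-model) PDB file
#'
#' Standard ATOM record columns; multiple frames are wrapped in
#' MODEL/ENDMDL. Coordinates are written with 3 decimals (the PDB format's
#' precision, and therefore the acknowledged round-trip tolerance).
#'
#' @param traj an `md_traj`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb_traj <- function(traj, path) {
  a <- traj$atoms
  nm <- ifelse(nchar(a$elety) < 4L, sprintf(" %-3s", a$elety),
               sprintf("%-4s", a$elety))
  multi <- n_frames(traj) > 1L
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(traj, f)
    lines <- sprintf(
      "ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)) %% 100000L, nm, "", a$resid, a$chain, a$resno, "",
      xyz[, 1L], xyz[, 2L], xyz[, 3L], 1, 0, a$elesy)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Default analysis window
#'
#' Frame indices retained for analysis after discarding the leading
#' (equilibration) fraction of a trajectory; by default the first 60% of
#' frames are dropped, mirroring the common practice of analysing only the
#' equilibrated tail of a production run.
#'
#' @param n total number of frames.
#' @param discard_frac fraction of leading frames to drop (default 0.6).
#' @return integer frame indices.
#' @export
analysis_window <- function(n, discard_frac = 0.6) {
  stopifnot(n >= 1L, discard_frac >= 0, discard_frac < 1)
  start <- floor(n * discard_frac) + 1L
  seq.int(start, n)
}

resolve_window <- function(traj, window) {
  n <- n_frames(traj)
  if (is.null(window)) return(analysis_window(n))
  window <- as.integer(window)
  if (length(window) == 0L || any(window < 1L | window > n)) {
    stop("analysis window out of bounds (1..", n, ")", call. = FALSE)
  }
  window
}

#' Residue table of a trajectory
#'
#' One row per (chain, resno) in atom order: convenience for per-residue
#' metrics.
#'
#' @param traj an `md_traj`.
#' @return data frame with `chain`, `resno`, `resid`.
#' @export
residue_table <- function(traj) {
  a <- traj$atoms
  key <- paste(a$chain, a$resno)
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             resid = a$resid[first], stringsAsFactors = FALSE)
}
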