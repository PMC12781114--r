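#' @useDynLib nqogate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct a molecular structure
#'
#' A `Structure` holds an ordered atom table and one set of Cartesian
#' coordinates in Angstrom. It is the topology against which trajectories,
#' selections, contacts and distances are interpreted.
#'
#' @param atoms data.frame with columns `eleno` (atom serial), `name`
#'   (atom name, e.g. `"CA"`), `element` (element symbol), `resid`
#'   (residue number), `resname` (residue name), `chain` (chain id).
#' @param coords numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @return object of class `Structure`.
#' @export
Structure <- function(atoms, coords) {
  coords <- as.matrix(coords)
  required <- c("eleno", "name", "element", "resid", "resname", "chain")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atoms table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) != nrow(coords))
    stop("atom table (", nrow(atoms), ") and coordinates (", nrow(coords),
         ") disagree on atom count")
  if (ncol(coords) != 3L) stop("coords must have 3 columns")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  # residue numbering must not decrease within a chain
  for (ch in unique(atoms$chain)) {
    r <- atoms$resid[atoms$chain == ch]
    if (is.unsorted(r)) stop("residue indices decrease within chain ", ch)
  }
  structure(list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
                 coords = unname(coords)),
            class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat("Structure:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resid))), "residues,",
      length(unique(x$atoms$chain)), "chain(s)\n")
  invisible(x)
}

n_atoms <- function(x) nrow(x$atoms)

#' Residue identifiers of a structure
#'
#' Residue identity is the pair (chain id, residue number), so multi-chain
#' topologies cannot collide. Returned in order of first appearance.
#'
#' @param structure a [Structure].
#' @return character vector of labels `"<chain>:<resid>"`.
#' @export
residue_ids <- function(structure) {
  unique(paste(structure$atoms$chain, structure$atoms$resid, sep = ":"))
}

# map each atom to the 1-based index of its residue in residue_ids() order
atom_residue_index <- function(structure) {
  lab <- paste(structure$atoms$chain, structure$atoms$resid, sep = ":")
  match(lab, unique(lab))
}

#' Construct a trajectory
#'
#' A `Trajectory` is a fixed topology plus ordered coordinate frames. Frames
#' are stored as a matrix with one row per frame and 3N columns in
#' (x1, y1, z1, x2, ...) order, the layout used throughout the package.
#'
#' @param topology a [Structure].
#' @param xyz numeric matrix, `n_frames x (3 * n_atoms)`.
#' @param frame_interval optional time between frames (arbitrary units).
#' @return object of class `Trajectory`.
#' @export
Trajectory <- function(topology, xyz, frame_interval = NULL) {
  if (!inherits(topology, "Structure")) stop("topology must be a Structure")
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * n_atoms(topology))
    stop("frame width ", ncol(xyz), " does not match topology atom count ",
         n_atoms(topology), " (expected ", 3L * n_atoms(topology), " columns)")
  if (nrow(xyz) < 1L) stop("trajectory must contain at least one frame")
  structure(list(topology = topology, xyz = unname(xyz),
                 frame_interval = frame_interval),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", nrow(x$xyz), "frames x", n_atoms(x$topology), "atoms\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory a [Trajectory].
#' @return integer frame count.
#' @export
n_frames <- function(trajectory) nrow(trajectory$xyz)

#' Extract one frame as an N x 3 coordinate matrix
#' @param trajectory a [Trajectory].
#' @param i frame index (1-based).
#' @return numeric matrix, atoms x 3.
#' @export
frame_coords <- function(trajectory, i) {
  if (i < 1L || i > n_frames(trajectory)) stop("frame index out of range")
  matrix(trajectory$xyz[i, ], ncol = 3L, byrow = TRUE)
}

# N x 3 matrix -> flat (x1,y1,z1,...) vector
flatten_coords <- function(coords) as.numeric(t(coords))

# flat vector -> N x 3
unflatten_coords <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

#' Keep the equilibrated tail of a trajectory
#'
#' Drops the initial (equilibration) part of a run and keeps the last
#' `ceiling(fraction * n_frames)` frames in their original order. For a
#' 1.0 microsecond run analysed over its last 0.8 microseconds this is
#' `keep_last_fraction = 0.8`.
#'
#' @param trajectory a [Trajectory].
#' @param keep_last_fraction fraction of frames to keep, in (0, 1].
#' @return a [Trajectory] with the trailing frames.
#' @export
trim_equilibration <- function(trajectory, keep_last_fraction) {
  if (!is.numeric(keep_last_fraction) || length(keep_last_fraction) != 1L ||
      keep_last_fraction <= 0 || keep_last_fraction > 1)
    stop("keep_last_fraction must lie in (0, 1]")
  nf <- n_frames(trajectory)
  keep <- ceiling(keep_last_fraction * nf)
  Trajectory(trajectory$topology,
             trajectory$xyz[seq.int(nf - keep + 1L, nf), , drop = FALSE],
             trajectory$frame_interval)
}
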