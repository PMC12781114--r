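#' Rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between the
#' selected atoms of `mobile` and `reference`, and applies that transform to
#' ALL atoms of `mobile`, so that downstream contacts and distances share one
#' frame of reference.
#'
#' @param mobile N x 3 coordinate matrix to move.
#' @param reference N x 3 coordinate matrix to match (same atom ordering).
#' @param selection an `AtomSelection` (or integer atom indices) defining the
#'   fit atoms; default all atoms.
#' @return list with `result` (class `SuperpositionResult`: `rotation` 3x3
#'   proper orthonormal, `translation`, `rmsd` in Angstrom over the fit
#'   atoms) and `coords` (all atoms, transformed).
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("mobile and reference must have identical dimensions")
  idx <- selection_indices(selection, nrow(mobile))
  if (length(idx) < 3L) stop("superposition needs at least 3 fit atoms")
  P <- mobile[idx, , drop = FALSE]
  Q <- reference[idx, , drop = FALSE]
  if (qr(sweep(P, 2, colMeans(P)))$rank < 2L ||
      qr(sweep(Q, 2, colMeans(Q)))$rank < 2L)
    stop("degenerate (collinear or coincident) fit selection")
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- sweep(mobile, 2, cp) %*% t(R)
  moved <- sweep(moved, 2, cq, `+`)
  translation <- as.numeric(cq - R %*% cp)
  res <- structure(list(rotation = R, translation = translation,
                        rmsd = rmsd_coords(moved[idx, , drop = FALSE], Q)),
                   class = "SuperpositionResult")
  list(result = res, coords = moved)
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("Superposition: rmsd %.4f A over fit atoms\n", x$rmsd))
  invisible(x)
}

selection_indices <- function(selection, n) {
  if (is.null(selection)) return(seq_len(n))
  idx <- if (inherits(selection, "AtomSelection")) selection$indices else
    as.integer(selection)
  if (!length(idx)) stop("empty atom selection")
  if (anyDuplicated(idx) || any(idx < 1L) || any(idx > n))
    stop("selection indices must be unique and within 1..", n)
  idx
}

# plain coordinate RMSD, no fitting
rmsd_coords <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame RMSD of a trajectory against a reference
#'
#' Each frame is first superposed onto `reference` at the fit selection, then
#' the RMSD over that selection is reported (post-fit RMSD).
#'
#' @param trajectory a [Trajectory].
#' @param reference N x 3 coordinate matrix (full topology).
#' @param selection fit/measure selection (default backbone-like: all atoms).
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(trajectory, reference, selection = NULL) {
  reference <- as.matrix(reference)
  vapply(seq_len(n_frames(trajectory)), function(f) {
    superpose(frame_coords(trajectory, f), reference, selection)$result$rmsd
  }, numeric(1))
}

#' Superpose every frame of a trajectory onto a reference
#'
#' @inheritParams rmsd_series
#' @return a [Trajectory] with all frames transformed.
#' @export
superpose_trajectory <- function(trajectory, reference, selection = NULL) {
  reference <- as.matrix(reference)
  xyz <- t(vapply(seq_len(n_frames(trajectory)), function(f) {
    flatten_coords(superpose(frame_coords(trajectory, f), reference,
                             selection)$coords)
  }, numeric(ncol(trajectory$xyz))))
  Trajectory(trajectory$topology, xyz, trajectory$frame_interval)
}
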