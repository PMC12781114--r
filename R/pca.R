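#' Principal component analysis of pooled backbone fluctuations
#'
#' Fits a Cartesian (mass-unweighted) PCA to the POOLED frames of one or more
#' trajectories. Every frame is first superposed onto a single common
#' reference at the fit selection, so that principal components are directly
#' comparable across systems; the covariance of the selected coordinates is
#' then diagonalised. Eigenvalues are sorted non-increasing and each
#' eigenvector's sign is fixed so its largest-magnitude entry is positive.
#'
#' @param trajectories a [Trajectory] or list of them (optionally named with
#'   system labels).
#' @param selection an `AtomSelection` on the shared topology (e.g.
#'   `select_atoms(top, "backbone")`).
#' @param reference N x 3 reference coordinates; default the first frame of
#'   the first trajectory.
#' @param align superpose frames onto the reference before the covariance
#'   (the default); set `FALSE` only for frames that are already in a
#'   common frame of reference.
#' @return a `PCModel`: `mean` (3k vector over selected atoms),
#'   `eigenvectors` (3k x m, columns orthonormal), `eigenvalues` (Angstrom^2,
#'   non-increasing), `variance_fractions`, plus the selection, reference and
#'   per-system frame bookkeeping used by [project()].
#' @export
fit_pca <- function(trajectories, selection, reference = NULL,
                    align = TRUE) {
  if (inherits(trajectories, "Trajectory")) trajectories <- list(trajectories)
  if (!length(trajectories)) stop("no trajectories supplied")
  labels <- names(trajectories)
  if (is.null(labels)) labels <- paste0("system", seq_along(trajectories))
  nat <- n_atoms(trajectories[[1]]$topology)
  idx <- selection_indices(selection, nat)
  for (tr in trajectories)
    if (n_atoms(tr$topology) != nat)
      stop("selection mismatch: trajectories disagree on atom count")
  if (is.null(reference)) reference <- frame_coords(trajectories[[1]], 1L)
  cols <- as.vector(rbind(3L * (idx - 1L) + 1L, 3L * (idx - 1L) + 2L,
                          3L * idx))
  pooled <- do.call(rbind, lapply(trajectories, function(tr) {
    if (align)
      superpose_trajectory(tr, reference, idx)$xyz[, cols, drop = FALSE]
    else tr$xyz[, cols, drop = FALSE]
  }))
  if (nrow(pooled) < 2L) stop("PCA needs at least 2 pooled frames")
  mu <- colMeans(pooled)
  centered <- sweep(pooled, 2, mu)
  cv <- crossprod(centered) / (nrow(pooled) - 1L)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  vec <- eg$vectors
  for (k in seq_len(ncol(vec))) {
    j <- which.max(abs(vec[, k]))
    if (vec[j, k] < 0) vec[, k] <- -vec[, k]
  }
  structure(list(mean = mu, eigenvectors = vec, eigenvalues = ev,
                 variance_fractions = if (sum(ev) > 0) ev / sum(ev) else ev,
                 selection = idx, reference = reference, align = align,
                 system_labels = labels,
                 frames_per_system = vapply(trajectories, n_frames,
                                            integer(1)),
                 total_variance = sum(diag(cv))),
            class = "PCModel")
}

#' @export
print.PCModel <- function(x, ...) {
  cat("PCModel:", length(x$eigenvalues), "modes over",
    length(x$selection), "atoms;",
    sprintf("PC1 %.1f%%, PC1-2 %.1f%% of variance\n",
            100 * x$variance_fractions[1],
            100 * sum(x$variance_fractions[1:min(2, length(x$eigenvalues))])))
  invisible(x)
}

#' Project a trajectory onto principal components
#'
#' Frames are superposed onto the model's reference (same fit selection used
#' when fitting) and scored as `(frame - mean) . eigenvector_k`.
#'
#' @param trajectory a [Trajectory] sharing the model's topology size.
#' @param model a `PCModel` from [fit_pca()].
#' @param n_components number of leading components to score.
#' @param system_label label carried into the `Projection`.
#' @return a `Projection`: `scores` (frames x n_components, Angstrom) and
#'   `system_label`.
#' @export
project <- function(trajectory, model, n_components = 2L,
                    system_label = "system") {
  if (!inherits(model, "PCModel")) stop("model must be a PCModel")
  if (n_components > ncol(model$eigenvectors))
    stop("n_components exceeds model rank")
  idx <- model$selection
  cols <- as.vector(rbind(3L * (idx - 1L) + 1L, 3L * (idx - 1L) + 2L,
                          3L * idx))
  sel_xyz <- if (isFALSE(model$align)) trajectory$xyz[, cols, drop = FALSE]
  else superpose_trajectory(trajectory, model$reference,
                            idx)$xyz[, cols, drop = FALSE]
  centered <- sweep(sel_xyz, 2, model$mean)
  scores <- centered %*% model$eigenvectors[, seq_len(n_components),
                                            drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(n_components))
  structure(list(scores = scores, system_label = system_label),
            class = "Projection")
}

#' @export
print.Projection <- function(x, ...) {
  cat("Projection '", x$system_label, "': ", nrow(x$scores), " frames x ",
      ncol(x$scores), " components\n", sep = "")
  invisible(x)
}

#' Cumulative variance captured by successive components (scree)
#'
#' @param model a `PCModel`.
#' @return numeric vector of cumulative variance fractions, non-decreasing,
#'   ending at 1.
#' @export
scree <- function(model) {
  if (!inherits(model, "PCModel")) stop("model must be a PCModel")
  cumsum(model$variance_fractions)
}

scott_bandwidth <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  if (s == 0) s <- 1e-8
  s * n^(-1 / 6)
}

#' 2D probability density of PC scores
#'
#' Builds, on a grid shared across all supplied systems, a normalised 2D
#' histogram of the first two score columns, optionally smoothed with a
#' Gaussian kernel (bandwidth by a Scott-type rule on the pooled scores).
#' This is the density behind conformational-state contour maps.
#'
#' @param projections a `Projection` or list of them.
#' @param bins grid bins per axis.
#' @param smoothing kernel bandwidth in score units (length 1 or 2); `NULL`
#'   for the Scott default, `0` for a raw histogram.
#' @return a `DensityMap` per system (list if several): `density` matrix
#'   (rows = PC1 bins, cols = PC2 bins, sums to 1), bin centers `x`/`y`,
#'   `mode_bin` (row, col) of the highest-density bin (ties resolved to the
#'   lowest column-major index).
#' @export
density2d <- function(projections, bins = 60L, smoothing = NULL) {
  single <- inherits(projections, "Projection")
  if (single) projections <- list(projections)
  all_scores <- do.call(rbind, lapply(projections, function(p)
    p$scores[, 1:2, drop = FALSE]))
  if (nrow(all_scores) < 2L) stop("need at least 2 frames to build a density")
  if (is.null(smoothing))
    smoothing <- c(scott_bandwidth(all_scores[, 1]),
                   scott_bandwidth(all_scores[, 2]))
  if (length(smoothing) == 1L) smoothing <- rep(smoothing, 2L)
  rx <- range(all_scores[, 1]); ry <- range(all_scores[, 2])
  pad <- c(diff(rx), diff(ry)) * 0.05 + 1e-9
  xb <- seq(rx[1] - pad[1], rx[2] + pad[1], length.out = bins + 1L)
  yb <- seq(ry[1] - pad[2], ry[2] + pad[2], length.out = bins + 1L)
  maps <- lapply(projections, function(p) {
    s <- p$scores
    ix <- pmin(pmax(findInterval(s[, 1], xb, all.inside = TRUE), 1L), bins)
    iy <- pmin(pmax(findInterval(s[, 2], yb, all.inside = TRUE), 1L), bins)
    h <- matrix(0, bins, bins)
    for (f in seq_len(nrow(s))) h[ix[f], iy[f]] <- h[ix[f], iy[f]] + 1
    h <- h / sum(h)
    if (any(smoothing > 0)) h <- smooth_gauss2d(h, smoothing,
                                                diff(xb[1:2]), diff(yb[1:2]))
    mb <- arrayInd(which.max(h), dim(h))
    structure(list(density = h,
                   x = (xb[-1] + xb[-length(xb)]) / 2,
                   y = (yb[-1] + yb[-length(yb)]) / 2,
                   mode_bin = as.integer(mb),
                   system_label = p$system_label),
              class = "DensityMap")
  })
  if (single) maps[[1]] else maps
}

# separable truncated-Gaussian convolution of a histogram; renormalised
smooth_gauss2d <- function(h, bw, dx, dy) {
  k1 <- function(bw, d) {
    m <- max(1L, ceiling(4 * bw / d))
    k <- stats::dnorm(seq(-m, m) * d, sd = bw)
    k / sum(k)
  }
  kx <- k1(bw[1], dx); ky <- k1(bw[2], dy)
  h <- apply(h, 2, function(col) conv_same(col, kx))
  h <- t(apply(h, 1, function(row) conv_same(row, ky)))
  h / sum(h)
}

conv_same <- function(v, k) {
  m <- (length(k) - 1L) / 2L
  out <- stats::filter(c(rep(0, m), v, rep(0, m)), k, sides = 2)
  as.numeric(out[(m + 1L):(m + length(v))])
}

#' Overlap coefficient of two density maps on a shared grid
#' @param a,b `DensityMap`s built by one [density2d()] call.
#' @return sum over bins of `min(a, b)`, in `[0, 1]`.
#' @export
density_overlap <- function(a, b) sum(pmin(a$density, b$density))

#' Most probable conformation of a system
#'
#' Returns the index of the frame nearest (Euclidean in PC space) to the
#' highest-density bin center; ties resolve to the lowest frame index. With
#' `marginal = "pc1"` or `"pc2"` the mode of the corresponding 1D marginal is
#' used instead of the joint 2D mode.
#'
#' @param projection the system's `Projection` (the one the density was
#'   built from).
#' @param density the system's `DensityMap`.
#' @param marginal `"2d"` (joint mode), `"pc1"` or `"pc2"`.
#' @return integer frame index.
#' @export
most_probable_frame <- function(projection, density, marginal = "2d") {
  marginal <- match.arg(marginal, c("2d", "pc1", "pc2"))
  s <- projection$scores
  if (!nrow(s)) stop("empty projection")
  if (marginal == "2d") {
    ctr <- c(density$x[density$mode_bin[1]], density$y[density$mode_bin[2]])
    d2 <- (s[, 1] - ctr[1])^2 + (s[, 2] - ctr[2])^2
  } else if (marginal == "pc1") {
    m <- rowSums(density$density)
    ctr <- density$x[which.max(m)]
    d2 <- (s[, 1] - ctr)^2
  } else {
    m <- colSums(density$density)
    ctr <- density$y[which.max(m)]
    d2 <- (s[, 2] - ctr)^2
  }
  unname(which.min(d2))
}

#' Export a principal component as a mean +/- displaced structure pair
#'
#' Writes two PDB models (mean plus and minus `scale` times the eigenvector
#' over the selected atoms; unselected atoms at the reference) for
#' visualising the motion captured by one component.
#'
#' @param model a `PCModel`.
#' @param topology the [Structure] the model was fitted on.
#' @param component component number.
#' @param path output PDB path.
#' @param scale displacement multiplier (default 3 standard deviations).
#' @return `path`, invisibly.
#' @export
export_pc_displacement <- function(model, topology, component, path,
                                   scale = NULL) {
  if (is.null(scale)) scale <- 3 * sqrt(model$eigenvalues[component])
  base <- flatten_coords(model$reference)
  idx <- model$selection
  cols <- as.vector(rbind(3L * (idx - 1L) + 1L, 3L * (idx - 1L) + 2L,
                          3L * idx))
  plus <- base; minus <- base
  plus[cols] <- model$mean + scale * model$eigenvectors[, component]
  minus[cols] <- model$mean - scale * model$eigenvectors[, component]
  write_trajectory(Trajectory(topology, rbind(plus, minus)), path,
                   format = "pdb")
  invisible(path)
}
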