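make_flat_traj <- function(xyz_list, stru) {
  Trajectory(stru, do.call(rbind, lapply(xyz_list, flatten_coords)))
}

toy_structure <- function(n_atoms) {
  atoms <- data.frame(eleno = seq_len(n_atoms), name = "CA", element = "C",
                      resid = seq_len(n_atoms), resname = "GLY", chain = "A")
  Structure(atoms, cbind(3.8 * seq_len(n_atoms), seq_len(n_atoms) %% 2, 0))
}

test_that("identical frames give an all-zero spectrum", {
  stru <- toy_structure(5)
  tr <- make_flat_traj(rep(list(stru$coords), 6), stru)
  m <- fit_pca(tr, select_atoms(stru, "all"))
  expect_true(all(m$eigenvalues < 1e-12))
})

test_that("displacement along one direction gives a rank-1 covariance", {
  stru <- toy_structure(4)
  # frames shifted along +x of atom 1 only: a single collective direction
  frames <- lapply(c(-2, -1, 0, 1, 2), function(s) {
    co <- stru$coords
    co[1, 1] <- co[1, 1] + s
    co
  })
  # frames are constructed in a common reference frame already; aligning
  # would absorb part of the planted motion into the rigid-body fit
  tr <- make_flat_traj(frames, stru)
  m <- fit_pca(tr, select_atoms(stru, "all"), reference = stru$coords,
               align = FALSE)
  expect_gt(m$variance_fractions[1], 0.99)
  expect_equal(sum(m$variance_fractions), 1, tolerance = 1e-8)
})

test_that("eigenvalues agree with a dense oracle on explicit Gaussian data", {
  set.seed(8)
  stru <- toy_structure(2)
  # 300 frames of 2 atoms with known anisotropic displacements, no rotation
  disp <- cbind(rnorm(300, 0, 2), rnorm(300, 0, 1), rnorm(300, 0, 0.5),
                rnorm(300, 0, 0.25), rnorm(300, 0, 0.1), rnorm(300, 0, 0.05))
  frames <- lapply(seq_len(300), function(f)
    stru$coords + matrix(disp[f, ], 2, 3, byrow = TRUE))
  tr <- make_flat_traj(frames, stru)
  m <- fit_pca(tr, select_atoms(stru, "all"), reference = stru$coords,
               align = FALSE)
  # oracle route: covariance assembled by an explicit outer-product loop
  # over the same frames, top eigenvalues by power iteration
  sel_xyz <- tr$xyz
  mu <- colMeans(sel_xyz)
  S <- matrix(0, 6, 6)
  for (f in seq_len(300)) S <- S + tcrossprod(sel_xyz[f, ] - mu)
  S <- S / 299
  expect_equal(m$eigenvalues[1:3], power_eigen(S, 3), tolerance = 1e-6)
  # trace conservation
  expect_equal(sum(m$eigenvalues), sum(diag(S)), tolerance = 1e-6)
  # cross-check against the bio3d reference PCA on the same frames
  ref_pca <- bio3d::pca.xyz(sel_xyz)
  expect_equal(m$eigenvalues, ref_pca$L, tolerance = 1e-6)
})

test_that("projection properties: zero at the mean, variance = eigenvalue,
           perfect reconstruction", {
  ens <- simulate_gate_ensemble(ensemble_spec(n_frames = 60, rng_seed = 9))
  sel <- select_atoms(ens$structure, "name CA")
  m <- fit_pca(ens$trajectory, sel)
  p <- project(ens$trajectory, m, n_components = length(m$eigenvalues))
  # score variance along k equals eigenvalue k (same frames as the fit)
  v <- apply(p$scores, 2, stats::var)
  expect_equal(unname(v[1:5]), m$eigenvalues[1:5], tolerance = 1e-6)
  # full-rank reconstruction returns the centered coordinates
  centered <- p$scores %*% t(m$eigenvectors)
  sel_xyz <- superpose_trajectory(ens$trajectory, m$reference,
                                  m$selection)$xyz
  cols <- as.vector(rbind(3L * (m$selection - 1L) + 1L,
                          3L * (m$selection - 1L) + 2L, 3L * m$selection))
  expect_equal(centered, sweep(sel_xyz[, cols], 2, m$mean),
               tolerance = 1e-8, ignore_attr = TRUE)
  # the mean structure itself projects to zero
  mean_frame <- frame_coords(ens$trajectory, 1)
  mean_frame[sel$indices, ] <- unflatten_coords(m$mean)
  tr1 <- Trajectory(ens$structure, matrix(flatten_coords(mean_frame), 1))
  expect_lt(max(abs(project(tr1, m, 2)$scores)), 1e-8)
  expect_error(project(ens$trajectory, m,
                       length(m$eigenvalues) + 1L), "rank")
})

test_that("eigenvectors are orthonormal with non-increasing eigenvalues", {
  ens <- simulate_gate_ensemble(ensemble_spec(n_frames = 40, rng_seed = 10))
  m <- fit_pca(ens$trajectory, select_atoms(ens$structure, "all"))
  G <- crossprod(m$eigenvectors)
  expect_equal(G, diag(ncol(G)), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(m$eigenvalues) <= 1e-10))
  expect_true(all(m$eigenvalues >= -1e-10))
  # sign convention: largest-magnitude entry of each eigenvector positive
  picks <- apply(m$eigenvectors, 2, function(v) v[which.max(abs(v))])
  expect_true(all(picks > 0))
})

test_that("scree is non-decreasing and ends at 1; isotropic case is linear", {
  ens <- simulate_gate_ensemble(ensemble_spec(n_frames = 30, rng_seed = 3))
  m <- fit_pca(ens$trajectory, select_atoms(ens$structure, "name CA"))
  cv <- scree(m)
  expect_true(all(diff(cv) >= -1e-12))
  expect_equal(cv[length(cv)], 1, tolerance = 1e-8)
  # rank-1 toy: scree saturates immediately
  stru <- toy_structure(3)
  frames <- lapply(c(-1, 0, 1), function(s) stru$coords + c(s, 0, 0))
  tr <- make_flat_traj(frames, stru)
  m1 <- fit_pca(tr, select_atoms(stru, "all"), reference = stru$coords,
                align = FALSE)
  expect_equal(scree(m1)[1], 1, tolerance = 1e-8)
  # isotropic d-dimensional Gaussian: cumulative ~ k/d
  set.seed(21)
  stru2 <- toy_structure(3)
  frames2 <- lapply(seq_len(4000), function(f)
    stru2$coords + matrix(rnorm(9, 0, 1), 3, 3))
  tr2 <- make_flat_traj(frames2, stru2)
  m2 <- fit_pca(tr2, select_atoms(stru2, "all"), reference = stru2$coords,
                align = FALSE)
  cum <- scree(m2)
  d <- length(cum)
  expect_lt(max(abs(cum - seq_len(d) / d)), 0.06)
})

test_that("densities normalise, separate well-separated systems, and locate
           the dominant state", {
  set.seed(12)
  stru <- toy_structure(4)
  mk <- function(center, n) lapply(seq_len(n), function(i)
    stru$coords + c(center + rnorm(1, 0, 0.3), 0, 0))
  trA <- make_flat_traj(mk(-6, 120), stru)
  trB <- make_flat_traj(mk(6, 120), stru)
  m <- fit_pca(list(A = trA, B = trB), select_atoms(stru, "all"),
               reference = stru$coords)
  pA <- project(trA, m, 2, "A"); pB <- project(trB, m, 2, "B")
  dens <- density2d(list(pA, pB), bins = 50)
  expect_equal(sum(dens[[1]]$density), 1, tolerance = 1e-9)
  expect_equal(sum(dens[[2]]$density), 1, tolerance = 1e-9)
  expect_false(identical(dens[[1]]$mode_bin, dens[[2]]$mode_bin))
  expect_lt(density_overlap(dens[[1]], dens[[2]]), 0.05)
  # all-identical scores put the whole mass into one bin (no smoothing)
  pC <- structure(list(scores = matrix(1, 30, 2,
                                       dimnames = list(NULL,
                                                       c("PC1", "PC2"))),
                       system_label = "C"), class = "Projection")
  dC <- density2d(pC, bins = 10, smoothing = 0)
  expect_equal(max(dC$density), 1)
})

test_that("most probable frame lands in the dominant state of a 90/10 mix", {
  set.seed(14)
  stru <- toy_structure(4)
  centers <- c(rep(-5, 180), rep(5, 20))  # 90% / 10% occupancy
  frames <- lapply(centers, function(c0)
    stru$coords + c(c0 + rnorm(1, 0, 0.4), 0, 0))
  tr <- make_flat_traj(frames, stru)
  m <- fit_pca(tr, select_atoms(stru, "all"), reference = stru$coords)
  p <- project(tr, m, 2)
  d <- density2d(p, bins = 40)
  idx <- most_probable_frame(p, d)
  expect_lte(idx, 180)  # a frame of the dominant (90%) state
  expect_identical(idx, most_probable_frame(p, d))  # deterministic
  # 1D marginals agree on this construction
  expect_lte(most_probable_frame(p, d, marginal = "pc1"), 180)
  # single-frame projection returns that frame
  tr1 <- Trajectory(stru, tr$xyz[1, , drop = FALSE])
  p1 <- project(tr1, m, 2)
  expect_identical(most_probable_frame(p1, d), 1L)
})
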