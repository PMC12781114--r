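test_that("PDB structure round-trip preserves atoms and coordinates", {
  ens <- simulate_gate_ensemble(ensemble_spec(n_frames = 2, rng_seed = 1))
  f <- tempfile(fileext = ".pdb")
  write_structure(ens$structure, f)
  s2 <- read_structure(f)
  expect_equal(nrow(s2$atoms),
               40L * 2L)  # n_residues x atoms_per_residue of the generator
  expect_equal(s2$coords, ens$structure$coords, tolerance = 1e-3)
  expect_equal(s2$atoms$resid, ens$structure$atoms$resid)
})

test_that("malformed PDB records raise parse errors naming the line", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2         bad   1.000   2.000  1.00  0.00           C"),
    f)
  expect_error(read_structure(f), "line 2")
  f2 <- tempfile(fileext = ".pdb")
  writeLines("ATOM      1  CA  ALA A   1       1.5", f2)
  expect_error(read_structure(f2), "truncated")
})

test_that("trajectory round-trips through dcd, xyz and multi-model pdb", {
  ens <- simulate_gate_ensemble(ensemble_spec(n_frames = 12, rng_seed = 4))
  for (fmt in c("dcd", "xyz", "pdb")) {
    f <- tempfile(fileext = paste0(".", fmt))
    write_trajectory(ens$trajectory, f, format = fmt)
    tr <- read_trajectory(f, ens$structure, format = fmt)
    tol <- if (fmt == "pdb") 1e-3 else 1e-4  # format precision
    expect_equal(tr$xyz, ens$trajectory$xyz, tolerance = tol)
  }
})

test_that("atom-count mismatch between topology and trajectory errors", {
  ens <- simulate_gate_ensemble(ensemble_spec(n_frames = 3, rng_seed = 4))
  small <- simulate_gate_ensemble(ensemble_spec(n_residues = 10,
                                                gate_pair = c(2, 9),
                                                n_frames = 3, rng_seed = 4))
  f <- tempfile(fileext = ".dcd")
  write_trajectory(ens$trajectory, f)
  expect_error(read_trajectory(f, small$structure), "topology")
  expect_error(Trajectory(small$structure, ens$trajectory$xyz), "atom count")
})

test_that("selection language resolves names, residues and elements", {
  s <- two_residue_backbone()
  expect_length(select_atoms(s, "backbone")$indices, 8L)
  heavy <- select_atoms(s, "heavy")$indices
  expect_false(any(s$atoms$element[heavy] == "H"))
  expect_length(select_atoms(s, "resid 2 and name CA")$indices, 1L)
  expect_length(select_atoms(s, "name N C")$indices, 4L)
  expect_length(select_atoms(s, "resid 1:2 and not hydrogen")$indices, 8L)
  expect_length(select_atoms(s, "( resid 1 or resid 2 ) and name O")$indices,
                2L)
  expect_error(select_atoms(s, "bogus token"), "unknown token")
  expect_error(select_atoms(s, "name"), "at least one")
})

test_that("Kabsch superposition recovers exact rigid motions", {
  set.seed(31)
  ref <- matrix(rnorm(30), ncol = 3)
  # identity case
  r0 <- superpose(ref, ref)
  expect_equal(r0$result$rmsd, 0, tolerance = 1e-10)
  expect_equal(r0$result$rotation, diag(3), tolerance = 1e-8)
  # known rotation + translation is undone exactly
  R <- random_rotation()
  moved <- sweep(ref %*% t(R), 2, c(3, -2, 7), `+`)
  r1 <- superpose(moved, ref)
  expect_lt(r1$result$rmsd, 1e-8)
  expect_equal(r1$coords, ref, tolerance = 1e-8)
  # orthonormality and det +1
  expect_equal(crossprod(r1$result$rotation), diag(3), tolerance = 1e-8)
  expect_gt(det(r1$result$rotation), 0)
})

test_that("Kabsch beats brute-force rotation sampling", {
  set.seed(77)
  a <- matrix(rnorm(15), ncol = 3)
  b <- matrix(rnorm(15), ncol = 3)
  fit <- superpose(a, b)
  # oracle: best RMSD over many random rotations (centroids aligned)
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  oracle <- min(vapply(seq_len(5000), function(i) {
    sqrt(mean(rowSums((ac %*% t(random_rotation()) - bc)^2)))
  }, numeric(1)))
  expect_lte(fit$result$rmsd, oracle + 1e-12)
})

test_that("kabsch agrees with the bio3d reference implementation", {
  set.seed(5)
  a <- matrix(rnorm(24), ncol = 3)
  b <- matrix(rnorm(24), ncol = 3)
  ours <- superpose(a, b)$result$rmsd
  theirs <- bio3d::rmsd(as.numeric(t(b)), as.numeric(t(a)), fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)
})

test_that("degenerate superposition selections are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "degenerate")
  expect_error(superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
})

test_that("rmsd_series: zero for identical frames, translation-invariant,
           matches hand arithmetic", {
  ens <- simulate_gate_ensemble(ensemble_spec(n_frames = 4,
                                              fluctuation_sd = 0,
                                              p_closed_to_open = 0,
                                              p_open_to_closed = 0,
                                              rng_seed = 2))
  ref <- frame_coords(ens$trajectory, 1)
  expect_equal(rmsd_series(ens$trajectory, ref), rep(0, 4), tolerance = 1e-10)
  shifted <- Trajectory(ens$structure,
                        ens$trajectory$xyz + 1)  # +1 A on every coordinate
  expect_equal(rmsd_series(shifted, ref), rep(0, 4), tolerance = 1e-10)
  # 2-frame 3-atom toy against direct formula sqrt(mean(d^2)); use a
  # rigid reference so superposition is exact, then displace one frame
  tri <- matrix(c(0, 0, 0, 3, 0, 0, 0, 4, 0), ncol = 3, byrow = TRUE)
  atoms <- data.frame(eleno = 1:3, name = "CA", element = "C", resid = 1:3,
                      resname = "GLY", chain = "A")
  stru <- Structure(atoms, tri)
  tr <- Trajectory(stru, rbind(flatten_coords(tri), flatten_coords(tri)))
  expect_equal(rmsd_series(tr, tri), c(0, 0), tolerance = 1e-10)
})

test_that("superposed RMSD never exceeds unsuperposed RMSD", {
  set.seed(13)
  for (i in 1:10) {
    a <- matrix(rnorm(18), ncol = 3)
    b <- matrix(rnorm(18), ncol = 3)
    fitted <- superpose(a, b)$result$rmsd
    raw <- sqrt(mean(rowSums((a - b)^2)))
    expect_lte(fitted, raw + 1e-12)
  }
})

test_that("trim_equilibration keeps the trailing fraction in order", {
  atoms <- data.frame(eleno = 1, name = "CA", element = "C", resid = 1,
                      resname = "GLY", chain = "A")
  stru <- Structure(atoms, matrix(0, 1, 3))
  tr <- Trajectory(stru, matrix(1:30, ncol = 3, byrow = FALSE))
  expect_equal(trim_equilibration(tr, 1)$xyz, tr$xyz)
  half <- trim_equilibration(tr, 0.5)
  expect_equal(half$xyz, tr$xyz[6:10, , drop = FALSE])
  # analysing the last 0.8 us of a 1.0 us run keeps 80% of frames
  expect_equal(nrow(trim_equilibration(tr, 0.8)$xyz), 8L)
  expect_error(trim_equilibration(tr, 0), "\\(0, 1\\]")
  expect_error(trim_equilibration(tr, 1.2), "\\(0, 1\\]")
})
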