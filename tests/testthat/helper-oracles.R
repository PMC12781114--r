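# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately use naive algorithms (all-pairs loops, power
# iteration) so they share no code path with the package implementation.

# all-pairs brute-force residue contact oracle (pure R double loop)
brute_contacts <- function(frame, topology, cutoff = 4.5, min_sep = 3L) {
  heavy <- which(toupper(topology$atoms$element) != "H")
  rmap <- match(paste(topology$atoms$chain, topology$atoms$resid, sep = ":"),
                residue_ids(topology))
  rlab <- residue_ids(topology)
  first <- match(seq_along(rlab), rmap)
  resseq <- topology$atoms$resid[first]
  reschain <- topology$atoms$chain[first]
  out <- NULL
  for (a in heavy) for (b in heavy) {
    if (b <= a) next
    ri <- rmap[a]; rj <- rmap[b]
    if (ri == rj) next
    if (reschain[ri] == reschain[rj] &&
        abs(resseq[ri] - resseq[rj]) < min_sep) next
    if (sqrt(sum((frame[a, ] - frame[b, ])^2)) <= cutoff) {
      i <- min(ri, rj); j <- max(ri, rj)
      out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) return(matrix(integer(0), 0, 2))
  unique(out[order(out[, 1], out[, 2]), , drop = FALSE])
}

# leading eigenvalues by power iteration with deflation (dense oracle)
power_eigen <- function(S, k = 3L, iters = 5000L) {
  vals <- numeric(k)
  for (m in seq_len(k)) {
    v <- seq_len(nrow(S)) / nrow(S)  # deterministic start
    for (i in seq_len(iters)) {
      v2 <- S %*% v
      nv <- sqrt(sum(v2^2))
      if (nv < 1e-30) break
      v <- as.numeric(v2 / nv)
    }
    vals[m] <- as.numeric(t(v) %*% S %*% v)
    S <- S - vals[m] * tcrossprod(v)
  }
  vals
}

# random rotation matrix (uniform via QR of Gaussian)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# random toy structure: n residues, 1-3 heavy atoms each, coords in a box
random_toy_structure <- function(n_res, box = 18, apr_max = 3L) {
  apr <- sample.int(apr_max, n_res, replace = TRUE)
  atoms <- data.frame(
    eleno = seq_len(sum(apr)),
    name = unlist(lapply(apr, function(k) c("CA", "CB", "CG")[seq_len(k)])),
    element = "C",
    resid = rep(seq_len(n_res), apr),
    resname = "ALA", chain = "A", stringsAsFactors = FALSE)
  co <- matrix(runif(sum(apr) * 3, 0, box), ncol = 3)
  Structure(atoms, co)
}

# contact probability matrix built directly from a matrix of values
cpm_from_matrix <- function(m, n_frames = 100L, min_sep = 3L) {
  structure(list(values = m, n_frames_used = n_frames,
                 min_sequence_separation = min_sep, cutoff = 4.5),
            class = "ContactProbabilityMatrix")
}

# two cliques of size k joined by one weak edge, as a probability matrix
planted_two_cliques <- function(k = 6L, p_in = 0.9, p_bridge = 0.1) {
  n <- 2L * k
  lab <- paste0("A:", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(lab, lab))
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
    m[i, j] <- p_in
    m[i + k, j + k] <- p_in
  }
  m[k, k + 1L] <- m[k + 1L, k] <- p_bridge
  m
}

# difference network from a raw df matrix
diffnet_from_matrix <- function(m, labels = c("wt", "mut")) {
  structure(list(df = m, system_labels = labels),
            class = "DifferenceNetwork")
}

# tiny 2-residue full-backbone structure for selection tests
two_residue_backbone <- function() {
  nm <- c("N", "CA", "C", "O", "H")
  atoms <- data.frame(eleno = 1:10, name = rep(nm, 2),
                      element = rep(c("N", "C", "C", "O", "H"), 2),
                      resid = rep(1:2, each = 5), resname = "ALA",
                      chain = "A", stringsAsFactors = FALSE)
  Structure(atoms, matrix(rnorm(30), ncol = 3))
}

# Table-style reference parameter sets used by recovery tests
wt_params <- list(kcat = 11, Ka = 0.4, Kb = 35, Kis = 1.1)
p78g_params <- list(kcat = 5.4, Ka = 130, Kb = 10, Kis = NULL)
wt_grid <- list(nadh = seq(30, 100, by = 10), coq0 = seq(30, 150, by = 20))
p78g_grid <- list(nadh = seq(10, 100, by = 10), coq0 = c(2, 4, 6, 8, 10))
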