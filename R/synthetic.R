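# run code under a seed without disturbing the caller's RNG stream
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

fail_field <- function(field, why) stop("invalid spec: field '", field, "' ",
                                        why, call. = FALSE)

#' Specification of a synthetic two-state gate ensemble
#'
#' Describes a toy linear chain whose gate residue pair switches between a
#' closed and an open separation following a two-state Markov chain, the
#' stand-in for undeposited gate-opening trajectories. Defaults mirror the
#' reported gate geometry: closed mean 11.6 A, open mean 21.0 A (a ~5.5 A
#' loop displacement scale lies between the two state shifts).
#'
#' @param n_residues residues in the chain.
#' @param atoms_per_residue 1-4 pseudo-heavy atoms per residue (CA + up to
#'   3 side-chain carbons).
#' @param closed_mean_distance,open_mean_distance state-conditional mean
#'   gate distances in Angstrom (open must exceed closed).
#' @param fluctuation_sd within-state Gaussian SD of the gate distance and
#'   of the per-coordinate jitter of non-gate residues (Angstrom).
#' @param p_open_to_closed,p_closed_to_open per-frame transition
#'   probabilities in `[0, 1]`.
#' @param n_frames frames to generate (>= 1).
#' @param gate_pair integer pair: residue indices of the gate.
#' @param start_state `"closed"` or `"open"`.
#' @param rng_seed integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return an `EnsembleSpec` list.
#' @export
ensemble_spec <- function(n_residues = 40L, atoms_per_residue = 2L,
                          closed_mean_distance = 11.6,
                          open_mean_distance = 21.0,
                          fluctuation_sd = 1.0,
                          p_open_to_closed = 0.05, p_closed_to_open = 0.05,
                          n_frames = 500L, gate_pair = c(10L, 30L),
                          start_state = "closed", rng_seed = 1L) {
  if (n_residues < 2) fail_field("n_residues", "must be >= 2")
  if (atoms_per_residue < 1 || atoms_per_residue > 4)
    fail_field("atoms_per_residue", "must be in 1..4")
  if (open_mean_distance <= closed_mean_distance)
    fail_field("open_mean_distance", "must exceed closed_mean_distance")
  if (fluctuation_sd < 0) fail_field("fluctuation_sd", "must be >= 0")
  for (f in c("p_open_to_closed", "p_closed_to_open")) {
    v <- get(f)
    if (!is.numeric(v) || v < 0 || v > 1) fail_field(f, "must lie in [0, 1]")
  }
  if (n_frames < 1) fail_field("n_frames", "must be >= 1")
  gate_pair <- as.integer(gate_pair)
  if (length(gate_pair) != 2L || any(gate_pair < 1L) ||
      any(gate_pair > n_residues) || gate_pair[1] == gate_pair[2])
    fail_field("gate_pair", "must be two distinct residue indices in range")
  start_state <- match.arg(start_state, c("closed", "open"))
  structure(list(n_residues = as.integer(n_residues),
                 atoms_per_residue = as.integer(atoms_per_residue),
                 closed_mean_distance = closed_mean_distance,
                 open_mean_distance = open_mean_distance,
                 fluctuation_sd = fluctuation_sd,
                 p_open_to_closed = p_open_to_closed,
                 p_closed_to_open = p_closed_to_open,
                 n_frames = as.integer(n_frames), gate_pair = gate_pair,
                 start_state = start_state,
                 rng_seed = as.integer(rng_seed)),
            class = "EnsembleSpec")
}

# reference geometry: CA spine along x, side-chain carbons branching off
reference_chain <- function(spec) {
  names4 <- c("CA", "CB", "CG", "CD")
  offs <- rbind(c(0, 0, 0), c(0, 1.53, 0), c(0, 2.35, 1.2), c(0, 3.2, 2.0))
  nr <- spec$n_residues; apr <- spec$atoms_per_residue
  atoms <- data.frame(
    eleno = seq_len(nr * apr),
    name = rep(names4[seq_len(apr)], nr),
    element = "C",
    resid = rep(seq_len(nr), each = apr),
    resname = "ALA",
    chain = "A", stringsAsFactors = FALSE)
  coords <- matrix(0, nr * apr, 3)
  for (r in seq_len(nr)) {
    rows <- ((r - 1L) * apr + 1L):(r * apr)
    coords[rows, ] <- offs[seq_len(apr), , drop = FALSE]
    coords[rows, 1] <- coords[rows, 1] + 3.8 * (r - 1L)
  }
  Structure(atoms, coords)
}

#' Simulate a two-state open/closed gate ensemble
#'
#' Generates a toy chain topology and a trajectory in which the gate-pair
#' CA-CA distance follows a two-state Markov chain with state-dependent
#' Gaussian means (shared `fluctuation_sd`), while all non-gate residues
#' receive independent Gaussian jitter about their reference positions.
#' The RNG substream order is fixed (state sequence, then gate-distance
#' noise, then jitter), so the output is bit-identical for a given seed.
#'
#' @param spec an [ensemble_spec()].
#' @return list with `structure` (the topology, reference coordinates),
#'   `trajectory` (a [Trajectory]), `states` (per-frame `"closed"`/`"open"`)
#'   and `gate_distances` (the realised CA-CA distances, Angstrom).
#' @export
simulate_gate_ensemble <- function(spec) {
  if (!inherits(spec, "EnsembleSpec")) stop("spec must be an EnsembleSpec")
  top <- reference_chain(spec)
  apr <- spec$atoms_per_residue
  ref <- top$coords
  i_res <- spec$gate_pair[1]; j_res <- spec$gate_pair[2]
  rows_j <- ((j_res - 1L) * apr + 1L):(j_res * apr)
  ca_i <- ref[(i_res - 1L) * apr + 1L, ]
  ca_j <- ref[(j_res - 1L) * apr + 1L, ]
  u <- (ca_j - ca_i) / sqrt(sum((ca_j - ca_i)^2))
  d_ref <- sqrt(sum((ca_j - ca_i)^2))
  gate_rows <- c(((i_res - 1L) * apr + 1L):(i_res * apr), rows_j)
  jitter_rows <- setdiff(seq_len(nrow(ref)), gate_rows)
  nf <- spec$n_frames
  local_seed(spec$rng_seed, {
    # substream 1: Markov state sequence
    states <- character(nf)
    cur <- spec$start_state
    for (f in seq_len(nf)) {
      states[f] <- cur
      p_flip <- if (cur == "closed") spec$p_closed_to_open else
        spec$p_open_to_closed
      if (stats::runif(1) < p_flip)
        cur <- if (cur == "closed") "open" else "closed"
    }
    # substream 2: gate-distance noise
    mu <- ifelse(states == "closed", spec$closed_mean_distance,
                 spec$open_mean_distance)
    d <- pmax(mu + stats::rnorm(nf, 0, spec$fluctuation_sd), 0.1)
    # substream 3: jitter of non-gate residues
    jit <- if (length(jitter_rows))
      array(stats::rnorm(nf * length(jitter_rows) * 3, 0,
                         spec$fluctuation_sd),
            dim = c(nf, length(jitter_rows), 3)) else NULL
    xyz <- matrix(0, nf, 3L * nrow(ref))
    for (f in seq_len(nf)) {
      co <- ref
      co[rows_j, ] <- sweep(co[rows_j, , drop = FALSE], 2,
                            (d[f] - d_ref) * u, `+`)
      if (length(jitter_rows)) co[jitter_rows, ] <-
          co[jitter_rows, ] + jit[f, , ]
      xyz[f, ] <- flatten_coords(co)
    }
    list(structure = top, trajectory = Trajectory(top, xyz),
         states = states, gate_distances = d)
  })
}

#' Specification of simulated kinetic datasets
#'
#' Ground-truth parameters and design for steady-state initial-rate tables
#' (ping-pong bi-bi, optionally with NADH substrate inhibition) and for
#' stopped-flow flavin-reduction transients. Defaults follow the measured
#' NQO regime: wild-type-like `kcat`, Michaelis and inhibition constants,
#' the stated steady-state concentration ranges, the 90-500 uM NADH
#' stopped-flow range, and a slow phase of rate 0.1 1/s carrying under 10%
#' of the amplitude. The instrument noise magnitudes (rate CV, trace SD in
#' AU) are assumptions: the source experiments state none.
#'
#' @param true_kcat turnover number, 1/s.
#' @param true_Ka Michaelis constant for NADH, uM.
#' @param true_Kb Michaelis constant for CoQ0, uM.
#' @param true_Kis NADH substrate-inhibition constant, uM, or `NULL` for no
#'   inhibition (plain ping-pong).
#' @param true_kred limiting flavin-reduction rate, 1/s.
#' @param true_Kd NADH dissociation constant of the reductive
#'   half-reaction, uM.
#' @param slow_phase_rate substrate-independent slow-phase rate, 1/s.
#' @param slow_phase_fraction slow-phase share of the total amplitude, in
#'   `[0, 0.1)`.
#' @param nadh_grid,coq0_grid steady-state concentration grids, uM.
#' @param noise_cv relative SD of the multiplicative Gaussian rate noise.
#' @param replicates replicate rate measurements per grid point.
#' @param total_amplitude,offset trace amplitude (B1 + B2) and floor C, AU.
#' @param trace_noise_sd additive Gaussian SD on traces, AU.
#' @param trace_points time points per trace (log-spaced).
#' @param rng_seed integer seed.
#' @return a `KineticsSimSpec` list.
#' @export
kinetics_sim_spec <- function(true_kcat = 11, true_Ka = 0.4, true_Kb = 35,
                              true_Kis = 1.1, true_kred = 4.8,
                              true_Kd = 450, slow_phase_rate = 0.1,
                              slow_phase_fraction = 0.08,
                              nadh_grid = seq(30, 100, by = 10),
                              coq0_grid = seq(30, 150, by = 20),
                              noise_cv = 0.03, replicates = 3L,
                              total_amplitude = 0.1, offset = 0.02,
                              trace_noise_sd = 5e-4, trace_points = 250L,
                              rng_seed = 1L) {
  pos <- c(true_kcat = true_kcat, true_Ka = true_Ka, true_Kb = true_Kb,
           true_kred = true_kred, true_Kd = true_Kd,
           slow_phase_rate = slow_phase_rate,
           total_amplitude = total_amplitude)
  for (f in names(pos)) if (!is.finite(pos[f]) || pos[f] <= 0)
    fail_field(f, "must be > 0")
  if (!is.null(true_Kis) && true_Kis <= 0) fail_field("true_Kis",
                                                      "must be > 0 or NULL")
  if (slow_phase_fraction < 0 || slow_phase_fraction >= 0.1)
    fail_field("slow_phase_fraction", "must lie in [0, 0.1)")
  if (noise_cv < 0) fail_field("noise_cv", "must be >= 0")
  if (replicates < 1) fail_field("replicates", "must be >= 1")
  if (!length(nadh_grid) || !length(coq0_grid))
    fail_field("concentration_grid", "must be non-empty")
  if (any(nadh_grid <= 0)) fail_field("nadh_grid", "must be > 0")
  if (any(coq0_grid <= 0)) fail_field("coq0_grid", "must be > 0")
  structure(list(true_kcat = true_kcat, true_Ka = true_Ka, true_Kb = true_Kb,
                 true_Kis = true_Kis, true_kred = true_kred,
                 true_Kd = true_Kd, slow_phase_rate = slow_phase_rate,
                 slow_phase_fraction = slow_phase_fraction,
                 nadh_grid = nadh_grid, coq0_grid = coq0_grid,
                 noise_cv = noise_cv, replicates = as.integer(replicates),
                 total_amplitude = total_amplitude, offset = offset,
                 trace_noise_sd = trace_noise_sd,
                 trace_points = as.integer(trace_points),
                 rng_seed = as.integer(rng_seed)),
            class = "KineticsSimSpec")
}

#' Ping-pong bi-bi rate law
#'
#' Normalised initial rate `v0/e` at NADH concentration `A` and CoQ0
#' concentration `B` (both uM). With a finite `Kis` the NADH
#' substrate-inhibition form is used:
#' `v0/e = A B kcat / (Ka B + Kb A (1 + A / Kis) + A B)`;
#' with `Kis = NULL` the plain ping-pong form
#' `v0/e = A B kcat / (A Kb + B Ka + A B)`.
#'
#' @param A,B substrate concentrations, uM.
#' @param kcat turnover number, 1/s.
#' @param Ka,Kb Michaelis constants, uM.
#' @param Kis inhibition constant, uM, or `NULL`.
#' @return `v0/e` in 1/s.
#' @export
pingpong_rate <- function(A, B, kcat, Ka, Kb, Kis = NULL) {
  if (is.null(Kis)) A * B * kcat / (A * Kb + B * Ka + A * B)
  else A * B * kcat / (Ka * B + Kb * A * (1 + A / Kis) + A * B)
}

#' Simulate a steady-state initial-rate table
#'
#' Evaluates the ping-pong rate law (with inhibition when `true_Kis` is
#' set) on the full NADH x CoQ0 grid, applies multiplicative Gaussian noise
#' with relative SD `noise_cv`, and replicates. Replicates are drawn
#' sequentially, so increasing `replicates` never perturbs earlier draws.
#'
#' @param spec a [kinetics_sim_spec()].
#' @return a `RateDataset` data.frame with columns `NADH_uM`, `CoQ0_uM`,
#'   `replicate`, `v0_over_e_per_s`.
#' @export
simulate_rates <- function(spec) {
  if (!inherits(spec, "KineticsSimSpec")) stop("spec must be a KineticsSimSpec")
  grid <- expand.grid(NADH_uM = spec$nadh_grid, CoQ0_uM = spec$coq0_grid,
                      KEEP.OUT.ATTRS = FALSE)
  v0 <- pingpong_rate(grid$NADH_uM, grid$CoQ0_uM, spec$true_kcat,
                      spec$true_Ka, spec$true_Kb, spec$true_Kis)
  local_seed(spec$rng_seed, {
    out <- do.call(rbind, lapply(seq_len(spec$replicates), function(r) {
      fac <- 1 + stats::rnorm(nrow(grid), 0, spec$noise_cv)
      data.frame(grid, replicate = r,
                 v0_over_e_per_s = pmax(v0 * fac, .Machine$double.eps))
    }))
    rate_dataset(out, provenance = "simulated")
  })
}

#' Construct / validate a rate dataset
#'
#' @param data data.frame with columns `NADH_uM`, `CoQ0_uM`,
#'   `v0_over_e_per_s` (and optionally `replicate`).
#' @param provenance free-text label.
#' @return a `RateDataset`.
#' @export
rate_dataset <- function(data, provenance = "unknown") {
  need <- c("NADH_uM", "CoQ0_uM", "v0_over_e_per_s")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("rate table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(data$NADH_uM <= 0) || any(data$CoQ0_uM <= 0))
    stop("substrate concentrations must be > 0")
  if (any(data$v0_over_e_per_s <= 0)) stop("rates must be > 0")
  if (is.null(data$replicate)) data$replicate <- 1L
  attr(data, "provenance") <- provenance
  class(data) <- c("RateDataset", "data.frame")
  data
}

#' Simulate stopped-flow flavin-reduction traces
#'
#' For each substrate concentration S the noiseless trace is
#' `A(t) = B1 exp(-kobs1 t) + B2 exp(-kobs2 t) + C` with
#' `kobs1 = kred S / (Kd + S)` (hyperbolic saturation),
#' `kobs2 = slow_phase_rate` (independent of S) and
#' `B2 / (B1 + B2) = slow_phase_fraction`. Time points are log-spaced over
#' at least five fast-phase lifetimes (extended to cover the slow phase);
#' additive Gaussian noise of SD `trace_noise_sd` is applied. Traces are
#' generated in the order of `substrate_concentrations`, each consuming its
#' own noise draws in sequence.
#'
#' @param spec a [kinetics_sim_spec()].
#' @param substrate_concentrations NADH concentrations, uM (all > 0).
#' @return list of `StoppedFlowTrace` data.frames (`time_s`, `A461`), each
#'   carrying its `substrate_concentration` and the generating `kobs1` as
#'   attributes.
#' @export
simulate_traces <- function(spec, substrate_concentrations) {
  if (!inherits(spec, "KineticsSimSpec")) stop("spec must be a KineticsSimSpec")
  if (any(substrate_concentrations <= 0))
    stop("substrate concentrations must be > 0")
  local_seed(spec$rng_seed + 1L, {
    lapply(substrate_concentrations, function(S) {
      kobs1 <- spec$true_kred * S / (spec$true_Kd + S)
      kobs2 <- spec$slow_phase_rate
      B2 <- spec$slow_phase_fraction * spec$total_amplitude
      B1 <- spec$total_amplitude - B2
      t_end <- max(5 / kobs1, 3 / kobs2)
      times <- exp(seq(log(1e-3), log(t_end),
                       length.out = spec$trace_points))
      A <- B1 * exp(-kobs1 * times) + B2 * exp(-kobs2 * times) + spec$offset
      if (spec$trace_noise_sd > 0)
        A <- A + stats::rnorm(length(A), 0, spec$trace_noise_sd)
      tr <- data.frame(time_s = times, A461 = A)
      attr(tr, "substrate_concentration") <- S
      attr(tr, "true_kobs1") <- kobs1
      class(tr) <- c("StoppedFlowTrace", "data.frame")
      tr
    })
  })
}

#' Write / read the tabular kinetic formats
#'
#' Rates: CSV with columns `NADH_uM, CoQ0_uM, replicate, v0_over_e_per_s`.
#' Traces: CSV with columns `time_s, A461` (one file per substrate
#' concentration; the concentration is stored in a `# NADH_uM=` header
#' comment).
#'
#' @param x a `RateDataset` or `StoppedFlowTrace`.
#' @param path output CSV path.
#' @return `path` invisibly (writers); the object (readers).
#' @name kinetics_io
NULL

#' @rdname kinetics_io
#' @export
write_rates_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("NADH_uM", "CoQ0_uM", "replicate",
                                        "v0_over_e_per_s")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname kinetics_io
#' @export
read_rates_csv <- function(path) {
  rate_dataset(utils::read.csv(path), provenance = path)
}

#' @rdname kinetics_io
#' @export
write_trace_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# NADH_uM=%g", attr(x, "substrate_concentration")), con)
  utils::write.csv(as.data.frame(x)[, c("time_s", "A461")], con,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname kinetics_io
#' @export
read_trace_csv <- function(path) {
  first <- readLines(path, n = 1L)
  conc <- if (grepl("^# NADH_uM=", first))
    as.numeric(sub("^# NADH_uM=", "", first)) else NA_real_
  tr <- utils::read.csv(path, comment.char = "#")
  if (is.unsorted(tr$time_s, strictly = TRUE))
    stop("trace times must be strictly increasing")
  attr(tr, "substrate_concentration") <- conc
  class(tr) <- c("StoppedFlowTrace", "data.frame")
  tr
}
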