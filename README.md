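# nqogate

Analysis toolkit for **conformational gating in NADH:quinone
oxidoreductase (NQO)** and for the enzyme kinetics that go with it.

NQO is a flavin (FMN) dependent enzyme that detoxifies quinones at the
expense of NADH. Access to its active site is controlled by a gate formed
by loop 3 of the TIM-barrel domain (residues 75–86) and the extended
domain; a hinge mutation (P78G) shifts this gate from a closed-dominant
to an open-dominant regime, with measurable consequences for substrate
binding and turnover. The package is aimed at structural biochemists and
enzymologists who want to quantify such gating from structural ensembles
and from kinetic experiments with one consistent, tested toolchain:

* **Trajectory layer** — PDB/DCD/XYZ input and output, an atom-selection
  mini-language, Kabsch superposition, per-frame RMSD, equilibration
  trimming.
* **Ensemble PCA** — pooled backbone covariance across systems,
  eigenvalue spectra and scree, per-system projections, shared-grid 2D
  probability densities of (PC1, PC2), most-probable-conformation
  extraction.
* **Difference contact network analysis (dCNA)** — heavy-atom residue
  contacts (any atom pair ≤ 4.5 Å, sequence separation ≥ 3), contact
  probabilities over frames, signed contact-probability differences
  `df = P_mut − P_wt`, consensus communities from stable contacts, and
  net `df` summed over community interfaces.
* **Gate geometry** — residue-pair (e.g. Q80 Cα – Y261 Cα) distance
  series and mean ± population-SD summaries.
* **Kinetics** — least-squares fits of the ping-pong bi-bi rate law
  `v0/e = A·B·kcat/(A·Kb + B·Ka + A·B)`, its NADH substrate-inhibition
  extension with `Kb·A·(1 + A/Kis)`, stopped-flow biexponential
  transients `A(t) = B1·e^(−kobs1 t) + B2·e^(−kobs2 t) + C`, the
  hyperbolic saturation `kobs = kred·S/(Kd + S)`, nested-model selection,
  catalytic efficiencies with error propagation, and fold changes.
* **Synthetic data** — seeded generators for two-state open/closed gate
  ensembles (Markov switching between state-conditional gate distances)
  and for kinetic datasets simulated from a ground-truth parameter set,
  used throughout the tests and the acceptance study.
* **Pipeline** — `run_pipeline()` drives simulate/ingest → trim → PCA +
  contacts + dCNA + distances → kinetic fits from one validated config
  (R list or YAML), writing CSV/JSON artifacts and a machine-readable
  run report; `inst/cli/nqogate.R` is a thin command-line wrapper.

## Worked example

Simulate a closed-dominant (wild-type-like) and an open-dominant
(mutant-like) gate ensemble, measure the gate, and fit kinetics
simulated in the mutant regime:

```r
library(nqogate)

wt_spec  <- ensemble_spec(closed_mean_distance = 11.6, open_mean_distance = 21.0,
                          fluctuation_sd = 1.4, p_closed_to_open = 0.002,
                          p_open_to_closed = 0.5, n_frames = 2000,
                          start_state = "closed", rng_seed = 101)
mut_spec <- ensemble_spec(closed_mean_distance = 11.6, open_mean_distance = 21.0,
                          fluctuation_sd = 2.9, p_closed_to_open = 0.5,
                          p_open_to_closed = 0.002, n_frames = 2000,
                          start_state = "open", rng_seed = 102)
wt  <- simulate_gate_ensemble(wt_spec)
mut <- simulate_gate_ensemble(mut_spec)
trim <- function(e) trim_equilibration(e$trajectory, 0.8)

gate_stats(distance_series(trim(wt),  "resid 10 and name CA", "resid 30 and name CA"))
#> GateStats: 11.7 +/- 1.5 A over 1600 frames
gate_stats(distance_series(trim(mut), "resid 10 and name CA", "resid 30 and name CA"))
#> GateStats: 21.0 +/- 2.9 A over 1600 frames
```

The closed-dominant system sits near its 11.6 Å configured mean, the
open-dominant one near 21.0 Å — the two-state emulation of the gate that
all structural stages are validated on.

```r
rates <- simulate_rates(kinetics_sim_spec(
  true_kcat = 5.4, true_Ka = 130, true_Kb = 10, true_Kis = NULL,
  nadh_grid = seq(10, 100, 10), coq0_grid = c(2, 4, 6, 8, 10),
  rng_seed = 7))
f1 <- fit_pingpong(rates)
f2 <- fit_pingpong_substrate_inhibition(rates)
select_model(f1, f2)
#> Model selection: eq1 (AICc eq1 -1081.43, eq2 -1079.29; F = 0.00, p = 1)
f1
#> Ping-pong bi-bi fit (no inhibition)
#>   kcat   = 5.262 +/- 0.15 1/s
#>   K_NADH = 126.6 +/- 4.9 uM
#>   K_CoQ0 = 9.495 +/- 0.37 uM
#>   R^2 = 0.9947 on 150 points
```

The selection correctly keeps the plain ping-pong law (the data were
generated without substrate inhibition) and the fit recovers the
generating parameters (5.4 s⁻¹, 130 µM, 10 µM) within its standard
errors. The stopped-flow side works the same way:

```r
sp <- kinetics_sim_spec(true_kred = 4.8, true_Kd = 450, rng_seed = 8)
conc <- c(90, 150, 250, 350, 500)
fits <- lapply(simulate_traces(sp, conc), fit_biexponential)
fits[[1]]
#> Biexponential fit:
#>   kobs1 = 0.8011 1/s (B1 = 0.0923 AU, 91.7% of amplitude)
#>   kobs2 = 0.08142 1/s (B2 = 0.00838 AU)
#>   C = 0.01929 AU, R^2 = 0.99985
fit_saturation(data.frame(S = conc, kobs = sapply(fits, `[[`, "kobs1")))
#> Saturation fit: kred = 4.785 +/- 0.014 1/s, Kd = 446.1 +/- 2.2 uM (R^2 = 1.0000)

fold_change(35, 10, c("K_CoQ0 wt", "K_CoQ0 P78G"))
#> 3.5-fold decrease (K_CoQ0 wt -> K_CoQ0 P78G)
```

The fast phase carries >90% of the amplitude, the slow phase is near
0.1 s⁻¹ and substrate independent, and the kobs1 values refit to the
generating `kred`/`Kd`.

For the full orchestration, `run_pipeline(default_run_config())` runs
every stage on a synthetic wild-type/mutant pair and writes projections,
densities, contact-probability and `df` matrices, community partitions,
gate statistics and kinetic fits under the configured output directory.

## Selection mini-language

`select_atoms(structure, expr)` understands `all`, `backbone` (N, CA, C,
O), `heavy`, `hydrogen`, `ca`, `name <...>`, `elem <...>`,
`chain <...>`, `resid <n|a:b> ...`, combined with `and`, `or`, `not` and
parentheses — e.g. `"resid 80 and name CA"`, `"heavy and chain A"`.
Keywords are lowercase; uppercase tokens are always arguments, so atom
names such as `CA` never collide with keywords.
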