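---
title: "Models and methods behind nqogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nqogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nqogate)
```

# Scope

`nqogate` implements the computational side of a conformational-gating
study of NADH:quinone oxidoreductase (NQO), a flavin-dependent enzyme
whose loop 3 (residues 75–86) together with the extended domain forms a
gate over the active site. A proline-to-glycine substitution in the gate
hinge (P78G) shifts the gate from a closed-dominant to an open-dominant
regime, and the package provides the two halves of the analysis that
quantify this:

1. **Structural ensembles** — trajectory handling, ensemble PCA,
   residue-contact probabilities with difference contact network analysis
   (dCNA) and consensus communities, and gate residue-pair distance
   statistics.
2. **Enzyme kinetics** — nonlinear least-squares fits of the ping-pong
   bi-bi steady-state rate law (with and without NADH substrate
   inhibition), stopped-flow biexponential transients, and the hyperbolic
   saturation of the observed flavin-reduction rate.

Because the original molecular-dynamics trajectories are not publicly
deposited, every structural routine is exercised on *synthetic* ensembles
with a controlled two-state gate, and validated by properties and
independent oracles rather than by reproducing published trajectory-derived
numbers. The published values (gate separations of 11.6 ± 1.4 Å closed
vs 21.0 ± 2.9 Å open, PC1 capturing ~51% and PC1+PC2 ~67% of the backbone
variance, 8 consensus communities with a −7.8 net contact change at the
gate interface) are treated as expected magnitudes that the synthetic
conditions emulate, not as assertions.

# The synthetic two-state gate ensemble

`ensemble_spec()` / `simulate_gate_ensemble()` build a toy linear chain
(one CA plus up to three pseudo side-chain carbons per residue, 3.8 Å CA
spacing) in which the distance between a designated gate residue pair
follows a two-state Markov chain:

* state-conditional Gaussian distances — `closed_mean_distance` (default
  11.6 Å) and `open_mean_distance` (default 21.0 Å) with a shared
  `fluctuation_sd`;
* per-frame transition probabilities `p_closed_to_open`,
  `p_open_to_closed`;
* independent Gaussian jitter (same SD) on all non-gate residues.

The second gate residue is displaced rigidly along the line joining the
two gate CA atoms, so the realised CA–CA distance equals the sampled value
exactly; `distance_series()` therefore recovers the generator's state
means to Monte-Carlo precision, which is one of the acceptance
properties. The RNG substream order is fixed (state sequence, then gate
noise, then jitter), making the output bit-identical for a given
`rng_seed`.

What the toy does **not** emulate: excluded volume, secondary structure,
solvent, correlated loop motions beyond the single gate coordinate, and
physically realistic contact topology. Passing tests on these ensembles
demonstrate the correctness of the *analysis operators* (distances, PCA,
contacts, communities), not the realism of any force field.

# Trajectory operations

Coordinates are in Å throughout (PDB convention). PDB reading/writing and
DCD reading go through `bio3d`; DCD writing is a minimal CHARMM-format
writer (single-precision, no unit cell) and plain XYZ is supported for
text round-trips. Residue identity is the pair (chain id, residue
number), so multi-chain topologies cannot collide.

Superposition is the Kabsch algorithm (SVD of the covariance of the
selected atoms, determinant-corrected for a proper rotation). The fitted
transform is applied to *all* atoms so that contacts and distances are
measured in one consistent frame of reference. Selections of fewer than
three atoms, or collinear ones, are rejected as degenerate.
`trim_equilibration(trajectory, f)` keeps the last `ceiling(f · n)`
frames — equilibration removal is deliberately the caller's explicit
step so downstream statistics are transparent.

# Ensemble PCA

`fit_pca()` pools the frames of all supplied systems, superposes each
frame onto a single common reference (default: the first frame of the
first system) at the fit selection, and diagonalises the mass-unweighted
Cartesian covariance of the selected coordinates. Pooling is the default
because it is what makes the principal components comparable across
systems when several trajectories are overlaid in one PC1/PC2 plane; a
single-system fit followed by `project()` onto other systems is available
by simply fitting on one trajectory. Sample (n−1) normalisation is used;
trace conservation (Σ eigenvalues = total variance of the pooled centered
coordinates) is asserted to 10⁻⁶ relative in the acceptance suite.

Numerical conventions:

* eigenvalues are clamped at zero from below and sorted non-increasing;
* each eigenvector's sign is fixed so its largest-magnitude entry is
  positive, making projections reproducible across platforms;
* `align = FALSE` skips the per-frame superposition for frames already
  expressed in a common reference frame (also the only meaningful mode
  for degenerate toys with fewer than three atoms).

`density2d()` histograms the first two score columns on a grid shared by
all systems and smooths with a separable truncated-Gaussian kernel. The
bandwidth default is a Scott-type rule, `sd · n^(−1/6)` per axis, on the
pooled scores; `smoothing = 0` gives the raw histogram. The mode bin is
the highest-density bin with ties resolved to the lowest column-major
index, and `most_probable_frame()` returns the frame nearest (Euclidean
in PC space) to the mode-bin center, ties to the lowest frame index.
Because the exact published estimator is unspecified, both the joint 2D
mode and the 1D marginal modes (`marginal = "pc1"` / `"pc2"`) are
provided.

# Contacts, dCNA and consensus communities

Two residues are in contact in a frame when **any** pair of their heavy
(non-hydrogen) atoms is within 4.5 Å (inclusive) and the residues are at
least 3 apart in sequence (i to i+n, n ≥ 3); pairs on different chains
always pass the separation filter. The kernel bins heavy atoms into a
cell list with cell edge equal to the cutoff (C++ via Rcpp, linear cost
in atom count), and the test suite requires exact set equality with a
pure-R all-pairs brute force on random toys. Cofactor/ligand atoms
participate only if present in the supplied topology — the default
synthetic systems are protein-only.

`contact_probabilities()` averages the per-frame indicator over frames;
`difference_network()` forms `df = P_B − P_A` per pair (positive =
contact formed going A→B, negative = broken), antisymmetric under
swapping the systems and bounded in [−1, 1].

Consensus communities: per trajectory block a residue graph is built from
stable contacts (occupancy ≥ `stable_threshold`, default 0.7 — the value
is a package choice, exposed as a parameter) with occupancy as edge
weight, and partitioned by greedy modularity maximisation
(`igraph::cluster_fast_greedy`). The dendrogram cut with maximal
modularity is selected explicitly, with ties broken toward the *coarsest*
partition so that a single clique is deterministically one community.
The consensus across blocks (default: 4 equal-length blocks per system)
assigns two residues to the same consensus community when they are
co-classified in more than half of the blocks; per-residue stability is
the mean fraction of a residue's consensus peers co-classified with it
per block. Residues with no stable contact in any block become flagged
singletons. Any modularity-based algorithm satisfies the qualitative
published description ("densely connected residues through stable
contacts"); this particular choice is documented and deterministic.

`community_difference()` sums signed pair `df` over every community
interface (each unordered residue pair once; intra-community sums on the
diagonal), so the interface totals plus intra terms conserve the total
pairwise `df` exactly. All pairs contribute to the interface sums, not
only those above the display threshold; `significant_edges()` (default
|df| ≥ 0.5, inclusive) is the separate mapping used to list the largest
individual changes.

# Kinetic models

With `A` = [NADH] and `B` = [CoQ0] in µM, the normalised initial rate is

* plain ping-pong bi-bi:
  `v0/e = A·B·kcat / (A·Kb + B·Ka + A·B)`
* with NADH dead-end inhibition of the reduced enzyme:
  `v0/e = A·B·kcat / (Ka·B + Kb·A·(1 + A/Kis) + A·B)`

Stopped-flow flavin-reduction transients at 461 nm follow

* `A(t) = B1·exp(−kobs1·t) + B2·exp(−kobs2·t) + C`

and the fast-phase rate saturates hyperbolically with substrate,

* `kobs = kred·S / (Kd + S)` (y-intercept fixed at zero).

`absorbance_to_rate()` performs the Beer–Lambert conversion of progress
slopes (default ε₃₄₀ = 6220 M⁻¹cm⁻¹ for NADH).

## Fitting strategy

All fitters use unweighted Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) on an internal log parameterisation, which
enforces strict positivity without constraint handling; results and
delta-method standard errors are reported on the natural scale from the
pseudo-inverted Gauss–Newton Hessian at the optimum (so practically
unidentifiable directions yield large finite errors instead of failures).
A deterministic multistart (base start from data heuristics — `kcat` near
the maximal rate, `Ka`/`Kb` near the median concentrations — plus fixed
±log 4 and ±log 16 single-parameter offsets, 8–9 starts) guards against
local minima; the lowest-RSS converged run wins. Unweighted residuals are
the default because no weighting scheme is published; the simulated noise
is multiplicative (constant CV), so a weighted option would be a natural
extension.

Biexponential initialisation is derived from the trace itself — offset
from the tail mean, fast rate from the 1/e crossing of the
baseline-subtracted signal, slow phase from a log-linear fit beyond three
fast lifetimes — and is therefore robust to logarithmically spaced
sampling. Phases are relabelled so `kobs1 ≥ kobs2`; a rate ratio below
1.5 is flagged as poorly separable.

## Model selection

The inhibition law nests the plain law, so the package decides between
them with the extra-sum-of-squares F-test at α = 0.05 and reports the
AICc of both models alongside. An information criterion was considered as
the deciding rule but rejected: for nested models AICc accepts the larger
model at a fixed asymptotic rate (roughly 8–16% depending on boundary
effects), which is incompatible with the ≥95% selection reliability the
package's acceptance study demands; the F-test controls exactly that
error rate by construction, and on strongly inhibited data its power is
effectively 1. With identical residuals the F statistic is 0 and the
simpler model wins.

## Identifiability of the closed-gate (wild-type-like) design

On the stated wild-type concentration grid (NADH 30–100 µM against
CoQ0 30–150 µM) with `Kis` ≈ 1.1 µM, the inhibition term dominates the
whole design (`A/Kis` ≈ 30–90), so the surface mainly constrains the
combination `kcat·Kis/Kb` and individual parameters carry large standard
errors — the same reason the published table flags the wild-type NADH
constant as unreliable. Recovery tests therefore compare estimates to
truth within two *combined* standard errors (fit SE and published SE in
quadrature), the criterion the acceptance suite applies to this layer.
The open-gate
(mutant-like) design without inhibition is well conditioned and recovers
all parameters tightly.

# Synthetic kinetic data: assumed noise and sampling

The experiments publish no instrument noise magnitudes, so the defaults
are assumptions, chosen once as typical for the instruments involved:

* initial rates: multiplicative Gaussian noise with CV 3% (rate errors
  scale with signal), 3 replicates per grid point;
* stopped-flow traces: additive Gaussian noise of SD 5×10⁻⁴ AU on a
  total amplitude of 0.1 AU, 250 points per trace, logarithmically
  spaced over at least five fast-phase lifetimes and extended to cover
  the slow phase (mimicking stopped-flow acquisition);
* the slow phase carries 8% of the amplitude at 0.1 s⁻¹, matching the
  published "less than 10%" / substrate-independent description.

Replicates and traces consume their noise draws sequentially, so
enlarging the design never perturbs earlier draws under the same seed.

# Problem sizes

The packaged demonstrations and checks run on one CPU in well under a
minute: synthetic ensembles of 40 residues × a few hundred to a few
thousand frames (50,000 for Monte-Carlo convergence checks of the
Markov chain), kinetic designs of 50–168 rate points and five traces of
250 points, and 200-replicate model-selection studies. These sizes are
the package's own choice of demonstration scale; every routine accepts
larger inputs unchanged.

# Known limitations

* The synthetic chain has no excluded volume; contact patterns are
  sparser and simpler than in a folded protein, so community structure in
  the *demo* pipeline is exercised mainly through planted-partition
  fixtures.
* PCA densities use a fixed-bandwidth Gaussian kernel on a histogram;
  very sharp, curved or multi-scale densities would deserve an adaptive
  estimator.
* Steady-state fitting is the published two-stage surface fit; a global
  (rates + transients) analysis is out of scope.
* The DCD writer emits the minimal CHARMM layout (no unit cell, no fixed
  atoms) — sufficient for analysis round-trips, not a general-purpose
  archival writer.
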