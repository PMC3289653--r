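---
title: "Free-energy simulation with path collective variables: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy simulation with path collective variables: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`pathcv` implements the full free-energy-simulation strategy used in path-based
studies of multi-step (bio)chemical reactions — guess-path generation by
sequential steering on simple reaction coordinates, path collective variables
(S, Z), iterative steered refinement of the reference path, umbrella sampling
in one or two dimensions, weighted-histogram (WHAM) reconstruction with
block-bootstrap errors, and the downstream analyses (minimax minimum
free-energy path, projection onto S, observables binned along the path,
steered-work barriers, gradient projections and zero-point-charge mutant
scans) — on desk-scale model systems with exactly known answers. The expensive
molecular engine of a real enzyme study (a QM/MM Hamiltonian over tens of
thousands of atoms) is deliberately replaced by a seedable Langevin sampler
over pluggable analytic potentials and small charged clusters, so that every
claim the toolkit makes can be checked against quadrature, closed forms, or
dense-grid search.

# The path collective variables

Given an ordered reference path of frames $R(1),\dots,R(N)$ and a metric
$D(R, R(i))$ — the (optionally superposition-aligned) mean square displacement
— the progress along and the distance from the path are

$$S(R) = \frac{\sum_{i=1}^{N} i\, e^{-\lambda D(R,R(i))}}
              {\sum_{i=1}^{N} e^{-\lambda D(R,R(i))}},
\qquad
Z(R) = -\frac{1}{\lambda}\,\ln \sum_{i=1}^{N} e^{-\lambda D(R,R(i))}.$$

$S$ runs from 1 (reactants) to $N$ (products) with no renormalization; $Z$ is
in squared coordinate units and is bounded by
$\min_i D - \ln(N)/\lambda \le Z \le \min_i D$. Both sums are evaluated in
log-sum-exp form so that large $\lambda D$ cannot underflow to 0/0. The
smoothing parameter follows the standard prescription
$\lambda = 2.3 / \langle D(R(i), R(i+1))\rangle$, which makes adjacent frames
distinguishable without starving distant ones; the toolkit's acceptance
checks are insensitive to $\pm 50\%$ changes of $\lambda$, which is the
relevant robustness statement since no universal value exists.

Gradients are analytic:
$\nabla S = -\lambda \sum_i (i - S)\, p_i \nabla D_i$ and
$\nabla Z = \sum_i p_i \nabla D_i$ with $p_i$ the normalized exponential
weights. For the aligned metric, $\nabla D_i$ uses the optimally superposed
reference frame and omits the derivative of the optimal rotation, which
vanishes at the superposition optimum; the only approximation that remains is
through the fixed weighting. Superposition itself is the closed-form
covariance/SVD construction with a determinant correction, with the mobile
frame's weights used both for centering and in the minimized objective
(uniform by default — nothing here assumes mass-weighting).

# Model systems

Three fixtures stand in for the paper-scale chemistry; their defaults are the
study conditions of every shipped test.

**Quartic double well** (`make_double_well`). With $u = x/a$,
$V = h(u^2-1)^2 + \tfrac{t}{4}(3u - u^3) + \tfrac{t}{2}$. The cubic tilt term
is chosen so the stationary points stay exactly at $x = -a, x_{TS}, +a$, making
minima, transition state, and both barriers closed-form. In one dimension the
free energy along $x$ equals $V(x)$ up to a constant, so umbrella sampling +
WHAM can be graded against an exact answer. Shipped conditions mirror a
proton-transfer-scale coordinate: barrier 3 kcal/mol, minima separation
0.7 Å, tilt 1 kcal/mol, sampled at 300 K (kT = 0.596 kcal/mol).

**Two-channel reactive surface** (`make_two_channel_surface`). A 2D surface
over an attack coordinate $x$ and a proton coordinate $y$: Gaussian wells at
the reactant (0,0) and product (1,1) basins, a Gaussian ridge along
$x + y = 1$, and two Gaussian "gates" lowering the ridge — a concerted one on
the diagonal and a shallower stepwise one where the attack coordinate leads.
It emulates the mechanistic competition between a stepwise and a concerted
nucleophilic-attack/proton-transfer channel. The shipped defaults (well depth
8, ridge 12, gates 9 and 4.5 kcal/mol, quartic confinement 25 kcal/mol per
unit$^4$) give a concerted barrier of about 8.4 kcal/mol (14 kT at 300 K) and
a stepwise barrier about 4 kcal/mol higher. Those scales are a deliberate
desk-scale choice: barriers of a real enzyme study (∼13–25 kcal/mol) are
20–40 kT and cannot be crossed, recrossed and error-barred in minutes of
single-core sampling; 14 kT preserves the rare-event character (unbiased
crossing times far exceed any shipped run) while keeping every campaign
oracle-checkable. The construction runs a dense-grid minimax search at build
time and attaches the basin minima, both channel saddles and a channel
classifier; a spec whose basins merge, or whose concerted saddle is not below
the stepwise one when required, is rejected.

**Charged cluster for mutant scans** (`make_mutant_cluster`). A mobile
"nucleophile" (charge −0.25 e) approaches a fixed charged scaffold along the
x axis (transverse harmonic restraints, k = 500 kcal/mol/Å², keep it
on-axis). Interactions are Coulombic with the constant
332.06 kcal·Å/(mol·e²). Three mutable sites probe the zero-point-charge
protocol: `stab` (+0.25 e placed to stabilize the close-approach geometry),
`mid` (+0.25 e on the midplane between the start and end geometries, so its
deletion cancels), and `destab` (−0.25 e, like-charged with the nucleophile).
Because the pull path is a straight line, the whole energy profile and every
mutant's barrier shift are closed-form Coulomb sums, evaluated on a dense
grid as the oracle.

# The sampling engine

Dynamics are Langevin with the BAOAB splitting: deterministic force
half-kicks and half-drifts around an exact Ornstein–Uhlenbeck velocity
update. The scheme samples configurations accurately at practical timesteps
and reduces to velocity Verlet as friction goes to zero (an energy-drift
check in the tests). Defaults: T = 300 K, friction 5 ps⁻¹, timestep 0.002 ps
(0.001 ps under stiff path-variable biases, whose effective force constants
$k_S |\nabla S|^2$ are an order of magnitude above the bare surface
curvatures), unit mass per coordinate. One RNG stream serves a run; campaign
stages and windows derive child seeds deterministically from (campaign seed,
index), so whole campaigns are bit-reproducible.

# Biases and work

Three restraint forms cover all protocols, with the half-k convention
($U = \tfrac{k}{2}(cv - c)^2$) so quoted constants map directly onto the
`k` fields: static harmonic (umbrella windows), moving harmonic
(steering; linear center schedule clamped at its target) and the one-sided
quartic wall $U = k\,(cv - z_{lim})^4$ above its limit, exactly zero below.
External work is accumulated as
$W(t) = \int_0^t (\partial U/\partial c)\,\dot c\,dt'$ by the trapezoid rule
at the sampling stride; across repeated pulls $\langle W\rangle \ge \Delta F$
(checked against quadrature), with the dissipation shrinking as the pull
slows.

# Composite protocols

**Guess path.** The reaction is divided into consecutive stages, each pulling
one simple reaction coordinate to its target with a moving harmonic
(k = 300 kcal/mol per unit², mirroring the distance-steering stage of an
enzyme study). Completed stages stay restrained at their targets while later
stages run — on a multi-well landscape an unrestrained early coordinate
would simply slide back.

**Steering along S.** A moving harmonic on S from 1 to N plus the quartic
wall on Z (defaults: limit 0.005 Å², k = 200 kcal/mol Å⁻⁸) that leaves the
system free to relax around the path while preventing escape from the
reactive tube.

**Iterative refinement** (`optimize_path`). Loop: reparameterize the current
trajectory into N equally spaced frames → steer along the resulting path
variables → extract the new trajectory; stop when the mean frame-wise RMSD
between successive paths falls below the tolerance. Reparameterization
smooths thermally noisy trajectories with a moving average before equal-arc
selection (the fluctuation arc length would otherwise dominate) and iterates
the selection on the reduced polyline until adjacent spacings are uniform.
When several replicate steers are run per iteration
(`steers_per_iteration`), the replicate with the lowest work barrier supplies
the next trajectory: the lowest-work route is the best current estimate of
the minimum free-energy channel, and this selection keeps the refinement
from oscillating between competing channels on single stochastic runs —
frame-wise averaging of two routes through different channels would
manufacture a path through neither. Non-convergence is a flagged result
carrying the whole difference series, not an exception.

For the shipped two-channel conditions the refinement protocol uses
k_S = 30 kcal/mol per S², pull speed 0.25 S/ps, timestep 0.001 ps, friction
2.5 ps⁻¹, three replicate steers per iteration, and a floor of six
iterations before the convergence rule may fire. The floor exists because a
path through the higher channel is locally self-consistent: successive
steers along it reproduce it, so the difference series can fall below
tolerance before any replicate has stumbled on the competing channel; six
iterations of three replicates give the discovery step enough independent
attempts. The softer spring (vs.
the 300 of the guess-path stage) is what lets the system relax transversally
far enough to find the competing channel on this unit-scale landscape: with
$k_S = 300$ per S² the restraint standard deviation (0.045 S units) is far
below the inter-channel distance and the refinement simply reproduces its
input channel. The reduced friction doubles the transverse diffusivity
(kT/γ per unit mass), so the system explores the full width between the
competing gates during the few picoseconds it spends at the ridge crossing;
at 5 ps⁻¹ and faster pulls the crossing-channel choice degenerates into a
coin flip that can leave the refinement stranded. Both constants are search-stage settings
only — the umbrella campaigns that produce free energies sample at the
standard 5 ps⁻¹.

**Umbrella campaigns.** Windows with strictly monotone centers, optional
chaining (each window starts from the previous window's final
configuration), a 50% equilibration discard per window (matching the
20-of-40-ps convention of the enzyme protocol), and per-window child seeds.
The 1D reference campaign mirrors the proton-transfer design: 22 windows
spaced 0.05 Å with k = 300 kcal/mol/Å². The 2D campaign restrains S
harmonically per window and Z harmonically to 0 (k = 500 kcal/mol Å⁻⁴ at the
shipped geometry; the window spring on S is 20 kcal/mol per S², chosen above
the FES curvature at the saddle so the biased ensembles stay unimodal —
below that threshold the windows jump the barrier hysteretically and leave a
support gap that WHAM correctly rejects as disconnected).

# WHAM

Binned WHAM (defaults 100 bins in 1D, 60×60 in 2D) solves
$P(b) \propto \sum_w n_w(b) \big/ \sum_w N_w e^{(f_w - U_w(b))/kT}$,
$f_w = -kT \ln \sum_b P(b) e^{-U_w(b)/kT}$ by minimizing the equivalent
convex objective (BFGS on the window free energies), then polishing with
direct sweeps until $\max_w |\Delta f_w|$ falls below the tolerance
(10⁻⁶ kcal/mol); iteration count and residual are recorded, and
non-convergence is flagged rather than thrown. Unoccupied bins stay `NA`;
windows with disjoint histogram support raise a connectivity error naming the
disconnected groups. Errors are per-bin standard deviations over block
bootstrap resamples of each window's series (block length one tenth of the
series, preserving short-range correlation), deterministic given a seed;
replicates warm-start from the full-data solution.

# FES analysis

The minimum free-energy path on a binned surface is defined as the minimax
(bottleneck-optimal) path over 8-connected occupied bins: cells are activated
in order of increasing free energy and merged by union–find, and the energy
at which the endpoints first join is exactly the saddle; a realizing path is
recovered by breadth-first search through the sub-level set. This definition
was chosen because its saddle is precisely the quantity compared with barrier
heights, and it is checkable by exhaustive threshold search on small grids.
Projection onto S is the Boltzmann integral
$F(S) = -kT \ln \sum_Z e^{-F(S,Z)/kT} \Delta Z$ over occupied bins.
Work-profile barriers are the largest forward rise of the work curve
(maximum minus the minimum over the pre-maximum segment). Gradient
projections are reported as the scale-free cosine
$|\nabla S \cdot \nabla d| / (\|\nabla S\|\,\|\nabla d\\|) \in [0,1]$ — a
deliberately normalization-free variant, since projection conventions differ
across codes; values near 1 mark internal coordinates that carry the mean
force along the progress variable.

# What the fixtures do and do not show

Passing the shipped campaigns demonstrates that the machinery — path
variables and their gradients, steering and work accounting, window
bookkeeping, WHAM unbiasing, error estimation and the downstream analyses —
is internally consistent and statistically calibrated against exact answers.
It does not demonstrate anything about real molecular systems: the fixtures
have no solvent, no multi-atom frames in the refinement loop (abstract
configurations are single-point frames with alignment off), barriers scaled
to desk-budget sampling, and Langevin friction standing in for solvent and
thermostat physics. Transfer to a molecular engine would keep every module
but replace the system layer.

# Numerical choices and degenerate inputs

Log-sum-exp stabilization throughout the path variables and WHAM; frames must
be label-comparable before any metric is evaluated; superposition rejects
collinear/coincident point sets; identical adjacent path frames, zero-length
trajectories, empty histogram supports, non-monotone schedules and mixed
temperatures are hard errors. The `mid` mutant's near-zero shift and the tie
between symmetric two-channel gates are resolved by construction, not by
tie-break heuristics; the minimax tie between equal-saddle channels returns
the first saddle value encountered in energy order (both are equal by
construction). Problem sizes in the shipped tests (window counts, steps per
window, bootstrap replicates, refinement iterations) are chosen as the
smallest sizes at which the statistical tolerances stated in the tests hold
with comfortable margins on a single core.

# Known limitations

- The aligned-metric gradient omits rotation derivatives (exact only at the
  superposition optimum) — standard practice, but it makes the aligned
  gradients approximate under strong weighting asymmetries.
- Binned WHAM has the usual O(bin-width²) discretization bias near sharp
  curvature; the shipped bin counts keep it well below the bootstrap error.
- The block-bootstrap error is a substitute for whatever estimator a given
  published study used when unstated; it quantifies sampling noise, not
  discretization or model bias.
- The refinement's lowest-work replicate selection assumes the work barrier
  ranks routes correctly on average; with a single replicate per iteration it
  degenerates to plain iteration and can stall in the higher channel.
- Abstract surfaces use single-point frames, so the aligned metric and
  mass-weighted superposition are exercised only by the molecular-frame code
  paths and their tests.
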