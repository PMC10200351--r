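---
title: "Partial graph transformation for ill-conditioned kinetic transition networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial graph transformation for ill-conditioned kinetic transition networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ktnreduce)
```

## The problem

Kinetic transition networks (KTNs) represent a system's dynamics as a
continuous-time Markov chain over discrete states — typically potential- or
free-energy minima — connected by transition rates. When the landscape has
deep metastable basins, the ratio between the fastest intra-basin rates and
the slowest inter-basin rates can span tens of orders of magnitude. Such
chains are *ill-conditioned*: eigendecompositions used to compute
first-passage time (FPT) distributions lose all precision, and standard
kinetic Monte Carlo (kMC) trajectories flicker inside basins essentially
forever before escaping.

`ktnreduce` attacks this by *partial graph transformation* (GT): states are
eliminated one at a time (or in blocks), and the branching probabilities
and waiting times of the retained states are renormalized so that
absorption probabilities and mean first-passage times (MFPTs) between
retained states are **exactly** preserved. Retaining, per community, the
boundary nodes (through which all inter-community flux passes) plus the
node of maximal stationary probability keeps the full FPT *distribution*
accurate in the metastable regime, while shrinking the state space by an
order of magnitude.

## Model and notation

A CTMC on $n$ states is specified by the rate matrix $K$ with
$K_{ij} \ge 0$ the rate $j \to i$ (column convention). Derived quantities:

* waiting times $\tau_j = 1 / \sum_{\gamma \ne j} K_{\gamma j}$;
* the column-stochastic branching matrix $B = K D^{-1}$,
  $B_{ij} = K_{ij}\tau_j$, the jump-chain probabilities;
* the generator $Q = K - D$ with $D_{jj} = 1/\tau_j$, so columns of $Q$
  sum to zero and $\mathrm{d}P/\mathrm{d}t = QP$ conserves probability;
* the stationary distribution $\pi$ with $Q\pi = 0$.

We assume detailed balance, $K_{ji}\pi_i = K_{ij}\pi_j$, throughout the
reduction theory; `check_detailed_balance()` measures the maximum relative
flux imbalance and the `reversible` flag requires it below $10^{-10}$.

### Graph transformation

Eliminating a single state $z$ renormalizes the retained states as
$$B'_{ij} = B_{ij} + \frac{B_{iz} B_{zj}}{1 - B_{zz}}, \qquad
  \tau'_i = \tau_i + \frac{\tau_z B_{zi}}{1 - B_{zz}},$$
and a set $Z$ can be removed at once through the Green's matrix
$G_Z = [I_Z - B_{ZZ}]^{-1}$:
$$B^Z = B_{\Omega\Omega} + B_{\Omega Z} G_Z B_{Z\Omega}, \qquad
  \tau^Z = \tau_\Omega + \tau_Z G_Z B_{Z\Omega}.$$
Two numerical safeguards matter in the ill-conditioned regime:

1. $1 - B_{zz}$ is always accumulated as $\sum_{\gamma \ne z} B_{\gamma z}$
   — a sum of non-negative terms of similar magnitude — never by
   subtraction from 1, so no catastrophic cancellation occurs even when
   $B_{zz} \to 1$.
2. Before a block solve, the reciprocal condition number of $I_Z - B_{ZZ}$
   is estimated (LAPACK 1-norm estimator via `rcond()`); above the
   configurable threshold (default $10^{10}$) the block is processed by
   the robust state-by-state formula instead.

The renormalized generator is $Q^Z = [B^Z - I]D^Z$ with
$[D^Z]_{ii} = 1/\tau^Z_i$, and the stationary distribution reweights by
the waiting-time inflation, $\pi^Z_i = \pi_i \tau^Z_i / \tau_i$, an
identity whose unit sum `renormalized_stationary()` asserts to $10^{-10}$
(a violation indicates an upstream bug, not something to renormalize
away). Self-loops $B^Z_{ii} > 0$ are genuine objects of the reduced chain:
the generator consumes them and the samplers fold them analytically, so
they are retained rather than renormalized out.

### What is retained

For a community partition $C$, the retained set is
$\bigcup_X \partial X \cup \{b_0(X)\}$: the boundary nodes (those with an
edge into another community) and the maximum-$\pi$ node of each community,
ties broken by smallest index. Boundary nodes mediate all inter-community
flux — the MFPT into a community equals the MFPT to its boundary — so
retaining them preserves inter-community MFPTs in both directions, and a
delta initial distribution at $b_0$ is preserved verbatim. Elimination
proceeds in ascending order of stationary probability (fast, insignificant
states first), in blocks of 64 by default; the result is
order-independent (verified to $10^{-10}$), so the order is purely a
numerical-robustness and fill-in heuristic.

## Spectral first-passage analysis

For target set $A$, the subsystem generator $Q_S$ over $S = \Omega
\setminus A$ gives the FPT density
$$p(t) = \sum_\ell \lambda_\ell c_\ell e^{-\lambda_\ell t}, \qquad
  c_\ell = \mathbf{1}_S\, (w^R_\ell \otimes w^L_\ell)\, P_S(0),$$
with $\{-\lambda_\ell\}$ the spectrum of $Q_S$. For reversible chains the
eigenproblem is solved on the symmetric similarity transform
$\Pi^{-1/2} Q_S \Pi^{1/2}$ ($\Pi = \mathrm{diag}\,\pi_S$), which
guarantees a real spectrum, orthonormal vectors and biorthonormal mapped
left/right eigenvectors; a general solver with explicit inversion is the
non-reversible fallback. The log-time density
$P(y) = \sum_\ell \lambda_\ell e^{y - \lambda_\ell e^y} c_\ell$,
$y = \ln t$, is the natural object for visualizing multi-peaked kinetics.

Completeness forces $\sum_\ell c_\ell = 1$. In ill-conditioned subsystems
the $c_\ell$ are differences of huge numbers; rather than returning
garbage, `fpt_distribution()` aborts when $|\sum c_\ell - 1| > 10^{-6}$ or
any $|c_\ell| > 10^3$ and recommends the GT route, which is immune. The
mean is always computed by the robust linear solve
$\tau_S G_S P_S(0)$ and cross-checked against the spectral
$\sum_\ell c_\ell/\lambda_\ell$.

Metastability of a node set $X$ is quantified via the two smallest
reversed-sign eigenvalues of $Q_X$: the mixing time
$\tau_m = 1/(\lambda_1 - \lambda_0)$ and the product $\lambda_0\tau_m$.
When $\lambda_0 \tau_m \ll 1$, any initial distribution that does not leak
before $\tau_m$ relaxes to the quasi-stationary distribution (the dominant
right eigenvector) before escaping, which is why escape statistics become
insensitive to the initial condition — the justification for discarding
community interiors.

### Initial distributions

Four standard initializations are provided for escape/first-passage
studies: `Boltz` (local equilibrium $\pi$ restricted to the community),
`Min` (delta at $b_0$), `Uni` (uniform), and `Mix` (uniform evolved under
the community subsystem for one mixing time, then renormalized; downstream
distributions carry the $\tau_m$ shift). `Uni` deliberately places weight
on boundary nodes and produces a short-time escape transient; `Mix`
interpolates back toward the quasi-stationary behaviour.

A caution on comparing initializations: the *linear-time* densities of
`Boltz` and `Min` always differ at $t < \tau_m$ (an interior delta has
zero initial escape flux; local equilibrium does not), by an amount
comparable to the overall peak $\sim \lambda_0$. The metastable-limit
insensitivity shows up in the log-time density and in the CDF/mean, where
the pre-mixing transient carries $O(\lambda_0 \tau_m)$ weight; the tests
compare those objects.

## Stochastic sampling

`kmc_trajectory()` is rejection-free kMC: jumps drawn from columns of $B$,
exponential sojourns with mean $\tau$. On reduced networks, self-loops are
folded analytically — a state with self-loop probability $s$ is left after
a geometric number of visits, so the sojourn is drawn as a single
exponential with mean $\tau/(1-s)$, preserving the sojourn distribution
exactly while avoiding iterated self-jumps. Ensembles seed each trajectory
as `seed + i`, making them reproducible and trivially parallelizable.

`basin_escape_sample()` treats one basin escape as an absorbing Markov
chain: all community states except the current one are GT-eliminated, the
residual self-loop is renormalized away, the exit node is drawn from the
exact absorption probabilities, and the escape time from an exponential
whose mean is the renormalized waiting time — the *exact* mean escape
time, by the GT invariant. The single-exponential shape is an
approximation that becomes exact in the metastable limit; higher moments
of the escape time are therefore approximate, which is documented
behaviour, not a bug. The full kinetic-path-sampling reverse
randomization machinery is intentionally out of scope.

## The synthetic landscape generator

`generate_landscape()` builds the benchmark family used throughout the
tests: wells on a lattice (default $3\times3$) with 110 states each
(~1000 nodes), node energies = well base + quadratic confinement + noise,
intra-well edges from a jittered nearest-pair rule on top of a spanning
tree (mean degree targeted at 8.7; empirical degree variance/mean stays
near 1, i.e. Poisson-like), and inter-well edges between the closest node
pairs of adjacent wells — those endpoints are the ground-truth boundary
nodes. Every edge carries a shared transition-state energy
$E^\dagger = \max(E_i, E_j) + b$ with $b$ drawn exponentially
(`intra_barrier_scale` / `inter_barrier_scale`, minimums `barrier_min` /
`inter_barrier_min`), so Arrhenius rates
$K_{ij} = \nu e^{-(E^\dagger - E_j)/T}$ satisfy detailed balance with
$\pi \propto e^{-E/T}$ *algebraically*. Rates are generated and stored in
log space; nothing underflows at large $b/T$.

The explicit `inter_barrier_min` floor exists because an exponential draw
alone cannot guarantee metastable communities: the slowest escape
eigenvalue is controlled by the *lowest* inter-community barrier. The
four-community test fixture (2×2 wells, 15 nodes each,
`inter_barrier_min = 4.5`) was calibrated once so that every community
satisfies $\lambda_0\tau_m \le 10^{-2}$ across seeds; the tests assert
that regime before making metastable-limit claims.

What the generator does **not** emulate: real KTNs have fat-tailed degree
distributions from low-barrier funnels, correlated barrier heights,
broken-detailed-balance measurement noise, and community structure that no
clustering recovers cleanly. Passing tests on this generator demonstrates
the *exact* GT invariants (which hold for any reversible chain) and the
metastable-limit approximations under controlled conditions; they do not
certify accuracy on a poorly partitioned real network at high temperature,
where the paper-level theory itself predicts degradation.

## Effective free energies and disconnectivity graphs

A reduced network is summarized thermodynamically by
$f_\omega = -k_BT\ln\pi^Z_\omega$ and, per edge, a transition-state free
energy defined to reproduce the renormalized rate through
$k = (k_BT/h)\,e^{-(f^\dagger - f_\omega)/k_BT}$ (units $k_B = h = 1$):
$$f^\dagger_{\omega\omega'} = f_{\omega'}
  - k_BT \ln\!\big([B^Z]_{\omega\omega'} / [\tau^Z]_{\omega'}\big)
  + k_BT \ln(k_BT/h).$$
The two directional forms of $f^\dagger$ coincide exactly iff the reduced
chain satisfies detailed balance with $\pi^Z$; `effective_free_energies()`
computes both and warns on disagreement, and
`rates_from_free_energies()` closes the round trip (asserted to
$10^{-10}$ in the tests). Note the *ratio* $B/\tau$ in the logarithm: that
ratio is the rate constant, and only this form makes the round trip an
identity.

`disconnectivity_tree()` sweeps an ascending level grid (default 50
uniform levels spanning $[\min f, \max f^\dagger]$): superbasins at a
threshold are connected components of the sub-threshold edge set, and
merges between levels create internal nodes. Leaf order is deterministic
(larger basin first, then smallest id). Uniform level spacing is a
pragmatic choice; continuous-level graphs convey the same structure.
`monotonic_sequence_minima()` restricts to minima with no lower direct
neighbour (ties broken by id), which isolates one representative per
monotonic-sequence basin.

## Numerical choices, degenerate inputs, limitations

* Dense linear algebra throughout. The intended scale is $10^2$–$10^4$
  states; GT fill-in densifies reduced models regardless, so a sparse
  path would buy little here and is not provided.
* Internal indices are 1-based contiguous (natural in R); file ids are
  arbitrary labels, mapped and preserved in all outputs.
* File rates can be exchanged in a log dialect (`log_rate_ij` columns, or
  the three-file log-weight convention) so deeply metastable models
  survive serialization.
* Stationary distributions come from Boltzmann weights in log space when
  energies are available (log-sum-exp, no underflow), else from a bordered
  null-space solve; ergodicity failures (disconnection, degenerate zero
  eigenvalue) are errors, not warnings.
* Eliminating an isolated node, an absorbing block, an empty community, a
  start node outside its community, or requesting `Mix` on a community
  whose eigensystem has lost precision are all hard errors with
  actionable messages.
* Problem sizes in the tests: random reversible networks of 8–50 nodes
  for the exactness properties (50 instances), the 60-node four-community
  fixture for metastable-regime fidelity (spectral + two 1000-trajectory
  ensembles), and the ~1000-node nine-community model for generator
  statistics and end-to-end reduction. These sizes keep the full suite
  around a minute while exercising every code path at the scale the
  method targets.

## Reproducing the headline numbers

`scripts/acceptance.R --seed S --out results/acceptance.json` regenerates
every quantity discussed here from scratch: GT exactness residuals
(MFPT preservation, order invariance, stationary identity), the
three-state chain's closed-form solution, kMC-vs-spectral agreement
(Kolmogorov–Smirnov), full-vs-reduced FPT and occupation fidelity on the
metastable fixture, the free-energy round trip, and the nine-community
reduction summary.
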