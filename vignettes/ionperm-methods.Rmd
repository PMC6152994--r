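---
title: "Methods: the toy channel and its permeation analysis chain"
author: "ionperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the toy channel and its permeation analysis chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionperm)
```

# The scientific problem

Voltage-gated sodium channels select Na$^+$ over K$^+$ at a narrow
selectivity filter whose signature residues — an inner ring containing two
carboxylates and a lysine, and an outer vestibular ring of four
carboxylates — are flexible and act collectively. Mechanistic simulation
studies of such filters analyze equilibrium trajectories through a standard
chain of statistics: occupancy-conditioned multi-ion free-energy landscapes
obtained by Boltzmann inversion, classification of ion/carboxylate binding
complexes with cutoffs taken from radial distribution functions,
permeation-event counting, coordination numbers, and alchemical free-energy
differences between ion species bound in representative complexes.

`ionperm` packages that analysis chain together with a coarse-grained
*toy channel* whose equilibrium trajectories exhibit the qualitative
phenomenology the chain is meant to measure — multi-ion occupancy,
carboxylate complexation that favors the smaller cation, a positively
charged lysine bead that sits in the permeation pathway, and knock-on-like
ion exchanges — at desk scale. The toy model is a test bed for the
analysis code, not a quantitative model of any real channel: all-atom
energetics, explicit water, the membrane and voltage are deliberately
absent, and no absolute barrier height of a real system is reproduced.

# The toy-channel Hamiltonian

All energies are in kcal/mol, lengths in Å, charges in units of e.
The particle roster contains mobile cations, eight tethered "carboxylate"
beads in two rings, one "lysine" bead, and a pinned, non-interacting
reference bead that defines the coordinate origin for the analysis.

The potential is a sum of five terms:

* **Screened Coulomb**, $k_C q_i q_j/(\varepsilon r_{ij})$ with
  $k_C = 332.0636$ kcal·Å/mol/e². A single uniform relative permittivity
  $\varepsilon$ stands in for all solvent and protein screening. The
  default is $\varepsilon = 20$, a standard effective value for a
  protein–water interface. With a much weaker interaction (e.g.
  $\varepsilon = 40$) the per-contact affinity difference between the two
  ion species (~0.7 kcal/mol) is smaller than the effect of the
  species-specific classification cutoffs, and the generator can no longer
  realize the qualitative Na-over-K asymmetry of tight complexes it is
  supposed to emulate; $\varepsilon = 20$ yields that asymmetry robustly
  while keeping the filter dynamic.
* **Soft-core repulsion** $A_{ij}(\sigma_{ij}/r)^{12}$ with
  $\sigma_{ij} = R_i + R_j$ and $A_{ij} = \sqrt{A_i A_j}$. An ion's contact
  radius is defined as its species parameter $\sigma$ (the ion–carboxylate
  contact distance) minus the carboxylate bead radius (1.4 Å), so
  ion–carboxylate contact occurs at exactly $\sigma$. Defaults
  $\sigma_\mathrm{Na} = 2.3$ Å and $\sigma_\mathrm{K} = 2.9$ Å give
  ion–carboxylate well depths of about $-6.3$ and $-4.9$ kcal/mol — the
  smaller cation binds carboxylates more strongly, the single microscopic
  asymmetry from which all selectivity observables of the toy derive.
* **Harmonic tethers** holding the carboxylate beads at their ring
  anchors. The default stiffness of 0.3 kcal/mol/Å² (RMS displacement
  ≈ 1.5 Å at the default temperature) makes the rings *flexible*:
  carboxylates can reach toward ions and jointly coordinate an ion pair.
  This flexibility is essential — with stiff tethers, two ions always
  prefer separate rings and tight two-ion/multi-carboxylate complexes
  essentially never form.
* **The lysine bead**: lateral harmonic restraint about the pore axis and
  an axial quartic double-well with minima at $z_\mathrm{up} = +2$ Å and
  $z_\mathrm{down} = -2$ Å separated by a 2 kcal/mol barrier — a two-state
  rotamer that can either participate in binding near the inner ring or
  swing down toward the cavity. Charge $+1$ e.
* **Radial confinement**: a half-harmonic wall beyond a piecewise-linear
  pore-radius profile (4 Å radius through the filter, opening to 8 Å
  reservoirs beyond $|z| \approx 15$ Å), applied to ions and the lysine
  bead; box walls reflect.

Geometry: the inner ring (4 beads, charge $-1$ each) is anchored at
$z = 5$ Å on a 2.5 Å circle; the outer ring at $z = 10$ Å on a 3.0 Å
circle, staggered by 45°. With tether softness included the charged
residues span roughly 10 Å of the pore axis, an asymmetric, flexible
charge cloud rather than two sharp sites. Ions enter from the $+z$
(extracellular) side; the cavity lies below the lysine.

An optional external axial field on ions — a quartic double-well or a
piecewise-constant 21-bin profile — exists purely for validation
experiments (parameter recovery and exact-enumeration checks).

Pairs closer than 0.1 Å are evaluated at 0.1 Å, so the energy is finite
for any configuration; samplers never see the singularity.

# Samplers

Two samplers share the Hamiltonian:

* **Overdamped Langevin** (Euler–Maruyama), fixed timestep (default
  0.02 ps), isotropic diffusion coefficient $D$ (default 0.2 Å²/ps),
  reflecting box walls. For *equilibrium* observables $D$ and the timestep
  only set how fast configuration space is explored, not the sampled
  distribution (up to the $O(\Delta t)$ discretization error, kept ≪ kBT
  per step at the defaults); validation experiments therefore use larger
  $D$ freely to accelerate barrier crossing.
* **Metropolis Monte Carlo** with single-particle Gaussian displacement
  proposals (default SD 0.3 Å). Optionally a fraction `p_big` of proposals
  uses a larger SD; the mixture is still symmetric, so detailed balance is
  preserved, and the large moves decorrelate hops between degenerate
  coordination basins. Moves leaving the box (or the support of a
  piecewise profile) are rejected.

Temperature enters only through $k_BT$; the default is 323.15 K
($k_BT = 0.642$ kcal/mol), chosen as a fluid-membrane simulation
temperature; it is configurable everywhere because no single value is
canonical for this kind of model.

Reproducibility: every stochastic routine consumes the R RNG after a
`set.seed(seed)` taken from its configuration, so a seed reproduces
trajectories bit-identically. The pipeline derives per-stage seeds by
hashing the stage name with the master seed, so stages are independently
reproducible.

# The analysis chain

## Axial states and PMFs

Per frame, the $z$ positions of ions strictly inside the channel region
($-15 < z < 15$ Å, measured relative to the reference/scaffold center of
mass) are rank-sorted: $z_1 \le z_2 \le z_3$ with $z_1$ the lower-most
ion, plus the centroids $z_{12}, z_{23}$ and the lysine position
$z_\mathrm{Lys}$. Rank coordinates deliberately discard ion identity, so
permuting ion labels leaves every PMF bit-identical. The strict-interior
boundary rule avoids double-counting frames during exchange at the
boundary.

The free energy is the Boltzmann inversion of the occupancy-conditioned
histogram, $W = -k_BT\,\ln\rho + C$, with $C$ fixed by setting the sampled
minimum to zero. The default bin width is 0.5 Å. Bins with zero counts are
masked (`NA`), never given infinite arithmetic values. Per-bin standard
errors come from a moving-block bootstrap over frames (default 200 blocks
of 200 saved frames), which respects serial correlation to the extent the
block exceeds the correlation time.

## Minimum-free-energy paths

The "minimum free energy path" is implemented as the *minimax bottleneck
path*: among all paths from the start region to the end region across
sampled bins (adjacency in 1D, 8-neighbor in 2D; masked bins are walls),
the one minimizing the highest $W$ encountered. The barrier is that
bottleneck height minus the minimum $W$ in the start region. This is a
documented algorithmic choice — visual path tracing on published maps is
not reproducible — and is validated against an independent
threshold-connectivity search on randomized grids.

## Complex classification

Binding cutoffs follow the radial-distribution-function convention: the
first minimum of the smoothed $g(r)$ after its first peak.
Species-specific defaults are ion–ion 4.7 Å / ion–carboxylate 3.8 Å for
the Na-like species and 5.5 / 4.2 Å for the K-like species. Each frame
receives exactly one label, with precedence
`tight-multi > ion+Lys > multi > single > unbound` (ordered by
specificity):

* **tight-multi** — two channel ions within the ion–ion cutoff *jointly*
  coordinated by ≥ 2 carboxylates, each within the ion–carboxylate cutoff
  of **both** ions. The bridging ("both") reading operationalizes a
  collectively bound cluster; the looser "either" reading turns out to be
  dominated by a pure geometry artifact in ring-shaped sites — the larger
  K-like pair cutoff (5.5 Å) swallows two ions bound on opposite sides of
  a ring (~5 Å apart) that share no coordination at all, inverting the
  species contrast for reasons unrelated to affinity.
* **ion+Lys** — the lysine bead and an ion each within the
  ion–carboxylate cutoff of ≥ 2 shared carboxylates: the joint
  ion–lysine–carboxylate complex.
* **multi** / **single** — some ion bound to ≥ 2 / exactly 1 carboxylate.
* **unbound** — no contact.

For a mixed-species pair the ion–ion cutoff is the mean of the two species
cutoffs. Summary tables report state fractions by occupancy class,
per-carboxylate and per-ring involvement under *both* normalizations (all
frames and bound frames), since published involvement percentages often
leave the denominator unstated.

## Permeation events

An event is a complete transit between two planes (two-plane hysteresis):
an ion must go from above the upper plane to below the lower plane
(inward) or the reverse. Single-plane recrossings are never counted; a
saved-frame stride that jumps both planes counts once. Default planes are
the mean lysine position ± 4 Å ("past the lysine"); for lysine-free
systems the channel boundaries are used. Net flux satisfies an exact
bookkeeping identity (first/last extreme side per ion) that the tests
assert on random walks.

## Alchemical selectivity (FEP/BAR)

Relative site binding free energies are computed by staged transformation
of the ion's short-range parameters ($\sigma$, amplitude; the charge stays
+1 e, so no soft-core scheme is needed) across 12 equally spaced λ
windows, with the ion held at the site by a spherical flat-bottom
restraint (radius 4 Å, wall 10 kcal/mol/Å²). Forward and reverse work
samples between neighboring windows feed either exponential averaging
(EXP) or the Bennett acceptance ratio (BAR, the default — it uses both
directions and has uniformly lower variance).

Each window is sampled by several independent Metropolis chains (default
4). The reported standard error combines a window-wise moving-block
bootstrap with the between-replica spread in quadrature; the replicate
term is essential because the site has degenerate coordination basins
whose interconversion is slower than a single window, a variance
contribution invisible to any within-chain estimator. The combination is
deliberately conservative (the components partially overlap).

Because sites are small, the package also carries an *exact oracle*:
direct 3D grid quadrature of both partition functions for any site with
one mobile particle, plus a quadrature restraint-release correction into a
declared standard volume (releasing into an unbounded volume is an error).
Tests require BAR to agree with quadrature within 2 SE, cycles to close,
and corrections to match the closed-form Gaussian-integral results.

In the toy, the bulk reference leg is exactly zero (an isolated ion's
partition function does not depend on $\sigma$), so
$\Delta\Delta G_\mathrm{site-bulk}$ equals the site leg. With the default
parameters the two-carboxylate site favors the Na-like species by
≈ 2 kcal/mol — same sign as, and deliberately scaled down from, all-atom
results for real filters.

## Structural metrics

RMSD/RMSF use orthogonal-Procrustes (Kabsch) superposition, globally or
per declared subunit; per-subunit fitting removes independent rigid-body
subunit motions, which otherwise inflate RMSF. Density maps are counts per
voxel per frame; the screened-Coulomb potential map is a time-averaged
qualitative analog (uniform dielectric, singularities capped at 1 Å), not
a Poisson–Boltzmann solution.

# What the generator emulates — and what it does not

Emulated: multi-ion occupancy of a flexible, asymmetric two-ring filter;
species-dependent carboxylate affinity (Na-like > K-like) producing more
frequent tight multi-ion/multi-carboxylate complexes and a Na-favoring
site ΔΔG; a charged lysine bead with up/down rotamer states in the
permeation pathway; knock-on-like exchanges among ions.

Not emulated: explicit hydration shells and dehydration barriers, protein
backbone rearrangement, membrane voltage and genuine steady-state flux,
absolute barrier heights or event rates of any real channel. Consequently,
passing tests demonstrate the *analysis machinery* is correct and the
generator's qualitative physics is as designed; they say nothing
quantitative about real channels, and published values (occupancy means,
event counts, kcal/mol differences) are not reproduction targets at desk
scale.

# Validation experiments and problem sizes

The package validates itself with fixed-seed experiments sized to run on a
laptop core in seconds to tens of seconds:

* *PMF parameter recovery*: one ion in a prescribed two-well axial
  potential (wells at ±6 Å, 2.0 kcal/mol central barrier), $10^6$ Langevin
  steps at $\Delta t = 0.05$ ps and $D = 1.5$ Å²/ps (≈ 260 well
  transitions); the Boltzmann-inverted PMF must match the input within
  0.15 kcal/mol RMS over bins with ≥ 100 counts, after removing the free
  offset constant.
* *Sampler exactness*: Metropolis sampling of a 21-bin piecewise-constant
  profile, thinned to near-independence (stride 200 with 30%
  large-displacement proposals), χ²-tested against exact enumeration over
  20 seeds; the per-seed p-values must behave like a correct null (≥ 18 of
  20 above 0.01) and the pooled χ² statistic (df = 400) must not reject.
  Requiring *all* 20 p-values above 0.01 would fail ≈ 18% of the time for
  a perfectly correct sampler, so the pooled form is used.
* *Classifier equivalence*: $10^4$ random mixed-species frames classified
  identically by the pipeline classifier and an independently coded
  brute-force classifier, plus the partition property.
* *Event ground truth*: a scripted 3-ion fixture with 7 known transits,
  and hysteresis-gap monotonicity across 5 widths.
* *FEP*: BAR vs quadrature within 2 SE, cycle closure, closed-form
  restraint corrections.
* *Directional selectivity*: tight-multi fractions from 2 × 75 000-sweep
  Metropolis runs per species (Na ≈ 3%, K ≈ 2%; the sign, not the
  magnitude, is the claim) and the positive site ΔΔG.

# Known limitations

* The uniform dielectric makes all electrostatics mean-field; ion–ion
  correlations mediated by solvent structure are absent.
* Langevin time is nominal: diffusion coefficients are sampling
  parameters, so event counts per nanosecond are not physical rates.
* The minimax path is one defensible definition of a conduction pathway;
  flux-weighted transition-path definitions would differ on rugged
  landscapes.
* Trajectory import supports PDB topology + DCD coordinates (via
  `bio3d`) and the native labeled-XYZ format; XTC and HDF5 are not
  supported in this implementation.
* `n_ions` per species is fixed during a run (no grand-canonical
  exchange); reservoirs are sized so ions can leave the filter region.
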