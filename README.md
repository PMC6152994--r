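# ionperm

Analysis toolkit for **selective ion permeation through a sodium-channel
selectivity filter**, built around a coarse-grained Brownian-dynamics toy
channel.

Mechanistic studies of Na⁺/K⁺ selectivity analyze equilibrium trajectories
of a filter whose carboxylate rings and signature lysine act collectively.
The statistics involved are standard but easy to get subtly wrong:
occupancy-conditioned multi-ion potentials of mean force, RDF-derived
binding cutoffs, complex-state classification, permeation-event counting,
coordination numbers, and alchemical (FEP) selectivity estimates. `ionperm`
implements that full chain for R, together with a toy channel — two rings
of tethered carboxylate beads, a two-rotamer lysine plug, mobile cations
with species-dependent carboxylate affinity — whose trajectories exhibit
the qualitative phenomenology the chain is meant to measure, at desk scale.

At the core:

* **Boltzmann inversion.** For rank-sorted axial ion coordinates
  (z₁ ≤ z₂ ≤ z₃, centroids z₁₂, z₂₃, and z_Lys, relative to the scaffold
  center of mass), the free energy is `W({z}) = −kBT ln ρ({z}) + C`, with
  ρ the unbiased histogram conditioned on pore occupancy, C fixed by a
  min-zero convention, and moving-block bootstrap errors. Barriers come
  from the minimax (bottleneck) path across the sampled grid.
* **Complex classification.** Species-specific cutoffs (ion–ion 4.7 Å /
  ion–carboxylate 3.8 Å for Na-like, 5.5 / 4.2 Å for K-like, the
  first-minimum-of-g(r) convention) drive a per-frame partition into
  `tight-multi > ion+Lys > multi > single > unbound`.
* **Event counting** with two-plane hysteresis around the lysine.
* **FEP/BAR.** Staged σ-interpolation of a restrained site ion, Bennett
  acceptance ratio with replicate-chain error bars, exact quadrature
  oracles, and restraint-release corrections.
* **Structure metrics.** Kabsch RMSD/RMSF (global or per-subunit), ion
  density maps, screened-Coulomb potential maps.

Trajectories come from the bundled samplers (overdamped Langevin or
Metropolis Monte Carlo; bit-reproducible under a seed) or from standard
MD files (PDB topology + DCD via `bio3d`, or the native labeled-XYZ
format) with role assignment by a selection spec.

## Worked example

Sample the default two-ring filter with two Na-like ions and run the
analysis chain:

```r
library(ionperm)
m   <- build_model()                      # default toy channel
cfg <- simulation_config(c(Na = 2), n_steps = 50000, save_stride = 10,
                         seed = 42, sampler = "metropolis")
tr  <- run_sampler(m, cfg)

st <- axial_states(tr, equil_discard = 0.1)
occupancy_distribution(st)$mean           # 2.00 — both ions stay in the filter

cls <- classify_frames(tr)
round(100 * table(cls$state) / nrow(cls), 1)
#> ion+Lys  multi  single  tight-multi  unbound
#>     4.3   80.9    11.8          2.9      0.1
complex_summary(cls)$ring_involvement["all_frames", ]
#> inner  outer   both
#> 0.805  0.961  0.767

g <- pmf(st, "z1", occupancy = 2)         # 1D PMF of the lower ion
site <- fep_site()                        # two-carboxylate binding site
site_dG_quadrature(m, site, "Na", "K")    # 1.97 kcal/mol
```

Reading: the ions reside in the filter essentially all the time, usually
bound to several carboxylates at once; both rings participate in binding
(cooperatively in ~77% of frames); tight two-ion/multi-carboxylate
clusters form ~3% of the time for the Na-like species (vs ~2% for the
K-like species under identical conditions — the toy's selectivity
signature). Converting the site ion from Na-like to K-like costs
+1.97 kcal/mol relative to bulk, i.e. the carboxylate site prefers the
smaller cation.

A command-line front end is installed with the package
(`exec/ionperm`): `ionperm simulate | pmf | complexes | events | fep | run`.

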