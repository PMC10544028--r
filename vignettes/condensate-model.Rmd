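---
title: "A coarse-grained model of peptide condensates with switchable cation-pi interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained model of peptide condensates with switchable cation-pi interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgphase)
```

## The scientific problem

Many intrinsically disordered proteins (IDPs) demix from solution into
liquid-like biomolecular condensates. Three interaction types dominate in
sequences built from charged and aromatic residues: screened charge-charge
electrostatics, aromatic pi-pi stacking, and cation-pi attraction between
positively charged and aromatic residues. Because cation-pi contacts couple
the charge content of a sequence to its aromatic content, there is a
trade-off: salt that weakens electrostatics frees positive residues to form
cation-pi contacts; charge clustering (high kappa) keeps them engaged in
salt bridges instead.

`cgphase` implements a minimal bead-per-residue model in which this
trade-off can be switched on and off: two otherwise identical force fields
that *include* or *exclude* the cation-pi term. Comparing paired
simulations isolates the contribution of cation-pi interactions to
condensate stability (critical temperature, density), energetics
(per-polymer interchain energy) and dynamics (internal diffusivity, shape).

## The model

Each residue is one bead of class `POS` (+1e), `NEG` (-1e) or `ARO`
(aromatic, neutral); natural sequences classified from the 20-letter
alphabet additionally carry inert `NEU` beads. The potential energy is

* **Electrostatics** (all charged pairs): Debye-Hueckel,
  `E = K q_i q_j B(kappa_D) exp(-kappa_D r) / (eps r)`, with
  `K = 332 kcal A/(mol e^2)`, solvent dielectric `eps = 80`, and
  `B(kappa_D) = exp(kappa_D a)/(1 + kappa_D a)` the finite-ion-size factor
  (ion radius `a = 4` A). The inverse screening length follows the standard
  aqueous Poisson-Boltzmann relation, `kappa_D ∝ sqrt(I / (eps T))`; at
  300 K and `eps = 80` the screening length is about `3.08/sqrt(I[M])` A.
  `B(0) = 1` recovers the bare Coulomb potential.
* **Dispersion** (pi-pi between ARO beads; cation-pi between ARO and POS
  beads when the model variant includes it): a 12-6 potential written as
  `E = eps_d [ (sigma/r)^12 - 2 (sigma/r)^6 ]`, so that `sigma = 7` A is
  the *optimal contact distance* and `eps_d` the well depth
  (0.2 kcal/mol for both terms by default; a 0.3 kcal/mol cation-pi
  variant is supported). NEG-ARO pairs get no attractive term.
* **Excluded volume** (all nonbonded pairs):
  `E = eps_rep (sigma_rep / r)^12` with `sigma_rep = 4` A, truncated at
  `2 sigma_rep`. The prefactor `eps_rep = 0.2` kcal/mol is a declared
  default chosen on the energy scale of the dispersion terms; only the
  steep core matters.
* **Bonded terms**: harmonic bonds `E = k_b (r - r0)^2`
  (`r0 = 3.8` A, `k_b = 20 kcal/(mol A^2)`) and a weak harmonic angle term
  (`theta0 = 2.12` rad, `k = 2 kcal/(mol rad^2)`); no dihedrals — the
  chains are fully flexible. 1-2 and 1-3 pairs are excluded from nonbonded
  terms. The bonded constants are declared defaults (conventional
  coarse-grained IDP values); they are configurable and the force-field
  config file records them.

Dispersion and electrostatics are truncated and energy-shifted at
`2.5 sigma` and `max(35 A, 4 Debye lengths)` (capped at half the box).
The scalar `dispersion_pair_energy()` defaults to the unshifted form so
that its minimum is exactly `-eps_d` at `sigma`; the engine always applies
the shift.

## Dynamics

`langevin_run()` integrates underdamped Langevin dynamics with the BAOAB
splitting, unit bead mass, in internal units (kcal/mol, Angstrom; the time
unit is `sqrt(mass A^2/(kcal/mol))`). The default timestep 0.1 and friction
0.1 per time unit keep the stiffest bond mode (`omega dt ~ 0.6`) stable;
quenched many-chain runs in this package use `dt = 0.05`. The noise stream
is an internal counter-based PRNG seeded from the protocol seed, so
trajectories are reproducible bit-for-bit on a given platform regardless of
R's RNG state. Coordinates are propagated unwrapped (displacement
statistics stay valid); the minimum-image convention handles periodic
interactions. Pair interactions go through a Verlet neighbour list with a
2 A skin, rebuilt on a displacement threshold; by contract its forces are
identical to the all-pairs evaluation, and the test suite asserts exactly
that.

A non-finite energy aborts a run, returning the frames saved so far with a
`completed = FALSE` flag.

## Sequence metrics and design

`compute_kappa()` implements the blob-based charge-patterning coefficient:
charge asymmetry `sigma = (f+ - f-)^2/(f+ + f-)` over overlapping blobs of
5 and 6 residues (zero for uncharged blobs), each blob-size statistic
normalised by the most segregated of the six block-orderings of the
positive/negative/neutral classes, then averaged. Arrangements in which
neutral beads separate the charge blocks can be more segregated than any
block layout; the sequence's own delta then caps kappa at 1, keeping the
statistic in [0, 1]. `compute_scd()` is the distance-weighted pair sum
`(1/N) sum q_i q_j sqrt(j - i)`. Aromatic and neutral beads carry zero
charge in both.

`design_sequence()` shuffles a fixed composition by swap moves, accepting
greedily whenever the objective (`|kappa - target|`, or kappa itself for
extremisation) does not worsen; ties are broken by the seeded proposal
stream. Ten thousand proposals comfortably reach kappa below 0.03 for the
14+/14-/12-aromatic 40-mer. The designed series S1-S5 fixes compositions
(18/18/4, three times 14/14/12, 8/8/24; net charge zero throughout, so FCR
runs 0.9 to 0.4 as phi runs 0.1 to 0.6) with kappa targets 0.47, 0.36,
0.20, 0.03 and 0.21; the S3 target is a declared mid value, since only the
S2-S4 span (0.36-0.03) is pinned. Whether SCD was also constrained in the
original designs is unstated; it is computed and reported but not
optimised.

## Condensate observables

* **Clustering**: chains are linked when any interchain bead pair is
  within 9 A (about 1.3 contact distances, a declared default); condensates
  are connected components of the chain graph.
* **Phase densities**: the largest cluster's bead count over its
  occupied-voxel volume (voxel edge = contact cutoff) gives the dense
  density; the rest of the box gives the dilute density. The voxel
  estimator replaces a convex hull (no 3-D hull routine is available to the
  package) and carries a documented bias bound of 25% on planted fixtures —
  boundary voxels are partially filled, so dense densities are slightly
  underestimated at small droplet sizes.
* **Critical temperature**: least squares of
  `rho_dense - rho_dilute = A (1 - T/T_C)^beta` with `beta` frozen at
  0.325. Low-temperature points where the gap shrinks as T decreases
  (re-entrance, driven by kinetic arrest of short-range contacts) are
  trimmed automatically; a two-segment slope-change diagnostic on the dense
  branch is reported as an independent check. `delta_tc_percent()`
  normalises the inclusive-exclusive shift by the exclusive-model `T_C` —
  the reference for the "normalised" percentage is an interpretation this
  package declares openly.
* **Energy gain**: the per-chain interchain potential energy of
  condensate-resident chains, inclusive minus exclusive, at matched salt
  and matched (reduced) temperature.
* **Diffusivity**: chain centre-of-mass MSD over all time origins, linear
  fit (free intercept) on the 10-50% lag window, `D = slope/6`. With the
  residency filter only chains continuously assigned to the largest cluster
  contribute, isolating dense-phase motion.
* **Shape**: gyration-tensor eigenvalues of the condensate;
  anisotropy `(l1+l2+l3)/l_min` equals 3 for an isotropic spectrum and
  grows with elongation; degenerate (coplanar) clouds are rejected.

## Reduced-scale study design

Quantitative phase-diagram campaigns (hundreds of chains, long scans over
temperature and salt) are cluster-scale work; this package targets desk
scale. The packaged directional experiment uses 10 chains of the designed
S2-like 40-mer in a 150 A box (the same overall bead density as 100 chains
in a 300 A box), seeds a droplet by placing the chains in the central
sub-box (`placement_fraction = 0.45` — the direct-coexistence analogue of
a pre-formed dense slab), and quenches to 120 K at 0.06 M salt, well below
both variants' critical temperatures. Initial configurations for quenched
runs are grown with a 6.5 A nonbonded separation floor so that freshly
placed beads do not start on the steep inner wall of the 7 A dispersion
core. Twenty thousand steps at `dt = 0.05` with the first half discarded
suffice for the contact network to equilibrate locally. Across three seeds
the cation-pi-inclusive variant is denser and more stabilised (per-polymer
interchain energy gain of order 10 kcal/mol) in every seed — the
directional, desk-scale counterpart of the positive critical-temperature
shifts seen at full scale. Absolute `T_C` values at this scale are not
comparable to full-scale results and are not asserted anywhere.

## The synthetic IDR generator

`synthesize_idr_set()` emulates two observed regimes of disordered
regions: a proteome-wide regime (`f+ = 0.13 - 0.28 phi`,
`f- = 0.145 - 0.13 phi`: both charge types deplete mildly and similarly as
aromatics enrich) and an LLPS-prone regime (`f+ = 0.13 - 0.39 phi`,
`f- = 0.17 - 1.05 phi`: much steeper loss of negative charge, hence a net
positive charge that grows with aromatic content). Per record it draws phi
uniformly — on [0, 0.30] for the proteome regime and [0, 0.15] for the
LLPS regime, the bin-aligned range on which both expected fractions stay
positive — sets the aromatic count deterministically from phi, and draws
the charge counts binomially at the lines evaluated at the *realized*
aromatic fraction. That last choice matters: with fully multinomial counts
the realized phi is a noisy measure of the drawn phi and errors-in-variables
attenuates the fitted slopes by far more than their standard errors, so no
binned fit could recover the generator. Conditioning the charge draws on
the realized phi makes the stated lines hold for exactly the quantity the
binned analysis regresses.

What passing the recovery test shows: the filter/bin/fit pipeline is an
unbiased estimator of a linear charge-aromatic relation under sampling
noise. What it does not show: anything about real proteomes — real IDR
sets have correlated lengths, compositional biases and non-uniform phi
distributions that the generator does not emulate. The analysis defaults
(phi bins of 0.05, bins with fewer than 10 members dropped, fits on bin
means unweighted by occupancy, with a count-weighted option) are declared
choices; the binned-fit recovery tests use 0.025-wide bins with a floor of
50 members to drop boundary-spill bins.

## Numerical choices and degenerate inputs

* Binodal fits require at least 3 points with a positive density gap
  (after re-entrance trimming) and fix `beta`; `T_C` is bounded below by
  the highest fitted temperature. The fit is exact on noiseless
  law-generated points and has median error below 2% under 2%
  multiplicative density noise.
* `kappa` is undefined (an error) for sequences without charges or shorter
  than 6 residues, and defined as 0 when the composition admits only one
  blob profile (e.g. a charge homopolymer).
* Beads closer than 0.5 A flag the configuration as unphysical rather than
  returning astronomical energies.
* Cluster-free frames yield a flagged dilute-only phase point; empty
  residency sets and windows beyond the trajectory span are errors.
* The repulsion term is truncated (not shifted) at `2 sigma_rep`, where its
  value is `eps_rep/4096 ~ 5e-5` kcal/mol — the discontinuity is far below
  thermal noise.

## Known limitations

* No explicit ions or water; the cation-pi strength is salt-independent by
  construction.
* No slab geometry, replica exchange or finite-size scaling; desk-scale
  `T_C` estimates are qualitative.
* The dense-phase voxel estimator's 25% bias bound dominates density
  uncertainty for droplets of a few hundred beads.
* Histidine is treated as neutral when classifying natural sequences;
  protonation states are not modelled.
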