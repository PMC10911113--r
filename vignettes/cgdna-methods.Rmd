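---
title: "The cgdna coarse-grained DNA and protein-DNA models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cgdna coarse-grained DNA and protein-DNA models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cgdna)
```

## The models

`cgdna` implements two closely related implicit-solvent coarse-grained
representations of double-stranded DNA, plus a one-bead-per-residue
hydropathy-scale (HPS) protein model and the cross-interactions that couple
the two.

**2-bead DNA.** Each nucleotide is two beads: a sugar-phosphate *backbone*
bead carrying charge -1 e (mass 178.08 amu) and a *base* bead (A/T/C/G, masses
134.1/125.1/110.1/150.1 amu). The potential energy has six contributions:

* **Bonds** `U = K (r - r0)^2` between consecutive backbones
  (K = 50 kcal/(mol A^2), r0 = 5.5 A) and backbone-base (50, 5.75 A).
  Note the convention without the 1/2 prefactor; the printed force constants
  reproduce the model only under this convention.
* **Angles** `U = K (cos(theta) - cos(theta0))^2` on backbone triples
  (K = 40 kcal/mol, theta0 = 180 deg).
* **Stacking**, a 12-10 potential `delta (5 (s/r)^12 - 6 (s/r)^10)` between
  consecutive intrastrand bases (sigma 3.6 A, sequence-dependent delta between
  6.2 and 11.0 kcal/mol, cutoff 6.2 A). The minimum is exactly `-delta` at
  `r = sigma`.
* **Hydrogen bonding**, the same 12-10 form between complementary
  (Watson-Crick) bases both intra- and interstrand, excluding intrastrand
  near neighbours (|i - j| <= 2): A-T sigma 6.0 A / delta 2.7 kcal/mol,
  C-G 5.5 / 3.3, cutoff 9.5 A.
* **Excluded volume**, a WCA potential (eps 4 kcal/mol, sigma 5.5 A) between
  intrastrand (i, i+2) bases and any base pair in neither the stacking nor
  the hydrogen-bonding class.
* **Electrostatics**, Debye-Hueckel screening between charged beads
  (eps_r = 80; kappa = 10 A at 100 mM and 8.8 A at 120 mM salt; cutoff
  3.5 kappa; plain truncation).

The packaged stacking/HB tables already include the calibrated global scales
(Delta_stack = 2.1, Delta_HB = 0.95); `dna_parameters(delta_stack=, delta_hb=)`
rescales *relative* to them, so the calibration is never applied twice.

**3-bead DNA** adds a small dummy hydrogen-bonding bead to each base (bonded
at 1.95 A with K = 50; mass half the base mass; a 180-degree cosine-squared
angle with K = 80 keeps it on the backbone-base axis). Hydrogen bonding moves
entirely onto complementary dummy pairs (a-t 1.65 A / 8.5 kcal/mol, c-g
1.65 / 10.4, cutoff 3.3 A = 2 sigma), which restores directionality that the
isotropic 2-bead base-base term lacks.

**Pair-classification subtlety (3-bead).** The excluded-volume rule covers
"bases contributing to neither stacking nor hydrogen bonding". In the 3-bead
model complementary base pairs *do* contribute to hydrogen bonding - through
their dummies - so those base pairs carry no direct base-base potential at
all. This reading is also mechanically required: with WCA between partner
bases, the dummies would have to bend ~50 degrees off their 180-degree angle
to bridge the contact gap, costing far more than the hydrogen bond returns,
and a paired duplex melts within 10^5 steps at 290 K. With the delegated
pairs excluded from WCA the dummies pair collinearly at zero angle strain and
the duplex is stable. We verified both readings by direct simulation.

**HPS protein layer.** One bead per residue at the C-alpha position, bonded
at 3.8 A (K = 10); Arg/Lys +1, Asp/Glu -1. Nonbonded protein-protein and
protein-DNA pairs use the Ashbaugh-Hatch form: with arithmetic-mixed sigma
and hydropathy lambda, `U = U_LJ + (1 - lambda) eps` inside the LJ minimum
and `lambda U_LJ` beyond, eps = 0.2 kcal/mol. Two hydropathy scales are
packaged (`hps_parameters(scale = "urry")`, the default, and `"kr"`); DNA
bead hydropathies are backbone 0.38, A 0.40, T 0.54, C 0.59, G 0.35. The
paper does not print a vdW diameter for DNA beads in the mixing rule; we use
the model's universal excluded-volume diameter 5.5 A. Dummy HB beads do not
interact with protein beads. Charged protein beads and DNA backbones interact
through the same Debye-Hueckel term.

## Starting structures

`build_bdna_coordinates()` generates an ideal B-form duplex (36 degree twist,
3.4 A rise by default). The backbone radius is fixed by closing the 5.5 A
backbone bond over one helical step (about 7.0 A); the base-bead radius and
phase, and the backbone groove phase, are solved numerically once per variant
so that bonds match their equilibrium lengths within 0.2 A, complementary HB
sites start inside their engagement band, and diagonal cross-strand contacts
stay outside the strongly repulsive cores. These radial placements are free
parameters of the builder (the model itself does not pin them); the solved
geometry is validated by the structural-recovery tests, which recover the
construction twist and rise exactly.

## Sampling

* `run_langevin()`: BAOAB-split Langevin dynamics, chosen for its stability
  and accurate configurational sampling with the stiff K = 50 bonds at the
  model's 10 fs timestep. The damping time is a parameter (default 10 ps,
  i.e. 1000 timesteps at dt = 10 fs; the source protocols state the damping
  ambiguously as "1000 timesteps" in one place and 1000 ps in another - our
  thermostat-invariance test shows equilibrium observables are insensitive
  across tau = 1-100 ps). With the thermostat off the scheme reduces to
  velocity Verlet and conserves energy to < 1e-3 kcal/mol per step.
  A note on stability: the 3-bead dummy-dummy pair (sigma 1.65 A, deep well,
  light beads) has a ~55 fs vibrational period, so dt = 10 fs is marginally
  stable and a thermal blow-up occurs roughly once per 10^7 steps. The
  integrator aborts loudly (never silently caps forces); long production
  drivers restart the affected walker from a seed-derived stream.
* `run_remd()`: temperature replica exchange; neighbour swaps every 100 steps
  (default) with probability `min(1, exp((beta_i - beta_j)(E_i - E_j)))`,
  exchanging configurations and rescaling velocities by `sqrt(T_new/T_old)`.
  Validated against closed-form Boltzmann statistics of a harmonic dimer and
  a two-state detailed-balance oracle.
* `run_umbrella()`: harmonic restraint `k_u (d - d0)^2` (no 1/2 - the same
  convention the WHAM layer consumes, matching the printed
  k_u = 0.5975 kcal/(mol A^2)) on the mass-weighted COM-COM distance of two
  bead groups; windows are chained so adjacent histograms overlap.

All runs are bitwise reproducible given a seed (the RNG is a self-contained
xoshiro256** stream; no platform-dependent distributions).

For the system sizes this package targets (tens to hundreds of beads) the
pair evaluation uses direct cutoff loops; no neighbour list is needed to meet
the documented run times.

## Observables

* `classify_hybridized()`: a site is engaged if any complementary site on the
  other strand is within 1.5 sigma_HB; a strand is hybridized if at least
  half of its sites are engaged (the boundary is inclusive: 7 of 14 counts).
  The duplex is reported melted when either strand is.
* `melting_analysis()` / `remd_melting()`: melted fraction per temperature
  with the fraction-based melting temperature interpolated at 0.5, and
  `Cv(T) = var(E) / (kB T^2)` with the calorimetric melting temperature at
  the maximum of a Gaussian-smoothed curve (bandwidth = ladder spacing).
  Uncertainties by block averaging / block jackknife (>= 3 blocks).
* `helical_parameters()`: the helical axis is approximated from centroids of
  nucleotide tetrads (residues i and i+3 on both strands, backbone and base
  beads), with local axis directions from anchor differences at a lag of up
  to 10 anchors (about one helical turn, which cancels the small radial
  offset of the centroids; exact on the ideal fixture). Base rise is the
  axial spacing of consecutive base-pair centres; base pairs per turn is 360
  degrees over the mean twist increment of the cross-base-pair vector about
  the local axis; width is reported as twice the mean radial distance of
  backbone beads plus one excluded-volume diameter (the steric
  surface-to-surface convention; `width_padding = 0` gives bead-centre
  values). Three terminal base pairs are excluded at each end, melted frames
  are excluded and counted, and within a frame only *intact* steps enter the
  statistics: both base pairs of a step must have their canonical partner
  site within 1.35 sigma_HB (tighter than the melting criterion because
  local helical geometry is undefined for transiently open or slipped
  pairs).
* `groove_widths()`: cross-strand backbone separations at a designated
  base-pair step (1-based, as in human-facing reports). The two offsets that
  define the grooves are frozen on the ideal fixture: scanning strand-2
  offsets within one helical turn, the *minor* groove is the maximal
  separation and the *major* groove the minimal one. In this bead-centre
  convention (no radius subtraction) ideal B-DNA gives minor ~17.7 A >
  major ~9.9 A, matching the magnitude pattern of the reference data where
  the printed "minor groove" value is the larger number. Frames whose +/- 2
  bp neighbourhood around the step is not intact are excluded.
* `wham_pmf()`: standard self-consistent WHAM over the window histograms
  (tolerance 1e-7 on the per-window shifts), followed by the radial Jacobian
  correction `F(r) = -kB T ln(P(r)/r^2) + C` with C fixed so F vanishes at
  the largest well-sampled distance `b` (bins with at least `min_count`
  total counts).
* `kd_from_pmf()`: `1/Kd = N_A Int_0^b 4 pi r^2 exp(-beta F(r)) dr`
  (trapezoid on the profile grid, A^3 converted to litres). A flat profile
  to b = 50 A gives the closed-form inverse sphere volume, ~3.2 mM.
* `contact_map()`: probability over frames that any bead pair between two
  groups is within the contact rule, by default 1.5 x the arithmetic-mean
  vdW diameter of the pair (the source analyses do not state their cutoff;
  ours is configurable and recorded).

## Study protocols and problem sizes

The package ships two reference protocols, scaled to a single desktop CPU:

* **Structure** (acceptance script): the 32 bp duplex
  `ATACAAAGGTGCGAGGTTTCTATGCTCCCACG` at 290 K, 100 mM. Each model variant is
  annealed from the ideal fixture through 150/190/230/260/290 K (20,000 steps
  per stage) and then run for 1,000,000 production steps (10 ns) in each of
  four independent walkers, pooled for analysis. Pooling independent walkers
  matters because the isotropic model's twist landscape is soft (below).
* **Melting sanity** (test suite): the 14 bp duplex `GCGTCATACAGTGC` /
  `GCACTGTATGACGC` at 120 mM stays hybridized over 10^6 steps at 290 K and
  dissociates within 10^6 steps at 420 K. The full melting-curve protocol
  (32 replicas, 250-450 K, 0.5 us each) and the dissociation-constant
  protocol (40 umbrella windows, 0.5 us each, WHAM, Eq. for Kd above) are
  cluster-scale; the machinery is validated here against analytic oracles at
  toy scale (harmonic-oscillator REMD, exactly sampled double-well PMFs)
  and a reduced 5-replica ladder that reproduces the qualitative melting
  contract.

## What the synthetic fixtures do and do not show

All test inputs are generated in code: ideal duplex fixtures, harmonic
dimers, exactly sampled biased distributions, two-state ensembles. These
validate the *estimators* (forces, integrators, WHAM, Kd quadrature,
structural recovery is exact on the ideal helix) independently of the force
field. They do not validate the force field against real DNA - that is what
the 290 K structural runs and the melting sanity checks probe.

## Known limitations

* **Twist softness.** With every printed parameter implemented and verified,
  the 290 K thermal ensemble of both variants settles at a mean twist of
  ~31-32 deg/bp (11.3-11.5 bp/turn) rather than the reference 9.2-9.9
  bp/turn. Quenching shows the uniformly twisted helix *is* the
  potential-energy minimum (hydrogen bonding favours it), but individual
  steps can untwist at roughly thermal cost, so twist defects are populated
  at 290 K and the ensemble mean drifts up in bp/turn and up in apparent
  radius (hence duplex width). Base rise, hydrogen-bond engagement, groove
  ordering and melting behaviour are insensitive to this mode and reproduce
  the reference values. The likely culprits are the exact 12-10 prefactors
  (the source equations are not printed; we use the canonical form with
  minimum -delta at sigma) or details of the unpublished helical-axis
  implementation we had to re-derive.
* Sequence-dependent bending mechanics are untuned (as in the source model).
* The nucleosome-scale applications (rigid-body histone cores, phase
  separation slabs) are out of scope; the interaction layer they need
  (HPS + DH + DNA) is fully present.
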