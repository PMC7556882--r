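---
title: "Identity-exchange sampling of lipid mixtures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identity-exchange sampling of lipid mixtures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The sampling problem

Lateral mixing of a multi-component lipid membrane is limited by in-plane
diffusion: two lipid species that start spatially segregated reach their
mixed equilibrium only after each molecule has diffused across the
segregation length, which is far beyond routine simulation budgets even for
coarse-grained models.  Identity-exchange sampling sidesteps diffusion
altogether: instead of waiting for two unlike lipids to trade places
physically, a Monte Carlo move swaps their *chemical identities* in place.
Because the two species of interest differ only in their head group — one
neutral head bead versus one unit-negative head bead, with a counterion per
charged lipid — the swap changes a single bead's type and charge per
molecule, and composition is held fixed by always exchanging a pair (one of
each species).

`mdas` implements three samplers over a common NVT molecular dynamics core:

* **md** — straightforward dynamics; mixing proceeds by diffusion only.
* **mcmd** — MD segments alternating with single-step Metropolis exchanges:
  a random unlike pair is selected uniformly over all |A| x |B| pairs, the
  potential-energy difference dU of the swapped assignment is computed at
  the current configuration, and the swap is accepted with
  min(1, exp(-dU/kT)).
* **mdas** — MD with alchemical steps.  The swap is carried out gradually
  along an alchemical trajectory (AT): the coupling parameter lambda runs
  from 0 to 1 in increments of delta-lambda, with M thermostatted MD steps
  at each fixed lambda.  The work is the sum of the potential-energy jumps
  at the increments, evaluated at the instantaneous configurations
  (velocities are untouched by an increment, so no kinetic term enters),

  w = sum_i [ U(lambda_i + dlambda)(x_i) - U(lambda_i)(x_i) ],

  and the move is accepted with min(1, exp(-w/kT)).  This is a
  nonequilibrium-candidate-move construction: by the Jarzynski relation the
  work-weighted acceptance yields the correct equilibrium distribution for
  any M and delta-lambda, while the relaxation during the trajectory keeps
  the typical work — and hence the rejection rate — low.  With
  delta-lambda = 1 and M = 0 the construction collapses exactly to the
  single-step Metropolis exchange, and the implementation reproduces the
  mcmd decision sequence draw for draw under a shared seed (a regression
  test asserts this bitwise).

On acceptance the simulation continues from the final AT configuration and
velocities; on rejection positions *and* velocities are restored exactly to
the pre-AT phase-space point.  Only conventional-MD configurations are
emitted as sampling frames.

## The interaction model

The package works in reduced units (sigma = 1, eps = 1, mass = 1; kT in
units of eps).  The documented correspondence for Martini-derived presets
is sigma = 0.47 nm, under which the 1.1 nm van der Waals cutoff becomes
2.34 sigma and the soft-core parameter 5.0 nm^2 becomes 22.6 sigma^2.

* **Van der Waals** — Lennard-Jones 4 eps ((s/r)^12 - (s/r)^6) with a
  symmetric per-bead-type table, cutoff, and potential shift so the energy
  is exactly zero at the cutoff.  The shift keeps exchange work free of
  cutoff discontinuities and is applied uniformly, including to the
  lambda-coupled terms.
* **Electrostatics** — reaction-field Coulomb
  pref q_i q_j / eps_r (1/r + k_rf r^2 - c_rf) with
  k_rf = (eps_rf - eps_r)/((2 eps_rf + eps_r) r_c^3), c_rf fixed by zeroing
  the energy at the cutoff; eps_rf = Inf gives the conducting-boundary
  limit.
* **Bonded** — harmonic bonds 0.5 k (r - r0)^2 and cosine-harmonic angles
  0.5 k (cos t - cos t0)^2 (the common coarse-grained form; it avoids the
  acos derivative singularity at straight angles).  Intramolecular
  nonbonded pairs are excluded — molecules here are 2-4 bead chains, so
  every intramolecular pair is a 1-2 or 1-3 neighbour.

### Alchemical coupling

Only interactions involving the two tagged head beads depend on lambda;
everything else is lambda-free, which keeps an increment an O(N) partial
computation rather than a full O(N^2) pass.  Charges always couple linearly
in energy (equivalently, linearly in the charge product against fixed
partners; the tagged-tagged Coulomb term is lambda-free because the product
of the two swapped charges is symmetric).  Van der Waals terms couple
either linearly — the default for the membrane exchange, where no bead
appears or vanishes and there is no endpoint catastrophe — or through the
soft-core form

U = 4 eps lambda (A^6 - A^3),  A = sigma^2 / (r^2 + delta (1 - lambda)),

which is finite at particle overlap for lambda < 1 and reduces to plain
Lennard-Jones at lambda = 1.  Soft-core is required when an endpoint has
eps = 0 (a vanishing bead), mirroring atomistic dual-topology exchanges.

## Dynamics and thermostats

Propagation is velocity Verlet; Langevin dynamics uses the BAOAB splitting
with the exact Ornstein-Uhlenbeck velocity update in the middle, and
stochastic velocity rescaling (Bussi-style, with the exact chi-squared
resampling of the kinetic energy) is provided as the alternative
velocity-rescaling scheme.  Langevin is the default for both sampling
segments and AT plateaus because it gives unambiguous canonical sampling
for the acceptance checks; its friction also stands in for the solvent the
toy model does not represent explicitly.  The default time step 0.005
reduced time units leaves a comfortable stability margin on the steepest
Lennard-Jones wall at kT = 1; the 1D harmonic-oscillator energy-drift test
(1e4 steps at dt = 0.01/omega, relative drift < 1e-4) pins the integrator's
symplectic behaviour.  Velocities are *not* resampled at exchange
boundaries: the exchanged heads change type and charge but not mass, so the
kinetic distribution is unaffected.

## Force-evaluation accounting

All method comparisons are per force evaluation, not per wall-clock second.
The convention: one evaluation per MD step (the end-of-step force
computation; plateau steps included); the lambda-increment energies are
tagged-pair partial terms computed alongside the neighbouring plateau force
calls and are not separately counted when M >= 1 — the same bookkeeping
engines use for "foreign lambda" energies — while a bare increment with no
plateau MD (M = 0, the single-step exchange) counts as one evaluation.  The
initial force computation of a run is bookkept as the closing evaluation of
the preceding run (restart semantics).  Under the reference schedule —
2000-step segments with a 1000-step AT (delta-lambda 0.01, lambda changed
every ten steps) — an MDAS attempt therefore costs exactly 3000 evaluations
and an MC-MD attempt 2001.

## The toy membrane

`membrane_preset()` defines a two-dimensional monolayer of 3-bead lipids
(head + 2 tails) on a jittered square lattice (spacing 1.07 sigma, ~82%
site occupancy), two species at 1:1, one counterion (+1) per charged lipid
on leftover lattice sites, and a short Langevin burst to relax the
placement.  Species A occupies the left half-box in the demixed start;
`build_mixed_reference()` assigns species by a uniform random permutation
instead.  The interaction defaults make the mixed state the equilibrium —
unlike-head contacts slightly favorable (eps 1.1 vs 0.75 for like heads)
and a charged-head/counterion attraction — while keeping diffusive mixing
slow relative to exchange moves, which is the regime in which
exchange-based sampling earns its cost.  Choices of record: kT = 1,
Langevin friction 5 (inverse reduced time), LJ/Coulomb cutoff 2.5 sigma,
Coulomb prefactor 2 with screening constant 1 and eps_rf = Inf (unit
charges then interact with just under 2 kT at contact, a
counterion-condensation regime in which the electrostatic part of the
exchange work is large enough for the gradual/single-step contrast to be
resolvable), bond k = 50, r0 = 1, angle k = 5 about a straight rest
angle.

What the generator does *not* emulate: explicit solvent (implicit-solvent
friction replaces it), a second leaflet, polarizable-water electrostatics,
and constant-pressure area fluctuations (the box is fixed).  Passing tests
therefore demonstrate the correctness and relative efficiency of the
samplers on a faithful miniature of the physics — short-range cohesion,
screened electrostatics with explicit counterions, slow diffusive mixing —
not quantitative agreement with any particular lipid force field.

## Measuring mixing

The mixing metric is the height of the tallest peak of the same-species
head-bead radial distribution function, max[g(r)], computed per block of
frames and tracked against cumulative force evaluations.  For a demixed
start it decays toward the plateau of the uniformly mixed state; the decay
is fitted with y = y_inf + a exp(-k t) by Levenberg-Marquardt least squares
(initialized from a log-linear regression of y - min y), and the speedup of
one sampler over another is the ratio of fitted rates with first-order
error propagation.  Numerical choices: RDF bin width 0.05 sigma; the peak
search excludes r < 0.5 sigma (excluded-volume region); blocks of 5-10
frames per series point; fits are unweighted.  A constant or non-decaying
series is reported as an error, never silently fitted.

`mixing_benchmark()` packages the standard comparison.  Three design
points deserve emphasis.  First, every sampler starts from the *same*
burned-in state: after building the demixed lattice, 2000 steps of plain MD
melt the artificial lattice order locally while leaving the species
segregation intact.  Without this shared burn-in the exponential fit
latches onto the fast structural melt (which all samplers share) rather
than the slow identity mixing (which distinguishes them).  Second,
acceptance is estimated from the work samples as mean min(1, exp(-w/kT))
with a bootstrap standard error — the estimator that remains informative
even when almost no move is accepted — rather than from the binomial accept
count.  Third, the gradual-versus-single-step acceptance comparison is
*paired* (`paired_exchange_acceptance()`): both protocols are evaluated on
the same proposal from the same phase-space point, so the environmental
variance that dominates two independent runs cancels in the difference.

Benchmark problem sizes (chosen as desk-scale study conditions): 100
lipids; MD reference of 100 x 2000 = 2e5 evaluations; an MDAS run of 1000
attempts with 50-step segments and 200-step ATs (delta-lambda 0.02,
M = 4; 250 evaluations per attempt); 800 paired proposals for the
acceptance comparison.  The AT length trades cost against counterion
relaxation: it gives the ions time to adjust to the migrating head charge,
which is what separates the MDAS work distribution from the single-step
one.

## Validation models

* **Frozen hexamer** — six single-bead molecules (3 A + 3 B) at fixed
  positions with unequal pair well depths and charges.  The 20 possible
  species arrangements can be enumerated exactly, so million-move
  exchange-only chains are checked against the exact Boltzmann weights by
  chi-square.  Chain samples are autocorrelated, so the test thins the
  chain (every 50th move) before the chi-square comparison; the chain
  length itself stays at 1e6 moves.
* **Harmonic stiffness switch** — one particle in an external harmonic well
  whose stiffness ramps from k0 to k1 with lambda, run through the *same*
  alchemical-trajectory code path as lipid exchanges.  The free energy
  difference is (kT/2) ln(k1/k0) per dimension, so the work samples test
  the Jarzynski identity <exp(-w/kT)> = exp(-dF/kT) quantitatively, and
  mean work must decrease monotonically toward dF as the plateau length M
  grows (the quasi-static limit).

## Degenerate inputs, tie-breaks, limitations

Zero-step segments and zero-molecule compositions are valid (no-ops);
r = 0 in a bare pair potential is a singular-separation error; a
lambda schedule is valid only if 1/delta-lambda is integral; tagging two
same-species molecules is an invalid-exchange error; a single-species
system cannot select an exchange pair.  Box dimensionality may be 1, 2 or 3
— 1D exists so the harmonic validation model runs through the production
code path; the membrane model is 2D; 3D is supported but untested at scale.
Neighbour search is all-pairs: at the desk-scale N of a few hundred the
compiled O(N^2) loop is sub-millisecond, so cell lists would add complexity
without measurable benefit at these sizes.  A single RNG stream drives
everything (pair selection, thermostat noise, acceptance draws), which is
what makes the MDAS/MC-MD draw-for-draw equivalence testable; identical
seeds and configs give byte-identical logs.  Known limitations: the
exchange machinery assumes the two species differ only in their head bead;
multi-pair simultaneous exchanges and inter-leaflet moves are out of scope;
counterions are never alchemically modified (they relax physically during
ATs, which is precisely why gradual exchanges of charged heads outperform
single-step ones).
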