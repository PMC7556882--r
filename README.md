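# mdas

Hybrid Monte Carlo / molecular dynamics sampling of binary lipid mixtures
by **alchemical identity exchange**, with a self-contained two-dimensional
Martini-like membrane toy model and a mixing/work analysis pipeline.

## The problem and the method

Heterogeneous membranes reach their mixed equilibrium through lateral
diffusion, which is painfully slow on simulation time scales.  When two
lipid species differ only in their head group — here a neutral head bead
versus a unit-negative one with explicit counterions — a Monte Carlo move
can swap the *identities* of a randomly chosen unlike pair in place,
bypassing diffusion while a fixed 1:1 composition is preserved.

Two exchange samplers are implemented over a common NVT Langevin-dynamics
core, plus plain MD as the reference:

* **MC-MD** — MD segments alternating with single-step Metropolis swaps,
  accepted with `min(1, exp(-dU/kT))`.
* **MDAS** (molecular dynamics with alchemical steps) — the swap is carried
  out gradually along an alchemical trajectory: lambda goes from 0 to 1 in
  increments `dlam` with `M` relaxation MD steps per plateau, accumulating
  the nonequilibrium work

  `w = sum_i [ U(lambda_i + dlam)(x_i) - U(lambda_i)(x_i) ]`,

  and the move is accepted with `min(1, exp(-w/kT))` — a
  nonequilibrium-candidate-move construction that is exact for any schedule
  (by the Jarzynski relation) and collapses to MC-MD at `dlam = 1, M = 0`.
  Rejected trajectories restore positions *and* velocities exactly.

All method comparisons are bookkept in **force evaluations**: one per MD
step, one per bare single-step exchange; under the reference schedule
(2000-step segments, 1000-step alchemical trajectories with `dlam = 0.01`
changed every ten steps) an MDAS attempt costs exactly 3000 evaluations and
an MC-MD attempt 2001.

Mixing is measured by the height of the tallest peak of the same-species
head-bead radial distribution function, `max[g(r)]`, which decays
exponentially to the mixed-state plateau; fitted rates per force evaluation
give speedup ratios between samplers.

## A worked example

```r
library(mdas)

# a demixed 1:1 membrane: 20 + 20 three-bead lipids + 20 counterions
cfg <- make_run_config(n_lipids_a = 20, n_lipids_b = 20, mode = "mdas",
                       md_segment_steps = 50, plateau_steps = 2,
                       delta_lambda = 0.02, n_attempts = 400,
                       frame_stride = 25, seed = 7)
res <- run_sampler(cfg)
print(res)
#> sampler_result: mode mdas - 400 exchange attempts, 800 frames, 60,000 force evaluations
#>   acceptance: 0.642  mean work: 0.4458 (vdw 0.0692, coulomb 0.377)
#>   cost per attempt: 150 force evaluations (50 segment + 100 attempt)

series <- max_gr_series(res$frames, "HB", window = 5)
fit <- fit_exponential(series)
print(fit)
#> exponential relaxation fit (n = 160):
#>   y_inf = 2.6439 +/- 0.036
#>   amplitude = 5.0949 +/- 0.57
#>   rate = 0.0011351 +/- 0.00019 per force evaluation

work_summary(res$work_log)
#> work summary over 400 attempts:
#>   mean total work 0.4458; vdw 0.06922 (15.5%), coulomb 0.3766 (84.5%), bonded 0 (0.0%)
```

Reading: with exchanges enabled, the charged-head pair correlation peak
relaxes from its demixed value toward the mixed plateau `y_inf ~ 2.6` at
about `1.1e-3` per force evaluation; roughly two thirds of the attempts are
accepted; the exchange work is dominated by the Coulomb term (the migrating
head charge must re-find a counterion environment), and the per-term
columns sum to the total row by row.

The standard three-way comparison (MD vs MDAS vs MC-MD from one burned-in
demixed membrane) is packaged as `mixing_benchmark(seed)`; it returns the
two fits, the speedup ratio with a propagated uncertainty, and work-based
acceptance estimates for both exchange samplers.

There is also a small command-line front end:

```sh
Rscript inst/exec/mdas simulate --mode mdas --seed 1 --out out/
Rscript inst/exec/mdas analyze work --in out/work_log.csv
```

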