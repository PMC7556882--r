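test_that("velocity Verlet is a fixed point at zero force and velocity", {
  box <- simulation_box(c(10, 10))
  sys <- particle_system(matrix(5, 1, 2), bead_types = "A",
                         molecule_ids = 1, box = box)
  zero <- function(x) matrix(0, nrow(x), 2)
  out <- velocity_verlet_step(sys, 0.01, forces = zero)
  expect_equal(out$x, sys$x)
  expect_equal(out$v, sys$v)
})

test_that("constant force reproduces uniformly accelerated motion", {
  box <- simulation_box(c(1e6, 1e6), periodic = FALSE)
  sys <- particle_system(matrix(0, 1, 2), bead_types = "A",
                         molecule_ids = 1, box = box)
  fconst <- c(0.3, -0.7)
  fp <- function(x) matrix(fconst, 1, 2)
  dt <- 0.01
  n <- 200
  for (i in seq_len(n)) sys <- velocity_verlet_step(sys, dt, forces = fp)
  t <- n * dt
  # velocity-Verlet positions are exact for constant acceleration
  expect_equal(sys$x[1, ], 0.5 * fconst * t^2, tolerance = 1e-10)
  expect_equal(sys$v[1, ], fconst * t, tolerance = 1e-10)
})

test_that("the integrator conserves energy on the harmonic oscillator", {
  # 1D oscillator, omega = 1, dt = 0.01/omega, 1e4 steps, thermostat off
  box <- simulation_box(1e6, periodic = FALSE)
  sys <- particle_system(matrix(1, 1, 1), bead_types = "A",
                         molecule_ids = 1, box = box)
  fp <- function(x) -x
  etot <- function(s) 0.5 * s$v[1, 1]^2 + 0.5 * s$x[1, 1]^2
  e0 <- etot(sys)
  emax_dev <- 0
  for (i in seq_len(10000)) {
    sys <- velocity_verlet_step(sys, 0.01, forces = fp)
    emax_dev <- max(emax_dev, abs(etot(sys) - e0))
  }
  expect_lt(emax_dev / e0, 1e-4)
})

test_that("thermostats produce canonical velocities", {
  set.seed(99)
  # free-particle gas: Langevin stationary variance kT/m (OU law) and
  # equipartition of the mean kinetic energy per dof
  n <- 100
  box <- simulation_box(c(50, 50))
  sys <- particle_system(matrix(runif(2 * n, 0, 50), n, 2),
                         bead_types = rep("A", n), molecule_ids = 1:n,
                         box = box, masses = 2)
  th <- thermostat_spec(0.7, "langevin", coupling = 2)
  ke <- numeric(400)
  for (i in seq_along(ke)) {
    sys <- thermostat_step(sys, th, 0.5)  # well beyond the OU correlation time
    ke[i] <- mean(sys$v^2) * 2 / 2  # m <v^2>/2 per dof
  }
  se <- sd(ke) / sqrt(length(ke))
  expect_lt(abs(mean(ke) - 0.7 / 2), 4 * se + 0.005)

  # velocity rescaling drives the kinetic energy to the target
  sys2 <- maxwell_velocities(sys, 5)  # far too hot
  th2 <- thermostat_spec(0.7, "velocity_rescaling", coupling = 0.5)
  for (i in 1:200) sys2 <- thermostat_step(sys2, th2, 0.1)
  temp <- mean(2 * 0.5 * 2 * sys2$v^2)  # 2K/dof with m = 2
  expect_lt(abs(temp - 0.7), 0.15)

  # infinite-friction Langevin limit resamples Maxwell velocities afresh
  th3 <- thermostat_spec(0.7, "langevin", coupling = 1e8)
  v_old <- sys$v
  sys3 <- thermostat_step(sys, th3, 1)
  expect_lt(abs(cor(as.vector(v_old), as.vector(sys3$v))), 0.2)
  expect_lt(abs(sd(sys3$v) - sqrt(0.7 / 2)), 0.05)
})

test_that("run_md_segment respects step and force-evaluation accounting", {
  fix <- make_random_gas(n = 6, seed = 21)
  th <- thermostat_spec(1, "langevin", 2)
  reset_force_evals()
  out <- run_md_segment(fix$system, fix$model, 0, 0.005, th)
  expect_identical(out$system$x, fix$system$x)
  expect_equal(force_eval_count(), 0)
  out <- run_md_segment(fix$system, fix$model, 137, 0.005, th,
                        frame_stride = 25, energy_stride = 50)
  expect_equal(force_eval_count(), 137)
  expect_length(out$frames, 5)   # floor(137/25)
  expect_equal(nrow(out$energy_log), 2)
  expect_equal(out$energy_log$step, c(50, 100))
  # frames carry increasing force-eval stamps
  fe <- vapply(unclass(out$frames), `[[`, numeric(1), "force_evals")
  expect_true(all(diff(fe) > 0))
})

test_that("identical seeds give bit-identical trajectories", {
  fix <- make_tiny_membrane(seed = 33)
  th <- thermostat_spec(1, "langevin", 5)
  set.seed(77)
  a <- run_md_segment(fix$system, fix$model, 150, 0.005, th)
  set.seed(77)
  b <- run_md_segment(fix$system, fix$model, 150, 0.005, th)
  expect_identical(a$system$x, b$system$x)
  expect_identical(a$system$v, b$system$v)
})

test_that("long equilibrium runs have stationary potential energy", {
  fix <- make_tiny_membrane(seed = 44, relax_steps = 500)
  th <- thermostat_spec(1, "langevin", 5)
  set.seed(10)
  out <- run_md_segment(fix$system, fix$model, 4000, 0.005, th,
                        energy_stride = 20)
  e <- out$energy_log$total
  h1 <- e[seq_len(100)]
  h2 <- e[101:200]
  pooled <- sqrt(sd(h1)^2 / 100 + sd(h2)^2 / 100)
  # generous bound: block means agree within a few combined stderr
  expect_lt(abs(mean(h1) - mean(h2)), 6 * pooled)
})
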