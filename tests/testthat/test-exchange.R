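test_that("pair selection is uniform over unlike pairs and errors without them", {
  fix <- make_frozen_hexamer()
  set.seed(1)
  draws <- t(replicate(20000, select_exchange_pair(fix$system, fix$model)))
  counts <- table(factor(paste(draws[, 1], draws[, 2]),
                         levels = as.vector(outer(1:3, 4:6, paste))))
  expect_length(counts, 9)
  chi <- chisq.test(as.vector(counts))
  expect_gt(chi$p.value, 0.001)

  # single unlike pair is always selected
  box <- simulation_box(c(6, 6))
  sys2 <- particle_system(matrix(c(1, 1, 3, 3), 2, 2, byrow = TRUE),
                          bead_types = c("A", "B"),
                          charges = c(0.5, -0.5), molecule_ids = 1:2,
                          box = box, type_labels = c("A", "B"))
  topo2 <- list(molecule_topology("A", 1), molecule_topology("B", 2))
  mod2 <- md_model(sys2, topo2,
                   pair_table(c("A", "B"), 1, 1, 2.5))
  expect_equal(select_exchange_pair(sys2, mod2), c(1, 2))

  # no B molecules at all -> error
  sys3 <- particle_system(matrix(c(1, 1, 3, 3), 2, 2, byrow = TRUE),
                          bead_types = c("A", "A"), molecule_ids = 1:2,
                          box = box, type_labels = c("A", "B"))
  topo3 <- list(molecule_topology("A", 1), molecule_topology("A", 2))
  mod3 <- md_model(sys3, topo3, pair_table(c("A", "B"), 1, 1, 2.5))
  expect_error(select_exchange_pair(sys3, mod3), "no unlike")
})

test_that("identically parameterized species always exchange with dU = 0", {
  # two labels with equal interaction parameters and equal (zero) charges
  box <- simulation_box(c(8, 8))
  set.seed(3)
  sys <- particle_system(matrix(runif(12, 0, 8), 6, 2),
                         bead_types = rep(c("A", "B"), 3),
                         molecule_ids = 1:6, box = box,
                         type_labels = c("A", "B"))
  topo <- lapply(1:6, function(i) molecule_topology(rep(c("A", "B"), 3)[i], i))
  mod <- md_model(sys, topo, pair_table(c("A", "B"), 1, 1, 2.5))
  th <- thermostat_spec(1, "langevin", 1)
  for (i in 1:5) {
    out <- mc_exchange_attempt(sys, mod, c(1, 2), th)
    expect_identical(out$outcome$work, 0)
    expect_true(out$outcome$accepted)
  }
})

test_that("Metropolis acceptance matches min(1, exp(-dU/kT)) empirically", {
  fix <- make_frozen_hexamer()
  th <- thermostat_spec(1, "langevin", 1)
  pair <- c(1, 4)
  dU <- mc_exchange_attempt(fix$system, fix$model, pair, th)$outcome$work
  p_theory <- min(1, exp(-dU / th$temperature))
  set.seed(8)
  n <- 4000
  acc <- logical(n)
  for (i in seq_len(n))
    acc[i] <- mc_exchange_attempt(fix$system, fix$model, pair, th)$outcome$accepted
  se <- sqrt(p_theory * (1 - p_theory) / n)
  expect_lt(abs(mean(acc) - p_theory), 4 * se + 1e-3)
})

test_that("alchemical work vanishes for identical endpoints and equals dU for a single step", {
  # identical endpoints: same parameters for A and B -> U is lambda-free
  box <- simulation_box(c(8, 8))
  set.seed(4)
  sys <- particle_system(matrix(runif(12, 0, 8), 6, 2),
                         bead_types = rep(c("A", "B"), 3),
                         molecule_ids = 1:6, box = box,
                         type_labels = c("A", "B"))
  topo <- lapply(1:6, function(i) molecule_topology(rep(c("A", "B"), 3)[i], i))
  mod <- md_model(sys, topo, pair_table(c("A", "B"), 1, 1, 2.5))
  th <- thermostat_spec(1, "langevin", 1)
  at <- alchemical_trajectory(sys, mod, c(1, 2),
                              alchemical_spec(0.1, 3), th, 0.005)
  expect_identical(at$record$w_total, 0)

  # delta_lambda = 1, M = 0 reproduces the single-step dU exactly
  fix <- make_frozen_hexamer()
  at1 <- alchemical_trajectory(fix$system, fix$model, c(2, 5),
                               alchemical_spec(1, 0), th, 0.005)
  dU <- mc_exchange_attempt(fix$system, fix$model, c(2, 5), th)$outcome
  expect_identical(at1$record$w_total, dU$work)
  expect_identical(at1$record$w_vdw, dU$decomposition$vdw)
  expect_identical(at1$record$force_evals_used, 1)
})

test_that("work decomposition closes and composition/charge are invariant", {
  fix <- make_tiny_membrane(seed = 51)
  th <- thermostat_spec(1, "langevin", 5)
  spec <- alchemical_spec(0.1, 2)
  set.seed(12)
  sys <- fix$system
  count_species <- function(s) table(s$type_labels[s$type])
  tab0 <- count_species(sys)
  q0 <- sum(sys$charge)
  for (i in 1:10) {
    out <- mdas_attempt(sys, fix$model, spec, th, 0.005)
    w <- out$outcome$decomposition
    expect_lt(abs(w$total - (w$vdw + w$coulomb + w$bonded)),
              1e-10 * max(1, abs(w$total)))
    sys <- out$system
    expect_identical(count_species(sys), tab0)
    expect_equal(sum(sys$charge), q0, tolerance = 1e-12)
  }
})

test_that("rejected attempts restore the pre-trajectory phase-space point exactly", {
  fix <- make_tiny_membrane(seed = 52)
  th <- thermostat_spec(1, "langevin", 5)
  spec <- alchemical_spec(0.1, 5)
  sys <- fix$system
  set.seed(13)
  seen_reject <- FALSE
  for (i in 1:30) {
    out <- mdas_attempt(sys, fix$model, spec, th, 0.005)
    if (!out$outcome$accepted) {
      expect_identical(out$system$x, sys$x)
      expect_identical(out$system$v, sys$v)
      expect_identical(out$system$type, sys$type)
      seen_reject <- TRUE
    }
    sys <- out$system
  }
  expect_true(seen_reject)
})

test_that("MDAS with a single-step schedule matches MC-MD draw for draw", {
  fix <- make_frozen_hexamer()
  th <- thermostat_spec(1, "langevin", 1)
  spec1 <- alchemical_spec(1, 0)
  run_chain <- function(kind, n = 300) {
    sys <- fix$system
    set.seed(91)
    acc <- logical(n)
    w <- numeric(n)
    for (i in seq_len(n)) {
      if (kind == "mc") {
        pair <- select_exchange_pair(sys, fix$model)
        out <- mc_exchange_attempt(sys, fix$model, pair, th)
      } else {
        out <- mdas_attempt(sys, fix$model, spec1, th, 0.005)
      }
      acc[i] <- out$outcome$accepted
      w[i] <- out$outcome$work
      sys <- out$system
    }
    list(acc = acc, w = w)
  }
  a <- run_chain("mc")
  b <- run_chain("mdas")
  expect_identical(a$acc, b$acc)
  expect_identical(a$w, b$w)
})

test_that("work samples satisfy the Jarzynski identity on the harmonic well", {
  # stiffness switch k0 = 1 -> k1 = 4: dF = (kT/2) ln 4
  set.seed(21)
  kT <- 1
  w <- harmonic_switching_work(3000, plateau_steps = 10, delta_lambda = 0.1,
                               k0 = 1, k1 = 4, kT = kT)
  est <- mean(exp(-w / kT))
  se <- sd(exp(-w / kT)) / sqrt(length(w))
  expect_lt(abs(est - exp(-0.5 * log(4))), 3.5 * se)
  # dissipation: mean work exceeds dF
  expect_gt(mean(w), 0.5 * log(4))
})

test_that("finer lambda staging at fixed trajectory length lowers the work", {
  # equilibrated mixed membrane: exchange free energies average to ~0, so
  # the mean work is dissipation-dominated and gradual staging must not
  # increase it (and the implied acceptance must not decrease)
  b <- build_mixed_reference(membrane_preset(n_a = 10, n_b = 10), seed = 53,
                             relax_steps = 500)
  th <- thermostat_spec(1, "langevin", 5)
  set.seed(61)
  pairs <- lapply(1:150, function(i) select_exchange_pair(b$system, b$model))
  specs <- list(alchemical_spec(1, 40), alchemical_spec(0.1, 4),
                alchemical_spec(0.025, 1))
  stats <- vapply(specs, function(sp) {
    set.seed(62)
    w <- vapply(seq_along(pairs), function(i) {
      alchemical_trajectory(b$system, b$model, pairs[[i]], sp, th,
                            0.005)$record$w_total
    }, numeric(1))
    c(mean(w), mean(pmin(1, exp(-w / th$temperature))))
  }, numeric(2))
  expect_true(all(diff(stats[1, ]) < 1e-3))   # mean work non-increasing
  expect_true(all(diff(stats[2, ]) > -1e-3))  # acceptance non-decreasing
})
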