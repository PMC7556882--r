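# independent brute-force oracle: all-pairs double loop in R over the
# scalar pair functions, with linear or soft-core mixing written out
brute_energy <- function(fix, pair = NULL, lambda = 0, softcore = FALSE,
                         delta = 22.6) {
  sys <- fix$system
  eps <- fix$pt$epsilon
  rc <- fix$pt$cutoff
  n <- nrow(sys$x)
  L <- sys$box$lengths
  ty0 <- sys$type
  q0 <- sys$charge
  ty1 <- ty0
  q1 <- q0
  if (!is.null(pair)) {
    ty1[pair] <- ty0[rev(pair)]
    q1[pair] <- q0[rev(pair)]
  }
  ev <- 0
  ec <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sys$x[i, ] - sys$x[j, ]
    dx <- dx - L * round(dx / L)
    r <- sqrt(sum(dx^2))
    tagged <- !is.null(pair) && (i %in% pair || j %in% pair)
    if (tagged) {
      if (softcore) {
        ev <- ev +
          softcore_lj_energy(r, eps[ty1[i], ty1[j]], 1, lambda, delta,
                             cutoff = rc, shifted = TRUE) +
          softcore_lj_energy(r, eps[ty0[i], ty0[j]], 1, 1 - lambda, delta,
                             cutoff = rc, shifted = TRUE)
      } else {
        ev <- ev +
          (1 - lambda) * lj_pair_energy(r, eps[ty0[i], ty0[j]], 1, rc, TRUE) +
          lambda * lj_pair_energy(r, eps[ty1[i], ty1[j]], 1, rc, TRUE)
      }
      if (!is.null(fix$el))
        ec <- ec + (1 - lambda) * coulomb_rf_energy(r, q0[i], q0[j], fix$el) +
          lambda * coulomb_rf_energy(r, q1[i], q1[j], fix$el)
    } else {
      ev <- ev + lj_pair_energy(r, eps[ty0[i], ty0[j]], 1, rc, TRUE)
      if (!is.null(fix$el))
        ec <- ec + coulomb_rf_energy(r, q0[i], q0[j], fix$el)
    }
  }
  list(vdw = ev, coulomb = ec)
}

test_that("pair potentials match their closed forms", {
  # LJ zero crossing and minimum
  expect_equal(lj_pair_energy(1, 1, 1), 0)
  expect_equal(lj_pair_energy(2^(1 / 6), 1, 1), -1)
  # frozen arithmetic oracle: shifted LJ at r = 0.9 sigma, cutoff 2.5
  expect_equal(lj_pair_energy(0.9, 1, 1, 2.5, shifted = TRUE),
               6.6524358443889131, tolerance = 1e-14)
  expect_equal(lj_pair_energy(3, 1, 1, cutoff = 2.5, shifted = TRUE), 0)
  expect_error(lj_pair_energy(0, 1, 1), "singular")

  # soft-core limits and frozen value (A = 1/3.5 at r = 1, lam = 0.5, delta = 5)
  r <- seq(0.1, 3, length.out = 50)
  expect_equal(softcore_lj_energy(r, 1, 1, 0, 5), rep(0, 50))
  expect_equal(softcore_lj_energy(r, 1, 1, 1, 5), lj_pair_energy(r, 1, 1))
  expect_equal(softcore_lj_energy(1, 1, 1, 0.5, 5),
               -0.045559248272403499, tolerance = 1e-14)
  expect_equal(softcore_lj_energy(1, 1, 1, 1, 0), 0)  # lam = 1 at r = sigma
  # finite at overlap for lam < 1
  expect_true(is.finite(softcore_lj_energy(0, 1, 1, 0.99, 5)))

  # reaction field: no charge, shift construction, frozen value
  el <- electrostatics_params(2.5, dielectric_screening = 15)
  expect_equal(coulomb_rf_energy(1.1, 0, 1, el), 0)
  expect_equal(coulomb_rf_energy(2.5, 1, 1, el), 0)
  expect_equal(coulomb_rf_energy(1.25, 1, 1, el),
               0.016666666666666666, tolerance = 1e-14)
  expect_error(coulomb_rf_energy(0, 1, 1, el), "singular")
})

test_that("soft-core energy is continuous in lambda and r", {
  # local continuity on a grid: an infinitesimal parameter step changes the
  # value only infinitesimally (relative to the local scale), including at
  # the endpoints where the value itself can be steep
  h <- 1e-7
  for (r in c(0.3, 0.9, 1.5)) {
    lam <- seq(0, 1 - h, length.out = 101)
    u <- softcore_lj_energy(r, 1, 1, lam, 5)
    uh <- vapply(lam, function(l) softcore_lj_energy(r, 1, 1, l + h, 5),
                 numeric(1))
    expect_lt(max(abs(uh - u) / pmax(1, abs(u))), 1e-4)
  }
  r <- seq(0.01, 2.5, length.out = 400)
  for (lam in c(0.2, 0.7, 0.999)) {
    u <- softcore_lj_energy(r, 1, 1, lam, 5)
    uh <- softcore_lj_energy(r + h, 1, 1, lam, 5)
    expect_true(all(is.finite(u)))
    expect_lt(max(abs(uh - u) / pmax(1, abs(u))), 1e-4)
  }
})

test_that("system energy equals the brute-force all-pairs oracle", {
  fix <- make_random_gas(n = 10, seed = 11)
  e <- system_energy(fix$system, fix$model)
  b <- brute_energy(fix)
  expect_equal(e$vdw, b$vdw, tolerance = 1e-12)
  expect_equal(e$coulomb, b$coulomb, tolerance = 1e-12)
  expect_equal(e$total, e$vdw + e$coulomb + e$bonded, tolerance = 1e-12)

  for (lam in c(0, 0.37, 1)) {
    e <- system_energy(fix$system, fix$model, pair = c(2, 3), lambda = lam)
    b <- brute_energy(fix, pair = c(2, 3), lambda = lam)
    expect_equal(e$vdw, b$vdw, tolerance = 1e-12)
    expect_equal(e$coulomb, b$coulomb, tolerance = 1e-12)
  }
  # soft-core coupling path
  sc <- alchemical_spec(vdw_coupling = "softcore", softcore_delta = 22.6)
  e <- system_energy(fix$system, fix$model, pair = c(2, 3), lambda = 0.37,
                     spec = sc)
  b <- brute_energy(fix, pair = c(2, 3), lambda = 0.37, softcore = TRUE)
  expect_equal(e$vdw, b$vdw, tolerance = 1e-12)
})

test_that("lambda endpoints reproduce plain energies of the relabeled system", {
  fix <- make_random_gas(n = 10, seed = 12)
  e0 <- system_energy(fix$system, fix$model, pair = c(1, 2), lambda = 0)
  e1 <- system_energy(fix$system, fix$model, pair = c(1, 2), lambda = 1)
  plain0 <- system_energy(fix$system, fix$model)
  sw <- fix$system
  sw$type[1:2] <- sw$type[2:1]
  sw$charge[1:2] <- sw$charge[2:1]
  plain1 <- system_energy(sw, fix$model)
  expect_identical(e0$total, plain0$total)
  expect_equal(e1$total, plain1$total, tolerance = 1e-14)
  # tagging two same-species molecules is an invalid exchange
  expect_error(system_energy(fix$system, fix$model, pair = c(1, 3)),
               "invalid exchange")
})

test_that("forces are the analytic gradient and obey Newton's third law", {
  fix <- make_random_gas(n = 8, seed = 13)
  # add a bonded dimer to exercise bond + angle gradients
  b <- make_tiny_membrane(n_a = 3, n_b = 3, seed = 14, relax_steps = 50)
  for (case in list(list(fix$system, fix$model, NULL, 0),
                    list(fix$system, fix$model, c(1, 2), 0.37),
                    list(b$system, b$model, NULL, 0))) {
    sys <- case[[1]]; mod <- case[[2]]
    f <- system_forces(sys, mod, pair = case[[3]], lambda = case[[4]])$forces
    expect_lt(max(abs(colSums(f))), 1e-9)
    h <- 1e-6
    idx <- c(1, nrow(sys$x))
    for (i in idx) for (k in 1:2) {
      sp <- sys; sp$x[i, k] <- sp$x[i, k] + h
      sm <- sys; sm$x[i, k] <- sm$x[i, k] - h
      fd <- -(system_energy(sp, mod, pair = case[[3]], lambda = case[[4]])$total -
              system_energy(sm, mod, pair = case[[3]], lambda = case[[4]])$total) / (2 * h)
      expect_equal(f[i, k], fd, tolerance = 1e-5)
    }
  }
})

test_that("an isolated particle feels no force and the counter advances per call", {
  box <- simulation_box(c(10, 10))
  sys <- particle_system(matrix(5, 1, 2), bead_types = "A",
                         molecule_ids = 1, box = box)
  mod <- md_model(sys, list(molecule_topology("other", 1)),
                  pair_table("A", 1, 1, 2.5))
  f <- system_forces(sys, mod)$forces
  expect_equal(f, matrix(0, 1, 2))
  reset_force_evals()
  for (i in 1:5) system_forces(sys, mod)
  expect_equal(force_eval_count(), 5)
})

test_that("energy decomposition closes on a full membrane", {
  b <- make_tiny_membrane(seed = 15)
  e <- system_energy(b$system, b$model)
  expect_equal(e$total, e$vdw + e$coulomb + e$bonded,
               tolerance = 1e-10)
  expect_true(e$bonded > 0)  # bonds and angles are active
})
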