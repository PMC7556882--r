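# Shared fixtures, all built in code.

# random two-species single-bead gas with charges (every bead its own
# molecule); used for brute-force energy/force oracles
make_random_gas <- function(n = 10, L = 8, seed = 1, charged = TRUE) {
  set.seed(seed)
  types <- rep(c("A", "B"), length.out = n)
  sys <- particle_system(matrix(runif(2 * n, 0, L), n, 2),
                         bead_types = types,
                         charges = if (charged) ifelse(types == "B", -0.5, 0.5) else 0,
                         molecule_ids = seq_len(n),
                         box = simulation_box(c(L, L)),
                         type_labels = c("A", "B"))
  topo <- lapply(seq_len(n), function(i) molecule_topology(types[i], i))
  pt <- pair_table(c("A", "B"), matrix(c(1, 1.3, 1.3, 0.6), 2, 2), 1,
                   cutoff = 2.5)
  el <- if (charged) electrostatics_params(2.5) else NULL
  list(system = sys, topologies = topo,
       model = md_model(sys, topo, pt, el), pt = pt, el = el)
}

# six single-bead particles (3 A + 3 B) on a fixed irregular ring; positions
# never move ("frozen"), only identities exchange.  Energy differences
# between the 20 species arrangements are of order kT.
make_frozen_hexamer <- function() {
  ang <- 2 * pi * (0:5) / 6 + c(0.05, -0.1, 0.2, 0, -0.15, 0.1)
  rad <- 1.15 + c(0, 0.08, -0.05, 0.1, 0, -0.07)
  pos <- cbind(6 + rad * cos(ang), 6 + rad * sin(ang))
  types <- c("A", "A", "A", "B", "B", "B")
  sys <- particle_system(pos, bead_types = types,
                         charges = ifelse(types == "B", -1 / 3, 1 / 3),
                         molecule_ids = 1:6,
                         box = simulation_box(c(12, 12)),
                         type_labels = c("A", "B"))
  topo <- lapply(1:6, function(i) molecule_topology(types[i], i))
  pt <- pair_table(c("A", "B"), matrix(c(1, 1.3, 1.3, 0.6), 2, 2), 1,
                   cutoff = 3)
  el <- electrostatics_params(3)
  list(system = sys, topologies = topo,
       model = md_model(sys, topo, pt, el))
}

# plain energy of the hexamer under a given A-subset assignment, via the
# package's scalar pair functions (independent of the compiled kernel path
# used by the samplers)
hexamer_energy <- function(fix, a_subset) {
  sys <- fix$system
  types <- ifelse(1:6 %in% a_subset, "A", "B")
  charge <- ifelse(types == "B", -1 / 3, 1 / 3)
  eps <- matrix(c(1, 1.3, 1.3, 0.6), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  el <- electrostatics_params(3)
  u <- 0
  for (i in 1:5) for (j in (i + 1):6) {
    dx <- sys$x[i, ] - sys$x[j, ]
    dx <- dx - 12 * round(dx / 12)
    r <- sqrt(sum(dx^2))
    u <- u + lj_pair_energy(r, eps[types[i], types[j]], 1, 3, TRUE) +
      coulomb_rf_energy(r, charge[i], charge[j], el)
  }
  u
}

# exact Boltzmann probabilities over the 20 arrangements (choose(6,3));
# returns list of subsets and probabilities
hexamer_boltzmann <- function(fix, kT = 1) {
  subsets <- utils::combn(6, 3, simplify = FALSE)
  u <- vapply(subsets, function(s) hexamer_energy(fix, s), numeric(1))
  p <- exp(-(u - min(u)) / kT)
  list(subsets = subsets, prob = p / sum(p), energy = u)
}

arrangement_id <- function(a_subset) paste(sort(a_subset), collapse = "-")

# tiny membrane for fast sampler-level tests
make_tiny_membrane <- function(n_a = 8, n_b = 8, seed = 5, relax_steps = 100) {
  build_system(n_a, n_b, membrane_preset(), "demixed", seed = seed,
               relax_steps = relax_steps)
}
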