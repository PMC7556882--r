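# Martini-like 2D binary lipid toy model: a monolayer of 3-bead lipids
# (head + 2 tail beads) of two species that differ only in the head bead
# (neutral HA vs unit-negative HB), plus explicit monovalent counterions.
# Implicit-solvent Langevin friction plays the role of the solvent.

#' Membrane preset
#'
#' Composition and interaction defaults for the binary lipid toy model.
#' The defaults are chosen so that the uniformly mixed state is the
#' equilibrium (unlike-head contacts are slightly favorable and the charged
#' head attracts its counterion) while mixing under straightforward MD is
#' slow relative to identity-exchange moves — the regime in which
#' exchange-based sampling is worth its cost.
#'
#' @param n_a,n_b lipid counts of the neutral-head (A) and charged-head (B)
#'   species.
#' @param head_b_charge charge of the B head bead; one counterion of charge
#'   `ion_charge` is added per unit of lipid charge to neutralize the
#'   system.
#' @param ion_charge counterion charge.
#' @param eps_tail baseline Lennard-Jones well depth (tails and
#'   cross-terms).
#' @param eps_head_like well depth for same-species head-head contacts.
#' @param eps_head_unlike well depth for unlike head-head contacts (made
#'   deeper than `eps_head_like` so mixing is thermodynamically favored).
#' @param eps_ion well depth of counterion interactions.
#' @param cutoff van der Waals and Coulomb cutoff (reduced length).
#' @param bond_k,bond_r0 harmonic bond stiffness and rest length.
#' @param angle_k chain cosine-harmonic angle stiffness (rest angle pi,
#'   i.e. straight chains); 0 disables the angle term.
#' @param lattice_a lattice spacing used for initial placement.
#' @param dielectric_screening,rf_dielectric,coulomb_prefactor reaction-field
#'   electrostatics parameters; see [electrostatics_params()].
#' @return an object of class `membrane_preset`.
#' @export
membrane_preset <- function(n_a = 50, n_b = 50, head_b_charge = -1,
                            ion_charge = 1, eps_tail = 1,
                            eps_head_like = 0.75, eps_head_unlike = 1.1,
                            eps_ion = 0.6, cutoff = 2.5, bond_k = 50,
                            bond_r0 = 1, angle_k = 5, lattice_a = 1.07,
                            dielectric_screening = 1, rf_dielectric = Inf,
                            coulomb_prefactor = 2) {
  if (n_a < 0 || n_b < 0) stop("lipid counts must be >= 0")
  structure(as.list(environment()), class = "membrane_preset")
}

#' @rdname membrane_preset
#' @param preset a `membrane_preset`.
#' @return `default_pair_table()` returns the [pair_table()] over the bead
#'   types HA (neutral head), HB (charged head), TL (tail), ION.
#' @export
default_pair_table <- function(preset) {
  labels <- c("HA", "HB", "TL", "ION")
  eps <- matrix(preset$eps_tail, 4, 4, dimnames = list(labels, labels))
  eps["HA", "HA"] <- eps["HB", "HB"] <- preset$eps_head_like
  eps["HA", "HB"] <- eps["HB", "HA"] <- preset$eps_head_unlike
  eps["ION", ] <- eps[, "ION"] <- preset$eps_ion
  pair_table(labels, eps, sigma = 1, cutoff = preset$cutoff, shift = TRUE)
}

#' @rdname membrane_preset
#' @return `default_electrostatics()` returns the matching
#'   [electrostatics_params()].
#' @export
default_electrostatics <- function(preset) {
  electrostatics_params(cutoff = preset$cutoff,
                        dielectric_screening = preset$dielectric_screening,
                        rf_dielectric = preset$rf_dielectric,
                        prefactor = preset$coulomb_prefactor)
}

#' Build a binary lipid monolayer system
#'
#' Places 3-bead lipids (head first) vertically on a jittered square
#' lattice, adds one monovalent counterion per unit of lipid charge on
#' leftover lattice sites, assigns Maxwell velocities, and optionally runs a
#' short Langevin burst to relax the lattice.  In the `"demixed"`
#' arrangement species A occupies the left half-box in x and species B the
#' right half (the far-from-equilibrium start whose relaxation defines the
#' mixing benchmark); in `"mixed"` species are assigned to lipid slots by a
#' uniform random permutation (the equilibrium reference).
#'
#' @param n_a,n_b lipid counts per species.
#' @param preset a [membrane_preset()] (its `n_a`/`n_b` are overridden by
#'   the explicit arguments).
#' @param arrangement `"demixed"` or `"mixed"`.
#' @param seed optional RNG seed.
#' @param relax_steps Langevin steps of the equilibration burst (dt 0.002).
#' @param kT temperature of the initial velocities and the burst.
#' @return list with `system`, `topologies` and a compiled `model`.
#' @export
build_system <- function(n_a, n_b, preset = membrane_preset(),
                         arrangement = c("demixed", "mixed"), seed = NULL,
                         relax_steps = 300, kT = 1) {
  arrangement <- match.arg(arrangement)
  if (!is.null(seed)) set.seed(seed)
  if (n_a < 0 || n_b < 0) stop("counts must be >= 0")
  labels <- c("HA", "HB", "TL", "ION")
  a <- preset$lattice_a
  ntr <- n_a + n_b
  lipid_charge <- n_b * preset$head_b_charge
  n_ion <- if (preset$ion_charge != 0) as.integer(round(-lipid_charge / preset$ion_charge)) else 0L
  if (n_ion < 0) stop("counterion charge has the wrong sign for neutralization")
  needed <- 3L * ntr + n_ion

  if (ntr == 0 && n_ion == 0) {
    box <- simulation_box(c(10, 10) * a)
    sys <- particle_system(matrix(numeric(0), 0, 2), bead_types = character(0),
                           molecule_ids = integer(0), box = box,
                           type_labels = labels)
    model <- md_model(sys, list(), default_pair_table(preset),
                      default_electrostatics(preset))
    return(list(system = sys, topologies = list(), model = model))
  }

  nsites <- ceiling(needed / 0.82)
  nx <- ceiling(sqrt(nsites))
  ny <- as.integer(ceiling(nsites / nx))
  colcap <- ny %/% 3L
  if (colcap < 1) stop("box too small to place 3-bead lipids")
  box <- simulation_box(c(nx, ny) * a)

  # spread n lipids over the given columns as evenly as possible
  distribute <- function(n, cols) {
    ncols <- length(cols)
    counts <- rep(n %/% ncols, ncols)
    extra <- n %% ncols
    if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
    if (any(counts > colcap))
      stop("density too high: ", n, " lipids over ", ncols,
           " columns exceed per-column capacity ", colcap)
    rep(cols, counts)
  }
  # lipid slots: (column, slot) with slot rows 3s, 3s+1, 3s+2, stacked from
  # the bottom of each column; leftover sites take the counterions
  if (arrangement == "demixed") {
    nxa <- nx %/% 2
    cols_a <- if (n_a > 0) distribute(n_a, seq_len(nxa) - 1L) else integer(0)
    cols_b <- if (n_b > 0) distribute(n_b, nx - seq_len(nx %/% 2)) else integer(0)
    slot_col <- c(cols_a, cols_b)
    species <- rep(c("A", "B"), c(n_a, n_b))
  } else {
    slot_col <- distribute(ntr, seq_len(nx) - 1L)
    species <- sample(rep(c("A", "B"), c(n_a, n_b)))
  }
  slot_s <- stats::ave(seq_along(slot_col), slot_col,
                       FUN = function(z) seq_along(z) - 1L)

  # occupied sites and leftover sites for ions
  occ <- matrix(FALSE, nx, ny)
  for (i in seq_len(ntr))
    occ[slot_col[i] + 1L, 3L * slot_s[i] + 1:3] <- TRUE
  free_idx <- which(!occ)
  if (length(free_idx) < n_ion)
    stop("density too high: no room for ", n_ion, " counterions")
  ion_sites <- if (n_ion > 0) sample(free_idx, n_ion) else integer(0)

  n_beads <- 3L * ntr + n_ion
  pos <- matrix(0, n_beads, 2)
  bead_types <- character(n_beads)
  charges <- numeric(n_beads)
  mol_id <- integer(n_beads)
  topologies <- vector("list", ntr + n_ion)
  for (i in seq_len(ntr)) {
    idx <- (3L * (i - 1L) + 1L):(3L * i)
    rows <- 3L * slot_s[i] + 0:2
    pos[idx, 1] <- (slot_col[i] + 0.5) * a
    pos[idx, 2] <- (rows + 0.5) * a
    bead_types[idx] <- c(if (species[i] == "A") "HA" else "HB", "TL", "TL")
    charges[idx[1]] <- if (species[i] == "B") preset$head_b_charge else 0
    mol_id[idx] <- i
    bonds <- rbind(c(idx[1], idx[2], preset$bond_k, preset$bond_r0),
                   c(idx[2], idx[3], preset$bond_k, preset$bond_r0))
    angles <- if (preset$angle_k > 0)
      matrix(c(idx[1], idx[2], idx[3], preset$angle_k, pi), 1, 5)
    topologies[[i]] <- molecule_topology(species[i], idx, bonds, angles)
  }
  for (i in seq_len(n_ion)) {
    bead <- 3L * ntr + i
    site <- ion_sites[i]
    cx <- (site - 1L) %% nx
    cy <- (site - 1L) %/% nx
    pos[bead, ] <- c((cx + 0.5) * a, (cy + 0.5) * a)
    bead_types[bead] <- "ION"
    charges[bead] <- preset$ion_charge
    mol_id[bead] <- ntr + i
    topologies[[ntr + i]] <- molecule_topology("ion", bead)
  }
  pos <- pos + matrix(runif(2 * n_beads, -0.03, 0.03) * a, n_beads, 2)

  sys <- particle_system(pos, bead_types = bead_types, charges = charges,
                         molecule_ids = mol_id, box = box,
                         type_labels = labels)
  model <- md_model(sys, topologies, default_pair_table(preset),
                    default_electrostatics(preset))
  sys <- maxwell_velocities(sys, kT)
  if (relax_steps > 0) {
    burst <- run_md_segment(sys, model, relax_steps, dt = 0.002,
                            thermostat = thermostat_spec(kT, "langevin", 10))
    sys <- burst$system
  }
  stopifnot(abs(sum(sys$charge)) < 1e-9)
  list(system = sys, topologies = topologies, model = model)
}

#' Demixed membrane (far-from-equilibrium start)
#'
#' @param preset a [membrane_preset()].
#' @param seed RNG seed.
#' @param relax_steps equilibration-burst length.
#' @param kT temperature.
#' @return list with `system`, `topologies`, `model`.
#' @export
build_demixed_membrane <- function(preset = membrane_preset(), seed = NULL,
                                   relax_steps = 300, kT = 1) {
  build_system(preset$n_a, preset$n_b, preset, "demixed", seed, relax_steps, kT)
}

#' Uniformly mixed reference membrane
#'
#' @inheritParams build_demixed_membrane
#' @return list with `system`, `topologies`, `model`.
#' @export
build_mixed_reference <- function(preset = membrane_preset(), seed = NULL,
                                  relax_steps = 300, kT = 1) {
  build_system(preset$n_a, preset$n_b, preset, "mixed", seed, relax_steps, kT)
}

#' Minimum interparticle distance
#'
#' Minimum-image minimum distance over particle pairs (diagnostic for
#' placement/relaxation quality).  By default pairs within the same molecule
#' are skipped, since bonded neighbours legitimately sit closer than the
#' nonbonded excluded-volume scale.
#'
#' @param system a [particle_system()].
#' @param exclude_intramolecular skip same-molecule pairs.
#' @return smallest pair distance (reduced length).
#' @export
min_pair_distance <- function(system, exclude_intramolecular = TRUE) {
  n <- nrow(system$x)
  if (n < 2) return(Inf)
  d2 <- matrix(0, n, n)
  for (k in seq_len(ncol(system$x))) {
    dx <- outer(system$x[, k], system$x[, k], "-")
    if (system$box$periodic[k]) {
      L <- system$box$lengths[k]
      dx <- dx - L * round(dx / L)
    }
    d2 <- d2 + dx^2
  }
  if (exclude_intramolecular)
    d2[outer(system$molecule_id, system$molecule_id, "==")] <- Inf
  sqrt(min(d2[upper.tri(d2)]))
}
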