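# Domain types: box, particle system, molecule topologies, interaction
# tables, thermostat and sampler specifications.  Reduced units throughout
# (sigma = 1, eps = 1, mass = 1; temperatures are kT in units of eps).

#' Simulation box
#'
#' @param lengths numeric vector of box edge lengths (reduced length units),
#'   one per dimension; dimensionality 1, 2 or 3 (the membrane model is 2D).
#' @param periodic logical, recycled per dimension.
#' @return an object of class `simulation_box`.
#' @export
simulation_box <- function(lengths, periodic = TRUE) {
  lengths <- as.numeric(lengths)
  d <- length(lengths)
  if (d < 1 || d > 3)
    stop("box dimensionality must be 1, 2 or 3, got ", d)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("all box lengths must be finite and > 0")
  periodic <- rep_len(as.logical(periodic), d)
  structure(list(lengths = lengths, periodic = periodic),
            class = "simulation_box")
}

#' Particle system
#'
#' The state evolved by the samplers: coordinates, velocities, masses,
#' charges and categorical bead types of all beads, plus the box.  Positions
#' are wrapped into the primary box image on construction.
#'
#' @param positions N x d matrix of coordinates (reduced length).
#' @param velocities N x d matrix (reduced velocity); zeros if `NULL`.
#' @param masses per-particle masses, recycled (reduced mass).
#' @param charges per-particle charges, recycled (reduced charge).
#' @param bead_types character vector of per-particle bead type labels.
#' @param molecule_ids integer per-particle molecule index.
#' @param box a [simulation_box()].
#' @param type_labels the full set of bead type labels (defines the order of
#'   rows/columns in the interaction tables); defaults to the sorted unique
#'   labels present.
#' @return an object of class `particle_system` with fields `x`, `v`,
#'   `mass`, `charge`, `type` (integer codes), `type_labels`,
#'   `molecule_id`, `box`.
#' @export
particle_system <- function(positions, velocities = NULL, masses = 1,
                            charges = 0, bead_types, molecule_ids, box,
                            type_labels = NULL) {
  if (!inherits(box, "simulation_box")) stop("box must be a simulation_box")
  x <- as.matrix(positions)
  storage.mode(x) <- "double"
  n <- nrow(x)
  d <- length(box$lengths)
  if (n > 0 && ncol(x) != d)
    stop("positions have ", ncol(x), " columns but the box is ", d, "-dimensional")
  if (n == 0) x <- matrix(numeric(0), 0, d)
  if (is.null(velocities)) velocities <- matrix(0, n, d)
  v <- as.matrix(velocities)
  storage.mode(v) <- "double"
  if (n == 0) v <- matrix(numeric(0), 0, d)
  if (!all(dim(v) == dim(x))) stop("velocities must match positions in shape")
  if (any(!is.finite(x)) || any(!is.finite(v)))
    stop("all coordinates and velocities must be finite")
  if (is.null(type_labels)) type_labels <- sort(unique(as.character(bead_types)))
  type <- match(as.character(bead_types), type_labels)
  if (n > 0 && anyNA(type)) stop("bead_types contain labels not in type_labels")
  sys <- structure(
    list(x = x, v = v,
         mass = rep_len(as.numeric(masses), n),
         charge = rep_len(as.numeric(charges), n),
         type = as.integer(type),
         type_labels = type_labels,
         molecule_id = as.integer(rep_len(molecule_ids, n)),
         box = box),
    class = "particle_system")
  wrap_positions(sys)
}

# wrap positions into [0, L) along periodic dimensions
wrap_positions <- function(system) {
  x <- system$x
  L <- system$box$lengths
  for (k in seq_along(L)) {
    if (system$box$periodic[k] && nrow(x) > 0)
      x[, k] <- x[, k] - L[k] * floor(x[, k] / L[k])
  }
  system$x <- x
  system
}

#' @export
print.particle_system <- function(x, ...) {
  n <- nrow(x$x)
  cat("particle_system:", n, "beads in", length(x$box$lengths), "D box [",
      paste(signif(x$box$lengths, 4), collapse = " x "), "]\n")
  if (n > 0) {
    tab <- table(x$type_labels[x$type])
    cat("  bead types:", paste(names(tab), tab, sep = ":", collapse = ", "), "\n")
    cat("  molecules:", length(unique(x$molecule_id)),
        " total charge:", sum(x$charge), "\n")
  }
  invisible(x)
}

#' Molecule topology
#'
#' @param species categorical species label; `"A"` (neutral head) and `"B"`
#'   (charged head) are the exchangeable lipid species, anything else (for
#'   example `"ion"`) is never selected for exchange.
#' @param particle_indices ordered global bead indices, head bead first.
#' @param bonds optional matrix with columns (i, j, spring constant, rest
#'   length); indices are global.
#' @param angles optional matrix with columns (i, j, k, stiffness, rest
#'   angle in radians); j is the apex.  The angle term is cosine-harmonic.
#' @return an object of class `molecule_topology`.
#' @export
molecule_topology <- function(species, particle_indices, bonds = NULL,
                              angles = NULL) {
  idx <- as.integer(particle_indices)
  if (length(idx) < 1 || anyNA(idx) || any(idx < 1))
    stop("particle_indices must be positive integers")
  if (anyDuplicated(idx)) stop("particle_indices must be unique within a molecule")
  if (!is.null(bonds)) {
    bonds <- matrix(as.numeric(bonds), ncol = 4)
    if (!all(bonds[, 1:2] %in% idx))
      stop("bond indices must belong to the molecule")
  }
  if (!is.null(angles)) {
    angles <- matrix(as.numeric(angles), ncol = 5)
    if (!all(angles[, 1:3] %in% idx))
      stop("angle indices must belong to the molecule")
  }
  structure(list(species = as.character(species), particle_indices = idx,
                 bonds = bonds, angles = angles),
            class = "molecule_topology")
}

#' Van der Waals interaction table
#'
#' Symmetric Lennard-Jones well depths and diameters over bead types, with a
#' shared cutoff and optional potential shift (the potential-shift modifier
#' keeps the pair energy continuous at the cutoff, so exchange work carries
#' no cutoff discontinuities).
#'
#' @param labels character bead type labels (row/column order).
#' @param epsilon,sigma symmetric matrices (reduced energy / length).  A
#'   scalar is expanded to a constant matrix.
#' @param cutoff cutoff distance (reduced length).
#' @param shift logical; subtract the pair energy at the cutoff.
#' @return object of class `pair_table`.
#' @export
pair_table <- function(labels, epsilon, sigma, cutoff, shift = TRUE) {
  nt <- length(labels)
  expand <- function(m) {
    if (length(m) == 1) m <- matrix(m, nt, nt)
    m <- as.matrix(m)
    if (!all(dim(m) == c(nt, nt))) stop("interaction matrix must be ", nt, " x ", nt)
    storage.mode(m) <- "double"
    m
  }
  epsilon <- expand(epsilon)
  sigma <- expand(sigma)
  if (max(abs(epsilon - t(epsilon))) > 1e-12 || max(abs(sigma - t(sigma))) > 1e-12)
    stop("epsilon and sigma matrices must be symmetric")
  if (any(epsilon < 0)) stop("epsilon must be >= 0")
  if (any(sigma <= 0)) stop("sigma must be > 0")
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  structure(list(labels = as.character(labels), epsilon = epsilon,
                 sigma = sigma, cutoff = as.numeric(cutoff),
                 shift = isTRUE(shift)),
            class = "pair_table")
}

#' Reaction-field electrostatics parameters
#'
#' Cutoff Coulomb treatment with a dielectric continuum beyond the cutoff:
#' U(r) = pref * qi qj / eps_r * (1/r + k_rf r^2 - c_rf), with
#' k_rf = (eps_rf - eps_r) / ((2 eps_rf + eps_r) r_c^3) and c_rf chosen so
#' the energy vanishes exactly at the cutoff.  `rf_dielectric = Inf` gives
#' the conducting-boundary limit k_rf = 1/(2 r_c^3).
#'
#' @param cutoff Coulomb cutoff (reduced length).
#' @param dielectric_screening relative screening constant eps_r (> 0).
#' @param rf_dielectric reaction-field dielectric eps_rf (may be `Inf`).
#' @param prefactor Coulomb prefactor in reduced units (the Bjerrum-scale
#'   constant; 1 by default so unit charges at unit distance interact with
#'   about one energy unit before screening).
#' @return object of class `electrostatics_params`.
#' @export
electrostatics_params <- function(cutoff, dielectric_screening = 1,
                                  rf_dielectric = Inf, prefactor = 1) {
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  if (!is.numeric(dielectric_screening) || dielectric_screening <= 0)
    stop("dielectric_screening must be > 0")
  structure(list(cutoff = as.numeric(cutoff),
                 dielectric_screening = as.numeric(dielectric_screening),
                 rf_dielectric = as.numeric(rf_dielectric),
                 prefactor = as.numeric(prefactor)),
            class = "electrostatics_params")
}

# reaction-field constants k_rf, c_rf
rf_constants <- function(elec) {
  rc <- elec$cutoff
  er <- elec$dielectric_screening
  erf <- elec$rf_dielectric
  krf <- if (is.infinite(erf)) 1 / (2 * rc^3) else (erf - er) / ((2 * erf + er) * rc^3)
  crf <- 1 / rc + krf * rc^2
  list(krf = krf, crf = crf)
}

#' Thermostat specification
#'
#' @param temperature target kT in reduced energy units (> 0).
#' @param scheme `"langevin"` (BAOAB friction + noise), `"velocity_rescaling"`
#'   (stochastic rescaling of the kinetic energy toward the target) or
#'   `"none"`.
#' @param coupling friction coefficient (langevin, reduced inverse time) or
#'   coupling time constant (velocity rescaling, reduced time); must be > 0
#'   unless `scheme = "none"`.
#' @return object of class `thermostat_spec`.
#' @export
thermostat_spec <- function(temperature,
                            scheme = c("langevin", "velocity_rescaling", "none"),
                            coupling = 1) {
  scheme <- match.arg(scheme)
  if (!is.numeric(temperature) || temperature <= 0)
    stop("temperature must be > 0")
  if (scheme != "none" && (!is.numeric(coupling) || coupling <= 0))
    stop("coupling must be > 0 for scheme '", scheme, "'")
  structure(list(temperature = as.numeric(temperature), scheme = scheme,
                 coupling = as.numeric(coupling)),
            class = "thermostat_spec")
}

.thermo_cpp <- function(thermostat) {
  code <- switch(thermostat$scheme, none = 0L, langevin = 1L,
                 velocity_rescaling = 2L)
  list(scheme = code, kT = thermostat$temperature,
       gamma = thermostat$coupling, tau = thermostat$coupling)
}

#' Alchemical exchange specification
#'
#' Defines how a pair of unlike lipids is converted into each other's
#' species.  The coupling parameter lambda runs from 0 (original identities)
#' to 1 (swapped identities) in increments of `delta_lambda`, with
#' `plateau_steps` MD steps at each fixed lambda.  Charges always couple
#' linearly in energy; the van der Waals part couples either linearly or
#' through the soft-core form that stays finite at particle overlap (needed
#' when a bead appears or vanishes at an endpoint).
#'
#' `delta_lambda = 1` with `plateau_steps = 0` reproduces a single-step
#' Metropolis exchange.
#'
#' @param delta_lambda lambda increment; 1/delta_lambda must be a positive
#'   integer.
#' @param plateau_steps M, the number of MD relaxation steps per lambda
#'   plateau (>= 0).
#' @param vdw_coupling `"linear"` or `"softcore"`.
#' @param softcore_delta soft-core delta in reduced length squared (>= 0).
#'   The documented Martini-derived preset is 5.0 nm^2, i.e. 22.6 in reduced
#'   units under the sigma = 0.47 nm convention.
#' @return object of class `alchemical_spec`.
#' @export
alchemical_spec <- function(delta_lambda = 0.01, plateau_steps = 10,
                            vdw_coupling = c("linear", "softcore"),
                            softcore_delta = 22.6) {
  vdw_coupling <- match.arg(vdw_coupling)
  if (!is.numeric(delta_lambda) || delta_lambda <= 0 || delta_lambda > 1)
    stop("delta_lambda must be in (0, 1]")
  nlam <- 1 / delta_lambda
  if (abs(nlam - round(nlam)) > 1e-9)
    stop("1/delta_lambda must be a positive integer (got delta_lambda = ",
         delta_lambda, ")")
  if (!is.numeric(plateau_steps) || plateau_steps < 0 ||
      plateau_steps != round(plateau_steps))
    stop("plateau_steps must be a non-negative integer")
  if (!is.numeric(softcore_delta) || softcore_delta < 0)
    stop("softcore_delta must be >= 0")
  structure(list(delta_lambda = as.numeric(delta_lambda),
                 plateau_steps = as.integer(plateau_steps),
                 vdw_coupling = vdw_coupling,
                 softcore_delta = as.numeric(softcore_delta)),
            class = "alchemical_spec")
}

#' Sampler schedule
#'
#' @param mode `"md"` (plain MD segments), `"mcmd"` (segments alternating
#'   with single-step exchanges) or `"mdas"` (segments alternating with
#'   alchemical trajectories).
#' @param md_segment_steps MD steps between exchange attempts (>= 0).
#' @param n_attempts number of segment/attempt cycles.
#' @param dt integrator time step (reduced time, > 0).
#' @param seed optional RNG seed applied at the start of a run.
#' @return object of class `sampler_schedule`.
#' @export
sampler_schedule <- function(mode = c("mdas", "mcmd", "md"),
                             md_segment_steps = 2000, n_attempts = 100,
                             dt = 0.005, seed = NULL) {
  mode <- match.arg(mode)
  if (md_segment_steps < 0 || md_segment_steps != round(md_segment_steps))
    stop("md_segment_steps must be a non-negative integer")
  if (n_attempts < 0 || n_attempts != round(n_attempts))
    stop("n_attempts must be a non-negative integer")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  structure(list(mode = mode, md_segment_steps = as.integer(md_segment_steps),
                 n_attempts = as.integer(n_attempts), dt = as.numeric(dt),
                 seed = seed),
            class = "sampler_schedule")
}

#' Compile an interaction model
#'
#' Bundles topologies and interaction tables into the flattened form the
#' compiled kernels consume, and records which bead type is the head of each
#' exchangeable species (taken from the system's initial assignment).
#'
#' @param system a [particle_system()].
#' @param topologies list of [molecule_topology()] covering every molecule,
#'   in molecule-id order.
#' @param pair_table a [pair_table()] whose labels match the system's
#'   `type_labels`.
#' @param electrostatics optional [electrostatics_params()].
#' @param field optional external harmonic field, `list(k, center)`
#'   (validation models only).
#' @param exclude_intramolecular logical; skip nonbonded interactions within
#'   a molecule (the usual convention for 2-4 bead coarse-grained lipids).
#' @return object of class `md_model`.
#' @export
md_model <- function(system, topologies, pair_table, electrostatics = NULL,
                     field = NULL, exclude_intramolecular = TRUE) {
  if (!inherits(system, "particle_system")) stop("system must be a particle_system")
  if (!inherits(pair_table, "pair_table")) stop("pair_table must be a pair_table")
  if (!identical(pair_table$labels, system$type_labels))
    stop("pair_table labels must match the system's type_labels")
  if (!is.null(electrostatics) && !inherits(electrostatics, "electrostatics_params"))
    stop("electrostatics must be electrostatics_params or NULL")
  nmol <- length(topologies)
  mol_head <- integer(nmol)
  mol_species <- character(nmol)
  bonds <- NULL
  angles <- NULL
  for (m in seq_len(nmol)) {
    topo <- topologies[[m]]
    if (!inherits(topo, "molecule_topology"))
      stop("topologies must be a list of molecule_topology objects")
    mol_head[m] <- topo$particle_indices[1]
    mol_species[m] <- topo$species
    if (!is.null(topo$bonds)) bonds <- rbind(bonds, topo$bonds)
    if (!is.null(topo$angles)) angles <- rbind(angles, topo$angles)
  }
  # head bead type of each exchangeable species, from the initial assignment
  species_head <- c(A = NA_integer_, B = NA_integer_)
  for (sp in c("A", "B")) {
    m <- which(mol_species == sp)
    if (length(m) > 0) species_head[sp] <- system$type[mol_head[m[1]]]
  }
  if (!anyNA(species_head) && species_head["A"] == species_head["B"])
    stop("species A and B must use distinct head bead type labels")
  elec_cpp <- NULL
  if (!is.null(electrostatics)) {
    kc <- rf_constants(electrostatics)
    elec_cpp <- list(pref = electrostatics$prefactor / electrostatics$dielectric_screening,
                     krf = kc$krf, crf = kc$crf, cutoff = electrostatics$cutoff)
  }
  structure(list(pair_table = pair_table, electrostatics = electrostatics,
                 field = field, topologies = topologies,
                 mol_head = mol_head, species_head = species_head,
                 bonds = bonds, angles = angles,
                 exclude_intramolecular = isTRUE(exclude_intramolecular),
                 elec_cpp = elec_cpp),
            class = "md_model")
}

# per-molecule species codes derived from the *current* head bead types:
# 0 = A, 1 = B, 2 = other
current_species <- function(system, model) {
  ht <- system$type[model$mol_head]
  sp <- rep.int(2L, length(ht))
  if (!is.na(model$species_head["A"])) sp[ht == model$species_head["A"]] <- 0L
  if (!is.na(model$species_head["B"])) sp[ht == model$species_head["B"]] <- 1L
  sp
}

# assemble the model list consumed by the C++ kernels
.cpp_model <- function(model, system) {
  list(eps = model$pair_table$epsilon, sigma = model$pair_table$sigma,
       cutoff = model$pair_table$cutoff, shift = model$pair_table$shift,
       elec = model$elec_cpp, bonds = model$bonds, angles = model$angles,
       field = model$field,
       exclude_intramolecular = model$exclude_intramolecular,
       mol_head = as.integer(model$mol_head),
       mol_species = current_species(system, model))
}

# alchemical state for a tagged unlike pair
.alch_pair <- function(system, model, pair, spec) {
  pair <- as.integer(pair)
  if (length(pair) != 2) stop("pair must be two molecule indices")
  sp <- current_species(system, model)
  if (any(pair < 1) || any(pair > length(sp))) stop("pair indices out of range")
  if (any(sp[pair] > 1L) || sp[pair[1]] == sp[pair[2]])
    stop("invalid exchange: the tagged molecules must be one A and one B lipid")
  list(kind = 1L, h1 = model$mol_head[pair[1]], h2 = model$mol_head[pair[2]],
       softcore = identical(spec$vdw_coupling, "softcore"),
       delta = spec$softcore_delta)
}

# apply an accepted identity swap to the R-side system
.bake_swap <- function(system, model, pair) {
  h <- model$mol_head[pair]
  system$type[h] <- system$type[rev(h)]
  system$charge[h] <- system$charge[rev(h)]
  system
}
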