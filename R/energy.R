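# Pairwise and total potential energies and forces, including the
# lambda-coupled alchemical interactions of a tagged lipid pair.

#' Lennard-Jones pair energy
#'
#' 4 eps ((sigma/r)^12 - (sigma/r)^6), optionally shifted so the energy is
#' zero at the cutoff, and identically zero beyond it.
#'
#' @param r separation(s), reduced length; must be > 0.
#' @param epsilon well depth (reduced energy).
#' @param sigma diameter (reduced length).
#' @param cutoff cutoff distance; `Inf` disables it.
#' @param shifted subtract the value at the cutoff.
#' @return energy (vectorized over `r`).
#' @export
lj_pair_energy <- function(r, epsilon, sigma, cutoff = Inf, shifted = FALSE) {
  if (any(r <= 0)) stop("singular separation: r must be > 0")
  s6 <- (sigma / r)^6
  u <- 4 * epsilon * (s6^2 - s6)
  if (shifted && is.finite(cutoff)) {
    sc6 <- (sigma / cutoff)^6
    u <- u - 4 * epsilon * (sc6^2 - sc6)
  }
  u[r >= cutoff] <- 0
  u
}

#' Soft-core Lennard-Jones energy
#'
#' The lambda-coupled soft-core form
#' U = 4 eps lambda (A^6 - A^3) with A = sigma^2 / (r^2 + delta (1 - lambda)).
#' It is finite for all r >= 0 whenever lambda < 1 and delta > 0, vanishes at
#' lambda = 0, and reduces to the plain 6-12 Lennard-Jones potential at
#' lambda = 1.  This avoids the end-point catastrophe when a bead appears or
#' disappears during an alchemical exchange.
#'
#' @inheritParams lj_pair_energy
#' @param lambda coupling parameter in \[0, 1\].
#' @param delta soft-core parameter (reduced length squared, >= 0).
#' @return energy (vectorized over `r`).
#' @export
softcore_lj_energy <- function(r, epsilon, sigma, lambda, delta,
                               cutoff = Inf, shifted = FALSE) {
  if (any(r < 0)) stop("r must be >= 0")
  if (any(lambda < 0) || any(lambda > 1)) stop("lambda must be in [0, 1]")
  if (any(delta < 0)) stop("delta must be >= 0")
  A <- sigma^2 / (r^2 + delta * (1 - lambda))
  u <- 4 * epsilon * lambda * (A^6 - A^3)
  if (shifted && is.finite(cutoff)) {
    Ac <- sigma^2 / (cutoff^2 + delta * (1 - lambda))
    u <- u - 4 * epsilon * lambda * (Ac^6 - Ac^3)
  }
  u[r >= cutoff] <- 0
  u
}

#' Reaction-field Coulomb pair energy
#'
#' U = pref qi qj / eps_r (1/r + k_rf r^2 - c_rf), zero at and beyond the
#' cutoff by construction of c_rf.
#'
#' @param r separation(s), > 0.
#' @param q_i,q_j charges (reduced units).
#' @param elec an [electrostatics_params()].
#' @return energy (vectorized over `r`).
#' @export
coulomb_rf_energy <- function(r, q_i, q_j, elec) {
  if (any(r <= 0)) stop("singular separation: r must be > 0")
  kc <- rf_constants(elec)
  pref <- elec$prefactor / elec$dielectric_screening
  u <- pref * q_i * q_j * (1 / r + kc$krf * r^2 - kc$crf)
  u[r >= elec$cutoff] <- 0
  u
}

.breakdown <- function(lst) {
  structure(list(total = lst$total, vdw = lst$vdw, coulomb = lst$coulomb,
                 bonded = lst$bonded),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("energy: total %.6g (vdw %.6g, coulomb %.6g, bonded %.6g)\n",
              x$total, x$vdw, x$coulomb, x$bonded))
  invisible(x)
}

# assemble the optional lambda state into the C++ alchemical list
.alch_state <- function(system, model, pair, lambda, spec, stiffness = NULL) {
  if (!is.null(stiffness)) {
    if (length(stiffness) != 2) stop("stiffness must be c(k0, k1)")
    return(list(alch = list(kind = 2L, k0 = stiffness[1], k1 = stiffness[2]),
                lambda = lambda))
  }
  if (is.null(pair)) return(list(alch = NULL, lambda = 0))
  if (is.null(spec)) spec <- alchemical_spec()
  list(alch = .alch_pair(system, model, pair, spec), lambda = lambda)
}

#' Total potential energy with per-term decomposition
#'
#' Sums pairwise van der Waals, reaction-field Coulomb and bonded terms
#' under the minimum-image convention.  When a tagged pair and lambda are
#' given, interactions involving the two tagged head beads are
#' lambda-coupled: Coulomb always linearly in energy, van der Waals linearly
#' or through the soft-core form according to the [alchemical_spec()].  At
#' lambda = 0 (1) the result equals the plain energy of the original
#' (swapped) species assignment.
#'
#' @param system a [particle_system()].
#' @param model an [md_model()].
#' @param pair optional: two molecule indices (one A and one B lipid).
#' @param lambda coupling parameter, used with `pair` or `stiffness`.
#' @param spec an [alchemical_spec()]; defaults used when `NULL`.
#' @param stiffness optional `c(k0, k1)` endpoint stiffnesses of a
#'   lambda-ramped external harmonic field (validation models).
#' @return an `energy_breakdown` (total, vdw, coulomb, bonded); the total
#'   equals the sum of the terms to accumulation tolerance.
#' @export
system_energy <- function(system, model, pair = NULL, lambda = 0,
                          spec = NULL, stiffness = NULL) {
  st <- .alch_state(system, model, pair, lambda, spec, stiffness)
  .breakdown(cpp_energy(system, .cpp_model(model, system), st$alch, st$lambda))
}

#' Forces on all particles
#'
#' Analytic gradient of [system_energy()]; each call advances the global
#' force-evaluation counter by one.
#'
#' @inheritParams system_energy
#' @return list with `forces` (N x d matrix) and `energy` (an
#'   `energy_breakdown` evaluated at the same configuration).
#' @export
system_forces <- function(system, model, pair = NULL, lambda = 0,
                          spec = NULL, stiffness = NULL) {
  st <- .alch_state(system, model, pair, lambda, spec, stiffness)
  out <- cpp_forces(system, .cpp_model(model, system), st$alch, st$lambda)
  .add_evals(1)
  list(forces = out$forces, energy = .breakdown(out$energy))
}

# lambda-dependent part of the potential only (tagged-pair nonbonded terms,
# or the ramped field); used for exchange energetics
partial_energy <- function(system, model, pair = NULL, lambda = 0,
                           spec = NULL, stiffness = NULL) {
  st <- .alch_state(system, model, pair, lambda, spec, stiffness)
  if (is.null(st$alch)) stop("partial_energy needs a tagged pair or a stiffness ramp")
  .breakdown(cpp_partial_energy(system, .cpp_model(model, system), st$alch,
                                st$lambda))
}
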