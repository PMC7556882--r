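# Identity-exchange moves: single-step Metropolis exchange (MC-MD) and the
# gradual alchemical-trajectory exchange with work-based acceptance (MDAS),
# plus the sampler orchestration that alternates MD segments with attempts.

.move_outcome <- function(accepted, w, pair, evals, draws) {
  structure(list(accepted = accepted,
                 work = w$total,
                 decomposition = w,
                 pair = pair,
                 force_evals_used = evals,
                 rng_draws_used = draws),
            class = "move_outcome")
}

#' @export
print.move_outcome <- function(x, ...) {
  cat(sprintf("exchange attempt (molecules %d <-> %d): %s, w = %.6g (vdw %.4g, coulomb %.4g, bonded %.4g), %g force evals\n",
              x$pair[1], x$pair[2], if (x$accepted) "ACCEPTED" else "rejected",
              x$work, x$decomposition$vdw, x$decomposition$coulomb,
              x$decomposition$bonded, x$force_evals_used))
  invisible(x)
}

#' Select a random unlike lipid pair
#'
#' Draws uniformly over all |A| x |B| pairs of different-species lipid
#' molecules (species derived from the current head bead types, so accepted
#' exchanges are reflected immediately).
#'
#' @param system a [particle_system()].
#' @param model an [md_model()].
#' @return integer vector `c(molecule_A, molecule_B)`.
#' @export
select_exchange_pair <- function(system, model) {
  sp <- current_species(system, model)
  a <- which(sp == 0L)
  b <- which(sp == 1L)
  if (length(a) == 0 || length(b) == 0)
    stop("no unlike molecule pair available for exchange (need both species)")
  ia <- min(length(a), 1L + as.integer(runif(1) * length(a)))
  ib <- min(length(b), 1L + as.integer(runif(1) * length(b)))
  c(a[ia], b[ib])
}

#' Energy difference of a single-step identity swap
#'
#' The potential-energy change of swapping the head-bead identities of the
#' tagged pair at the current configuration, decomposed per term; this is
#' the dU of the Metropolis criterion, computed without drawing an
#' acceptance decision.  Costs one force evaluation.
#'
#' @param system a [particle_system()].
#' @param model an [md_model()].
#' @param pair two molecule indices (one A, one B).
#' @return an `energy_breakdown`.
#' @export
mc_delta_energy <- function(system, model, pair) {
  alch <- .alch_pair(system, model, pair, alchemical_spec())
  out <- .breakdown(cpp_mc_delta(system, .cpp_model(model, system), alch))
  .add_evals(1)
  out
}

#' Single-step Metropolis identity exchange
#'
#' Computes the energy difference of swapping the head-bead identities
#' (bead type and charge) of the tagged pair at the current configuration
#' and accepts with min(1, exp(-dU/kT)).  On acceptance the swap is applied
#' in place; on rejection the system is returned unchanged.  Velocities are
#' untouched either way.  Costs one force evaluation.
#'
#' @param system a [particle_system()].
#' @param model an [md_model()].
#' @param pair two molecule indices (one A, one B), e.g. from
#'   [select_exchange_pair()].
#' @param thermostat a [thermostat_spec()] (supplies kT).
#' @return list with `outcome` (a `move_outcome`) and `system`.
#' @export
mc_exchange_attempt <- function(system, model, pair, thermostat) {
  alch <- .alch_pair(system, model, pair, alchemical_spec())
  dU <- .breakdown(cpp_mc_delta(system, .cpp_model(model, system), alch))
  .add_evals(1)
  u <- runif(1)
  accepted <- log(u) < -dU$total / thermostat$temperature
  if (accepted) system <- .bake_swap(system, model, pair)
  list(outcome = .move_outcome(accepted, dU, pair, evals = 1, draws = 1),
       system = system)
}

#' Alchemical trajectory
#'
#' Runs the plateau/increment loop that gradually converts the tagged pair
#' into each other's species: M thermostatted MD steps at fixed lambda, then
#' a lambda increment, repeated from lambda = 0 until lambda = 1.  The work
#' is the sum of potential-energy jumps at the increments, evaluated at the
#' instantaneous configurations (no kinetic contribution), accumulated per
#' interaction term in parallel.  The input system is left untouched; the
#' trial final state (with the swap applied) is returned alongside the work
#' record.
#'
#' @inheritParams mc_exchange_attempt
#' @param spec an [alchemical_spec()].
#' @param dt MD time step for the plateaus.
#' @return list with `record` (class `work_record`: per-term work, force
#'   evaluation cost) and `state` (the trial final system at lambda = 1).
#' @export
alchemical_trajectory <- function(system, model, pair, spec, thermostat, dt) {
  if (!inherits(spec, "alchemical_spec")) stop("spec must be an alchemical_spec")
  alch <- .alch_pair(system, model, pair, spec)
  out <- cpp_alch_traj(system, .cpp_model(model, system), alch,
                       .thermo_cpp(thermostat), dt, spec$delta_lambda,
                       spec$plateau_steps)
  .add_evals(out$nevals)
  trial <- system
  trial$x <- out$state$x
  trial$v <- out$state$v
  trial <- .bake_swap(trial, model, pair)
  attr(trial, "cached_forces") <- NULL
  record <- structure(list(w_total = out$w_total, w_vdw = out$w_vdw,
                           w_coulomb = out$w_coulomb, w_bonded = out$w_bonded,
                           pair = pair, force_evals_used = out$nevals),
                      class = "work_record")
  list(record = record, state = trial)
}

#' @export
print.work_record <- function(x, ...) {
  cat(sprintf("alchemical trajectory work: %.6g (vdw %.4g, coulomb %.4g, bonded %.4g); %g force evals\n",
              x$w_total, x$w_vdw, x$w_coulomb, x$w_bonded,
              x$force_evals_used))
  invisible(x)
}

#' MDAS exchange attempt
#'
#' Selects an unlike pair (unless one is given), runs an alchemical
#' trajectory and accepts with min(1, exp(-w/kT)).  On acceptance the
#' simulation continues from the last configuration and velocities of the
#' lambda = 1 state; on rejection positions AND velocities are restored
#' exactly to the pre-trajectory state.  With `delta_lambda = 1` and
#' `plateau_steps = 0` the attempt is draw-for-draw equivalent to
#' [mc_exchange_attempt()].
#'
#' @inheritParams alchemical_trajectory
#' @param pair optional pair; drawn with [select_exchange_pair()] when
#'   `NULL`.
#' @return list with `outcome` (a `move_outcome`) and `system`.
#' @export
mdas_attempt <- function(system, model, spec, thermostat, dt, pair = NULL) {
  draws <- 1
  if (is.null(pair)) {
    pair <- select_exchange_pair(system, model)
    draws <- draws + 2
  }
  at <- alchemical_trajectory(system, model, pair, spec, thermostat, dt)
  w <- at$record
  u <- runif(1)
  accepted <- log(u) < -w$w_total / thermostat$temperature
  out_system <- if (accepted) at$state else system
  wbk <- structure(list(total = w$w_total, vdw = w$w_vdw,
                        coulomb = w$w_coulomb, bonded = w$w_bonded),
                   class = "energy_breakdown")
  list(outcome = .move_outcome(accepted, wbk, pair,
                               evals = w$force_evals_used, draws = draws),
       system = out_system)
}

#' Run a full sampling simulation
#'
#' The orchestration loop: `n_attempts` cycles of an MD segment followed by
#' an exchange attempt (single-step for `mcmd`, alchemical trajectory for
#' `mdas`; `md` runs segments only).  Only conventional-MD configurations
#' are emitted as sampling frames; the cumulative force-evaluation count is
#' recorded with every frame and attempt.
#'
#' @param config a `run_config` from [make_run_config()] or
#'   [load_config()]; supplies the system composition, interactions,
#'   thermostat, schedule and alchemical parameters.
#' @param system,model optional pre-built [particle_system()] /
#'   [md_model()]; built from the config's membrane preset when `NULL`.
#' @return an object of class `sampler_result`: `work_log` and `energy_log`
#'   data frames, `frames`, the final `system`, `model`, the acceptance
#'   rate, and the number of force evaluations used.  When
#'   `config$out_dir` is non-empty the logs, trajectory and effective
#'   config are also written there.
#' @export
run_sampler <- function(config, system = NULL, model = NULL) {
  config <- validate_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(system)) {
    built <- build_system(n_a = config$n_lipids_a, n_b = config$n_lipids_b,
                          preset = preset_from_config(config),
                          arrangement = config$arrangement,
                          relax_steps = config$relax_steps)
    system <- built$system
    model <- built$model
  }
  if (is.null(model)) stop("a model must accompany a user-supplied system")
  thermostat <- thermostat_spec(config$temperature, config$thermostat,
                                config$thermostat_coupling)
  spec <- alchemical_spec(config$delta_lambda, config$plateau_steps,
                          config$vdw_coupling, config$softcore_delta)
  mode_code <- switch(config$mode, md = 0L, mcmd = 1L, mdas = 2L)
  out <- cpp_run_sampler(system, .cpp_model(model, system),
                         .thermo_cpp(thermostat), mode_code,
                         as.integer(config$md_segment_steps),
                         as.integer(config$n_attempts), config$dt,
                         spec$delta_lambda, spec$plateau_steps,
                         identical(spec$vdw_coupling, "softcore"),
                         spec$softcore_delta,
                         as.integer(config$frame_stride),
                         as.integer(config$energy_stride), 0)
  .add_evals(out$nevals)
  final <- system
  final$x <- out$state$x
  final$v <- out$state$v
  final$type <- out$state$type
  final$charge <- out$state$charge
  wl <- as.data.frame(out$work_log)
  res <- structure(list(work_log = wl,
                        energy_log = .elog_df(out$energy_log),
                        frames = .frames_object(out$frames, final),
                        system = final, model = model, config = config,
                        acceptance = if (nrow(wl) > 0) mean(wl$accepted) else NA_real_,
                        force_evals = out$nevals),
                   class = "sampler_result")
  if (nzchar(config$out_dir)) write_run_outputs(res, config$out_dir)
  res
}

#' @export
print.sampler_result <- function(x, ...) {
  cat("sampler_result: mode", x$config$mode, "-", nrow(x$work_log),
      "exchange attempts,", length(x$frames), "frames,",
      format(x$force_evals, big.mark = ","), "force evaluations\n")
  if (nrow(x$work_log) > 0) {
    cat(sprintf("  acceptance: %.3g  mean work: %.4g (vdw %.3g, coulomb %.3g)\n",
                x$acceptance, mean(x$work_log$w_total),
                mean(x$work_log$w_vdw), mean(x$work_log$w_coulomb)))
    cat(sprintf("  cost per attempt: %g force evaluations (%d segment + %g attempt)\n",
                x$config$md_segment_steps + x$work_log$evals_attempt[1],
                x$config$md_segment_steps, x$work_log$evals_attempt[1]))
  }
  invisible(x)
}

#' Work samples from lambda-ramped harmonic-well switching
#'
#' A one-particle validation model for the alchemical-trajectory machinery:
#' an external harmonic well whose stiffness ramps from k0 to k1 with
#' lambda.  Each trajectory starts from an exact canonical sample of the k0
#' well and runs the same plateau/increment loop used for lipid exchanges.
#' The free energy difference is known analytically,
#' dF = (kT/2) d ln(k1/k0) in d dimensions, so the work samples test the
#' Jarzynski identity <exp(-w/kT)> = exp(-dF/kT).
#'
#' @param n_at number of independent alchemical trajectories.
#' @param plateau_steps M, MD steps per lambda plateau.
#' @param delta_lambda lambda increment (1/delta_lambda integral).
#' @param k0,k1 endpoint stiffnesses (> 0).
#' @param kT temperature.
#' @param gamma Langevin friction.
#' @param dt MD time step.
#' @param d dimensionality of the well (default 1).
#' @return numeric vector of work values (length `n_at`).
#' @export
harmonic_switching_work <- function(n_at, plateau_steps, delta_lambda,
                                    k0 = 1, k1 = 4, kT = 1, gamma = 1,
                                    dt = 0.01, d = 1) {
  if (k0 <= 0 || k1 <= 0) stop("k0 and k1 must be > 0")
  spec <- alchemical_spec(delta_lambda, plateau_steps)  # validates inputs
  box <- simulation_box(rep(1e6, d), periodic = FALSE)
  center <- rep(0, d)
  tab <- pair_table("P", epsilon = 0, sigma = 1, cutoff = 0.1)
  thermo <- .thermo_cpp(thermostat_spec(kT, "langevin", gamma))
  alch <- list(kind = 2L, k0 = k0, k1 = k1)
  w <- numeric(n_at)
  sys <- particle_system(matrix(0, 1, d), bead_types = "P", molecule_ids = 1,
                         box = box)
  topo <- list(molecule_topology("other", 1))
  model <- md_model(sys, topo, tab, field = list(k = k0, center = center))
  cppm <- .cpp_model(model, sys)
  for (i in seq_len(n_at)) {
    sys$x <- matrix(rnorm(d, sd = sqrt(kT / k0)), 1, d)
    sys$v <- matrix(rnorm(d, sd = sqrt(kT)), 1, d)
    out <- cpp_alch_traj(sys, cppm, alch, thermo, dt, spec$delta_lambda,
                         spec$plateau_steps)
    w[i] <- out$w_total
    .add_evals(out$nevals)
  }
  w
}
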