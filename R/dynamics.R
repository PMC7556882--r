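# NVT molecular dynamics propagation, used both for sampling segments and
# for the relaxation plateaus of alchemical trajectories.

#' Maxwell-Boltzmann velocities
#'
#' Draw velocities from the Maxwell distribution at temperature kT.
#'
#' @param system a [particle_system()].
#' @param kT target temperature (reduced energy units).
#' @return the system with resampled velocities.
#' @export
maxwell_velocities <- function(system, kT) {
  n <- nrow(system$x)
  d <- ncol(system$x)
  if (n > 0)
    system$v <- matrix(rnorm(n * d), n, d) * sqrt(kT / system$mass)
  system
}

#' One velocity-Verlet step
#'
#' Standard velocity-Verlet update (no thermostat); positions are re-wrapped
#' into the box and exactly one force evaluation is consumed per step (the
#' end-of-step force, reused across half-kicks via a cache carried on the
#' returned system).
#'
#' Forces come either from the compiled interaction model or from a
#' user-supplied force provider (an R function of the N x d position matrix
#' returning an N x d force matrix), which is convenient for analytic test
#' problems.
#'
#' @param system a [particle_system()].
#' @param dt time step (> 0).
#' @param model an [md_model()]; ignored when `forces` is given.
#' @param forces optional force provider function.
#' @return the updated system, carrying the cached end-of-step forces in
#'   `attr(, "cached_forces")`.
#' @export
velocity_verlet_step <- function(system, dt, model = NULL, forces = NULL) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  if (is.null(forces) && is.null(model))
    stop("either a model or a force provider is required")
  f0 <- attr(system, "cached_forces")
  if (is.null(forces)) forces <- function(x) {
    sys2 <- system
    sys2$x <- x
    cpp_forces(sys2, .cpp_model(model, sys2), NULL, 0)$forces
  }
  if (is.null(f0)) f0 <- forces(system$x)  # bookkept against the previous run
  m <- system$mass
  v <- system$v + 0.5 * dt * f0 / m
  x <- system$x + dt * v
  system$x <- x
  system <- wrap_positions(system)
  f1 <- forces(system$x)
  .add_evals(1)
  if (any(!is.finite(system$x)))
    stop("dynamics blew up: non-finite coordinates after step (max displacement ",
         signif(max(abs(dt * v)), 3), ")")
  system$v <- v + 0.5 * dt * f1 / m
  attr(system, "cached_forces") <- f1
  system
}

#' One thermostat step
#'
#' Applies the stochastic velocity update of the chosen scheme over a time
#' interval `dt`: the exact Ornstein-Uhlenbeck update for Langevin friction
#' plus noise, or stochastic velocity rescaling of the total kinetic energy
#' toward the target (Bussi-style).  Positions are untouched.
#'
#' @param system a [particle_system()].
#' @param thermostat a [thermostat_spec()] with scheme not `"none"`.
#' @param dt time interval.
#' @return the system with updated velocities.
#' @export
thermostat_step <- function(system, thermostat, dt) {
  if (!inherits(thermostat, "thermostat_spec")) stop("need a thermostat_spec")
  if (thermostat$scheme == "none") stop("thermostat scheme is 'none'")
  system$v <- cpp_thermostat_step(system$v, system$mass,
                                  .thermo_cpp(thermostat), dt)
  system
}

.frames_object <- function(frames_cpp, system) {
  structure(frames_cpp,
            class = "md_frames",
            box = system$box,
            type_labels = system$type_labels,
            molecule_id = system$molecule_id)
}

#' @export
print.md_frames <- function(x, ...) {
  cat("md_frames:", length(x), "frames")
  if (length(x) > 0)
    cat(" of", nrow(x[[1]]$x), "beads; force evals",
        signif(x[[1]]$force_evals, 6), "..",
        signif(x[[length(x)]]$force_evals, 6))
  cat("\n")
  invisible(x)
}

#' @export
`[.md_frames` <- function(x, i) {
  out <- unclass(x)[i]
  attributes(out) <- c(attributes(out),
                       attributes(x)[c("class", "box", "type_labels",
                                       "molecule_id")])
  out
}

#' @export
c.md_frames <- function(...) {
  parts <- list(...)
  out <- unlist(lapply(parts, unclass), recursive = FALSE)
  attributes(out) <- attributes(parts[[1]])[c("class", "box", "type_labels",
                                              "molecule_id")]
  out
}

#' Run a straightforward MD segment
#'
#' Propagates `n_steps` of thermostatted velocity-Verlet dynamics in the
#' compiled core.  The force-evaluation counter advances by exactly
#' `n_steps`.  Observers are configured through strides: every
#' `frame_stride` steps a configuration frame is captured (positions, bead
#' types, charges, cumulative force evaluations) and every `energy_stride`
#' steps a row is appended to the energy log.
#'
#' @param system a [particle_system()].
#' @param model an [md_model()].
#' @param n_steps number of MD steps (>= 0).
#' @param dt time step.
#' @param thermostat a [thermostat_spec()].
#' @param frame_stride frame capture stride (0 = none).
#' @param energy_stride energy log stride (0 = none).
#' @return list with `system` (final state), `frames` (an `md_frames`
#'   object) and `energy_log` (data frame with step, force_evals, total,
#'   vdw, coulomb, bonded, kinetic, temperature).
#' @export
run_md_segment <- function(system, model, n_steps, dt, thermostat,
                           frame_stride = 0, energy_stride = 0) {
  if (n_steps < 0 || n_steps != round(n_steps))
    stop("n_steps must be a non-negative integer")
  if (n_steps == 0)
    return(list(system = system, frames = .frames_object(list(), system),
                energy_log = .elog_df(matrix(numeric(0), 0, 8))))
  out <- cpp_md_run(system, .cpp_model(model, system), NULL, 0,
                    as.integer(n_steps), dt, .thermo_cpp(thermostat),
                    as.integer(frame_stride), as.integer(energy_stride), 0)
  .add_evals(out$nevals)
  system$x <- out$state$x
  system$v <- out$state$v
  attr(system, "cached_forces") <- NULL
  list(system = system,
       frames = .frames_object(out$frames, system),
       energy_log = .elog_df(out$energy_log))
}

.elog_df <- function(m) {
  df <- as.data.frame(m)
  if (ncol(df) == 8)
    names(df) <- c("step", "force_evals", "total", "vdw", "coulomb",
                   "bonded", "kinetic", "temperature")
  df
}
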