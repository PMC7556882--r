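# The standard mixing benchmark: relaxation of the demixed toy membrane
# under straightforward MD, MDAS and MC-MD, compared per force evaluation.

#' Paired acceptance comparison of gradual vs single-step exchange
#'
#' For each trial, one unlike pair is proposed from the current
#' configuration and *both* exchange protocols are evaluated on that same
#' proposal: the single-step energy difference dU, and the work w of an
#' alchemical trajectory started from the same phase-space point (the
#' trajectory is discarded; no move is ever accepted).  The system is then
#' decorrelated with a short MD segment before the next trial.  Because the
#' two acceptance factors min(1, exp(-./kT)) share the proposal and its
#' environment, the variance of their difference is far below that of two
#' independent runs — this is the estimator to use when asking which
#' protocol is accepted more often.
#'
#' @param system,model a starting [particle_system()] and its
#'   [md_model()].
#' @param spec the [alchemical_spec()] of the gradual protocol.
#' @param thermostat a [thermostat_spec()].
#' @param dt MD time step.
#' @param n_trials number of paired proposals.
#' @param segment_steps decorrelation MD steps between trials.
#' @return list with `acceptance_mdas`, `acceptance_mcmd` (each
#'   estimate + bootstrap se), `gap` (paired estimate + se of the
#'   difference), and the paired `work_mdas` / `work_mcmd` samples.
#' @export
paired_exchange_acceptance <- function(system, model, spec, thermostat, dt,
                                       n_trials = 800, segment_steps = 50) {
  kT <- thermostat$temperature
  w_at <- numeric(n_trials)
  w_mc <- numeric(n_trials)
  sys <- system
  for (i in seq_len(n_trials)) {
    pair <- select_exchange_pair(sys, model)
    w_mc[i] <- mc_delta_energy(sys, model, pair)$total
    w_at[i] <- alchemical_trajectory(sys, model, pair, spec, thermostat,
                                     dt)$record$w_total
    sys <- run_md_segment(sys, model, segment_steps, dt, thermostat)$system
  }
  p_at <- pmin(1, exp(-w_at / kT))
  p_mc <- pmin(1, exp(-w_mc / kT))
  d <- p_at - p_mc
  list(acceptance_mdas = acceptance_from_work(w_at, kT),
       acceptance_mcmd = acceptance_from_work(w_mc, kT),
       gap = list(estimate = mean(d), se = sd(d) / sqrt(n_trials)),
       work_mdas = w_at, work_mcmd = w_mc)
}

#' Mixing benchmark on the demixed toy membrane
#'
#' Builds the demixed 1:1 membrane, burns it in with a short plain-MD
#' equilibration (2000 steps) so the initial lattice placement has melted
#' into a locally equilibrated but still demixed liquid, and then runs each
#' sampler from that same state.  Mixing is measured as the relaxation of
#' max\[g(r)\] of the charged-species head beads against force evaluations:
#' an exponential fit per sampler, the MDAS-over-MD speedup ratio, and
#' work-based acceptance estimates for the exchange samplers.  The burn-in
#' matters: without it the fits latch onto the fast structural melt of the
#' initial lattice instead of the slow identity mixing that the samplers
#' are being compared on.
#'
#' The default problem sizes keep the benchmark at desk scale: 100 lipids,
#' a 200,000-evaluation MD reference (100 segments of 2000 steps), and an
#' MDAS run of `n_attempts` cycles with 50-step segments and 200-step
#' alchemical trajectories (delta-lambda 0.02, four plateau steps), i.e.
#' 250 evaluations per attempt.  The trajectory length gives the
#' counterions time to adjust to the migrating head charge, which is what
#' separates the MDAS work distribution from the single-step one.
#' Acceptance probabilities are estimated from work samples as mean
#' min(1, exp(-w/kT)) — usable even when almost nothing is accepted — and
#' the gradual/single-step comparison uses the paired estimator of
#' [paired_exchange_acceptance()].
#'
#' @param seed RNG seed; every run derives from it.
#' @param n_lipids lipids per species.
#' @param n_md_segments MD reference segments (2000 steps each).
#' @param n_attempts exchange attempts for the MDAS and MC-MD runs.
#' @param window frames per mixing-series point.
#' @param burn_in_steps plain-MD equilibration steps shared by all runs.
#' @param include_mcmd also run the MC-MD comparison.
#' @return list with `fit_md`, `fit_mdas`, `speedup`, `acceptance_mdas`,
#'   `acceptance_mcmd`, the raw `series_*` and the sampler results.
#' @export
mixing_benchmark <- function(seed = 1, n_lipids = 50, n_md_segments = 100,
                             n_attempts = 1000, window = 5,
                             burn_in_steps = 2000, include_mcmd = TRUE) {
  base <- list(n_lipids_a = n_lipids, n_lipids_b = n_lipids)
  cfg0 <- do.call(make_run_config, base)
  set.seed(seed)
  built <- build_system(n_lipids, n_lipids, preset_from_config(cfg0),
                        "demixed", relax_steps = cfg0$relax_steps)
  thermostat <- thermostat_spec(cfg0$temperature, cfg0$thermostat,
                                cfg0$thermostat_coupling)
  eq <- run_md_segment(built$system, built$model, burn_in_steps, cfg0$dt,
                       thermostat)
  start <- eq$system

  cfg_md <- do.call(make_run_config,
                    c(base, list(mode = "md", n_attempts = n_md_segments,
                                 md_segment_steps = 2000, frame_stride = 250,
                                 seed = seed)))
  res_md <- run_sampler(cfg_md, system = start, model = built$model)
  series_md <- max_gr_series(res_md$frames, "HB", window = window)
  fit_md <- fit_exponential(series_md)

  cfg_x <- do.call(make_run_config,
                   c(base, list(mode = "mdas", n_attempts = n_attempts,
                                md_segment_steps = 50, plateau_steps = 4,
                                delta_lambda = 0.02, frame_stride = 25,
                                seed = seed + 1)))
  res_x <- run_sampler(cfg_x, system = start, model = built$model)
  series_x <- max_gr_series(res_x$frames, "HB", window = window)
  fit_x <- fit_exponential(series_x)
  kT <- cfg_x$temperature
  acc_x <- acceptance_from_work(res_x$work_log$w_total, kT)

  out <- list(fit_md = fit_md, fit_mdas = fit_x,
              speedup = speedup(fit_x, fit_md),
              acceptance_mdas = acc_x,
              series_md = series_md, series_mdas = series_x,
              md = res_md, mdas = res_x)
  if (include_mcmd) {
    set.seed(seed + 2)
    thermostat <- thermostat_spec(cfg_x$temperature, cfg_x$thermostat,
                                  cfg_x$thermostat_coupling)
    spec <- alchemical_spec(cfg_x$delta_lambda, cfg_x$plateau_steps,
                            cfg_x$vdw_coupling, cfg_x$softcore_delta)
    out$paired <- paired_exchange_acceptance(start, built$model, spec,
                                             thermostat, cfg_x$dt)
    out$acceptance_mdas <- out$paired$acceptance_mdas
    out$acceptance_mcmd <- out$paired$acceptance_mcmd
  }
  out
}
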