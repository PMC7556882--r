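# Measurement pipeline: radial distribution functions, the max[g(r)] mixing
# metric against force evaluations, exponential relaxation fits, speedup
# ratios, and work statistics.

# resolve a selection (type labels, logical mask or indices) against a frame
.resolve_selection <- function(frame, selection, type_labels) {
  if (is.character(selection)) {
    codes <- match(selection, type_labels)
    if (anyNA(codes)) stop("unknown bead type label(s): ",
                           paste(selection[is.na(codes)], collapse = ", "))
    which(frame$type %in% codes)
  } else if (is.logical(selection)) {
    which(selection)
  } else {
    as.integer(selection)
  }
}

#' Radial distribution function
#'
#' g(r) of a bead selection over one or more frames, normalized for the box
#' dimensionality (annulus areas in 2D, shell volumes in 3D) so that an
#' ideal gas gives g = 1.  The default selection in the mixing analysis is
#' the head beads of one species.
#'
#' @param frames an `md_frames` object (from [run_md_segment()] or
#'   [run_sampler()]).
#' @param selection character vector of bead type labels, a logical mask or
#'   integer bead indices.
#' @param r_max histogram range; must not exceed half the smallest box
#'   edge.  Defaults to that bound.
#' @param bin_width bin width (reduced length).
#' @param n_bins alternative to `bin_width`.
#' @return object of class `rdf_result`: data frame with `bin_centers` and
#'   `g`, plus attributes (`bin_width`, `n_frames`, `selection`).
#' @export
radial_distribution <- function(frames, selection, r_max = NULL,
                                bin_width = 0.05, n_bins = NULL) {
  if (length(frames) < 1) stop("need at least one frame")
  box <- attr(frames, "box")
  labels <- attr(frames, "type_labels")
  d <- length(box$lengths)
  if (!d %in% c(2, 3)) stop("RDF supports 2D and 3D boxes")
  half <- min(box$lengths) / 2
  if (is.null(r_max)) r_max <- half
  if (r_max > half + 1e-9)
    stop("r_max must not exceed half the smallest box edge (", signif(half, 4), ")")
  if (is.null(n_bins)) n_bins <- max(1L, as.integer(round(r_max / bin_width)))
  counts <- numeric(n_bins)
  nsel <- NULL
  for (fr in frames) {
    sel <- .resolve_selection(fr, selection, labels)
    if (length(sel) == 0) stop("empty selection")
    if (is.null(nsel)) nsel <- length(sel)
    counts <- counts + cpp_rdf_counts(fr$x, box$lengths, box$periodic,
                                      as.integer(sel), r_max, as.integer(n_bins))
  }
  nf <- length(frames)
  edges <- seq(0, r_max, length.out = n_bins + 1)
  vol <- prod(box$lengths)
  shell <- if (d == 2) pi * diff(edges^2) else (4 / 3) * pi * diff(edges^3)
  # ideal-gas pair count per frame and bin: N(N-1)/2 * shell / volume
  expected <- nsel * (nsel - 1) / 2 * shell / vol
  g <- counts / (nf * expected)
  structure(data.frame(bin_centers = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                       g = g),
            class = c("rdf_result", "data.frame"),
            bin_width = r_max / n_bins, n_frames = nf, selection = selection)
}

#' Mixing series: max\[g(r)\] against force evaluations
#'
#' The height of the tallest peak of the selection's pair correlation
#' function, computed per block of `window` consecutive frames, reported
#' against the cumulative force-evaluation stamp of each block.  For a
#' demixed start the series decays toward the plateau of the uniformly
#' mixed state; its exponential rate per force evaluation is the mixing
#' speed measure.
#'
#' @inheritParams radial_distribution
#' @param r_min_exclusion peak search excludes r below this (the
#'   excluded-volume region); default 0.5 sigma.
#' @param window frames per series point.
#' @return object of class `mixing_series`: data frame with `force_evals`
#'   (strictly increasing) and `max_gr`.
#' @export
max_gr_series <- function(frames, selection, r_min_exclusion = 0.5,
                          window = 10, r_max = NULL, bin_width = 0.05) {
  nf <- length(frames)
  if (nf < 1) stop("need at least one frame")
  nblock <- nf %/% window
  if (nblock < 1) stop("fewer frames (", nf, ") than the window (", window, ")")
  fe <- numeric(nblock)
  mg <- numeric(nblock)
  for (b in seq_len(nblock)) {
    idx <- ((b - 1) * window + 1):(b * window)
    block <- frames[idx]
    attributes(block) <- attributes(frames)[c("class", "box", "type_labels",
                                              "molecule_id")]
    rdf <- radial_distribution(block, selection, r_max = r_max,
                               bin_width = bin_width)
    keep <- rdf$bin_centers > r_min_exclusion
    if (!any(keep)) stop("r_min_exclusion excludes every bin")
    mg[b] <- max(rdf$g[keep])
    fe[b] <- mean(vapply(block, function(f) f$force_evals, numeric(1)))
  }
  if (any(diff(fe) <= 0)) stop("force-evaluation stamps must be strictly increasing")
  structure(data.frame(force_evals = fe, max_gr = mg),
            class = c("mixing_series", "data.frame"))
}

#' Exponential relaxation fit
#'
#' Nonlinear least squares of y = y_inf + a exp(-k t) to a mixing series
#' (t = force evaluations), initialized from a log-linear regression of
#' y - min(y).  Uncertainties come from the parameter covariance of the
#' Levenberg-Marquardt fit.
#'
#' @param series a `mixing_series`, or any data frame whose first two
#'   columns are t and y.
#' @return object of class `relaxation_fit` with `y_inf`, `amplitude`,
#'   `rate` (per force evaluation), standard errors, and the residual norm.
#'   A non-decaying or constant series is an error, not a silent result.
#' @export
fit_exponential <- function(series) {
  t <- as.numeric(series[[1]])
  y <- as.numeric(series[[2]])
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(y) < 5) stop("need at least 5 points for the exponential fit")
  if (sd(y) == 0) stop("series is constant; no decay to fit")
  # initialization: plateau from the tail, amplitude from the head, rate
  # from the 1/e crossing; falls back to a log-linear regression of
  # y - min(y) when the crossing is undefined (slow, clean decays)
  n4 <- max(3L, length(y) %/% 4L)
  y_inf0 <- mean(tail(y, n4))
  a0 <- mean(head(y, max(1L, n4 %/% 3L))) - y_inf0
  k0 <- NA_real_
  if (a0 > 0) {
    cross <- which(y <= y_inf0 + a0 / exp(1))[1]
    if (!is.na(cross) && cross > 1 && t[cross] > t[1])
      k0 <- 1 / (t[cross] - t[1])
  }
  if (!is.finite(k0)) {
    z <- y - min(y)
    pos <- z > 0
    if (sum(pos) < 3) stop("series does not decay; cannot initialize fit")
    ll <- lm(log(z[pos]) ~ t[pos])
    k0 <- -coef(ll)[[2]]
    a0 <- exp(coef(ll)[[1]])
    y_inf0 <- min(y)
    if (!is.finite(k0) || k0 <= 0)
      stop("series does not decay (log-linear slope is non-negative)")
  }
  start <- list(y_inf = y_inf0, a = a0, k = k0)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ y_inf + a * exp(-k * t),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("exponential fit did not converge: ",
                             conditionMessage(e)))
  est <- coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  if (!is.finite(est[["k"]]) || est[["k"]] <= 0)
    stop("exponential fit did not converge to a decaying solution (k <= 0)")
  structure(list(y_inf = est[["y_inf"]], amplitude = est[["a"]],
                 rate = est[["k"]],
                 se_y_inf = se[["y_inf"]], se_amplitude = se[["a"]],
                 se_rate = se[["k"]],
                 residual_norm = sqrt(sum(residuals(fit)^2)),
                 n = length(y), fit = fit),
            class = "relaxation_fit")
}

#' @export
print.relaxation_fit <- function(x, ...) {
  cat(sprintf("exponential relaxation fit (n = %d):\n", x$n))
  cat(sprintf("  y_inf = %.5g +/- %.2g\n", x$y_inf, x$se_y_inf))
  cat(sprintf("  amplitude = %.5g +/- %.2g\n", x$amplitude, x$se_amplitude))
  cat(sprintf("  rate = %.5g +/- %.2g per force evaluation\n", x$rate, x$se_rate))
  invisible(x)
}

#' Mixing speedup ratio
#'
#' Ratio of two fitted relaxation rates (enhanced over reference) with
#' first-order propagation of the two standard errors.
#'
#' @param fit_enhanced,fit_reference `relaxation_fit` objects.
#' @return object of class `speedup_estimate` with `ratio` and `se`.
#' @export
speedup <- function(fit_enhanced, fit_reference) {
  ke <- fit_enhanced$rate
  kr <- fit_reference$rate
  if (!is.finite(kr) || kr <= 0) stop("reference rate must be > 0")
  ratio <- ke / kr
  se <- ratio * sqrt((fit_enhanced$se_rate / ke)^2 +
                     (fit_reference$se_rate / kr)^2)
  structure(list(ratio = ratio, se = se), class = "speedup_estimate")
}

#' @export
print.speedup_estimate <- function(x, ...) {
  cat(sprintf("mixing speedup: %.3g +/- %.2g\n", x$ratio, x$se))
  invisible(x)
}

#' Acceptance probability estimated from work samples
#'
#' Mean of min(1, exp(-w/kT)) over the work samples, with a bootstrap
#' standard error.  This is how the average acceptance of an exchange move
#' is estimated from exploratory alchemical trajectories even when no move
#' was actually accepted.
#'
#' @param work numeric work samples (reduced energy).
#' @param kT temperature.
#' @param n_boot bootstrap resamples for the standard error.
#' @return list with `estimate` and `se`.
#' @export
acceptance_from_work <- function(work, kT, n_boot = 1000) {
  if (length(work) < 1) stop("need at least one work sample")
  p <- pmin(1, exp(-work / kT))
  p[is.nan(p)] <- 0  # w = +Inf contributes 0
  est <- mean(p)
  se <- if (length(p) > 1 && n_boot > 0) {
    sd(vapply(seq_len(n_boot),
              function(i) mean(p[sample.int(length(p), replace = TRUE)]),
              numeric(1)))
  } else 0
  list(estimate = est, se = se)
}

#' Work histogram and per-term decomposition
#'
#' Histogram of total work over a work log plus the mean per-term work and
#' each term's percentage of the mean total (computed on matched attempts,
#' i.e. the same rows for every term, so the percentages and means are
#' mutually consistent).
#'
#' @param work_log data frame with columns `w_total`, `w_vdw`,
#'   `w_coulomb`, `w_bonded` (as produced by [run_sampler()]).
#' @param bins histogram bin count.
#' @return object of class `work_summary` with `histogram` (breaks/counts),
#'   `mean_work` (named per-term means) and `percent` (named percentages of
#'   the mean total).
#' @export
work_summary <- function(work_log, bins = 30) {
  need <- c("w_total", "w_vdw", "w_coulomb", "w_bonded")
  if (!all(need %in% names(work_log)))
    stop("work_log must have columns ", paste(need, collapse = ", "))
  if (nrow(work_log) == 0) stop("empty work log")
  h <- graphics::hist(work_log$w_total, breaks = bins, plot = FALSE)
  means <- vapply(work_log[need], mean, numeric(1))
  pct <- if (means[["w_total"]] != 0)
    100 * means[c("w_vdw", "w_coulomb", "w_bonded")] / means[["w_total"]]
  else setNames(rep(NA_real_, 3), c("w_vdw", "w_coulomb", "w_bonded"))
  names(pct) <- c("vdw", "coulomb", "bonded")
  structure(list(histogram = list(breaks = h$breaks, counts = h$counts,
                                  mids = h$mids),
                 mean_work = setNames(means, c("total", "vdw", "coulomb", "bonded")),
                 percent = pct, n = nrow(work_log)),
            class = "work_summary")
}

#' @export
print.work_summary <- function(x, ...) {
  cat(sprintf("work summary over %d attempts:\n", x$n))
  cat(sprintf("  mean total work %.4g; vdw %.4g (%.1f%%), coulomb %.4g (%.1f%%), bonded %.4g (%.1f%%)\n",
              x$mean_work[["total"]],
              x$mean_work[["vdw"]], x$percent[["vdw"]],
              x$mean_work[["coulomb"]], x$percent[["coulomb"]],
              x$mean_work[["bonded"]], x$percent[["bonded"]]))
  invisible(x)
}
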