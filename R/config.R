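# Run configuration: a flat key = value file covering system composition,
# interactions, thermostat, sampler schedule, alchemical parameters and
# analysis defaults.  Every key is validated at load time; unknown keys are
# rejected by name.

.config_registry <- function() {
  num <- function(default, check = function(v) TRUE, msg = "invalid value")
    list(type = "numeric", default = default, check = check, msg = msg)
  int <- function(default, check = function(v) v >= 0, msg = "must be a non-negative integer")
    list(type = "integer", default = default, check = check, msg = msg)
  chr <- function(default, choices = NULL)
    list(type = "character", default = default, choices = choices)
  pos <- function(v) is.finite(v) && v > 0
  nneg <- function(v) is.finite(v) && v >= 0
  list(
    # composition / toy membrane
    n_lipids_a = int(50), n_lipids_b = int(50),
    arrangement = chr("demixed", c("demixed", "mixed")),
    relax_steps = int(300),
    lattice_a = num(1.07, pos, "must be > 0"),
    head_b_charge = num(-1),
    eps_tail = num(1, nneg, "must be >= 0"),
    eps_head_like = num(0.75, nneg, "must be >= 0"),
    eps_head_unlike = num(1.1, nneg, "must be >= 0"),
    eps_ion = num(0.6, nneg, "must be >= 0"),
    bond_k = num(50, nneg, "must be >= 0"),
    bond_r0 = num(1, pos, "must be > 0"),
    angle_k = num(5, nneg, "must be >= 0"),
    # interactions
    cutoff = num(2.5, pos, "must be > 0"),
    dielectric_screening = num(1, pos, "must be > 0"),
    rf_dielectric = num(Inf, function(v) v > 0, "must be > 0 (Inf allowed)"),
    coulomb_prefactor = num(2),
    # thermostat / dynamics
    temperature = num(1, pos, "must be > 0"),
    thermostat = chr("langevin", c("langevin", "velocity_rescaling", "none")),
    thermostat_coupling = num(5, pos, "must be > 0"),
    dt = num(0.005, pos, "must be > 0"),
    # sampler schedule
    mode = chr("mdas", c("md", "mcmd", "mdas")),
    md_segment_steps = int(2000),
    n_attempts = int(100),
    # alchemical spec
    delta_lambda = num(0.01, function(v) {
      v > 0 && v <= 1 && abs(1 / v - round(1 / v)) < 1e-9
    }, "1/delta_lambda must be a positive integer"),
    plateau_steps = int(10),
    vdw_coupling = chr("linear", c("linear", "softcore")),
    softcore_delta = num(22.6, nneg, "must be >= 0"),
    # observers / analysis defaults
    frame_stride = int(100),
    energy_stride = int(0),
    rdf_bin_width = num(0.05, pos, "must be > 0"),
    r_min_exclusion = num(0.5, nneg, "must be >= 0"),
    rdf_window = int(10, function(v) v >= 1, "must be >= 1"),
    # bookkeeping
    seed = int(1),
    out_dir = chr("")
  )
}

#' Build a run configuration
#'
#' All parameters default to the documented toy-membrane study conditions;
#' any subset can be overridden by name.  Unknown names are an error.
#'
#' @param ... named overrides of registry keys (see [load_config()] for the
#'   full key list and meanings).
#' @return an object of class `run_config`.
#' @export
make_run_config <- function(...) {
  reg <- .config_registry()
  cfg <- lapply(reg, `[[`, "default")
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == "")))
    stop("all config overrides must be named")
  validate_config(structure(modifyList(cfg, over, keep.null = TRUE),
                            class = "run_config"), allow_extra = FALSE)
}

#' Validate a run configuration
#'
#' @param config a `run_config` (or plain named list).
#' @param allow_extra unused; unknown keys always raise an error naming the
#'   key.
#' @return the validated config (classed, with types coerced).
#' @export
validate_config <- function(config, allow_extra = FALSE) {
  reg <- .config_registry()
  unknown <- setdiff(names(config), names(reg))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- lapply(reg, `[[`, "default")
  for (key in names(config)) {
    spec <- reg[[key]]
    v <- config[[key]]
    if (spec$type == "character") {
      v <- as.character(v)
      if (!is.null(spec$choices) && !v %in% spec$choices)
        stop("config key '", key, "': must be one of ",
             paste(spec$choices, collapse = ", "))
    } else {
      v <- suppressWarnings(as.numeric(v))
      if (length(v) != 1 || is.na(v))
        stop("config key '", key, "': not a number")
      if (spec$type == "integer") {
        if (v != round(v) || !spec$check(v))
          stop("config key '", key, "': ", spec$msg)
        v <- as.integer(v)
      } else if (!spec$check(v)) {
        stop("config key '", key, "': ", spec$msg)
      }
    }
    out[[key]] <- v
  }
  structure(out, class = "run_config")
}

#' Load a run configuration from a flat key = value file
#'
#' Lines are `key = value`; blank lines and lines starting with `#` are
#' ignored.  Every key is validated against the registry (type, range and
#' cross-constraints such as 1/delta_lambda being integral); unknown keys
#' are an error naming the offending key, and omitted keys take their
#' documented defaults.
#'
#' @param path config file path.
#' @return an object of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- which(vapply(kv, length, integer(1)) != 3)
  if (length(bad) > 0)
    stop("malformed config line: '", lines[bad[1]], "'")
  cfg <- setNames(lapply(kv, function(m) trimws(m[3])),
                  vapply(kv, `[[`, character(1), 2))
  if (anyDuplicated(names(cfg)))
    stop("duplicate config key(s): ",
         paste(unique(names(cfg)[duplicated(names(cfg))]), collapse = ", "))
  validate_config(cfg)
}

#' Save a run configuration
#'
#' Writes `key = value` lines; [load_config()] of the result reproduces the
#' effective configuration exactly.
#'
#' @param config a `run_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  vals <- vapply(names(config), function(k) {
    v <- config[[k]]
    if (is.character(v)) v else .fmt(v)
  }, character(1))
  writeLines(paste(names(config), "=", vals), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (k in names(x)) cat("  ", k, "=", format(x[[k]]), "\n")
  invisible(x)
}

# membrane preset assembled from config keys
preset_from_config <- function(config) {
  membrane_preset(n_a = config$n_lipids_a, n_b = config$n_lipids_b,
                  head_b_charge = config$head_b_charge,
                  eps_tail = config$eps_tail,
                  eps_head_like = config$eps_head_like,
                  eps_head_unlike = config$eps_head_unlike,
                  eps_ion = config$eps_ion, cutoff = config$cutoff,
                  bond_k = config$bond_k, bond_r0 = config$bond_r0,
                  angle_k = config$angle_k, lattice_a = config$lattice_a,
                  dielectric_screening = config$dielectric_screening,
                  rf_dielectric = config$rf_dielectric,
                  coulomb_prefactor = config$coulomb_prefactor)
}
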