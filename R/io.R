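# Trajectory and system I/O: extended-XYZ frames (full precision, bit-exact
# numeric round trips) and run output writers.

.fmt <- function(x) sprintf("%.17g", x)

.frame_comment <- function(box, force_evals, step, with_vel) {
  d <- length(box$lengths)
  props <- if (with_vel)
    sprintf("species:S:1:pos:R:%d:vel:R:%d:molecule:I:1:charge:R:1:mass:R:1", d, d)
  else
    sprintf("species:S:1:pos:R:%d:molecule:I:1:charge:R:1", d)
  sprintf("Properties=%s Lattice=\"%s\" Periodic=\"%s\" force_evals=%s step=%s",
          props,
          paste(.fmt(box$lengths), collapse = " "),
          paste(ifelse(box$periodic, "T", "F"), collapse = " "),
          .fmt(force_evals), .fmt(step))
}

#' Write frames as extended XYZ
#'
#' Each frame is written with the bead count, a comment line carrying the
#' box, the cumulative force-evaluation stamp and the step, and one line per
#' bead (species label, coordinates, molecule id, charge).  Numbers are
#' written at full precision so read/write round trips are bit-exact.
#'
#' @param frames an `md_frames` object (possibly empty).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  box <- attr(frames, "box")
  labels <- attr(frames, "type_labels")
  molid <- attr(frames, "molecule_id")
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- nrow(fr$x)
    writeLines(as.character(n), con)
    writeLines(.frame_comment(box, fr$force_evals, fr$step, FALSE), con)
    if (n > 0) {
      coords <- apply(fr$x, 1, function(r) paste(.fmt(r), collapse = " "))
      writeLines(paste(labels[fr$type], coords, molid, .fmt(fr$charge)), con)
    }
  }
  invisible(path)
}

.parse_comment <- function(line, lineno) {
  get_field <- function(key, quoted = FALSE) {
    pat <- if (quoted) paste0(key, "=\"([^\"]*)\"") else paste0(key, "=([^ ]+)")
    m <- regmatches(line, regexec(pat, line))[[1]]
    if (length(m) < 2) stop("malformed frame header at line ", lineno,
                            ": missing ", key)
    m[2]
  }
  list(lengths = as.numeric(strsplit(get_field("Lattice", TRUE), " +")[[1]]),
       periodic = strsplit(get_field("Periodic", TRUE), " +")[[1]] == "T",
       force_evals = as.numeric(get_field("force_evals")),
       step = as.numeric(get_field("step")),
       with_vel = grepl("vel:R", line, fixed = TRUE))
}

#' Read extended-XYZ frames
#'
#' @param path file written by [write_frames()] (or hand-written in the same
#'   layout).
#' @param type_labels bead type label set defining the integer codes;
#'   defaults to the sorted unique labels found in the file.
#' @return an `md_frames` object.
#' @export
read_frames <- function(path, type_labels = NULL) {
  lines <- readLines(path)
  frames <- list()
  box <- NULL
  molid <- NULL
  species_all <- character(0)
  i <- 1
  raw <- list()
  while (i <= length(lines)) {
    if (!grepl("^\\s*[0-9]+\\s*$", lines[i]))
      stop("parse error at line ", i, ": expected a bead count")
    n <- as.integer(lines[i])
    if (i + 1 > length(lines)) stop("parse error at line ", i + 1,
                                    ": missing frame header")
    hdr <- .parse_comment(lines[i + 1], i + 1)
    body <- if (n > 0) lines[(i + 2):(i + 1 + n)] else character(0)
    if (length(body) != n) stop("parse error at line ", i, ": truncated frame")
    parts <- strsplit(trimws(body), "\\s+")
    d <- length(hdr$lengths)
    ncol_expect <- 1 + d + (if (hdr$with_vel) d else 0) + 2 +
      (if (hdr$with_vel) 1 else 0)
    bad <- which(vapply(parts, length, integer(1)) != ncol_expect)
    if (length(bad) > 0)
      stop("parse error at line ", i + 1 + bad[1], ": expected ",
           ncol_expect, " fields")
    raw[[length(raw) + 1]] <- list(n = n, hdr = hdr, parts = parts)
    species_all <- union(species_all,
                         vapply(parts, `[[`, character(1), 1))
    i <- i + 2 + n
  }
  if (is.null(type_labels)) type_labels <- sort(species_all)
  for (rf in raw) {
    n <- rf$n
    hdr <- rf$hdr
    d <- length(hdr$lengths)
    if (is.null(box)) box <- simulation_box(hdr$lengths, hdr$periodic)
    m <- if (n > 0) do.call(rbind, lapply(rf$parts, function(p) as.numeric(p[-1])))
         else matrix(numeric(0), 0, d + 2)
    species <- vapply(rf$parts, `[[`, character(1), 1)
    type <- match(species, type_labels)
    if (n > 0 && anyNA(type)) stop("unknown species label in ", path)
    x <- m[, seq_len(d), drop = FALSE]
    off <- d
    vel <- NULL
    if (hdr$with_vel) {
      vel <- m[, off + seq_len(d), drop = FALSE]
      off <- off + d
    }
    mol <- as.integer(m[, off + 1])
    charge <- m[, off + 2]
    mass <- if (hdr$with_vel) m[, off + 3] else NULL
    if (is.null(molid)) molid <- mol
    fr <- list(x = x, type = as.integer(type), charge = charge,
               force_evals = hdr$force_evals, step = hdr$step)
    if (!is.null(vel)) fr$v <- vel
    if (!is.null(mass)) fr$mass <- mass
    frames[[length(frames) + 1]] <- fr
  }
  structure(frames, class = "md_frames", box = box,
            type_labels = type_labels, molecule_id = molid)
}

#' Serialize a particle system to extended XYZ
#'
#' Single-frame variant that additionally stores velocities and masses, so
#' that [read_system()] reproduces positions, velocities and charges
#' bit-exactly.
#'
#' @param system a [particle_system()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_system <- function(system, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(system$x)
  writeLines(as.character(n), con)
  writeLines(.frame_comment(system$box, 0, 0, TRUE), con)
  if (n > 0) {
    rows <- vapply(seq_len(n), function(i) {
      paste(system$type_labels[system$type[i]],
            paste(.fmt(system$x[i, ]), collapse = " "),
            paste(.fmt(system$v[i, ]), collapse = " "),
            system$molecule_id[i], .fmt(system$charge[i]),
            .fmt(system$mass[i]))
    }, character(1))
    writeLines(rows, con)
  }
  invisible(path)
}

#' @rdname write_system
#' @param type_labels label set defining integer type codes (defaults to the
#'   labels found).
#' @return `read_system()` returns the reconstructed [particle_system()].
#' @export
read_system <- function(path, type_labels = NULL) {
  frames <- read_frames(path, type_labels)
  if (length(frames) != 1) stop("expected a single-frame system file")
  fr <- frames[[1]]
  if (is.null(fr$v)) stop("system file lacks velocity columns")
  box <- attr(frames, "box")
  particle_system(fr$x, fr$v, masses = fr$mass, charges = fr$charge,
                  bead_types = attr(frames, "type_labels")[fr$type],
                  molecule_ids = attr(frames, "molecule_id"), box = box,
                  type_labels = attr(frames, "type_labels"))
}

# write standard run outputs into a directory
write_run_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(result$work_log, file.path(dir, "work_log.csv"), row.names = FALSE)
  write.csv(result$energy_log, file.path(dir, "energy_log.csv"),
            row.names = FALSE)
  write_frames(result$frames, file.path(dir, "trajectory.xyz"))
  write_system(result$system, file.path(dir, "final_system.xyz"))
  save_config(result$config, file.path(dir, "config_effective.cfg"))
  log <- c(paste("mdas run log -", format(Sys.time())),
           paste("mode:", result$config$mode),
           paste("attempts:", nrow(result$work_log)),
           paste("acceptance:", signif(result$acceptance, 4)),
           paste("force evaluations:", result$force_evals),
           paste("package version:",
                 as.character(utils::packageVersion("mdas"))))
  writeLines(log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
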