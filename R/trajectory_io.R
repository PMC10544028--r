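#' Write a trajectory as extended-XYZ frames
#'
#' One block per saved frame: bead count, a comment line with
#' `Lattice`/`Properties`/step/time metadata, then one line per bead whose
#' element column encodes the bead class (K = positive, E = negative,
#' F = aromatic, G = neutral). Coordinates are written unwrapped.
#'
#' @param traj a `cg_trajectory`.
#' @param path output `.xyz` path.
#' @param sidecar optional path for a JSON metadata sidecar (seed, model
#'   parameters, salt, temperature, box); default `paste0(path, ".json")`,
#'   `NA` to skip.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path,
                                 sidecar = paste0(path, ".json")) {
  stopifnot(inherits(traj, "cg_trajectory"))
  n <- nrow(traj$system$positions)
  el <- CG_ENCODE[traj$system$classes]
  L <- traj$system$box_length
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(traj$frames)) {
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Lattice="%g 0 0 0 %g 0 0 0 %g" Properties=species:S:1:pos:R:3:chain:I:1 step=%d time=%g',
      L, L, L, traj$steps[k], traj$times[k]), con)
    p <- traj$frames[[k]]
    writeLines(sprintf("%s %.6f %.6f %.6f %d", el, p[, 1], p[, 2], p[, 3],
                       traj$system$chain_id), con)
  }
  if (!is.na(sidecar)) {
    meta <- list(
      n_beads = n, n_frames = length(traj$frames),
      box_length = L, periodic = traj$system$periodic,
      temperature = traj$temperature, seed = traj$seed,
      timestep = traj$timestep, friction = traj$friction,
      salt = traj$cond$ionic_strength, dielectric = traj$cond$dielectric,
      ion_radius = traj$cond$ion_radius,
      model = if (isTRUE(traj$params$include_cation_pi))
        "cation-pi-inclusive" else "cation-pi-exclusive",
      forcefield = traj$params[!vapply(traj$params, is.null, logical(1))],
      completed = traj$completed)
    jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory written by [write_trajectory_xyz()]
#'
#' @param path `.xyz` file.
#' @param sidecar optional JSON sidecar path; when found, run metadata
#'   (temperature, seed, salt, force field) is restored.
#' @return a `cg_trajectory` (without velocities).
#' @export
read_trajectory_xyz <- function(path, sidecar = paste0(path, ".json")) {
  lines <- readLines(path)
  frames <- list(); steps <- integer(); times <- numeric()
  chain_id <- NULL; classes <- NULL; L <- NA_real_
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    hdr <- lines[i + 1]
    steps <- c(steps, as.integer(sub(".*step=(\\d+).*", "\\1", hdr)))
    times <- c(times, as.numeric(sub(".*time=([-0-9.eE+]+).*", "\\1", hdr)))
    if (is.na(L)) {
      L <- as.numeric(strsplit(sub('.*Lattice="([^"]+)".*', "\\1", hdr),
                               " ")[[1]][1])
    }
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(block, "\\s+")
    if (is.null(classes)) {
      el <- vapply(parts, `[[`, "", 1L)
      classes <- names(CG_ENCODE)[match(el, CG_ENCODE)]
      chain_id <- as.integer(vapply(parts, `[[`, "", 5L))
    }
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  meta <- if (!is.na(sidecar) && file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else list()
  params <- if (!is.null(meta$forcefield)) {
    ffl <- meta$forcefield
    ffl$cutoff_elec <- if (is.null(ffl$cutoff_elec)) NULL else ffl$cutoff_elec
    do.call(forcefield_params, ffl)
  } else forcefield_params()
  cond <- solvent_conditions(
    ionic_strength = meta$salt %||% 0.02,
    temperature = meta$temperature %||% 300,
    dielectric = meta$dielectric %||% 80,
    ion_radius = meta$ion_radius %||% 4)
  system <- system_configuration(frames[[1]] %% L, chain_id, classes, L,
                                 periodic = meta$periodic %||% TRUE)
  structure(list(frames = frames, steps = steps, times = times,
                 energies = NULL, system = system, params = params,
                 cond = cond, temperature = cond$temperature,
                 seed = meta$seed %||% NA_integer_,
                 timestep = meta$timestep %||% NA_real_,
                 friction = meta$friction %||% NA_real_,
                 completed = meta$completed %||% TRUE),
            class = "cg_trajectory")
}

#' Write the per-frame energy time series of a run to CSV
#' @param traj a `cg_trajectory` produced by [langevin_run()].
#' @param path output CSV path.
#' @export
write_energy_csv <- function(traj, path) {
  stopifnot(inherits(traj, "cg_trajectory"), !is.null(traj$energies))
  utils::write.csv(traj$energies, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
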