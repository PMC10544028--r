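#' Langevin simulation protocol
#'
#' Internal units: energies in kcal/mol, lengths in Angstrom, unit bead mass;
#' the time unit is `sqrt(mass A^2 / (kcal/mol))`. The integrator is the
#' BAOAB splitting of underdamped Langevin dynamics.
#'
#' @param timestep integration step, internal time units (default 0.1, well
#'   below the stability limit of the stiffest bond mode).
#' @param friction Langevin friction, 1/time unit.
#' @param n_steps number of integration steps.
#' @param save_every save a frame every this many steps.
#' @param seed integer seed for the velocity and noise stream.
#' @param temperatures optional temperature list (K) for scans.
#' @return a `cg_protocol`.
#' @export
simulation_protocol <- function(timestep = 0.1, friction = 0.1,
                                n_steps = 10000L, save_every = 100L,
                                seed = 1L, temperatures = NULL) {
  stopifnot(timestep > 0, friction >= 0, n_steps >= 1, save_every >= 1)
  structure(list(timestep = timestep, friction = friction,
                 n_steps = as.integer(n_steps),
                 save_every = as.integer(save_every),
                 seed = as.integer(seed), temperatures = temperatures),
            class = "cg_protocol")
}

#' Run underdamped Langevin dynamics
#'
#' Integrates the system with the BAOAB scheme at the requested thermostat
#' temperature; bit-for-bit reproducible for a given seed (single-threaded
#' engine). Coordinates are propagated unwrapped so displacement statistics
#' remain valid; minimum-image convention handles periodic interactions. A
#' non-finite energy aborts the run, preserving the frames saved so far.
#'
#' @param system a `cg_system`.
#' @param protocol a `cg_protocol`.
#' @param params a `cg_forcefield`.
#' @param cond a `cg_solvent`; `temperature` overrides its temperature field
#'   when given.
#' @param temperature thermostat temperature, K (defaults to
#'   `cond$temperature`).
#' @return a `cg_trajectory`: list with `frames` (list of n x 3 matrices,
#'   unwrapped), `steps`, `times`, `energies` (data.frame per saved frame),
#'   `system`, and run metadata (`params`, `cond`, `temperature`, `seed`,
#'   `completed`).
#' @export
langevin_run <- function(system, protocol, params = forcefield_params(),
                         cond = solvent_conditions(),
                         temperature = cond$temperature) {
  stopifnot(inherits(system, "cg_system"), inherits(protocol, "cg_protocol"))
  cond_t <- cond
  cond_t$temperature <- temperature
  ff <- engine_ff_list(params, cond_t, if (system$periodic)
    system$box_length else Inf)
  kT <- .KB_KCAL * temperature
  res <- langevin_cpp(system$positions, class_codes(system$classes),
                      system$chain_id, system$box_length, system$periodic,
                      ff, protocol$timestep, protocol$friction, kT,
                      protocol$n_steps, protocol$save_every,
                      as.double(protocol$seed))
  n <- nrow(system$positions)
  n_saved <- res$n_saved
  frames <- vector("list", n_saved)
  for (k in seq_len(n_saved)) {
    frames[[k]] <- matrix(res$frames[((k - 1) * 3 * n + 1):(k * 3 * n)],
                          ncol = 3, byrow = TRUE)
  }
  energies <- as.data.frame(res$energies)
  energies$step <- res$steps
  structure(list(frames = frames, steps = res$steps,
                 times = res$steps * protocol$timestep,
                 energies = energies, system = system,
                 params = params, cond = cond_t, temperature = temperature,
                 seed = protocol$seed, timestep = protocol$timestep,
                 friction = protocol$friction,
                 completed = res$completed,
                 final_velocities = res$final_velocities),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("<cg_trajectory> ", length(x$frames), " frames, ",
      nrow(x$system$positions), " beads, T = ", x$temperature, " K",
      if (!x$completed) " [ABORTED: non-finite energy]" else "", "\n",
      sep = "")
  invisible(x)
}

#' Paired temperature scans for the two model variants
#'
#' Runs the cation-pi-inclusive and -exclusive models over a common
#' temperature list with identical seeds and initial configurations, the
#' direct-coexistence protocol behind phase diagrams and the critical-
#' temperature shift. At least three temperatures are required so the binodal
#' fit downstream is identified.
#'
#' @param seq a `cg_sequence`.
#' @param n_chains chain copies in the box.
#' @param box_length cubic box edge, Angstrom.
#' @param temperatures numeric vector (K), length >= 3.
#' @param cond a `cg_solvent` (fixes the salt concentration).
#' @param params a `cg_forcefield`; its `include_cation_pi` flag is
#'   overridden per variant.
#' @param protocol a `cg_protocol` (its `seed` seeds both variants alike).
#' @param placement_fraction passed to [build_initial_configuration()].
#' @return a `cg_scan`: nested list `runs[[variant]][[i]]` of
#'   `cg_trajectory` objects tagged by temperature, model and salt.
#' @export
coexistence_scan <- function(seq, n_chains, box_length, temperatures,
                             cond = solvent_conditions(),
                             params = forcefield_params(),
                             protocol = simulation_protocol(),
                             placement_fraction = 1) {
  if (length(temperatures) < 3) {
    stop("at least 3 temperatures are required for binodal fitting")
  }
  system <- build_initial_configuration(
    seq, n_chains, box_length, seed = protocol$seed, params = params,
    placement_fraction = placement_fraction)
  runs <- list(inclusive = vector("list", length(temperatures)),
               exclusive = vector("list", length(temperatures)))
  for (variant in names(runs)) {
    p_v <- params
    p_v$include_cation_pi <- variant == "inclusive"
    for (i in seq_along(temperatures)) {
      tr <- langevin_run(system, protocol, p_v, cond,
                         temperature = temperatures[i])
      tr$model <- variant
      tr$salt <- cond$ionic_strength
      runs[[variant]][[i]] <- tr
    }
  }
  structure(list(runs = runs, temperatures = temperatures,
                 sequence = seq, cond = cond, n_chains = n_chains,
                 box_length = box_length),
            class = "cg_scan")
}

#' Time-averaged radius of gyration of a single chain
#'
#' Runs one chain in a large open (non-periodic) box and block-averages the
#' instantaneous radius of gyration over the post-equilibration segment.
#'
#' @param seq a `cg_sequence`.
#' @param cond a `cg_solvent`.
#' @param params a `cg_forcefield`.
#' @param protocol a `cg_protocol`.
#' @param equilibration fraction of frames discarded from the front.
#' @param n_blocks number of blocks for the standard error.
#' @param system optional pre-built single-chain `cg_system` (e.g. an exact
#'   rod); default grows one chain in an open box.
#' @return list with `rg` (mean, Angstrom), `se` (block standard error),
#'   `rg_t` (per-frame values) and `flagged` (TRUE when fewer than
#'   `n_blocks` usable frames).
#' @export
single_chain_rg <- function(seq, cond = solvent_conditions(),
                            params = forcefield_params(),
                            protocol = simulation_protocol(),
                            equilibration = 0.5, n_blocks = 5L,
                            system = NULL) {
  if (is.null(system)) {
    box <- max(200, seq$length * params$bond_r0 * 3)
    system <- build_initial_configuration(seq, 1L, box, seed = protocol$seed,
                                          params = params)
    system$periodic <- FALSE
  }
  stopifnot(max(system$chain_id) == 1L)
  tr <- langevin_run(system, protocol, params, cond)
  keep <- tr$frames[seq_along(tr$frames) >
                      floor(equilibration * length(tr$frames))]
  rg_t <- vapply(keep, function(p) {
    cm <- colMeans(p)
    sqrt(mean(rowSums(sweep(p, 2, cm)^2)))
  }, numeric(1))
  flagged <- length(rg_t) < n_blocks
  se <- NA_real_
  if (!flagged) {
    blocks <- split(rg_t, cut(seq_along(rg_t), n_blocks, labels = FALSE))
    bm <- vapply(blocks, mean, numeric(1))
    se <- stats::sd(bm) / sqrt(length(bm))
  }
  list(rg = mean(rg_t), se = se, rg_t = rg_t, flagged = flagged,
       trajectory = tr)
}
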