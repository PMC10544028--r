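# integer encoding of bead classes shared with the C++ engine
class_codes <- function(classes) {
  match(classes, CG_CLASSES)
}

#' Construct (and validate) a many-chain bead configuration
#'
#' @param positions numeric matrix (n_beads x 3), Angstrom.
#' @param chain_id integer vector mapping each bead to its chain (1-based;
#'   chains must be contiguous index ranges).
#' @param classes character vector of bead classes per bead.
#' @param box_length cubic box edge, Angstrom.
#' @param periodic logical; apply periodic boundaries / minimum image.
#' @param sequence optional `cg_sequence` the chains were built from.
#' @return a `cg_system`.
#' @export
system_configuration <- function(positions, chain_id, classes, box_length,
                                 periodic = TRUE, sequence = NULL) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, nrow(positions) == length(chain_id),
            length(classes) == length(chain_id), box_length > 0)
  if (is.unsorted(chain_id)) stop("chains must be contiguous index ranges")
  if (!all(classes %in% CG_CLASSES)) stop("unknown bead class")
  if (periodic) positions <- positions %% box_length
  structure(list(positions = positions, chain_id = as.integer(chain_id),
                 classes = classes, box_length = box_length,
                 periodic = isTRUE(periodic), sequence = sequence),
            class = "cg_system")
}

#' @export
print.cg_system <- function(x, ...) {
  cat("<cg_system> ", nrow(x$positions), " beads in ",
      max(x$chain_id), " chains; box ", x$box_length, " A",
      if (x$periodic) " (periodic)" else "", "\n", sep = "")
  invisible(x)
}

#' Grow an initial many-chain configuration
#'
#' Places `n_chains` copies of a sequence at random positions in a cubic box,
#' each grown as a self-avoiding random walk with step length `bond_r0`; no
#' two beads end up closer than `min_sep`. Placement is deterministic given
#' the seed. `placement_fraction < 1` confines the chain origins to a central
#' sub-box, which seeds a compact droplet for direct-coexistence runs at
#' reduced scale.
#'
#' @param seq a `cg_sequence` (pure 3-letter or classified).
#' @param n_chains number of chain copies.
#' @param box_length cubic box edge, Angstrom.
#' @param seed integer seed.
#' @param params a `cg_forcefield` (supplies `bond_r0` and `sigma_rep`).
#' @param min_sep minimum allowed interbead distance, Angstrom.
#' @param placement_fraction fraction of the box edge (centred) within which
#'   chain start points are drawn.
#' @param max_retries growth retries per chain before the build is rejected.
#' @return a `cg_system`.
#' @export
build_initial_configuration <- function(seq, n_chains, box_length, seed = 1L,
                                        params = forcefield_params(),
                                        min_sep = params$sigma_rep,
                                        placement_fraction = 1,
                                        max_retries = 200L) {
  stopifnot(inherits(seq, "cg_sequence"), n_chains >= 1, box_length > 0,
            placement_fraction > 0, placement_fraction <= 1)
  n_res <- seq$length
  # quick feasibility bound: each bead needs ~min_sep^3 of volume
  if (n_chains * n_res * min_sep^3 > (box_length * placement_fraction)^3) {
    stop("infeasible placement: ", n_chains, " chains of ", n_res,
         " beads cannot fit a ", box_length, " A box at separation ",
         min_sep, " A")
  }
  set.seed(seed)
  b <- params$bond_r0
  lo <- box_length * (1 - placement_fraction) / 2
  hi <- box_length - lo
  all_pos <- matrix(NA_real_, n_chains * n_res, 3)
  n_placed <- 0L
  min2 <- min_sep^2
  # occupancy grid for O(1) neighbour queries during growth
  cell <- max(min_sep, 1e-3)
  n_cell <- max(1L, floor(box_length / cell))
  cell <- box_length / n_cell
  grid <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(ix) paste(ix, collapse = ",")
  cell_of <- function(p) floor((p %% box_length) / cell) %% n_cell
  too_close <- function(p) {
    ix <- cell_of(p)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      k <- key((ix + c(dx, dy, dz)) %% n_cell)
      ids <- grid[[k]]
      if (is.null(ids)) next
      d <- sweep(all_pos[ids, , drop = FALSE], 2, p)
      d <- d - box_length * round(d / box_length)
      if (any(rowSums(d * d) < min2)) return(TRUE)
    }
    FALSE
  }
  register <- function(p, id) {
    k <- key(cell_of(p))
    grid[[k]] <- c(grid[[k]], id)
  }
  for (c_i in seq_len(n_chains)) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      pos <- matrix(NA_real_, n_res, 3)
      pos[1, ] <- stats::runif(3, lo, hi)
      if (too_close(pos[1, ])) next
      ok <- TRUE
      for (r in seq_len(n_res)[-1]) {
        grew <- FALSE
        for (g in 1:30) {
          u <- stats::rnorm(3)
          step <- b * u / sqrt(sum(u^2))
          cand <- pos[r - 1, ] + step
          # self-avoidance within the growing chain (bonded neighbour exempt)
          if (r == 2L) {
            if (too_close(cand)) next
            pos[r, ] <- cand
            grew <- TRUE
            break
          }
          dself <- sweep(pos[seq_len(r - 2), , drop = FALSE], 2, cand)
          dself <- dself - box_length * round(dself / box_length)
          if (any(rowSums(dself * dself) < min2)) next
          if (too_close(cand)) next
          pos[r, ] <- cand
          grew <- TRUE
          break
        }
        if (!grew) { ok <- FALSE; break }
      }
      if (ok) { placed <- TRUE; break }
    }
    if (!placed) {
      stop("placement failure: chain ", c_i, " could not be grown after ",
           max_retries, " retries (box too small or too crowded)")
    }
    idx <- (n_placed + 1):(n_placed + n_res)
    all_pos[idx, ] <- pos
    for (r in seq_len(n_res)) register(pos[r, ], idx[r])
    n_placed <- n_placed + n_res
  }
  system_configuration(all_pos, rep(seq_len(n_chains), each = n_res),
                       rep(seq$residues, n_chains), box_length,
                       periodic = TRUE, sequence = seq)
}

# flat list of engine parameters: force field + solvent-derived quantities
engine_ff_list <- function(params, cond, box_length = Inf) {
  c(unclass(params)[c("eps_pipi", "eps_catpi", "include_cation_pi",
                      "sigma_contact", "sigma_rep", "eps_rep", "k_coulomb",
                      "bond_r0", "bond_k", "angle_theta0", "angle_k",
                      "cutoff_disp")],
    list(cutoff_elec_resolved = resolve_cutoff_elec(params, cond, box_length),
         kappa_d = debye_inverse_length(cond),
         debye_b = debye_B(cond),
         dielectric = cond$dielectric))
}

#' Total potential energy and analytic forces of a configuration
#'
#' Evaluates every term of the model (screened electrostatics, dispersion,
#' excluded-volume repulsion, harmonic bonds and angles) with minimum-image
#' periodic boundaries, returning the energy breakdown and the per-bead force
#' vectors (negative analytic gradient). Nonbonded terms exclude 1-2 and 1-3
#' same-chain pairs; dispersion and electrostatics are truncated and
#' energy-shifted at their cutoffs.
#'
#' @param system a `cg_system`.
#' @param params a `cg_forcefield`.
#' @param cond a `cg_solvent`.
#' @param all_pairs logical; evaluate over all pairs (`TRUE`) or through the
#'   engine's neighbour list (`FALSE`). Results are identical by contract.
#' @param overlap_floor hard minimum interbead distance, Angstrom; closer
#'   configurations are rejected as unphysical.
#' @return list with components `electrostatic`, `dispersion`, `repulsion`,
#'   `bond`, `angle`, `bonded`, `total` (kcal/mol) and `forces`
#'   (n x 3 matrix, kcal/(mol A)).
#' @export
total_energy_forces <- function(system, params = forcefield_params(),
                                cond = solvent_conditions(),
                                all_pairs = TRUE, overlap_floor = 0.5) {
  stopifnot(inherits(system, "cg_system"))
  dmin <- min_pair_distance_cpp(system$positions, system$box_length,
                                system$periodic)
  if (is.finite(dmin) && dmin < overlap_floor) {
    stop("flagged configuration: bead overlap at ", format(dmin, digits = 3),
         " A (< ", overlap_floor, " A floor)")
  }
  ff <- engine_ff_list(params, cond, if (system$periodic)
    system$box_length else Inf)
  out <- energy_forces_cpp(system$positions, class_codes(system$classes),
                           system$chain_id, system$box_length,
                           system$periodic, ff, all_pairs = all_pairs,
                           skin = 2.0)
  out$bonded <- out$bond + out$angle
  out
}
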