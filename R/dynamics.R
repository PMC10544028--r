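#' Per-polymer interchain energy gain from cation-pi interactions
#'
#' For each trajectory, averages the interchain potential energy per
#' condensate-resident chain (each chain's nonbonded energy with all other
#' chains, restricted to chains of the largest cluster) over the
#' post-equilibration frames, then reports the inclusive-minus-exclusive
#' difference. Negative values mean the cation-pi-inclusive condensate
#' stabilises each polymer. Both trajectories must be sampled at matched
#' conditions (same salt; matched reduced temperature).
#'
#' @param traj_incl,traj_excl `cg_trajectory` objects (or lists of
#'   trajectories for independent-run uncertainties) from the inclusive and
#'   exclusive model variants.
#' @param cutoff clustering contact cutoff, Angstrom.
#' @param min_cluster_chains smallest chain count accepted as a condensate.
#' @param equilibration fraction of frames discarded from the front.
#' @return a `cg_energy_gain`: `delta_e` (kcal/mol per polymer),
#'   `e_inclusive`, `e_exclusive` (their per-variant means), per-trajectory
#'   values and, with >= 2 trajectories per variant, a standard deviation.
#' @export
per_polymer_energy_gain <- function(traj_incl, traj_excl, cutoff = 9,
                                    min_cluster_chains = 3L,
                                    equilibration = 0.5) {
  as_list <- function(x) if (inherits(x, "cg_trajectory")) list(x) else x
  traj_incl <- as_list(traj_incl); traj_excl <- as_list(traj_excl)
  one <- function(tr) {
    sys <- tr$system
    ff <- engine_ff_list(tr$params, tr$cond,
                         if (sys$periodic) sys$box_length else Inf)
    idx <- seq_along(tr$frames)
    idx <- idx[idx > floor(equilibration * length(idx))]
    vals <- vapply(idx, function(k) {
      p <- tr$frames[[k]]
      cl <- find_clusters(p, sys$chain_id, sys$box_length, sys$periodic,
                          cutoff)
      chains <- largest_cluster_chains(cl, min_cluster_chains)
      if (is.null(chains)) return(NA_real_)
      e <- interchain_energy_cpp(as.matrix(p), class_codes(sys$classes),
                                 sys$chain_id, sys$box_length, sys$periodic,
                                 ff)
      mean(e[chains])
    }, numeric(1))
    if (all(is.na(vals))) {
      stop("no condensate present in a trajectory: energy gain undefined")
    }
    mean(vals, na.rm = TRUE)
  }
  e_i <- vapply(traj_incl, one, numeric(1))
  e_x <- vapply(traj_excl, one, numeric(1))
  structure(list(delta_e = mean(e_i) - mean(e_x),
                 e_inclusive = mean(e_i), e_exclusive = mean(e_x),
                 per_traj_inclusive = e_i, per_traj_exclusive = e_x,
                 sd = if (length(e_i) > 1 && length(e_x) > 1)
                   sqrt(stats::var(e_i) / length(e_i) +
                          stats::var(e_x) / length(e_x)) else NA_real_),
            class = "cg_energy_gain")
}

#' @export
print.cg_energy_gain <- function(x, ...) {
  cat("<cg_energy_gain> delta E per polymer =",
      format(x$delta_e, digits = 4), "kcal/mol",
      "(inclusive", format(x$e_inclusive, digits = 4), ", exclusive",
      format(x$e_exclusive, digits = 4), ")\n")
  invisible(x)
}

# per-chain centres of mass for every frame: matrix frames x chains x 3
chain_com_series <- function(traj, chains = NULL) {
  sys <- traj$system
  if (is.null(chains)) chains <- seq_len(max(sys$chain_id))
  coms <- lapply(traj$frames, function(p) {
    t(vapply(chains, function(c_i)
      colMeans(p[sys$chain_id == c_i, , drop = FALSE]), numeric(3)))
  })
  coms
}

#' Diffusion coefficient from the mean squared displacement
#'
#' Computes the chain centre-of-mass MSD (averaged over chains and over time
#' origins) on unwrapped coordinates, fits a line (free intercept) over the
#' 10-50% lag window and returns `D = slope / 6` (three-dimensional
#' diffusion). With `residency = TRUE` only chains continuously assigned to
#' the largest cluster across the whole window contribute, isolating
#' dense-phase diffusion.
#'
#' @param traj a `cg_trajectory` with unwrapped frames ([langevin_run()]
#'   output).
#' @param chains chain subset (default all).
#' @param window two fractions of the trajectory time span bounding the MSD
#'   fit window, default `c(0.1, 0.5)`.
#' @param residency logical; require continuous largest-cluster membership.
#' @param cutoff,min_cluster_chains clustering parameters for residency.
#' @return a `cg_diffusion`: `d` (A^2 per time unit), `msd` data.frame
#'   (lag time, msd), `fit` (the `lm`), `n_chains_used`, `residency`.
#' @export
msd_diffusion <- function(traj, chains = NULL, window = c(0.1, 0.5),
                          residency = FALSE, cutoff = 9,
                          min_cluster_chains = 3L) {
  stopifnot(inherits(traj, "cg_trajectory"), length(window) == 2,
            window[1] >= 0, window[2] > window[1])
  if (window[2] > 1) {
    stop("fit window exceeds the trajectory span")
  }
  n_frames <- length(traj$frames)
  if (n_frames < 4) stop("trajectory too short for an MSD fit")
  sys <- traj$system
  if (is.null(chains)) chains <- seq_len(max(sys$chain_id))
  if (residency) {
    resident <- Reduce(intersect, lapply(traj$frames, function(p) {
      cl <- find_clusters(p, sys$chain_id, sys$box_length, sys$periodic,
                          cutoff)
      largest_cluster_chains(cl, min_cluster_chains) %||% integer()
    }))
    chains <- intersect(chains, resident)
    if (length(chains) == 0) {
      stop("empty residency set: no chain stayed in the condensate for the",
           " whole window")
    }
  }
  coms <- chain_com_series(traj, chains)
  arr <- simplify2array(coms)              # chains x 3 x frames
  if (length(chains) == 1L) dim(arr) <- c(1, 3, n_frames)
  max_lag <- n_frames - 1L
  lags <- seq_len(max_lag)
  msd <- vapply(lags, function(l) {
    d <- arr[, , (1 + l):n_frames, drop = FALSE] -
      arr[, , 1:(n_frames - l), drop = FALSE]
    mean(apply(d^2, c(1, 3), sum))
  }, numeric(1))
  dt_frame <- diff(traj$times[1:2])
  tau <- lags * dt_frame
  span <- max(tau)
  sel <- tau >= window[1] * span & tau <= window[2] * span
  fit <- stats::lm(msd[sel] ~ tau[sel])
  d <- max(unname(stats::coef(fit)[2]) / 6, 0)
  structure(list(d = d, msd = data.frame(tau = tau, msd = msd),
                 fit = fit, window = window,
                 n_chains_used = length(chains), residency = residency),
            class = "cg_diffusion")
}

#' @export
print.cg_diffusion <- function(x, ...) {
  cat("<cg_diffusion> D =", format(x$d, digits = 4),
      "A^2/time unit over", x$n_chains_used, "chains",
      if (x$residency) "(condensate-resident)" else "", "\n")
  invisible(x)
}

#' Change in normalised droplet diffusivity between model variants
#'
#' `(D_droplet/D_bulk)_inclusive - (D_droplet/D_bulk)_exclusive`; negative
#' values mean cation-pi interactions slow internal diffusion relative to
#' the dilute phase.
#'
#' @param d_droplet_incl,d_bulk_incl,d_droplet_excl,d_bulk_excl diffusion
#'   coefficients (`cg_diffusion` objects or bare numbers).
#' @return dimensionless difference of ratios.
#' @export
diffusivity_change <- function(d_droplet_incl, d_bulk_incl,
                               d_droplet_excl, d_bulk_excl) {
  val <- function(x) if (inherits(x, "cg_diffusion")) x$d else as.numeric(x)
  bi <- val(d_bulk_incl); bx <- val(d_bulk_excl)
  if (bi <= 0 || bx <= 0) stop("zero bulk diffusivity: ratio undefined")
  val(d_droplet_incl) / bi - val(d_droplet_excl) / bx
}

#' Gyration-tensor shape anisotropy of a bead cloud
#'
#' Eigenvalues of the (unit-mass) gyration tensor
#' `S = (1/N) sum (r - rcm)(r - rcm)^T` characterise the cloud's principal
#' extents; the anisotropy parameter is `(l1 + l2 + l3) / min(l)`. It equals
#' 3 exactly for an isotropic spectrum (spherical condensate) and grows with
#' elongation. Degenerate (coplanar or collinear) sets have a vanishing
#' smallest eigenvalue and are rejected.
#'
#' @param coords n x 3 coordinate matrix (n >= 4).
#' @return a `cg_shape`: sorted `eigenvalues` (decreasing) and `anisotropy`.
#' @examples
#' g <- expand.grid(x = 1:3, y = 1:3, z = 1:3)
#' shape_anisotropy(as.matrix(g))$anisotropy
#' @export
shape_anisotropy <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3)
  if (nrow(coords) < 4) stop("shape anisotropy needs >= 4 beads")
  cc <- sweep(coords, 2, colMeans(coords))
  s <- crossprod(cc) / nrow(coords)
  ev <- sort(eigen(s, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  if (ev[3] <= 1e-10 * sum(ev)) {
    stop("degenerate bead set (coplanar or collinear): anisotropy undefined")
  }
  structure(list(eigenvalues = ev, anisotropy = sum(ev) / ev[3]),
            class = "cg_shape")
}

#' @export
print.cg_shape <- function(x, ...) {
  cat("<cg_shape> anisotropy =", format(x$anisotropy, digits = 4),
      "; eigenvalues:", paste(format(x$eigenvalues, digits = 4),
                              collapse = ", "), "\n")
  invisible(x)
}
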