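#' Identify condensates by single-linkage chain clustering
#'
#' Two chains are linked iff any interchain bead pair lies within the contact
#' cutoff (minimum image); condensates are the connected components of the
#' resulting chain graph. The default cutoff of 9 A is about 1.3 times the
#' dispersion contact distance, so bound pairs are always captured.
#'
#' @param positions n x 3 bead coordinate matrix, or a `cg_system`.
#' @param chain_id per-bead chain index (ignored when a `cg_system` is
#'   given).
#' @param box_length cubic box edge (ignored for a `cg_system`).
#' @param periodic logical (ignored for a `cg_system`).
#' @param cutoff contact cutoff, Angstrom.
#' @return a `cg_clusters`: `labels` (chain -> cluster), `sizes` (chains per
#'   cluster, decreasing), `largest` (label of the largest cluster).
#' @export
find_clusters <- function(positions, chain_id = NULL, box_length = NULL,
                          periodic = TRUE, cutoff = 9) {
  stopifnot(cutoff > 0)
  if (inherits(positions, "cg_system")) {
    chain_id <- positions$chain_id
    box_length <- positions$box_length
    periodic <- positions$periodic
    positions <- positions$positions
  }
  n_chain <- max(chain_id)
  edges <- chain_contact_pairs_cpp(as.matrix(positions),
                                   as.integer(chain_id),
                                   box_length, periodic, cutoff)
  g <- igraph::make_empty_graph(n = n_chain, directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  sizes <- sort(tabulate(comp$membership), decreasing = TRUE)
  largest <- which.max(tabulate(comp$membership))
  structure(list(labels = comp$membership, sizes = sizes,
                 largest = largest, n_chains = n_chain),
            class = "cg_clusters")
}

# chains belonging to the largest cluster, or NULL if below min size
largest_cluster_chains <- function(cl, min_chains) {
  chains <- which(cl$labels == cl$largest)
  if (length(chains) < min_chains) return(NULL)
  chains
}

# occupied-voxel volume (A^3) of a bead set: number of voxels of edge `voxel`
# containing at least one bead, times the voxel volume
occupied_volume <- function(coords, box_length, voxel) {
  ix <- floor((coords %% box_length) / voxel)
  n_occ <- nrow(unique(ix))
  n_occ * voxel^3
}

#' Dense- and dilute-phase bead densities of coexistence trajectories
#'
#' For each analysed frame the largest chain cluster defines the dense phase;
#' its bead density is the cluster's bead count over its occupied-voxel
#' volume (voxel edge = contact cutoff), and the dilute density is the
#' remaining beads over the remaining box volume. Frame values are averaged
#' per trajectory; across several independent trajectories the standard
#' deviation of the trajectory means is reported.
#'
#' @param trajs a `cg_trajectory` or list of them (same temperature).
#' @param cutoff clustering contact cutoff, Angstrom.
#' @param voxel voxel edge of the dense-volume estimator, Angstrom.
#' @param min_cluster_chains smallest chain count accepted as a condensate.
#' @param equilibration fraction of frames discarded from the front.
#' @return a `cg_phase_point`: `temperature`, `rho_dense`, `rho_dilute`
#'   (beads/A^3), `sd_dense`, `sd_dilute` (across trajectories),
#'   `dense_absent` flag (TRUE when no frame had a qualifying condensate, in
#'   which case `rho_dense` is `NA` and `rho_dilute` is the overall density).
#' @export
phase_densities <- function(trajs, cutoff = 9, voxel = cutoff,
                            min_cluster_chains = 3L, equilibration = 0.5) {
  if (inherits(trajs, "cg_trajectory")) trajs <- list(trajs)
  per_traj <- lapply(trajs, function(tr) {
    sys <- tr$system
    n <- nrow(sys$positions)
    idx <- seq_along(tr$frames)
    idx <- idx[idx > floor(equilibration * length(idx))]
    dd <- vapply(idx, function(k) {
      p <- tr$frames[[k]]
      cl <- find_clusters(p, sys$chain_id, sys$box_length, sys$periodic,
                          cutoff)
      chains <- largest_cluster_chains(cl, min_cluster_chains)
      v_box <- sys$box_length^3
      if (is.null(chains)) return(c(NA_real_, n / v_box))
      sel <- sys$chain_id %in% chains
      v_dense <- occupied_volume(p[sel, , drop = FALSE], sys$box_length,
                                 voxel)
      v_dense <- min(v_dense, 0.95 * v_box)
      rho_d <- sum(sel) / v_dense
      rho_l <- (n - sum(sel)) / (v_box - v_dense)
      c(rho_d, rho_l)
    }, numeric(2))
    c(dense = mean(dd[1, ], na.rm = TRUE), dilute = mean(dd[2, ]),
      frac_found = mean(!is.na(dd[1, ])))
  })
  m <- do.call(rbind, per_traj)
  dense_absent <- all(is.nan(m[, "dense"]) | m[, "frac_found"] == 0)
  rho_dense <- if (dense_absent) NA_real_ else mean(m[, "dense"], na.rm = TRUE)
  structure(list(
    temperature = trajs[[1]]$temperature,
    rho_dense = rho_dense,
    rho_dilute = mean(m[, "dilute"]),
    sd_dense = if (nrow(m) > 1 && !dense_absent)
      stats::sd(m[, "dense"]) else NA_real_,
    sd_dilute = if (nrow(m) > 1) stats::sd(m[, "dilute"]) else NA_real_,
    n_trajectories = nrow(m), dense_absent = dense_absent),
    class = "cg_phase_point")
}

#' @export
print.cg_phase_point <- function(x, ...) {
  cat("<cg_phase_point> T =", x$temperature, "K; rho_dense =",
      format(x$rho_dense, digits = 4), "; rho_dilute =",
      format(x$rho_dilute, digits = 4), "beads/A^3\n")
  invisible(x)
}

#' Fit the binodal density gap and extract the critical temperature
#'
#' Least-squares fit of `rho_dense - rho_dilute = A (1 - T/T_C)^beta` with
#' the critical exponent frozen at `beta = 0.325`. Low-temperature points
#' where the density gap shrinks as temperature decreases (re-entrant
#' behaviour, driven by kinetic arrest of short-range contacts) are trimmed
#' from the fit window automatically and reported. A slope-change diagnostic
#' on the dense branch (the temperature at which a two-segment linear fit of
#' `rho_dense(T)` breaks) is returned alongside as an independent check on
#' `T_C`.
#'
#' @param points data.frame with columns `temperature`, `rho_dense`,
#'   `rho_dilute`, or a list of `cg_phase_point` objects.
#' @param beta critical exponent (fixed; default 0.325).
#' @param trim_reentrant logical, trim the low-T re-entrant points.
#' @return object of class `cg_binodal_fit` with components `t_c`,
#'   `amplitude`, `beta`, `points` (used), `trimmed` (excluded rows),
#'   `residuals`, `slope_change_t` and the underlying `nls` fit.
#' @examples
#' tt <- seq(150, 270, by = 20)
#' gap <- 0.004 * pmax(0, 1 - tt / 300)^0.325
#' fit <- fit_critical_temperature(
#'   data.frame(temperature = tt, rho_dense = gap + 1e-5, rho_dilute = 1e-5))
#' coef(fit)
#' @export
fit_critical_temperature <- function(points, beta = 0.325,
                                     trim_reentrant = TRUE) {
  if (is.list(points) && !is.data.frame(points) &&
      inherits(points[[1]], "cg_phase_point")) {
    points <- do.call(rbind, lapply(points, function(p)
      data.frame(temperature = p$temperature, rho_dense = p$rho_dense,
                 rho_dilute = p$rho_dilute)))
  }
  stopifnot(all(c("temperature", "rho_dense", "rho_dilute") %in%
                  names(points)))
  pts <- points[stats::complete.cases(
    points[, c("temperature", "rho_dense", "rho_dilute")]), ]
  pts$gap <- pts$rho_dense - pts$rho_dilute
  pts <- pts[pts$gap > 0, ]
  pts <- pts[order(pts$temperature, decreasing = TRUE), ]
  trimmed <- pts[0, ]
  if (trim_reentrant && nrow(pts) >= 3) {
    # walking from high T down, the gap must be non-decreasing; drop the tail
    ok <- cummax(pts$gap) <= pts$gap * (1 + 1e-9)
    if (any(!ok)) {
      first_bad <- which(!ok)[1]
      trimmed <- pts[first_bad:nrow(pts), ]
      pts <- pts[seq_len(first_bad - 1L), ]
    }
  }
  if (nrow(pts) < 3) {
    stop("binodal fit needs at least 3 points with a positive density gap",
         if (nrow(trimmed) > 0) " after re-entrance trimming" else "")
  }
  t_max <- max(pts$temperature)
  start <- list(t_c = t_max * 1.05, A = max(pts$gap))
  fit <- minpack.lm::nlsLM(
    gap ~ A * pmax(1 - temperature / t_c, 0)^beta,
    data = pts, start = start,
    lower = c(t_c = t_max + 1e-6, A = 0),
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                         ptol = 1e-15))
  co <- stats::coef(fit)
  # slope-change diagnostic on the dense branch
  slope_change_t <- NA_real_
  if (nrow(pts) >= 4) {
    tt <- pts$temperature
    sse <- vapply(2:(nrow(pts) - 1), function(k) {
      lo <- pts[seq_len(k), ]; hi <- pts[k:nrow(pts), ]
      sum(stats::resid(stats::lm(rho_dense ~ temperature, lo))^2) +
        sum(stats::resid(stats::lm(rho_dense ~ temperature, hi))^2)
    }, numeric(1))
    slope_change_t <- tt[1 + which.min(sse)]
  }
  structure(list(t_c = unname(co["t_c"]), amplitude = unname(co["A"]),
                 beta = beta, points = pts, trimmed = trimmed,
                 residuals = stats::resid(fit),
                 slope_change_t = slope_change_t, fit = fit),
            class = "cg_binodal_fit")
}

#' @rdname fit_critical_temperature
#' @param ... passed through to [fit_critical_temperature()].
#' @export
fit_binodal <- function(points, ...) fit_critical_temperature(points, ...)

#' @export
print.cg_binodal_fit <- function(x, ...) {
  cat("<cg_binodal_fit> T_C =", format(x$t_c, digits = 5),
      "K; A =", format(x$amplitude, digits = 4),
      "; beta =", x$beta, "(fixed)\n")
  cat("  fitted on", nrow(x$points), "points;",
      nrow(x$trimmed), "re-entrant point(s) trimmed\n")
  invisible(x)
}

#' @export
coef.cg_binodal_fit <- function(object, ...) {
  c(t_c = object$t_c, A = object$amplitude, beta = object$beta)
}

#' @export
summary.cg_binodal_fit <- function(object, ...) {
  out <- list(coef = coef(object),
              rse = sqrt(mean(object$residuals^2)),
              n = nrow(object$points), trimmed = nrow(object$trimmed),
              slope_change_t = object$slope_change_t,
              nls_summary = summary(object$fit))
  class(out) <- "summary.cg_binodal_fit"
  out
}

#' @export
print.summary.cg_binodal_fit <- function(x, ...) {
  cat("Binodal fit: gap = A (1 - T/T_C)^beta, beta fixed at",
      x$coef[["beta"]], "\n")
  cat("  T_C =", format(x$coef[["t_c"]], digits = 6),
      " A =", format(x$coef[["A"]], digits = 4), "\n")
  cat("  points:", x$n, " trimmed:", x$trimmed,
      " RMS residual:", format(x$rse, digits = 3), "\n")
  cat("  dense-branch slope change near T =",
      format(x$slope_change_t, digits = 5), "\n")
  invisible(x)
}

#' @export
predict.cg_binodal_fit <- function(object, newdata = NULL, ...) {
  tt <- if (is.null(newdata)) object$points$temperature
        else newdata$temperature
  object$amplitude * pmax(1 - tt / object$t_c, 0)^object$beta
}

#' @export
residuals.cg_binodal_fit <- function(object, ...) object$residuals

#' @export
plot.cg_binodal_fit <- function(x, ...) {
  p <- x$points
  graphics::plot(c(p$rho_dilute, p$rho_dense),
                 c(p$temperature, p$temperature),
                 xlab = expression(rho ~ (beads/A^3)),
                 ylab = "T (K)", main = "Binodal", ...)
  tt <- seq(min(p$temperature), x$t_c, length.out = 100)
  gap <- predict(x, data.frame(temperature = tt))
  mid <- (p$rho_dense + p$rho_dilute) / 2
  mid_f <- stats::approx(p$temperature, mid, xout = tt, rule = 2)$y
  graphics::lines(mid_f - gap / 2, tt, lty = 2)
  graphics::lines(mid_f + gap / 2, tt, lty = 2)
  graphics::abline(h = x$t_c, col = "grey50", lty = 3)
  invisible(x)
}

#' Critical-temperature shift between model variants, in percent
#'
#' `100 (T_C,incl - T_C,excl) / T_C,excl`: the stabilisation contributed by
#' cation-pi interactions, normalised by the exclusive-model critical
#' temperature.
#'
#' @param fit_incl,fit_excl `cg_binodal_fit` objects (or bare numbers).
#' @return percentage (positive when the inclusive model is more stable).
#' @export
delta_tc_percent <- function(fit_incl, fit_excl) {
  tc <- function(f) if (inherits(f, "cg_binodal_fit")) f$t_c else as.numeric(f)
  100 * (tc(fit_incl) - tc(fit_excl)) / tc(fit_excl)
}
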