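test_that("chain clustering matches the transitive-closure oracle", {
  # two distant chains: singletons
  pos <- rbind(cbind(1:5 * 3.8, 10, 10), cbind(1:5 * 3.8, 100, 100))
  cl <- find_clusters(pos, rep(1:2, each = 5), 300, TRUE, cutoff = 9)
  expect_equal(cl$sizes, c(1, 1))

  # planted 5/3/2 groups
  pl <- cgphase:::planted_cluster_frame(seed = 4)
  cl2 <- find_clusters(pl$positions, pl$chain_id, pl$box, TRUE, cutoff = 9)
  expect_equal(cl2$sizes, c(5, 3, 2))
  edges <- cgphase:::chain_contact_pairs_cpp(pl$positions,
                                             as.integer(pl$chain_id),
                                             pl$box, TRUE, 9)
  oracle <- oracle_components(edges, max(pl$chain_id))
  expect_equal(canonical_partition(cl2$labels), canonical_partition(oracle))

  # all chains overlapping: one cluster
  pos3 <- do.call(rbind, lapply(1:4, function(i)
    cbind(1:5 * 3.8, 50 + i, 50)))
  cl3 <- find_clusters(pos3, rep(1:4, each = 5), 300, TRUE, cutoff = 9)
  expect_equal(cl3$sizes, 4)

  # randomized frames against the oracle, exhaustive on <= 12 chains
  set.seed(31)
  for (rep_i in 1:15) {
    n_chain <- sample(3:12, 1)
    pos_r <- do.call(rbind, lapply(seq_len(n_chain), function(i) {
      base <- runif(3, 0, 120)
      t(replicate(4, base + runif(3, -4, 4)))
    }))
    ch <- rep(seq_len(n_chain), each = 4)
    cl_r <- find_clusters(pos_r, ch, 120, TRUE, cutoff = 15)
    edges_r <- cgphase:::chain_contact_pairs_cpp(pos_r, as.integer(ch),
                                                 120, TRUE, 15)
    expect_equal(canonical_partition(cl_r$labels),
                 canonical_partition(oracle_components(edges_r, n_chain)))
  }
})

# wrap a single frame as a one-frame trajectory for density analysis
frame_trajectory <- function(positions, chain_id, classes, box,
                             temperature = 300) {
  sys <- system_configuration(positions, chain_id, classes, box)
  structure(list(frames = list(positions), steps = 0L, times = 0,
                 energies = NULL, system = sys,
                 params = forcefield_params(), cond = solvent_conditions(),
                 temperature = temperature, seed = 1L, timestep = 0.1,
                 friction = 0.1, completed = TRUE),
            class = "cg_trajectory")
}

test_that("phase densities recover a planted dense cube within bias bounds", {
  pd <- cgphase:::planted_density_box(seed = 2)
  # each bead its own chain, all within the contact cutoff of a neighbour
  n <- nrow(pd$positions)
  tr <- frame_trajectory(pd$positions, seq_len(n), rep("ARO", n), pd$box)
  pp <- phase_densities(tr, cutoff = 9, equilibration = 0)
  expect_false(pp$dense_absent)
  # documented bias bound of the occupied-voxel estimator: 25 percent
  expect_lt(abs(pp$rho_dense - pd$rho_true) / pd$rho_true, 0.25)
  expect_lt(pp$rho_dilute, 0.1 * pd$rho_true)

  # dispersed gas: dense phase flagged absent, dilute density = N/V
  set.seed(5)
  gas <- matrix(runif(60, 0, 200), ncol = 3)
  tr_gas <- frame_trajectory(gas, 1:20, rep("POS", 20), 200)
  pp_gas <- phase_densities(tr_gas, cutoff = 9, equilibration = 0)
  expect_true(pp_gas$dense_absent)
  expect_true(is.na(pp_gas$rho_dense))
  expect_equal(pp_gas$rho_dilute, 20 / 200^3)

  # identical trajectories: zero standard deviation across replicates
  pp2 <- phase_densities(list(tr, tr), cutoff = 9, equilibration = 0)
  expect_equal(pp2$sd_dense, 0)
  expect_equal(pp2$sd_dilute, 0)
})

test_that("binodal fit recovers exact and noisy synthetic data", {
  pts <- cgphase:::binodal_points(t_c = 300, A = 0.004, beta = 0.325,
                                  temperatures = seq(150, 285, by = 15))
  fit <- fit_critical_temperature(pts)
  expect_equal(fit$t_c, 300, tolerance = 1e-6)
  expect_equal(fit$amplitude, 0.004, tolerance = 1e-6)
  expect_equal(fit$beta, 0.325)

  # T_C invariant under uniform density rescaling
  pts_s <- pts
  pts_s$rho_dense <- pts$rho_dense * 7.3
  pts_s$rho_dilute <- pts$rho_dilute * 7.3
  expect_equal(fit_critical_temperature(pts_s)$t_c, fit$t_c,
               tolerance = 1e-9)

  # 2 points rejected
  expect_error(fit_critical_temperature(pts[1:2, ]), "at least 3")

  # median T_C error under 2 percent multiplicative noise, 50 replicates
  set.seed(12)
  errs <- replicate(50, {
    noisy <- pts
    noisy$rho_dense <- pts$rho_dense * (1 + rnorm(nrow(pts), 0, 0.02))
    abs(fit_critical_temperature(noisy)$t_c - 300) / 300
  })
  expect_lte(median(errs), 0.02)
})

test_that("re-entrant low-temperature points are trimmed before fitting", {
  pts <- cgphase:::binodal_points(t_c = 300, A = 0.004, beta = 0.325,
                                  temperatures = seq(180, 285, by = 15))
  reent <- data.frame(temperature = c(150, 165),
                      rho_dense = c(0.0020, 0.0028),
                      rho_dilute = c(1e-5, 1e-5))
  fit <- fit_critical_temperature(rbind(reent, pts))
  expect_equal(nrow(fit$trimmed), 2)
  expect_equal(sort(fit$trimmed$temperature), c(150, 165))
  expect_equal(fit$t_c, 300, tolerance = 1e-6)
})

test_that("delta T_C percentages follow from the fits", {
  pts <- cgphase:::binodal_points(300, 0.004, 0.325, seq(150, 285, 15))
  fit <- fit_critical_temperature(pts)
  expect_equal(delta_tc_percent(fit, fit), 0)
  expect_equal(delta_tc_percent(450, 300), 50)
  # planted 30 percent gap recovered through the full fit pipeline
  pts_i <- cgphase:::binodal_points(390, 0.0045, 0.325, seq(150, 285, 15))
  fit_i <- fit_critical_temperature(pts_i)
  fit_x <- fit_critical_temperature(pts)
  expect_equal(delta_tc_percent(fit_i, fit_x), 30, tolerance = 1e-4)
})

test_that("a single cation-pi contact changes the energy by its well depth", {
  pos <- rbind(c(50, 50, 50), c(57, 50, 50))
  sys <- system_configuration(pos, c(1, 2), c("ARO", "POS"), 200,
                              periodic = FALSE)
  cond <- solvent_conditions()
  e_incl <- total_energy_forces(sys, forcefield_params(
    include_cation_pi = TRUE), cond)$total
  e_excl <- total_energy_forces(sys, forcefield_params(
    include_cation_pi = FALSE), cond)$total
  # derived expectation: shifted 12-6 at its optimum
  eps <- 0.2; rc <- 17.5; sr6 <- (7 / rc)^6
  expected <- -eps - eps * (sr6^2 - 2 * sr6)
  expect_equal(e_incl - e_excl, expected, tolerance = 1e-12)
})

test_that("energy gain vanishes without aromatic residues", {
  seq <- coarse_sequence(rep(c("POS", "NEG"), 10))
  sys <- build_initial_configuration(seq, 4, 60, seed = 3,
                                     placement_fraction = 0.6,
                                     min_sep = 6.5)
  proto <- simulation_protocol(timestep = 0.05, friction = 0.1,
                               n_steps = 1500, save_every = 150, seed = 3)
  cond <- solvent_conditions(ionic_strength = 0.02, temperature = 120)
  tr_i <- langevin_run(sys, proto, forcefield_params(
    include_cation_pi = TRUE), cond, 120)
  tr_x <- langevin_run(sys, proto, forcefield_params(
    include_cation_pi = FALSE), cond, 120)
  g <- per_polymer_energy_gain(tr_i, tr_x, min_cluster_chains = 2L)
  expect_equal(g$delta_e, 0)
})

test_that("MSD diffusion recovers a planted Brownian coefficient", {
  br <- cgphase:::brownian_com_tracks(n_chains = 40, n_frames = 250,
                                      dt = 1, d_true = 5, seed = 8)
  tr <- tracks_to_trajectory(br$table)
  est <- msd_diffusion(tr)
  # empirical CI from single-chain estimates
  d_i <- vapply(1:40, function(c_i)
    msd_diffusion(tr, chains = c_i)$d, numeric(1))
  ci <- mean(d_i) + c(-3, 3) * sd(d_i) / sqrt(length(d_i))
  expect_gte(5, ci[1])
  expect_lte(5, ci[2])
  expect_equal(est$d, 5, tolerance = 0.2)

  # frozen coordinates diffuse nowhere
  frz <- br$table
  frz[, c("x", "y", "z")] <- 0
  expect_equal(msd_diffusion(tracks_to_trajectory(frz))$d, 0)

  # window beyond the trajectory span is rejected
  expect_error(msd_diffusion(tr, window = c(0.5, 2)), "exceeds")
})

test_that("residency filtering keeps only continuously condensed chains", {
  # 4 tight chains plus 2 far-away singletons, static over 6 frames
  centre <- c(60, 60, 60)
  mk_chain <- function(origin) cbind(origin[1] + (0:3) * 3.8, origin[2],
                                     origin[3])
  pos <- rbind(mk_chain(centre), mk_chain(centre + c(0, 4, 0)),
               mk_chain(centre + c(0, 0, 4)), mk_chain(centre + c(0, 4, 4)),
               mk_chain(c(10, 10, 10)), mk_chain(c(110, 110, 110)))
  ch <- rep(1:6, each = 4)
  sys <- system_configuration(pos, ch, rep("ARO", 24), 240)
  frames <- replicate(6, pos, simplify = FALSE)
  tr <- structure(list(frames = frames, steps = 0:5, times = 0:5,
                       energies = NULL, system = sys,
                       params = forcefield_params(),
                       cond = solvent_conditions(), temperature = 300,
                       seed = 1L, timestep = 1, friction = 0.1,
                       completed = TRUE), class = "cg_trajectory")
  est <- msd_diffusion(tr, residency = TRUE)
  expect_equal(est$n_chains_used, 4)
  # an all-dilute trajectory has an empty residency set
  tr_far <- tr
  tr_far$system$chain_id <- rep(1:12, each = 2)
  expect_error(msd_diffusion(tr_far, residency = TRUE,
                             min_cluster_chains = 12L), "empty residency")
})

test_that("diffusivity change is the difference of the two ratios", {
  expect_equal(diffusivity_change(1, 2, 1, 2), 0)
  expect_equal(diffusivity_change(0.2, 1, 0.5, 1), -0.3)
  expect_error(diffusivity_change(1, 0, 1, 2), "zero bulk")
  # planted ratios recovered end-to-end from Brownian fixtures
  br_fast <- cgphase:::brownian_com_tracks(80, 300, 1, d_true = 4, seed = 2)
  br_slow <- cgphase:::brownian_com_tracks(80, 300, 1, d_true = 1, seed = 3)
  d_b <- msd_diffusion(tracks_to_trajectory(br_fast$table))$d
  d_d <- msd_diffusion(tracks_to_trajectory(br_slow$table))$d
  change <- diffusivity_change(d_d, d_b, d_b, d_b)
  expect_equal(change, 1 / 4 - 1, tolerance = 0.12)
})

test_that("shape anisotropy: sphere anchor, planted axes, degeneracy", {
  g <- as.matrix(expand.grid(x = 1:4, y = 1:4, z = 1:4))
  s <- shape_anisotropy(g)
  expect_equal(s$anisotropy, 3)

  # Gaussian cloud with axis standard deviations 2:1:1 -> anisotropy 6
  set.seed(17)
  n <- 60000
  cloud <- cbind(rnorm(n, 0, 2), rnorm(n, 0, 1), rnorm(n, 0, 1))
  s2 <- shape_anisotropy(cloud)
  expect_equal(s2$anisotropy, 6, tolerance = 0.05)
  # cross-check against a direct eigen-decomposition
  ev <- sort(eigen(crossprod(sweep(cloud, 2, colMeans(cloud))) / n,
                   symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  expect_equal(s2$eigenvalues, ev, tolerance = 1e-12)
  expect_equal(s2$anisotropy, sum(ev) / ev[3], tolerance = 1e-12)

  # rotation and translation invariance; always >= 3
  th <- 0.7
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  s3 <- shape_anisotropy(sweep(cloud %*% rot, 2, c(5, -3, 11), "+"))
  expect_equal(s3$anisotropy, s2$anisotropy, tolerance = 1e-8)
  set.seed(23)
  for (i in 1:10) {
    pts <- matrix(rnorm(3 * 30), ncol = 3) %*% diag(runif(3, 0.5, 3))
    expect_gte(shape_anisotropy(pts)$anisotropy, 3)
  }

  expect_error(shape_anisotropy(cbind(1:9, 0, 0)), "degenerate")
  expect_error(shape_anisotropy(cbind(1:3, 1, 1)), ">= 4 beads")
})
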