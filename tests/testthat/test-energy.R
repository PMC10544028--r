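test_that("Debye screening follows the closed-form aqueous relation", {
  expect_equal(debye_inverse_length(solvent_conditions(ionic_strength = 0)),
               0)
  # independent assembly of the closed form: lambda_D = C / sqrt(I) at
  # fixed T, eps, with C from the physical constants
  cond <- solvent_conditions(ionic_strength = 0.02, temperature = 300,
                             dielectric = 80)
  c_oracle <- sqrt(80 * 8.8541878128e-12 * 1.380649e-23 * 300 /
                     (2000 * 6.02214076e23 * 1.602176634e-19^2)) * 1e10
  expect_equal(1 / debye_inverse_length(cond), c_oracle / sqrt(0.02),
               tolerance = 1e-12)
  # sqrt(I) scaling: 4x the salt halves the screening length
  cond4 <- solvent_conditions(ionic_strength = 0.08)
  expect_equal(1 / debye_inverse_length(cond4),
               0.5 / debye_inverse_length(cond), tolerance = 1e-12)
  # B factor: exp(ka)/(1+ka), unity without salt
  expect_equal(debye_B(solvent_conditions(ionic_strength = 0)), 1)
  ka <- debye_inverse_length(cond) * 4
  expect_equal(debye_B(cond), exp(ka) / (1 + ka), tolerance = 1e-12)
})

test_that("electrostatic pair energy: Coulomb anchor, nulls and screening", {
  cond0 <- solvent_conditions(ionic_strength = 0, dielectric = 1)
  expect_equal(electrostatic_pair_energy(1, 1, 1, cond0), 332)
  expect_equal(electrostatic_pair_energy(0, 1, 5, cond0), 0)
  expect_error(electrostatic_pair_energy(1, 1, 0, cond0), "r must be")
  # symmetric in (i, j), sign from charge product
  c2 <- solvent_conditions(ionic_strength = 0.02)
  expect_equal(electrostatic_pair_energy(1, -1, 6, c2),
               electrostatic_pair_energy(-1, 1, 6, c2))
  # screening monotonicity vs direct formula at both salts, every r
  lo <- solvent_conditions(ionic_strength = 0.02)
  hi <- solvent_conditions(ionic_strength = 0.06)
  rr <- seq(3, 40, by = 0.5)
  e_lo <- electrostatic_pair_energy(1, 1, rr, lo)
  e_hi <- electrostatic_pair_energy(1, 1, rr, hi)
  oracle <- function(cond, r) {
    kd <- debye_inverse_length(cond)
    332 * exp(kd * 4) / (1 + kd * 4) * exp(-kd * r) / (80 * r)
  }
  expect_equal(e_lo, oracle(lo, rr), tolerance = 1e-12)
  expect_equal(e_hi, oracle(hi, rr), tolerance = 1e-12)
  expect_true(all(abs(e_hi) < abs(e_lo)))
})

test_that("12-6 dispersion has its minimum at sigma with depth eps", {
  expect_equal(dispersion_pair_energy(7, 0.2, 7), -0.2)
  opt <- optimize(dispersion_pair_energy, c(4, 14), eps = 0.2, sigma = 7)
  expect_equal(opt$minimum, 7, tolerance = 1e-5)
  expect_equal(dispersion_pair_energy(14, 0.2, 7),
               0.2 * ((1 / 2)^12 - 2 * (1 / 2)^6), tolerance = 1e-12)
  # truncated-shifted variant vanishes at and beyond the cutoff
  expect_equal(dispersion_pair_energy(17.5, 0.2, 7, cutoff = 17.5), 0)
  expect_equal(dispersion_pair_energy(20, 0.2, 7, cutoff = 17.5), 0)
  expect_error(dispersion_pair_energy(-1, 0.2, 7), "r must be")
})

test_that("excluded-volume repulsion is a truncated r^-12 core", {
  p <- forcefield_params()
  expect_equal(repulsion_pair_energy(4, p), 0.2)
  expect_equal(repulsion_pair_energy(8, p), 0.2 / 4096, tolerance = 1e-15)
  rr <- seq(1, 7.9, by = 0.1)
  e <- repulsion_pair_energy(rr, p)
  expect_equal(e, 0.2 * (4 / rr)^12, tolerance = 1e-12)
  expect_true(all(diff(e) < 0))
  expect_equal(repulsion_pair_energy(9, p), 0)
})

test_that("pair dispatch activates the right terms per class pair", {
  incl <- forcefield_params(include_cation_pi = TRUE)
  excl <- forcefield_params(include_cation_pi = FALSE)
  expect_setequal(pair_interaction_dispatch("ARO", "POS", excl),
                  "repulsion")
  expect_setequal(pair_interaction_dispatch("ARO", "POS", incl),
                  c("dispersion", "repulsion"))
  expect_setequal(pair_interaction_dispatch("ARO", "ARO", excl),
                  c("dispersion", "repulsion"))
  expect_setequal(pair_interaction_dispatch("POS", "NEG", incl),
                  c("electrostatics", "repulsion"))
  expect_setequal(pair_interaction_dispatch("POS", "POS", incl),
                  c("electrostatics", "repulsion"))
  expect_setequal(pair_interaction_dispatch("ARO", "NEG", incl),
                  "repulsion")
  expect_setequal(pair_interaction_dispatch("NEU", "POS", incl),
                  "repulsion")
})

test_that("forces equal the negative finite-difference gradient", {
  cond <- solvent_conditions(ionic_strength = 0.02)
  params <- forcefield_params()
  for (seed in c(1, 2, 3)) {
    sys <- make_test_system(seed)
    out <- total_energy_forces(sys, params, cond)
    expect_equal(out$total, out$electrostatic + out$dispersion +
                   out$repulsion + out$bond + out$angle)
    fd <- fd_forces(sys, params, cond)
    scale <- max(abs(fd))
    expect_lt(max(abs(out$forces - fd)) / scale, 1e-6)
  }
  # each term individually: switch the others off (small jitter so bonds
  # and angles are off their rest geometry and exert real forces)
  sys <- make_test_system(4)
  set.seed(14)
  sys$positions <- sys$positions +
    matrix(runif(length(sys$positions), -0.05, 0.05), ncol = 3)
  variants <- list(
    forcefield_params(eps_pipi = 0, eps_catpi = 0, eps_rep = 0,
                      bond_k = 0, angle_k = 0),              # elec only
    forcefield_params(k_coulomb = 0, eps_rep = 0, bond_k = 0,
                      angle_k = 0),                          # dispersion only
    forcefield_params(k_coulomb = 0, eps_pipi = 0, eps_catpi = 0,
                      bond_k = 0, angle_k = 0),              # repulsion only
    forcefield_params(k_coulomb = 0, eps_pipi = 0, eps_catpi = 0,
                      eps_rep = 0, angle_k = 0),             # bonds only
    forcefield_params(k_coulomb = 0, eps_pipi = 0, eps_catpi = 0,
                      eps_rep = 0, bond_k = 0))              # angles only
  for (p in variants) {
    out <- total_energy_forces(sys, p, cond)
    fd <- fd_forces(sys, p, cond)
    expect_lt(max(abs(out$forces - fd)) / max(abs(fd)), 1e-6)
  }
})

test_that("isolated far-apart beads have zero energy and forces", {
  pos <- rbind(c(10, 10, 10), c(150, 150, 150))
  sys <- system_configuration(pos, c(1, 2), c("POS", "NEG"), 1e4,
                              periodic = FALSE)
  out <- total_energy_forces(sys, forcefield_params(cutoff_elec = 35),
                             solvent_conditions())
  expect_equal(out$total, 0)
  expect_equal(max(abs(out$forces)), 0)
})

test_that("energy is invariant under translation and rotation (open box)", {
  sys <- make_test_system(5)
  cond <- solvent_conditions()
  e0 <- total_energy_forces(sys, cond = cond)$total
  sys_t <- sys
  sys_t$positions <- sweep(sys$positions, 2, c(11.3, -40.2, 5.5), "+")
  expect_equal(total_energy_forces(sys_t, cond = cond)$total, e0,
               tolerance = 1e-10)
  th <- 0.83
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  sys_r <- sys
  sys_r$positions <- sys$positions %*% rot
  expect_equal(total_energy_forces(sys_r, cond = cond)$total, e0,
               tolerance = 1e-10)
})

test_that("minimum image: integer-lattice translates have equal energy", {
  set.seed(8)
  seq <- coarse_sequence(rep(c("POS", "NEG", "ARO"), 3))
  sys <- build_initial_configuration(seq, 3, 50, seed = 8)
  cond <- solvent_conditions(ionic_strength = 0.06)
  e0 <- total_energy_forces(sys, cond = cond)$total
  sys_t <- sys
  sys_t$positions <- sys$positions +
    matrix(50 * c(2, -1, 3), nrow(sys$positions), 3, byrow = TRUE)
  expect_equal(total_energy_forces(sys_t, cond = cond)$total, e0,
               tolerance = 1e-9)
})

test_that("neighbour-list evaluation matches all-pairs exactly", {
  seq <- coarse_sequence(rep(c("POS", "NEG", "ARO"), 4))
  sys <- build_initial_configuration(seq, 4, 70, seed = 12)
  cond <- solvent_conditions(ionic_strength = 0.06)
  a <- total_energy_forces(sys, cond = cond, all_pairs = TRUE)
  b <- total_energy_forces(sys, cond = cond, all_pairs = FALSE)
  expect_identical(a$total, b$total)
  expect_identical(a$forces, b$forces)
})

test_that("zero-strength cation-pi reproduces the exclusive model exactly", {
  sys <- make_test_system(9)
  cond <- solvent_conditions()
  incl0 <- total_energy_forces(sys, forcefield_params(
    eps_catpi = 0, include_cation_pi = TRUE), cond)
  excl <- total_energy_forces(sys, forcefield_params(
    include_cation_pi = FALSE), cond)
  expect_identical(incl0$total, excl$total)
  expect_identical(incl0$forces, excl$forces)
  expect_identical(incl0$dispersion, excl$dispersion)
})

test_that("inclusive model is never higher in energy at contact range", {
  # ARO and POS beads exactly at the dispersion optimum: adding the
  # cation-pi term can only lower the energy
  pos <- rbind(c(50, 50, 50), c(57, 50, 50))
  sys <- system_configuration(pos, c(1, 2), c("ARO", "POS"), 200,
                              periodic = FALSE)
  cond <- solvent_conditions()
  e_incl <- total_energy_forces(sys, forcefield_params(
    include_cation_pi = TRUE), cond)$total
  e_excl <- total_energy_forces(sys, forcefield_params(
    include_cation_pi = FALSE), cond)$total
  expect_lt(e_incl, e_excl)
})

test_that("overlapping beads below the hard floor are flagged", {
  pos <- rbind(c(50, 50, 50), c(50.2, 50, 50))
  sys <- system_configuration(pos, c(1, 2), c("POS", "NEG"), 200,
                              periodic = FALSE)
  expect_error(total_energy_forces(sys), "flagged configuration")
})

test_that("force-field config files round-trip through key = value text", {
  params <- forcefield_params(eps_catpi = 0.3, include_cation_pi = FALSE,
                              cutoff_elec = 42)
  cond <- solvent_conditions(ionic_strength = 0.06, temperature = 250)
  path <- tempfile(fileext = ".cfg")
  write_ff_config(params, cond, path)
  back <- read_ff_config(path)
  expect_equal(back$params[names(back$params) != "cutoff_elec"],
               params[names(params) != "cutoff_elec"])
  expect_equal(back$params$cutoff_elec, 42)
  expect_equal(back$cond, cond)
  # malformed line is reported
  writeLines(c("eps_pipi = 0.2", "nonsense line"), path)
  expect_error(read_ff_config(path), "malformed")
  unlink(path)
})
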