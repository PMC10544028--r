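# physical constants (SI) used to assemble the Debye screening relation
.NA_AVOGADRO <- 6.02214076e23
.E_CHARGE <- 1.602176634e-19
.KB_SI <- 1.380649e-23
.EPS0 <- 8.8541878128e-12
.KB_KCAL <- 0.0019872041  # Boltzmann constant, kcal/(mol K)

#' Solvent conditions for the screened-electrostatics model
#'
#' @param ionic_strength monovalent salt ionic strength, mol/L.
#' @param temperature absolute temperature, K.
#' @param dielectric relative solvent dielectric constant (80 for water).
#' @param ion_radius effective ion radius `a` entering the finite-ion-size
#'   factor `B`, in Angstrom.
#' @return a `cg_solvent` list.
#' @export
solvent_conditions <- function(ionic_strength = 0.02, temperature = 300,
                               dielectric = 80, ion_radius = 4) {
  stopifnot(ionic_strength >= 0, temperature > 0, dielectric > 0,
            ion_radius > 0)
  structure(list(ionic_strength = ionic_strength, temperature = temperature,
                 dielectric = dielectric, ion_radius = ion_radius),
            class = "cg_solvent")
}

#' Inverse Debye screening length
#'
#' `kappa_D = sqrt(2000 N_A e^2 I / (eps eps0 kB T))` for a 1:1 salt,
#' expressed in 1/Angstrom; `1/kappa_D` is the Debye screening length. Zero
#' ionic strength gives `kappa_D = 0` (unscreened Coulomb). At 300 K and
#' dielectric 80 the screening length is about `3.08/sqrt(I[M])` Angstrom.
#'
#' @param cond a `cg_solvent`.
#' @return inverse length in 1/Angstrom.
#' @examples
#' 1 / debye_inverse_length(solvent_conditions(ionic_strength = 0.02))
#' @export
debye_inverse_length <- function(cond) {
  stopifnot(inherits(cond, "cg_solvent"))
  if (cond$ionic_strength == 0) return(0)
  k2 <- 2000 * .NA_AVOGADRO * .E_CHARGE^2 * cond$ionic_strength /
    (cond$dielectric * .EPS0 * .KB_SI * cond$temperature)  # 1/m^2
  sqrt(k2) * 1e-10
}

#' Finite-ion-size Debye--Hueckel prefactor B
#'
#' `B(kappa_D) = exp(kappa_D a) / (1 + kappa_D a)`, the standard correction
#' for ions of radius `a`; `B(0) = 1` recovers the bare Coulomb potential.
#'
#' @param cond a `cg_solvent`.
#' @return dimensionless factor >= 1.
#' @export
debye_B <- function(cond) {
  ka <- debye_inverse_length(cond) * cond$ion_radius
  exp(ka) / (1 + ka)
}

#' Force-field parameters of the coarse-grained model
#'
#' Defaults reproduce the reference parameterisation: pi-pi and cation-pi
#' dispersion wells of 0.2 kcal/mol at an optimal contact distance of 7 A,
#' excluded-volume repulsion with sigma 4 A, Coulomb constant 332
#' kcal A/(mol e^2), harmonic bonds (r0 = 3.8 A, k = 20 kcal/(mol A^2)) and a
#' weak harmonic angle term (theta0 = 2.12 rad, k = 2 kcal/(mol rad^2)); no
#' dihedrals. `include_cation_pi` switches the ARO-POS dispersion term on and
#' off, defining the cation-pi-inclusive and -exclusive model variants.
#'
#' @param eps_pipi pi-pi well depth, kcal/mol.
#' @param eps_catpi cation-pi well depth, kcal/mol.
#' @param include_cation_pi logical; include the ARO-POS dispersion term.
#' @param sigma_contact optimal dispersion contact distance, A.
#' @param sigma_rep excluded-volume length scale, A.
#' @param eps_rep excluded-volume prefactor, kcal/mol.
#' @param k_coulomb Coulomb constant, kcal A/(mol e^2).
#' @param bond_r0,bond_k harmonic bond rest length (A) and stiffness.
#' @param angle_theta0,angle_k harmonic angle rest angle (rad) and stiffness.
#' @param cutoff_disp dispersion cutoff, A (energy-shifted to 0 there).
#' @param cutoff_elec electrostatic cutoff, A; `NULL` selects
#'   `max(35, 4 / kappa_D)` at run time (capped at half the box length).
#' @return a `cg_forcefield` list.
#' @export
forcefield_params <- function(eps_pipi = 0.2, eps_catpi = 0.2,
                              include_cation_pi = TRUE,
                              sigma_contact = 7, sigma_rep = 4,
                              eps_rep = 0.2, k_coulomb = 332,
                              bond_r0 = 3.8, bond_k = 20,
                              angle_theta0 = 2.12, angle_k = 2,
                              cutoff_disp = 2.5 * sigma_contact,
                              cutoff_elec = NULL) {
  stopifnot(sigma_contact > sigma_rep, sigma_rep > 0, eps_pipi >= 0,
            eps_catpi >= 0, eps_rep >= 0, k_coulomb >= 0, bond_k >= 0,
            angle_k >= 0, cutoff_disp > sigma_contact)
  structure(list(eps_pipi = eps_pipi, eps_catpi = eps_catpi,
                 include_cation_pi = isTRUE(include_cation_pi),
                 sigma_contact = sigma_contact, sigma_rep = sigma_rep,
                 eps_rep = eps_rep, k_coulomb = k_coulomb,
                 bond_r0 = bond_r0, bond_k = bond_k,
                 angle_theta0 = angle_theta0, angle_k = angle_k,
                 cutoff_disp = cutoff_disp, cutoff_elec = cutoff_elec),
            class = "cg_forcefield")
}

# resolved electrostatic cutoff for a given solvent and (optional) box
resolve_cutoff_elec <- function(params, cond, box_length = Inf) {
  rc <- params$cutoff_elec
  if (is.null(rc)) {
    kd <- debye_inverse_length(cond)
    rc <- if (kd > 0) max(35, 4 / kd) else Inf
  }
  min(rc, box_length / 2)
}

#' Screened electrostatic pair energy
#'
#' Debye--Hueckel interaction
#' `E = K q_i q_j B(kappa_D) exp(-kappa_D r) / (eps r)` between two point
#' charges, in kcal/mol. With zero ionic strength and unit dielectric this is
#' the bare Coulomb energy (`K = 332 kcal/mol` for unit charges at 1 A).
#'
#' @param q_i,q_j charges in units of e.
#' @param r separation, A (> 0).
#' @param cond a `cg_solvent`.
#' @param params a `cg_forcefield` (supplies the Coulomb constant).
#' @return energy in kcal/mol.
#' @export
electrostatic_pair_energy <- function(q_i, q_j, r, cond,
                                      params = forcefield_params()) {
  if (any(r <= 0)) stop("r must be > 0")
  if (q_i == 0 || q_j == 0) return(rep(0, length(r)))
  kd <- debye_inverse_length(cond)
  params$k_coulomb * q_i * q_j * debye_B(cond) * exp(-kd * r) /
    (cond$dielectric * r)
}

#' 12-6 dispersion pair energy
#'
#' `E(r) = eps * ((sigma/r)^12 - 2 (sigma/r)^6)`: the minimum sits at exactly
#' `r = sigma` with depth `-eps` (sigma is the optimal contact distance, not
#' the zero crossing). When a finite `cutoff` is supplied the potential is
#' truncated there and shifted so that `E(cutoff) = 0`, the form used inside
#' the simulation engine.
#'
#' @param r separation(s), A (> 0).
#' @param eps well depth, kcal/mol.
#' @param sigma optimal contact distance, A.
#' @param cutoff truncation distance, A; `Inf` (default) for the pure form.
#' @return energy in kcal/mol.
#' @export
dispersion_pair_energy <- function(r, eps, sigma, cutoff = Inf) {
  if (any(r <= 0)) stop("r must be > 0")
  lj <- function(x) {
    sr6 <- (sigma / x)^6
    eps * (sr6^2 - 2 * sr6)
  }
  e <- lj(r)
  if (is.finite(cutoff)) {
    e <- ifelse(r < cutoff, e - lj(cutoff), 0)
  }
  e
}

#' Excluded-volume repulsion pair energy
#'
#' `E(r) = eps_rep * (sigma_rep / r)^12`, truncated to zero beyond
#' `2 * sigma_rep`. Applied between every nonbonded bead pair.
#'
#' @param r separation(s), A (> 0).
#' @param params a `cg_forcefield`.
#' @return energy in kcal/mol.
#' @export
repulsion_pair_energy <- function(r, params = forcefield_params()) {
  if (any(r <= 0)) stop("r must be > 0")
  ifelse(r <= 2 * params$sigma_rep,
         params$eps_rep * (params$sigma_rep / r)^12, 0)
}

#' Interaction terms applicable to a bead-class pair
#'
#' Aromatic-aromatic pairs interact through pi-pi dispersion; aromatic-
#' positive pairs through cation-pi dispersion only in the inclusive model;
#' charged-charged pairs through screened electrostatics; every pair also
#' feels the excluded-volume repulsion. Aromatic-negative pairs get no
#' attractive term.
#'
#' @param class_i,class_j bead classes (`"POS"`, `"NEG"`, `"ARO"`, `"NEU"`).
#' @param params a `cg_forcefield`.
#' @return character vector drawn from
#'   `c("electrostatics", "dispersion", "repulsion")`.
#' @export
pair_interaction_dispatch <- function(class_i, class_j,
                                      params = forcefield_params()) {
  stopifnot(class_i %in% CG_CLASSES, class_j %in% CG_CLASSES)
  cls <- sort(c(class_i, class_j))
  terms <- "repulsion"
  if (all(cls %in% c("POS", "NEG"))) terms <- c("electrostatics", terms)
  if (identical(cls, c("ARO", "ARO"))) terms <- c("dispersion", terms)
  if (identical(cls, c("ARO", "POS")) && params$include_cation_pi) {
    terms <- c("dispersion", terms)
  }
  terms
}

#' Write force-field and solvent parameters to a key = value text config
#' @param params a `cg_forcefield`.
#' @param cond a `cg_solvent`.
#' @param path output file.
#' @export
write_ff_config <- function(params, cond, path) {
  vals <- c(unclass(params), unclass(cond))
  vals$include_cation_pi <- as.integer(vals$include_cation_pi)
  if (is.null(vals$cutoff_elec)) vals$cutoff_elec <- "auto"
  lines <- c(
    "# cgphase force-field + solvent config",
    "# energies kcal/mol, lengths Angstrom, angles rad, ionic strength mol/L,",
    "# temperature K; cutoff_elec = auto means max(35 A, 4 Debye lengths)",
    paste(names(vals), "=", vapply(vals, function(v)
      format(v, digits = 12), character(1))))
  writeLines(lines, path)
  invisible(path)
}

#' Read force-field and solvent parameters from a key = value text config
#' @param path file written by [write_ff_config()] (or hand-edited).
#' @return list with elements `params` (`cg_forcefield`) and `cond`
#'   (`cg_solvent`).
#' @export
read_ff_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- which(vapply(kv, length, integer(1)) != 2L)
  if (length(bad)) stop("malformed config line: ", lines[bad[1]])
  vals <- stats::setNames(lapply(kv, `[[`, 2L),
                          vapply(kv, `[[`, 1L, FUN.VALUE = character(1)))
  num <- function(k, default) {
    if (is.null(vals[[k]])) return(default)
    if (identical(vals[[k]], "auto")) return(NULL)
    as.numeric(vals[[k]])
  }
  params <- forcefield_params(
    eps_pipi = num("eps_pipi", 0.2), eps_catpi = num("eps_catpi", 0.2),
    include_cation_pi = num("include_cation_pi", 1) != 0,
    sigma_contact = num("sigma_contact", 7), sigma_rep = num("sigma_rep", 4),
    eps_rep = num("eps_rep", 0.2), k_coulomb = num("k_coulomb", 332),
    bond_r0 = num("bond_r0", 3.8), bond_k = num("bond_k", 20),
    angle_theta0 = num("angle_theta0", 2.12), angle_k = num("angle_k", 2),
    cutoff_disp = num("cutoff_disp", 17.5),
    cutoff_elec = num("cutoff_elec", NULL))
  cond <- solvent_conditions(
    ionic_strength = num("ionic_strength", 0.02),
    temperature = num("temperature", 300),
    dielectric = num("dielectric", 80),
    ion_radius = num("ion_radius", 4))
  list(params = params, cond = cond)
}
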