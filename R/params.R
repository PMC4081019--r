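#' Debye screening length for a monovalent salt solution
#'
#' Standard ionic-screening formula \eqn{\kappa^{-1} =
#' \sqrt{\epsilon_0 \epsilon_r k_B T / (2 N_A e^2 I)}} with ionic strength
#' `I` equal to the molar concentration for a 1:1 salt.  At 0.1 M, eps_r = 80
#' and 298 K this evaluates to about 10 Angstrom.
#'
#' @param conc salt concentration in mol/L.
#' @param eps_r relative dielectric constant (default 80).
#' @param temperature absolute temperature in K (default 298).
#' @return screening length in Angstrom.
#' @export
debye_length <- function(conc, eps_r = 80, temperature = 298) {
  if (any(conc <= 0)) stop("salt concentration must be positive")
  eps0 <- 8.8541878128e-12    # F/m
  kB <- 1.380649e-23          # J/K
  NA_ <- 6.02214076e23        # 1/mol
  e <- 1.602176634e-19        # C
  I_m3 <- conc * 1000 * NA_   # ions per m^3 per species
  lam <- sqrt(eps0 * eps_r * kB * temperature / (2 * e^2 * I_m3))
  lam * 1e10
}

#' Force-field parameters of the flexible binding model
#'
#' Energies are in native-contact units, lengths in nm.  Harmonic terms use
#' the convention `V = k * (x - x0)^2` (no factor 1/2).
#'
#' @param k_bond bond spring constant (energy/nm^2); also used for the linkage
#'   bond.
#' @param k_angle angle spring constant (energy/rad^2).
#' @param contact_dihedral_ratio total native-contact to total dihedral energy
#'   ratio used to set the dihedral strength (default 2).
#' @param eps_contact per-contact well depth (default 1, the energy unit).
#' @param rep_sigma excluded-volume diameter, nm.
#' @param rep_eps repulsion strength.
#' @param rep_cutoff repulsion cutoff, nm (energy-shifted to zero there).
#' @param lambda_hp overall hydrophobic strength (default 0.92, calibrated so
#'   the free-monomer affinity is in the experimentally observed range).
#' @param hp_r0 optimal hydrophobic pair distance, nm (default 0.8).
#' @param hp_c switching steepness, nm^-1 (default 10, i.e. 1 per Angstrom).
#' @param alpha_hp heterogeneity exponent of the hydrophobic matrix.
#' @param ebar_hp normalisation scale of the hydrophobic matrix.
#' @param eps_r relative dielectric constant.
#' @param salt_conc monovalent salt concentration, mol/L (default 0.1; sets
#'   the Debye length, about 1 nm).
#' @param temperature_K physical temperature used for the screening length.
#' @param q_his histidine sidechain charge.
#' @param k_B Boltzmann constant in reduced units (see [UB_KB]).
#' @return a list of class `ff_params`.
#' @export
ff_params <- function(k_bond = 10000, k_angle = 20,
                      contact_dihedral_ratio = 2, eps_contact = 1,
                      rep_sigma = 0.4, rep_eps = 1, rep_cutoff = 1.0,
                      lambda_hp = 0.92, hp_r0 = 0.8, hp_c = 10,
                      alpha_hp = 1, ebar_hp = -3.7,
                      eps_r = 80, salt_conc = 0.1, temperature_K = 298,
                      q_his = 0.5, k_B = UB_KB) {
  lambda_d <- debye_length(salt_conc, eps_r, temperature_K) / 10  # nm
  stopifnot(lambda_hp >= 0, lambda_d > 0)
  p <- list(k_bond = k_bond, k_angle = k_angle,
            contact_dihedral_ratio = contact_dihedral_ratio,
            eps_contact = eps_contact,
            rep_sigma = rep_sigma, rep_eps = rep_eps, rep_cutoff = rep_cutoff,
            lambda_hp = lambda_hp, hp_r0 = hp_r0, hp_c = hp_c,
            alpha_hp = alpha_hp, ebar_hp = ebar_hp,
            eps_r = eps_r, salt_conc = salt_conc,
            temperature_K = temperature_K,
            lambda_d = lambda_d,
            elec_cutoff = 3 * lambda_d,
            # truncate the hydrophobic switch where both its value and its
            # derivative are negligible (s ~ 2e-7)
            hp_cutoff = hp_r0 + atanh(1 - 4e-7) / hp_c,
            q_his = q_his, k_B = k_B)
  class(p) <- "ff_params"
  p
}

#' Simulation configuration
#'
#' Defaults follow the production protocol: reduced temperature 50 (close to
#' but below the folding temperature), time step 0.0005, Langevin coupling
#' time 1.0 (friction = 1/coupling), eight independent replicas, effective
#' protein concentration 5 mM realised as a cubic periodic box.
#'
#' @param temperature reduced temperature.
#' @param dt time step, reduced time units.
#' @param coupling_time Langevin coupling time; friction gamma = 1/coupling.
#' @param steps production steps per replica.
#' @param replicas number of independent replicas.
#' @param seeds integer seeds, one per replica (default `seed_base + 0:(r-1)`).
#' @param seed_base base seed used when `seeds` is NULL.
#' @param concentration effective molar concentration used to size the box
#'   (mol/L); ignored when `box` is given.
#' @param box cubic box side in nm, or NULL to derive it from `concentration`
#'   (0 disables periodicity).
#' @param stride save a frame every `stride` steps.
#' @param mass bead mass.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(temperature = 50, dt = 5e-4, coupling_time = 1.0,
                       steps = 200000L, replicas = 8L, seeds = NULL,
                       seed_base = 1000L, concentration = 0.005, box = NULL,
                       stride = 200L, mass = 1) {
  stopifnot(dt > 0, steps > 0, replicas >= 1)
  if (is.null(seeds)) seeds <- seed_base + seq_len(replicas) - 1L
  if (length(seeds) != replicas) stop("need one seed per replica")
  if (is.null(box)) box <- box_from_concentration(2, concentration)
  cfg <- list(temperature = temperature, dt = dt,
              coupling_time = coupling_time, steps = as.integer(steps),
              replicas = as.integer(replicas), seeds = as.integer(seeds),
              concentration = concentration, box = box,
              stride = as.integer(stride), mass = mass)
  class(cfg) <- "sim_config"
  cfg
}

#' Cubic box side for a target effective concentration
#'
#' `side = (count / (concentration * N_A))^(1/3)`; two molecules at 5 mM give
#' a box of about 8.7 nm.
#'
#' @param count number of molecules in the box.
#' @param concentration molar concentration (mol/L).
#' @return box side in nm.
#' @export
box_from_concentration <- function(count, concentration) {
  if (count < 1 || concentration <= 0)
    stop("count must be >= 1 and concentration positive")
  NA_ <- 6.02214076e23
  vol_L <- count / (concentration * NA_)
  vol_nm3 <- vol_L * 1e24      # 1 L = 1e24 nm^3
  vol_nm3^(1 / 3)
}
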