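# named energy breakdown in the exported field names
.breakdown <- function(v) {
  c(E_bond = unname(v["bond"]), E_angle = unname(v["angle"]),
    E_dihedral = unname(v["dihedral"]), E_contact = unname(v["contact"]),
    E_repulsive = unname(v["repulsive"]), E_link = unname(v["link"]),
    E_elec = unname(v["elec"]), E_HP = unname(v["hp"]),
    E_total = unname(v["total"]))
}

.xyz_or_model <- function(model, xyz) {
  if (is.null(xyz)) bead_xyz(model) else {
    stopifnot(is.matrix(xyz), ncol(xyz) == 3)
    xyz
  }
}

#' Total energy of a conformation with per-term decomposition
#'
#' Evaluates the full Hamiltonian `H = V_folding + V_binding`: structure-based
#' folding terms (bonds, angles, dihedrals, native contacts, excluded-volume
#' repulsion) plus the physics-based binding terms accumulated over
#' inter-monomer pairs only (Debye-Hueckel electrostatics, hydrophobic
#' attraction and the linkage bond, if any).
#'
#' @param model a `bead_model` with charges assigned.
#' @param topology a `cg_topology` consistent with the model.
#' @param params `ff_params`.
#' @param xyz optional `n x 3` coordinates in nm (default: the model's own).
#' @param box cubic box side in nm for minimum-image treatment of
#'   inter-monomer pairs (0 = no periodicity).
#' @return named numeric vector: `E_bond`, `E_angle`, `E_dihedral`,
#'   `E_contact`, `E_repulsive`, `E_link`, `E_elec`, `E_HP`, `E_total`.
#' @export
total_energy <- function(model, topology, params = ff_params(), xyz = NULL,
                         box = 0) {
  spec <- .engine_spec(model, topology, params, box = box)
  .breakdown(.cg_energy_cpp(spec, .xyz_or_model(model, xyz)))
}

#' Structure-based (folding) energy terms only
#'
#' Same decomposition as [total_energy()] but with inter-monomer non-bonded
#' pairs removed, leaving the structure-based force field of the folded units
#' (intra-monomer repulsion included; `E_elec`, `E_HP` are zero by
#' construction).
#'
#' @inheritParams total_energy
#' @return named numeric vector as in [total_energy()].
#' @export
sbm_energy <- function(model, topology, params = ff_params(), xyz = NULL) {
  spec <- .engine_spec(model, topology, params, box = 0, intra_only = TRUE)
  .breakdown(.cg_energy_cpp(spec, .xyz_or_model(model, xyz)))
}

#' Inter-monomer Debye-Hueckel electrostatic energy
#'
#' Screened Coulomb sum over inter-monomer charged bead pairs,
#' `q_i q_j K / (eps_r r) * exp(-r / lambda_D)`, truncated at `3 * lambda_D`
#' with both the energy and the force shifted to zero at the cutoff.
#' Intra-monomer pairs are excluded: folding interactions are
#' structure-based.
#'
#' @inheritParams total_energy
#' @return total energy, with a data frame of per-pair terms (`i`, `j`, `r`,
#'   `energy`) as attribute `"pairs"`.
#' @export
elec_energy <- function(model, params = ff_params(), xyz = NULL, box = 0) {
  b <- model$beads
  xyz <- .xyz_or_model(model, xyz)
  ch <- which(b$charge != 0)
  i <- rep(ch, each = length(ch)); j <- rep(ch, times = length(ch))
  keep <- i < j & b$mono[i] != b$mono[j]
  i <- i[keep]; j <- j[keep]
  if (length(i) == 0L) {
    out <- 0
    attr(out, "pairs") <- data.frame(i = integer(), j = integer(),
                                     r = numeric(), energy = numeric())
    return(out)
  }
  d <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
  if (box > 0) d <- d - box * round(d / box)
  r <- sqrt(rowSums(d^2))
  pref <- b$charge[i] * b$charge[j] * .K_COULOMB / params$eps_r
  rc <- params$elec_cutoff
  exc <- exp(-rc / params$lambda_d)
  shift <- exc / rc
  dslope <- exc * (1 / rc^2 + 1 / (params$lambda_d * rc))
  e <- ifelse(r < rc,
              pref * (exp(-r / params$lambda_d) / r - shift +
                        dslope * (r - rc)), 0)
  out <- sum(e)
  attr(out, "pairs") <- data.frame(i = i, j = j, r = r, energy = e)
  out
}

#' Inter-monomer hydrophobic energy
#'
#' Sum over inter-monomer sidechain bead pairs of
#' `-lambda_HP * eps_ij * s(r)` with the smooth switching function
#' `s(r) = (1 + tanh(C * (r0 - r))) / 2`, which saturates to 1 well below the
#' optimal distance `r0` and to 0 well above it.
#'
#' @inheritParams total_energy
#' @param hp an `hp_matrix` (default: built from `params`).
#' @return total energy with per-pair terms as attribute `"pairs"`.
#' @export
hp_energy <- function(model, params = ff_params(), xyz = NULL, box = 0,
                      hp = NULL) {
  if (is.null(hp))
    hp <- build_hydrophobic_matrix(alpha = params$alpha_hp,
                                   ebar = params$ebar_hp)
  b <- model$beads
  xyz <- .xyz_or_model(model, xyz)
  sc <- which(b$kind == "sidechain")
  i <- rep(sc, each = length(sc)); j <- rep(sc, times = length(sc))
  keep <- i < j & b$mono[i] != b$mono[j]
  i <- i[keep]; j <- j[keep]
  if (length(i) == 0L) {
    out <- 0
    attr(out, "pairs") <- data.frame(i = integer(), j = integer(),
                                     r = numeric(), energy = numeric())
    return(out)
  }
  d <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
  if (box > 0) d <- d - box * round(d / box)
  r <- sqrt(rowSums(d^2))
  depth <- params$lambda_hp * hp$eps[cbind(b$restype[i], b$restype[j])]
  s <- 0.5 * (1 + tanh(params$hp_c * (params$hp_r0 - r)))
  e <- ifelse(r < params$hp_cutoff, -depth * s, 0)
  out <- sum(e)
  attr(out, "pairs") <- data.frame(i = i, j = j, r = r, energy = e)
  out
}

#' Forces (negative gradient of the full Hamiltonian)
#'
#' @inheritParams total_energy
#' @return `n x 3` matrix of forces, energy/nm.
#' @export
cg_forces <- function(model, topology, params = ff_params(), xyz = NULL,
                      box = 0) {
  spec <- .engine_spec(model, topology, params, box = box)
  .cg_forces_cpp(spec, .xyz_or_model(model, xyz))
}

#' Per-frame energy decomposition of a trajectory
#'
#' @param traj a `cg_trajectory`.
#' @param model,topology,params model objects matching the trajectory.
#' @return data frame with one row per frame and the [total_energy()] fields.
#' @export
trajectory_energies <- function(traj, model, topology,
                                params = ff_params()) {
  spec <- .engine_spec(model, topology, params, box = traj$box)
  em <- .cg_energy_frames_cpp(spec, traj$pos)
  out <- as.data.frame(em)
  names(out) <- c("E_bond", "E_angle", "E_dihedral", "E_contact",
                  "E_repulsive", "E_link", "E_elec", "E_HP", "E_total")
  out$frame <- seq_len(nrow(out))
  out$time <- traj$time
  out
}

#' Write a per-frame energy table as TSV
#'
#' @param energies data frame from [trajectory_energies()].
#' @param file output path.
#' @export
write_energy_tsv <- function(energies, file) {
  write.table(energies, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
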