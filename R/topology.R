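# linkage chemistry: donor is always the distal G76 backbone bead; acceptor is
# the proximal Lys sidechain bead (isopeptide, r0 = 0.40 nm) or the proximal
# M1 backbone bead (peptide, r0 = 0.38 nm)
.linkage_sites <- list(
  free = NULL,
  M1  = list(resno = 1,  kind = "backbone",  r0 = 0.38),
  K6  = list(resno = 6,  kind = "sidechain", r0 = 0.40),
  K11 = list(resno = 11, kind = "sidechain", r0 = 0.40),
  K27 = list(resno = 27, kind = "sidechain", r0 = 0.40),
  K29 = list(resno = 29, kind = "sidechain", r0 = 0.40),
  K33 = list(resno = 33, kind = "sidechain", r0 = 0.40),
  K48 = list(resno = 48, kind = "sidechain", r0 = 0.40),
  K63 = list(resno = 63, kind = "sidechain", r0 = 0.40))

#' Valid linkage type names
#' @return character vector of the nine valid linkage values.
#' @export
linkage_types <- function() names(.linkage_sites)

#' Specify a diUb linkage
#'
#' @param type one of `"free"`, `"M1"`, `"K6"`, `"K11"`, `"K27"`, `"K29"`,
#'   `"K33"`, `"K48"`, `"K63"`.
#' @param r0 reference bond length in nm (default: 0.40 for the seven
#'   isopeptide types, 0.38 for the M1 peptide bond).
#' @param k_b spring constant (energy/nm^2); defaults to the backbone bond
#'   constant at topology-build time when NA.
#' @return list of class `linkage_spec`.
#' @export
linkage_spec <- function(type = "free", r0 = NULL, k_b = NA_real_) {
  if (!type %in% names(.linkage_sites)) {
    stop("unknown linkage '", type, "'; valid values are: ",
         paste(names(.linkage_sites), collapse = ", "))
  }
  site <- .linkage_sites[[type]]
  if (is.null(r0)) r0 <- if (is.null(site)) NA_real_ else site$r0
  structure(list(type = type, site = site, r0 = r0, k_b = k_b),
            class = "linkage_spec")
}

#' Build the coarse-grained topology
#'
#' Constructs all bonded terms from the model's (native) coordinates:
#' sequential backbone bonds, backbone-sidechain bonds, backbone angles and
#' the two angles orienting each sidechain, backbone dihedrals (cosine series
#' with 1x and 3x terms) and one sidechain-orientation dihedral per sidechain
#' bead; plus the native-contact set replicated per monomer, the exclusion
#' list, and - for a linked dimer - exactly one inter-monomer harmonic bond.
#'
#' The dihedral strength is set from the contact set so that the total native
#' contact energy and the total dihedral strength are in the ratio
#' `params$contact_dihedral_ratio` (default 2:1), the usual stabilising-energy
#' rescaling of structure-based models.
#'
#' @param model a `bead_model` in its native (reference) conformation.
#' @param contacts residue-level contact table from
#'   [detect_native_contacts()], applied to each monomer.
#' @param linkage a `linkage_spec` or a linkage type name.
#' @param params `ff_params`.
#' @return an object of class `cg_topology`.
#' @export
build_topology <- function(model, contacts, linkage = "free",
                           params = ff_params()) {
  if (is.character(linkage)) linkage <- linkage_spec(linkage)
  stopifnot(inherits(linkage, "linkage_spec"))
  if (linkage$type != "free" && model$n_mono != 2L)
    stop("linkage '", linkage$type, "' requires a two-monomer model")

  b <- model$beads
  xyz <- bead_xyz(model)
  n <- nrow(b)
  dist_ij <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  angle_ijk <- function(i, j, k) {
    u <- xyz[i, ] - xyz[j, ]; v <- xyz[k, ] - xyz[j, ]
    acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
  }
  dihedral_ijkl <- function(i, j, k, l) {
    b1 <- xyz[j, ] - xyz[i, ]; b2 <- xyz[k, ] - xyz[j, ]; b3 <- xyz[l, ] - xyz[k, ]
    m <- c(b1[2]*b2[3]-b1[3]*b2[2], b1[3]*b2[1]-b1[1]*b2[3], b1[1]*b2[2]-b1[2]*b2[1])
    nn <- c(b2[2]*b3[3]-b2[3]*b3[2], b2[3]*b3[1]-b2[1]*b3[3], b2[1]*b3[2]-b2[2]*b3[1])
    atan2(sqrt(sum(b2^2)) * sum(b1 * nn), sum(m * nn))
  }

  bonds <- list(); angles <- list(); dihedrals <- list(); conts <- list()
  for (m in seq_len(model$n_mono)) {
    sel <- which(b$mono == m)
    resnos <- sort(unique(b$resno[sel]))
    ca <- vapply(resnos, function(r) bead_index(model, m, r, "backbone")[1], 0L)
    sc <- vapply(resnos, function(r) {
      i <- bead_index(model, m, r, "sidechain")
      if (length(i)) i[1] else NA_integer_
    }, 0L)
    nr <- length(resnos)
    consec <- which(diff(resnos) == 1L)

    for (t in consec)
      bonds[[length(bonds) + 1L]] <- c(ca[t], ca[t + 1L])
    for (t in which(!is.na(sc)))
      bonds[[length(bonds) + 1L]] <- c(ca[t], sc[t])

    for (t in seq_len(nr - 2L)) {
      if (all(diff(resnos[t:(t + 2L)]) == 1L))
        angles[[length(angles) + 1L]] <- c(ca[t], ca[t + 1L], ca[t + 2L])
    }
    for (t in which(!is.na(sc))) {
      if (t > 1L && resnos[t] - resnos[t - 1L] == 1L)
        angles[[length(angles) + 1L]] <- c(ca[t - 1L], ca[t], sc[t])
      if (t < nr && resnos[t + 1L] - resnos[t] == 1L)
        angles[[length(angles) + 1L]] <- c(sc[t], ca[t], ca[t + 1L])
    }

    for (t in seq_len(nr - 3L)) {
      if (all(diff(resnos[t:(t + 3L)]) == 1L))
        dihedrals[[length(dihedrals) + 1L]] <-
          c(ca[t], ca[t + 1L], ca[t + 2L], ca[t + 3L], 1L)
    }
    # sidechain orientation: improper-like dihedral fixing chirality of SC(i)
    # about the CA(i-1)-CA(i)-CA(i+1) frame
    for (t in which(!is.na(sc))) {
      if (t > 1L && t < nr && resnos[t] - resnos[t - 1L] == 1L &&
          resnos[t + 1L] - resnos[t] == 1L)
        dihedrals[[length(dihedrals) + 1L]] <-
          c(ca[t - 1L], ca[t + 1L], ca[t], sc[t], 2L)
    }

    if (nrow(contacts) > 0L) {
      bkey <- paste(b$mono, b$resno, b$kind, sep = "|")
      i1 <- match(paste(m, contacts$res_i, contacts$kind_i, sep = "|"), bkey)
      i2 <- match(paste(m, contacts$res_j, contacts$kind_j, sep = "|"), bkey)
      ok <- !is.na(i1) & !is.na(i2)
      conts[[m]] <- data.frame(i = i1[ok], j = i2[ok],
                               r_n = contacts$r_n[ok],
                               eps = contacts$eps[ok] * params$eps_contact)
    }
  }

  bm <- do.call(rbind, bonds)
  bonds_df <- if (is.null(bm)) {
    data.frame(i = integer(), j = integer(), r0 = numeric(), k = numeric())
  } else {
    out <- data.frame(i = bm[, 1], j = bm[, 2])
    out$r0 <- mapply(dist_ij, out$i, out$j)
    out$k <- params$k_bond
    out
  }

  am <- do.call(rbind, angles)
  angles_df <- if (is.null(am)) {
    data.frame(i = integer(), j = integer(), k = integer(),
               theta0 = numeric(), k_theta = numeric())
  } else {
    out <- data.frame(i = am[, 1], j = am[, 2], k = am[, 3])
    out$theta0 <- mapply(angle_ijk, out$i, out$j, out$k)
    out$k_theta <- params$k_angle
    out
  }

  dm <- do.call(rbind, dihedrals)
  dihedrals_df <- if (is.null(dm)) {
    data.frame(i = integer(), j = integer(), k = integer(), l = integer(),
               type = integer(), phi0 = numeric())
  } else {
    out <- data.frame(i = dm[, 1], j = dm[, 2], k = dm[, 3],
                      l = dm[, 4], type = dm[, 5])
    out$phi0 <- mapply(dihedral_ijkl, out$i, out$j, out$k, out$l)
    out
  }

  contacts_df <- if (length(conts)) do.call(rbind, conts) else
    data.frame(i = integer(), j = integer(), r_n = numeric(), eps = numeric())
  rownames(contacts_df) <- NULL

  # contact:dihedral total-energy rescaling
  total_contact <- sum(contacts_df$eps)
  ndih <- nrow(dihedrals_df)
  k_dih <- if (ndih > 0 && total_contact > 0)
    total_contact / (params$contact_dihedral_ratio * ndih) else 1
  dihedrals_df$k_phi <- k_dih

  link <- NULL
  if (linkage$type != "free") {
    site <- linkage$site
    distal_res <- max(b$resno[b$mono == 1L])
    di <- bead_index(model, 1L, distal_res, "backbone")
    ai <- bead_index(model, 2L, site$resno, site$kind)
    if (length(di) != 1L || length(ai) != 1L)
      stop("cannot locate linkage beads for ", linkage$type)
    kb <- if (is.na(linkage$k_b)) params$k_bond else linkage$k_b
    link <- list(type = linkage$type, i = di, j = ai,
                 r0 = linkage$r0, k = kb)
  }

  # exclusions: all pairs inside any bonded term, all contact pairs, the link
  ex <- rbind(
    cbind(bonds_df$i, bonds_df$j),
    cbind(angles_df$i, angles_df$j), cbind(angles_df$j, angles_df$k),
    cbind(angles_df$i, angles_df$k),
    cbind(dihedrals_df$i, dihedrals_df$j), cbind(dihedrals_df$i, dihedrals_df$k),
    cbind(dihedrals_df$i, dihedrals_df$l), cbind(dihedrals_df$j, dihedrals_df$k),
    cbind(dihedrals_df$j, dihedrals_df$l), cbind(dihedrals_df$k, dihedrals_df$l),
    cbind(contacts_df$i, contacts_df$j),
    if (!is.null(link)) cbind(link$i, link$j))
  if (is.null(ex) || nrow(ex) == 0L) {
    ex <- data.frame(i = integer(), j = integer())
  } else {
    ex <- cbind(pmin(ex[, 1], ex[, 2]), pmax(ex[, 1], ex[, 2]))
    ex <- unique(data.frame(i = ex[, 1], j = ex[, 2]))
    ex <- ex[order(ex$i, ex$j), ]
    rownames(ex) <- NULL
  }

  structure(list(version = "1.0", n_beads = n,
                 bonds = bonds_df, angles = angles_df,
                 dihedrals = dihedrals_df, contacts = contacts_df,
                 link = link, exclusions = ex),
            class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat("CG topology:", x$n_beads, "beads;", nrow(x$bonds), "bonds,",
      nrow(x$angles), "angles,", nrow(x$dihedrals), "dihedrals,",
      nrow(x$contacts), "native contacts\n")
  if (!is.null(x$link)) {
    cat("  linkage:", x$link$type, " beads", x$link$i, "-", x$link$j,
        " r0 =", x$link$r0, "nm\n")
  } else cat("  linkage: free (none)\n")
  invisible(x)
}

#' Serialise / restore a topology as versioned JSON
#'
#' Numeric parameters round-trip at full precision.
#'
#' @param topology a `cg_topology`.
#' @param file optional output path; when NULL the JSON string is returned.
#' @return [topology_to_json()]: the path or JSON string;
#'   [topology_from_json()]: a `cg_topology`.
#' @export
topology_to_json <- function(topology, file = NULL) {
  payload <- unclass(topology)
  js <- jsonlite::toJSON(payload, digits = I(17), dataframe = "columns",
                         auto_unbox = TRUE, null = "null", pretty = FALSE)
  if (is.null(file)) return(as.character(js))
  writeLines(js, file)
  invisible(file)
}

#' @rdname topology_to_json
#' @param x a path to a JSON file or a JSON string.
#' @export
topology_from_json <- function(x) {
  src <- if (file.exists(x)) x else x
  obj <- jsonlite::fromJSON(src, simplifyDataFrame = TRUE)
  if (is.null(obj$version)) stop("not a serialized topology (missing version)")
  fix_types <- function(df, int_cols) {
    df <- as.data.frame(df)
    for (cl in names(df)) {
      df[[cl]] <- if (cl %in% int_cols) as.integer(df[[cl]])
                  else as.numeric(df[[cl]])
    }
    df
  }
  link <- obj$link
  if (!is.null(link)) {
    link$i <- as.integer(link$i); link$j <- as.integer(link$j)
    link$r0 <- as.numeric(link$r0); link$k <- as.numeric(link$k)
  }
  topo <- list(version = obj$version, n_beads = as.integer(obj$n_beads),
               bonds = fix_types(obj$bonds, c("i", "j")),
               angles = fix_types(obj$angles, c("i", "j", "k")),
               dihedrals = fix_types(obj$dihedrals,
                                     c("i", "j", "k", "l", "type")),
               contacts = fix_types(obj$contacts, c("i", "j")),
               link = link,
               exclusions = fix_types(obj$exclusions, c("i", "j")))
  class(topo) <- "cg_topology"
  topo
}

#' One-call model construction from residue records
#'
#' Convenience wrapper: coarse-grains the monomer, assigns charges, detects
#' native contacts, duplicates the unit into a dimer (for any linkage,
#' including "free" with two copies) and builds the topology.
#'
#' @param residues monomer residue records ([parse_pdb()] output).
#' @param linkage linkage type name or `linkage_spec`.
#' @param params `ff_params`.
#' @param dimer build a two-monomer system (default TRUE; FALSE gives the
#'   isolated monomer model).
#' @param contact_cutoff,contact_min_sep native-contact recipe parameters
#'   (Angstrom / residues).
#' @return list with `model` (`bead_model`), `topology` (`cg_topology`),
#'   `contacts` (residue-level table) and `params`.
#' @export
cg_model <- function(residues, linkage = "free", params = ff_params(),
                     dimer = TRUE, contact_cutoff = 4.5,
                     contact_min_sep = 3) {
  contacts <- detect_native_contacts(residues, contact_cutoff,
                                     contact_min_sep)
  m1 <- assign_charges(coarse_grain(residues, "distal"), params$q_his)
  if (dimer) {
    m2 <- assign_charges(coarse_grain(residues, "proximal"), params$q_his)
    model <- combine_monomers(m1, m2,
                              source = attr(residues, "source") %||% "dimer")
  } else {
    model <- m1
  }
  topo <- build_topology(model, contacts, linkage, params)
  list(model = model, topology = topo, contacts = contacts, params = params)
}

# ---------------------------------------------------------------------------
# engine specification handed to the compiled kernels
# ---------------------------------------------------------------------------
.engine_spec <- function(model, topology, params, box = 0,
                         hp = NULL, intra_only = FALSE) {
  b <- model$beads
  n <- nrow(b)
  if (topology$n_beads != n) stop("topology/bead count mismatch")
  if (is.null(hp))
    hp <- build_hydrophobic_matrix(alpha = params$alpha_hp,
                                   ebar = params$ebar_hp)

  excl <- matrix(FALSE, n, n)
  ex <- topology$exclusions
  excl[cbind(ex$i, ex$j)] <- TRUE
  excl[cbind(ex$j, ex$i)] <- TRUE

  ut <- which(upper.tri(matrix(0, n, n)) & !excl, arr.ind = TRUE)
  i <- ut[, 1]; j <- ut[, 2]
  inter <- b$mono[i] != b$mono[j]
  if (intra_only) {
    keep <- !inter
    i <- i[keep]; j <- j[keep]; inter <- inter[keep]
  }
  qq <- b$charge[i] * b$charge[j]
  aq <- ifelse(inter & qq != 0, qq * .K_COULOMB / params$eps_r, 0)
  scsc <- b$kind[i] == "sidechain" & b$kind[j] == "sidechain"
  epsij <- hp$eps[cbind(b$restype[i], b$restype[j])]
  heps <- ifelse(inter & scsc, params$lambda_hp * epsij, 0)

  dih <- topology$dihedrals
  list(
    n = n,
    mono = as.integer(b$mono),
    bonds_idx = cbind(as.integer(topology$bonds$i) - 1L,
                      as.integer(topology$bonds$j) - 1L),
    bonds_par = cbind(topology$bonds$r0, topology$bonds$k),
    angles_idx = cbind(as.integer(topology$angles$i) - 1L,
                       as.integer(topology$angles$j) - 1L,
                       as.integer(topology$angles$k) - 1L),
    angles_par = cbind(topology$angles$theta0, topology$angles$k_theta),
    dihedrals_idx = cbind(as.integer(dih$i) - 1L, as.integer(dih$j) - 1L,
                          as.integer(dih$k) - 1L, as.integer(dih$l) - 1L),
    dihedrals_par = cbind(dih$phi0, dih$k_phi, dih$type),
    contacts_idx = cbind(as.integer(topology$contacts$i) - 1L,
                         as.integer(topology$contacts$j) - 1L),
    contacts_par = cbind(topology$contacts$r_n, topology$contacts$eps),
    link_idx = if (is.null(topology$link)) integer(0) else
      c(as.integer(topology$link$i) - 1L, as.integer(topology$link$j) - 1L),
    link_par = if (is.null(topology$link)) numeric(0) else
      c(topology$link$r0, topology$link$k),
    pairs_idx = cbind(as.integer(i) - 1L, as.integer(j) - 1L),
    pairs_par = cbind(as.numeric(inter), aq, heps),
    params = list(box = box, lambda_d = params$lambda_d,
                  elec_cutoff = params$elec_cutoff,
                  hp_r0 = params$hp_r0, hp_c = params$hp_c,
                  hp_cutoff = params$hp_cutoff,
                  rep_sigma = params$rep_sigma, rep_eps = params$rep_eps,
                  rep_cutoff = params$rep_cutoff))
}
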