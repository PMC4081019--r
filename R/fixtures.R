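# ---------------------------------------------------------------------------
# Download-free synthetic inputs.  These fixtures validate mechanics, not
# biology: they exercise every code path (PDB parsing, coarse graining,
# contacts, charges, energetics, dynamics, analysis, classification) without
# any experimental structure.
# ---------------------------------------------------------------------------

.res_record <- function(chain, resno, resname, names, xyz) {
  list(chain = chain, resno = resno, resname = resname,
       atoms = data.frame(name = names,
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          occ = 1, stringsAsFactors = FALSE))
}

#' Miniature two-domain dimer fixture
#'
#' A 12-residue idealized helical-hairpin domain (two short helices joined by
#' a turn, sidechain pseudo-atoms pointing radially off the helix axes),
#' duplicated into a two-domain dimer.  The sequence mixes hydrophobic,
#' charged and neutral residues (including one glycine) so that bead counting,
#' charge assignment and both Debye-Hueckel and hydrophobic terms are
#' exercised.  Fully deterministic for a given seed.
#'
#' @param seed integer seed (used only for the optional coordinate jitter).
#' @param jitter Gaussian coordinate noise, Angstrom (default 0 -
#'   byte-reproducible geometry).
#' @param separation inter-domain centre offset along y, Angstrom.
#' @param params `ff_params`.
#' @return list with `residues` (one domain, class `ub_residues`), `model`
#'   (two-domain `bead_model` with charges), `topology`, `contacts`, `params`
#'   and `patches` (mock patch residue sets).
#' @export
make_mini_dimer <- function(seed = 1L, jitter = 0, separation = 16,
                            params = ff_params()) {
  seq3 <- c("LEU", "LYS", "GLU", "ILE", "PHE", "GLY",
            "ASP", "ALA", "VAL", "ARG", "HIS", "SER")
  nres <- length(seq3)
  # helix 1 up (residues 1-5), turn (6-7), helix 2 down (8-12)
  ca <- matrix(0, nres, 3)
  dir <- matrix(0, nres, 3)
  for (i in 1:5) {
    a <- (i - 1) * 100 * pi / 180
    ca[i, ] <- c(2.3 * cos(a), 2.3 * sin(a), 1.5 * (i - 1))
    dir[i, ] <- c(cos(a), sin(a), 0)
  }
  for (i in 8:12) {
    a <- (12 - i) * 100 * pi / 180 + pi
    ca[i, ] <- c(9 + 2.3 * cos(a), 2.3 * sin(a), 1.5 * (12 - i))
    dir[i, ] <- c(cos(a), sin(a), 0)
  }
  # arched turn between helix tops
  p5 <- ca[5, ]; p8 <- ca[8, ]
  ca[6, ] <- p5 + (p8 - p5) / 3 + c(0, 0, 2.5)
  ca[7, ] <- p5 + 2 * (p8 - p5) / 3 + c(0, 0, 2.5)
  dir[6, ] <- c(0, 0, 1); dir[7, ] <- c(0, 0, 1)

  one_sc <- c("ALA", "SER", "CYS", "THR", "VAL")
  build_domain <- function(chain, transform) {
    lapply(seq_len(nres), function(i) {
      rn <- seq3[i]
      if (rn == "GLY") {
        nm <- "CA"; xyz <- ca[i, , drop = FALSE]
      } else if (rn %in% one_sc) {
        nm <- c("CA", "CB")
        xyz <- rbind(ca[i, ], ca[i, ] + 1.5 * dir[i, ])
      } else {
        nm <- c("CA", "CB", "CG")
        xyz <- rbind(ca[i, ], ca[i, ] + 1.5 * dir[i, ],
                     ca[i, ] + 2.9 * dir[i, ])
      }
      .res_record(chain, i, rn, nm, transform(xyz))
    })
  }
  idt <- function(x) x
  flip <- function(x) {
    # rotate 180 degrees about z and offset along +y: surfaces face each other
    out <- x %*% diag(c(-1, -1, 1))
    out[, 1] <- out[, 1] + 9
    out[, 2] <- out[, 2] + separation
    out
  }
  resA <- structure(build_domain("A", idt), class = "ub_residues",
                    source = "mini_dimer_synthetic")
  resB <- structure(build_domain("B", flip), class = "ub_residues",
                    source = "mini_dimer_synthetic")
  if (jitter > 0) {
    resA <- .jitter_residues(resA, jitter, seed)
    resB <- .jitter_residues(resB, jitter, seed + 1L)
  }

  contacts <- detect_native_contacts(resA)
  m1 <- assign_charges(coarse_grain(resA, "distal"), params$q_his)
  m2 <- assign_charges(coarse_grain(resB, "proximal"), params$q_his)
  model <- combine_monomers(m1, m2, source = "mini_dimer_synthetic")
  topo <- build_topology(model, contacts, "free", params)
  list(residues = resA, residues_b = resB, model = model, topology = topo,
       contacts = contacts, params = params,
       patches = list(I44 = c(4L, 5L), I36 = c(1L, 9L)))
}

.jitter_residues <- function(res, sigma, seed) {
  .local_rng(seed, function() {
    out <- lapply(res, function(r) {
      n <- nrow(r$atoms)
      r$atoms$x <- r$atoms$x + rnorm(n, sd = sigma)
      r$atoms$y <- r$atoms$y + rnorm(n, sd = sigma)
      r$atoms$z <- r$atoms$z + rnorm(n, sd = sigma)
      r
    })
    structure(out, class = "ub_residues", source = attr(res, "source"))
  })
}

#' Write synthetic residue records as a PDB file
#'
#' Companion to the fixture generators so every downstream code path reads the
#' same file format as real inputs.
#'
#' @param residues a `ub_residues` object.
#' @param file output path.
#' @export
fixture_to_pdb <- function(residues, file) {
  at <- do.call(rbind, lapply(residues, function(r)
    data.frame(chain = r$chain, resno = r$resno, resid = r$resname,
               elety = r$atoms$name, x = r$atoms$x, y = r$atoms$y,
               z = r$atoms$z, stringsAsFactors = FALSE)))
  bio3d::write.pdb(file = file, xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, resid = at$resid, elety = at$elety,
                   chain = at$chain, o = rep(1, nrow(at)), b = rep(0, nrow(at)))
  invisible(file)
}

#' Synthetic ubiquitin-sequence surrogate monomer
#'
#' A SYNTHETIC stand-in for a real ubiquitin crystal structure, for use where
#' no experimental structure is available: the true 76-residue ubiquitin
#' sequence (so bead counts, glycine handling, charges and linkage sites are
#' exact) threaded onto an idealized compact fold - a constant-speed spherical
#' spiral C-alpha trace (radius ~1 nm, consecutive C-alpha spacing 3.8
#' Angstrom) with sidechain pseudo-atoms alternating between the outer surface
#' and the core.  The geometry is NOT the ubiquitin fold; fold-specific
#' quantities (native contact map, patch geometry, linkage-site distances)
#' differ from the real protein, and results obtained with this surrogate
#' validate the machinery, not ubiquitin biology.
#'
#' @param radius sphere radius of the C-alpha trace, Angstrom.
#' @param jitter optional Gaussian coordinate noise, Angstrom.
#' @param seed seed for the jitter.
#' @return a `ub_residues` object (source label "ub_synthetic").
#' @export
make_ub_monomer <- function(radius = 10, jitter = 0, seed = 1L) {
  seq1 <- strsplit(paste0(
    "MQIFVKTLTGKTITLEVEPSDTIENVKAKIQDKEGIPPDQQRLIFAGKQL",
    "EDGRTLSDYNIQKESTLHLVLRLRGG"), "")[[1]]
  stopifnot(length(seq1) == 76L)
  n <- 76L
  step <- 3.8
  zfrac <- 0.95
  z <- radius * zfrac * (1 - 2 * (seq_len(n) - 1) / (n - 1))
  rho <- sqrt(pmax(radius^2 - z^2, 1e-6))
  phi <- numeric(n)
  for (i in 2:n) {
    dz2 <- (z[i] - z[i - 1])^2
    cosd <- (rho[i]^2 + rho[i - 1]^2 + dz2 - step^2) / (2 * rho[i] * rho[i - 1])
    cosd <- max(-1, min(1, cosd))
    phi[i] <- phi[i - 1] + acos(cosd)
  }
  ca <- cbind(rho * cos(phi), rho * sin(phi), z)
  radial <- ca / sqrt(rowSums(ca^2))

  one_sc <- c("A", "S", "C", "T", "V")
  res <- lapply(seq_len(n), function(i) {
    rn <- .aa1to3[[seq1[i]]]
    sgn <- if (i %% 2 == 0) 1 else -1       # alternate surface / core
    if (seq1[i] == "G") {
      nm <- "CA"; xyz <- ca[i, , drop = FALSE]
    } else if (seq1[i] %in% one_sc) {
      nm <- c("CA", "CB")
      xyz <- rbind(ca[i, ], ca[i, ] + sgn * 1.6 * radial[i, ])
    } else {
      nm <- c("CA", "CB", "CG")
      xyz <- rbind(ca[i, ], ca[i, ] + sgn * 1.6 * radial[i, ],
                   ca[i, ] + sgn * 3.0 * radial[i, ])
    }
    .res_record("A", i, rn, nm, xyz)
  })
  res <- structure(res, class = "ub_residues", source = "ub_synthetic")
  if (jitter > 0) res <- .jitter_residues(res, jitter, seed)
  res
}

# rotation taking unit vector a to unit vector b
.rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (c_ < -1 + 1e-12) {
    # opposite vectors: rotate pi about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a; v <- v / sqrt(sum(v^2))
    return(2 * tcrossprod(v) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

.axis_rotation <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  vx <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                 -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * vx + (1 - cos(angle)) * (vx %*% vx)
}

#' State-mixture trajectory with known ground truth
#'
#' Generates frames of a two-monomer system by rigid placement from geometric
#' templates that provably map to the intended state labels under the given
#' cutoffs: open (large centre-of-mass separation), closed (I44 patch centres
#' facing at short range), I36-I36 and I36-I44 (the corresponding patch pair
#' facing), other-compact (units close, all patches pointing away).  Exact
#' multinomial allocation: the label counts equal `round(fractions * frames)`
#' (largest-remainder correction), shuffled in seeded order with a small
#' rigid-body jitter per frame.  Every template is verified against the
#' classifier at build time; a violating template is an error.
#'
#' @param fractions named numeric vector over a subset of
#'   `c("open","closed","I36-I36","I36-I44","other-compact")`, summing to 1.
#' @param frames number of frames.
#' @param seed integer seed.
#' @param cutoffs `state_cutoffs`.
#' @param monomer a `ub_residues` monomer (default [make_ub_monomer()]).
#' @param patches patch definitions (default [ub_patches()]).
#' @return list with `traj` (a `cg_trajectory`), `labels` (factor, ground
#'   truth) and `model` (the dimer `bead_model`).
#' @export
make_state_mixture_trajectory <- function(fractions, frames = 1000L,
                                          seed = 1L,
                                          cutoffs = state_cutoffs(),
                                          monomer = make_ub_monomer(),
                                          patches = ub_patches()) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  valid <- c("open", "closed", "I36-I36", "I36-I44", "other-compact")
  if (!all(names(fractions) %in% valid))
    stop("fractions must be named by: ", paste(valid, collapse = ", "))

  m1 <- coarse_grain(monomer, "distal")
  m2 <- coarse_grain(monomer, "proximal")
  model <- combine_monomers(m1, m2, source = "state_mixture_synthetic")
  beads <- model$beads
  mono <- beads$mono
  x1 <- bead_xyz(m1)
  x1 <- sweep(x1, 2, colMeans(x1))
  x2n <- x1                                  # identical fold

  pc <- function(xyz, members) {
    sel <- m1$beads$resno %in% members
    colMeans(xyz[sel, , drop = FALSE])
  }
  p44 <- pc(x1, patches$I44); p36 <- pc(x1, patches$I36)

  # rigid placement of monomer 2 with patch `pa` of unit 1 facing patch `pb`
  # of unit 2 at gap `g`, rolled by `rho` about the facing axis
  facing <- function(pa, pb, g, rho) {
    u <- pa / sqrt(sum(pa^2))
    pb_dir <- pb / sqrt(sum(pb^2))
    R <- .axis_rotation(u, rho) %*% .rotation_between(pb_dir, -u)
    x2 <- x2n %*% t(R)
    pb_rot <- as.vector(R %*% pb)
    target <- pa + g * u
    sweep(x2, 2, target - pb_rot, "+")
  }
  away <- function(d) {
    # patches of both units point away from the partner
    u <- -p44 / sqrt(sum(p44^2))
    R <- .rotation_between(-u, u)            # flip unit 2
    x2 <- x2n %*% t(R)
    sweep(x2, 2, d * u - colMeans(x2), "+")
  }

  ops_of <- function(x2) {
    xyz <- rbind(x1, x2)
    nd <- function(a, b) sqrt(sum((a - b)^2))
    q44 <- pc(x2, patches$I44); q36 <- pc(x2, patches$I36)
    data.frame(d_com = nd(colMeans(x1), colMeans(x2)),
               d_I44I44 = nd(p44, q44), d_I36I36 = nd(p36, q36),
               d_I36I44 = min(nd(p36, q44), nd(p44, q36)))
  }

  template_for <- function(label) {
    cands <- switch(label,
      "open" = list(sweep(x2n, 2, c(cutoffs$open + 1.5, 0, 0), "+")),
      "closed" = lapply(seq(0, 2 * pi, length.out = 25)[-25], function(r)
        facing(p44, p44, 0.45, r)),
      "I36-I36" = lapply(seq(0, 2 * pi, length.out = 49)[-49], function(r)
        facing(p36, p36, 0.5, r)),
      "I36-I44" = lapply(seq(0, 2 * pi, length.out = 49)[-49], function(r)
        facing(p36, p44, 0.5, r)),
      "other-compact" = list(away(2.6)))
    for (x2 in cands) {
      lab <- as.character(classify_frame(ops_of(x2), cutoffs))
      if (lab == label) return(x2)
    }
    stop("no geometric template maps to label '", label,
         "' under the given cutoffs")
  }

  templates <- lapply(setNames(names(fractions), names(fractions)),
                      template_for)

  # exact largest-remainder allocation
  raw <- fractions * frames
  cnt <- floor(raw)
  rem <- frames - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  labels <- rep(names(fractions), times = cnt)

  n <- nrow(beads)
  pos <- array(0, dim = c(n, 3, frames))
  labels <- .local_rng(seed, function() sample(labels))
  .local_rng(seed + 1L, function() {
    for (f in seq_len(frames)) {
      x2 <- templates[[labels[f]]]
      x2 <- sweep(x2, 2, runif(3, -0.02, 0.02), "+")   # small rigid jitter
      Rg <- .random_rotation()                         # global pose
      tg <- runif(3, -1, 1)
      xyz <- rbind(x1, x2) %*% t(Rg)
      pos[, , f] <<- sweep(xyz, 2, tg, "+")
    }
  })

  traj <- structure(list(pos = pos, time = seq_len(frames), box = 0,
                         seed = seed,
                         beads = beads[, c("mono", "resno", "kind",
                                           "charge", "restype")]),
                    class = "cg_trajectory")
  got <- classify_frame(compute_order_params(traj, patches = patches),
                        cutoffs)
  if (!all(as.character(got) == labels))
    stop("internal error: generated frames do not classify as intended")
  list(traj = traj,
       labels = factor(labels, levels = levels(got)),
       model = model)
}

#' Harmonic two-bead fixture with closed-form moments
#'
#' A single harmonic bond `V = k (r - r0)^2` between two beads, plus the
#' equilibrium bond-length variance `<(r - r0)^2> = k_B T / (2 k)` (exact in
#' the stiff-spring limit) for integrator acceptance tests.
#'
#' @param k spring constant, energy/nm^2.
#' @param r0 reference length, nm.
#' @param temperature reduced temperature.
#' @param k_B Boltzmann constant.
#' @return list with `model`, `topology`, `variance` and `kT`.
#' @export
make_harmonic_fixture <- function(k = 200, r0 = 1.0, temperature = 50,
                                  k_B = UB_KB) {
  stopifnot(k > 0)
  beads <- data.frame(mono = 1L, resno = 1:2, kind = "backbone",
                      x = c(0, r0), y = 0, z = 0, mass = 1, charge = 0,
                      restype = "G", stringsAsFactors = FALSE)
  model <- structure(list(beads = beads, n_mono = 1L,
                          source = "harmonic_fixture"),
                     class = "bead_model")
  topo <- structure(list(
    version = "1.0", n_beads = 2L,
    bonds = data.frame(i = 1L, j = 2L, r0 = r0, k = k),
    angles = data.frame(i = integer(), j = integer(), k = integer(),
                        theta0 = numeric(), k_theta = numeric()),
    dihedrals = data.frame(i = integer(), j = integer(), k = integer(),
                           l = integer(), type = integer(), phi0 = numeric(),
                           k_phi = numeric()),
    contacts = data.frame(i = integer(), j = integer(), r_n = numeric(),
                          eps = numeric()),
    link = NULL,
    exclusions = data.frame(i = 1L, j = 2L)), class = "cg_topology")
  list(model = model, topology = topo,
       variance = k_B * temperature / (2 * k),
       kT = k_B * temperature, temperature = temperature)
}
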