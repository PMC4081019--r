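# shared fixtures, built once per test session
mini <- make_mini_dimer()
ub_res <- make_ub_monomer()
ub_seq <- vapply(ub_res, `[[`, "", "resname")

# independent brute-force energy oracle (plain R, no shared code with the
# compiled kernels): recomputes every Hamiltonian term from first principles
oracle_energy <- function(model, topo, params, xyz, box = 0) {
  b <- model$beads
  n <- nrow(b)
  dvec <- function(i, j, inter = FALSE) {
    d <- xyz[i, ] - xyz[j, ]
    if (inter && box > 0) d <- d - box * round(d / box)
    d
  }
  E <- c(bond = 0, angle = 0, dihedral = 0, contact = 0, repulsive = 0,
         link = 0, elec = 0, hp = 0)
  for (r in seq_len(nrow(topo$bonds))) {
    w <- topo$bonds[r, ]
    E["bond"] <- E["bond"] + w$k * (sqrt(sum(dvec(w$i, w$j)^2)) - w$r0)^2
  }
  if (!is.null(topo$link)) {
    l <- topo$link
    E["link"] <- l$k * (sqrt(sum(dvec(l$i, l$j)^2)) - l$r0)^2
  }
  for (r in seq_len(nrow(topo$angles))) {
    w <- topo$angles[r, ]
    u <- dvec(w$i, w$j); v <- dvec(w$k, w$j)
    th <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
    E["angle"] <- E["angle"] + w$k_theta * (th - w$theta0)^2
  }
  dihef <- function(i, j, k, l) {
    b1 <- xyz[j, ] - xyz[i, ]; b2 <- xyz[k, ] - xyz[j, ]; b3 <- xyz[l, ] - xyz[k, ]
    m <- c(b1[2]*b2[3]-b1[3]*b2[2], b1[3]*b2[1]-b1[1]*b2[3], b1[1]*b2[2]-b1[2]*b2[1])
    nn <- c(b2[2]*b3[3]-b2[3]*b3[2], b2[3]*b3[1]-b2[1]*b3[3], b2[1]*b3[2]-b2[2]*b3[1])
    atan2(sqrt(sum(b2^2)) * sum(b1 * nn), sum(m * nn))
  }
  for (r in seq_len(nrow(topo$dihedrals))) {
    w <- topo$dihedrals[r, ]
    dphi <- dihef(w$i, w$j, w$k, w$l) - w$phi0
    E["dihedral"] <- E["dihedral"] + if (w$type == 1)
      w$k_phi * ((1 - cos(dphi)) + 0.5 * (1 - cos(3 * dphi))) else
      w$k_phi * (1 - cos(dphi))
  }
  for (r in seq_len(nrow(topo$contacts))) {
    w <- topo$contacts[r, ]
    x <- w$r_n / sqrt(sum(dvec(w$i, w$j)^2))
    E["contact"] <- E["contact"] + w$eps * (5 * x^12 - 6 * x^10)
  }
  hp <- build_hydrophobic_matrix(alpha = params$alpha_hp, ebar = params$ebar_hp)
  excl <- matrix(FALSE, n, n)
  excl[cbind(topo$exclusions$i, topo$exclusions$j)] <- TRUE
  excl[cbind(topo$exclusions$j, topo$exclusions$i)] <- TRUE
  rc_r <- params$rep_cutoff
  shift_rep <- params$rep_eps * (params$rep_sigma / rc_r)^12
  dslope_rep <- 12 * shift_rep / rc_r
  rc_e <- params$elec_cutoff
  exc <- exp(-rc_e / params$lambda_d)
  shift_el <- exc / rc_e
  dslope_el <- exc * (1 / rc_e^2 + 1 / (params$lambda_d * rc_e))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (excl[i, j]) next
    inter <- b$mono[i] != b$mono[j]
    r <- sqrt(sum(dvec(i, j, inter)^2))
    if (r < rc_r)
      E["repulsive"] <- E["repulsive"] +
        params$rep_eps * (params$rep_sigma / r)^12 - shift_rep +
        dslope_rep * (r - rc_r)
    if (inter && b$charge[i] * b$charge[j] != 0 && r < rc_e)
      E["elec"] <- E["elec"] + b$charge[i] * b$charge[j] * 138.935458 /
        params$eps_r * (exp(-r / params$lambda_d) / r - shift_el +
                          dslope_el * (r - rc_e))
    if (inter && b$kind[i] == "sidechain" && b$kind[j] == "sidechain" &&
        r < params$hp_cutoff)
      E["hp"] <- E["hp"] - params$lambda_hp * hp$eps[b$restype[i], b$restype[j]] *
        0.5 * (1 + tanh(params$hp_c * (params$hp_r0 - r)))
  }
  c(E, total = sum(E))
}

# rigid rotation matrix about a random axis
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2+z^2), 2*(x*y - w*z), 2*(x*z + w*y),
           2*(x*y + w*z), 1 - 2*(x^2+z^2), 2*(y*z - w*x),
           2*(x*z - w*y), 2*(y*z + w*x), 1 - 2*(x^2+y^2)), 3, 3, byrow = TRUE)
}

model_xyz <- function(model) as.matrix(model$beads[, c("x", "y", "z")])
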