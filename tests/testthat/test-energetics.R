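test_that("Debye length has the right magnitude and scaling", {
  l1 <- debye_length(0.1, 80, 298)
  expect_equal(debye_length(0.4, 80, 298), l1 / 2, tolerance = 1e-12)
  expect_gt(debye_length(1e-9), 1e4)   # Coulomb limit: diverges
  expect_error(debye_length(0), "positive")
})

test_that("electrostatic energy matches closed forms and a brute-force sum", {
  p <- mini$params
  # no charged beads -> 0
  m0 <- mini$model
  m0$beads$charge <- 0
  expect_equal(as.numeric(elec_energy(m0, p)), 0)
  # single +1/+1 pair at r = lambda_D: Coulomb * exp(-1), minus the shift
  beads <- data.frame(mono = c(1L, 2L), resno = 1L, kind = "sidechain",
                      x = c(0, p$lambda_d), y = 0, z = 0, mass = 1,
                      charge = 1, restype = "K")
  pair <- structure(list(beads = beads, n_mono = 2L, source = "pair"),
                    class = "bead_model")
  rc <- p$elec_cutoff
  shift <- exp(-3) / rc
  dslope <- exp(-3) * (1 / rc^2 + 1 / (p$lambda_d * rc))
  expected <- 138.935458 / p$eps_r *
    (exp(-1) / p$lambda_d - shift + dslope * (p$lambda_d - rc))
  expect_equal(as.numeric(elec_energy(pair, p)), expected, tolerance = 1e-12)
  # 5-charge fixture against an exhaustive double loop
  set.seed(42)
  b5 <- data.frame(mono = c(1L, 1L, 2L, 2L, 2L), resno = 1:5,
                   kind = "sidechain",
                   x = runif(5, 0, 1.5), y = runif(5, 0, 1.5),
                   z = runif(5, 0, 1.5),
                   mass = 1, charge = c(1, -1, 1, 0.5, -1), restype = "K")
  m5 <- structure(list(beads = b5, n_mono = 2L, source = "q5"),
                  class = "bead_model")
  brute <- 0
  for (i in 1:2) for (j in 3:5) {
    r <- sqrt(sum((b5[i, c("x", "y", "z")] - b5[j, c("x", "y", "z")])^2))
    if (r < rc)
      brute <- brute + b5$charge[i] * b5$charge[j] * 138.935458 / p$eps_r *
        (exp(-r / p$lambda_d) / r - shift + dslope * (r - rc))
  }
  expect_equal(as.numeric(elec_energy(m5, p)), brute, tolerance = 1e-12)
})

test_that("hydrophobic switching has the stated limits and midpoint", {
  p <- mini$params
  hp <- build_hydrophobic_matrix()
  mk <- function(r) {
    beads <- data.frame(mono = c(1L, 2L), resno = 1L, kind = "sidechain",
                        x = c(0, r), y = 0, z = 0, mass = 1, charge = 0,
                        restype = "L")
    structure(list(beads = beads, n_mono = 2L, source = "LL"),
              class = "bead_model")
  }
  depth <- p$lambda_hp * hp$eps["L", "L"]
  expect_equal(as.numeric(hp_energy(mk(0.2), p)), -depth, tolerance = 1e-4)
  expect_equal(as.numeric(hp_energy(mk(p$hp_r0), p)), -depth / 2,
               tolerance = 1e-12)
  expect_lt(abs(hp_energy(mk(2.0), p)), 1e-6)
  # monotonically non-decreasing in the pair distance
  rs <- seq(0.2, 1.6, by = 0.02)
  es <- vapply(rs, function(r) as.numeric(hp_energy(mk(r), p)), 0)
  expect_true(all(diff(es) >= -1e-12))
})

test_that("structure-based terms are at their minima in the native state", {
  E <- sbm_energy(mini$model, mini$topology, mini$params)
  expect_equal(E[["E_bond"]], 0, tolerance = 1e-12)
  expect_equal(E[["E_angle"]], 0, tolerance = 1e-12)
  expect_equal(E[["E_dihedral"]], 0, tolerance = 1e-12)
  expect_equal(E[["E_contact"]], -sum(mini$topology$contacts$eps))
  expect_equal(E[["E_elec"]], 0)   # inter-monomer terms absent by definition
  expect_equal(E[["E_HP"]], 0)
})

test_that("a stretched bond costs k * delta^2", {
  hf <- make_harmonic_fixture(k = 200, r0 = 1)
  xyz <- model_xyz(hf$model)
  xyz[2, 1] <- xyz[2, 1] + 0.1
  E <- total_energy(hf$model, hf$topology, xyz = xyz)
  expect_equal(E[["E_bond"]], 200 * 0.1^2, tolerance = 1e-12)
})

test_that("full Hamiltonian matches the independent oracle on random frames", {
  set.seed(7)
  for (rep in 1:3) {
    xyz <- model_xyz(mini$model) + matrix(rnorm(46 * 3, sd = 0.01), ncol = 3)
    got <- total_energy(mini$model, mini$topology, mini$params, xyz)
    want <- oracle_energy(mini$model, mini$topology, mini$params, xyz)
    expect_equal(got[["E_total"]], want[["total"]], tolerance = 1e-9)
    expect_equal(got[["E_elec"]], want[["elec"]], tolerance = 1e-9)
    expect_equal(got[["E_HP"]], want[["hp"]], tolerance = 1e-9)
    expect_equal(got[["E_contact"]], want[["contact"]], tolerance = 1e-9)
    # bookkeeping: total equals the sum of the decomposition
    expect_equal(got[["E_total"]],
                 sum(got[setdiff(names(got), "E_total")]), tolerance = 1e-9)
  }
})

test_that("monomers at infinite separation have zero binding energy", {
  xyz <- model_xyz(mini$model)
  sel <- mini$model$beads$mono == 2L
  xyz[sel, 1] <- xyz[sel, 1] + 100
  E <- total_energy(mini$model, mini$topology, mini$params, xyz)
  expect_equal(E[["E_elec"]], 0)
  expect_equal(E[["E_HP"]], 0)
})

test_that("energies are invariant under rigid rotation and translation", {
  set.seed(11)
  xyz <- model_xyz(mini$model)
  E0 <- total_energy(mini$model, mini$topology, mini$params, xyz)
  for (rep in 1:5) {
    R <- random_rotation()
    t <- rnorm(3, sd = 3)
    xyz2 <- sweep(xyz %*% t(R), 2, t, "+")
    E1 <- total_energy(mini$model, mini$topology, mini$params, xyz2)
    expect_equal(E1, E0, tolerance = 1e-9)
  }
})

test_that("DH energy approaches bare Coulomb at low salt and vanishes at high salt", {
  mk_p <- function(conc) ff_params(salt_conc = conc)
  beads <- data.frame(mono = c(1L, 2L), resno = 1L, kind = "sidechain",
                      x = c(0, 0.5), y = 0, z = 0, mass = 1, charge = 1,
                      restype = "K")
  pair <- structure(list(beads = beads, n_mono = 2L, source = "pair"),
                    class = "bead_model")
  coulomb <- 138.935458 / 80 / 0.5
  e_low <- as.numeric(elec_energy(pair, mk_p(1e-6)))
  expect_equal(e_low, coulomb, tolerance = 1e-2)
  e_high <- as.numeric(elec_energy(pair, mk_p(20)))
  expect_lt(abs(e_high), 0.05 * coulomb)
})

test_that("forces are antiparallel for an isolated pair and sum to zero", {
  hf <- make_harmonic_fixture(k = 200, r0 = 1)
  xyz <- model_xyz(hf$model)
  xyz[2, ] <- c(0.8, 0.3, -0.2)
  f <- cg_forces(hf$model, hf$topology, xyz = xyz)
  expect_equal(unname(f[1, ] + f[2, ]), c(0, 0, 0), tolerance = 1e-12)
  u <- (xyz[2, ] - xyz[1, ]) / sqrt(sum((xyz[2, ] - xyz[1, ])^2))
  cross <- f[1, ] - sum(f[1, ] * u) * u
  expect_equal(unname(cross), c(0, 0, 0), tolerance = 1e-10)
  # net force zero on the full fixture
  f2 <- cg_forces(mini$model, mini$topology, mini$params)
  expect_equal(unname(colSums(f2)), c(0, 0, 0), tolerance = 1e-9)
})
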