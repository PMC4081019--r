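# tiny trajectory helper: wrap explicit frames for a model
wrap_traj <- function(model, frames, box = 0) {
  pos <- array(0, dim = c(nrow(model$beads), 3, length(frames)))
  for (f in seq_along(frames)) pos[, , f] <- frames[[f]]
  structure(list(pos = pos, time = seq_along(frames), box = box, seed = 0L,
                 beads = model$beads[, c("mono", "resno", "kind", "charge",
                                         "restype")]),
            class = "cg_trajectory")
}

ub_dimer <- local({
  m1 <- coarse_grain(ub_res, "distal")
  m2 <- coarse_grain(ub_res, "proximal")
  combine_monomers(m1, m2)
})

test_that("order parameters match an independent centroid oracle", {
  xyz <- model_xyz(ub_dimer)
  sel2 <- ub_dimer$beads$mono == 2L
  # superposed monomers: all inter-unit distances zero
  tr0 <- wrap_traj(ub_dimer, list(xyz))
  op0 <- compute_order_params(tr0)
  expect_equal(op0$d_com, 0, tolerance = 1e-12)
  expect_equal(op0$d_I44I44, 0, tolerance = 1e-12)
  expect_equal(op0$d_I36I36, 0, tolerance = 1e-12)
  # translating one monomer by 3 nm moves d_com by exactly 3 nm
  xyz3 <- xyz; xyz3[sel2, 1] <- xyz3[sel2, 1] + 3
  op3 <- compute_order_params(wrap_traj(ub_dimer, list(xyz3)))
  expect_equal(op3$d_com, 3, tolerance = 1e-12)
  expect_equal(op3$d_M1G76,
               sqrt(sum((xyz3[ub_dimer$beads$mono == 1L &
                                ub_dimer$beads$resno == 1L &
                                ub_dimer$beads$kind == "backbone", ] -
                         xyz3[sel2 & ub_dimer$beads$resno == 76L &
                                ub_dimer$beads$kind == "backbone", ])^2)))
  # brute-force patch-centroid oracle on a random rigid placement
  set.seed(21)
  R <- random_rotation()
  xyzr <- xyz
  xyzr[sel2, ] <- sweep(xyz[sel2, ] %*% t(R), 2, c(2.5, 1, -0.5), "+")
  op <- compute_order_params(wrap_traj(ub_dimer, list(xyzr)))
  pc <- function(mono, members) {
    s <- ub_dimer$beads$mono == mono & ub_dimer$beads$resno %in% members
    colMeans(xyzr[s, , drop = FALSE])
  }
  p <- ub_patches()
  expect_equal(op$d_I44I44, sqrt(sum((pc(1, p$I44) - pc(2, p$I44))^2)),
               tolerance = 1e-12)
  expect_equal(op$d_I36I44,
               min(sqrt(sum((pc(1, p$I36) - pc(2, p$I44))^2)),
                   sqrt(sum((pc(1, p$I44) - pc(2, p$I36))^2))),
               tolerance = 1e-12)
  expect_lte(op$d_I36I44, max(sqrt(sum((pc(1, p$I36) - pc(2, p$I44))^2)),
                              sqrt(sum((pc(1, p$I44) - pc(2, p$I36))^2))))
  # invariance under a global rigid motion
  Rg <- random_rotation()
  xyzg <- sweep(xyzr %*% t(Rg), 2, c(1, 2, 3), "+")
  opg <- compute_order_params(wrap_traj(ub_dimer, list(xyzg)))
  expect_equal(opg$d_com, op$d_com, tolerance = 1e-9)
  expect_equal(opg$d_I44I44, op$d_I44I44, tolerance = 1e-9)
  expect_equal(opg$d_I36I36, op$d_I36I36, tolerance = 1e-9)
})

test_that("Kabsch RMSD is zero under rigid motion and exact on a constructed deformation", {
  set.seed(3)
  x <- matrix(rnorm(60), 20, 3)
  expect_equal(kabsch_rmsd(x, x), 0, tolerance = 1e-12)
  R <- random_rotation()
  y <- sweep(x %*% t(R), 2, c(1, -2, 0.5), "+")
  expect_equal(kabsch_rmsd(y, x), 0, tolerance = 1e-10)
  # cross-check against the established superposition in bio3d
  z <- x + matrix(rnorm(60, sd = 0.3), 20, 3)
  oracle <- bio3d::rmsd(a = as.vector(t(x)), b = as.vector(t(z)), fit = TRUE)
  expect_equal(kabsch_rmsd(z, x), oracle, tolerance = 2e-3)  # bio3d rounds
  expect_error(kabsch_rmsd(x, x[1:10, ]), "mismatch")
})

test_that("free-energy surfaces follow -kT ln P", {
  # uniform samples: flat surface at 0
  set.seed(8)
  n <- 20000
  f <- fes_2d(runif(n), runif(n), bins = 4, kT = 1)
  expect_true(all(is.finite(f$F)))
  expect_lt(max(f$F), 0.1)
  expect_equal(min(f$F), 0)
  # occupancy ratio e gives dF exactly 1 kT
  x <- c(rep(0.25, 2718), rep(0.75, 1000))
  f2 <- fes_2d(x, rep(0, length(x)), bins = list(c(0, 0.5, 1), c(-1, 1)))
  expect_equal(f2$F[2, 1] - f2$F[1, 1], log(2718 / 1000), tolerance = 1e-12)
  # merged replicas equal concatenated samples (estimator consistency)
  x1 <- rnorm(5000); y1 <- rnorm(5000)
  x2 <- rnorm(5000, 0.5); y2 <- rnorm(5000, -0.25)
  br <- list(seq(-5, 6, by = 0.5), seq(-6, 5, by = 0.5))
  merged <- fes_2d(c(x1, x2), c(y1, y2), bins = br)
  expect_equal(merged$counts,
               fes_2d(x1, y1, bins = br)$counts +
                 fes_2d(x2, y2, bins = br)$counts)
  # bivariate Gaussian: quadratic well recovered within binning error
  g <- fes_2d(rnorm(2e5), rnorm(2e5), bins = list(seq(-2, 2, 0.25),
                                                  seq(-2, 2, 0.25)))
  cx <- (head(g$breaks_x, -1) + tail(g$breaks_x, -1)) / 2
  cy <- (head(g$breaks_y, -1) + tail(g$breaks_y, -1)) / 2
  theo <- outer(cx, cy, function(a, b) (a^2 + b^2) / 2)
  theo <- theo - min(theo)
  ok <- g$counts > 200
  expect_lt(max(abs(g$F[ok] - theo[ok])), 0.15)
  expect_error(fes_2d(numeric(0), numeric(0)), "non-empty")
})

test_that("interfacial contact profiles match a brute-force count", {
  xyz <- model_xyz(ub_dimer)
  sel2 <- ub_dimer$beads$mono == 2L
  near <- xyz; near[sel2, 1] <- near[sel2, 1] + 2.2
  far <- xyz; far[sel2, 1] <- far[sel2, 1] + 50
  tr <- wrap_traj(ub_dimer, list(near, near, far))
  prof <- interfacial_contact_profile(tr, cutoff = 0.8, d_com_max = 3.2)
  expect_equal(prof$frames_used, 2L)
  # brute force on the qualifying frame
  b <- ub_dimer$beads
  i1 <- which(!sel2); i2 <- which(sel2)
  cnt1 <- numeric(76); cnt2 <- numeric(76)
  for (i in i1) for (j in i2) {
    if (sqrt(sum((near[i, ] - near[j, ])^2)) < 0.8) {
      cnt1[b$resno[i]] <- cnt1[b$resno[i]] + 1
      cnt2[b$resno[j]] <- cnt2[b$resno[j]] + 1
    }
  }
  expect_gt(sum(cnt1), 0)
  expect_equal(prof$distal, cnt1)
  expect_equal(prof$proximal, cnt2)
  expect_equal(sum(prof$matrix), sum(cnt1))
  expect_setequal(prof$hot_spots_distal, which(cnt1 > 1))
  # fully separated frames: all-zero profile with a warning
  expect_warning(p0 <- interfacial_contact_profile(wrap_traj(ub_dimer,
                                                             list(far))),
                 "no frames")
  expect_equal(sum(p0$distal), 0)
})

test_that("symmetry score behaves as a correlation", {
  expect_equal(symmetry_score(c(0, 1, 2, 3), c(0, 1, 2, 3)), 1)
  set.seed(99)
  nulls <- replicate(200, {
    a <- rpois(76, 1); b <- sample(a)
    suppressWarnings(symmetry_score(a, b))
  })
  expect_lt(abs(mean(nulls, na.rm = TRUE)), 0.1)   # permutation null ~ 0
  expect_warning(s <- symmetry_score(rep(1, 5), c(1, 2, 3, 4, 5)),
                 "zero-variance")
  expect_true(is.na(s))
  expect_error(symmetry_score(1:3, 1:4), "length")
})

test_that("RMSF is zero for rigid motion and sqrt(3) sigma for isotropic jitter", {
  m <- coarse_grain(ub_res)
  xyz <- model_xyz(m)
  set.seed(12)
  rigid <- lapply(1:10, function(i)
    sweep(xyz %*% t(random_rotation()), 2, rnorm(3), "+"))
  tr <- wrap_traj(m, rigid)
  r0 <- rmsf(tr)
  expect_lt(max(r0$rmsf), 1e-8)
  sigma <- 0.02
  jit <- lapply(1:400, function(i)
    xyz + matrix(rnorm(length(xyz), sd = sigma), ncol = 3))
  r1 <- rmsf(wrap_traj(m, jit))
  expect_equal(mean(r1$rmsf), sqrt(3) * sigma, tolerance = 0.05)
  expect_error(rmsf(wrap_traj(m, rigid[1])), "2 frames")
})

test_that("autocorrelation times recover white-noise and AR(1) closed forms", {
  set.seed(31)
  w <- autocorrelation_time(rnorm(20000))
  expect_lt(abs(w$tau - 1), 0.2)
  expect_true(w$reliable)
  rho <- 0.9
  x <- as.numeric(arima.sim(list(ar = rho), 200000))
  a <- autocorrelation_time(x)
  expect_equal(a$tau, (1 + rho) / (1 - rho), tolerance = 0.15)
  short <- autocorrelation_time(as.numeric(arima.sim(list(ar = 0.999), 500)))
  expect_false(short$reliable)
})

test_that("minimum RMSD over a growing trajectory is non-increasing", {
  set.seed(2)
  ref <- model_xyz(ub_dimer)[ub_dimer$beads$kind == "backbone", ]
  frames <- lapply(1:20, function(i) ref + matrix(rnorm(length(ref), sd = 0.1),
                                                  ncol = 3))
  r <- vapply(frames, kabsch_rmsd, 0, ref = ref)
  run_min <- cummin(r)
  expect_true(all(diff(run_min) <= 0))
})
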