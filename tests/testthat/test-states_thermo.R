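op_row <- function(d_com, d44, d3636, d3644) {
  data.frame(d_com = d_com, d_I44I44 = d44, d_I36I36 = d3636,
             d_I36I44 = d3644)
}

test_that("classification follows the stated precedence and is total", {
  cuts <- state_cutoffs()
  expect_equal(as.character(classify_frame(op_row(5, 0.5, 0.5, 0.5))), "open")
  expect_equal(as.character(classify_frame(op_row(2, 0.5, 2, 2))), "closed")
  # closed wins over both I36 interfaces
  expect_equal(as.character(classify_frame(op_row(2, 0.5, 0.5, 0.5))),
               "closed")
  expect_equal(as.character(classify_frame(op_row(2, 2, 0.9, 2))), "I36-I36")
  expect_equal(as.character(classify_frame(op_row(2, 2, 2, 0.9))), "I36-I44")
  # I36-I36 requires the other interfaces unformed: cross distance formed
  # falls through to I36-I44
  expect_equal(as.character(classify_frame(op_row(2, 2, 0.9, 0.9))),
               "I36-I44")
  expect_equal(as.character(classify_frame(op_row(2, 2, 2, 2))),
               "other-compact")
  expect_error(classify_frame(data.frame(d_com = 1)), "missing")
  # total function: every random frame gets exactly one of the five labels
  set.seed(4)
  ops <- op_row(runif(500, 0, 6), runif(500, 0.3, 3), runif(500, 0.3, 3),
                runif(500, 0.3, 3))
  lab <- classify_frame(ops)
  expect_false(any(is.na(lab)))
  expect_equal(length(lab), 500L)
})

test_that("populations sum correctly and are stable under duplication/merging", {
  set.seed(14)
  ops <- op_row(runif(2000, 0, 6), runif(2000, 0.3, 3), runif(2000, 0.3, 3),
                runif(2000, 0.3, 3))
  p <- state_populations(ops)
  expect_equal(sum(p$mean[c("open", "closed", "compact")]), 100)
  expect_equal(p$mean[["compact"]],
               sum(p$mean[c("I36-I36", "I36-I44", "other")]))
  # duplicating frames leaves fractions unchanged
  p2 <- state_populations(rbind(ops, ops))
  expect_equal(p2$mean, p$mean)
  # merging replicas equals the weighted per-replica mean
  opsA <- ops[1:500, ]; opsB <- ops[501:2000, ]
  pm <- state_populations(list(opsA, opsB))
  labA <- classify_frame(opsA); labB <- classify_frame(opsB)
  manual_open <- mean(c(mean(labA == "open") * 100,
                        mean(labB == "open") * 100))
  expect_equal(pm$mean[["open"]], manual_open)
  expect_error(state_populations(list()), "empty")
})

test_that("prescribed 15/15/70 mixtures are recovered within 3 sigma binomial", {
  n <- 4000L
  mix <- make_state_mixture_trajectory(
    c(open = 0.15, closed = 0.15, `other-compact` = 0.70),
    frames = n, seed = 6)
  ops <- compute_order_params(mix$traj)
  p <- state_populations(ops)
  for (s in c("open", "closed", "compact")) {
    target <- c(open = 15, closed = 15, compact = 70)[[s]]
    se <- 100 * sqrt(target / 100 * (1 - target / 100) / n)
    expect_lt(abs(p$mean[[s]] - target), 3 * se + 1e-9)
  }
  # classification round-trip is exact on template frames
  expect_equal(as.character(classify_frame(ops)), as.character(mix$labels))
})

test_that("entropy-enthalpy decomposition obeys F = H - TS and its limits", {
  set.seed(23)
  x <- rnorm(20000)
  # energy independent of x: |rho_HF| indistinguishable from the permutation
  # null (median over independent draws against the null 95th percentile)
  E0 <- rnorm(20000)
  th0 <- entropy_enthalpy(x, E0, bins = 30)
  obs <- replicate(7, abs(entropy_enthalpy(x, rnorm(20000),
                                           bins = 30)$rho_HF))
  null95 <- quantile(replicate(200, {
    abs(entropy_enthalpy(x, sample(E0), bins = 30)$rho_HF)
  }), 0.95)
  expect_lt(median(obs), null95)
  # identity holds bin-wise exactly
  pr <- th0$profile[th0$profile$used, ]
  expect_equal(pr$F, pr$H - pr$TS, tolerance = 1e-12)
  # E = a x + small noise: enthalpy tracks free energy, rho_HF -> 1 where
  # F is dominated by H... along |x| both rise together
  x2 <- abs(rnorm(20000))
  E2 <- 3 * x2 + rnorm(20000, sd = 0.01)
  th2 <- entropy_enthalpy(x2, E2, bins = 30)
  expect_gt(th2$rho_HF, 0.9)
  expect_error(entropy_enthalpy(1:3, 1:4), "equal-length")
})

test_that("Kd estimation follows the documented two-particle convention", {
  box <- box_from_concentration(2, 0.005)
  V <- box^3 * 1e-24
  NA_ <- 6.02214076e23
  k <- estimate_kd(0.5, box_nm = box)
  expect_equal(k$Kd, (1 - 0.5)^2 / (0.5 * NA_ * V), tolerance = 1e-12)
  expect_match(k$convention, "two-particle")
  # P_b -> 1 drives Kd -> 0, monotone decreasing in P_b
  ks <- vapply(seq(0.05, 0.95, by = 0.05),
               function(p) estimate_kd(p, box_nm = box)$Kd, 0)
  expect_true(all(diff(ks) < 0))
  expect_equal(estimate_kd(1, box_nm = box)$Kd, 0)
  expect_equal(estimate_kd(0, box_nm = box)$Kd, Inf)
  expect_true(is.finite(estimate_kd(0, box_nm = box)$lower_bound))
})

test_that("three-state arithmetic reconciles the two two-state readouts", {
  a <- three_state_apparent(0.150, 0.151, 0.699)
  expect_equal(a$apparent_open, 0.849)
  expect_equal(a$apparent_closed, 0.850)
  # compact = 0: both schemes agree with the true split
  b <- three_state_apparent(0.3, 0.7, 0)
  expect_equal(b$apparent_open, 0.3)
  expect_equal(b$apparent_closed, 0.7)
  # apparent open always >= true open
  set.seed(9)
  for (i in 1:20) {
    v <- runif(3); v <- v / sum(v)
    r <- three_state_apparent(v[1], v[2], v[3])
    expect_gte(r$apparent_open, v[1] - 1e-12)
  }
  expect_error(three_state_apparent(-0.1, 0.5, 0.6), "negative")
  expect_error(three_state_apparent(0.5, 0.2, 0.2), "sum")
})

test_that("loop-closure entropy follows the Gaussian-chain closed form", {
  r <- loop_entropy(N = 152, b = 3.8, I = 4.0, m = 0)
  direct <- (3 / (2 * pi * 152 * 3.8^2))^(3 / 2) * (4 * pi / 3) * 4^3
  expect_equal(r$P, direct, tolerance = 1e-12)
  expect_equal(r$dS, log(direct))
  expect_lt(r$dS, 0)                       # always an entropy cost
  # |dS| grows with chain length at fixed b, I
  ds <- vapply(c(50, 100, 200, 400), function(n) loop_entropy(N = n)$dS, 0)
  expect_true(all(diff(abs(ds)) > 0))
  # constraints already present shorten the effective chain: cheaper closure
  expect_gt(loop_entropy(m = 3)$dS, loop_entropy(m = 0)$dS)
})
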