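test_that("EXP estimator handles trivial and constant work distributions", {
  # identical states
  e0 <- exp_estimate(rep(0, 100), ctx300, n_boot = 0)
  expect_equal(e0$value, 0)
  # constant shift: beta dG = c exactly
  ec <- exp_estimate(rep(3.2, 50), ctx300, n_boot = 0)
  expect_equal(ec$breakdown$beta_dG, 3.2)
  expect_equal(ec$value, 3.2 * kT300)
  expect_error(exp_estimate(numeric(0), ctx300), "2 work samples")
  expect_error(exp_estimate(rep(Inf, 10), ctx300), "degenerate")
})

test_that("EXP recovers the Gaussian closed form m - s^2/2", {
  # closed form verified independently by quadrature
  expect_equal(gaussian_exp_quadrature(2, 1), 1.5, tolerance = 1e-9)
  g <- gaussian_work_samples(2, 1, 1e5, seed = 7)
  est <- exp_estimate(g$delta_u, ctx300, n_boot = 200, seed = 3)
  beta_dG <- est$breakdown$beta_dG
  sd_red <- est$sd / kT300
  expect_lt(abs(beta_dG - 1.5), 3 * sd_red)
  # no overflow for extreme reduced work
  big <- exp_estimate(c(650, 700, 690), ctx300, n_boot = 0)
  expect_true(is.finite(big$value))
})

test_that("MBAR recovers the harmonic ladder and matches the BAR oracle", {
  lad <- harmonic_ladder_ensemble(c(1, 2, 4, 8), 2000, seed = 11)
  fit <- mbar_solve(lad$matrix)
  expect_true(fit$converged)
  steps <- diff(fit$f)
  # each analytic step is 0.5*ln 2; SD of a 2000-sample window step ~ 0.02
  expect_true(all(abs(steps - 0.5 * log(2)) < 3 * 0.02))
  # identical rows give zero difference
  u_same <- rbind(rnorm(100)^2, 0)
  u_same[2, ] <- u_same[1, ]
  f_same <- mbar_solve(reduced_potential_matrix(u_same, c(50, 50)))$f
  expect_equal(f_same[2], 0, tolerance = 1e-9)
  # K = 2 equals independent BAR root-finding
  lad2 <- harmonic_ladder_ensemble(c(1, 4), 2000, seed = 42)
  u <- lad2$matrix$u; nk <- lad2$matrix$n_k
  i0 <- seq_len(nk[1]); i1 <- nk[1] + seq_len(nk[2])
  bar <- bar_oracle(u[2, i0] - u[1, i0], u[1, i1] - u[2, i1])
  mb <- mbar_solve(lad2$matrix, tol = 1e-12)$f[2]
  expect_lt(abs(bar - mb), 1e-6)
})

test_that("MBAR is gauge-invariant and stable under state duplication", {
  lad <- harmonic_ladder_ensemble(c(1, 3, 9), 500, seed = 5)
  f0 <- mbar_solve(lad$matrix, tol = 1e-11)$f
  # adding a constant to one sample's entire column changes nothing
  u2 <- lad$matrix$u
  u2[, 17] <- u2[, 17] + 35
  f1 <- mbar_solve(reduced_potential_matrix(u2, lad$matrix$n_k), tol = 1e-11)$f
  expect_equal(f1, f0, tolerance = 1e-10)
  # splitting one state's samples into two duplicate states keeps all df
  u <- lad$matrix$u; nk <- lad$matrix$n_k
  u_dup <- rbind(u[1, ], u)           # duplicate state 1's row
  nk_dup <- c(250L, 250L, nk[-1])     # its samples split across the twins
  f_dup <- mbar_solve(reduced_potential_matrix(u_dup, nk_dup), tol = 1e-11)$f
  expect_equal(f_dup[2], 0, tolerance = 1e-8)          # twin states coincide
  expect_equal(diff(f_dup[-1]), diff(f0), tolerance = 1e-8)
})

test_that("forward and reverse EXP biases bracket MBAR on oscillator ladders", {
  fwd <- rev_ <- mb <- numeric(20)
  for (s in 1:20) {
    lad <- harmonic_ladder_ensemble(c(1, 25), 500, seed = s)
    u <- lad$matrix$u; nk <- lad$matrix$n_k
    i0 <- seq_len(nk[1]); i1 <- nk[1] + seq_len(nk[2])
    fwd[s] <- exp_estimate(u[2, i0] - u[1, i0], ctx300, n_boot = 0)$breakdown$beta_dG
    rev_[s] <- -exp_estimate(u[1, i1] - u[2, i1], ctx300, n_boot = 0)$breakdown$beta_dG
    mb[s] <- mbar_solve(lad$matrix)$f[2]
  }
  # the one-sided estimators are biased in opposite directions; their
  # seed-averaged values bracket the (consistent) MBAR estimate
  expect_gte(mean(fwd), mean(mb))
  expect_gte(mean(mb), mean(rev_))
  expect_lt(abs(mean(mb) - 0.5 * log(25)), 0.05)
})

test_that("overlap matrix is row-stochastic with sensible limits", {
  # identical states: all entries 1/K
  n <- 400
  set.seed(3)
  x <- rnorm(n)
  u <- rbind(0.5 * x^2, 0.5 * x^2, 0.5 * x^2)
  fit <- mbar_solve(reduced_potential_matrix(u, c(150L, 150L, 100L)), tol = 1e-13)
  O <- mbar_overlap(fit)$matrix
  # indistinguishable states: every weight collapses to N_j / N
  expect_equal(O, matrix(rep(c(150, 150, 100) / 400, each = 3), 3),
               tolerance = 1e-10)
  # with equal counts that is exactly 1/K everywhere
  fit_eq <- mbar_solve(reduced_potential_matrix(u[, 1:300], c(100L, 100L, 100L)),
                       tol = 1e-13)
  expect_equal(max(abs(mbar_overlap(fit_eq)$matrix - 1 / 3)), 0, tolerance = 1e-8)
  # far-separated oscillators: essentially no off-diagonal weight
  set.seed(9)
  xa <- rnorm(500, -10, sd = sqrt(1 / 50)); xb <- rnorm(500, 10, sd = sqrt(1 / 50))
  xs <- c(xa, xb)
  u2 <- rbind(0.5 * 50 * (xs + 10)^2, 0.5 * 50 * (xs - 10)^2)
  fit2 <- mbar_solve(reduced_potential_matrix(u2, c(500L, 500L)))
  O2 <- mbar_overlap(fit2)
  expect_lt(O2$matrix[1, 2], 1e-3)
  expect_lt(O2$matrix[2, 1], 1e-3)
  expect_equal(O2$bottleneck$states, c(1L, 2L))
  # rows sum to 1 for random valid inputs (at full self-consistency)
  lad <- harmonic_ladder_ensemble(c(1, 2, 4), 300, seed = 21)
  O3 <- mbar_overlap(mbar_solve(lad$matrix, tol = 1e-13))$matrix
  expect_equal(rowSums(O3), rep(1, 3), tolerance = 1e-10)
})

test_that("restraint release correction matches 3D quadrature", {
  # k chosen so the restraint volume equals V0: zero correction
  k_match <- 2 * pi * kT300 / ctx300$standard_volume^(2 / 3)
  expect_equal(harmonic_restraint_correction(k_match, ctx300), 0, tolerance = 1e-10)
  # generic (k, T) vs radial quadrature of int exp(-beta k r^2/2) 4 pi r^2 dr
  for (k in c(0.5, 2, 10)) {
    for (temp in c(280, 300, 330)) {
      cc <- thermo_context(temp)
      kT <- thermal_energy(cc)
      vol <- stats::integrate(function(r) 4 * pi * r^2 * exp(-k * r^2 / (2 * kT)),
                              0, Inf, rel.tol = 1e-12)$value
      expect_equal(harmonic_restraint_correction(k, cc),
                   -kT * log(cc$standard_volume / vol), tolerance = 1e-8)
    }
  }
  # doubling V0 changes the correction by -kT ln 2 exactly
  ctx2 <- thermo_context(300)
  ctx2$standard_volume <- 2 * ctx2$standard_volume
  expect_equal(harmonic_restraint_correction(3, ctx2) -
                 harmonic_restraint_correction(3, ctx300),
               -kT300 * log(2), tolerance = 1e-12)
  expect_error(harmonic_restraint_correction(-1, ctx300), "positive")
})

test_that("thermodynamic cycle assembly is antisymmetric and exact on ladders", {
  a <- free_energy_estimate(-40, 0.3, "MBAR")
  b <- free_energy_estimate(-40, 0.4, "MBAR")
  z <- cycle_binding_dG(a, b, 0)
  expect_equal(z$value, 0)
  expect_equal(z$sd, sqrt(0.3^2 + 0.4^2))
  # swapping legs flips the leg-difference sign
  p <- free_energy_estimate(-42, 0.1, "MBAR")
  q <- free_energy_estimate(-37, 0.1, "MBAR")
  expect_equal(cycle_binding_dG(p, q, 0)$value, -cycle_binding_dG(q, p, 0)$value)
  # synthetic analytic cycle: both legs harmonic ladders with known df
  kTc <- kT300
  lad_c <- harmonic_ladder_ensemble(c(1, 8), 4000, seed = 2)
  lad_s <- harmonic_ladder_ensemble(c(1, 2), 4000, seed = 3)
  leg_c <- free_energy_estimate(kTc * mbar_solve(lad_c$matrix)$f[2], 0, "MBAR")
  leg_s <- free_energy_estimate(kTc * mbar_solve(lad_s$matrix)$f[2], 0, "MBAR")
  truth <- -(kTc * 0.5 * log(8) - kTc * 0.5 * log(2))
  got <- cycle_binding_dG(leg_c, leg_s, 0)$value
  expect_equal(got, truth, tolerance = 0.05)
})

test_that("block bootstrap is deterministic and tracks the CLT scale", {
  expect_equal(bootstrap_uncertainty(rep(5, 100), mean, n_boot = 50, seed = 1), 0)
  set.seed(12)
  x <- rnorm(5000)
  sd1 <- bootstrap_uncertainty(x, mean, n_blocks = 5, n_boot = 500, seed = 9)
  sd2 <- bootstrap_uncertainty(x, mean, n_blocks = 5, n_boot = 500, seed = 9)
  expect_identical(sd1, sd2)
  expect_lt(abs(sd1 - 1 / sqrt(5000)) / (1 / sqrt(5000)), 0.3)
  expect_error(bootstrap_uncertainty(1:3, mean, n_blocks = 5), "shorter")
})

test_that("lambda schedules enforce electrostatics-first decoupling", {
  sch <- lambda_schedule(lambda_coul = c(1, 0.5, 0, 0, 0),
                         lambda_vdw = c(1, 1, 1, 0.5, 0))
  expect_equal(sch$stage, c("electrostatics", "electrostatics", "electrostatics",
                            "vdw", "vdw"))
  expect_error(lambda_schedule(c(1, 0.5), c(0.5, 0.5)), "lambda_coul = 0")
  expect_error(lambda_schedule(c(2), c(1)), "\\[0, 1\\]")
})

test_that("zero-sample perturbation states are solved and flagged", {
  lad <- harmonic_ladder_ensemble(c(1, 4), 1000, seed = 6)
  u <- rbind(lad$matrix$u, 0.5 * 2 * (2 * lad$matrix$u[1, ]))  # a third Hamiltonian
  M <- reduced_potential_matrix(u, c(1000L, 1000L, 0L))
  fit <- mbar_solve(M)
  expect_equal(fit$perturbation_states, 3L)
  expect_true(is.finite(fit$f[3]))
})
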