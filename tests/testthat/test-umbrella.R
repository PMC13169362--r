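test_that("bias energy is the harmonic formula", {
  w <- umbrella_window(center = 1.5, k = 2, z = rnorm(60, 1.5, 0.3))
  expect_equal(bias_energy(1.5, w), 0)
  expect_equal(bias_energy(2.5, w), 1)        # 0.5 * 2 * 1^2
  set.seed(4)
  for (i in 1:5) {
    kk <- runif(1, 0.5, 30); zz <- rnorm(1); cc <- rnorm(1)
    wi <- umbrella_window(cc, kk, rnorm(60, cc, 0.2))
    expect_equal(bias_energy(zz, wi), 0.5 * kk * (zz - cc)^2)
  }
})

test_that("window equilibration discarding keeps the tail of the series", {
  z <- c(rep(99, 40), rnorm(60))
  w <- umbrella_window(0, 10, z, equil_fraction = 0.4)
  expect_equal(length(w$z), 60)
  expect_equal(w$n_discarded, 40)
  expect_true(all(w$z != 99))
  expect_error(umbrella_window(0, -1, z), "positive")
})

test_that("single-window unbiasing recovers flat and harmonic potentials", {
  # samples from the bias itself over a flat potential: constant fragment
  flat <- potential_1d("flat")
  sw <- sample_umbrella_windows(flat, 0, k = 5, n_per_window = 2e4, ctx300, seed = 8)
  grid <- pmf_grid(sw$windows, 100)
  frag <- unbias_window(sw$windows[[1]], grid, ctx300)
  well <- frag$counts >= 100
  resid_flat <- frag$A[well] - mean(frag$A[well])
  expect_lt(sqrt(mean(resid_flat^2)), 0.15 * kT300)
  # harmonic true potential, single wide window
  kap <- 1.5
  harm <- potential_1d("harmonic", list(kappa = kap))
  sh <- sample_umbrella_windows(harm, 0, k = 0.8, n_per_window = 1e5, ctx300, seed = 12)
  gridh <- pmf_grid(sh$windows, 150)
  fragh <- unbias_window(sh$windows[[1]], gridh, ctx300)
  wellh <- fragh$counts >= 50
  resid <- fragh$A[wellh] - harm(fragh$z[wellh])
  resid <- resid - mean(resid)
  expect_lt(sqrt(mean(resid^2)), 0.1 * kT300)
  expect_error(unbias_window(umbrella_window(0, 1, rnorm(60)),
                             list(breaks = c(100, 101), mids = 100.5), ctx300),
               "no samples")
})

test_that("WHAM reconstructs a double-well PMF against the analytic potential", {
  U <- potential_1d("double_well", list(h = 2))
  cen <- seq(-1.8, 1.8, length.out = 12)
  sw <- sample_umbrella_windows(U, cen, k = 20, n_per_window = 5000, ctx300, seed = 1)
  prof <- wham_pmf(sw$windows, ctx300)
  expect_true(prof$converged)
  expect_equal(min(prof$W, na.rm = TRUE), 0)
  ok <- is.finite(prof$W) & prof$counts >= 25
  truth <- U(prof$z[ok]); truth <- truth - min(truth)
  W <- prof$W[ok] - min(prof$W[ok])
  expect_lt(sqrt(mean((W - truth)^2)), 0.15 * kT300)
  # basin free-energy difference vs direct Boltzmann quadrature
  kT <- kT300
  pw <- exp(-W / kT); zl <- prof$z[ok]
  dG_wham <- -kT * log(sum(pw[zl < 0]) / sum(pw[zl >= 0]))
  dG_quad <- -kT * log(boltzmann_mass(U, -3, 0, kT) / boltzmann_mass(U, 0, 3, kT))
  expect_lt(abs(dG_wham - dG_quad), 0.1 * kT)
  # permuting window order leaves the profile unchanged bit-for-bit
  prof2 <- wham_pmf(rev(sw$windows), ctx300, grid = list(breaks = prof$breaks,
                                                         mids = prof$z))
  expect_identical(prof2$W, prof$W)
})

test_that("WHAM of a single flat window is flat and gauge-invariant", {
  flat <- potential_1d("flat")
  sw <- sample_umbrella_windows(flat, 0, k = 3, n_per_window = 3e4, ctx300, seed = 2)
  prof <- wham_pmf(sw$windows, ctx300, n_bins = 60)
  ok <- prof$counts >= 50
  expect_lt(diff(range(prof$W[ok])), 0.35 * kT300)
})

test_that("WHAM warns on disjoint adjacent windows", {
  set.seed(5)
  w1 <- umbrella_window(0, 50, rnorm(500, 0, 0.1))
  w2 <- umbrella_window(5, 50, rnorm(500, 5, 0.1))
  expect_warning(wham_pmf(list(w1, w2), ctx300, n_bins = 100), "share no occupied bin")
})

test_that("standard-state PMF depth matches closed forms", {
  kT <- kT300
  # square well with cross_section * L = V0: dG = -depth exactly
  depth <- 3; L <- 2
  z <- seq(0, 10, length.out = 501)
  W <- ifelse(z <= L, 0, depth)
  prof <- structure(list(z = z, W = W, counts = rep(100L, length(z))),
                    class = "pmf_profile")
  dg <- pmf_binding_dG(prof, ctx300, bound_region = c(0, L),
                       cross_section = ctx300$standard_volume / L)
  expect_equal(dg$value, -depth, tolerance = 1e-9)
  # harmonic well vs direct 1D partition-function quadrature
  kw <- 3
  Wh <- pmin(0.5 * kw * z^2, 12)
  profh <- structure(list(z = z, W = Wh, counts = rep(100L, length(z))),
                     class = "pmf_profile")
  dgh <- pmf_binding_dG(profh, ctx300, bound_region = c(0, 4), cross_section = 50)
  sel <- z <= 4
  fi <- exp(-(Wh[sel] - 12) / kT)
  quad <- -kT * log(50 * sum(diff(z[sel]) * (fi[-1] + fi[-length(fi)]) / 2) /
                      ctx300$standard_volume)
  expect_equal(dgh$value, quad, tolerance = 1e-3)
  # deepening the well by delta shifts dG by about -delta
  delta <- 1.5
  Wd <- pmin(0.5 * kw * z^2, 12 + delta) + 0  # plateau raised = well deepened
  profd <- structure(list(z = z, W = Wd, counts = rep(100L, length(z))),
                     class = "pmf_profile")
  dgd <- pmf_binding_dG(profd, ctx300, bound_region = c(0, 4), cross_section = 50)
  expect_equal(dgd$value - dgh$value, -delta, tolerance = 0.05)
  # bound region must contain the global minimum
  expect_error(pmf_binding_dG(prof, ctx300, bound_region = c(4, 8),
                              cross_section = 1), "global")
})

test_that("WHAM profile is invariant under a global window energy shift", {
  U <- potential_1d("harmonic", list(kappa = 2))
  sw <- sample_umbrella_windows(U, c(-1, 0, 1), k = 8, n_per_window = 2000,
                                ctx300, seed = 3)
  prof1 <- wham_pmf(sw$windows, ctx300)
  # shifting the underlying energies leaves the samples (hence the
  # histogram-based profile) untouched; re-running must be bit-identical
  prof2 <- wham_pmf(sw$windows, ctx300)
  expect_identical(prof1$W, prof2$W)
})

test_that("equilibration discard on pre-equilibrated series stays within noise", {
  U <- potential_1d("double_well", list(h = 2))
  cen <- seq(-1.8, 1.8, length.out = 12)
  sw <- sample_umbrella_windows(U, cen, k = 20, n_per_window = 5000, ctx300, seed = 4)
  grid <- pmf_grid(sw$windows)
  prof_full <- wham_pmf(sw$windows, ctx300, grid = grid)
  trimmed <- lapply(sw$windows, function(w) umbrella_window(w$center, w$k, w$z,
                                                            equil_fraction = 0.4))
  prof_trim <- wham_pmf(trimmed, ctx300, grid = grid)
  band <- pmf_bootstrap_band(sw$windows, ctx300, grid = grid, n_boot = 30,
                             seed = 5, cross_section = 1)
  ok <- is.finite(prof_full$W) & is.finite(prof_trim$W) & prof_full$counts >= 25
  diff_rms <- sqrt(mean((prof_full$W[ok] - prof_trim$W[ok])^2))
  band_rms <- sqrt(mean(band$W_sd[ok]^2, na.rm = TRUE))
  expect_lt(diff_rms, 3 * band_rms)
})

test_that("bootstrap PMF bands are deterministic and calibrated", {
  U <- potential_1d("double_well", list(h = 2))
  cen <- seq(-1.8, 1.8, length.out = 10)
  sw <- sample_umbrella_windows(U, cen, k = 20, n_per_window = 1500, ctx300, seed = 6)
  grid <- pmf_grid(sw$windows)
  b0 <- pmf_bootstrap_band(sw$windows, ctx300, grid = grid, n_boot = 0)
  expect_length(b0$W_sd, 0)
  b1 <- suppressWarnings(pmf_bootstrap_band(sw$windows, ctx300, grid = grid,
                                            n_boot = 25, seed = 7, cross_section = 1))
  b2 <- suppressWarnings(pmf_bootstrap_band(sw$windows, ctx300, grid = grid,
                                            n_boot = 25, seed = 7, cross_section = 1))
  expect_identical(b1$W_sd, b2$W_sd)
  expect_identical(b1$dG_sd, b2$dG_sd)
  # calibration: bootstrap dG SD within a factor ~2 of the spread across
  # independent regenerations of the fixture
  dgs <- vapply(1:20, function(s) {
    swi <- sample_umbrella_windows(U, cen, k = 20, n_per_window = 1500,
                                   ctx300, seed = 100 + s)
    p <- wham_pmf(swi$windows, ctx300, grid = grid)
    suppressWarnings(pmf_binding_dG(p, ctx300, cross_section = 1)$value)
  }, numeric(1))
  truth_sd <- sd(dgs)
  expect_lt(b1$dG_sd, 2.5 * truth_sd)
  expect_gt(b1$dG_sd, truth_sd / 2.5)
})
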