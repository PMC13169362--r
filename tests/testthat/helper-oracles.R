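# Shared fixtures and independent oracles used across the suite.

ctx300 <- thermo_context(300)
kT300 <- thermal_energy(ctx300)

# Bennett acceptance ratio by direct root-finding on the implicit
# equation: independent oracle for two-state MBAR.
# wf = u1 - u0 on samples from state 0; wr = u0 - u1 on samples from 1.
bar_oracle <- function(wf, wr, tol = 1e-13) {
  M <- log(length(wf) / length(wr))
  fn <- function(df) {
    sum(1 / (1 + exp(M + wf - df))) - sum(1 / (1 + exp(-M + wr + df)))
  }
  stats::uniroot(fn, c(-200, 200), tol = tol)$root
}

# Gaussian EXP limit by numerical quadrature of int N(x; m, s) e^-x dx.
gaussian_exp_quadrature <- function(m, s) {
  f <- function(x) stats::dnorm(x, m, s) * exp(-x)
  -log(stats::integrate(f, m - 12 * s, m + 12 * s, rel.tol = 1e-12)$value)
}

# 1D Boltzmann quadrature of a potential over an interval (probability
# mass), on a dense grid.
boltzmann_mass <- function(U, lo, hi, kT, n = 40001) {
  z <- seq(lo, hi, length.out = n)
  w <- exp(-U(z) / kT)
  sum((w[-1] + w[-n]) / 2) * (hi - lo) / (n - 1)
}

# Spherical-cap SASA of two identical spheres of expanded radius R at
# centre distance d (each loses one cap of height R - d/2).
two_sphere_sasa <- function(R, d) {
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

# Analytic Born solvation energy of a single sphere.
born_energy <- function(q, a, eps_out, C = 332.0637, eps_in = 1) {
  -(C * q^2 / (2 * a)) * (1 / eps_in - 1 / eps_out)
}

# Quantum harmonic-oscillator entropy (kcal/(mol K)) of an isotropic
# 3D Gaussian particle of mass m (amu) and positional sd (A).
ho_entropy_3d <- function(m_amu, sd_A, T) {
  hbar <- 1.054571817e-34; kB <- 1.380649e-23
  amu <- 1.66053906660e-27
  kTJ <- kB * T
  omega <- sqrt(kTJ / (m_amu * amu * (sd_A * 1e-10)^2))
  u <- hbar * omega / kTJ
  3 * 1.9872036e-3 * (u / (exp(u) - 1) - log(1 - exp(-u)))
}

# Brute-force OLS by dense grid search over (slope, intercept);
# independent of lm().
grid_search_fit <- function(x, y, span = 6, n = 601) {
  sl <- seq(-span, span, length.out = n)
  ic <- seq(min(y) - span, max(y) + span, length.out = n)
  best <- c(NA, NA, Inf)
  for (s in sl) {
    res2 <- outer(ic, seq_along(x), function(b, i) (y[i] - (s * x[i] + b))^2)
    ss <- rowSums(res2)
    j <- which.min(ss)
    if (ss[j] < best[3]) best <- c(s, ic[j], ss[j])
  }
  list(slope = best[1], intercept = best[2], D = sqrt(best[3] / length(x)))
}

# Small neutral two-sphere solute helper.
sphere_solute <- function(x, radius, charge = 0) {
  toy_solute(data.frame(x = x, y = 0, z = 0, charge = charge,
                        radius = radius, mass = 12.011))
}
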