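# Alchemical leg: EXP and MBAR estimators over a lambda ladder, overlap
# diagnostics, restraint/standard-state correction and cycle assembly.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Reduced potential matrix for multistate estimation
#'
#' Holds u[k, n]: the dimensionless (reduced) potential energy of sample n
#' evaluated under state k's Hamiltonian, together with the number of
#' samples originating from each state. This is the substrate for both the
#' exponential-averaging and MBAR estimators.
#'
#' @param u Numeric `K x N` matrix of reduced potentials; all entries
#'   finite.
#' @param n_k Integer vector of length K: samples drawn from each state
#'   (columns are ordered state-by-state). `sum(n_k)` must equal `ncol(u)`.
#'   Zero-sample states are legal "perturbation targets" and are flagged.
#' @param lambda Optional data.frame with columns `lambda_coul`,
#'   `lambda_vdw` (one row per state) describing the decoupling schedule.
#'
#' @return An object of class `reduced_potential_matrix`.
#' @export
reduced_potential_matrix <- function(u, n_k, lambda = NULL) {
  u <- as.matrix(u)
  if (nrow(u) < 2L) stop("reduced_potential_matrix: need K >= 2 states")
  if (any(!is.finite(u))) stop("reduced_potential_matrix: all entries must be finite")
  n_k <- as.integer(n_k)
  if (length(n_k) != nrow(u)) stop("reduced_potential_matrix: one count per state required")
  if (any(n_k < 0)) stop("reduced_potential_matrix: negative sample counts")
  if (sum(n_k) != ncol(u)) stop("reduced_potential_matrix: sum(n_k) must equal ncol(u)")
  if (!is.null(lambda) && nrow(lambda) != nrow(u)) {
    stop("reduced_potential_matrix: lambda table must have one row per state")
  }
  structure(list(u = u, n_k = n_k, lambda = lambda),
            class = "reduced_potential_matrix")
}

#' @export
print.reduced_potential_matrix <- function(x, ...) {
  cat(sprintf("<reduced_potential_matrix> K = %d states, N = %d samples (n_k: %s)\n",
              nrow(x$u), ncol(x$u), paste(x$n_k, collapse = ", ")))
  invisible(x)
}

#' Lambda decoupling schedule
#'
#' Electrostatics are decoupled first (lambda_coul varied at full vdW
#' coupling), then van der Waals (at lambda_coul = 0); within a stage the
#' lambda values must be monotone.
#'
#' @param lambda_coul,lambda_vdw Numeric vectors in \[0, 1\], one entry per
#'   state, in ladder order.
#' @return A data.frame of class `lambda_schedule` with a `stage` column
#'   ("electrostatics" or "vdw").
#' @export
lambda_schedule <- function(lambda_coul, lambda_vdw) {
  if (length(lambda_coul) != length(lambda_vdw)) stop("lambda_schedule: unequal lengths")
  if (any(lambda_coul < 0 | lambda_coul > 1 | lambda_vdw < 0 | lambda_vdw > 1)) {
    stop("lambda_schedule: lambda values must lie in [0, 1]")
  }
  stage <- ifelse(lambda_vdw == 1, "electrostatics", "vdw")
  if (any(stage == "vdw" & lambda_coul != 0)) {
    stop("lambda_schedule: vdW stage requires lambda_coul = 0 (electrostatics removed first)")
  }
  for (s in unique(stage)) {
    lam <- if (s == "electrostatics") lambda_coul[stage == s] else lambda_vdw[stage == s]
    if (is.unsorted(lam) && is.unsorted(rev(lam))) {
      stop("lambda_schedule: lambda values must be monotone within a stage")
    }
  }
  out <- data.frame(lambda_coul = lambda_coul, lambda_vdw = lambda_vdw, stage = stage)
  class(out) <- c("lambda_schedule", "data.frame")
  out
}

#' Exponential-averaging (Zwanzig) free-energy estimate
#'
#' One-sided free-energy difference between two states from work samples
#' `delta_u = u_B - u_A` (reduced units) drawn in state A:
#' `dG = -kT * log mean exp(-delta_u)`, accumulated in log space so that
#' `|delta_u|` up to ~700 does not overflow.
#'
#' @param delta_u Numeric vector of at least 2 finite reduced work samples.
#' @param ctx A [thermo_context()].
#' @param n_boot Bootstrap resamples for the uncertainty (0 disables).
#' @param n_blocks Contiguous blocks for the block bootstrap.
#' @param seed Seed for the bootstrap resampling.
#' @return A [free_energy_estimate()] (kcal/mol), method "EXP". The
#'   breakdown records the reduced-unit estimate as `beta_dG`.
#' @export
exp_estimate <- function(delta_u, ctx, n_boot = 200L, n_blocks = 5L, seed = 1L) {
  assert_ctx(ctx)
  if (length(delta_u) < 2L) stop("exp_estimate: need at least 2 work samples")
  if (any(!is.finite(delta_u))) {
    if (all(!is.finite(delta_u))) stop("exp_estimate: degenerate overlap (all weights infinite)")
    stop("exp_estimate: non-finite work samples")
  }
  kT <- thermal_energy(ctx)
  beta_dG <- function(w) -(logsumexp(-w) - log(length(w)))
  est <- beta_dG(delta_u)
  sd <- NA_real_
  if (n_boot > 0L && length(delta_u) >= n_blocks) {
    sd <- kT * bootstrap_uncertainty(delta_u, beta_dG, n_blocks = n_blocks,
                                     n_boot = n_boot, seed = seed)
  }
  free_energy_estimate(kT * est, sd, method = "EXP",
                       breakdown = list(beta_dG = est, n = length(delta_u)))
}

mbar_log_denominator <- function(u, n_k, f) {
  # log sum_j N_j exp(f_j - u_jn), per sample; zero-count states drop out
  keep <- which(n_k > 0)
  lw <- log(n_k[keep]) + f[keep] - u[keep, , drop = FALSE]
  apply(lw, 2, logsumexp)
}

#' Solve the MBAR self-consistent equations
#'
#' Estimates the dimensionless free energy of every state in a
#' [reduced_potential_matrix()] by self-consistent iteration of the
#' multistate Bennett acceptance ratio fixed point
#' `f_k = -log sum_n exp(-u_kn) / sum_j N_j exp(f_j - u_jn)`,
#' with all sums accumulated by log-sum-exp. The gauge is fixed at
#' `f_1 = 0` (first state).
#'
#' @param M A [reduced_potential_matrix()].
#' @param ctx Optional [thermo_context()]; when supplied the kcal/mol
#'   values are attached alongside the reduced ones.
#' @param tol Convergence tolerance on `max |f^(t) - f^(t-1)|` (reduced
#'   units).
#' @param max_iter Maximum self-consistent iterations.
#' @return A list of class `mbar_result`: `f` (reduced free energies, state
#'   1 gauge-fixed to 0), `f_kcal` (if ctx given), `converged`, `iterations`,
#'   `residual`, `perturbation_states` (indices with zero samples) and the
#'   inputs needed by [mbar_overlap()].
#' @export
mbar_solve <- function(M, ctx = NULL, tol = 1e-8, max_iter = 10000L) {
  if (!inherits(M, "reduced_potential_matrix")) stop("mbar_solve: M must be a reduced_potential_matrix")
  if (tol <= 0) stop("mbar_solve: tol must be positive")
  u <- M$u; n_k <- M$n_k
  K <- nrow(u)
  pert <- which(n_k == 0L)
  f <- numeric(K)
  iter <- 0L
  resid <- Inf
  repeat {
    iter <- iter + 1L
    log_denom <- mbar_log_denominator(u, n_k, f)
    f_new <- -apply(-u - rep(log_denom, each = K), 1, logsumexp)
    f_new <- f_new - f_new[1]
    resid <- max(abs(f_new - f))
    f <- f_new
    if (resid < tol) break
    if (iter >= max_iter) {
      stop(sprintf("mbar_solve: not converged after %d iterations (last residual %.3g)",
                   iter, resid))
    }
  }
  out <- list(f = f, converged = TRUE, iterations = iter, residual = resid,
              perturbation_states = pert, u = u, n_k = n_k)
  if (!is.null(ctx)) {
    assert_ctx(ctx)
    out$f_kcal <- f * thermal_energy(ctx)
    out$temperature <- ctx$temperature
  }
  class(out) <- "mbar_result"
  out
}

#' @export
print.mbar_result <- function(x, ...) {
  cat(sprintf("<mbar_result> K = %d, converged in %d iterations (residual %.2g)\n",
              length(x$f), x$iterations, x$residual))
  cat("  f (reduced, state 1 = 0): ", paste(sprintf("%.4f", x$f), collapse = ", "), "\n")
  if (length(x$perturbation_states)) {
    cat("  perturbation (zero-sample) states:",
        paste(x$perturbation_states, collapse = ", "), "\n")
  }
  invisible(x)
}

#' MBAR overlap matrix
#'
#' The row-stochastic K x K matrix `O[i, j] = sum_n N_j W_ni W_nj` built
#' from the converged MBAR weights `W_nk = exp(f_k - u_kn) / sum_j N_j
#' exp(f_j - u_jn)`. Entry (i, j) measures how well samples usable for
#' state i also represent state j; small nearest-neighbour entries flag a
#' lambda-schedule bottleneck with insufficient phase-space overlap.
#'
#' @param fit An [mbar_solve()] result.
#' @return A list of class `overlap_matrix`: `matrix` (K x K, rows sum to
#'   1) and `bottleneck` (the smallest off-diagonal entry between adjacent
#'   states, with its index pair).
#' @export
mbar_overlap <- function(fit) {
  if (!inherits(fit, "mbar_result") || !isTRUE(fit$converged)) {
    stop("mbar_overlap: requires a converged mbar_solve() result")
  }
  u <- fit$u; n_k <- fit$n_k; f <- fit$f
  K <- nrow(u)
  log_denom <- mbar_log_denominator(u, n_k, f)
  logW <- f - u - rep(log_denom, each = K)   # K x N, log W_nk by row k
  W <- exp(logW)
  O <- W %*% t(W * n_k)                      # O[i,j] = sum_n W_ni N_j W_nj
  nb <- cbind(seq_len(K - 1L), 2:K)
  vals <- O[nb]
  vals2 <- O[nb[, 2:1, drop = FALSE]]
  worst <- which.min(pmin(vals, vals2))
  structure(list(matrix = O,
                 bottleneck = list(value = min(vals[worst], vals2[worst]),
                                   states = c(worst, worst + 1L))),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("<overlap_matrix> K = %d, bottleneck O[%d,%d] = %.4g\n",
              nrow(x$matrix), x$bottleneck$states[1], x$bottleneck$states[2],
              x$bottleneck$value))
  invisible(x)
}

#' Standard-state correction for releasing a harmonic restraint
#'
#' Analytic free-energy cost of releasing a ligand held by an isotropic 3D
#' harmonic restraint of force constant `k_restraint` into the 1 M
#' standard-state volume V0:
#' `dG_release = -kT * log( V0 / (2 pi kT / k)^{3/2} )`.
#' By convention the value is added to the decoupled-leg sum of the
#' thermodynamic cycle.
#'
#' @param k_restraint Restraint force constant, kcal/mol/A^2 (> 0).
#' @param ctx A [thermo_context()].
#' @return Correction energy in kcal/mol.
#' @export
harmonic_restraint_correction <- function(k_restraint, ctx) {
  assert_ctx(ctx)
  if (!is.numeric(k_restraint) || k_restraint <= 0) {
    stop("harmonic_restraint_correction: k_restraint must be positive")
  }
  kT <- thermal_energy(ctx)
  v_restraint <- (2 * pi * kT / k_restraint)^(3 / 2)
  -kT * log(ctx$standard_volume / v_restraint)
}

#' Assemble the binding free energy from the thermodynamic cycle
#'
#' Combines the complex-leg and solvent-leg decoupling free energies with
#' the restraint/standard-state correction:
#' `dG_bind = -(dG_complex - dG_solvent) + dG_restraint`, uncertainties in
#' quadrature. Negative values are favourable binding.
#'
#' @param complex_leg,solvent_leg [free_energy_estimate()]s for decoupling
#'   the ligand in the complex and in solvent, at the same temperature.
#' @param restraint_corr Restraint correction (kcal/mol), e.g. from
#'   [harmonic_restraint_correction()]; default 0.
#' @return A [free_energy_estimate()], method tag from the complex leg.
#' @export
cycle_binding_dG <- function(complex_leg, solvent_leg, restraint_corr = 0) {
  for (leg in list(complex_leg, solvent_leg)) {
    if (!inherits(leg, "free_energy_estimate")) {
      stop("cycle_binding_dG: legs must be free_energy_estimate objects")
    }
  }
  tc <- attr(complex_leg, "temperature"); ts <- attr(solvent_leg, "temperature")
  if (!is.null(tc) && !is.null(ts) && !isTRUE(all.equal(tc, ts))) {
    stop("cycle_binding_dG: legs estimated at different temperatures")
  }
  value <- -(complex_leg$value - solvent_leg$value) + restraint_corr
  sds <- c(complex_leg$sd, solvent_leg$sd)
  sd <- if (all(is.na(sds))) NA_real_ else sqrt(sum(sds^2, na.rm = TRUE))
  free_energy_estimate(value, sd, method = complex_leg$method,
                       breakdown = list(complex_leg = complex_leg$value,
                                        solvent_leg = solvent_leg$value,
                                        restraint_correction = restraint_corr),
                       notes = "dG_bind = -(complex - solvent) + restraint correction")
}

#' Block-bootstrap uncertainty of a statistic of a time series
#'
#' Splits a (possibly autocorrelated) series into `n_blocks` contiguous
#' blocks, resamples whole blocks with replacement `n_boot` times, and
#' returns the standard deviation of the statistic across resamples.
#' Deterministic given `seed`. Five blocks emulate five statistically
#' independent sub-trajectory replicas.
#'
#' @param samples Numeric vector (time-ordered) or a list/matrix the
#'   statistic understands; must be at least `n_blocks` long.
#' @param statistic Function of one resampled series returning a scalar.
#' @param n_blocks Number of contiguous blocks (>= 2).
#' @param n_boot Number of bootstrap resamples.
#' @param seed RNG seed.
#' @return The bootstrap standard deviation (scalar).
#' @export
bootstrap_uncertainty <- function(samples, statistic, n_blocks = 5L,
                                  n_boot = 200L, seed = 1L) {
  n <- if (is.matrix(samples)) ncol(samples) else length(samples)
  if (n_blocks < 2L) stop("bootstrap_uncertainty: n_blocks must be >= 2")
  if (n < n_blocks) stop("bootstrap_uncertainty: series shorter than n_blocks")
  bounds <- floor(seq(0, n, length.out = n_blocks + 1L))
  blocks <- lapply(seq_len(n_blocks), function(b) (bounds[b] + 1L):bounds[b + 1L])
  take <- if (is.matrix(samples)) {
    function(idx) samples[, idx, drop = FALSE]
  } else {
    function(idx) samples[idx]
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  stats_out <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    pick <- sample.int(n_blocks, n_blocks, replace = TRUE)
    idx <- unlist(blocks[pick], use.names = FALSE)
    stats_out[b] <- tryCatch(statistic(take(idx)),
                             error = function(e) stop(sprintf(
                               "bootstrap_uncertainty: statistic failed on resample %d: %s",
                               b, conditionMessage(e))))
  }
  stats::sd(stats_out)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Statistical-inefficiency subsampler
#'
#' Optional decorrelation helper (off by default throughout the package:
#' inputs are assumed pre-subsampled, and block bootstrapping handles the
#' residual correlation). Estimates the integrated autocorrelation time of
#' the series and returns indices of an effectively independent subsample.
#'
#' @param x Numeric time series.
#' @param max_lag Largest lag examined (default `length(x) %/% 2`).
#' @return Integer indices into `x`, spaced by the statistical
#'   inefficiency `g = 1 + 2 * tau`.
#' @export
subsample_indices <- function(x, max_lag = length(x) %/% 2L) {
  n <- length(x)
  if (n < 4L) return(seq_len(n))
  xc <- x - mean(x)
  v <- mean(xc^2)
  if (v == 0) return(seq_len(n))
  tau <- 0
  for (lag in seq_len(min(max_lag, n - 1L))) {
    c_t <- mean(xc[1:(n - lag)] * xc[(lag + 1):n]) / v
    if (c_t <= 0) break
    tau <- tau + c_t * (1 - lag / n)
  }
  g <- max(1, 1 + 2 * tau)
  unique(round(seq(1L, n, by = g)))
}
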