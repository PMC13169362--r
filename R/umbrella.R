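# Umbrella-sampling leg: harmonic windows, per-window unbiasing, WHAM
# reconstruction, standard-state binding free energy from the PMF depth,
# block-bootstrap error bands.

#' Umbrella window
#'
#' A biased simulation window: harmonic bias centre and force constant plus
#' the time-ordered reaction-coordinate samples recorded under the bias.
#' The reaction coordinate is the ligand-pocket centre-of-mass distance in
#' the intended use, but the module is coordinate-agnostic.
#'
#' @param center Bias centre z_i (A).
#' @param k Force constant k_i (kcal/mol/A^2, > 0).
#' @param z Numeric vector of reaction-coordinate samples (A, time order).
#' @param equil_fraction Fraction of the series discarded from the front
#'   as equilibration (default 0; the analysis convention for long MD
#'   series is 0.4).
#' @return An object of class `umbrella_window` (the retained samples are
#'   in `$z`; the discarded count is recorded).
#' @export
umbrella_window <- function(center, k, z, equil_fraction = 0) {
  if (!is.numeric(k) || k <= 0) stop("umbrella_window: force constant must be positive")
  if (equil_fraction < 0 || equil_fraction >= 1) stop("umbrella_window: equil_fraction in [0, 1)")
  if (any(!is.finite(z))) stop("umbrella_window: samples must be finite")
  n_drop <- floor(length(z) * equil_fraction)
  z_keep <- if (n_drop > 0) z[-seq_len(n_drop)] else z
  if (length(z_keep) < 1L) stop("umbrella_window: no samples retained")
  structure(list(center = as.numeric(center), k = as.numeric(k),
                 z = as.numeric(z_keep), n_discarded = n_drop,
                 equil_fraction = equil_fraction),
            class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf("<umbrella_window> center %.3f A, k %.2f kcal/mol/A^2, %d samples (%d discarded)\n",
              x$center, x$k, length(x$z), x$n_discarded))
  invisible(x)
}

#' Harmonic bias energy of a window
#'
#' @param z Reaction-coordinate value(s), A.
#' @param window An [umbrella_window()] (or a list with `center`, `k`).
#' @return `0.5 * k * (z - center)^2` in kcal/mol (vectorised).
#' @export
bias_energy <- function(z, window) {
  if (any(!is.finite(z))) stop("bias_energy: z must be finite")
  0.5 * window$k * (z - window$center)^2
}

#' Default histogram grid over a set of windows
#'
#' 200 uniform bins spanning the min/max of all samples, padded by one bin
#' width on each side; binning is half-open `[lo, hi)`.
#'
#' @param windows List of [umbrella_window()]s.
#' @param n_bins Number of bins.
#' @return List with `breaks` (length n_bins + 1) and `mids`.
#' @export
pmf_grid <- function(windows, n_bins = 200L) {
  zr <- range(unlist(lapply(windows, `[[`, "z")))
  w <- diff(zr) / n_bins
  if (w <= 0) w <- 1e-3
  breaks <- seq(zr[1] - w, zr[2] + w, length.out = n_bins + 1L)
  list(breaks = breaks, mids = (breaks[-1] + breaks[-length(breaks)]) / 2)
}

bin_counts <- function(z, breaks) {
  # half-open [lo, hi) bins
  idx <- findInterval(z, breaks, rightmost.closed = FALSE, left.open = FALSE)
  idx[idx < 1L | idx > length(breaks) - 1L] <- NA_integer_
  tabulate(idx, nbins = length(breaks) - 1L)
}

#' Unbias a single umbrella window onto a grid
#'
#' Histogram estimate of the biased free energy `A'(s) = -kT ln p_biased`,
#' minus the bias `w(s)`, minus the window free-energy constant
#' `-kT ln <exp(-w/kT)>` (the log-average of the Boltzmann-weighted bias,
#' taken over the window's samples). Empty bins are returned as `NA`
#' (masked), never zero-filled. The fragment is defined up to an additive
#' constant.
#'
#' @param window An [umbrella_window()] with >= 50 retained samples.
#' @param grid A grid from [pmf_grid()] (or list with `breaks`, `mids`).
#' @param ctx A [thermo_context()].
#' @return List of class `pmf_fragment`: `z` (bin mids), `A` (kcal/mol,
#'   NA where unsampled), `counts`.
#' @export
unbias_window <- function(window, grid, ctx) {
  assert_ctx(ctx)
  if (length(window$z) < 50L) stop("unbias_window: need >= 50 retained samples")
  kT <- thermal_energy(ctx)
  counts <- bin_counts(window$z, grid$breaks)
  if (all(counts == 0L)) {
    stop(sprintf("unbias_window: window at center %.3f has no samples on the grid", window$center))
  }
  p <- counts / sum(counts)
  A_biased <- ifelse(counts > 0L, -kT * log(p), NA_real_)
  w <- bias_energy(grid$mids, window)
  f_win <- -kT * log(mean(exp(-bias_energy(window$z, window) / kT)))
  A <- A_biased - w - f_win
  structure(list(z = grid$mids, A = A, counts = counts), class = "pmf_fragment")
}

#' Reconstruct a PMF from umbrella windows by WHAM
#'
#' Standard weighted-histogram self-consistency: the unbiased bin
#' probability combines every window's histogram,
#' `p(s) = sum_i n_i(s) / sum_i N_i exp[(f_i - w_i(s)) / kT]`, and the
#' window constants are updated as
#' `f_i = -kT ln sum_s p(s) exp(-w_i(s)/kT)`, iterated until the largest
#' change in any f_i is below `tol` (in kcal/mol, default 1e-7 kT).
#' The profile `W(z) = -kT ln p(z)` is normalized so its minimum is 0.
#'
#' @param windows List of >= 1 [umbrella_window()]s (a warning is issued if
#'   adjacent windows share no occupied bin).
#' @param ctx A [thermo_context()].
#' @param grid Optional grid from [pmf_grid()]; default 200 bins over all
#'   samples.
#' @param n_bins Bin count when `grid` is NULL.
#' @param tol Convergence tolerance on window constants (kcal/mol); the
#'   default is 1e-7 * kT.
#' @param max_iter Iteration cap.
#' @return An object of class `pmf_profile`: `z`, `W` (kcal/mol, min 0, NA
#'   on unsampled bins), `counts` (total samples per bin, for masking
#'   statistically empty tails), `f_windows` (window constants in
#'   centre-sorted order), `converged`, `iterations`, `residual`.
#' @export
wham_pmf <- function(windows, ctx, grid = NULL, n_bins = 200L,
                     tol = NULL, max_iter = 100000L) {
  assert_ctx(ctx)
  if (!length(windows)) stop("wham_pmf: no windows supplied")
  kT <- thermal_energy(ctx)
  if (is.null(tol)) tol <- 1e-7 * kT
  if (is.null(grid)) grid <- pmf_grid(windows, n_bins)
  mids <- grid$mids
  # canonical window order: the reconstruction is then bit-identical under
  # any permutation of the input list
  windows <- windows[order(vapply(windows, `[[`, numeric(1), "center"),
                           vapply(windows, `[[`, numeric(1), "k"))]
  n_win <- length(windows)
  H <- vapply(windows, function(w) bin_counts(w$z, grid$breaks), integer(length(mids)))
  H <- matrix(H, nrow = length(mids))          # bins x windows
  N_i <- colSums(H)
  if (any(N_i == 0)) {
    bad <- which(N_i == 0)
    stop(sprintf("wham_pmf: window(s) %s have no samples on the grid",
                 paste(bad, collapse = ", ")))
  }
  # order windows by centre for the overlap diagnostic
  ord <- order(vapply(windows, `[[`, numeric(1), "center"))
  if (n_win > 1L) {
    occ <- H[, ord, drop = FALSE] > 0
    for (i in seq_len(n_win - 1L)) {
      if (!any(occ[, i] & occ[, i + 1L])) {
        warning(sprintf("wham_pmf: windows centred %.3f and %.3f share no occupied bin",
                        windows[[ord[i]]]$center, windows[[ord[i + 1L]]]$center))
      }
    }
  }
  n_s <- rowSums(H)
  W_bias <- vapply(windows, function(w) bias_energy(mids, w), numeric(length(mids)))
  W_bias <- matrix(W_bias, nrow = length(mids))  # bins x windows
  expw <- exp(-W_bias / kT)
  f <- numeric(n_win)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- as.numeric(expw %*% (N_i * exp(f / kT)))
    p <- ifelse(denom > 0, n_s / denom, 0)
    zmass <- colSums(p * expw)
    f_new <- -kT * log(zmass)
    f_new <- f_new - f_new[1]
    resid <- max(abs(f_new - f))
    f <- f_new
    if (resid < tol) break
    if (iter >= max_iter) {
      stop(sprintf("wham_pmf: not converged after %d iterations (residual %.3g kcal/mol)",
                   iter, resid))
    }
  }
  denom <- as.numeric(expw %*% (N_i * exp(f / kT)))
  p <- ifelse(denom > 0 & n_s > 0, n_s / denom, NA_real_)
  W <- -kT * log(p)
  W <- W - min(W, na.rm = TRUE)
  structure(list(z = mids, W = W, counts = n_s, f_windows = f, converged = TRUE,
                 iterations = iter, residual = resid, breaks = grid$breaks),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  rng <- range(x$W, na.rm = TRUE)
  cat(sprintf("<pmf_profile> %d bins over [%.3f, %.3f] A, range %.3f kcal/mol, %d WHAM iterations\n",
              length(x$z), min(x$z), max(x$z), diff(rng), x$iterations))
  invisible(x)
}

#' Standard-state binding free energy from a PMF
#'
#' Integrates the Boltzmann factor of the PMF over the bound region,
#' converts the bound 1D partition function to a volume with an effective
#' lateral cross-section, and references it to the 1 M standard state:
#' `dG_bind = -kT ln[ (cross_section / V0) * int_bound exp(-(W - W_unbound)/kT) dz ]`,
#' with `W_unbound` the mean of the flat plateau at the unbound (large-z)
#' end of the profile. Negative values are favourable.
#'
#' @param profile A [pmf_profile()].
#' @param ctx A [thermo_context()].
#' @param bound_region Length-2 numeric z-interval (A). Default: from the
#'   grid start to the first point past the global minimum where W rises
#'   2 kT above it.
#' @param cross_section Effective lateral area (A^2). Either give it
#'   directly, or give `k_lat` (kcal/mol/A^2) from the lateral restraints
#'   to use `2 pi kT / k_lat`; when neither is given, 1 A^2 is used with a
#'   warning.
#' @param k_lat Lateral restraint force constant (see `cross_section`).
#' @param plateau_fraction Trailing fraction of the grid used for the
#'   unbound plateau (default 0.15).
#' @param flat_slope_warn Warn when the plateau |slope| exceeds this many
#'   kT/A (default 0.5).
#' @return A [free_energy_estimate()] (method "WHAM"); the breakdown holds
#'   `W_unbound`, the bound integral and the region used.
#' @export
pmf_binding_dG <- function(profile, ctx, bound_region = NULL,
                           cross_section = NULL, k_lat = NULL,
                           plateau_fraction = 0.15, flat_slope_warn = 0.5) {
  assert_ctx(ctx)
  kT <- thermal_energy(ctx)
  z <- profile$z; W <- profile$W
  ok <- is.finite(W)
  if (is.null(cross_section)) {
    if (!is.null(k_lat)) {
      cross_section <- 2 * pi * kT / k_lat
    } else {
      warning("pmf_binding_dG: no cross_section or k_lat given; using 1 A^2")
      cross_section <- 1
    }
  }
  i_min <- which.min(ifelse(ok, W, Inf))
  if (is.null(bound_region)) {
    after <- which(ok & seq_along(z) > i_min & W > W[i_min] + 2 * kT)
    hi <- if (length(after)) z[min(after)] else z[max(which(ok))]
    bound_region <- c(z[min(which(ok))], hi)
  }
  if (bound_region[2] > max(z) + 1e-9 || bound_region[1] < min(z) - 1e-9) {
    stop("pmf_binding_dG: bound region must lie within the grid span")
  }
  in_bound <- ok & z >= bound_region[1] & z <= bound_region[2]
  if (!any(in_bound)) stop("pmf_binding_dG: bound region contains no sampled grid points")
  if (!(z[i_min] >= bound_region[1] && z[i_min] <= bound_region[2])) {
    stop("pmf_binding_dG: bound region excludes the global PMF minimum")
  }
  # plateau at the unbound (high-z) end
  n_tail <- max(2L, ceiling(sum(ok) * plateau_fraction))
  tail_idx <- utils::tail(which(ok), n_tail)
  W_unb <- mean(W[tail_idx])
  slope <- stats::coef(stats::lm(W[tail_idx] ~ z[tail_idx]))[2] / kT
  if (is.finite(slope) && abs(slope) > flat_slope_warn) {
    warning(sprintf("pmf_binding_dG: unbound end not flat (|slope| = %.2f kT/A)", abs(slope)))
  }
  zi <- z[in_bound]
  fi <- exp(-(W[in_bound] - W_unb) / kT)
  integral <- sum(diff(zi) * (fi[-1] + fi[-length(fi)]) / 2)  # trapezoid, A
  value <- -kT * log(cross_section * integral / ctx$standard_volume)
  free_energy_estimate(value, NA_real_, method = "WHAM",
                       breakdown = list(W_unbound = W_unb,
                                        bound_integral_A = integral,
                                        cross_section_A2 = cross_section,
                                        bound_region = bound_region))
}

#' Block-bootstrap error band for a WHAM PMF
#'
#' Resamples each window's time series in contiguous blocks, re-runs WHAM
#' per resample, and returns the pointwise standard deviation of the
#' profile plus the standard deviation of the standard-state binding free
#' energy. Each resampled profile is min-normalized exactly as the point
#' estimate is, so the band measures spread about the normalized profile.
#'
#' @param windows List of [umbrella_window()]s.
#' @param ctx A [thermo_context()].
#' @param grid Optional fixed grid (defaults to [pmf_grid()] of the full
#'   data so all resamples share bins).
#' @param n_blocks Contiguous blocks per window (default 5).
#' @param n_boot Number of bootstrap replicas (0 returns empty bands).
#' @param seed RNG seed; the run is deterministic given it.
#' @param ... Passed to [pmf_binding_dG()] (bound_region, cross_section,
#'   k_lat).
#' @return List of class `pmf_band`: `z`, `W_sd` (pointwise SD), `dG_sd`,
#'   `n_failed` (resamples where WHAM failed; more than 10% is an error).
#' @export
pmf_bootstrap_band <- function(windows, ctx, grid = NULL, n_blocks = 5L,
                               n_boot = 100L, seed = 1L, ...) {
  assert_ctx(ctx)
  if (is.null(grid)) grid <- pmf_grid(windows)
  if (n_boot == 0L) {
    return(structure(list(z = grid$mids, W_sd = numeric(0), dG_sd = NA_real_,
                          n_failed = 0L), class = "pmf_band"))
  }
  for (w in windows) {
    if (length(w$z) < n_blocks) stop("pmf_bootstrap_band: window too short to split into blocks")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  profiles <- matrix(NA_real_, nrow = length(grid$mids), ncol = n_boot)
  dGs <- rep(NA_real_, n_boot)
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    res_windows <- lapply(windows, function(w) {
      n <- length(w$z)
      bounds <- floor(seq(0, n, length.out = n_blocks + 1L))
      pick <- sample.int(n_blocks, n_blocks, replace = TRUE)
      idx <- unlist(lapply(pick, function(p) (bounds[p] + 1L):bounds[p + 1L]))
      umbrella_window(w$center, w$k, w$z[idx])
    })
    prof <- tryCatch(suppressWarnings(wham_pmf(res_windows, ctx, grid = grid)),
                     error = function(e) NULL)
    if (is.null(prof)) { n_failed <- n_failed + 1L; next }
    dG <- tryCatch(suppressWarnings(pmf_binding_dG(prof, ctx, ...))$value,
                   error = function(e) NA_real_)
    profiles[, b] <- prof$W
    dGs[b] <- dG
  }
  if (n_failed > 0.1 * n_boot) {
    stop(sprintf("pmf_bootstrap_band: %d/%d resamples failed WHAM", n_failed, n_boot))
  }
  structure(list(z = grid$mids,
                 W_sd = apply(profiles, 1, stats::sd, na.rm = TRUE),
                 dG_sd = stats::sd(dGs, na.rm = TRUE),
                 n_failed = n_failed),
            class = "pmf_band")
}
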