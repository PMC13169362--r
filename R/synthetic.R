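# Synthetic-data generators with analytic ground truth: biased umbrella
# samples over known 1D potentials, harmonic-oscillator lambda ladders,
# Gaussian work distributions, toy charged complexes, perturbed snapshot
# ensembles, and a full synthetic affinity study. Every generator takes an
# explicit seed and stamps it (with its parameters) into the ground truth.

ground_truth <- function(generator, seed, ...) {
  structure(list(generator = generator, seed = seed, ...),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s (seed %d)\n", x$generator, x$seed))
  invisible(x)
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  expr
}

#' Built-in 1D test potentials
#'
#' Returns `U(z)` in kcal/mol for the named potential:
#' \describe{
#'   \item{flat}{0 everywhere.}
#'   \item{harmonic}{`0.5 * kappa * z^2` (`pars$kappa`).}
#'   \item{double_well}{`h * (z^2 - 1)^2` (`pars$h`), wells at z = -1, +1.}
#'   \item{square_well}{`-depth` inside `[lo, hi]`, 0 outside
#'     (`pars$depth`, `pars$lo`, `pars$hi`).}
#'   \item{tabulated}{linear interpolation of `pars$z`, `pars$U`.}
#' }
#'
#' @param name Potential name.
#' @param pars Named list of parameters.
#' @return Function `U(z)` (vectorised).
#' @export
potential_1d <- function(name = c("flat", "harmonic", "double_well",
                                  "square_well", "tabulated"),
                         pars = list()) {
  name <- match.arg(name)
  switch(name,
    flat = function(z) rep(0, length(z)),
    harmonic = {
      kappa <- pars$kappa %||% 1
      function(z) 0.5 * kappa * z^2
    },
    double_well = {
      hgt <- pars$h %||% 2
      function(z) hgt * (z^2 - 1)^2
    },
    square_well = {
      depth <- pars$depth %||% 3; lo <- pars$lo %||% -1; hi <- pars$hi %||% 1
      function(z) ifelse(z >= lo & z <= hi, -depth, 0)
    },
    tabulated = {
      zt <- pars$z; Ut <- pars$U
      function(z) stats::approx(zt, Ut, xout = z, rule = 2)$y
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Inverse-CDF sampler on a dense grid for a 1D density prop. to exp(-E/kT).
sample_boltzmann_1d <- function(energy_fun, z_lo, z_hi, n, kT, n_grid = 1e4) {
  zg <- seq(z_lo, z_hi, length.out = n_grid)
  E <- energy_fun(zg)
  w <- exp(-(E - min(E)) / kT)
  edge_mass <- max(w[1], w[length(w)]) / max(w)
  if (edge_mass > 1e-3) {
    stop("sample_boltzmann_1d: density not confined on the grid (bias too weak or grid too small)")
  }
  cdf <- cumsum(w); cdf <- cdf / cdf[length(cdf)]
  u <- stats::runif(n)
  # invert by interpolation on the strictly increasing part of the CDF
  keep <- c(TRUE, diff(cdf) > 0)
  stats::approx(cdf[keep], zg[keep], xout = u, rule = 2)$y
}

#' Sample umbrella windows over a known 1D potential
#'
#' Draws i.i.d. samples from each window's biased Boltzmann density
#' `p_i(z) prop. exp(-[U(z) + 0.5 k_i (z - z_i)^2] / kT)` by inverse-CDF
#' inversion on a dense grid (default 10^4 points), giving exact (to grid
#' resolution) equilibrium samples with no burn-in ambiguity.
#'
#' @param potential Function `U(z)` (kcal/mol), e.g. from
#'   [potential_1d()].
#' @param centers Window centres z_i (A).
#' @param k Force constant(s), kcal/mol/A^2 (recycled).
#' @param n_per_window Samples per window.
#' @param ctx A [thermo_context()].
#' @param seed RNG seed.
#' @param span Sampling support padding beyond the window centres
#'   (default 6 thermal widths of the stiffest bias).
#' @return List with `windows` (list of [umbrella_window()]) and
#'   `truth` (a `ground_truth` carrying the potential and parameters).
#' @export
sample_umbrella_windows <- function(potential, centers, k, n_per_window,
                                    ctx, seed = 1L, span = NULL) {
  assert_ctx(ctx)
  kT <- thermal_energy(ctx)
  k <- rep_len(k, length(centers))
  if (is.null(span)) span <- 6 * sqrt(kT / min(k))
  windows <- with_seed(seed, {
    lapply(seq_along(centers), function(i) {
      biased <- function(z) potential(z) + 0.5 * k[i] * (z - centers[i])^2
      z <- sample_boltzmann_1d(biased, centers[i] - span, centers[i] + span,
                               n_per_window, kT)
      umbrella_window(centers[i], k[i], z)
    })
  })
  list(windows = windows,
       truth = ground_truth("sample_umbrella_windows", seed,
                            potential = potential, centers = centers, k = k,
                            n_per_window = n_per_window,
                            temperature = ctx$temperature))
}

#' Harmonic-oscillator lambda ladder with analytic free energies
#'
#' Each state k is a 1D harmonic oscillator with reduced potential
#' `u_k(x) = 0.5 K_k x^2`; samples are drawn from each state's Gaussian
#' (sd `1/sqrt(K_k)`) and evaluated under every state's Hamiltonian. The
#' analytic reduced free energies are `f_k = 0.5 ln(K_k / 2 pi)` up to the
#' gauge constant, so consecutive `Delta f = 0.5 ln(K_{k+1}/K_k)`.
#'
#' @param K Spring constants (reduced units), all positive.
#' @param n_per_state Samples per state.
#' @param seed RNG seed.
#' @return List with `matrix` (a [reduced_potential_matrix()]) and `truth`
#'   (`f` = analytic reduced free energies, gauge f\[1\] = 0).
#' @export
harmonic_ladder_ensemble <- function(K, n_per_state, seed = 1L) {
  if (any(K <= 0)) stop("harmonic_ladder_ensemble: spring constants must be positive")
  nK <- length(K)
  x <- with_seed(seed, {
    unlist(lapply(K, function(kk) stats::rnorm(n_per_state, sd = 1 / sqrt(kk))))
  })
  u <- 0.5 * outer(K, x^2)
  M <- reduced_potential_matrix(u, rep(n_per_state, nK))
  f <- 0.5 * log(K / (2 * pi))
  list(matrix = M,
       truth = ground_truth("harmonic_ladder_ensemble", seed, K = K,
                            n_per_state = n_per_state, f = f - f[1]))
}

#' Gaussian work samples with a closed-form EXP limit
#'
#' i.i.d. Normal(m, s^2) reduced work samples; for a Gaussian work
#' distribution the exponential-averaging identity gives
#' `beta dG = m - s^2 / 2` exactly.
#'
#' @param m,s Mean and SD of the reduced work.
#' @param n Number of samples (>= 1).
#' @param seed RNG seed.
#' @return List with `delta_u` (samples) and `truth` (`beta_dG`).
#' @export
gaussian_work_samples <- function(m, s, n, seed = 1L) {
  if (s < 0) stop("gaussian_work_samples: s must be >= 0")
  if (n < 1) stop("gaussian_work_samples: n must be >= 1")
  delta_u <- with_seed(seed, stats::rnorm(n, mean = m, sd = s))
  list(delta_u = delta_u,
       truth = ground_truth("gaussian_work_samples", seed, m = m, s = s,
                            n = n, beta_dG = m - s^2 / 2))
}

#' Build a deterministic toy protein-ligand complex
#'
#' A desk-scale binding "pocket": a ring of pseudo-residues (backbone N,
#' CA, C, O plus a CB side-chain atom each) arranged on a shell around a
#' small ligand cluster at the origin. Charges, radii, LJ parameters and
#' masses are assigned deterministically from the seed. Side-chain
#' distances to the nearest ligand atom can be scripted per residue for
#' contact tests.
#'
#' @param n_residues Protein pseudo-residues (ring positions).
#' @param n_ligand_atoms Ligand heavy atoms (clustered near the origin).
#' @param shell_radius Distance of the residue ring from the origin, A.
#' @param charge_scale SD of the assigned partial charges, e (0 = neutral).
#' @param scripted_distances Optional numeric vector (length
#'   `n_residues`): the CB side-chain atom of residue i is placed exactly
#'   this far (A) from the nearest ligand atom.
#' @param seed RNG seed (assignment noise only; geometry is deterministic).
#' @return List with `solute` (a [toy_solute()]; ligand chain "L", protein
#'   chain "A"), `truth`.
#' @export
build_toy_complex <- function(n_residues = 6, n_ligand_atoms = 5,
                              shell_radius = 6, charge_scale = 0.2,
                              scripted_distances = NULL, seed = 1L) {
  n_atoms_total <- n_residues * 5 + n_ligand_atoms
  if (n_atoms_total > 500) stop("build_toy_complex: > 500 atoms is beyond desk scale")
  rows <- with_seed(seed, {
    lig_xyz <- matrix(stats::rnorm(n_ligand_atoms * 3, sd = 0.8), ncol = 3)
    lig_xyz <- sweep(lig_xyz, 2, colMeans(lig_xyz))
    lig <- data.frame(
      x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3],
      charge = if (charge_scale > 0) stats::rnorm(n_ligand_atoms, sd = charge_scale) else 0,
      radius = 1.7, mass = 12.011, eps = 0.1, sigma = 3.4,
      name = paste0("C", seq_len(n_ligand_atoms)), element = "C",
      resname = "LIG", resno = 1L, chain = "L", role = "ligand")
    prot <- vector("list", n_residues)
    for (r in seq_len(n_residues)) {
      ang <- 2 * pi * (r - 1) / n_residues
      base <- shell_radius * c(cos(ang), sin(ang), 0)
      # backbone N, CA, C, O around the base point; CB toward the ligand
      off <- rbind(N = c(-0.8, 0, 0.9), CA = c(0, 0, 0.5), C = c(0.8, 0, 0.9),
                   O = c(1.2, 0, 1.9))
      dir_in <- -base / sqrt(sum(base^2))
      cb <- base + 1.5 * dir_in
      if (!is.null(scripted_distances)) {
        # place CB exactly scripted_distances[r] from the nearest ligand atom
        d_lig <- sqrt(rowSums(sweep(lig_xyz, 2, base, "-")^2))
        nearest <- lig_xyz[which.min(d_lig), ]
        u_dir <- (base - nearest); u_dir <- u_dir / sqrt(sum(u_dir^2))
        cb <- nearest + scripted_distances[r] * u_dir
      }
      xyz_r <- rbind(sweep(off, 2, base, "+"), CB = cb)
      prot[[r]] <- data.frame(
        x = xyz_r[, 1], y = xyz_r[, 2], z = xyz_r[, 3],
        charge = if (charge_scale > 0) stats::rnorm(5, sd = charge_scale) else 0,
        radius = c(1.55, 1.7, 1.7, 1.52, 1.7),
        mass = c(14.007, 12.011, 12.011, 15.999, 12.011),
        eps = c(0.17, 0.1, 0.1, 0.21, 0.1), sigma = c(3.25, 3.4, 3.4, 3.0, 3.4),
        name = c("N", "CA", "C", "O", "CB"), element = c("N", "C", "C", "O", "C"),
        resname = "ALA", resno = r, chain = "A",
        role = c(rep("backbone", 4), "sidechain"))
    }
    rbind(lig, do.call(rbind, prot))
  })
  rownames(rows) <- NULL
  solute <- toy_solute(rows)
  xyz <- solute_xyz(solute)
  dmin <- min(stats::dist(xyz))
  if (dmin < 0.5) {
    stop(sprintf("build_toy_complex: overlapping atoms (min distance %.2f A); try another seed", dmin))
  }
  list(solute = solute,
       truth = ground_truth("build_toy_complex", seed,
                            n_residues = n_residues,
                            n_ligand_atoms = n_ligand_atoms,
                            shell_radius = shell_radius,
                            scripted_distances = scripted_distances))
}

#' Perturb a solute into a Gaussian snapshot ensemble
#'
#' Frames are the base coordinates plus isotropic Gaussian positional
#' noise of the given SD per atom per axis, so the per-atom coordinate
#' covariance is `sd^2 I` by construction -- the analytic ground truth
#' driving the quasi-harmonic entropy checks.
#'
#' @param solute A [toy_solute()].
#' @param sd Positional noise SD, A (>= 0; scalar or per-atom).
#' @param n_frames Number of frames.
#' @param seed RNG seed.
#' @param origin Origin tag for the ensemble.
#' @return List with `ensemble` (a [snapshot_ensemble()]) and `truth`.
#' @export
perturb_ensemble <- function(solute, sd, n_frames, seed = 1L, origin = "complex") {
  if (any(sd < 0)) stop("perturb_ensemble: sd must be >= 0")
  n <- nrow(solute)
  sd_atom <- rep_len(sd, n)
  base <- solute_xyz(solute)
  xyz <- with_seed(seed, {
    noise <- array(stats::rnorm(n * 3 * n_frames, sd = sd_atom), dim = c(n, 3, n_frames))
    array(base, dim = c(n, 3, n_frames)) + noise
  })
  list(ensemble = snapshot_ensemble(solute, xyz, origin = origin),
       truth = ground_truth("perturb_ensemble", seed, sd = sd,
                            n_frames = n_frames, covariance = "sd^2 * I"))
}

#' Synthetic paralogue affinity study with known selectivity
#'
#' Emulates the cross-method selectivity comparison: a panel of ligands
#' with known true per-target binding free energies, an exact
#' experimental IC50 table consistent with them (inverse of the
#' `dG = RT ln IC50` conversion), and per-method computed affinities
#' `dG_true + Normal(0, sd_method)` for each named method. Feeds
#' [method_comparison_table()] end to end.
#'
#' @param true_ddG Numeric vector of true selectivities
#'   `dG(target1) - dG(target2)` per ligand, kcal/mol.
#' @param method_sd Named numeric vector of per-method noise SDs
#'   (kcal/mol), e.g. `c(MMPBSA = 2, ABFE = 0.5)`.
#' @param ic50_target1 Base IC50 values for target1, molar (recycled;
#'   default 3e-9, a typical potent inhibitor).
#' @param ctx A [thermo_context()].
#' @param seed RNG seed.
#' @param ligands Ligand names (default "lig1"...).
#' @param target1,target2 Target names.
#' @return List with `ic50` (records for both targets), `affinities`
#'   (experimental + per-method [affinity_record()]s), `truth` (`ddG`,
#'   per-target `dG`).
#' @export
synthetic_affinity_study <- function(true_ddG, method_sd, ctx,
                                     ic50_target1 = 3e-9, seed = 1L,
                                     ligands = NULL,
                                     target1 = "PARP1", target2 = "PARP2") {
  assert_ctx(ctx)
  if (any(method_sd < 0)) stop("synthetic_affinity_study: noise SDs must be >= 0")
  nl <- length(true_ddG)
  if (is.null(ligands)) ligands <- paste0("lig", seq_len(nl))
  RT <- thermal_energy(ctx)
  ic50_1 <- rep_len(ic50_target1, nl)
  dG1 <- RT * log(ic50_1)
  dG2 <- dG1 - true_ddG
  ic50_2 <- exp(dG2 / RT)
  ic50 <- rbind(
    data.frame(ligand = ligands, target = target1, ic50 = ic50_1, sigma = NA_real_,
               note = "synthetic", stringsAsFactors = FALSE),
    data.frame(ligand = ligands, target = target2, ic50 = ic50_2, sigma = NA_real_,
               note = "synthetic", stringsAsFactors = FALSE))
  aff <- ic50_to_dG(ic50, ctx)
  method_aff <- with_seed(seed, {
    out <- list()
    for (m in names(method_sd)) {
      noise1 <- stats::rnorm(nl, sd = method_sd[[m]])
      noise2 <- stats::rnorm(nl, sd = method_sd[[m]])
      out[[m]] <- rbind(
        affinity_record(ligands, target1, dG1 + noise1, method_sd[[m]], m),
        affinity_record(ligands, target2, dG2 + noise2, method_sd[[m]], m))
    }
    do.call(rbind, out)
  })
  affinities <- rbind(aff, method_aff)
  rownames(affinities) <- NULL
  list(ic50 = ic50, affinities = affinities,
       truth = ground_truth("synthetic_affinity_study", seed,
                            ddG = stats::setNames(true_ddG, ligands),
                            dG_target1 = dG1, dG_target2 = dG2,
                            method_sd = method_sd))
}

#' The experimental IC50 panel of eight PARP inhibitors
#'
#' The clinical and preclinical inhibitor panel with literature IC50
#' values (nM) against PARP1 and PARP2, as a tidy molar table ready for
#' [ic50_to_dG()].
#'
#' @return A data.frame with columns `ligand`, `target`, `ic50` (molar).
#' @export
parp_ic50_table <- function() {
  lig <- c("saruparib", "NMS-P118", "veliparib", "olaparib",
           "rucaparib", "niraparib", "talazoparib", "pamiparib")
  parp1_nM <- c(3, 9, 8.3, 1.1, 3.2, 3.8, 2.59, 1.3)
  parp2_nM <- c(1400, 1390, 11, 0.9, 28.2, 2.1, 0.89, 0.9)
  rbind(
    data.frame(ligand = lig, target = "PARP1", ic50 = parp1_nM * 1e-9),
    data.frame(ligand = lig, target = "PARP2", ic50 = parp2_nM * 1e-9))
}
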