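# End-point MM/PB(GB)SA: molecular-mechanics interaction energies,
# finite-difference linearized Poisson-Boltzmann polar solvation, OBC-II
# generalized Born, Shrake-Rupley SASA, quasi-harmonic entropy and the
# frame-averaged decomposition.

# ---- molecular mechanics -------------------------------------------------

#' Protein-ligand molecular-mechanics interaction energy
#'
#' Pairwise Coulomb and Lennard-Jones energies between two disjoint atom
#' selections of one frame, with no cutoff and no periodicity (desk-scale
#' toy solutes). LJ parameters combine by Lorentz-Berthelot rules:
#' `sigma_ij = (sigma_i + sigma_j)/2`, `eps_ij = sqrt(eps_i eps_j)`.
#'
#' @param solute A [toy_solute()] providing charges and LJ parameters.
#' @param coords Optional `n x 3` coordinate matrix for the frame
#'   (defaults to the topology coordinates).
#' @param protein_idx,ligand_idx Disjoint integer (or logical) atom
#'   selections.
#' @param ctx A [thermo_context()] (supplies the Coulomb constant).
#' @return Named numeric vector `c(elec = ..., vdw = ...)` in kcal/mol.
#' @export
mm_interaction_energy <- function(solute, protein_idx, ligand_idx,
                                  ctx, coords = NULL) {
  assert_ctx(ctx)
  if (is.null(coords)) coords <- solute_xyz(solute)
  protein_idx <- to_index(protein_idx, nrow(solute))
  ligand_idx <- to_index(ligand_idx, nrow(solute))
  if (length(intersect(protein_idx, ligand_idx))) {
    stop("mm_interaction_energy: selections must be disjoint")
  }
  if (!length(protein_idx) || !length(ligand_idx)) {
    stop("mm_interaction_energy: empty selection")
  }
  P <- coords[protein_idx, , drop = FALSE]
  L <- coords[ligand_idx, , drop = FALSE]
  d2 <- outer(rowSums(P^2), rowSums(L^2), "+") - 2 * P %*% t(L)
  d2[d2 < 0] <- 0
  r <- sqrt(d2)
  if (any(r < 0.1)) stop("mm_interaction_energy: overlapping atoms (r < 0.1 A)")
  qq <- outer(solute$charge[protein_idx], solute$charge[ligand_idx])
  elec <- ctx$coulomb_constant * sum(qq / r)
  eps_ij <- sqrt(outer(solute$eps[protein_idx], solute$eps[ligand_idx]))
  sig_ij <- outer(solute$sigma[protein_idx], solute$sigma[ligand_idx], "+") / 2
  sr6 <- (sig_ij / r)^6
  vdw <- sum(4 * eps_ij * (sr6^2 - sr6))
  c(elec = elec, vdw = vdw)
}

to_index <- function(idx, n) {
  if (is.logical(idx)) idx <- which(idx)
  idx <- as.integer(idx)
  if (any(idx < 1L | idx > n)) stop("atom index out of range")
  idx
}

# ---- finite-difference linearized Poisson-Boltzmann ----------------------

# Debye screening kappa^2 in 1/A^2 for a 1:1 electrolyte of ionic strength
# I (mol/L) in a solvent of dielectric eps_out.
debye_kappa2 <- function(ionic_strength, eps_out, ctx) {
  n_dens <- ionic_strength * 6.02214076e-4   # ions/A^3 per mol/L
  8 * pi * ctx$coulomb_constant * n_dens / (thermal_energy(ctx) * eps_out)
}

# Conjugate gradient with Jacobi preconditioning for the 7-point stencil
# system; operands are 3D arrays over interior nodes.
pb_cg <- function(apply_A, diag_A, b, tol = 1e-6, max_iter = 5000L) {
  x <- array(0, dim = dim(b))
  r <- b
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = x, iterations = 0L, residual = 0))
  z <- r / diag_A
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(max_iter)) {
    Ap <- apply_A(p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    res <- sqrt(sum(r^2)) / bnorm
    if (res < tol) return(list(x = x, iterations = it, residual = res))
    z <- r / diag_A
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop(sprintf("pb solver: CG not converged after %d iterations (residual %.3g)",
               max_iter, res))
}

# Trilinear spreading of point charges to grid nodes. Returns the node
# charge array (e); conserves total charge exactly for interior atoms.
spread_charges <- function(xyz, q, origin, h, dims) {
  Q <- array(0, dim = dims)
  fx <- (xyz[, 1] - origin[1]) / h
  fy <- (xyz[, 2] - origin[2]) / h
  fz <- (xyz[, 3] - origin[3]) / h
  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  wx <- fx - i0; wy <- fy - j0; wz <- fz - k0
  if (any(i0 < 1 | i0 > dims[1] - 2 | j0 < 1 | j0 > dims[2] - 2 |
          k0 < 1 | k0 > dims[3] - 2)) {
    stop("pb solver: atom too close to the grid boundary; increase padding")
  }
  for (a in seq_along(q)) {
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      w <- (if (di) wx[a] else 1 - wx[a]) *
           (if (dj) wy[a] else 1 - wy[a]) *
           (if (dk) wz[a] else 1 - wz[a])
      ii <- i0[a] + di + 1L; jj <- j0[a] + dj + 1L; kk <- k0[a] + dk + 1L
      Q[ii, jj, kk] <- Q[ii, jj, kk] + w * q[a]
    }
  }
  Q
}

# Trilinear interpolation of a grid field at atom positions.
interp_field <- function(F, xyz, origin, h) {
  fx <- (xyz[, 1] - origin[1]) / h
  fy <- (xyz[, 2] - origin[2]) / h
  fz <- (xyz[, 3] - origin[3]) / h
  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  wx <- fx - i0; wy <- fy - j0; wz <- fz - k0
  out <- numeric(nrow(xyz))
  for (a in seq_len(nrow(xyz))) {
    v <- 0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      w <- (if (di) wx[a] else 1 - wx[a]) *
           (if (dj) wy[a] else 1 - wy[a]) *
           (if (dk) wz[a] else 1 - wz[a])
      v <- v + w * F[i0[a] + di + 1L, j0[a] + dj + 1L, k0[a] + dk + 1L]
    }
    out[a] <- v
  }
  out
}

# One linearized-PB (or uniform-dielectric reference) solve. Returns the
# potential at the atom positions, kcal/(mol e).
pb_solve_one <- function(xyz, q, radius, origin, h, dims, eps_in, eps_out,
                         kappa2, ctx, uniform = FALSE, cg_tol = 1e-6) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  # node dielectric: eps_in inside any atom sphere, else eps_out
  if (uniform) {
    E <- array(eps_in, dim = dims)
    lam <- array(0, dim = dims)
  } else {
    gx <- origin[1] + h * (seq_len(nx) - 1L)
    gy <- origin[2] + h * (seq_len(ny) - 1L)
    gz <- origin[3] + h * (seq_len(nz) - 1L)
    inside <- array(FALSE, dim = dims)
    for (a in seq_len(nrow(xyz))) {
      ix <- which(abs(gx - xyz[a, 1]) <= radius[a])
      iy <- which(abs(gy - xyz[a, 2]) <= radius[a])
      iz <- which(abs(gz - xyz[a, 3]) <= radius[a])
      if (!length(ix) || !length(iy) || !length(iz)) next
      d2 <- outer(outer((gx[ix] - xyz[a, 1])^2, (gy[iy] - xyz[a, 2])^2, "+"),
                  (gz[iz] - xyz[a, 3])^2, "+")
      inside[ix, iy, iz] <- inside[ix, iy, iz] | (d2 <= radius[a]^2)
    }
    E <- array(eps_out, dim = dims)
    E[inside] <- eps_in
    lam <- array(eps_out * kappa2, dim = dims)
    lam[inside] <- 0
  }
  hm <- function(a, b) 2 * a * b / (a + b)
  # face dielectrics between node i-1 and i along each axis
  ExF <- hm(E[-nx, , ], E[-1, , ])   # (nx-1, ny, nz)
  EyF <- hm(E[, -ny, ], E[, -1, ])
  EzF <- hm(E[, , -nz], E[, , -1])
  ii <- 2:(nx - 1); jj <- 2:(ny - 1); kk <- 2:(nz - 1)
  # per-interior-node face coefficients
  cxm <- ExF[ii - 1, jj, kk]; cxp <- ExF[ii, jj, kk]
  cym <- EyF[ii, jj - 1, kk]; cyp <- EyF[ii, jj, kk]
  czm <- EzF[ii, jj, kk - 1]; czp <- EzF[ii, jj, kk]
  diagA <- cxm + cxp + cym + cyp + czm + czp + lam[ii, jj, kk] * h^2
  apply_A <- function(x) {
    X <- array(0, dim = dims)
    X[ii, jj, kk] <- x
    diagA * x -
      (cxm * X[ii - 1, jj, kk] + cxp * X[ii + 1, jj, kk] +
       cym * X[ii, jj - 1, kk] + cyp * X[ii, jj + 1, kk] +
       czm * X[ii, jj, kk - 1] + czp * X[ii, jj, kk + 1])
  }
  # Dirichlet boundary: Debye-Hueckel (or Coulomb/eps_in for reference)
  PHI_B <- array(0, dim = dims)
  bset <- function(idx_list) idx_list
  gx <- origin[1] + h * (seq_len(nx) - 1L)
  gy <- origin[2] + h * (seq_len(ny) - 1L)
  gz <- origin[3] + h * (seq_len(nz) - 1L)
  kap <- sqrt(kappa2)
  bc_value <- function(px, py, pz) {
    v <- 0
    for (a in seq_len(nrow(xyz))) {
      r <- sqrt((px - xyz[a, 1])^2 + (py - xyz[a, 2])^2 + (pz - xyz[a, 3])^2)
      r <- pmax(r, 1e-6)
      v <- v + if (uniform) {
        ctx$coulomb_constant * q[a] / (eps_in * r)
      } else {
        ctx$coulomb_constant * q[a] * exp(-kap * r) / (eps_out * r)
      }
    }
    v
  }
  # fill the six faces
  gxy <- expand.grid(x = gx, y = gy)
  gxz <- expand.grid(x = gx, z = gz)
  gyz <- expand.grid(y = gy, z = gz)
  PHI_B[, , 1]  <- matrix(bc_value(gxy$x, gxy$y, gz[1]), nx, ny)
  PHI_B[, , nz] <- matrix(bc_value(gxy$x, gxy$y, gz[nz]), nx, ny)
  PHI_B[, 1, ]  <- matrix(bc_value(gxz$x, gy[1], gxz$z), nx, nz)
  PHI_B[, ny, ] <- matrix(bc_value(gxz$x, gy[ny], gxz$z), nx, nz)
  PHI_B[1, , ]  <- matrix(bc_value(gx[1], gyz$y, gyz$z), ny, nz)
  PHI_B[nx, , ] <- matrix(bc_value(gx[nx], gyz$y, gyz$z), ny, nz)
  Q <- spread_charges(xyz, q, origin, h, dims)
  leak <- abs(sum(Q) - sum(q))
  if (leak > 1e-6) stop(sprintf("pb solver: gridded charge leak %.3g e", leak))
  b <- 4 * pi * ctx$coulomb_constant * Q[ii, jj, kk] / h
  # boundary contributions enter b through the eliminated neighbours
  b[1, , ] <- b[1, , ] + cxm[1, , ] * PHI_B[1, jj, kk]
  b[dim(b)[1], , ] <- b[dim(b)[1], , ] + cxp[dim(b)[1], , ] * PHI_B[nx, jj, kk]
  b[, 1, ] <- b[, 1, ] + cym[, 1, ] * PHI_B[ii, 1, kk]
  b[, dim(b)[2], ] <- b[, dim(b)[2], ] + cyp[, dim(b)[2], ] * PHI_B[ii, ny, kk]
  b[, , 1] <- b[, , 1] + czm[, , 1] * PHI_B[ii, jj, 1]
  b[, , dim(b)[3]] <- b[, , dim(b)[3]] + czp[, , dim(b)[3]] * PHI_B[ii, jj, nz]
  sol <- pb_cg(apply_A, diagA, b, tol = cg_tol)
  PHI <- PHI_B
  PHI[ii, jj, kk] <- sol$x
  interp_field(PHI, xyz, origin, h)
}

#' Polar solvation energy by finite-difference linearized Poisson-Boltzmann
#'
#' Solves the linearized Poisson-Boltzmann equation on a uniform grid
#' (7-point stencil, harmonic-mean face dielectrics, trilinear charge
#' spreading, Debye-Hueckel Dirichlet boundary values, Jacobi-
#' preconditioned conjugate gradients to relative residual 1e-6) and
#' returns the polar solvation free energy
#' `dG = 0.5 * sum_i q_i (phi_solvated(r_i) - phi_reference(r_i))`, where
#' the reference solve uses a uniform `eps_in` dielectric and no salt so
#' the grid self-energy cancels.
#'
#' The dielectric boundary is the union of van der Waals spheres (no
#' molecular-surface construction); grid discretisation error is roughly
#' quadratic in `h`, so pairing two spacings with
#' `richardson = TRUE` sharpens a Born-type energy considerably.
#'
#' @param solute A [toy_solute()] (charges, radii, coordinates).
#' @param ctx A [thermo_context()].
#' @param h Grid spacing, A (<= 1 recommended).
#' @param padding Clearance between any atom sphere and the box edge, A
#'   (>= 8 recommended).
#' @param eps_in,eps_out Solute and solvent dielectric constants.
#' @param ionic_strength 1:1 electrolyte ionic strength, mol/L.
#' @param coords Optional frame coordinates overriding the topology.
#' @param cg_tol Linear-solver relative residual tolerance.
#' @return Polar solvation energy, kcal/mol.
#' @export
pb_polar_energy <- function(solute, ctx, h = 0.5, padding = 8,
                            eps_in = 1, eps_out = 80, ionic_strength = 0.15,
                            coords = NULL, cg_tol = 1e-6) {
  assert_ctx(ctx)
  xyz <- if (is.null(coords)) solute_xyz(solute) else as.matrix(coords)
  q <- solute$charge
  radius <- solute$radius
  if (all(q == 0)) return(0)
  lo <- apply(xyz - radius, 2, min) - padding
  hi <- apply(xyz + radius, 2, max) + padding
  dims <- pmax(ceiling((hi - lo) / h) + 1L, 8L)
  origin <- lo
  kappa2 <- debye_kappa2(ionic_strength, eps_out, ctx)
  phi_solv <- pb_solve_one(xyz, q, radius, origin, h, dims, eps_in, eps_out,
                           kappa2, ctx, uniform = FALSE, cg_tol = cg_tol)
  phi_ref <- pb_solve_one(xyz, q, radius, origin, h, dims, eps_in, eps_out,
                          kappa2 = 0, ctx, uniform = TRUE, cg_tol = cg_tol)
  0.5 * sum(q * (phi_solv - phi_ref))
}

#' Richardson-extrapolated PB polar energy over two grid spacings
#'
#' Runs [pb_polar_energy()] at a coarse and a fine spacing and removes the
#' leading O(h^2) discretisation error:
#' `E = (s^2 E_fine - E_coarse) / (s^2 - 1)` with `s = h_coarse/h_fine`.
#'
#' @inheritParams pb_polar_energy
#' @param h_pair Two grid spacings, coarse then fine (default `c(0.8, 0.4)`).
#' @return List with `value` (extrapolated energy), `coarse`, `fine`.
#' @export
pb_polar_energy_richardson <- function(solute, ctx, h_pair = c(0.8, 0.4), ...) {
  if (length(h_pair) != 2L || h_pair[1] <= h_pair[2]) {
    stop("pb_polar_energy_richardson: give h_pair = c(coarse, fine)")
  }
  e_c <- pb_polar_energy(solute, ctx, h = h_pair[1], ...)
  e_f <- pb_polar_energy(solute, ctx, h = h_pair[2], ...)
  s2 <- (h_pair[1] / h_pair[2])^2
  list(value = (s2 * e_f - e_c) / (s2 - 1), coarse = e_c, fine = e_f)
}

# ---- generalized Born (OBC-II) -------------------------------------------

# HCT pairwise descreening integral for atom i (un-offset radius rho_i)
# against neighbour j at distance r with scaled radius sj.
hct_integral <- function(rho_i, r, sj) {
  if (rho_i >= r + sj) return(0)          # neighbour buried inside rho_i
  Uinv <- 1 / (r + sj)
  Linv <- 1 / max(rho_i, abs(r - sj))
  I <- Linv - Uinv +
    0.25 * (r - sj^2 / r) * (Uinv^2 - Linv^2) +
    (0.5 / r) * log(Uinv / Linv)
  if (rho_i < sj - r) I <- I + 2 * (1 / rho_i - Linv)
  0.5 * I
}

#' Effective Born radii by OBC-II pairwise descreening
#'
#' Hawkins-Cramer-Truhlar descreening sums rescaled by the OBC-II
#' correction `1/R_i = 1/rho_i - tanh(alpha Psi - beta Psi^2 + gamma
#' Psi^3) / radius_i`, with `Psi = I_i rho_i` and parameters alpha = 1.0,
#' beta = 0.8, gamma = 4.85. `rho_i = radius_i - offset`; the default
#' offset of 0 makes the isolated-atom Born radius equal the intrinsic
#' radius exactly.
#'
#' @param solute A [toy_solute()].
#' @param coords Optional frame coordinates.
#' @param offset Born radius offset, A (default 0).
#' @param scale Descreening scale applied to neighbour radii (default 0.8).
#' @return Numeric vector of effective Born radii (A).
#' @export
gb_born_radii <- function(solute, coords = NULL, offset = 0, scale = 0.8) {
  xyz <- if (is.null(coords)) solute_xyz(solute) else as.matrix(coords)
  n <- nrow(xyz)
  rho <- solute$radius - offset
  if (any(rho <= 0)) stop("gb_born_radii: offset exceeds an atomic radius")
  s <- scale * rho
  R <- numeric(n)
  alpha <- 1.0; beta <- 0.8; gamma <- 4.85
  for (i in seq_len(n)) {
    I_i <- 0
    for (j in seq_len(n)) {
      if (i == j) next
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      I_i <- I_i + hct_integral(rho[i], r, s[j])
    }
    psi <- I_i * rho[i]
    inv <- 1 / rho[i] - tanh(alpha * psi - beta * psi^2 + gamma * psi^3) / solute$radius[i]
    if (inv <= 0) {
      stop(sprintf("gb_born_radii: non-positive Born radius for atom %d (%s)",
                   i, solute$name[i]))
    }
    R[i] <- 1 / inv
  }
  R
}

#' Polar solvation energy by generalized Born (OBC-II)
#'
#' Pairwise generalized-Born energy
#' `-0.5 C (1/eps_in - 1/eps_out) sum_ij q_i q_j / f_GB` with
#' `f_GB = sqrt(r^2 + R_i R_j exp(-r^2 / (4 R_i R_j)))`; the i = j term is
#' the self-energy with `f_GB = R_i`. For a single atom this reduces
#' exactly to the Born formula.
#'
#' @inheritParams gb_born_radii
#' @param ctx A [thermo_context()].
#' @param eps_in,eps_out Solute and solvent dielectrics.
#' @return Polar solvation energy, kcal/mol.
#' @export
gb_polar_energy <- function(solute, ctx, eps_in = 1, eps_out = 80,
                            coords = NULL, offset = 0, scale = 0.8) {
  assert_ctx(ctx)
  xyz <- if (is.null(coords)) solute_xyz(solute) else as.matrix(coords)
  R <- gb_born_radii(solute, coords = xyz, offset = offset, scale = scale)
  q <- solute$charge
  n <- length(q)
  d2 <- as.matrix(stats::dist(xyz))^2
  RR <- outer(R, R)
  fgb <- sqrt(d2 + RR * exp(-d2 / (4 * RR)))
  diag(fgb) <- R
  pref <- -0.5 * ctx$coulomb_constant * (1 / eps_in - 1 / eps_out)
  pref * sum(outer(q, q) / fgb)
}

# ---- SASA ----------------------------------------------------------------

# Deterministic quasi-uniform unit-sphere points (golden-spiral lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Places a quasi-uniform point lattice on each atom's expanded sphere
#' (radius + probe); a point is accessible iff it lies outside every other
#' atom's expanded sphere. Per-atom area is the accessible fraction of
#' `4 pi (r_i + probe)^2`.
#'
#' @param solute A [toy_solute()].
#' @param probe Probe radius, A (water: 1.4).
#' @param n_points Lattice points per atom (>= 32; default 960).
#' @param coords Optional frame coordinates.
#' @return List with `total` (A^2) and `per_atom` (numeric vector).
#' @export
sasa <- function(solute, probe = 1.4, n_points = 960L, coords = NULL) {
  if (n_points < 32L) stop("sasa: n_points < 32 gives unusable precision")
  xyz <- if (is.null(coords)) solute_xyz(solute) else as.matrix(coords)
  n <- nrow(xyz)
  rad <- solute$radius + probe
  pts <- sphere_points(n_points)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    p <- pts * rad[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      dij <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (dij >= rad[i] + rad[j]) next
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 + (p[, 3] - xyz[j, 3])^2
      acc <- acc & (d2 > rad[j]^2)
      if (!any(acc)) break
    }
    per_atom[i] <- mean(acc) * 4 * pi * rad[i]^2
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' Nonpolar (hydrophobic) solvation energy from SASA
#'
#' Linear surface-area model `gamma * SASA + b` for the hydrophobic
#' desolvation term.
#'
#' @param total_sasa Total solvent-accessible surface area, A^2 (>= 0).
#' @param gamma Surface tension coefficient, kcal/mol/A^2.
#' @param b Offset, kcal/mol.
#' @return Energy in kcal/mol.
#' @export
nonpolar_energy <- function(total_sasa, gamma = 0.00542, b = 0.92) {
  if (any(total_sasa < 0)) stop("nonpolar_energy: negative SASA")
  gamma * total_sasa + b
}

# ---- quasi-harmonic entropy ----------------------------------------------

# SI constants for the frequency/entropy conversion only.
.HBAR_J_S <- 1.054571817e-34
.KB_J_K <- 1.380649e-23
.AMU_KG <- 1.66053906660e-27
.KCALMOL_J <- 4184 / 6.02214076e23   # J per molecule per (kcal/mol)

# Kabsch superposition of frame onto ref (mass-weighted), returns moved frame.
kabsch_fit <- function(frame, ref, masses) {
  wc_f <- center_of_mass(frame, masses)
  wc_r <- center_of_mass(ref, masses)
  A <- sweep(frame, 2, wc_f)
  B <- sweep(ref, 2, wc_r)
  H <- t(A * masses) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  Rm <- sv$v %*% D %*% t(sv$u)
  sweep(A %*% t(Rm), 2, wc_r, "+")
}

# Entropy (kcal/(mol K)) of one ensemble from the mass-weighted covariance.
qh_entropy_one <- function(ensemble, ctx, fit = TRUE, eig_tol = 1e-8) {
  xyz <- ensemble$xyz
  n_at <- dim(xyz)[1]; nf <- dim(xyz)[3]
  if (nf < 3 * n_at + 1) {
    stop(sprintf("quasiharmonic entropy: need >= 3N+1 = %d frames, got %d",
                 3 * n_at + 1, nf))
  }
  masses <- ensemble$topology$mass
  do_fit <- fit && n_at >= 3
  X <- matrix(aperm(xyz, c(3, 1, 2)), nrow = nf)   # frames x (atom-major, then axis)
  # reorder to atom-interleaved (x1 y1 z1 x2 ...) for mass weighting clarity
  X <- X[, as.vector(t(matrix(seq_len(3 * n_at), ncol = 3)))]
  if (do_fit) {
    for (pass in 1:2) {
      ref <- matrix(colMeans(X), ncol = 3, byrow = TRUE)
      for (f in seq_len(nf)) {
        fr <- matrix(X[f, ], ncol = 3, byrow = TRUE)
        X[f, ] <- as.vector(t(kabsch_fit(fr, ref, masses)))
      }
    }
  }
  C <- stats::cov(X)
  mw <- sqrt(rep(masses, each = 3))
  C <- C * outer(mw, mw)               # amu A^2
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) {
    # identical frames: no configurational fluctuation, zero entropy
    return(list(S = 0, n_modes = 0L, n_dropped = 3L * n_at, frequencies_s1 = numeric(0)))
  }
  keep <- ev > eig_tol * max(ev)
  n_dropped <- sum(!keep)
  ev <- ev[keep]
  if (!length(ev)) stop("quasiharmonic entropy: degenerate modes (all variance removed)")
  kT_J <- .KB_J_K * ctx$temperature
  lam_SI <- ev * .AMU_KG * 1e-20       # kg m^2
  omega <- sqrt(kT_J / lam_SI)         # 1/s
  u <- .HBAR_J_S * omega / kT_J
  s_modes <- u / (exp(u) - 1) - log(1 - exp(-u))
  list(S = ctx$gas_constant * sum(s_modes), n_modes = length(ev),
       n_dropped = n_dropped, frequencies_s1 = omega)
}

#' Quasi-harmonic configurational entropy term
#'
#' Builds the mass-weighted covariance of the (optionally least-squares
#' superposed) coordinate fluctuations, converts its eigenvalues to
#' quasi-harmonic frequencies `omega_i = sqrt(kT / lambda_i)` and sums the
#' quantum harmonic-oscillator entropy over modes. With protein and ligand
#' selections it returns the binding entropy term
#' `-T dS = -T (S_complex - S_protein - S_ligand)` of the single-trajectory
#' protocol; without selections it returns `-T S` of the ensemble itself.
#'
#' Near-zero eigenvalues (the rigid-body modes removed by superposition)
#' are dropped by a relative tolerance and their count reported.
#' Superposition requires >= 3 atoms and is skipped (with the fluctuations
#' used as-is) below that.
#'
#' @param ensemble A [snapshot_ensemble()] of the complex with at least
#'   `3 N + 1` frames.
#' @param ctx A [thermo_context()].
#' @param protein_idx,ligand_idx Optional disjoint selections for the
#'   complex - protein - ligand difference.
#' @param fit Superpose frames to the mean before the covariance.
#' @return List of class `qh_entropy`: `minus_TdS` (kcal/mol), `S_complex`,
#'   `S_protein`, `S_ligand` (kcal/(mol K), NA when not computed),
#'   `n_dropped_modes`.
#' @export
quasiharmonic_entropy <- function(ensemble, ctx, protein_idx = NULL,
                                  ligand_idx = NULL, fit = TRUE) {
  assert_ctx(ctx)
  stopifnot(inherits(ensemble, "snapshot_ensemble"))
  cpx <- qh_entropy_one(ensemble, ctx, fit = fit)
  if (is.null(protein_idx) && is.null(ligand_idx)) {
    out <- list(minus_TdS = -ctx$temperature * cpx$S, S_complex = cpx$S,
                S_protein = NA_real_, S_ligand = NA_real_,
                n_dropped_modes = cpx$n_dropped)
    class(out) <- "qh_entropy"
    return(out)
  }
  prot <- qh_entropy_one(subset_ensemble(ensemble, protein_idx, "protein"), ctx, fit = fit)
  lig <- qh_entropy_one(subset_ensemble(ensemble, ligand_idx, "ligand"), ctx, fit = fit)
  dS <- cpx$S - prot$S - lig$S
  out <- list(minus_TdS = -ctx$temperature * dS, S_complex = cpx$S,
              S_protein = prot$S, S_ligand = lig$S,
              n_dropped_modes = cpx$n_dropped)
  class(out) <- "qh_entropy"
  out
}

# ---- full decomposition --------------------------------------------------

#' Single-trajectory MM/PB(GB)SA decomposition
#'
#' Frame-by-frame end-point binding energetics over a complex ensemble:
#' the molecular-mechanics interaction energy (electrostatic + van der
#' Waals), the polar solvation difference complex - protein - ligand (PB
#' or GB), the SASA nonpolar difference, and (optionally) the
#' quasi-harmonic entropy term added once from the whole ensemble. The
#' protein-only and ligand-only terms are computed on sub-selections of
#' the complex frames (single-trajectory protocol), so bonded terms cancel
#' identically and the enthalpy reduces to the interaction energy.
#'
#' @param ensemble A complex [snapshot_ensemble()].
#' @param protein_idx,ligand_idx Disjoint atom selections covering the
#'   complex.
#' @param ctx A [thermo_context()].
#' @param solvent "GB" (default) or "PB".
#' @param entropy Include the quasi-harmonic `-T dS` term.
#' @param gamma,b Nonpolar model parameters (per species; the offsets
#'   difference to `-b` in the decomposition).
#' @param eps_in,eps_out,ionic_strength Dielectric/salt settings.
#' @param h,padding PB grid settings (ignored for GB).
#' @param sasa_points SASA lattice size.
#' @param max_failed_fraction Abort when more than this fraction of frames
#'   fail (default 0.05); individual failures are logged in the result.
#' @return An object of class `energy_decomposition` with frame-averaged
#'   fields `dE_MM` (and `elec`, `vdw`), `dG_polar`, `dG_nonpolar`,
#'   `minus_TdS`, `dH`, `dG_solvation`, `total`, the per-frame series, and
#'   the options used. The bookkeeping identity
#'   `total = dE_MM + dG_polar + dG_nonpolar + minus_TdS` holds exactly.
#' @export
mmpbsa_decompose <- function(ensemble, protein_idx, ligand_idx, ctx,
                             solvent = c("GB", "PB"), entropy = FALSE,
                             gamma = 0.00542, b = 0.92,
                             eps_in = 1, eps_out = 80, ionic_strength = 0.15,
                             h = 0.8, padding = 8, sasa_points = 240L,
                             max_failed_fraction = 0.05) {
  assert_ctx(ctx)
  solvent <- match.arg(solvent)
  topo <- ensemble$topology
  n <- nrow(topo)
  protein_idx <- to_index(protein_idx, n)
  ligand_idx <- to_index(ligand_idx, n)
  if (length(intersect(protein_idx, ligand_idx))) stop("mmpbsa_decompose: selections overlap")
  sub_solute <- function(idx) {
    s <- topo[idx, , drop = FALSE]; class(s) <- c("toy_solute", "data.frame"); s
  }
  prot <- sub_solute(protein_idx); lig <- sub_solute(ligand_idx)
  nf <- n_frames(ensemble)
  per_frame <- data.frame(frame = seq_len(nf), elec = NA_real_, vdw = NA_real_,
                          dG_polar = NA_real_, dG_nonpolar = NA_real_)
  errors <- character(0)
  polar_fun <- function(sol, xy) {
    if (solvent == "GB") {
      gb_polar_energy(sol, ctx, eps_in = eps_in, eps_out = eps_out, coords = xy)
    } else {
      pb_polar_energy(sol, ctx, h = h, padding = padding, eps_in = eps_in,
                      eps_out = eps_out, ionic_strength = ionic_strength,
                      coords = xy)
    }
  }
  for (f in seq_len(nf)) {
    res <- tryCatch({
      xy <- frame_coords(ensemble, f)
      mm <- mm_interaction_energy(topo, protein_idx, ligand_idx, ctx, coords = xy)
      gp <- polar_fun(topo, xy) - polar_fun(prot, xy[protein_idx, , drop = FALSE]) -
        polar_fun(lig, xy[ligand_idx, , drop = FALSE])
      np <- nonpolar_energy(sasa(topo, n_points = sasa_points, coords = xy)$total, gamma, b) -
        nonpolar_energy(sasa(prot, n_points = sasa_points,
                             coords = xy[protein_idx, , drop = FALSE])$total, gamma, b) -
        nonpolar_energy(sasa(lig, n_points = sasa_points,
                             coords = xy[ligand_idx, , drop = FALSE])$total, gamma, b)
      c(mm["elec"], mm["vdw"], gp, np)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      errors <- c(errors, sprintf("frame %d: %s", f, res))
    } else {
      per_frame[f, 2:5] <- res
    }
  }
  if (length(errors) > max_failed_fraction * nf) {
    stop("mmpbsa_decompose: too many failed frames:\n  ",
         paste(utils::head(errors, 5), collapse = "\n  "))
  }
  ok <- !is.na(per_frame$elec)
  elec <- mean(per_frame$elec[ok]); vdw <- mean(per_frame$vdw[ok])
  dE_MM <- elec + vdw
  dG_polar <- mean(per_frame$dG_polar[ok])
  dG_np <- mean(per_frame$dG_nonpolar[ok])
  minus_TdS <- 0
  ent <- NULL
  if (entropy) {
    ent <- quasiharmonic_entropy(ensemble, ctx, protein_idx, ligand_idx)
    minus_TdS <- ent$minus_TdS
  }
  out <- list(dE_MM = dE_MM, elec = elec, vdw = vdw,
              dG_polar = dG_polar, dG_nonpolar = dG_np,
              dG_solvation = dG_polar + dG_np,
              minus_TdS = minus_TdS, dH = dE_MM,
              total = dE_MM + dG_polar + dG_np + minus_TdS,
              per_frame = per_frame, entropy = ent,
              frame_errors = errors,
              options = list(solvent = solvent, entropy = entropy,
                             gamma = gamma, b = b, eps_in = eps_in,
                             eps_out = eps_out, ionic_strength = ionic_strength,
                             temperature = ctx$temperature))
  class(out) <- "energy_decomposition"
  out
}

#' @export
print.energy_decomposition <- function(x, ...) {
  cat(sprintf("<energy_decomposition> (%s, %d frames)\n", x$options$solvent,
              nrow(x$per_frame)))
  cat(sprintf("  dE_MM       %10.3f  (elec %.3f, vdw %.3f)\n", x$dE_MM, x$elec, x$vdw))
  cat(sprintf("  dG_polar    %10.3f\n", x$dG_polar))
  cat(sprintf("  dG_nonpolar %10.3f\n", x$dG_nonpolar))
  cat(sprintf("  -T dS       %10.3f\n", x$minus_TdS))
  cat(sprintf("  total       %10.3f kcal/mol\n", x$total))
  invisible(x)
}
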