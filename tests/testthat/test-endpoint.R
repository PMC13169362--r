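test_that("MM interaction energy reproduces Coulomb and LJ limits", {
  # two unit charges at r = C/100 A: elec = 100 kcal/mol
  pair <- toy_solute(data.frame(x = c(0, 3.320637), y = 0, z = 0,
                                charge = c(1, 1), radius = 1.5, mass = 12,
                                eps = 0, sigma = 3))
  e <- mm_interaction_energy(pair, 1, 2, ctx300)
  expect_equal(unname(e["elec"]), 100, tolerance = 1e-10)
  # zero charges: elec = 0
  pair0 <- toy_solute(data.frame(x = c(0, 3), y = 0, z = 0, charge = 0,
                                 radius = 1.5, mass = 12, eps = 0.2, sigma = 3))
  expect_equal(unname(mm_interaction_energy(pair0, 1, 2, ctx300)["elec"]), 0)
  # LJ minimum: r = sigma_ij * 2^(1/6) gives vdw = -eps_ij
  sig <- 3.2; epsd <- 0.15
  rmin <- sig * 2^(1 / 6)
  mini <- toy_solute(data.frame(x = c(0, rmin), y = 0, z = 0, charge = 0,
                                radius = 1.5, mass = 12, eps = epsd, sigma = sig))
  expect_equal(unname(mm_interaction_energy(mini, 1, 2, ctx300)["vdw"]), -epsd,
               tolerance = 1e-12)
  # overlapping atoms rejected
  clash <- toy_solute(data.frame(x = c(0, 0.05), y = 0, z = 0, charge = 0,
                                 radius = 1.5, mass = 12))
  expect_error(mm_interaction_energy(clash, 1, 2, ctx300), "overlap")
})

test_that("FD Poisson-Boltzmann matches the Born ion closed form", {
  ion <- toy_solute(data.frame(x = 0, y = 0, z = 0, charge = 1, radius = 2,
                               mass = 12))
  born <- born_energy(1, 2, 80)
  r <- pb_polar_energy_richardson(ion, ctx300, h_pair = c(0.8, 0.4),
                                  ionic_strength = 0)
  expect_lt(abs(r$value - born) / abs(born), 0.03)
  # grid convergence: the fine solve is closer than the coarse one
  expect_lt(abs(r$fine - born), abs(r$coarse - born))
  # screened case vs Born + Debye-Hueckel term
  I <- 0.15
  rs <- pb_polar_energy_richardson(ion, ctx300, h_pair = c(0.8, 0.4),
                                   ionic_strength = I)
  kap <- sqrt(bindfe:::debye_kappa2(I, 80, ctx300))
  analytic <- born + -(ctx300$coulomb_constant / (2 * 80)) * kap / (1 + kap * 2)
  expect_lt(abs(rs$value - analytic) / abs(analytic), 0.05)
  # neutral solute costs nothing
  expect_identical(pb_polar_energy(toy_solute(data.frame(
    x = 0, y = 0, z = 0, charge = 0, radius = 2, mass = 12)), ctx300), 0)
})

test_that("PB solvation is negative for net-charged solutes", {
  set.seed(31)
  sol <- toy_solute(data.frame(x = c(0, 2.8), y = 0, z = 0,
                               charge = c(0.6, 0.4), radius = c(1.6, 1.8),
                               mass = 12))
  e <- pb_polar_energy(sol, ctx300, h = 0.6, ionic_strength = 0)
  expect_lt(e, 0)
})

test_that("generalized Born reduces to the Born formula for one sphere", {
  ion <- toy_solute(data.frame(x = 0, y = 0, z = 0, charge = 1, radius = 2,
                               mass = 12))
  expect_equal(gb_born_radii(ion), 2)
  expect_equal(gb_polar_energy(ion, ctx300), born_energy(1, 2, 80),
               tolerance = 1e-10)
  # the i = j self term uses f_GB = R_i: doubling the charge quadruples it
  ion2 <- toy_solute(data.frame(x = 0, y = 0, z = 0, charge = 2, radius = 2,
                                mass = 12))
  expect_equal(gb_polar_energy(ion2, ctx300), 4 * gb_polar_energy(ion, ctx300),
               tolerance = 1e-10)
})

test_that("GB tracks the PB solver on a small multi-atom solute", {
  tri <- toy_solute(data.frame(x = c(0, 3, 1.2), y = c(0, 0, 2.4), z = 0,
                               charge = c(0.4, -0.5, 0.3),
                               radius = c(1.6, 1.7, 1.5), mass = 12))
  pb <- pb_polar_energy_richardson(tri, ctx300, h_pair = c(0.8, 0.4),
                                   ionic_strength = 0)
  gb <- gb_polar_energy(tri, ctx300)
  expect_lt(abs(gb - pb$value) / abs(pb$value), 0.15)
})

test_that("Shrake-Rupley SASA matches sphere and two-cap closed forms", {
  one <- sphere_solute(0, 1.5)
  s1 <- sasa(one, n_points = 4000)
  expect_equal(s1$total, 4 * pi * 2.9^2, tolerance = 0.01 * 4 * pi * 2.9^2)
  # far-separated spheres are additive
  two_far <- sphere_solute(c(0, 50), c(1.5, 1.5))
  s_far <- sasa(two_far, n_points = 960)
  expect_equal(s_far$total, 2 * s1$total, tolerance = 1e-6)
  # overlapping spheres vs the analytic two-cap area
  d <- 2.0
  two <- sphere_solute(c(0, d), c(1.5, 1.5))
  s2 <- sasa(two, n_points = 4000)
  expect_lt(abs(s2$total - two_sphere_sasa(2.9, d)) / two_sphere_sasa(2.9, d), 0.01)
  expect_error(sasa(one, n_points = 16), "32")
})

test_that("SASA decreases monotonically as two spheres approach", {
  areas <- vapply(seq(6, 1, by = -0.5), function(d) {
    sasa(sphere_solute(c(0, d), c(1.5, 1.5)), n_points = 960)$total
  }, numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
})

test_that("nonpolar term is the linear SASA model", {
  expect_equal(nonpolar_energy(0, b = 0), 0)
  expect_equal(nonpolar_energy(1000, gamma = 0.00542, b = 0.92), 6.34)
  expect_equal(nonpolar_energy(2000) - nonpolar_energy(1000),
               nonpolar_energy(1000) - nonpolar_energy(0))
  expect_error(nonpolar_energy(-5), "negative")
})

test_that("quasi-harmonic entropy matches the analytic oscillator", {
  atom <- toy_solute(data.frame(x = 0, y = 0, z = 0, charge = 0, radius = 1.7,
                                mass = 12.011))
  pe <- perturb_ensemble(atom, sd = 0.3, n_frames = 5000, seed = 4)
  q <- quasiharmonic_entropy(pe$ensemble, ctx300)
  S_an <- ho_entropy_3d(12.011, 0.3, 300)
  expect_lt(abs(q$S_complex - S_an) / S_an, 0.02)
  # identical frames: zero entropy
  pe0 <- perturb_ensemble(atom, sd = 0, n_frames = 10, seed = 1)
  expect_equal(quasiharmonic_entropy(pe0$ensemble, ctx300)$S_complex, 0)
  # entropy increases with temperature at fixed geometry
  q_hot <- quasiharmonic_entropy(pe$ensemble, thermo_context(600))
  expect_gt(q_hot$S_complex, q$S_complex)
  # too few frames rejected
  pe_short <- perturb_ensemble(atom, sd = 0.3, n_frames = 3, seed = 2)
  expect_error(quasiharmonic_entropy(pe_short$ensemble, ctx300), "frames")
})

test_that("MM/PBSA decomposition bookkeeping is exact and toggles entropy", {
  tc <- build_toy_complex(n_residues = 5, n_ligand_atoms = 4, seed = 3)
  lig <- which(tc$solute$chain == "L")
  prot <- which(tc$solute$chain == "A")
  pe <- perturb_ensemble(tc$solute, sd = 0.08, n_frames = 4, seed = 2)
  dec <- mmpbsa_decompose(pe$ensemble, prot, lig, ctx300, solvent = "GB")
  expect_identical(dec$total,
                   dec$dE_MM + dec$dG_polar + dec$dG_nonpolar + dec$minus_TdS)
  expect_identical(dec$dG_solvation, dec$dG_polar + dec$dG_nonpolar)
  expect_identical(dec$dH, dec$dE_MM)
  # term-by-term oracle on one frame
  xy <- frame_coords(pe$ensemble, 1)
  mm <- mm_interaction_energy(tc$solute, prot, lig, ctx300, coords = xy)
  expect_equal(dec$per_frame$elec[1], unname(mm["elec"]))
  expect_equal(dec$per_frame$vdw[1], unname(mm["vdw"]))
  sub_sol <- function(i) { s <- tc$solute[i, ]; class(s) <- class(tc$solute); s }
  gp_hand <- gb_polar_energy(tc$solute, ctx300, coords = xy) -
    gb_polar_energy(sub_sol(prot), ctx300, coords = xy[prot, ]) -
    gb_polar_energy(sub_sol(lig), ctx300, coords = xy[lig, ])
  expect_equal(dec$per_frame$dG_polar[1], gp_hand)
})

test_that("a non-interacting ghost ligand contributes nothing", {
  tc <- build_toy_complex(n_residues = 4, n_ligand_atoms = 3,
                          charge_scale = 0, seed = 6)
  sol <- tc$solute
  sol$eps <- 0
  sol <- toy_solute(as.data.frame(sol))
  lig <- which(sol$chain == "L"); prot <- which(sol$chain == "A")
  pe <- perturb_ensemble(sol, sd = 0.05, n_frames = 3, seed = 9)
  dec <- mmpbsa_decompose(pe$ensemble, prot, lig, ctx300, solvent = "GB")
  expect_equal(dec$dE_MM, 0)
  expect_equal(dec$dG_polar, 0)
})

test_that("entropy toggle changes the total by exactly minus_TdS", {
  tc <- build_toy_complex(n_residues = 4, n_ligand_atoms = 3, seed = 8)
  lig <- which(tc$solute$chain == "L"); prot <- which(tc$solute$chain == "A")
  nf <- 3 * nrow(tc$solute) + 2
  pe <- perturb_ensemble(tc$solute, sd = 0.12, n_frames = nf, seed = 5)
  off <- mmpbsa_decompose(pe$ensemble, prot, lig, ctx300, solvent = "GB",
                          entropy = FALSE)
  on <- mmpbsa_decompose(pe$ensemble, prot, lig, ctx300, solvent = "GB",
                         entropy = TRUE)
  expect_equal(on$total - off$total, on$minus_TdS)
  expect_false(on$minus_TdS == 0)
})
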