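# bindfe

Multimethod binding free-energy and selectivity analysis for
protein–ligand systems, in R.

Selective inhibition of one paralogue over a close relative — the
motivating case is PARP1 over PARP2, where next-generation inhibitors
such as saruparib achieve several-hundred-fold selectivity — comes down
to small differences of binding free energy, ΔΔG = ΔG_bind(PARP1) −
ΔG_bind(PARP2), of a few kcal/mol. `bindfe` implements the three
standard computational routes to ΔG_bind from sampled molecular data,
the statistics that compare them with experiment, and synthetic-data
generators with analytic ground truth so every stage can be validated
without any molecular-dynamics engine:

* **End-point MM/PB(GB)SA** — ΔG ≈ ΔE_MM + ΔG_polar + ΔG_nonpolar −
  TΔS over an equilibrium snapshot ensemble (single-trajectory
  protocol), with a finite-difference linearized Poisson–Boltzmann
  solver, a generalized-Born (OBC-II) alternative, Shrake–Rupley SASA
  for the nonpolar term, and quasi-harmonic configurational entropy.
* **Alchemical absolute binding free energies (ABFE)** — free-energy
  differences across a λ-decoupling ladder from reduced potentials
  u_k(x_n), by exponential averaging (Zwanzig), ΔG = −kT ln⟨e^(−βΔU)⟩,
  and by the multistate Bennett acceptance ratio (MBAR) fixed point
  f̂_k = −ln Σ_n e^(−u_k(x_n)) / Σ_j N_j e^(f̂_j − u_j(x_n)), with
  overlap-matrix diagnostics, an analytic harmonic-restraint
  standard-state correction, and thermodynamic-cycle assembly.
* **Umbrella sampling** — harmonic-bias windows U_i(z) = ½k_i(z−z_i)²
  along a ligand–pocket COM distance, WHAM reconstruction of the PMF
  W(z), block-bootstrap error bands, and a standard-state ΔG_bind from
  the PMF depth.
* **Selectivity statistics** — IC50 → ΔG conversion (ΔG = RT ln IC50),
  first-order error propagation σ_ΔG ≈ RT σ_IC50/IC50, per-ligand ΔΔG,
  and cross-method regression reporting R² and the deviation metric
  D = √((1/n) Σ (y_fit,i − y_data,i)²).
* **Contact analysis** — per-residue contact frequencies from ligand
  heavy atoms to side-chain centres of mass, shared/exclusive
  classification across paralogues, and per-residue interaction-energy
  decomposition that sums exactly to the total.

Uncertainties throughout use a block bootstrap with five contiguous
blocks, emulating five statistically independent sub-trajectory
replicas.

## Worked example

Convert the experimental IC50 panel of eight PARP inhibitors to binding
free energies and selectivities:

```r
library(bindfe)
ctx <- thermo_context(300)
aff <- ic50_to_dG(parp_ic50_table(), ctx)
mc  <- method_comparison_table(aff, "PARP1", "PARP2")
print(mc$ddG[, c("ligand", "EXPERIMENT")], digits = 3)
#>        ligand EXPERIMENT
#> 1   saruparib     -3.664
#> 2    NMS-P118     -3.005
#> 3   veliparib     -0.168
#> 4    olaparib      0.120
#> 5   rucaparib     -1.297
#> 6   niraparib      0.354
#> 7 talazoparib      0.637
#> 8   pamiparib      0.219
```

Negative ΔΔG means PARP1-selective: saruparib's −3.66 kcal/mol is
RT ln(3 nM / 1400 nM) at 300 K, the ~470-fold selectivity window, while
veliparib and olaparib are essentially non-selective.

An alchemical ladder with analytic ground truth (Δf = ½ ln 2 ≈ 0.3466
per step) solved by MBAR, with its overlap diagnostic:

```r
lad <- harmonic_ladder_ensemble(c(1, 2, 4, 8), 2000, seed = 11)
fit <- mbar_solve(lad$matrix)
print(fit)
#> <mbar_result> K = 4, converged in 12 iterations (residual 4.9e-09)
#>   f (reduced, state 1 = 0):  0.0000, 0.3378, 0.6769, 1.0205
print(mbar_overlap(fit))
#> <overlap_matrix> K = 4, bottleneck O[2,3] = 0.2454
```

A full umbrella-sampling pipeline on a double-well landscape runs as
`sample_umbrella_windows()` → `wham_pmf()` → `pmf_binding_dG()` →
`pmf_bootstrap_band()`; MM/PB(GB)SA decomposition of a toy complex as
`build_toy_complex()` → `perturb_ensemble()` → `mmpbsa_decompose()`.
See the methods vignette (`vignettes/binding-free-energy-methods.Rmd`)
for the models, parameter choices and limitations.

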