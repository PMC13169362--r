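---
title: "Binding free-energy methods in bindfe: models, parameters, validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding free-energy methods in bindfe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindfe)
```

`bindfe` estimates protein–ligand binding free energies three ways —
end-point MM/PB(GB)SA, alchemical decoupling (EXP/MBAR), and umbrella
sampling (WHAM) — and compares them against experimental affinities
with paralogue-selectivity statistics. This vignette is the package's
account of the science: the models and their assumptions, the
parameters that matter, the numerical choices, what the synthetic-data
generators do and do not emulate, and the known limitations.

## Units and thermodynamic context

Everything is in Å, kcal/mol, elementary charges, amu and kelvin. A
`thermo_context()` pins the gas constant (1.9872036×10⁻³ kcal/(mol K)),
the 1 M standard-state volume (1660.5392 Å³ per molecule) and the
Coulomb constant (332.0637 kcal Å/(mol e²)) so results are bit-stable.
At the default 300 K, kT = 0.59616 kcal/mol. Atom tables are 1-based,
as is idiomatic in R; PDB serial numbers are carried only for
round-trip output. Reaction coordinates read from GROMACS-style XVG
files are converted from nm to Å at the single I/O conversion site.

## Alchemical estimators

The substrate is a K-state × N-sample matrix of *reduced* potentials
u_k(x_n) plus per-state sample counts. Two estimators are provided.

**Exponential averaging (Zwanzig).** ΔG = −kT ln⟨e^(−Δu)⟩, accumulated
with log-sum-exp so reduced work up to ~700 cannot overflow. One-sided
averaging is systematically biased when overlap is poor: the forward
estimator is biased high, the reverse (negated) biased low. The suite
verifies this bracketing on harmonic ladders as a property of the
estimator *means* over 20 fixed seeds — per-seed bracketing is not
guaranteed when one direction has good overlap and noise exceeds bias.

**MBAR.** The self-consistent fixed point is iterated directly
(log-sum-exp accumulated), gauge-fixed at f₁ = 0, to a default
tolerance of 10⁻⁸ reduced units on max |Δf| within 10 000 iterations.
Self-consistent iteration converges slowly for near-degenerate ladders
but is simple and monotone; the fixed point, not the iteration
schedule, is the contract. States with zero samples are legal
perturbation targets and flagged in the result. The overlap matrix
O_ij = Σ_n W_ni N_j W_nj is row-stochastic at self-consistency (rows
sum to 1 to 10⁻¹⁰ when solved at tolerance 10⁻¹³); the smallest
nearest-neighbour entry is reported as the ladder's bottleneck. For
indistinguishable states every entry collapses to N_j/N (equal to 1/K
only for equal counts).

**Uncertainty.** Block bootstrap: the series is cut into five
contiguous blocks (mimicking five independent sub-trajectory
replicas), blocks are resampled with replacement, and the SD of the
statistic over resamples is reported. MBAR's asymptotic covariance is
deliberately not the default; the block scheme handles residual time
correlation that the asymptotic formula assumes away. An optional
autocorrelation-based subsampler (`subsample_indices()`) exists but is
off by default — inputs are assumed pre-subsampled.

**Standard-state correction.** Decoupling a restrained ligand requires
releasing the restraint into the 1 M volume. We use the analytic
isotropic-harmonic release, ΔG = −kT ln[V°/(2πkT/k)^(3/2)]. Real
protocols restrain one ligand heavy atom plus protein residues with
orientational terms whose correction has no simple closed form; the
isotropic formula is this package's explicit, testable choice (verified
against 3D quadrature), with `k_restraint` exposed. The thermodynamic
cycle is assembled as ΔG_bind = −(ΔG_complex − ΔG_solvent) + ΔG_restraint,
uncertainties in quadrature; negative values are favourable.

## Umbrella sampling and WHAM

Windows carry a harmonic bias ½k_i(z−z_i)² and a time-ordered series of
reaction-coordinate samples; an `equil_fraction` can discard the front
of each series (0.4 is the convention for long MD series; the suite
checks that discarding 40 % of a pre-equilibrated synthetic series
moves the profile by less than the bootstrap band). The default
histogram grid is 200 uniform half-open bins spanning all samples
padded by one bin. WHAM iterates the standard two equations to a
tolerance of 10⁻⁷ kT on the window constants (cap 100 000 iterations).
Windows are canonically ordered by centre internally, so permuting the
input list reproduces the profile bit-for-bit. Adjacent windows with no
shared occupied bin trigger a warning; a window with no samples on the
grid is an error naming the window.

The profile is normalized to min 0 and reported with per-bin total
counts. Bins with few counts have standard errors of order kT/√n — a
bin with 25 counts is uncertain by ~0.2 kT, and rarely-visited tail
bins can be off by several kT without any methodological failure. The
validation therefore evaluates profile RMSD over bins with ≥ 25 counts;
users should mask similarly before interpreting tails.

**PMF depth → ΔG_bind.** The bound region integrates
∫ e^(−β(W−W_unbound)) dz (trapezoid); W_unbound is the mean over the
trailing 15 % of the grid, with a warning if that plateau has |slope| >
0.5 kT/Å. The 1D integral becomes a volume through an effective lateral
cross-section: either supplied directly, or 2πkT/k_lat from a stated
lateral restraint constant, or 1 Å² with a logged warning (real
protocols restrain ~6 ligand heavy atoms laterally but constants are
rarely reported; the default is deliberately conservative and visible).
The default bound region runs from the grid start to the first point
after the global minimum where W rises 2 kT above it — a PMF basin edge
convention, configurable because no universal definition exists. A
bound region excluding the global minimum is an error. The square-well
identity (cross-section × width = V° ⇒ ΔG = −depth exactly) and a 1D
quadrature oracle validate the conversion.

Bootstrap bands re-run WHAM per block-resample of every window series;
resampled profiles are min-normalized like the point estimate. More
than 10 % resample failures is an error.

## MM/PB(GB)SA

Single-trajectory protocol: protein-only and ligand-only terms are
computed on sub-selections of the complex frames, so bonded terms
cancel identically and ΔH reduces to the protein–ligand interaction
energy (Coulomb with no cutoff plus Lennard-Jones under
Lorentz–Berthelot combination; atoms closer than 0.1 Å are a geometry
error). The bookkeeping identity total = ΔE_MM + ΔG_polar +
ΔG_nonpolar + (−TΔS) holds exactly by construction and is asserted on
every run.

**Poisson–Boltzmann.** The linearized PB equation is discretized on a
uniform grid: 7-point stencil, harmonic-mean dielectrics at face
midpoints, trilinear charge spreading (conserves gridded charge to
10⁻⁶ e by construction; violations abort), Debye–Hückel Dirichlet
boundary values, Jacobi-preconditioned conjugate gradients to relative
residual 10⁻⁶. ΔG_polar = ½Σq_i[φ_solv(r_i) − φ_ref(r_i)] with the
reference solved at uniform ε_in and κ = 0 on the same grid, cancelling
the grid self-energy. The dielectric boundary is the union of van der
Waals spheres — no solvent-excluded molecular surface — which
overestimates solvent penetration into crevices; a documented
limitation appropriate to desk-scale solutes. Discretization error is
approximately O(h²), so `pb_polar_energy_richardson()` pairs two
spacings (default 0.8/0.4 Å) and removes the leading term; on the Born
ion this lands within ~0.5 % of the closed form (3 % is the acceptance
bound). Defaults: ε_in = 1, ε_out = 80, ionic strength 0.15 M, 8 Å
padding. Debye screening uses κ² = 8πC·I·N_A/(kT ε_out) for a 1:1
electrolyte (λ_D ≈ 7.9 Å at 0.15 M, 300 K).

**Generalized Born.** The "GB5-class" model is implemented as OBC-II:
Hawkins–Cramer–Truhlar pairwise descreening integrals with neighbour
scaling 0.8, OBC rescaling tanh(αΨ − βΨ² + γΨ³) with α = 1.0, β = 0.8,
γ = 4.85. The Born-radius offset is 0 Å by default (configurable):
with the conventional 0.09 Å offset an isolated atom's Born radius
would not equal its intrinsic radius, and the package treats the exact
single-sphere Born reduction as a defining property of the
implementation. GB agrees with the FD-PB solver within ~2 % on small
multi-atom test solutes (15 % is the acceptance bound).

**SASA and the nonpolar term.** Shrake–Rupley with a deterministic
golden-spiral point lattice (default 960 points; < 32 is rejected),
probe 1.4 Å; nonpolar energy γ·SASA + b with the classical γ = 0.00542
kcal/mol/Å², b = 0.92 kcal/mol. Each species gets the offset b, so the
complex − protein − ligand difference contributes −b.

**Quasi-harmonic entropy.** Mass-weighted covariance of coordinate
fluctuations; eigenvalues λ become frequencies ω = √(kT/λ); the quantum
harmonic-oscillator entropy is summed over modes; the binding term is
−T(S_complex − S_protein − S_ligand). At least 3N+1 frames are
required. Frames are Kabsch-superposed to the iterated mean by default;
superposition necessarily leaves ~6 near-zero rigid-body modes, which
are dropped by a relative eigenvalue tolerance (10⁻⁸) and counted in
the output. For fewer than 3 atoms superposition is skipped — fitting
would absorb the very fluctuations being measured, and the package's
analytic oracle (an unconstrained 3D Gaussian particle, matched within
2 % at 5000 frames) runs in that regime. Identical frames give S = 0.
Normal-mode entropy is out of scope.

## Selectivity statistics

IC50 values in molar convert as ΔG = RT ln(IC50); σ_ΔG ≈ RT σ_IC50/IC50
by first-order propagation, and an absent σ stays absent rather than
becoming zero. ΔΔG = ΔG(target1) − ΔG(target2) per ligand and method,
σ in quadrature; negative means selective for target1. Method-vs-method
comparison fits ordinary least squares of y on x — the package's
explicit resolution of an ambiguity (orthogonal regression would also
be defensible; y-on-x is chosen and logged because the comparisons
treat one axis as reference). Fits are unweighted; per-point σ values
are carried for display. R² is computed from residual and total sums of
squares (a perfect fit of constant y is defined as R² = 1), and the
deviation metric D is the root mean squared residual about the fitted
line, in kcal/mol. Fewer than 3 points or zero x-variance are errors;
named ligands can be excluded and are logged (the classical use is
excluding a known outlier such as veliparib). The bundled
`parp_ic50_table()` carries the eight-inhibitor experimental panel
(IC50s in nM for PARP1/PARP2) used by the examples and the acceptance
script.

## Contact analysis

A residue is in contact in a frame when the minimum distance from any
ligand heavy atom (non-hydrogen; hydrogens ignored even if selected) to
the residue's side-chain centre of mass (backbone = N, CA, C, O;
glycine falls back to CA) is within the cutoff. Cutoff 5.0 Å and
frequency threshold 0.5 are defaults, stamped into every output, since
no universal convention exists; both are monotone knobs (frequency is
non-decreasing in cutoff, a tested invariant). Paralogue
correspondences are user-supplied one-to-one tables — sequence
alignment is out of scope. Classification partitions mapped residues
into shared / exclusive-to-A / exclusive-to-B (disjoint and exhaustive
over contacting residues, property-tested); contacting residues missing
from the mapping are reported separately, never dropped. Per-residue
Coulomb+LJ decomposition sums exactly to the total interaction energy
because residues partition the protein atoms.

## Synthetic data: what it does and does not emulate

Generators produce inputs with the statistical structure each estimator
assumes, plus analytic ground truth, a stamped seed and parameters:

* `sample_umbrella_windows()` — i.i.d. draws from the biased Boltzmann
  density by inverse-CDF on a 10⁴-point grid: exact to grid resolution,
  no burn-in ambiguity, and an error if the bias fails to confine the
  density on the grid.
* `harmonic_ladder_ensemble()` — Gaussian states with f_k = ½ln(K_k/2π),
  the workhorse for EXP/MBAR validation.
* `gaussian_work_samples()` — Normal(m, s²) reduced work with the
  closed-form EXP limit βΔG = m − s²/2.
* `build_toy_complex()` / `perturb_ensemble()` — a deterministic
  pseudo-residue pocket around a small ligand cluster with assigned
  charges/radii/LJ/masses (overlapping geometries are rejected with a
  reseed hint), and Gaussian positional noise with known covariance
  σ²I.
* `synthetic_affinity_study()` — exact experimental IC50 pairs inverted
  from a true ΔΔG vector plus per-method Gaussian noise on ΔG.

i.i.d. sampling is the deliberate simplification: real MD samples are
autocorrelated, and real ensembles have anharmonic, multi-basin
fluctuations. Passing tests therefore demonstrate estimator
correctness — unbiasedness, gauge properties, closed-form agreement —
not robustness to slow conformational degrees of freedom, force-field
error, or buried-water effects, which are exactly the failure modes
that separate the three methods on real systems. The block bootstrap
is still exercised meaningfully because blocks are resampled as units
regardless of intra-block correlation.

## Problem sizes

The validation suite and acceptance script run at sizes chosen to make
statistical tolerances meaningful on a single CPU in minutes: 10⁵ work
samples for the EXP identity; 2000 samples/state on a 4-state ladder
for MBAR (per-step SD ≈ 0.02); 12 windows × 5000 samples for the WHAM
double-well (RMSD bound 0.15 kT over bins with ≥ 25 counts); Born-ion
PB at h = 0.8 and 0.4 Å; 5000 frames for the entropy oracle; 50
regenerations for selectivity sign recovery and 20 for the
noise-ordering of D.

## Known limitations

* PB uses the van der Waals surface, linear response, and 1:1
  electrolyte only; no nonlinear PB, no solvent-excluded surface, no
  explicit or structured water.
* MM terms have no cutoff and no periodicity — correct for toy solutes,
  not a simulation engine.
* The restraint correction is isotropic-harmonic; orientational
  restraint corrections are not modelled.
* WHAM is the only PMF estimator (no MBAR-based PMF); profiles are 1D
  and aperiodic.
* Entropy is quasi-harmonic only.
* Regression is unweighted y-on-x; no errors-in-variables model.
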