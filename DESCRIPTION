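Package: bindfe
Title: Multimethod Binding Free Energy and Selectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimators and diagnostics for protein-ligand binding free
    energies from sampled molecular data: end-point MM/PB(GB)SA with a
    finite-difference linearized Poisson-Boltzmann solver, generalized-Born
    (OBC-II) polar solvation, Shrake-Rupley solvent-accessible surface area
    and quasi-harmonic entropy; alchemical absolute binding free energies
    from lambda-ladder reduced potentials via exponential averaging
    (Zwanzig) and the multistate Bennett acceptance ratio (MBAR) with
    overlap diagnostics and standard-state restraint corrections; umbrella
    sampling potentials of mean force via WHAM with block-bootstrap error
    bands and a standard-state binding free energy from the PMF depth;
    paralogue selectivity statistics (IC50 to free-energy conversion with
    error propagation, ddG, regression with a deviation metric); residue
    contact maps and per-residue interaction-energy decomposition; and
    synthetic-data generators with analytic ground truth for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
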