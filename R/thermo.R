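#' Thermodynamic context
#'
#' Bundles the temperature with the physical constants every estimator in
#' the package shares. Units are fixed package-wide: angstrom, kcal/mol,
#' elementary charges, amu, kelvin.
#'
#' @param temperature Absolute temperature in kelvin. Must be positive.
#'
#' @return An object of class `thermo_context` with fields `temperature`
#'   (K), `gas_constant` (kcal/(mol K)), `standard_volume` (A^3 per
#'   molecule at 1 M) and `coulomb_constant` (kcal A / (mol e^2)).
#'
#' @details The gas constant is pinned at 1.9872036e-3 kcal/(mol K), the
#'   standard-state volume at 1660.5392 A^3 (the volume per molecule at
#'   1 mol/L) and the Coulomb constant at 332.0637 kcal A / (mol e^2), so
#'   that derived quantities are bit-stable across platforms.
#'
#' @examples
#' ctx <- thermo_context(300)
#' thermal_energy(ctx)  # ~0.596 kcal/mol
#' @export
thermo_context <- function(temperature = 300) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("invalid thermodynamic context: temperature must be a single positive finite number (kelvin)")
  }
  structure(
    list(
      temperature = as.numeric(temperature),
      gas_constant = 1.9872036e-3,
      standard_volume = 1660.5392,
      coulomb_constant = 332.0637
    ),
    class = "thermo_context"
  )
}

#' @export
print.thermo_context <- function(x, ...) {
  cat(sprintf("<thermo_context> T = %g K, kT = %.6g kcal/mol, V0 = %.4f A^3\n",
              x$temperature, thermal_energy(x), x$standard_volume))
  invisible(x)
}

assert_ctx <- function(ctx) {
  if (!inherits(ctx, "thermo_context")) {
    stop("expected a thermo_context (see thermo_context())")
  }
  invisible(ctx)
}

#' Thermal energy kT
#'
#' @param ctx A [thermo_context()].
#' @return The thermal energy `R * T` in kcal/mol.
#' @export
thermal_energy <- function(ctx) {
  assert_ctx(ctx)
  ctx$gas_constant * ctx$temperature
}

#' Reduced (dimensionless) potential energy
#'
#' Divides an energy by the thermal energy kT, i.e. multiplies by
#' beta = 1/(kT).
#'
#' @param U Energy in kcal/mol (vectorised).
#' @param ctx A [thermo_context()].
#' @return `U / thermal_energy(ctx)`, dimensionless.
#' @export
reduced_potential <- function(U, ctx) {
  assert_ctx(ctx)
  if (!is.numeric(U) || any(!is.finite(U))) {
    stop("reduced_potential: U must be finite numeric (kcal/mol)")
  }
  U / thermal_energy(ctx)
}

#' Mass-weighted center of mass
#'
#' @param coords Numeric matrix, one row per atom, columns x/y/z (A).
#' @param masses Numeric vector of atomic masses (amu), positive.
#' @return Length-3 numeric vector: the center of mass in A.
#' @export
center_of_mass <- function(coords, masses) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0L) stop("center_of_mass: empty atom selection")
  if (ncol(coords) != 3L) stop("center_of_mass: coords must be an n x 3 matrix")
  if (length(masses) != nrow(coords)) stop("center_of_mass: one mass per atom required")
  if (any(!is.finite(masses)) || any(masses <= 0)) stop("center_of_mass: masses must be positive and finite")
  if (any(!is.finite(coords))) stop("center_of_mass: coordinates must be finite")
  as.numeric(colSums(coords * masses) / sum(masses))
}
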