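# Closed-form conversions used in colloidal characterization of liposome /
# DNA complexes: dynamic-light-scattering diffusion coefficient to size, and
# electrophoretic mobility to zeta potential.

#' Solvent conditions for colloidal conversions
#'
#' @param temperature Absolute temperature, K.
#' @param viscosity Dynamic viscosity, Pa s. Default: water at 25 C.
#' @param permittivity Absolute permittivity, F/m. Default: water at 25 C
#'   (relative permittivity ~78.3).
#' @return A `solvent_conditions` list.
#' @export
solvent_conditions <- function(temperature = 298.15, viscosity = 8.9e-4,
                               permittivity = 6.93e-10) {
  check_number(temperature, "temperature", lower = 0, allow_zero = FALSE)
  check_number(viscosity, "viscosity", lower = 0, allow_zero = FALSE)
  check_number(permittivity, "permittivity", lower = 0, allow_zero = FALSE)
  structure(
    list(temperature = temperature, viscosity = viscosity,
         permittivity = permittivity),
    class = "solvent_conditions"
  )
}

boltzmann_k <- 1.380649e-23 # J/K, exact (SI definition)

#' Hydrodynamic radius from a diffusion coefficient (Stokes-Einstein)
#'
#' `R_H = k_B T / (6 pi eta D)`: the radius of the sphere that would diffuse
#' with coefficient `D` in a solvent of viscosity `eta` at temperature `T`.
#'
#' @param D Translational diffusion coefficient, m^2/s (> 0). Vectorized.
#' @param cond A [solvent_conditions()] object.
#' @return Hydrodynamic radius in metres (multiply by 1e9 for nm).
#' @export
#' @examples
#' hydrodynamic_radius(2.45e-11) * 1e9 # ~10 nm
hydrodynamic_radius <- function(D, cond = solvent_conditions()) {
  if (!inherits(cond, "solvent_conditions")) {
    stop_invalid("`cond` must come from solvent_conditions().")
  }
  if (!is.numeric(D) || any(!is.finite(D)) || any(D <= 0)) {
    stop_invalid("`D` must be positive and finite (m^2/s).")
  }
  boltzmann_k * cond$temperature / (6 * pi * cond$viscosity * D)
}

#' Zeta potential from electrophoretic mobility (Smoluchowski)
#'
#' `zeta = u eta / epsilon`, with `u` the electrophoretic mobility and
#' `epsilon` the absolute permittivity of the solvent. The sign of the
#' result follows the sign of the mobility.
#'
#' @param u Electrophoretic mobility, m^2/(V s). Vectorized.
#' @inheritParams hydrodynamic_radius
#' @return Zeta potential in volts (multiply by 1e3 for mV).
#' @export
#' @examples
#' zeta_from_mobility(2e-8) * 1e3 # ~25.7 mV
zeta_from_mobility <- function(u, cond = solvent_conditions()) {
  if (!inherits(cond, "solvent_conditions")) {
    stop_invalid("`cond` must come from solvent_conditions().")
  }
  if (!is.numeric(u) || any(!is.finite(u))) {
    stop_invalid("`u` must be finite (m^2/(V s)).")
  }
  u * cond$viscosity / cond$permittivity
}
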