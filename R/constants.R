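#' Physical constants (2019 SI exact values)
#'
#' Single source of truth for every unit conversion in the package. Energies
#' cross the API in kcal mol^-1; diffusion arithmetic is done in SI and
#' converted to M^-1 s^-1 at the boundary.
#'
#' @return Named list with elements:
#'   \describe{
#'     \item{kB}{Boltzmann constant, J K^-1}
#'     \item{h}{Planck constant, J s}
#'     \item{NA_}{Avogadro constant, mol^-1}
#'     \item{c_cm}{speed of light, cm s^-1 (for wavenumber conversions)}
#'     \item{R_kcal}{gas constant, kcal mol^-1 K^-1}
#'     \item{kcal_per_mol_J}{J per kcal mol^-1 (per molecule: divide by NA_)}
#'   }
#' @examples
#' pc <- phys_constants()
#' pc$kB * 298.15 / pc$h   # TST prefactor at 298.15 K, ~6.21e12 s^-1
#' @export
phys_constants <- function() {
  list(
    kB = 1.380649e-23,
    h = 6.62607015e-34,
    NA_ = 6.02214076e23,
    c_cm = 2.99792458e10,
    R_kcal = 1.987204e-3,
    kcal_per_mol_J = 4184
  )
}

#' TST frequency prefactor k_B T / h
#'
#' @param temperature Temperature in kelvin.
#' @return Prefactor in s^-1 (6.2124e12 at 298.15 K).
#' @export
kbt_over_h <- function(temperature) {
  stopifnot(is.numeric(temperature), all(temperature > 0))
  pc <- phys_constants()
  pc$kB * temperature / pc$h
}

#' Convert a wavenumber to the dimensionless tunneling variable u = h c nu / (k_B T)
#'
#' @param nu_imag Wavenumber magnitude, cm^-1.
#' @param temperature Kelvin.
#' @return Dimensionless u.
#' @keywords internal
wavenumber_u <- function(nu_imag, temperature) {
  pc <- phys_constants()
  pc$h * pc$c_cm * nu_imag / (pc$kB * temperature)
}

#' Standard-state correction from 1 atm to 1 M
#'
#' Activation free energies read from channel tables are assumed to already be
#' referenced to the 1 M standard state. Users post-processing raw
#' quantum-chemistry output (1 atm ideal-gas reference) can apply this
#' correction, Delta G(1M) = Delta G(1atm) + Delta n * RT ln(R'T), where
#' R' = 0.082057 L atm mol^-1 K^-1 and Delta n is the change in molecularity
#' (-1 for a bimolecular step passing through one transition state).
#'
#' @param delta_g Free energy in kcal mol^-1 at the 1 atm standard state.
#' @param temperature Kelvin.
#' @param delta_n Change in moles along the step (default -1, bimolecular).
#' @return Free energy in kcal mol^-1 at the 1 M standard state.
#' @export
standard_state_1m <- function(delta_g, temperature = 298.15, delta_n = -1) {
  pc <- phys_constants()
  delta_g + delta_n * pc$R_kcal * temperature * log(0.082057 * temperature)
}
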