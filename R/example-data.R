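#' Reference datasets for a pyrroloquinoxaline antioxidant
#'
#' Bundled channel tables, conditions and a DPPH plate for ethyl
#' 1,2-diphenyl-1H-pyrrolo[2,3-b]quinoxaline-3-carboxylate (compound "3a" of
#' the synthesized series) reacting with HO and HOO radicals, as reported in
#' the source study of that compound. Sets:
#' \describe{
#'   \item{HO_gas_thermo}{reaction free energies of all 27 candidate channels
#'     toward HO (2 FHT, 24 RAF, 1 SET), gas phase}
#'   \item{HOO_thermo}{free energies toward HOO (2 FHT + SET; all
#'     endergonic)}
#'   \item{HO_gas_kinetics}{the 24 kinetically evaluated gas-phase channels
#'     with activation energies, tunneling corrections, path degeneracies and
#'     the published rate constants in \code{k_ref}}
#'   \item{HO_pentyl_ethanoate}{the three dominant channels re-evaluated in
#'     the lipid-mimetic solvent, published apparent rates in \code{k_ref}}
#' }
#' The degeneracy values record the reading implied by reconstructing the
#' published gas-phase FHT rates (sigma = 3 for the two alkyl H-transfer
#' sites) and the lipid rates (sigma = 1); the source tables do not state
#' sigma explicitly.
#'
#' @param set Dataset name, see above.
#' @return A \code{channel_table}.
#' @examples
#' tab <- example_channels("HO_gas_kinetics")
#' overall_rate(tab$k_ref)  # ~2.7e11 M^-1 s^-1
#' @export
example_channels <- function(set = c("HO_gas_thermo", "HOO_thermo",
                                     "HO_gas_kinetics",
                                     "HO_pentyl_ethanoate")) {
  set <- match.arg(set)
  file <- switch(set,
    HO_gas_thermo = "channels_ho_gas_thermo.csv",
    HOO_thermo = "channels_hoo_thermo.csv",
    HO_gas_kinetics = "channels_ho_gas_kinetics.csv",
    HO_pentyl_ethanoate = "channels_ho_pentyl_ethanoate.csv"
  )
  read_channels(system.file("extdata", file, package = "radscav",
                            mustWork = TRUE))
}

#' Reference reaction conditions
#'
#' \describe{
#'   \item{gas}{298.15 K, no diffusion correction}
#'   \item{pentyl_ethanoate}{298.15 K lipid-mimetic solvent: viscosity
#'     8.62e-4 Pa s (standard solvent tables, 298.15 K) with default Stokes
#'     radii of 4.0e-10 m (solute) and 2.0e-10 m (HO radical)}
#' }
#'
#' @param name "gas" or "pentyl_ethanoate".
#' @return A \code{conditions} object.
#' @export
example_conditions <- function(name = c("gas", "pentyl_ethanoate")) {
  name <- match.arg(name)
  read_conditions(system.file("extdata",
                              paste0("conditions_", name, ".yaml"),
                              package = "radscav", mustWork = TRUE))
}

#' Reference DPPH plate
#'
#' The DPPH screen of the pyrroloquinoxaline series (compounds 3a-3e) with
#' quercetin as positive control, concentration ladder 8/32/128/265
#' microgram mL^-1. The published screen reports scavenging percentages, not
#' raw absorbances; the bundled CSV back-computes synthetic OD readings from
#' those percentages around a control OD of 0.800, so the SP values are exact
#' while the ODs are a reconstruction (single replicate). Censored EC50
#' values of the screen are reported against a 128 microgram mL^-1 cap, the
#' convention of the original report, so the plates carry
#' \code{censor_at = 128}.
#'
#' @param compound One of "3a".."3e" or "quercetin".
#' @return An \code{assay_plate}. Quercetin carries molar mass 302.24 g/mol,
#'   the series compounds 393.44 g/mol.
#' @examples
#' fit_dose_response(example_plate("3a"))        # censored: >128
#' fit_dose_response(example_plate("quercetin")) # numeric EC50
#' @export
example_plate <- function(compound = c("3a", "3b", "3c", "3d", "3e",
                                       "quercetin")) {
  compound <- match.arg(compound)
  mm <- if (compound == "quercetin") 302.24 else 393.44
  read_plate(system.file("extdata", "plate_dpph_synthetic_od.csv",
                         package = "radscav", mustWork = TRUE),
             compound = compound, molar_mass = mm, censor_at = 128)
}
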