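#' Reaction free energy from species free energies
#'
#' Standard thermochemistry combination: sum of product free energies minus
#' sum of reactant free energies, in consistent units (kcal mol^-1).
#'
#' @param product_g Numeric vector of product free energies.
#' @param reactant_g Numeric vector of reactant free energies.
#' @return Signed Delta G of reaction, kcal mol^-1.
#' @examples
#' reaction_free_energy(10.0, 31.7)  # -21.7
#' @export
reaction_free_energy <- function(product_g, reactant_g) {
  if (length(product_g) == 0 || length(reactant_g) == 0) {
    stop("product and reactant free-energy lists must be non-empty")
  }
  stopifnot(is.numeric(product_g), is.numeric(reactant_g),
            all(is.finite(product_g)), all(is.finite(reactant_g)))
  sum(product_g) - sum(reactant_g)
}

#' Thermodynamic viability screening
#'
#' A channel proceeds to kinetic evaluation only if its reaction free energy
#' is strictly below the threshold (default 0: spontaneous reactions only).
#' Nonviable single-electron-transfer channels are tagged "SET excluded",
#' mirroring the screening taxonomy in which SET is never evaluated
#' kinetically here.
#'
#' @param channels A \code{channel_table}.
#' @param threshold Viability threshold on dg_rxn, kcal mol^-1 (default 0,
#'   strict inequality).
#' @return The input table with logical column \code{viable} and character
#'   column \code{reason} ("spontaneous", "nonspontaneous", "SET excluded")
#'   appended; row order preserved. Class \code{screening_table}.
#' @examples
#' tab <- channel_table(site = c("C12", "C4", "SET"),
#'                      mechanism = c("RAF", "RAF", "SET"),
#'                      dg_rxn = c(-20.7, 4.2, 155.6))
#' screen_channels(tab)
#' @export
screen_channels <- function(channels, threshold = 0) {
  channels <- validate_channels(channels)
  if (any(is.na(channels$dg_rxn))) {
    bad <- which(is.na(channels$dg_rxn))[1]
    stop("channel '", channels$site[bad], "' (", channels$mechanism[bad],
         ") has no dg_rxn; screening requires a reaction free energy")
  }
  viable <- channels$dg_rxn < threshold
  reason <- ifelse(viable, "spontaneous",
                   ifelse(channels$mechanism == "SET",
                          "SET excluded", "nonspontaneous"))
  out <- channels
  out$viable <- viable
  out$reason <- reason
  class(out) <- unique(c("screening_table", class(channels)))
  out
}

#' Keep the viable channels of a screening result
#'
#' @param screened A \code{screening_table} from \code{\link{screen_channels}}.
#' @return A \code{channel_table} restricted to viable rows (screening columns
#'   dropped).
#' @export
viable_channels <- function(screened) {
  stopifnot(inherits(screened, "screening_table"))
  out <- screened[screened$viable, , drop = FALSE]
  out$viable <- NULL
  out$reason <- NULL
  rownames(out) <- NULL
  class(out) <- setdiff(class(out), "screening_table")
  validate_channels(out)
}
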