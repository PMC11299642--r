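#' Reaction conditions
#'
#' Temperature plus medium description. For a condensed medium, viscosity and
#' Stokes radii enable the diffusion correction; gas phase means no encounter
#' limit (k_app = k_act exactly).
#'
#' @param temperature Kelvin (default 298.15).
#' @param medium "gas" or a solvent name (e.g. "pentyl ethanoate").
#' @param viscosity Dynamic viscosity eta, Pa s (required for diffusion math).
#' @param solute_radius,radical_radius Stokes radii, metres.
#' @param reaction_distance Encounter distance R_AB, metres; defaults to the
#'   sum of the two radii when both are given.
#' @return An object of class \code{conditions}.
#' @examples
#' conditions()  # gas, 298.15 K
#' conditions(medium = "pentyl ethanoate", viscosity = 8.62e-4,
#'            solute_radius = 4.0e-10, radical_radius = 2.0e-10)
#' @export
conditions <- function(temperature = 298.15, medium = "gas",
                       viscosity = NULL, solute_radius = NULL,
                       radical_radius = NULL, reaction_distance = NULL) {
  if (!is.numeric(temperature) || length(temperature) != 1 ||
      !is.finite(temperature) || temperature <= 0) {
    stop("temperature must be a single positive number (kelvin)")
  }
  chk_pos <- function(x, name) {
    if (!is.null(x) && (!is.numeric(x) || length(x) != 1 || x <= 0)) {
      stop(name, " must be a single positive number when given")
    }
  }
  chk_pos(viscosity, "viscosity")
  chk_pos(solute_radius, "solute_radius")
  chk_pos(radical_radius, "radical_radius")
  chk_pos(reaction_distance, "reaction_distance")
  if (is.null(reaction_distance) && !is.null(solute_radius) &&
      !is.null(radical_radius)) {
    reaction_distance <- solute_radius + radical_radius
  }
  structure(
    list(temperature = temperature, medium = medium,
         viscosity = viscosity, solute_radius = solute_radius,
         radical_radius = radical_radius,
         reaction_distance = reaction_distance),
    class = "conditions"
  )
}

#' Is a conditions object a gas-phase specification?
#' @param cond A \code{conditions} object.
#' @return TRUE when no diffusion correction applies.
#' @export
is_gas_phase <- function(cond) {
  stopifnot(inherits(cond, "conditions"))
  identical(tolower(cond$medium), "gas") || is.null(cond$viscosity)
}

#' Read conditions from a YAML file
#'
#' Recognised keys: \code{temperature_K} (default 298.15), \code{medium}
#' (default "gas"), \code{viscosity_Pa_s}, \code{solute_radius_m},
#' \code{radical_radius_m}, \code{reaction_distance_m}.
#'
#' @param path YAML file path.
#' @return A \code{conditions} object.
#' @export
read_conditions <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.list(y)) stop("conditions YAML must be a mapping: ", path)
  conditions(
    temperature = if (!is.null(y$temperature_K)) as.numeric(y$temperature_K)
                  else 298.15,
    medium = if (!is.null(y$medium)) as.character(y$medium) else "gas",
    viscosity = if (!is.null(y$viscosity_Pa_s)) as.numeric(y$viscosity_Pa_s)
                else NULL,
    solute_radius = if (!is.null(y$solute_radius_m))
                      as.numeric(y$solute_radius_m) else NULL,
    radical_radius = if (!is.null(y$radical_radius_m))
                       as.numeric(y$radical_radius_m) else NULL,
    reaction_distance = if (!is.null(y$reaction_distance_m))
                          as.numeric(y$reaction_distance_m) else NULL
  )
}

#' @export
print.conditions <- function(x, ...) {
  cat("<conditions> T = ", x$temperature, " K, medium = ", x$medium, sep = "")
  if (!is.null(x$viscosity)) {
    cat(", eta = ", format(x$viscosity), " Pa s", sep = "")
  }
  if (!is.null(x$reaction_distance)) {
    cat(", R_AB = ", format(x$reaction_distance), " m", sep = "")
  }
  cat("\n")
  invisible(x)
}
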