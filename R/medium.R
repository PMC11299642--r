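#' Stokes-Einstein diffusion coefficient
#'
#' D = k_B T / (6 pi eta r) for a spherical solute of Stokes radius r in a
#' continuum of viscosity eta.
#'
#' @param radius Stokes radius, metres (> 0).
#' @param viscosity Dynamic viscosity, Pa s (> 0).
#' @param temperature Kelvin.
#' @return Diffusion coefficient, m^2 s^-1.
#' @examples
#' stokes_einstein_d(2.0e-10, 8.62e-4)  # ~1.27e-9 m^2/s
#' @export
stokes_einstein_d <- function(radius, viscosity, temperature = 298.15) {
  if (any(radius <= 0) || any(viscosity <= 0)) {
    stop("radius and viscosity must be > 0")
  }
  if (any(temperature <= 0)) stop("temperature must be positive")
  pc <- phys_constants()
  pc$kB * temperature / (6 * pi * viscosity * radius)
}

#' Smoluchowski encounter rate constant
#'
#' Steady-state diffusional encounter rate k_D = 4 pi R_AB (D_A + D_B) N_A,
#' converted from m^3 s^-1 per pair to M^-1 s^-1 (factor 1000 L m^-3).
#'
#' @param reaction_distance Encounter distance R_AB, metres (> 0).
#' @param d_total Mutual diffusion coefficient D_A + D_B, m^2 s^-1 (>= 0).
#' @return Encounter rate constant, M^-1 s^-1.
#' @examples
#' smoluchowski_kd(4.0e-10, 2.0e-9)  # ~6.05e9
#' @export
smoluchowski_kd <- function(reaction_distance, d_total) {
  if (any(reaction_distance <= 0)) stop("reaction_distance must be > 0")
  if (any(d_total < 0)) stop("d_total must be >= 0")
  pc <- phys_constants()
  4 * pi * reaction_distance * d_total * pc$NA_ * 1000
}

#' Encounter rate from a conditions object
#'
#' Convenience wrapper: Stokes-Einstein diffusion coefficients for solute and
#' radical from the stored radii and viscosity, then the Smoluchowski rate at
#' the stored reaction distance.
#'
#' @param cond A \code{conditions} object with viscosity, both radii and a
#'   reaction distance.
#' @return Encounter rate constant k_D, M^-1 s^-1.
#' @export
diffusion_rate <- function(cond) {
  stopifnot(inherits(cond, "conditions"))
  if (is.null(cond$viscosity) || is.null(cond$solute_radius) ||
      is.null(cond$radical_radius) || is.null(cond$reaction_distance)) {
    stop("diffusion correction needs viscosity, both radii and a reaction ",
         "distance in the conditions (medium '", cond$medium, "')")
  }
  d_total <- stokes_einstein_d(cond$solute_radius, cond$viscosity,
                               cond$temperature) +
    stokes_einstein_d(cond$radical_radius, cond$viscosity, cond$temperature)
  smoluchowski_kd(cond$reaction_distance, d_total)
}

#' Collins-Kimball apparent rate constant
#'
#' Interpolates between activation control and diffusion control:
#' k_app = k_D k_act / (k_D + k_act), never exceeding either input.
#' An infinite k_diff (gas phase) returns k_act exactly.
#'
#' @param k_act Activation-controlled (TST) rate constant, M^-1 s^-1.
#' @param k_diff Diffusional encounter rate constant, M^-1 s^-1 (may be Inf).
#' @return Apparent rate constant, M^-1 s^-1. Vectorized.
#' @examples
#' collins_kimball(5.36e8, 2.59e9)  # ~4.44e8
#' @export
collins_kimball <- function(k_act, k_diff) {
  if (any(k_act < 0) || any(k_diff < 0)) stop("rate constants must be >= 0")
  if (any(k_act == 0 & k_diff == 0)) {
    stop("k_act and k_diff cannot both be zero")
  }
  ifelse(is.infinite(k_diff), k_act,
         ifelse(is.infinite(k_act), k_diff,
                ifelse(k_act + k_diff == 0, 0,
                       k_diff * k_act / (k_diff + k_act))))
}

.extract_kapp <- function(rates) {
  if (is.data.frame(rates)) {
    if (!"k_app" %in% names(rates)) stop("rate table lacks a k_app column")
    rates$k_app
  } else if (is.numeric(rates)) {
    rates
  } else {
    stop("rates must be a rate_table or a numeric vector of k_app values")
  }
}

#' Branching ratios
#'
#' Percent contribution of each channel to the channel-set total:
#' Gamma_i = 100 k_app,i / sum_j k_app,j. Full precision is kept internally;
#' round only in reports.
#'
#' @param rates A \code{rate_table} or a numeric vector of apparent rate
#'   constants.
#' @return Same shape as the input: a rate table with \code{gamma} filled, or
#'   a numeric vector of percentages summing to 100.
#' @examples
#' branching_ratios(c(4.10e8, 4.40e8, 5.60e6))  # ~ 47.9 / 51.4 / 0.7
#' @export
branching_ratios <- function(rates) {
  k <- .extract_kapp(rates)
  if (length(k) == 0) stop("no channels to take branching ratios over")
  if (any(k < 0)) stop("rate constants must be >= 0")
  total <- sum(k)
  if (total <= 0) stop("all rate constants are zero; branching undefined")
  gamma <- 100 * k / total
  if (is.data.frame(rates)) {
    rates$gamma <- gamma
    rates
  } else {
    gamma
  }
}

#' Overall rate constant
#'
#' Arithmetic sum of the apparent rate constants of every channel in the set.
#'
#' @param rates A \code{rate_table} or numeric vector of k_app values.
#' @return Overall rate constant, M^-1 s^-1.
#' @examples
#' overall_rate(c(4.10e8, 4.40e8, 5.60e6))  # 8.556e8
#' @export
overall_rate <- function(rates) {
  k <- .extract_kapp(rates)
  if (length(k) == 0) stop("cannot take the overall rate of an empty set")
  if (any(k < 0)) stop("rate constants must be >= 0")
  sum(k)
}

#' Screen, evaluate and aggregate a channel set
#'
#' The full pipeline: thermodynamic screening, per-channel TST rates with the
#' requested tunneling treatment, diffusion correction when the conditions
#' describe a viscous medium, branching ratios and the overall rate constant.
#'
#' @inheritParams evaluate_channels
#' @param threshold Screening threshold on dg_rxn (default 0, strict).
#' @return List with elements \code{screening} (full screening table),
#'   \code{rates} (rate table for viable channels, gamma filled) and
#'   \code{k_overall}.
#' @export
scavenging_kinetics <- function(channels, cond = conditions(),
                                tunneling = tunneling_spec("supplied"),
                                threshold = 0) {
  screened <- screen_channels(channels, threshold = threshold)
  viable <- viable_channels(screened)
  rates <- evaluate_channels(viable, cond, tunneling)
  rates <- branching_ratios(rates)
  list(screening = screened, rates = rates, k_overall = overall_rate(rates))
}

#' @export
print.rate_table <- function(x, digits = 3, ...) {
  cat("<rate_table> ", nrow(x), " channel(s)", sep = "")
  if (nrow(x) > 0 && !any(is.na(x$gamma))) {
    cat("; k_overall = ", format(sum(x$k_app), digits = 3), " M^-1 s^-1",
        sep = "")
  }
  cat("\n")
  print.data.frame(x, digits = digits, ...)
  invisible(x)
}
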