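#' Conventional TST rate constant
#'
#' k = sigma * kappa * (k_B T / h) * exp(-DeltaG'/ (R T)) with the activation
#' free energy referenced to the 1 M standard state, so the bimolecular rate
#' constant comes out directly in M^-1 s^-1. With sigma = kappa = 1 and
#' DeltaG' = 0 this is the bare frequency prefactor k_B T / h.
#'
#' @param delta_g_act Activation free energy, kcal mol^-1 (1 M standard state).
#' @param temperature Kelvin (default 298.15).
#' @param sigma Reaction-path degeneracy, integer >= 1 (default 1).
#' @param kappa Tunneling correction, >= 1 (default 1).
#' @return Rate constant, M^-1 s^-1.
#' @examples
#' tst_rate(7.2, kappa = 1.2)   # ~3.9e7 M^-1 s^-1
#' @export
tst_rate <- function(delta_g_act, temperature = 298.15, sigma = 1, kappa = 1) {
  stopifnot(is.numeric(delta_g_act), all(is.finite(delta_g_act)))
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop("temperature must be positive")
  }
  if (any(sigma < 1)) stop("sigma must be >= 1")
  if (any(kappa < 1)) stop("kappa must be >= 1 (no tunneling = 1)")
  pc <- phys_constants()
  sigma * kappa * kbt_over_h(temperature) *
    exp(-delta_g_act / (pc$R_kcal * temperature))
}

#' Wigner tunneling correction
#'
#' Lowest-order correction from the imaginary frequency at the saddle point:
#' kappa = 1 + u^2 / 24 with u = h c nu' / (k_B T). Valid for modest barrier
#' curvature (u not large); used here as the fallback when full Eckart barrier
#' parameters are unavailable.
#'
#' @param nu_imag Imaginary-frequency magnitude, cm^-1 (>= 0).
#' @param temperature Kelvin.
#' @return Dimensionless kappa >= 1.
#' @examples
#' wigner_kappa(1000, 298.15)  # ~1.97
#' @export
wigner_kappa <- function(nu_imag, temperature = 298.15) {
  stopifnot(is.numeric(nu_imag))
  if (any(nu_imag < 0)) stop("nu_imag must be >= 0")
  if (any(temperature <= 0)) stop("temperature must be positive")
  u <- wavenumber_u(nu_imag, temperature)
  1 + u^2 / 24
}

# hnu in kcal/mol per cm^-1: h * c * NA / 4184
.wavenumber_kcal <- function(nu_imag) {
  pc <- phys_constants()
  nu_imag * pc$h * pc$c_cm * pc$NA_ / pc$kcal_per_mol_J
}

# log(sinh(x)) and log(cosh(x)) safe for large x >= 0
.logsinh <- function(x) ifelse(x < 20, log(sinh(x)), x + log1p(-exp(-2 * x)) - log(2))
.logcosh <- function(x) ifelse(x < 20, log(cosh(x)), x + log1p(exp(-2 * x)) - log(2))
.logadd <- function(a, b) pmax(a, b) + log1p(exp(-abs(a - b)))

#' Transmission probability through an asymmetric Eckart barrier
#'
#' Two-parameter Eckart barrier fixed by the forward barrier V_f, reverse
#' barrier V_r and the magnitude of the imaginary frequency nu' at the saddle
#' point. Energies are measured from the reactant asymptote; the probability
#' is zero below the product asymptote max(0, V_f - V_r).
#'
#' @param energy Energy (kcal mol^-1), may be a vector.
#' @param v_forward,v_reverse Barrier heights, kcal mol^-1 (> 0).
#' @param nu_imag Imaginary-frequency magnitude, cm^-1 (> 0).
#' @return Transmission probability in [0, 1].
#' @export
eckart_transmission <- function(energy, v_forward, v_reverse, nu_imag) {
  if (v_forward <= 0 || v_reverse <= 0) stop("barriers must be > 0")
  if (nu_imag <= 0) stop("nu_imag must be > 0")
  w <- .wavenumber_kcal(nu_imag)
  alpha1 <- 2 * pi * v_forward / w
  alpha2 <- 2 * pi * v_reverse / w
  inv_d <- 1 / (1 / sqrt(alpha1) + 1 / sqrt(alpha2))
  e0 <- max(0, v_forward - v_reverse)
  p <- numeric(length(energy))
  open_ch <- energy > e0
  if (!any(open_ch)) return(p)
  e <- energy[open_ch]
  a <- 2 * sqrt(2 * pi * e / w) * inv_d
  b <- 2 * sqrt(2 * pi * (e - v_forward + v_reverse) / w) * inv_d
  d2 <- alpha1 * alpha2 - pi^2 / 4
  if (d2 >= 0) {
    d <- 2 * sqrt(d2)
    logp <- log(2) + .logsinh(a) + .logsinh(b) -
      .logadd(.logcosh(a + b), .logcosh(d))
  } else {
    # wide/low barrier: the "cosh(d)" term becomes cos(|d|), bounded by 1
    dcos <- cos(2 * sqrt(-d2))
    lc <- .logcosh(a + b)
    logp <- ifelse(a + b < 25,
                   log(2) + .logsinh(a) + .logsinh(b) - log(cosh(a + b) + dcos),
                   log(2) + .logsinh(a) + .logsinh(b) - lc)
  }
  p[open_ch] <- pmin(1, exp(logp))
  p
}

#' Eckart tunneling correction
#'
#' Boltzmann average of the asymmetric-Eckart transmission probability,
#' normalized by the classical one-dimensional flux over the barrier:
#' kappa = exp(V_f / RT) / (RT) * integral_0^Inf P(E) exp(-E / RT) dE.
#' The integral is evaluated adaptively on [max(0, V_f - V_r), V_f + 40 RT]
#' (the integrand decays as exp(-E/RT)), split at E = V_f where the integrand
#' changes character, with relative tolerance 1e-8.
#'
#' @param v_forward,v_reverse Barrier heights, kcal mol^-1 (> 0).
#' @param nu_imag Imaginary-frequency magnitude, cm^-1 (> 0).
#' @param temperature Kelvin.
#' @return Dimensionless kappa >= 1 (up to quadrature tolerance).
#' @examples
#' eckart_kappa(5, 25, 1200)   # strongly exothermic H-transfer-like barrier
#' @export
eckart_kappa <- function(v_forward, v_reverse, nu_imag, temperature = 298.15) {
  if (v_forward <= 0 || v_reverse <= 0 || nu_imag <= 0) {
    stop("v_forward, v_reverse and nu_imag must all be > 0")
  }
  if (temperature <= 0) stop("temperature must be positive")
  pc <- phys_constants()
  rt <- pc$R_kcal * temperature
  beta <- 1 / rt
  f <- function(e) {
    eckart_transmission(e, v_forward, v_reverse, nu_imag) * exp(-beta * e)
  }
  e0 <- max(0, v_forward - v_reverse)
  e_top <- v_forward + 40 * rt
  # the transmission switches from ~0 to ~1 over an energy window of order
  # h*nu around E = V_f; bracket that window so the quadrature resolves it
  # even in the near-classical (small nu) limit where it becomes a step
  width <- max(10 * .wavenumber_kcal(nu_imag), 1e-6)
  brk <- sort(unique(pmin(e_top, pmax(e0, c(e0, v_forward - width,
                                            v_forward + width, e_top)))))
  # absolute floor: raw-integral error below this changes kappa by < 1e-12
  negligible <- 1e-12 * rt * exp(-beta * v_forward)
  ints <- lapply(seq_len(length(brk) - 1), function(i) {
    stats::integrate(f, brk[i], brk[i + 1], rel.tol = 1e-10,
                     abs.tol = negligible, subdivisions = 500L,
                     stop.on.error = FALSE)
  })
  bad <- vapply(ints, function(z) {
    ok_msg <- z$message %in% c("OK", "roundoff error was detected")
    !ok_msg && !(abs(z$value) < negligible && z$abs.error < negligible)
  }, logical(1))
  if (any(bad)) {
    stop("Eckart quadrature did not converge: ",
         ints[[which(bad)[1]]]$message,
         " (V_f=", v_forward, ", V_r=", v_reverse, ", nu=", nu_imag, ")")
  }
  total <- sum(vapply(ints, `[[`, numeric(1), "value"))
  exp(beta * v_forward) * beta * total
}

#' Tunneling specification
#'
#' Declares how the tunneling correction is resolved for each channel:
#' \describe{
#'   \item{supplied}{use the channel's \code{kappa} column as-is (how tabulated
#'     literature corrections are consumed)}
#'   \item{wigner}{compute from the channel's \code{nu_imag}}
#'   \item{eckart}{compute from \code{v_forward}, \code{v_reverse},
#'     \code{nu_imag}}
#'   \item{none}{kappa = 1}
#' }
#' @param mode One of "supplied", "wigner", "eckart", "none".
#' @return An object of class \code{tunneling_spec}.
#' @export
tunneling_spec <- function(mode = c("supplied", "wigner", "eckart", "none")) {
  mode <- match.arg(mode)
  structure(list(mode = mode), class = "tunneling_spec")
}

#' Per-channel rate constants
#'
#' Evaluates conventional TST for every channel: \code{k_tst} is the bare
#' rate (no degeneracy, no tunneling), \code{k_act = sigma * kappa * k_tst}.
#' In gas-phase conditions \code{k_app = k_act} exactly (no encounter limit);
#' in a viscous medium the Smoluchowski encounter rate \code{k_diff} is
#' computed from the conditions and \code{k_app} is the Collins-Kimball
#' interpolation.
#'
#' @param channels A \code{channel_table} (typically the viable subset from
#'   \code{\link{screen_channels}}); every row needs \code{dg_act} and a
#'   resolvable tunneling correction.
#' @param cond A \code{conditions} object (default gas at 298.15 K).
#' @param tunneling A \code{tunneling_spec} (default "supplied").
#' @return A \code{rate_table} data.frame with columns site, mechanism,
#'   kappa, sigma, k_tst, k_act, k_diff, k_app, gamma (gamma NA until
#'   \code{\link{branching_ratios}} fills it).
#' @export
evaluate_channels <- function(channels, cond = conditions(),
                              tunneling = tunneling_spec("supplied")) {
  channels <- validate_channels(channels)
  stopifnot(inherits(cond, "conditions"), inherits(tunneling, "tunneling_spec"))
  n <- nrow(channels)
  if (n == 0) {
    out <- data.frame(site = character(0), mechanism = character(0),
                      kappa = numeric(0), sigma = integer(0),
                      k_tst = numeric(0), k_act = numeric(0),
                      k_diff = numeric(0), k_app = numeric(0),
                      gamma = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("rate_table", class(out))
    return(out)
  }
  no_act <- is.na(channels$dg_act)
  if (any(no_act)) {
    stop("channel '", channels$site[which(no_act)[1]],
         "' has no dg_act; kinetic evaluation needs an activation energy")
  }
  temp <- cond$temperature
  kap <- switch(tunneling$mode,
    supplied = {
      if (any(is.na(channels$kappa))) {
        stop("channel '", channels$site[which(is.na(channels$kappa))[1]],
             "' has no supplied kappa")
      }
      channels$kappa
    },
    wigner = {
      if (any(is.na(channels$nu_imag))) {
        stop("channel '", channels$site[which(is.na(channels$nu_imag))[1]],
             "' has no nu_imag for the Wigner correction")
      }
      wigner_kappa(channels$nu_imag, temp)
    },
    eckart = {
      need <- is.na(channels$v_forward) | is.na(channels$v_reverse) |
        is.na(channels$nu_imag)
      if (any(need)) {
        stop("channel '", channels$site[which(need)[1]],
             "' lacks Eckart barrier parameters (v_forward, v_reverse, nu_imag)")
      }
      mapply(eckart_kappa, channels$v_forward, channels$v_reverse,
             channels$nu_imag, MoreArgs = list(temperature = temp))
    },
    none = rep(1, n)
  )
  k_tst <- tst_rate(channels$dg_act, temp, sigma = 1, kappa = 1)
  k_act <- channels$sigma * kap * k_tst
  if (is_gas_phase(cond)) {
    k_diff <- rep(NA_real_, n)
    k_app <- k_act
  } else {
    kd <- diffusion_rate(cond)
    k_diff <- rep(kd, n)
    k_app <- collins_kimball(k_act, k_diff)
  }
  out <- data.frame(site = channels$site, mechanism = channels$mechanism,
                    kappa = kap, sigma = channels$sigma,
                    k_tst = k_tst, k_act = k_act,
                    k_diff = k_diff, k_app = k_app,
                    gamma = NA_real_, stringsAsFactors = FALSE)
  class(out) <- c("rate_table", class(out))
  out
}
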