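# run expr under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("seed must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate a reaction-channel table
#'
#' Seeded generator with the statistical structure the kinetics pipeline
#' assumes: reaction free energies uniform on a range spanning strongly
#' exothermic to moderately endothermic channels, activation energies tied to
#' them by a Bell-Evans-Polanyi-type linear free-energy relation
#' dG_act = a + b dG_rxn + eps (eps Gaussian, floored at 0), tunneling
#' corrections log-uniform on the supplied range, degeneracy 1. The linear
#' relation is a modeling convenience for exercising the pipeline, not a
#' physical claim.
#'
#' @param n_sites Number of channels (>= 1).
#' @param dg_rxn_range Range of dG_rxn, kcal mol^-1 (default -25..15).
#' @param bep_intercept,bep_slope Linear free-energy relation coefficients
#'   (defaults 10 and 0.4).
#' @param noise_sd Gaussian noise on dG_act, kcal mol^-1 (default 1).
#' @param kappa_range Tunneling-correction range (default 1.0..5.2).
#' @param seed Integer seed (required; determinism contract).
#' @param radical Radical label (default "HO").
#' @return A \code{channel_table} with n_sites rows, sites "S1".."Sn".
#' @export
simulate_channels <- function(n_sites = 24, dg_rxn_range = c(-25, 15),
                              bep_intercept = 10, bep_slope = 0.4,
                              noise_sd = 1, kappa_range = c(1.0, 5.2),
                              seed, radical = "HO") {
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (diff(range(dg_rxn_range)) < 0 || length(dg_rxn_range) != 2) {
    stop("dg_rxn_range must be an interval")
  }
  if (any(kappa_range < 1) || length(kappa_range) != 2) {
    stop("kappa_range must be an interval with lower bound >= 1")
  }
  .with_seed(seed, {
    dg_rxn <- stats::runif(n_sites, dg_rxn_range[1], dg_rxn_range[2])
    dg_act <- pmax(0, bep_intercept + bep_slope * dg_rxn +
                     stats::rnorm(n_sites, 0, noise_sd))
    kappa <- exp(stats::runif(n_sites, log(kappa_range[1]),
                              log(kappa_range[2])))
    mech <- sample(c("FHT", "RAF"), n_sites, replace = TRUE)
    channel_table(site = paste0("S", seq_len(n_sites)), mechanism = mech,
                  radical = radical, dg_rxn = dg_rxn, dg_act = dg_act,
                  kappa = kappa, sigma = 1L)
  })
}

#' Simulate a DPPH assay plate
#'
#' Scavenging percentages follow a four-parameter logistic with bottom 0
#' (SP = top / (1 + (EC50/c)^hill)); per-well Gaussian noise in SP points is
#' added, then absorbances are back-computed around a fixed control OD:
#' OD_1 = OD_0 (1 - SP/100), floored at 0 (absorbance cannot go negative).
#'
#' @param true_ec50 True EC50, microgram mL^-1 (> 0).
#' @param hill Hill slope (> 0, default 1).
#' @param top Upper plateau, percent (default 100).
#' @param concentrations Tested ladder, microgram mL^-1 (default the DPPH
#'   screen ladder 8/32/128/265).
#' @param noise_sd Additive noise in SP points (default 2).
#' @param n_replicates Wells per concentration (default 3).
#' @param od_control Control absorbance (default 0.8).
#' @param seed Integer seed (required).
#' @param compound Compound name (metadata).
#' @return An \code{assay_plate}.
#' @export
simulate_plate <- function(true_ec50, hill = 1, top = 100,
                           concentrations = c(8, 32, 128, 265),
                           noise_sd = 2, n_replicates = 3,
                           od_control = 0.8, seed, compound = "simulated") {
  if (true_ec50 <= 0 || hill <= 0) stop("true_ec50 and hill must be > 0")
  if (anyDuplicated(concentrations)) stop("concentrations must be distinct")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  conc <- rep(concentrations, each = n_replicates)
  sp_true <- .fpl(conc, top, true_ec50, hill)
  .with_seed(seed, {
    sp_obs <- sp_true + stats::rnorm(length(conc), 0, noise_sd)
    od <- pmax(0, od_control * (1 - sp_obs / 100))
    assay_plate(concentration = conc, od_sample = od,
                od_control = od_control,
                replicate = rep(seq_len(n_replicates),
                                times = length(concentrations)),
                compound = compound)
  })
}

#' Perturb a geometry with Cartesian Gaussian noise
#'
#' Adds independent N(0, sd) displacements to every coordinate; with sd = 0
#' the geometry is returned unchanged. Deterministic under a fixed seed.
#'
#' @param base A \code{molecule_geometry}.
#' @param noise_sd Displacement standard deviation, angstroms (>= 0).
#' @param seed Integer seed (required).
#' @return A perturbed \code{molecule_geometry} with the same labels.
#' @export
simulate_perturbed_geometry <- function(base, noise_sd, seed) {
  stopifnot(inherits(base, "molecule_geometry"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  .with_seed(seed, {
    coords <- base$coords +
      matrix(stats::rnorm(length(base$coords), 0, noise_sd),
             nrow = nrow(base$coords))
    molecule_geometry(base$labels, base$elements, coords)
  })
}

#' Regular polygon geometry
#'
#' Convenience constructor for test and example structures: an n-gon of given
#' circumradius in the z = 0 plane, optionally rotated/translated.
#'
#' @param n Number of vertices (default 6).
#' @param radius Circumradius, angstroms (default 1.39, aromatic C-C ring).
#' @param element Element symbol for every vertex (default "C").
#' @param prefix Label prefix (default element).
#' @return A \code{molecule_geometry}.
#' @export
polygon_geometry <- function(n = 6, radius = 1.39, element = "C",
                             prefix = element) {
  theta <- 2 * pi * (seq_len(n) - 1) / n
  molecule_geometry(paste0(prefix, seq_len(n)), rep(element, n),
                    cbind(radius * cos(theta), radius * sin(theta), 0))
}

#' Apply a rigid motion to a geometry
#'
#' Rotation about an axis through the origin followed by a translation.
#' Internal-coordinate metrics must be invariant under this map.
#'
#' @param g A \code{molecule_geometry}.
#' @param axis Rotation axis (length-3, need not be unit).
#' @param angle Rotation angle, degrees.
#' @param translation Length-3 translation vector, angstroms.
#' @return The transformed \code{molecule_geometry}.
#' @export
rigid_transform <- function(g, axis = c(0, 0, 1), angle = 0,
                            translation = c(0, 0, 0)) {
  stopifnot(inherits(g, "molecule_geometry"))
  ax <- axis / .vnorm(axis)
  th <- angle * pi / 180
  kmat <- matrix(c(0, -ax[3], ax[2],
                   ax[3], 0, -ax[1],
                   -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
  rot <- diag(3) + sin(th) * kmat + (1 - cos(th)) * (kmat %*% kmat)
  coords <- sweep(g$coords %*% t(rot), 2, -translation)
  molecule_geometry(g$labels, g$elements, coords)
}
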