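tmpfile <- function(ext = "") tempfile(fileext = ext)

# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# fixed-grid trapezoid evaluation of the Eckart thermal average
trapezoid_eckart_kappa <- function(v_forward, v_reverse, nu_imag,
                                   temperature = 298.15,
                                   n_points = 100001L) {
  rt <- 1.987204e-3 * temperature
  e0 <- max(0, v_forward - v_reverse)
  e_top <- v_forward + 40 * rt
  e <- seq(e0, e_top, length.out = n_points)
  fx <- eckart_transmission(e, v_forward, v_reverse, nu_imag) * exp(-e / rt)
  h <- e[2] - e[1]
  area <- h * (sum(fx) - 0.5 * fx[1] - 0.5 * fx[length(fx)])
  exp(v_forward / rt) / rt * area
}

# brute-force plane search: minimise the r.m.s. perpendicular distance over
# unit normals, refining a spherical grid around the running optimum
grid_search_plane_rmsd <- function(coords, levels = 8L, grid = 40L) {
  x <- sweep(coords, 2, colMeans(coords))
  rmsd_of <- function(theta, phi) {
    n <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
    sqrt(mean((x %*% n)^2))
  }
  t0 <- pi / 2; p0 <- 0; half_t <- pi / 2; half_p <- pi
  best <- Inf
  for (lvl in seq_len(levels)) {
    th <- seq(t0 - half_t, t0 + half_t, length.out = grid)
    ph <- seq(p0 - half_p, p0 + half_p, length.out = grid)
    vals <- outer(th, ph, Vectorize(rmsd_of))
    idx <- arrayInd(which.min(vals), dim(vals))
    t0 <- th[idx[1]]; p0 <- ph[idx[2]]
    best <- min(best, vals[idx])
    half_t <- half_t * 3 / (grid - 1)
    half_p <- half_p * 3 / (grid - 1)
  }
  best
}

# random rigid motion with a seeded generator (does not touch package code)
random_rigid_copy <- function(g, seed) {
  set.seed(seed)
  ax <- stats::rnorm(3)
  rigid_transform(g, axis = ax, angle = stats::runif(1, 0, 360),
                  translation = stats::rnorm(3, sd = 5))
}

gas_kinetics_fixture <- function() example_channels("HO_gas_kinetics")
lipid_fixture <- function() example_channels("HO_pentyl_ethanoate")
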