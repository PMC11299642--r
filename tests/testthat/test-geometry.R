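test_that("bond lengths, angles and dihedrals match constructed shapes", {
  g <- molecule_geometry(c("A", "B", "C", "D"), rep("C", 4),
                         rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                               c(2, 1, 0)))
  expect_equal(bond_length(g, "A", "B"), 1)
  expect_equal(bond_angle(g, "A", "B", "C"), 180)
  expect_equal(bond_angle(g, "B", "C", "D"), 90)
  # square corners: three consecutive vertices
  sq <- molecule_geometry(paste0("S", 1:4), rep("C", 4),
                          rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                                c(0, 1, 0)))
  expect_equal(bond_angle(sq, "S1", "S2", "S3"), 90)
  # cis/trans torsions
  butane_trans <- molecule_geometry(paste0("T", 1:4), rep("C", 4),
                                    rbind(c(0, 1, 0), c(0, 0, 0),
                                          c(1, 0, 0), c(1, -1, 0)))
  expect_equal(abs(dihedral(butane_trans, "T1", "T2", "T3", "T4")), 180)
  expect_error(bond_length(g, "A", "Z"), "unknown atom label")
  expect_error(dihedral(g, "A", "B", "C", "C3"), "unknown atom label")
})

test_that("internal coordinates are invariant under rigid motions", {
  g <- simulate_perturbed_geometry(polygon_geometry(8), 0.2, seed = 4)
  for (seed in 1:5) {
    h <- random_rigid_copy(g, seed)
    expect_equal(bond_length(h, "C1", "C4"), bond_length(g, "C1", "C4"),
                 tolerance = 1e-9)
    expect_equal(bond_angle(h, "C1", "C3", "C6"),
                 bond_angle(g, "C1", "C3", "C6"), tolerance = 1e-9)
    expect_equal(abs(dihedral(h, "C1", "C2", "C3", "C4")),
                 abs(dihedral(g, "C1", "C2", "C3", "C4")), tolerance = 1e-9)
    expect_equal(mean_plane_rmsd(h, h$labels), mean_plane_rmsd(g, g$labels),
                 tolerance = 1e-9)
  }
})

test_that("mean-plane r.m.s. deviation is zero iff coplanar and matches oracles", {
  hex <- polygon_geometry(6)
  expect_equal(mean_plane_rmsd(hex, hex$labels), 0, tolerance = 1e-12)
  # one atom pushed out of plane: grid-search oracle agreement
  coords <- hex$coords
  coords[1, 3] <- 0.1
  bumped <- molecule_geometry(hex$labels, hex$elements, coords)
  rmsd <- mean_plane_rmsd(bumped, bumped$labels)
  expect_gt(rmsd, 0)
  expect_equal(rmsd, grid_search_plane_rmsd(coords), tolerance = 1e-6)
  # eigen-decomposition oracle on random point sets
  for (seed in 1:5) {
    set.seed(seed)
    pts <- matrix(stats::rnorm(21), ncol = 3)
    g <- molecule_geometry(paste0("X", 1:7), rep("C", 7), pts)
    ctr <- sweep(pts, 2, colMeans(pts))
    lam_min <- min(eigen(crossprod(ctr), symmetric = TRUE)$values)
    expect_equal(mean_plane_rmsd(g, g$labels), sqrt(lam_min / 7),
                 tolerance = 1e-9)
  }
  expect_error(mean_plane_rmsd(hex, c("C1", "C2")), "3 atoms")
  line <- molecule_geometry(c("L1", "L2", "L3"), rep("C", 3),
                            rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_error(mean_plane_rmsd(line, line$labels), "collinear")
})

test_that("plane-plane angles reproduce constructed inclinations acutely", {
  hex1 <- polygon_geometry(6, prefix = "A")
  hex2 <- polygon_geometry(6, prefix = "B")
  both <- molecule_geometry(
    c(hex1$labels, hex2$labels), c(hex1$elements, hex2$elements),
    rbind(hex1$coords, rigid_transform(hex2, axis = c(1, 0, 0),
                                       angle = 57.83,
                                       translation = c(5, 0, 0))$coords))
  expect_equal(plane_plane_angle(both, hex1$labels, hex2$labels), 57.83,
               tolerance = 1e-6)
  # parallel and perpendicular references
  par <- molecule_geometry(
    c(hex1$labels, hex2$labels), c(hex1$elements, hex2$elements),
    rbind(hex1$coords, sweep(hex2$coords, 2, c(0, 0, 3), "+")))
  expect_equal(plane_plane_angle(par, hex1$labels, hex2$labels), 0,
               tolerance = 1e-9)
  perp <- molecule_geometry(
    c(hex1$labels, hex2$labels), c(hex1$elements, hex2$elements),
    rbind(hex1$coords, rigid_transform(hex2, axis = c(0, 1, 0), angle = 90,
                                       translation = c(5, 0, 0))$coords))
  expect_equal(plane_plane_angle(perp, hex1$labels, hex2$labels), 90,
               tolerance = 1e-9)
  # obtuse constructions still report the acute angle
  obt <- molecule_geometry(
    c(hex1$labels, hex2$labels), c(hex1$elements, hex2$elements),
    rbind(hex1$coords, rigid_transform(hex2, axis = c(1, 0, 0), angle = 120,
                                       translation = c(5, 0, 0))$coords))
  expect_equal(plane_plane_angle(obt, hex1$labels, hex2$labels), 60,
               tolerance = 1e-6)
})

test_that("hydrogen-bond geometry closes by the law of cosines", {
  # place D-H...A with d_DH = 0.93 A, d_HA = 2.35 A and a 150 deg angle at H;
  # the donor-acceptor distance then follows from the law of cosines
  ang <- 150 * pi / 180
  d <- c(-0.93, 0, 0)
  a <- 2.35 * c(cos(pi - ang), sin(pi - ang), 0)
  g <- molecule_geometry(c("C17", "H17", "O21"), c("C", "H", "O"),
                         rbind(d, c(0, 0, 0), a))
  hb <- hbond_geometry(g, "C17", "H17", "O21")
  expect_equal(hb$d_dh, 0.93, tolerance = 1e-9)
  expect_equal(hb$d_ha, 2.35, tolerance = 1e-9)
  expect_equal(hb$angle_dha, 150, tolerance = 0.5)
  expect_equal(hb$d_da,
               sqrt(0.93^2 + 2.35^2 - 2 * 0.93 * 2.35 * cos(ang)),
               tolerance = 1e-9)
  # collinear: angle 180 and distances additive
  lin <- molecule_geometry(c("D", "H", "A"), c("N", "H", "O"),
                           rbind(c(0, 0, 0), c(1, 0, 0), c(2.8, 0, 0)))
  hb2 <- hbond_geometry(lin, "D", "H", "A")
  expect_equal(hb2$angle_dha, 180)
  expect_equal(hb2$d_da, hb2$d_dh + hb2$d_ha)
  # triangle inequality on random geometries
  for (seed in 1:5) {
    rg <- simulate_perturbed_geometry(polygon_geometry(3, prefix = "R"), 0.5,
                                      seed = seed)
    hb3 <- hbond_geometry(rg, "R1", "R2", "R3")
    expect_lte(hb3$d_da, hb3$d_dh + hb3$d_ha + 1e-12)
  }
})

test_that("geometry comparison reports per-coordinate and maximum deviations", {
  hex <- polygon_geometry(6)
  bonds <- list(c("C1", "C2"), c("C2", "C3"), c("C1", "C4"))
  angles <- list(c("C1", "C2", "C3"), c("C2", "C3", "C4"))
  same <- compare_geometries(hex, hex, bonds, angles)
  expect_equal(same$max_bond_dev, 0)
  expect_equal(same$max_angle_dev, 0)
  # stretch one bond by exactly +0.02 A along its axis
  coords <- hex$coords
  dir <- (coords[2, ] - coords[1, ]) / sqrt(sum((coords[2, ] - coords[1, ])^2))
  coords[1, ] <- coords[1, ] - 0.02 * dir
  stretched <- molecule_geometry(hex$labels, hex$elements, coords)
  cmp <- compare_geometries(hex, stretched, bonds = list(c("C1", "C2")))
  expect_equal(cmp$max_bond_dev, 0.02, tolerance = 1e-9)
  expect_equal(cmp$bond_deviations$dev_pct, 100 * 0.02 / 1.39,
               tolerance = 1e-6)
  # invariant under independent rigid motions of either structure
  cmp2 <- compare_geometries(random_rigid_copy(hex, 21),
                             random_rigid_copy(stretched, 22),
                             bonds = list(c("C1", "C2")))
  expect_equal(cmp2$max_bond_dev, cmp$max_bond_dev, tolerance = 1e-9)
  # label mapping between differently named structures
  renamed <- molecule_geometry(paste0("X", 1:6), hex$elements, hex$coords)
  mapping <- stats::setNames(paste0("X", 1:6), hex$labels)
  cmp3 <- compare_geometries(hex, renamed, bonds, angles, mapping = mapping)
  expect_equal(cmp3$max_bond_dev, 0)
  expect_error(
    compare_geometries(hex, renamed, bonds = list(c("C1", "C2"))),
    "unknown atom label"
  )
})
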