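test_that("the TST rate reduces to the bare prefactor at zero barrier", {
  expect_equal(tst_rate(0, 298.15, 1, 1), 6.2124e12, tolerance = 1e-4)
  # adding RT ln(10) to the barrier divides the rate by exactly 10
  shift <- 1.987204e-3 * 298.15 * log(10)
  expect_equal(tst_rate(5 + shift), tst_rate(5) / 10, tolerance = 1e-12)
  # strictly decreasing in the barrier, linear in sigma and kappa
  expect_gt(tst_rate(4), tst_rate(4.1))
  expect_equal(tst_rate(6, sigma = 2, kappa = 1.5),
               3 * tst_rate(6), tolerance = 1e-12)
  expect_error(tst_rate(5, kappa = 0.5), "kappa")
  expect_error(tst_rate(5, sigma = 0), "sigma")
})

test_that("published gas-phase rate constants are reconstructed row-wise", {
  tab <- gas_kinetics_fixture()
  k <- tst_rate(tab$dg_act, 298.15, tab$sigma, tab$kappa)
  rel <- abs(k - tab$k_ref) / tab$k_ref
  # C4 and C19 print identical (dG_act, kappa) but rate constants 10% apart,
  # so at most one of the pair can be reconstructed; compare against the
  # mutually consistent rows
  consistent <- tab$site != "C19"
  expect_lt(max(rel[consistent]), 0.10)
  # spot values: aromatic addition at C5, alkyl H-abstraction with sigma = 3
  expect_equal(k[tab$site == "C5"], 3.98e7, tolerance = 0.10)
  expect_equal(k[tab$site == "C13"], 7.60e10, tolerance = 0.10)
  expect_equal(k[tab$site == "C24-H"], 7.83e5, tolerance = 0.10)
  # without the path degeneracy the alkyl site would be ~3x slower
  expect_equal(tst_rate(11.0, 298.15, 1, 5.2), 2.8e5, tolerance = 0.02)
})

test_that("degeneracy and tunneling enter multiplicatively and exchangeably", {
  expect_equal(tst_rate(7, sigma = 2, kappa = 1.3),
               tst_rate(7, sigma = 1, kappa = 2.6), tolerance = 1e-12)
})

test_that("the Wigner correction matches its closed form", {
  expect_equal(wigner_kappa(0, 298.15), 1.0)
  expect_equal(wigner_kappa(1000, 298.15), 1.9703, tolerance = 1e-3)
  # colder means more tunneling
  expect_gt(wigner_kappa(800, 149.075), wigner_kappa(800, 298.15))
  expect_error(wigner_kappa(-10), "nu_imag")
})

test_that("Eckart kappa approaches 1 as the barrier curvature vanishes", {
  expect_equal(eckart_kappa(5, 5, 0.1, 298.15), 1.0, tolerance = 1e-3)
})

test_that("Eckart agrees with Wigner in the small-curvature regime", {
  kap_e <- eckart_kappa(5, 5, 300, 298.15)
  kap_w <- wigner_kappa(300, 298.15)
  expect_equal(kap_e, kap_w, tolerance = 0.05)
})

test_that("adaptive Eckart quadrature matches a dense trapezoid oracle", {
  cases <- list(c(5, 5, 300), c(5, 25, 1200), c(8, 8, 1000),
                c(12, 4, 600), c(10, 10, 1500))
  for (p in cases) {
    adaptive <- eckart_kappa(p[1], p[2], p[3], 298.15)
    brute <- trapezoid_eckart_kappa(p[1], p[2], p[3], 298.15)
    expect_equal(adaptive, brute, tolerance = 1e-6)
    expect_gte(adaptive, 1 - 1e-9)
  }
  expect_error(eckart_kappa(-1, 5, 1000), "> 0")
  expect_error(eckart_kappa(5, 5, -100), "> 0")
})

test_that("channel evaluation produces k_act = sigma kappa k_tst in the gas phase", {
  tab <- gas_kinetics_fixture()
  rates <- evaluate_channels(tab, conditions())
  expect_equal(nrow(rates), nrow(tab))
  expect_equal(rates$k_act, rates$sigma * rates$kappa * rates$k_tst,
               tolerance = 1e-12)
  expect_equal(rates$k_app, rates$k_act, tolerance = 1e-15)  # no encounter limit
  expect_true(all(is.na(rates$k_diff)))
  expect_equal(rates$k_act[rates$site == "C13"], 7.2e10, tolerance = 0.02)

  expect_equal(nrow(evaluate_channels(tab[0, ], conditions())), 0)
  no_act <- channel_table("C9", "RAF", dg_rxn = -3)
  expect_error(evaluate_channels(no_act), "dg_act")
  no_eck <- channel_table("C9", "RAF", dg_rxn = -3, dg_act = 5)
  expect_error(evaluate_channels(no_eck, tunneling = tunneling_spec("eckart")),
               "C9")
})

test_that("tunneling modes resolve kappa from the right columns", {
  tab <- channel_table("C1", "RAF", dg_rxn = -5, dg_act = 6, nu_imag = 1000,
                       v_forward = 6, v_reverse = 20)
  r_none <- evaluate_channels(tab, tunneling = tunneling_spec("none"))
  expect_equal(r_none$kappa, 1)
  r_wig <- evaluate_channels(tab, tunneling = tunneling_spec("wigner"))
  expect_equal(r_wig$kappa, wigner_kappa(1000, 298.15))
  r_eck <- evaluate_channels(tab, tunneling = tunneling_spec("eckart"))
  expect_equal(r_eck$kappa, eckart_kappa(6, 20, 1000, 298.15))
  expect_error(evaluate_channels(tab, tunneling = tunneling_spec("supplied")),
               "kappa")
})
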