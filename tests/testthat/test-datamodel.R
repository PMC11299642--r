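test_that("constants give the 298.15 K TST prefactor", {
  expect_equal(kbt_over_h(298.15), 6.2124e12, tolerance = 1e-4)
  pc <- phys_constants()
  expect_equal(pc$R_kcal * 298.15, 0.59248, tolerance = 1e-4)
})

test_that("channel CSV reader parses rows, defaults and blanks", {
  path <- tmpfile()
  writeLines(c(
    "site,mechanism,radical,dG_rxn,dG_act,kappa,sigma,nu_imag,v_forward,v_reverse",
    "C23-H,FHT,HO,-21.7,4.1,2.5,3,,,",
    "C12,RAF,HO,-20.7,2.3,1.2,,,,"
  ), path)
  tab <- read_channels(path)
  expect_s3_class(tab, "channel_table")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$dg_rxn[1], -21.7)
  expect_equal(tab$dg_act[1], 4.1)
  expect_equal(tab$kappa[1], 2.5)
  expect_equal(tab$sigma, c(3L, 1L))        # blank sigma defaults to 1
  expect_true(is.na(tab$nu_imag[1]))
})

test_that("channel reader accepts empty tables and rejects bad rows", {
  hdr <- "site,mechanism,radical,dG_rxn,dG_act,kappa,sigma,nu_imag,v_forward,v_reverse"
  path <- tmpfile()
  writeLines(hdr, path)
  expect_equal(nrow(read_channels(path)), 0)

  writeLines(c(hdr, "C1,XYZ,HO,-1,,,1,,,"), path)
  expect_error(read_channels(path), "unknown mechanism 'XYZ'")

  writeLines(c(hdr, "C1,RAF,HO,abc,,,1,,,"), path)
  expect_error(read_channels(path), "non-numeric")

  writeLines(c(hdr, "C1,RAF,HO,-1,,,1,,,", "C1,RAF,HO,-2,,,1,,,"), path)
  expect_error(read_channels(path), "duplicate channel")

  expect_error(
    channel_table("SET", "SET", dg_rxn = 155.6, dg_act = 5),
    "SET"
  )
  expect_error(channel_table("C1", "RAF", kappa = 0.5), "kappa")
  expect_error(channel_table("C1", "RAF", sigma = 0), "sigma")
})

test_that("channel writer emits what the reader accepts (round trip)", {
  tab <- channel_table(site = c("C12", "C23-H", "SET"),
                       mechanism = c("RAF", "FHT", "SET"),
                       radical = "HO", dg_rxn = c(-20.7, -21.7, 155.6),
                       dg_act = c(2.3, 4.1, NA), kappa = c(1.2, 2.5, NA),
                       sigma = c(1L, 3L, 1L), nu_imag = c(NA, 1500, NA))
  path <- tmpfile()
  write_channels(tab, path)
  back <- read_channels(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})

test_that("conditions YAML applies defaults and validates", {
  path <- tmpfile()
  writeLines("medium: gas", path)
  cond <- read_conditions(path)
  expect_equal(cond$temperature, 298.15)
  expect_true(is_gas_phase(cond))

  writeLines(c("medium: pentyl ethanoate", "viscosity_Pa_s: 8.62e-4",
               "solute_radius_m: 4.0e-10", "radical_radius_m: 2.0e-10"), path)
  cond <- read_conditions(path)
  expect_false(is_gas_phase(cond))
  expect_equal(cond$viscosity, 8.62e-4)
  expect_equal(cond$reaction_distance, 6.0e-10)  # default = sum of radii

  writeLines("temperature_K: -5", path)
  expect_error(read_conditions(path), "temperature")
})

test_that("XYZ round trip preserves labels and coordinates to 1e-6 A", {
  g <- polygon_geometry(6)
  g <- simulate_perturbed_geometry(g, 0.3, seed = 11)
  path <- tmpfile(".xyz")
  write_xyz(g, path)
  back <- read_xyz(path)
  expect_equal(back$labels, g$labels)
  expect_lt(max(abs(back$coords - g$coords)), 1e-6)
})

test_that("XYZ reader handles labels, auto-numbering and malformed counts", {
  path <- tmpfile(".xyz")
  writeLines(c("3", "water-ish", "O 0 0 0", "H 0.96 0 0", "H -0.24 0.93 0"),
             path)
  g <- read_xyz(path)
  expect_equal(g$labels, c("O1", "H1", "H2"))
  expect_equal(unname(g$coords[2, 1]), 0.96)

  writeLines(c("5", "too few atoms", "O 0 0 0", "H 1 0 0"), path)
  expect_error(read_xyz(path), "count mismatch")
  writeLines(c("notanumber", "x", "O 0 0 0"), path)
  expect_error(read_xyz(path), "malformed")
})

test_that("report writer emits per-channel rows plus an overall summary", {
  res <- scavenging_kinetics(gas_kinetics_fixture())
  path <- tmpfile(".csv")
  write_report(res$rates, path)
  rep <- utils::read.csv(path)
  expect_equal(nrow(rep), nrow(res$rates) + 1)
  expect_equal(rep$site[nrow(rep)], "OVERALL")
  expect_equal(rep$k_app[nrow(rep)], res$k_overall, tolerance = 1e-12)

  jpath <- tmpfile(".json")
  write_report(res$rates, jpath)
  parsed <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(parsed$k_overall, res$k_overall, tolerance = 1e-9)
  expect_equal(nrow(parsed$channels), nrow(res$rates))
})
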