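test_that("delta 13C to atom% conversion matches the closed form", {
  # independent arithmetic: R = R_VPDB (d/1000 + 1); atom% = 100 R/(1+R)
  r_vpdb <- 0.0111802
  expect_equal(delta_to_atom_percent(0), 100 * r_vpdb / (1 + r_vpdb),
               tolerance = 1e-14)
  for (d in c(-50, -10, 0, 250, 2000)) {
    r <- r_vpdb * (d / 1000 + 1)
    expect_equal(delta_to_atom_percent(d), 100 * r / (1 + r), tolerance = 1e-14)
  }
  # alternative standard ratio is honoured
  expect_equal(delta_to_atom_percent(0, r_vpdb = 0.011237),
               100 * 0.011237 / 1.011237, tolerance = 1e-14)
})

test_that("delta/atom% round trip is exact and limits behave", {
  deltas <- seq(-50, 2000, length.out = 41)
  back <- atom_percent_to_delta(delta_to_atom_percent(deltas))
  expect_equal(back, deltas, tolerance = 1e-12)
  atoms <- c(0.5, 1.08, 1.1057, 3, 50, 99)
  expect_equal(delta_to_atom_percent(atom_percent_to_delta(atoms)), atoms,
               tolerance = 1e-12)
  # delta -> -1000 sends atom% to 0+
  expect_lt(delta_to_atom_percent(-1000 + 1e-9), 1e-10)
  expect_gt(delta_to_atom_percent(-1000 + 1e-9), 0)
  expect_error(delta_to_atom_percent(-1000), "-1000")
  expect_error(atom_percent_to_delta(0), "0, 100")
})

test_that("concentration-to-flux conversion reproduces ideal-gas arithmetic", {
  d <- incubation_design(temperature_c = 15, soil_mass_g = 20,
                         headspace_volume_l = 0.1)
  # hand computation: n_air = P V / (R T); 1 mmol/mol net over 2 h
  n_air <- 101325 * 0.1e-3 / (8.314462618 * 288.15)
  expected <- (1e-3 * n_air) * 12.011 * 1e6 / 20 / (2 / 24)
  expect_equal(concentration_to_cflux(1, 0, d, accumulation_hours = 2),
               expected, tolerance = 1e-12)
})

test_that("flux conversion is linear in net concentration and volume", {
  d <- incubation_design()
  base <- concentration_to_cflux(1.5, 0.5, d, accumulation_hours = 2)
  expect_equal(concentration_to_cflux(2.5, 0.5, d, accumulation_hours = 2),
               2 * base, tolerance = 1e-12)
  d2 <- incubation_design(headspace_volume_l = 2 * d$headspace_volume_l)
  expect_equal(concentration_to_cflux(1.5, 0.5, d2, accumulation_hours = 2),
               2 * base, tolerance = 1e-12)
  # zero net respiration
  expect_equal(concentration_to_cflux(0.8, 0.8, d), 0)
  # round trip through the inverse
  expect_equal(cflux_to_net_concentration(base, d, accumulation_hours = 2),
               1.0, tolerance = 1e-12)
})

test_that("negative net concentrations flag or fail by size", {
  d <- incubation_design()
  expect_error(concentration_to_cflux(0.4, 0.5, d), "negative net")
  expect_warning(out <- concentration_to_cflux(0.5 - 1e-12, 0.5, d),
                 "clamped")
  expect_equal(out, 0)
})

test_that("incubation reader accepts well-formed tables", {
  rows <- c(
    "s1,b1,control,1,1,0.8,,1.08,",
    "s1,b1,control,1,3,0.7,,1.08,",
    "s1,b2,glucose,1,1,1.2,,2.0,",
    "s1,b2,glucose,1,3,1.1,,1.9,",
    "s1,b3,blank,1,1,0.05,,1.08,",
    "s1,b3,blank,1,3,0.05,,1.08,"
  )
  x <- read_incubation_table(write_incubation_csv(rows), default_design)
  expect_equal(nrow(x), 6L)
  expect_setequal(unique(x$day), c(1, 3))

  # a full simulated schedule is inferred from the data
  case <- noiseless_case(1)
  expect_setequal(unique(case$records$day), c(1, 3, 8, 15, 35, 65))
})

test_that("incubation reader converts delta 13C to atom% at ingest", {
  rows <- c("s1,b1,control,1,1,0.8,,,0",
            "s1,b2,glucose,1,1,1.2,,2.0,")
  x <- read_incubation_table(write_incubation_csv(rows), default_design)
  expect_equal(x$atom_pc[1], delta_to_atom_percent(0), tolerance = 1e-12)
  expect_false("delta13c_permil" %in% names(x))
})

test_that("incubation reader rejects malformed tables with row context", {
  ok <- c("s1,b1,control,1,1,0.8,,1.08,",
          "s1,b2,glucose,1,1,1.2,,2.0,",
          "s1,b3,blank,1,1,0.05,,1.08,")
  expect_error(
    read_incubation_table(write_incubation_csv(
      c(ok, "s1,b4,glucose2,1,1,1.0,,2.0,"))),
    "row 4.*glucose2")
  expect_error(
    read_incubation_table(write_incubation_csv(
      c(ok, "s1,b1,control,1,1,0.7,,1.08,"))),
    "duplicate")
  expect_error(
    read_incubation_table(write_incubation_csv(
      c(ok, "s1,b5,control,2,1,,,1.08,"))),
    "neither")
  expect_error(
    read_incubation_table(write_incubation_csv(
      c(ok, "s1,b5,control,2,3,0.9,,1.2,-10"))),
    "not both")
  expect_error(
    read_incubation_table(write_incubation_csv(
      c(ok, "s1,b5,control,2,3,0.9,,,"))),
    "exactly one")
})

test_that("header-only incubation file yields an empty collection with a warning", {
  path <- write_incubation_csv(character())
  expect_warning(x <- read_incubation_table(path), "no rows")
  expect_equal(nrow(x), 0L)
})

test_that("covariate tables validate and round trip", {
  tr <- generate_transect(4, seed = 3)
  path <- tempfile(fileext = ".csv")
  readr::write_csv(tr$covariates, path)
  back <- read_covariates_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tr$covariates),
               tolerance = 1e-12)
  bad <- tr$covariates
  bad$group[5] <- "climate"
  expect_error(validate_covariates(bad), "unknown covariate group")
  expect_error(validate_covariates(rbind(tr$covariates, tr$covariates[1, ])),
               "duplicate")
})

test_that("design and config validation catch bad inputs", {
  expect_error(incubation_design(schedule = c(3, 1)), "increasing")
  expect_error(incubation_design(glucose_atom_pc = 0.5), "1, 100")
  expect_error(incubation_design(accumulation_hours = c(2, 8)), "match")
  cfg <- read_priming_config(NULL)
  expect_s3_class(cfg$design, "incubation_design")
  # YAML round trip honours overridden keys
  p <- tempfile(fileext = ".yaml")
  writeLines(c("design:", "  temperature_c: 20.0", "  schedule: [1, 5, 10]",
               "  accumulation_hours: 4.0",
               "constants:", "  r_vpdb: 0.011237"), p)
  cfg2 <- read_priming_config(p)
  expect_equal(cfg2$design$temperature_c, 20)
  expect_equal(cfg2$design$schedule, c(1, 5, 10))
  expect_equal(cfg2$constants$r_vpdb, 0.011237)
})
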