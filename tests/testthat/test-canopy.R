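test_that("stand WUE is the basal-area-weighted species mean", {
  single <- data.frame(species = "Avicennia germinans",
    basal_area_fraction = 1)
  expect_equal(stand_wue(single), 3.82)

  thirds <- data.frame(
    species = c("Avicennia germinans", "Laguncularia racemosa",
      "Rhizophora mangle"),
    basal_area_fraction = c(1, 1, 1) / 3)
  # hand-weighted mean oracle
  expect_equal(stand_wue(thirds), (3.82 + 4.57 + 5.15) / 3)

  degenerate <- data.frame(
    species = c("Avicennia germinans", "Laguncularia racemosa",
      "Rhizophora mangle"),
    basal_area_fraction = c(1, 0, 0))
  expect_equal(stand_wue(degenerate), 3.82)

  unknown <- data.frame(species = "Nypa fruticans", basal_area_fraction = 1)
  expect_error(stand_wue(unknown), class = "mangroflux_missing_species")
})

test_that("unit constants satisfy the molar identity", {
  const <- unit_constants()
  expect_lt(abs(const$mm_to_mol_h2o_per_m2 - 1000 / const$molar_mass_h2o),
    0.01)
  expect_error(unit_constants(mm_to_mol_h2o_per_m2 = 50),
    class = "mangroflux_invalid_input")
})

test_that("the transpiration-to-carbon unit chain is correct and linear", {
  expect_equal(npp_from_ec(0, 4.57), 0)
  # hand unit-chain oracle
  expect_equal(npp_from_ec(500, 4.57),
    500 * 55.51 * 0.00457 * 44.01 * 0.273 / 1000)
  expect_equal(npp_from_ec(500, 4.57), 1.524, tolerance = 1e-3)
  expect_equal(npp_from_ec(1000, 4.57), 2 * npp_from_ec(500, 4.57))
  expect_error(npp_from_ec(-1, 4.57), class = "mangroflux_invalid_input")
})

test_that("the unit chain and the calibrated slope agree in order of magnitude", {
  # g C per mm H2O at stand WUE 4.5 vs the model's 1000/384.59
  g_c_per_mm <- npp_from_ec(1, 4.5) * 1000
  implied <- 1000 / 384.59
  expect_lt(max(g_c_per_mm, implied) / min(g_c_per_mm, implied), 1.5)
})

test_that("the linear transpiration model evaluates and inverts", {
  m <- ec_npp_model()
  expect_equal(ec_from_npp(0, m), 33.56)
  expect_equal(ec_from_npp(1.0, m), 418.15)
  expect_equal(ec_from_npp(0.5, m), 225.855)
  expect_error(ec_from_npp(-0.1, m), class = "mangroflux_invalid_input")
  expect_error(ec_npp_model(slope = 0), class = "mangroflux_invalid_input")
})

test_that("npp_from_ec composes with its inverse to the identity", {
  wue <- 4.57
  const <- unit_constants()
  k <- const$mm_to_mol_h2o_per_m2 * (wue / 1000) * const$molar_mass_co2 *
    const$c_fraction / 1000
  ec <- c(10, 500, 1300)
  expect_equal(npp_from_ec(ec, wue, const) / k, ec, tolerance = 1e-12)
})

test_that("refitting noiseless model output recovers the model exactly", {
  npp <- c(0.2, 0.5, 0.9, 1.4, 2.0)
  pairs <- tibble::tibble(npp = npp, ec = ec_from_npp(npp))
  fit <- suppressWarnings(fit_ec_npp(pairs))
  expect_equal(fit$model$slope, 384.59, tolerance = 1e-9)
  expect_equal(fit$model$intercept, 33.56, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)

  expect_error(fit_ec_npp(pairs[1:2, ]), class = "mangroflux_invalid_input")
  same <- tibble::tibble(npp = rep(1, 4), ec = 1:4)
  expect_error(fit_ec_npp(same), class = "mangroflux_degenerate_fit")
})

test_that("small calibration noise keeps r-squared at the reported level", {
  withr::local_seed(11)
  npp <- runif(40, 0.2, 2.2)
  ec <- ec_from_npp(npp) + rnorm(40, 0, 25)
  fit <- fit_ec_npp(tibble::tibble(npp = npp, ec = ec))
  expect_gte(fit$r_squared, 0.955)
  expect_lt(fit$p_value, 0.001)
})

test_that("sap-flow slope fitting matches the two-point and OLS oracles", {
  two <- tibble::tibble(dbh_cm = c(8, 24), water_use_l_day = c(0.76, 9.31))
  fit <- fit_sapflow(two)
  expect_equal(fit$slope, (9.31 - 0.76) / (24 - 8))
  expect_equal(round(fit$slope, 2), 0.53)

  for (slope in c(1.4, 3.5)) {
    dbh <- seq(5, 45, by = 5)
    line <- tibble::tibble(dbh_cm = dbh, water_use_l_day = slope * dbh)
    expect_equal(suppressWarnings(fit_sapflow(line))$slope, slope, tolerance = 1e-12)
  }

  same <- tibble::tibble(dbh_cm = c(10, 10), water_use_l_day = c(1, 2))
  expect_error(fit_sapflow(same), class = "mangroflux_degenerate_fit")

  cfg <- generator_config(seed = 5)
  sap <- gen_sapflow(cfg, n = 200)
  fit2 <- fit_sapflow(sap)
  oracle <- oracle_ols(sap$dbh_cm, sap$water_use_l_day)
  expect_equal(fit2$slope, oracle[["slope"]], tolerance = 1e-9)
  expect_lt(abs(fit2$slope - 1.4), 0.1)
})

test_that("flux cross-check and efflux adjustment follow the stated arithmetic", {
  expect_equal(nee_cross_check(1.0, 1.0), tibble::tibble(abs_dev = 0, rel_dev = 0))
  chk <- nee_cross_check(1.2, 0.99)
  expect_equal(chk$abs_dev, 0.21)
  expect_equal(chk$rel_dev, 0.175)
  chk2 <- nee_cross_check(2.0, 1.0)
  expect_equal(chk2$abs_dev, 1.0)
  expect_equal(chk2$rel_dev, 0.5)
  expect_error(nee_cross_check(0, 1), class = "mangroflux_invalid_input")

  expect_equal(efflux_adjust(2.16, 1.2), 0.96)
  expect_equal(efflux_adjust(1.65, 0.8), 0.85)
  expect_equal(efflux_adjust(1.3, 0), 1.3)
  expect_warning(expect_equal(efflux_adjust(0.5, 1.2), -0.7))
})

test_that("site tables gain predicted transpiration per the model", {
  sites <- gen_site_table(generator_config(seed = 9, n_sites = 10))
  out <- add_site_ec(sites)
  expect_equal(out$ec_mm, 384.59 * sites$npp_total + 33.56)
})
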