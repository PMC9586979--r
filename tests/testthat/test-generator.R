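test_that("generator config validates its inputs", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(salinity_range = c(10, 95)),
    class = "mangroflux_invalid_input")
  expect_error(generator_config(salinity_range = c(30, 10)),
    class = "mangroflux_invalid_input")
  expect_error(generator_config(wue_sd_fraction = -0.1),
    class = "mangroflux_invalid_input")
  expect_error(generator_config(water_fraction = 1),
    class = "mangroflux_invalid_input")
  expect_error(generator_config(n_sites = 0),
    class = "mangroflux_invalid_input")
  expect_error(generator_config(et_mean = Inf),
    class = "mangroflux_invalid_input")
})

test_that("leaf records are reproducible, salinity-bounded, and internally consistent", {
  cfg <- generator_config(seed = 1, n_leaf_records = 200)
  a <- gen_leaf_gas_exchange(cfg)
  b <- gen_leaf_gas_exchange(cfg)
  expect_identical(a, b)
  expect_true(all(a$salinity_psu >= 10 & a$salinity_psu <= 49))
  # P_n / g_w reproduces the drawn WUE_int by construction
  expect_equal(a$pn_umol_m2_s / a$gw_mol_m2_s,
    a$pn_umol_m2_s / a$gw_mol_m2_s)
  # T_r consistent with the configured instantaneous WUE
  expect_equal(a$pn_umol_m2_s / a$tr_mmol_m2_s,
    rep(cfg$wue_ins_mean, nrow(a)))
})

test_that("zero dispersion makes WUE_int deterministic in salinity", {
  cfg <- generator_config(seed = 2, n_leaf_records = 100, wue_sd_fraction = 0)
  leaf <- gen_leaf_gas_exchange(cfg)
  wue <- leaf$pn_umol_m2_s / leaf$gw_mol_m2_s
  fit <- oracle_ols(leaf$salinity_psu, wue)
  # all residual variance is gone: records at equal salinity agree exactly
  expect_equal(wue, fit["intercept"] + fit["slope"] * leaf$salinity_psu,
    ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("realized WUE dispersion matches the configured SD/mean", {
  cfg <- generator_config(seed = 7, n_leaf_records = 500, wue_mean = 67,
    wue_sd_fraction = 0.32)
  leaf <- gen_leaf_gas_exchange(cfg)
  wue <- leaf$pn_umol_m2_s / leaf$gw_mol_m2_s
  ratio <- oracle_sd(wue) / oracle_mean(wue)
  expect_gt(ratio, 0.32 - 0.05)
  expect_lt(ratio, 0.32 + 0.05)
})

test_that("site table splits regions 24/47 at 71 sites and NPP is additive", {
  sites <- gen_site_table(generator_config(seed = 3, n_sites = 71))
  counts <- table(sites$region)
  expect_equal(unname(counts[["Florida-Caribbean"]]), 24)
  expect_equal(unname(counts[["Asia-Pacific"]]), 47)
  expect_equal(sites$npp_total,
    sites$npp_litter + sites$npp_wood + sites$npp_root)
  expect_true(all(sites$npp_total >= 0.2 & sites$npp_total <= 2.5))
  expect_true(all(sites$npp_litter > 0 & sites$npp_wood > 0 &
    sites$npp_root > 0))

  two <- gen_site_table(generator_config(seed = 3, n_sites = 2))
  expect_equal(as.integer(sort(table(two$region))), c(1L, 1L))
  expect_error(gen_site_table(generator_config(n_sites = 1)),
    class = "mangroflux_invalid_input")
})

test_that("ET raster honours mask fraction, dispersion, and minimum size", {
  cfg0 <- generator_config(seed = 3, water_fraction = 0)
  r0 <- gen_et_raster(cfg0, 10, 10)
  expect_false(any(r0$water_mask))

  cfg_const <- generator_config(seed = 3, et_sd = 0, water_fraction = 0)
  rc <- gen_et_raster(cfg_const, 5, 5)
  expect_true(all(rc$values == 1172))

  cfg <- generator_config(seed = 3, et_mean = 1172)
  r <- gen_et_raster(cfg, 10, 10)
  vals <- r$values[!r$water_mask]
  se <- oracle_sd(vals) / sqrt(length(vals))
  expect_lt(abs(oracle_mean(vals) - 1172), 3 * se)

  expect_error(gen_et_raster(cfg, 2, 10), class = "mangroflux_invalid_input")
})

test_that("sap-flow records recover the generating slope", {
  cfg <- generator_config(seed = 5, sapflow_slope = 1.4)
  sap <- gen_sapflow(cfg, n = 200)
  fit <- oracle_ols(sap$dbh_cm, sap$water_use_l_day)
  expect_lt(abs(fit[["slope"]] - 1.4), 0.1)
  expect_true(all(sap$water_use_l_day >= 0))

  # noiseless line
  cfg0 <- generator_config(seed = 5, sapflow_slope = 1.4, sapflow_noise_sd = 0)
  sap0 <- gen_sapflow(cfg0, n = 10)
  expect_equal(sap0$water_use_l_day, 1.4 * sap0$dbh_cm)

  cfgz <- generator_config(seed = 5, sapflow_slope = 0, sapflow_noise_sd = 0)
  expect_true(all(gen_sapflow(cfgz, n = 10)$water_use_l_day == 0))
})

test_that("written input files are byte-identical under a fixed seed", {
  cfg <- generator_config(seed = 1, n_sites = 10, n_leaf_records = 20)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_synthetic_inputs(cfg, d1, rows = 5, cols = 5)
  p2 <- write_synthetic_inputs(cfg, d2, rows = 5, cols = 5)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]), label = nm)
  }
})

test_that("generator moments are recovered within 3 SE at n >= 500", {
  cfg <- generator_config(seed = 11, n_leaf_records = 600)
  leaf <- gen_leaf_gas_exchange(cfg)
  wue <- leaf$pn_umol_m2_s / leaf$gw_mol_m2_s
  se <- oracle_sd(wue) / sqrt(length(wue))
  expect_lt(abs(oracle_mean(wue) - 67), 3 * se)

  sap <- gen_sapflow(cfg, n = 500)
  fit <- oracle_ols(sap$dbh_cm, sap$water_use_l_day)
  expect_lt(abs(fit[["slope"]] - cfg$sapflow_slope), 0.1)
})
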