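#' Configuration for the synthetic-data generator
#'
#' Bundles every generating parameter for the synthetic inputs that stand in
#' for the literature-derived tables the analysis consumes: leaf gas-exchange
#' records, the two-region site table of net primary productivity (NPP), a
#' water-masked annual evapotranspiration (ET) grid, and per-tree sap-flow
#' records. Defaults are the study conditions of the analysis: leaf records
#' spanning soil salinities of 10-49 psu with intrinsic water-use efficiency
#' (WUE) centred on 67 umol CO2 (mol H2O)^-1 and dispersion equal to 32% of
#' the mean; 71 sites split 24/47 between a Florida-Caribbean and an
#' Asia-Pacific region; ET averaging 1172 mm yr^-1; and tree water use rising
#' 1.4 L day^-1 per cm of stem diameter (dbh).
#'
#' A single `seed` drives all four generators through fixed per-stream
#' sub-seeds, so the full input set is reproducible from one integer.
#'
#' @param seed Integer seed for all streams.
#' @param n_sites Number of mangrove study sites.
#' @param n_leaf_records Number of leaf gas-exchange records.
#' @param salinity_range Length-2 numeric, porewater salinity bounds (psu),
#'   within `[0, 90]`.
#' @param wue_mean Target mean intrinsic WUE, umol CO2 (mol H2O)^-1.
#' @param wue_sd_fraction Target SD/mean of intrinsic WUE (dimensionless).
#' @param wue_salinity_slope Generating slope of intrinsic WUE on salinity,
#'   umol CO2 (mol H2O)^-1 psu^-1. The default rises from about 40 at 10 psu
#'   to about 95 at 49 psu, bracketing a mid-range median of 67.
#' @param wue_ins_mean Instantaneous WUE used to emit consistent leaf
#'   transpiration, mmol CO2 (mol H2O)^-1.
#' @param et_mean,et_sd Mean and SD of annual ET (mm yr^-1).
#' @param water_fraction Fraction of grid cells masked as open water, in
#'   `[0, 1)`.
#' @param sapflow_slope Tree water use per dbh, L day^-1 cm^-1.
#' @param sapflow_noise_sd SD of sap-flow noise, L day^-1.
#'
#' @return A list of class `generator_config`.
#' @examples
#' cfg <- generator_config(seed = 7, n_leaf_records = 100)
#' leaf <- gen_leaf_gas_exchange(cfg)
#' @export
generator_config <- function(seed = 1L,
                             n_sites = 71L,
                             n_leaf_records = 500L,
                             salinity_range = c(10, 49),
                             wue_mean = 67,
                             wue_sd_fraction = 0.32,
                             wue_salinity_slope = 55 / 39,
                             wue_ins_mean = 4.57,
                             et_mean = 1172,
                             et_sd = 150,
                             water_fraction = 0.3,
                             sapflow_slope = 1.4,
                             sapflow_noise_sd = 1.0) {
  check_number(seed, "seed")
  check_count(n_sites, "n_sites")
  check_count(n_leaf_records, "n_leaf_records")
  check_number(salinity_range, "salinity_range", lower = 0, upper = 90)
  if (length(salinity_range) != 2 || salinity_range[2] < salinity_range[1]) {
    abort("`salinity_range` must be (min, max) with max >= min.",
      class = "mangroflux_invalid_input")
  }
  check_number(wue_mean, "wue_mean", lower = 0)
  check_number(wue_sd_fraction, "wue_sd_fraction", lower = 0)
  check_number(wue_salinity_slope, "wue_salinity_slope", lower = 0)
  check_number(wue_ins_mean, "wue_ins_mean", lower = 0)
  check_number(et_mean, "et_mean", lower = 0)
  check_number(et_sd, "et_sd", lower = 0)
  check_number(water_fraction, "water_fraction", lower = 0)
  if (water_fraction >= 1) {
    abort("`water_fraction` must be < 1.", class = "mangroflux_invalid_input")
  }
  check_number(sapflow_slope, "sapflow_slope", lower = 0)
  check_number(sapflow_noise_sd, "sapflow_noise_sd", lower = 0)
  structure(
    list(
      seed = as.integer(seed), n_sites = as.integer(n_sites),
      n_leaf_records = as.integer(n_leaf_records),
      salinity_range = as.numeric(salinity_range),
      wue_mean = wue_mean, wue_sd_fraction = wue_sd_fraction,
      wue_salinity_slope = wue_salinity_slope, wue_ins_mean = wue_ins_mean,
      et_mean = et_mean, et_sd = et_sd, water_fraction = water_fraction,
      sapflow_slope = sapflow_slope, sapflow_noise_sd = sapflow_noise_sd
    ),
    class = "generator_config"
  )
}

check_generator_config <- function(config) {
  if (!inherits(config, "generator_config")) {
    abort("`config` must be created by `generator_config()`.",
      class = "mangroflux_invalid_input")
  }
  invisible(config)
}

mangrove_species_pool <- c(
  "Rhizophora mangle", "Avicennia germinans", "Laguncularia racemosa",
  "Bruguiera gymnorhiza", "Sonneratia alba", "Aegiceras corniculatum"
)

#' Generate synthetic leaf gas-exchange records
#'
#' Draws salinities uniformly over the configured range and intrinsic WUE as a
#' positive linear function of salinity plus Gaussian noise. The noise SD is
#' solved so the realized SD/mean matches `wue_sd_fraction`:
#' the salinity slope already contributes variance `b^2 * var(salinity)`, and
#' the residual variance makes up the difference (floored at zero, in which
#' case the realized dispersion exceeds the target). Net photosynthesis and
#' stomatal conductance are emitted so their ratio equals the drawn WUE, and
#' leaf transpiration is consistent with the configured instantaneous WUE.
#'
#' @param config A [generator_config()].
#' @return A tibble with columns `species`, `site`, `salinity_psu`,
#'   `pn_umol_m2_s`, `gw_mol_m2_s`, `tr_mmol_m2_s`, `ci_ul_l`.
#' @export
gen_leaf_gas_exchange <- function(config) {
  check_generator_config(config)
  withr::local_seed(substream_seed(config$seed, 1L))
  n <- config$n_leaf_records
  rng <- config$salinity_range
  salinity <- runif(n, rng[1], rng[2])
  b <- config$wue_salinity_slope
  a <- config$wue_mean - b * mean(rng)
  var_sal <- (rng[2] - rng[1])^2 / 12
  target_sd <- config$wue_sd_fraction * config$wue_mean
  noise_sd <- sqrt(max(target_sd^2 - b^2 * var_sal, 0))
  wue <- pmax(a + b * salinity + rnorm(n, 0, noise_sd), 0.1)
  gw <- runif(n, 0.05, 0.5)
  pn <- wue * gw
  tr <- pn / config$wue_ins_mean
  tibble(
    species = sample(mangrove_species_pool, n, replace = TRUE),
    site = paste0("S", sample.int(9, n, replace = TRUE)),
    salinity_psu = salinity,
    pn_umol_m2_s = pn,
    gw_mol_m2_s = gw,
    tr_mmol_m2_s = tr,
    ci_ul_l = runif(n, 150, 350)
  )
}

#' Generate a synthetic two-region site table
#'
#' Splits `n_sites` between a Florida-Caribbean and an Asia-Pacific region in
#' the 24:47 proportion of the study sites (rounded for other totals), and
#' draws per-site NPP totals from a positive-truncated normal restricted to a
#' plausible 0.2-2.5 kg C m^-2 yr^-1 band, partitioned into litter, wood and
#' root components that sum exactly to the total.
#'
#' @param config A [generator_config()]; requires `n_sites >= 2`.
#' @return A tibble with columns `site`, `region`, `lat`, `lon`,
#'   `salinity_psu`, `npp_litter`, `npp_wood`, `npp_root`, `npp_total`
#'   (kg C m^-2 yr^-1).
#' @export
gen_site_table <- function(config) {
  check_generator_config(config)
  if (config$n_sites < 2) {
    abort("`n_sites` must be >= 2.", class = "mangroflux_invalid_input")
  }
  withr::local_seed(substream_seed(config$seed, 2L))
  n <- config$n_sites
  n_fc <- as.integer(round(n * 24 / 71))
  n_fc <- max(1L, min(n - 1L, n_fc))
  region <- c(rep("Florida-Caribbean", n_fc), rep("Asia-Pacific", n - n_fc))
  total <- rnorm(n, 1.0, 0.45)
  bad <- which(total < 0.2 | total > 2.5)
  while (length(bad) > 0) {
    total[bad] <- rnorm(length(bad), 1.0, 0.45)
    bad <- which(total < 0.2 | total > 2.5)
  }
  # component shares: litter/wood/root around 30/40/30 with sampling noise
  shares <- matrix(stats::rgamma(3 * n, shape = c(6, 8, 6)), ncol = 3, byrow = TRUE)
  shares <- shares / rowSums(shares)
  litter <- total * shares[, 1]
  wood <- total * shares[, 2]
  root <- total * shares[, 3]
  lat <- ifelse(region == "Florida-Caribbean", runif(n, 9, 27), runif(n, -20, 25))
  lon <- ifelse(region == "Florida-Caribbean", runif(n, -88, -60), runif(n, 95, 160))
  tibble(
    site = sprintf("site_%03d", seq_len(n)),
    region = region,
    lat = lat, lon = lon,
    salinity_psu = runif(n, config$salinity_range[1], config$salinity_range[2]),
    npp_litter = litter, npp_wood = wood, npp_root = root,
    npp_total = litter + wood + root
  )
}

#' Generate a synthetic water-masked annual ET grid
#'
#' Annual ET values are drawn from a positive-truncated normal with the
#' configured mean and SD; a Boolean water mask flags approximately
#' `water_fraction` of cells as open water. Grids smaller than 3 x 3 are
#' rejected because the Moore neighborhood is undefined there.
#'
#' @param config A [generator_config()].
#' @param rows,cols Grid dimensions (>= 3).
#' @param origin Latitude/longitude of the north-west corner.
#' @return An [et_raster()] object.
#' @export
gen_et_raster <- function(config, rows = 30, cols = 30, origin = c(25, -81)) {
  check_generator_config(config)
  check_count(rows, "rows")
  check_count(cols, "cols")
  if (rows < 3 || cols < 3) {
    abort("`rows` and `cols` must both be >= 3 (neighborhood undefined).",
      class = "mangroflux_invalid_input")
  }
  withr::local_seed(substream_seed(config$seed, 3L))
  values <- matrix(rnorm_pos(rows * cols, config$et_mean, config$et_sd),
    nrow = rows, ncol = cols)
  mask <- matrix(runif(rows * cols) < config$water_fraction,
    nrow = rows, ncol = cols)
  if (all(mask)) mask[ceiling(rows / 2), ceiling(cols / 2)] <- FALSE
  et_raster(values, water_mask = mask, origin = origin)
}

#' Generate synthetic sap-flow records
#'
#' Tree water use is linear in stem diameter: `water_use = slope * dbh +`
#' Gaussian noise, floored at zero.
#'
#' @param config A [generator_config()].
#' @param dbh_range Length-2 positive numeric, dbh bounds in cm.
#' @param n Number of trees (>= 3).
#' @return A tibble with columns `tree_id`, `dbh_cm`, `water_use_l_day`.
#' @export
gen_sapflow <- function(config, dbh_range = c(5, 45), n = 200) {
  check_generator_config(config)
  check_number(dbh_range, "dbh_range", lower = .Machine$double.eps)
  check_count(n, "n")
  if (n < 3) abort("`n` must be >= 3.", class = "mangroflux_invalid_input")
  withr::local_seed(substream_seed(config$seed, 4L))
  dbh <- runif(n, dbh_range[1], dbh_range[2])
  wu <- pmax(config$sapflow_slope * dbh + rnorm(n, 0, config$sapflow_noise_sd), 0)
  tibble(tree_id = sprintf("tree_%03d", seq_len(n)), dbh_cm = dbh,
    water_use_l_day = wu)
}

round6 <- function(data) {
  mutate(data, across(dplyr::where(is.numeric), ~ round(.x, 6)))
}

#' Write the full synthetic input set to disk
#'
#' Writes `leaf_gasex.csv`, `sites.csv`, `sapflow.csv`, the ET grid as
#' `et_raster.csv` (row-major, north-west origin) with `et_mask.csv`, and a
#' `manifest.json` recording the configuration. Numeric columns are written
#' rounded to 6 decimals so repeated runs under the same seed are
#' byte-identical.
#'
#' @param config A [generator_config()].
#' @param dir Output directory (created if absent).
#' @param rows,cols ET grid dimensions.
#' @return Invisibly, a named character vector of the files written.
#' @export
write_synthetic_inputs <- function(config, dir, rows = 30, cols = 30) {
  check_generator_config(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  leaf <- round6(gen_leaf_gas_exchange(config))
  sites <- round6(gen_site_table(config))
  sap <- round6(gen_sapflow(config))
  raster <- gen_et_raster(config, rows, cols)
  paths <- c(
    leaf_gasex = file.path(dir, "leaf_gasex.csv"),
    sites = file.path(dir, "sites.csv"),
    sapflow = file.path(dir, "sapflow.csv"),
    et_raster = file.path(dir, "et_raster.csv"),
    et_mask = file.path(dir, "et_mask.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  readr::write_csv(leaf, paths[["leaf_gasex"]])
  readr::write_csv(sites, paths[["sites"]])
  readr::write_csv(sap, paths[["sapflow"]])
  write_et_raster(raster, paths[["et_raster"]], paths[["et_mask"]])
  jsonlite::write_json(
    list(generator = unclass(config), rows = rows, cols = cols),
    paths[["manifest"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
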