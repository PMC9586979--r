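#' Pipeline configuration
#'
#' Assembles the per-stage parameter blocks of the end-to-end pipeline:
#' generate synthetic inputs, convert site NPP to canopy transpiration, fit
#' the sap-flow slope, project transpiration against the ET grid, build the
#' ecoregional water account, and run the salinity sweep of the tree
#' simulator. All randomness flows from the single `seed`.
#'
#' @param seed Integer top-level seed.
#' @param out_dir Output directory for stage files and the run report.
#' @param stages Character subset of
#'   `c("gen_data", "convert", "project", "account", "simulate")`; stages
#'   always execute in this dependency order.
#' @param generator A [generator_config()]; its seed is overridden by `seed`.
#' @param raster_rows,raster_cols ET grid dimensions.
#' @param neighborhood ET extraction neighborhood, 1 or 9.
#' @param sd_fraction Potential-scenario dispersion fraction (default 0.32).
#' @param ecoregions_path Optional CSV path for the account stage; defaults
#'   to the packaged ecoregion table.
#' @param salinities Salinity grid for the simulation stage, psu.
#' @param sim_years Simulated years per salinity.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("mangroflux_run_"),
                            stages = c("gen_data", "convert", "project",
                              "account", "simulate"),
                            generator = generator_config(seed = seed),
                            raster_rows = 30, raster_cols = 30,
                            neighborhood = 9, sd_fraction = 0.32,
                            ecoregions_path = NULL,
                            salinities = seq(0, 80, by = 10),
                            sim_years = 200) {
  known <- c("gen_data", "convert", "project", "account", "simulate")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) {
    abort(sprintf("Unknown stage(s): %s", paste(bad, collapse = ", ")),
      class = "mangroflux_invalid_input")
  }
  generator$seed <- as.integer(seed)
  structure(
    list(seed = as.integer(seed), out_dir = out_dir,
      stages = known[known %in% stages], generator = generator,
      raster_rows = raster_rows, raster_cols = raster_cols,
      neighborhood = neighborhood, sd_fraction = sd_fraction,
      ecoregions_path = ecoregions_path, salinities = salinities,
      sim_years = sim_years),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path A `.yaml`/`.yml` or `.json` file whose top-level keys are
#'   [pipeline_config()] arguments (generator parameters under `generator`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path), class = "mangroflux_io_error")
  }
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  gen_args <- raw$generator %||% list()
  raw$generator <- NULL
  args <- raw
  if (length(gen_args) > 0) {
    args$generator <- do.call(generator_config,
      c(gen_args, list(seed = raw$seed %||% 1L)))
  }
  do.call(pipeline_config, args)
}

#' Validate a pipeline input file against a schema
#'
#' Checks column presence (order-insensitive) and value ranges without
#' modifying the data.
#'
#' @param path CSV file to check.
#' @param schema One of `"leaf_gasex"`, `"sites"`, `"sapflow"`,
#'   `"ecoregions"`, `"services"`.
#' @return A character vector of violations; empty means the file is valid.
#' @export
validate_inputs <- function(path, schema = c("leaf_gasex", "sites", "sapflow",
                                             "ecoregions", "services")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    abort(sprintf("Cannot read input file: %s", path),
      class = "mangroflux_io_error")
  }
  data <- tryCatch(readr::read_csv(path, show_col_types = FALSE),
    error = function(e) abort(sprintf("Cannot parse %s: %s", path,
      conditionMessage(e)), class = "mangroflux_io_error"))
  required <- switch(schema,
    leaf_gasex = c("species", "site", "salinity_psu", "pn_umol_m2_s",
      "gw_mol_m2_s"),
    sites = c("site", "region", "salinity_psu", "npp_litter", "npp_wood",
      "npp_root", "npp_total"),
    sapflow = c("tree_id", "dbh_cm", "water_use_l_day"),
    ecoregions = c("name", "ec_et_pct", "ec_et_sd", "n_studies", "et_mm",
      "area_ha"),
    services = c("ecosystem", "service", "value_usd_ha_yr"))
  violations <- character()
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    violations <- c(violations,
      sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
    return(violations)
  }
  range_check <- function(col, test, msg) {
    bad <- sum(!test(data[[col]]), na.rm = TRUE)
    if (bad > 0) sprintf("%d row(s) violate: %s", bad, msg) else character()
  }
  violations <- c(violations, switch(schema,
    leaf_gasex = c(
      range_check("salinity_psu", function(x) x >= 0, "salinity_psu >= 0"),
      range_check("gw_mol_m2_s", function(x) x > 0, "gw_mol_m2_s > 0")),
    sites = c(
      range_check("salinity_psu", function(x) x >= 0, "salinity_psu >= 0"),
      range_check("npp_total", function(x) x > 0, "npp_total > 0"),
      range_check("npp_litter", function(x) x > 0, "npp_litter > 0"),
      range_check("npp_wood", function(x) x > 0, "npp_wood > 0"),
      range_check("npp_root", function(x) x > 0, "npp_root > 0")),
    sapflow = c(
      range_check("dbh_cm", function(x) x > 0, "dbh_cm > 0"),
      range_check("water_use_l_day", function(x) x >= 0,
        "water_use_l_day >= 0")),
    ecoregions = c(
      range_check("ec_et_pct", function(x) x > 0 & x < 100,
        "0 < ec_et_pct < 100"),
      range_check("et_mm", function(x) x > 0, "et_mm > 0"),
      range_check("area_ha", function(x) x >= 0, "area_ha >= 0")),
    services = range_check("value_usd_ha_yr", function(x) x >= 0,
      "value_usd_ha_yr >= 0")))
  violations
}

stage_entry <- function(name, outputs, summary, data_for_checksum) {
  list(stage = name, outputs = unname(outputs), summary = summary,
    checksum = rlang::hash(data_for_checksum))
}

#' Run the pipeline end-to-end
#'
#' Executes the configured stages in dependency order, writes each stage's
#' outputs under `out_dir`, and collects per-stage summaries (counts, means,
#' table checksums) into a machine-readable report
#' (`run_report.json`). Identical configuration and seed give identical
#' outputs and checksums; logging is purely observational.
#'
#' @param config A [pipeline_config()], or a path to a YAML/JSON file for
#'   [read_pipeline_config()].
#' @return The report, a list of class `run_report`, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, stages = list())
  add <- function(entry) report$stages[[length(report$stages) + 1]] <<- entry
  ran <- function(stage) stage %in% config$stages

  fail <- function(stage, e) {
    abort(sprintf("Stage '%s' failed: %s", stage, conditionMessage(e)),
      class = "mangroflux_stage_error")
  }

  sites <- NULL; raster <- NULL

  if (ran("gen_data")) {
    tryCatch({
      paths <- write_synthetic_inputs(config$generator, config$out_dir,
        rows = config$raster_rows, cols = config$raster_cols)
      leaf <- gen_leaf_gas_exchange(config$generator)
      sites <- gen_site_table(config$generator)
      raster <- gen_et_raster(config$generator, config$raster_rows,
        config$raster_cols)
      add(stage_entry("gen_data", paths,
        list(n_leaf = nrow(leaf), n_sites = nrow(sites),
          raster_cells = length(raster$values),
          masked_cells = sum(raster$water_mask),
          et_mean_unmasked = mean(raster$values[!raster$water_mask])),
        list(leaf, sites, raster$values, raster$water_mask)))
    }, error = function(e) fail("gen_data", e))
  }

  if (ran("convert")) {
    tryCatch({
      if (is.null(sites)) {
        sites <- readr::read_csv(file.path(config$out_dir, "sites.csv"),
          show_col_types = FALSE)
      }
      sites <- add_site_ec(sites)
      sap <- gen_sapflow(config$generator)
      sap_fit <- fit_sapflow(sap)
      path <- file.path(config$out_dir, "sites_ec.csv")
      readr::write_csv(round6(sites), path)
      add(stage_entry("convert", path,
        list(n_sites = nrow(sites), mean_ec_mm = mean(sites$ec_mm),
          sapflow_slope_l_day_cm = sap_fit$slope),
        sites))
    }, error = function(e) fail("convert", e))
  }

  if (ran("project")) {
    tryCatch({
      if (is.null(raster)) {
        raster <- read_et_raster(file.path(config$out_dir, "et_raster.csv"),
          file.path(config$out_dir, "et_mask.csv"))
      }
      # assign each site a deterministic unmasked cell
      withr::local_seed(substream_seed(config$seed, 6L))
      land <- which(!raster$water_mask, arr.ind = TRUE)
      pick <- land[sample.int(nrow(land), nrow(sites), replace = TRUE), ,
        drop = FALSE]
      sites$row <- pick[, 1]
      sites$col <- pick[, 2]
      ratios <- project_sites(sites, raster, neighborhood = config$neighborhood)
      summ <- summarize_ratios(ratios)
      path <- file.path(config$out_dir, "ratios.csv")
      readr::write_csv(round6(ratios), path)
      add(stage_entry("project", path,
        list(n_sites = nrow(ratios), mean_ratio_pct = summ$mean_pct,
          se_ratio_pct = summ$se_pct,
          potential_ratio_pct = potential_ratio(summ$mean_pct,
            config$sd_fraction)),
        ratios))
    }, error = function(e) fail("project", e))
  }

  if (ran("account")) {
    tryCatch({
      eco <- ecoregion_table(config$ecoregions_path)
      acct <- build_account(eco)
      totals <- account_totals(acct)
      path <- file.path(config$out_dir, "water_account.csv")
      readr::write_csv(as_tibble(acct), path)
      add(stage_entry("account", path,
        list(n_ecoregions = nrow(acct),
          total_avg_gl = totals$total_avg_gl,
          total_pot_gl = totals$total_pot_gl),
        as_tibble(acct)))
    }, error = function(e) fail("account", e))
  }

  if (ran("simulate")) {
    tryCatch({
      cfg <- bettina_config(years = config$sim_years, seed = config$seed)
      sweep <- salinity_sweep(config$salinities, cfg)
      path <- file.path(config$out_dir, "salinity_sweep.csv")
      readr::write_csv(as_tibble(sweep), path)
      lo <- sweep$uptake_l_day[which.min(sweep$salinity_psu)]
      hi <- sweep$uptake_l_day[which.max(sweep$salinity_psu)]
      add(stage_entry("simulate", path,
        list(n_salinities = nrow(sweep),
          uptake_at_min_salinity_l_day = lo,
          uptake_at_max_salinity_l_day = hi,
          max_over_min_uptake = ifelse(lo > 0, hi / lo, NA_real_)),
        as_tibble(sweep)))
    }, error = function(e) fail("simulate", e))
  }

  report_path <- file.path(config$out_dir, "run_report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)
  structure(report, class = "run_report", path = report_path)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d): %d stage(s)\n", x$seed,
    length(x$stages)))
  for (s in x$stages) {
    cat(sprintf("  %-9s checksum %s\n", s$stage, substr(s$checksum, 1, 12)))
  }
  invisible(x)
}
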