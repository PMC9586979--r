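#' Packaged ecoregion water-use table
#'
#' The seven terrestrial ecoregions adjacent to mangroves with their
#' transpiration-to-ET ratios (percent, with SD), study counts, annual ET
#' (mm yr^-1) and the mangrove area associated with each ecoregion (ha), as
#' transcribed from the published global comparison table. These are the
#' inputs from which every reduction column is recomputed.
#'
#' @param path Optional CSV path with columns `name`, `ec_et_pct`,
#'   `ec_et_sd`, `n_studies`, `et_mm`, `area_ha`; defaults to the packaged
#'   table.
#' @return A tibble, one row per ecoregion.
#' @export
ecoregion_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ecoregions.csv",
    package = "mangroflux", mustWork = TRUE)
  out <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(out,
    c("name", "ec_et_pct", "ec_et_sd", "n_studies", "et_mm", "area_ha"),
    "ecoregion table")
  if (any(out$ec_et_pct <= 0 | out$ec_et_pct >= 100)) {
    abort("`ec_et_pct` must lie strictly between 0 and 100.",
      class = "mangroflux_invalid_input")
  }
  if (any(out$et_mm <= 0) || any(out$area_ha < 0)) {
    abort("`et_mm` must be > 0 and `area_ha` >= 0.",
      class = "mangroflux_invalid_input")
  }
  out
}

#' Mangrove reference ratios and ET
#'
#' The mangrove transpiration-to-ET reference used by the accounting engine:
#' the rounded average (43%) and low-salinity potential (57%) ratios and the
#' mangrove-area ET (1172 mm yr^-1). The rounded ratios are used in the table
#' arithmetic because only they reproduce the printed reduction cells (e.g.
#' 0.27 x 1076 = 290.52). Both published dispersion conventions are stored:
#' the table's +/-2 / +/-3 (SD) and the text's 3.0 / 4.0 (SE of the per-site
#' means); they are carried, not reconciled.
#'
#' @param avg_ratio_pct,potential_ratio_pct Reference ratios, percent;
#'   potential must be >= average.
#' @param et_mm Mangrove-area ET, mm yr^-1 (> 0).
#' @param avg_sd_pct,potential_sd_pct Tabled dispersion, percentage points.
#' @param avg_se_pct,potential_se_pct Reported SE of the per-site means.
#' @return A list of class `mangrove_reference`.
#' @export
mangrove_reference <- function(avg_ratio_pct = 43, potential_ratio_pct = 57,
                               et_mm = 1172,
                               avg_sd_pct = 2, potential_sd_pct = 3,
                               avg_se_pct = 3.0, potential_se_pct = 4.0) {
  check_number(avg_ratio_pct, "avg_ratio_pct", lower = .Machine$double.eps)
  check_number(potential_ratio_pct, "potential_ratio_pct",
    lower = .Machine$double.eps)
  if (potential_ratio_pct < avg_ratio_pct) {
    abort("`potential_ratio_pct` must be >= `avg_ratio_pct`.",
      class = "mangroflux_invalid_input")
  }
  check_number(et_mm, "et_mm", lower = .Machine$double.eps)
  structure(
    list(avg_ratio_pct = avg_ratio_pct,
      potential_ratio_pct = potential_ratio_pct, et_mm = et_mm,
      avg_sd_pct = avg_sd_pct, potential_sd_pct = potential_sd_pct,
      avg_se_pct = avg_se_pct, potential_se_pct = potential_se_pct),
    class = "mangrove_reference"
  )
}

#' Per-area water-use reduction of mangroves relative to an ecoregion
#'
#' `(eco_ratio - mangrove_ratio) / 100 * eco_et`, in mm H2O yr^-1. Negative
#' when the ecoregion transpires a smaller share of ET than the mangrove
#' reference.
#'
#' @param eco_ratio_pct Ecoregion transpiration-to-ET ratio, percent (> 0).
#' @param mangrove_ratio_pct Mangrove reference ratio, percent (> 0).
#' @param eco_et Ecoregion ET, mm yr^-1 (> 0).
#' @return Reduction in mm H2O yr^-1 (may be negative).
#' @examples
#' reduction_mm(70, 43, 1076) # 290.52
#' @export
reduction_mm <- function(eco_ratio_pct, mangrove_ratio_pct, eco_et) {
  check_number(eco_ratio_pct, "eco_ratio_pct", lower = .Machine$double.eps)
  check_number(mangrove_ratio_pct, "mangrove_ratio_pct",
    lower = .Machine$double.eps)
  check_number(eco_et, "eco_et", lower = .Machine$double.eps)
  (eco_ratio_pct - mangrove_ratio_pct) / 100 * eco_et
}

#' Convert mm of water over ground area to kL per hectare
#'
#' 1 mm = 1 L m^-2 = 10 kL ha^-1, so the conversion is exactly `10 * x`.
#'
#' @param x mm H2O yr^-1.
#' @return kL H2O ha^-1 yr^-1.
#' @examples
#' mm_to_kl_per_ha(290.52) # 2905.2
#' @export
mm_to_kl_per_ha <- function(x) {
  check_number(x, "x")
  10 * x
}

#' Scale a per-hectare volume to a global total
#'
#' `klha * area_ha / 1e6`, giving gigaliters per year.
#'
#' @param klha kL H2O ha^-1 yr^-1.
#' @param area_ha Mangrove area associated with the ecoregion, ha (>= 0).
#' @return GL H2O yr^-1.
#' @examples
#' scale_global(2905, 11233190) # 32632.42
#' @export
scale_global <- function(klha, area_ha) {
  check_number(klha, "klha")
  check_number(area_ha, "area_ha", lower = 0)
  klha * area_ha / 1e6
}

#' Build the ecoregional water account
#'
#' For each ecoregion and both scenarios (average and low-salinity
#' potential), chains [reduction_mm()] -> [mm_to_kl_per_ha()] ->
#' [scale_global()]. Totals are computed from unrounded per-row values, so
#' they can differ from the sum of display-rounded cells by up to about 0.1%.
#'
#' @param ecoregions A tibble as from [ecoregion_table()]; ecoregion names
#'   must be unique.
#' @param ref A [mangrove_reference()].
#' @return A tibble of class `water_account` with one row per ecoregion and
#'   columns `name`, `diff_avg_pct`, `diff_pot_pct`, `reduction_avg_mm`,
#'   `reduction_pot_mm`, `reduction_avg_klha`, `reduction_pot_klha`,
#'   `area_ha`, `global_avg_gl`, `global_pot_gl`. [glance()] returns the
#'   totals.
#' @examples
#' acct <- build_account()
#' glance(acct)
#' @export
build_account <- function(ecoregions = ecoregion_table(),
                          ref = mangrove_reference()) {
  stopifnot(inherits(ref, "mangrove_reference"))
  check_columns(ecoregions, c("name", "ec_et_pct", "et_mm", "area_ha"),
    "ecoregion table")
  if (nrow(ecoregions) < 1) {
    abort("At least one ecoregion is required.", class = "mangroflux_invalid_input")
  }
  if (anyDuplicated(ecoregions$name)) {
    abort("Duplicate ecoregion names.", class = "mangroflux_invalid_table")
  }
  rows <- mutate(as_tibble(ecoregions),
    diff_avg_pct = .data$ec_et_pct - ref$avg_ratio_pct,
    diff_pot_pct = .data$ec_et_pct - ref$potential_ratio_pct,
    reduction_avg_mm = reduction_mm(.data$ec_et_pct, ref$avg_ratio_pct, .data$et_mm),
    reduction_pot_mm = reduction_mm(.data$ec_et_pct, ref$potential_ratio_pct, .data$et_mm),
    reduction_avg_klha = mm_to_kl_per_ha(.data$reduction_avg_mm),
    reduction_pot_klha = mm_to_kl_per_ha(.data$reduction_pot_mm),
    global_avg_gl = scale_global(.data$reduction_avg_klha, .data$area_ha),
    global_pot_gl = scale_global(.data$reduction_pot_klha, .data$area_ha)
  )
  rows <- select(rows, "name", "diff_avg_pct", "diff_pot_pct",
    "reduction_avg_mm", "reduction_pot_mm", "reduction_avg_klha",
    "reduction_pot_klha", "area_ha", "global_avg_gl", "global_pot_gl")
  structure(rows,
    class = c("water_account", class(rows)),
    reference = ref,
    totals = tibble(
      total_avg_gl = sum(rows$global_avg_gl),
      total_pot_gl = sum(rows$global_pot_gl)))
}

#' Totals of a water account
#'
#' @param account A `water_account` from [build_account()].
#' @return A tibble with `total_avg_gl` and `total_pot_gl` (GL yr^-1).
#' @export
account_totals <- function(account) {
  stopifnot(inherits(account, "water_account"))
  attr(account, "totals")
}

#' Land-conversion water-use scenario
#'
#' Additional transpirational water loss when mangrove area is converted to a
#' vegetation type with a higher transpiration-to-ET ratio (the oil-palm
#' case by default: mature plantations transpire 53-70% of ET, versus the
#' mangrove 43%, over the 18,467 ha converted in southeast Asia, at the
#' mangrove-area ET of 1172 mm yr^-1).
#'
#' @param converted_ratio_range Length-2 percent bounds of the replacement
#'   vegetation's ratio.
#' @param mangrove_ratio_pct Mangrove reference ratio, percent.
#' @param et_mm ET over the converted area, mm yr^-1 (> 0).
#' @param area_ha Converted area, ha (>= 0).
#' @return A tibble with one row per bound: `converted_ratio_pct`,
#'   `difference_mm`, `difference_klha`, `additional_gl`.
#' @examples
#' conversion_scenario() # 21.6 and 58.4 GL yr^-1 at 1 decimal
#' @export
conversion_scenario <- function(converted_ratio_range = c(53, 70),
                                mangrove_ratio_pct = 43, et_mm = 1172,
                                area_ha = 18467) {
  check_number(converted_ratio_range, "converted_ratio_range",
    lower = .Machine$double.eps)
  check_number(et_mm, "et_mm", lower = .Machine$double.eps)
  check_number(area_ha, "area_ha", lower = 0)
  diff_mm <- (converted_ratio_range - mangrove_ratio_pct) / 100 * et_mm
  tibble(
    converted_ratio_pct = converted_ratio_range,
    difference_mm = diff_mm,
    difference_klha = mm_to_kl_per_ha(diff_mm),
    additional_gl = scale_global(mm_to_kl_per_ha(diff_mm), area_ha)
  )
}

#' Virtual water value of an ecosystem service
#'
#' The economic value generated per millimetre of canopy transpiration:
#' `value / ec`. Used to compare e.g. the food-production value per unit of
#' consumptive water between mangroves and terrestrial ecoregions.
#'
#' @param value_usd_ha_yr Service value, USD ha^-1 yr^-1 (>= 0).
#' @param ec_mm Canopy transpiration, mm H2O yr^-1 (> 0).
#' @return USD per mm of H2O.
#' @export
virtual_water_value <- function(value_usd_ha_yr, ec_mm) {
  check_number(value_usd_ha_yr, "value_usd_ha_yr", lower = 0)
  if (any(!is.finite(ec_mm)) || any(ec_mm <= 0)) {
    abort("`ec_mm` must be finite and > 0.",
      class = "mangroflux_invalid_denominator")
  }
  value_usd_ha_yr / ec_mm
}

#' Append virtual-water values to a services table
#'
#' @param services A data frame with columns `ecosystem`, `service`,
#'   `value_usd_ha_yr` and either an `ec_mm` column or the `ec_mm` argument.
#' @param ec_mm Canopy transpiration (scalar or per-row), mm yr^-1; used when
#'   the table has no `ec_mm` column.
#' @return The table with a `usd_per_mm` column appended.
#' @export
virtual_water <- function(services, ec_mm = NULL) {
  check_columns(services, c("ecosystem", "service", "value_usd_ha_yr"),
    "services table")
  services <- as_tibble(services)
  if (!"ec_mm" %in% names(services)) {
    if (is.null(ec_mm)) {
      abort("Provide `ec_mm` as a column or argument.",
        class = "mangroflux_invalid_input")
    }
    services$ec_mm <- ec_mm
  }
  mutate(services, usd_per_mm = virtual_water_value(.data$value_usd_ha_yr,
    .data$ec_mm))
}
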