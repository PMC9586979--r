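#' Species-level instantaneous WUE reference table
#'
#' Light-saturated, leaf-level instantaneous WUE for the three dominant
#' neotropical mangrove species, with standard errors:
#' *Avicennia germinans* 3.82 +/- 0.3, *Laguncularia racemosa* 4.57 +/- 0.3 and
#' *Rhizophora mangle* 5.15 +/- 0.4 mmol CO2 (mol H2O)^-1. Shipped as a CSV
#' (`species_wue.csv`) that users may extend with further species.
#'
#' @param path Optional path to a CSV with columns `species`,
#'   `wue_ins_mmol_mol`, `se`; defaults to the packaged table.
#' @return A tibble with columns `species`, `wue_ins_mmol_mol`, `se`.
#' @export
species_wue <- function(path = NULL) {
  path <- path %||% system.file("extdata", "species_wue.csv",
    package = "mangroflux", mustWork = TRUE)
  out <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(out, c("species", "wue_ins_mmol_mol", "se"), "species WUE table")
  if (any(out$wue_ins_mmol_mol <= 0)) {
    abort("`wue_ins_mmol_mol` must be > 0.", class = "mangroflux_invalid_input")
  }
  out
}

#' Basal-area-weighted stand WUE
#'
#' Stratifies species-level instantaneous WUE by the basal-area composition
#' of a stand. Fractions are normalized to sum to one.
#'
#' @param composition A data frame with columns `species` and
#'   `basal_area_fraction` (non-negative; normalized internally).
#' @param wue_table A species WUE table as from [species_wue()].
#' @return The stand-level instantaneous WUE, mmol CO2 (mol H2O)^-1.
#' @examples
#' stand_wue(data.frame(species = "Avicennia germinans",
#'                      basal_area_fraction = 1))
#' @export
stand_wue <- function(composition, wue_table = species_wue()) {
  check_columns(composition, c("species", "basal_area_fraction"), "composition")
  w <- composition$basal_area_fraction
  check_number(w, "basal_area_fraction", lower = 0)
  if (sum(w) <= 0) {
    abort("Basal-area fractions must sum to a positive value.",
      class = "mangroflux_invalid_input")
  }
  w <- w / sum(w)
  unknown <- setdiff(composition$species, wue_table$species)
  if (length(unknown) > 0) {
    abort(sprintf("Species missing from the WUE table: %s",
      paste(unknown, collapse = ", ")), class = "mangroflux_missing_species")
  }
  wue <- wue_table$wue_ins_mmol_mol[match(composition$species, wue_table$species)]
  sum(w * wue)
}

#' Molar unit-chain constants
#'
#' Constants of the transpiration-to-carbon conversion: molar masses of water
#' and CO2, the carbon fraction of CO2 as used in the accounting arithmetic
#' (0.273 exactly, as conventionally printed, rather than 12.011/44.01), and
#' the moles of water in 1 mm over 1 m^2 (1000 g / 18.015 g mol^-1 = 55.51).
#'
#' @param molar_mass_h2o,molar_mass_co2 g mol^-1.
#' @param c_fraction kg C per kg CO2.
#' @param mm_to_mol_h2o_per_m2 mol H2O m^-2 per mm; must equal
#'   `1000 / molar_mass_h2o` within 0.01.
#' @return A named list of constants.
#' @export
unit_constants <- function(molar_mass_h2o = 18.015, molar_mass_co2 = 44.01,
                           c_fraction = 0.273,
                           mm_to_mol_h2o_per_m2 = 55.51) {
  if (abs(mm_to_mol_h2o_per_m2 - 1000 / molar_mass_h2o) > 0.01) {
    abort("`mm_to_mol_h2o_per_m2` must equal 1000/molar_mass_h2o within 0.01.",
      class = "mangroflux_invalid_input")
  }
  list(molar_mass_h2o = molar_mass_h2o, molar_mass_co2 = molar_mass_co2,
    c_fraction = c_fraction, mm_to_mol_h2o_per_m2 = mm_to_mol_h2o_per_m2)
}

#' Convert canopy transpiration to NPP through the molar unit chain
#'
#' `NPP = E_c * 55.51 * (WUE_ins / 1000) * 44.01 * 0.273 / 1000`:
#' mm of water become mol H2O m^-2, instantaneous WUE (mmol CO2 per mol H2O)
#' converts those to mol CO2, the molar mass gives g CO2, the carbon fraction
#' gives g C, and the final division yields kg C m^-2 yr^-1.
#'
#' @param ec Canopy transpiration, mm H2O yr^-1 (>= 0).
#' @param wue Stand instantaneous WUE, mmol CO2 (mol H2O)^-1.
#' @param constants A list from [unit_constants()].
#' @return NPP in kg C m^-2 yr^-1.
#' @examples
#' npp_from_ec(500, 4.57) # about 1.524
#' @export
npp_from_ec <- function(ec, wue, constants = unit_constants()) {
  check_number(ec, "ec", lower = 0)
  check_number(wue, "wue", lower = 0)
  ec * constants$mm_to_mol_h2o_per_m2 * (wue / 1000) *
    constants$molar_mass_co2 * constants$c_fraction / 1000
}

#' Linear canopy-transpiration model on NPP
#'
#' The calibrated linear relationship `E_c = slope * NPP + intercept` with
#' `E_c` in mm H2O yr^-1 and NPP in kg C m^-2 yr^-1; the default coefficients
#' (384.59, 33.56) are the published calibration used to project mangrove
#' canopy transpiration from site NPP.
#'
#' @param slope mm H2O yr^-1 per (kg C m^-2 yr^-1); must be > 0.
#' @param intercept mm H2O yr^-1.
#' @return An object of class `ec_npp_model`.
#' @export
ec_npp_model <- function(slope = 384.59, intercept = 33.56) {
  check_number(slope, "slope", lower = .Machine$double.eps)
  check_number(intercept, "intercept")
  structure(list(slope = slope, intercept = intercept), class = "ec_npp_model")
}

#' @export
print.ec_npp_model <- function(x, ...) {
  cat(sprintf("E_c = %.4g * NPP + %.4g  (mm H2O yr^-1)\n", x$slope, x$intercept))
  invisible(x)
}

#' Predict canopy transpiration from NPP
#'
#' @param npp NPP, kg C m^-2 yr^-1 (>= 0). Vectorized.
#' @param model An [ec_npp_model()].
#' @return Canopy transpiration, mm H2O yr^-1.
#' @examples
#' ec_from_npp(0) # the model intercept, 33.56
#' @export
ec_from_npp <- function(npp, model = ec_npp_model()) {
  check_number(npp, "npp", lower = 0)
  model$slope * npp + model$intercept
}

#' Append predicted canopy transpiration to a site table
#'
#' @param sites A site tibble with an `npp_total` column.
#' @param model An [ec_npp_model()].
#' @return `sites` with an `ec_mm` column appended.
#' @export
add_site_ec <- function(sites, model = ec_npp_model()) {
  check_columns(sites, "npp_total", "site table")
  mutate(as_tibble(sites), ec_mm = ec_from_npp(.data$npp_total, model))
}

#' Fit the canopy transpiration vs NPP relationship
#'
#' OLS of `ec` on `npp` over paired observations, as used to calibrate the
#' predictive model. Requires at least three pairs with distinct NPP values.
#'
#' @param data A data frame of paired observations.
#' @param npp,ec Unquoted column names (defaults `npp`, `ec`).
#' @return An object of class `ec_npp_fit` containing an [ec_npp_model()]
#'   (`model`), `r_squared`, `p_value` of the slope, `n` and the `lm` fit.
#'   Supports [tidy()] and [glance()].
#' @export
fit_ec_npp <- function(data, npp = npp, ec = ec) {
  npp <- enquo(npp)
  ec <- enquo(ec)
  check_columns(data, c(as_name(npp), as_name(ec)), "data")
  df <- tibble(x = dplyr::pull(data, !!npp), y = dplyr::pull(data, !!ec))
  df <- filter(df, is.finite(.data$x), is.finite(.data$y))
  if (nrow(df) < 3) {
    abort("At least 3 (npp, ec) pairs are required.",
      class = "mangroflux_invalid_input")
  }
  if (length(unique(df$x)) < 2) {
    abort("All NPP values are identical; the design is singular.",
      class = "mangroflux_degenerate_fit")
  }
  fit <- lm(y ~ x, data = df)
  sm <- summary(fit)
  structure(
    list(
      model = ec_npp_model(unname(coef(fit)[2]), unname(coef(fit)[1])),
      r_squared = sm$r.squared,
      p_value = sm$coefficients[2, 4],
      n = nrow(df),
      lm = fit
    ),
    class = "ec_npp_fit"
  )
}

#' @export
print.ec_npp_fit <- function(x, ...) {
  print(x$model)
  cat(sprintf("  r^2 = %.4f, slope p = %.3g, n = %d\n",
    x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Fit tree water use per unit stem diameter
#'
#' OLS slope of individual tree water use (L day^-1) on dbh (cm); for exactly
#' two distinct points this equals the finite-difference slope. Display
#' rounding of the slope is to 2 decimals (round-half-even, R's default).
#'
#' @param data A data frame of sap-flow records.
#' @param dbh,water_use Unquoted columns (defaults `dbh_cm`, `water_use_l_day`).
#' @return An object of class `sapflow_fit` with `slope`
#'   (L day^-1 cm^-1), `intercept`, `r_squared`, `n`, and the `lm` fit.
#'   Supports [tidy()] and [glance()].
#' @examples
#' fit <- fit_sapflow(data.frame(dbh_cm = c(8, 24),
#'                               water_use_l_day = c(0.76, 9.31)))
#' round(fit$slope, 2) # 0.53
#' @export
fit_sapflow <- function(data, dbh = dbh_cm, water_use = water_use_l_day) {
  dbh <- enquo(dbh)
  water_use <- enquo(water_use)
  check_columns(data, c(as_name(dbh), as_name(water_use)), "data")
  df <- tibble(x = dplyr::pull(data, !!dbh), y = dplyr::pull(data, !!water_use))
  df <- filter(df, is.finite(.data$x), is.finite(.data$y))
  if (nrow(df) < 2 || length(unique(df$x)) < 2) {
    abort("At least 2 records with distinct dbh are required.",
      class = "mangroflux_degenerate_fit")
  }
  fit <- lm(y ~ x, data = df)
  sm <- summary(fit)
  structure(
    list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = sm$r.squared,
      n = nrow(df),
      lm = fit
    ),
    class = "sapflow_fit"
  )
}

#' @export
print.sapflow_fit <- function(x, ...) {
  cat(sprintf("Tree water use: %.2f L day^-1 cm^-1 of dbh (n = %d, r^2 = %.3f)\n",
    x$slope, x$n, x$r_squared))
  invisible(x)
}

#' Cross-check predicted NPP against a flux-derived estimate
#'
#' Absolute deviation between the transpiration-predicted NPP and an
#' independently measured (e.g. eddy-covariance-derived) NPP, and the same
#' deviation relative to the prediction.
#'
#' @param npp_predicted Predicted NPP, kg C m^-2 (> 0).
#' @param npp_flux_derived Flux-derived NPP, kg C m^-2.
#' @return A tibble with columns `abs_dev` and `rel_dev` (fraction of
#'   predicted).
#' @export
nee_cross_check <- function(npp_predicted, npp_flux_derived) {
  check_number(npp_predicted, "npp_predicted", lower = .Machine$double.eps)
  check_number(npp_flux_derived, "npp_flux_derived")
  abs_dev <- abs(npp_predicted - npp_flux_derived)
  tibble(abs_dev = abs_dev, rel_dev = abs_dev / npp_predicted)
}

#' Subtract soil and pneumatophore CO2 efflux from a gross carbon estimate
#'
#' Period accounting (annual or partial-year) is the caller's responsibility;
#' both operands must cover the same period. A negative result is returned
#' but flagged with a warning.
#'
#' @param gross_c Gross carbon estimate, kg C m^-2 per period (>= 0).
#' @param efflux Soil + pneumatophore CO2 efflux, kg C m^-2 per period (>= 0).
#' @return `gross_c - efflux`.
#' @examples
#' efflux_adjust(2.16, 1.2) # 0.96
#' @export
efflux_adjust <- function(gross_c, efflux) {
  check_number(gross_c, "gross_c", lower = 0)
  check_number(efflux, "efflux", lower = 0)
  out <- gross_c - efflux
  if (any(out < 0)) {
    warn("Efflux exceeds the gross carbon estimate; negative NPP returned.")
  }
  out
}
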