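#' Intrinsic water-use efficiency
#'
#' The ratio of net photosynthesis to stomatal conductance to water vapor.
#' With `p_n` in umol CO2 m^-2 s^-1 and `g_w` in mol H2O m^-2 s^-1 the result
#' is in umol CO2 (mol H2O)^-1.
#'
#' @param p_n Net photosynthesis, umol CO2 m^-2 s^-1.
#' @param g_w Stomatal conductance, mol H2O m^-2 s^-1 (> 0).
#' @return Numeric vector of intrinsic WUE values.
#' @examples
#' wue_int(10, 0.2) # 50
#' @export
wue_int <- function(p_n, g_w) {
  if (any(!is.finite(p_n)) || any(!is.finite(g_w)) || any(g_w <= 0)) {
    abort("`g_w` must be finite and > 0 (and `p_n` finite).",
      class = "mangroflux_invalid_record")
  }
  p_n / g_w
}

#' Instantaneous water-use efficiency
#'
#' The ratio of net photosynthesis to leaf transpiration. With `p_n` in
#' umol CO2 m^-2 s^-1 and `t_r` in mmol H2O m^-2 s^-1 the ratio umol/mmol is
#' numerically identical to mmol CO2 (mol H2O)^-1, so the conversion factor
#' is exactly 1; no silent power-of-ten rescaling is applied.
#'
#' @param p_n Net photosynthesis, umol CO2 m^-2 s^-1.
#' @param t_r Leaf transpiration, mmol H2O m^-2 s^-1 (> 0, not missing).
#' @return Numeric vector, mmol CO2 (mol H2O)^-1.
#' @examples
#' wue_ins(3.82, 1.0) # 3.82
#' @export
wue_ins <- function(p_n, t_r) {
  if (any(is.na(t_r)) || any(!is.finite(t_r)) || any(t_r <= 0) ||
      any(!is.finite(p_n))) {
    abort("`t_r` must be present, finite and > 0 (and `p_n` finite).",
      class = "mangroflux_invalid_record")
  }
  p_n / t_r
}

#' Add WUE columns to a leaf gas-exchange table
#'
#' Computes per-record intrinsic WUE (where conductance is positive) and
#' instantaneous WUE (where transpiration is present and positive). Records
#' missing an optional field are retained with `NA` in the derived column and
#' the count of such records is reported.
#'
#' @param data A data frame with columns `pn_umol_m2_s`, `gw_mol_m2_s` and
#'   optionally `tr_mmol_m2_s`.
#' @return The input as a tibble with `wue_int` and (when transpiration is
#'   available) `wue_ins` columns appended.
#' @export
add_wue <- function(data) {
  check_columns(data, c("pn_umol_m2_s", "gw_mol_m2_s"), "leaf gas-exchange data")
  data <- as_tibble(data)
  ok_gw <- is.finite(data$gw_mol_m2_s) & data$gw_mol_m2_s > 0
  data$wue_int <- ifelse(ok_gw, data$pn_umol_m2_s / data$gw_mol_m2_s, NA_real_)
  if (any(!ok_gw)) {
    inform(sprintf("%d record(s) lack positive stomatal conductance; wue_int set to NA.",
      sum(!ok_gw)))
  }
  if ("tr_mmol_m2_s" %in% names(data)) {
    ok_tr <- is.finite(data$tr_mmol_m2_s) & data$tr_mmol_m2_s > 0
    data$wue_ins <- ifelse(ok_tr, data$pn_umol_m2_s / data$tr_mmol_m2_s, NA_real_)
    if (any(!ok_tr)) {
      inform(sprintf("%d record(s) lack positive transpiration; wue_ins set to NA.",
        sum(!ok_tr)))
    }
  }
  data
}

#' Summarize a WUE distribution
#'
#' Computes the box statistics used throughout the analysis: count, mean,
#' median, sample SD (n - 1 denominator), first and third quartiles by
#' linearly interpolated order statistics (type-7 quantiles), and the ratio
#' SD/mean. Missing values are dropped with a reported count. Optionally
#' grouped, e.g. by species or site.
#'
#' @param data A data frame of leaf records.
#' @param value Unquoted column to summarize (default `wue_int`).
#' @param group_by Optional unquoted grouping column.
#' @return A tibble with columns `n`, `mean`, `median`, `sd`, `q1`, `q3`,
#'   `sd_over_mean` (one row per group).
#' @export
wue_summary <- function(data, value = wue_int, group_by = NULL) {
  value <- enquo(value)
  group_by <- enquo(group_by)
  check_columns(data, as_name(value), "data")
  x <- as_tibble(data)
  n_na <- sum(is.na(dplyr::pull(x, !!value)))
  if (n_na > 0) {
    inform(sprintf("%d record(s) with missing values dropped.", n_na))
    x <- filter(x, !is.na(!!value))
  }
  if (nrow(x) == 0) {
    abort("No data to summarize.", class = "mangroflux_no_data")
  }
  if (!rlang::quo_is_null(group_by)) x <- group_by(x, !!group_by)
  out <- summarise(x,
    n = dplyr::n(),
    mean = mean(!!value),
    median = median(!!value),
    sd = sd(!!value),
    q1 = quantile(!!value, 0.25, type = 7, names = FALSE),
    q3 = quantile(!!value, 0.75, type = 7, names = FALSE),
    .groups = "drop")
  mutate(out,
    sd = ifelse(n == 1, 0, sd),
    sd_over_mean = ifelse(mean > 0, sd / mean, NA_real_))
}

#' Fit the salinity response of intrinsic WUE
#'
#' Ordinary least squares of WUE on porewater salinity. The positive slope of
#' this relationship is what motivates the low-salinity "potential"
#' transpiration scenario: leaves become more water-use efficient as root-zone
#' salinity rises, so fresher porewater implies higher canopy transpiration
#' for the same carbon gain.
#'
#' @param data A data frame with the WUE and salinity columns.
#' @param value Unquoted WUE column (default `wue_int`).
#' @param salinity Unquoted salinity column (default `salinity_psu`).
#' @return An object of class `wue_salinity_fit` with elements `slope`,
#'   `intercept`, `r_squared`, `p_value` (slope), `n`, and the underlying
#'   `lm` fit. Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_salinity_response <- function(data, value = wue_int, salinity = salinity_psu) {
  value <- enquo(value)
  salinity <- enquo(salinity)
  check_columns(data, c(as_name(value), as_name(salinity)), "data")
  df <- tibble(
    y = dplyr::pull(data, !!value),
    s = dplyr::pull(data, !!salinity))
  df <- filter(df, is.finite(.data$y), is.finite(.data$s))
  if (nrow(df) < 3) {
    abort("At least 3 complete records are required.",
      class = "mangroflux_invalid_input")
  }
  if (length(unique(df$s)) < 2) {
    abort("All salinities are identical; the fit is singular.",
      class = "mangroflux_singular_fit")
  }
  fit <- lm(y ~ s, data = df)
  sm <- summary(fit)
  structure(
    list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = sm$r.squared,
      p_value = sm$coefficients[2, 4],
      n = nrow(df),
      model = fit
    ),
    class = "wue_salinity_fit"
  )
}

#' @export
print.wue_salinity_fit <- function(x, ...) {
  cat("Intrinsic WUE ~ salinity (OLS)\n")
  cat(sprintf("  slope     %.4f umol mol^-1 psu^-1 (p = %.3g)\n", x$slope, x$p_value))
  cat(sprintf("  intercept %.4f umol mol^-1\n", x$intercept))
  cat(sprintf("  r^2       %.4f   n = %d\n", x$r_squared, x$n))
  invisible(x)
}
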