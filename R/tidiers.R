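# broom-style tidiers for the package's fitted objects.

tidy_lm_inner <- function(fit) {
  sm <- summary(fit)$coefficients
  tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p.value = unname(sm[, "Pr(>|t|)"])
  )
}

#' Tidy a WUE-salinity fit
#'
#' @param x A `wue_salinity_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model term.
#' @method tidy wue_salinity_fit
#' @export
tidy.wue_salinity_fit <- function(x, ...) {
  out <- tidy_lm_inner(x$model)
  out$term <- c("(Intercept)", "salinity_psu")
  out
}

#' @rdname tidy.wue_salinity_fit
#' @method glance wue_salinity_fit
#' @export
glance.wue_salinity_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, p.value = x$p_value, nobs = x$n,
    slope = x$slope, intercept = x$intercept)
}

#' Tidy a canopy transpiration vs NPP fit
#'
#' @param x An `ec_npp_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model term.
#' @method tidy ec_npp_fit
#' @export
tidy.ec_npp_fit <- function(x, ...) {
  out <- tidy_lm_inner(x$lm)
  out$term <- c("(Intercept)", "npp")
  out
}

#' @rdname tidy.ec_npp_fit
#' @method glance ec_npp_fit
#' @export
glance.ec_npp_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, p.value = x$p_value, nobs = x$n,
    slope = x$model$slope, intercept = x$model$intercept)
}

#' Tidy a sap-flow per-dbh fit
#'
#' @param x A `sapflow_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model term.
#' @method tidy sapflow_fit
#' @export
tidy.sapflow_fit <- function(x, ...) {
  out <- tidy_lm_inner(x$lm)
  out$term <- c("(Intercept)", "dbh_cm")
  out
}

#' @rdname tidy.sapflow_fit
#' @method glance sapflow_fit
#' @export
glance.sapflow_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, nobs = x$n, slope = x$slope,
    intercept = x$intercept)
}

#' Totals of a water account, as glance()
#'
#' @param x A `water_account`.
#' @param ... Unused.
#' @return A one-row tibble with `total_avg_gl` and `total_pot_gl`.
#' @method glance water_account
#' @export
glance.water_account <- function(x, ...) {
  account_totals(x)
}
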