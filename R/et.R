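#' Gridded annual evapotranspiration raster
#'
#' A light-weight container for a 1-km gridded annual ET product: a numeric
#' matrix of mm H2O yr^-1, a Boolean water mask of the same shape (TRUE =
#' open-water cell, excluded from all extraction), the latitude/longitude of
#' the north-west corner and the cell size in km.
#'
#' @param values Numeric matrix, mm H2O yr^-1; unmasked cells must be > 0.
#' @param water_mask Logical matrix of the same dimensions, or `NULL` for no
#'   water.
#' @param origin Length-2 numeric `(lat, lon)` of the NW corner.
#' @param cell_size Cell size in km (default 1).
#' @return An object of class `et_raster`.
#' @export
et_raster <- function(values, water_mask = NULL, origin = c(0, 0),
                      cell_size = 1) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.", class = "mangroflux_invalid_input")
  }
  if (is.null(water_mask)) {
    water_mask <- matrix(FALSE, nrow(values), ncol(values))
  }
  if (!is.matrix(water_mask) || !is.logical(water_mask) ||
      !all(dim(water_mask) == dim(values))) {
    abort("`water_mask` must be a logical matrix matching `values`.",
      class = "mangroflux_invalid_input")
  }
  if (any(values[!water_mask] <= 0, na.rm = TRUE)) {
    abort("Unmasked ET values must be > 0.", class = "mangroflux_invalid_input")
  }
  check_number(origin, "origin")
  check_number(cell_size, "cell_size", lower = .Machine$double.eps)
  structure(
    list(values = values, water_mask = water_mask,
      origin = as.numeric(origin), cell_size = cell_size),
    class = "et_raster"
  )
}

#' @export
print.et_raster <- function(x, ...) {
  cat(sprintf("ET raster: %d x %d cells of %g km, %d water-masked\n",
    nrow(x$values), ncol(x$values), x$cell_size, sum(x$water_mask)))
  cat(sprintf("  NW origin (%.3f, %.3f); unmasked mean %.1f mm yr^-1\n",
    x$origin[1], x$origin[2], mean(x$values[!x$water_mask])))
  invisible(x)
}

#' Write / read an ET raster as plain CSV grids
#'
#' The value grid is written row-major from the north-west origin, one raster
#' row per CSV line, no header; the mask is written the same way as 0/1.
#'
#' @param raster An [et_raster()].
#' @param values_path,mask_path Output CSV paths.
#' @return Invisibly, the paths written.
#' @export
write_et_raster <- function(raster, values_path, mask_path) {
  utils::write.table(round(raster$values, 6), values_path, sep = ",",
    row.names = FALSE, col.names = FALSE)
  utils::write.table(raster$water_mask * 1L, mask_path, sep = ",",
    row.names = FALSE, col.names = FALSE)
  invisible(c(values_path, mask_path))
}

#' @rdname write_et_raster
#' @param origin,cell_size Passed to [et_raster()].
#' @export
read_et_raster <- function(values_path, mask_path = NULL, origin = c(0, 0),
                           cell_size = 1) {
  values <- as.matrix(utils::read.table(values_path, sep = ","))
  dimnames(values) <- NULL
  mask <- NULL
  if (!is.null(mask_path)) {
    mask <- as.matrix(utils::read.table(mask_path, sep = ",")) == 1
    dimnames(mask) <- NULL
  }
  et_raster(values, mask, origin = origin, cell_size = cell_size)
}

#' Extract ET for a site cell with the Moore-neighborhood rule
#'
#' With `neighborhood = 1` the focal cell value is returned. With
#' `neighborhood = 9` the unweighted mean of the focal cell and its up-to-8
#' neighbors is returned, excluding out-of-bounds cells and cells flagged as
#' open water (ET cannot be compared with canopy transpiration there). A
#' masked or out-of-bounds focal cell is an error.
#'
#' @param raster An [et_raster()].
#' @param row,col Focal cell indices (1-based from the NW corner).
#' @param neighborhood 1 or 9.
#' @return A one-row tibble with `et_mm` and `cells_used`.
#' @export
extract_et <- function(raster, row, col, neighborhood = 9) {
  stopifnot(inherits(raster, "et_raster"))
  if (!neighborhood %in% c(1, 9)) {
    abort("`neighborhood` must be 1 or 9.", class = "mangroflux_invalid_input")
  }
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  if (row < 1 || row > nr || col < 1 || col > nc) {
    abort("Focal cell is out of bounds.", class = "mangroflux_no_land_cell")
  }
  if (raster$water_mask[row, col]) {
    abort("Focal cell is water-masked; no land cell to extract.",
      class = "mangroflux_no_land_cell")
  }
  if (neighborhood == 1) {
    return(tibble(et_mm = raster$values[row, col], cells_used = 1L))
  }
  rows <- max(1, row - 1):min(nr, row + 1)
  cols <- max(1, col - 1):min(nc, col + 1)
  sub_v <- raster$values[rows, cols, drop = FALSE]
  sub_m <- raster$water_mask[rows, cols, drop = FALSE]
  tibble(et_mm = mean(sub_v[!sub_m]), cells_used = sum(!sub_m))
}

#' Map latitude/longitude to the nearest raster cell
#'
#' Nearest-cell assignment from the north-west origin, row-major, using
#' 111.32 km per degree of latitude and the cosine of the origin latitude for
#' longitude (adequate at the 1-km scale of the product).
#'
#' @param raster An [et_raster()].
#' @param lat,lon Coordinates (vectorized).
#' @return A tibble with columns `row` and `col`, clamped to the grid.
#' @export
cell_from_latlon <- function(raster, lat, lon) {
  km_lat <- 111.32
  km_lon <- 111.32 * cos(raster$origin[1] * pi / 180)
  row <- floor((raster$origin[1] - lat) * km_lat / raster$cell_size) + 1L
  col <- floor((lon - raster$origin[2]) * km_lon / raster$cell_size) + 1L
  tibble(
    row = pmin(pmax(as.integer(row), 1L), nrow(raster$values)),
    col = pmin(pmax(as.integer(col), 1L), ncol(raster$values)))
}

#' Canopy-transpiration-to-ET ratio
#'
#' @param ec Canopy transpiration, mm yr^-1 (>= 0).
#' @param et Evapotranspiration, mm yr^-1 (> 0).
#' @return The ratio as a percentage, `100 * ec / et`.
#' @examples
#' round(ec_et_ratio(872, 1378)) # 63
#' @export
ec_et_ratio <- function(ec, et) {
  check_number(ec, "ec", lower = 0)
  if (any(!is.finite(et)) || any(et <= 0)) {
    abort("`et` must be finite and > 0.", class = "mangroflux_invalid_denominator")
  }
  100 * ec / et
}

#' Low-salinity "potential" ratio adjustment
#'
#' Re-scales the dispersion of leaf-level intrinsic WUE along the salinity
#' gradient (SD expressed as a fraction of the mean, 0.32 in the source
#' analysis) onto the mean transpiration-to-ET ratio and adds it, giving the
#' ratio expected if porewaters freshened: `mean_ratio * (1 + sd_fraction)`.
#' Because the adjustment is linear it can equivalently be applied per site
#' before averaging; both entry points are exposed (apply this function to a
#' vector of per-site ratios for the per-site route).
#'
#' @param mean_ratio Mean ratio, percent (> 0).
#' @param sd_fraction SD as a fraction of the mean (>= 0); default 0.32.
#' @return The adjusted ratio, percent.
#' @examples
#' potential_ratio(43.4) # 57.29
#' @export
potential_ratio <- function(mean_ratio, sd_fraction = 0.32) {
  check_number(mean_ratio, "mean_ratio", lower = .Machine$double.eps)
  check_number(sd_fraction, "sd_fraction", lower = 0)
  mean_ratio * (1 + sd_fraction)
}

#' Mean and standard error of site ratios
#'
#' @param x A numeric vector of per-site ratios (percent), or a data frame
#'   with a `ratio_pct` column.
#' @return A tibble with `mean_pct`, `se_pct` (sd/sqrt(n)) and `n`.
#' @export
summarize_ratios <- function(x) {
  if (is.data.frame(x)) {
    check_columns(x, "ratio_pct", "ratio results")
    x <- x$ratio_pct
  }
  x <- x[is.finite(x)]
  if (length(x) < 2) {
    abort("At least 2 ratios are required to estimate a standard error.",
      class = "mangroflux_no_variance")
  }
  tibble(mean_pct = mean(x), se_pct = sd(x) / sqrt(length(x)),
    n = length(x))
}

#' Project site canopy transpiration against gridded ET
#'
#' For each site, extracts ET at its raster cell (by `row`/`col` columns if
#' present, otherwise by nearest-cell lookup from `lat`/`lon`) with the
#' requested neighborhood rule, and computes the per-site
#' transpiration-to-ET ratio.
#'
#' @param sites A site tibble with an `ec_mm` column (see [add_site_ec()])
#'   and either `row`+`col` or `lat`+`lon` columns.
#' @param raster An [et_raster()].
#' @param neighborhood 1 or 9 (default 9).
#' @return A tibble with columns `site`, `ec_mm`, `et_mm`, `ratio_pct`,
#'   `cells_used`.
#' @export
project_sites <- function(sites, raster, neighborhood = 9) {
  check_columns(sites, "ec_mm", "site table")
  sites <- as_tibble(sites)
  if (!all(c("row", "col") %in% names(sites))) {
    check_columns(sites, c("lat", "lon"), "site table")
    cells <- cell_from_latlon(raster, sites$lat, sites$lon)
    sites$row <- cells$row
    sites$col <- cells$col
  }
  extracted <- purrr::map2(sites$row, sites$col,
    ~ extract_et(raster, .x, .y, neighborhood = neighborhood))
  extracted <- bind_rows(extracted)
  tibble(
    site = if ("site" %in% names(sites)) sites$site else
      sprintf("site_%03d", seq_len(nrow(sites))),
    ec_mm = sites$ec_mm,
    et_mm = extracted$et_mm,
    ratio_pct = ec_et_ratio(sites$ec_mm, extracted$et_mm),
    cells_used = extracted$cells_used
  )
}
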