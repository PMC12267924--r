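#' Define the occupancy grid
#'
#' A global longitude/latitude grid used for area-of-occupancy (AOO)
#' estimation. The default cell size of 0.7 decimal degrees gives
#' (111.195 * 0.7)^2 ~ 6058 km2 per cell at the equator, i.e. the
#' "c. 6000 km2 at the equator" resolution used for the range analyses.
#' Cell areas shrink poleward with the cosine of the cell-centre latitude.
#'
#' @param cell_size_deg cell edge length in decimal degrees (default 0.7).
#' @param lon0,lat0 grid origin (default -180, -90).
#' @return an object of class `grid_spec`.
#' @export
#' @examples
#' g <- grid_spec()
#' cell_area_km2(g, lat_row = cell_index(g, 0, 0)$row) # ~6058 km2
grid_spec <- function(cell_size_deg = 0.7, lon0 = -180, lat0 = -90) {
  assert_scalar_number(cell_size_deg, "cell_size_deg", min = 1e-6, max = 90)
  structure(
    list(cell_size_deg = cell_size_deg, lon0 = lon0, lat0 = lat0,
         km_per_deg = 111.195),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  eq <- (x$km_per_deg * x$cell_size_deg)^2
  cat(sprintf("<grid_spec> %.3f deg cells, origin (%g, %g), %.0f km2 at equator\n",
              x$cell_size_deg, x$lon0, x$lat0, eq))
  invisible(x)
}

#' Map coordinates to grid cell indices
#'
#' @param grid a [grid_spec()].
#' @param lon,lat numeric vectors of coordinates (equal length).
#' @return a tibble with integer columns `col`, `row`. Points exactly on the
#'   far edge of the grid (lon = 180, lat = 90) are assigned to the last cell.
#' @export
cell_index <- function(grid, lon, lat) {
  cs <- grid$cell_size_deg
  col <- floor((lon - grid$lon0) / cs)
  row <- floor((lat - grid$lat0) / cs)
  # close the far edges so lon = 180 / lat = 90 stay on the grid
  ncol_max <- floor((180 - grid$lon0) / cs + 1e-9) - 1
  nrow_max <- floor((90 - grid$lat0) / cs + 1e-9) - 1
  tibble::tibble(col = as.integer(pmin(col, ncol_max)),
                 row = as.integer(pmin(row, nrow_max)))
}

#' Per-cell area in km2
#'
#' Area model: `(111.195 * cell_size)^2 * cos(latitude of cell centre)`.
#'
#' @param grid a [grid_spec()].
#' @param lat_row integer row indices (from [cell_index()]).
#' @return numeric vector of areas in km2.
#' @export
cell_area_km2 <- function(grid, lat_row) {
  cs <- grid$cell_size_deg
  lat_centre <- grid$lat0 + (lat_row + 0.5) * cs
  (grid$km_per_deg * cs)^2 * cos(lat_centre * pi / 180)
}

cell_centre <- function(grid, col, row) {
  cs <- grid$cell_size_deg
  tibble::tibble(lon = grid$lon0 + (col + 0.5) * cs,
                 lat = grid$lat0 + (row + 0.5) * cs)
}

#' Occupied grid cells of a point set
#'
#' Set of distinct grid cells containing at least one occurrence. Duplicate
#' points collapse; row order is irrelevant.
#'
#' @inheritParams cell_index
#' @return tibble (`col`, `row`, `area_km2`), one row per occupied cell,
#'   ordered by (`col`, `row`).
#' @export
occupied_cells <- function(grid, lon, lat) {
  if (length(lon) == 0) {
    return(tibble::tibble(col = integer(), row = integer(), area_km2 = numeric()))
  }
  cells <- dplyr::distinct(cell_index(grid, lon, lat))
  cells <- dplyr::arrange(cells, .data$col, .data$row)
  cells$area_km2 <- cell_area_km2(grid, cells$row)
  cells
}

aoo_km2 <- function(cells) sum(cells$area_km2)
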