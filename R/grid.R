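#' Define a consistent latitude-longitude analysis grid
#'
#' The comparison of point chronologies, fine satellite cells and coarse model
#' cells takes place on one shared coarse grid. Cells are half-open on both
#' axes: a point on a cell's southern or western edge belongs to that cell,
#' never to its neighbour, so every coordinate inside the domain maps to
#' exactly one cell.
#'
#' @param cell_size Cell edge length in degrees (default 2.81, the coarsest
#'   native model resolution in the study design).
#' @param lat_origin Southern edge of the domain in degrees north
#'   (default 50, the southern limit of the boreal zone).
#' @param lon_origin Western edge in degrees east, in \[-180, 180).
#' @param n_lat,n_lon Number of rows (south to north) and columns
#'   (west to east).
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(n_lat = 4, n_lon = 8)
#' cell_index(g, 51, -179)
#' @export
grid_spec <- function(cell_size = 2.81, lat_origin = 50, lon_origin = -180,
                      n_lat = 11, n_lon = 128) {
  stopifnot(cell_size > 0, n_lat >= 1, n_lon >= 1)
  if (lat_origin + n_lat * cell_size > 90 + 1e-9)
    stop("grid extends north of 90N")
  g <- list(cell_size = cell_size, lat_origin = lat_origin,
            lon_origin = lon_origin, n_lat = as.integer(n_lat),
            n_lon = as.integer(n_lon))
  class(g) <- "grid_spec"
  g
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %.2f deg, lat [%.2f, %.2f), lon origin %.2f\n",
              x$n_lat, x$n_lon, x$cell_size, x$lat_origin,
              x$lat_origin + x$n_lat * x$cell_size, x$lon_origin))
  invisible(x)
}

normalize_lon <- function(lon) lon - 360 * floor((lon + 180) / 360)

#' Map coordinates to grid cells
#'
#' @param grid A [grid_spec()].
#' @param lat,lon Numeric vectors of coordinates (degrees). Longitudes are
#'   normalized to \[-180, 180) first.
#' @return A data.frame with integer columns `row`, `col` (1-based); `NA` for
#'   points outside the grid domain.
#' @export
cell_index <- function(grid, lat, lon) {
  stopifnot(inherits(grid, "grid_spec"), length(lat) == length(lon),
            all(is.finite(lat)), all(is.finite(lon)))
  lon <- normalize_lon(lon)
  row <- floor((lat - grid$lat_origin) / grid$cell_size) + 1
  col <- floor((lon - grid$lon_origin) / grid$cell_size) + 1
  bad <- row < 1 | row > grid$n_lat | col < 1 | col > grid$n_lon
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Cell-center coordinates
#'
#' @param grid A [grid_spec()].
#' @return A list with numeric vectors `lat` (length `n_lat`) and `lon`
#'   (length `n_lon`) of cell-center coordinates.
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  list(lat = grid$lat_origin + (seq_len(grid$n_lat) - 0.5) * grid$cell_size,
       lon = grid$lon_origin + (seq_len(grid$n_lon) - 0.5) * grid$cell_size)
}

#' Annual gridded field
#'
#' A single variable on the consistent grid, one value per cell per year.
#' Values are stored as a 3-d array indexed `[year, row, col]`; `NA` marks
#' missing cell-years.
#'
#' @param grid A [grid_spec()].
#' @param years Contiguous ascending integer calendar years.
#' @param values Array with dim `c(length(years), n_lat, n_lon)`, or a single
#'   number to fill.
#' @param variable,units Variable name and unit strings.
#' @return Object of class `annual_field`.
#' @export
annual_field <- function(grid, years, values, variable = "index", units = "1") {
  stopifnot(inherits(grid, "grid_spec"))
  years <- as.integer(years)
  if (length(years) > 1 && any(diff(years) != 1L))
    stop("years must be contiguous ascending")
  if (length(values) == 1)
    values <- array(values, dim = c(length(years), grid$n_lat, grid$n_lon))
  stopifnot(identical(dim(values), c(length(years), grid$n_lat, grid$n_lon)))
  structure(list(grid = grid, years = years, values = values,
                 variable = variable, units = units),
            class = "annual_field")
}

#' Monthly gridded field
#'
#' Twelve values per cell per year, stored `[year, month, row, col]`.
#'
#' @inheritParams annual_field
#' @param values Array with dim `c(length(years), 12, n_lat, n_lon)` or a
#'   single number to fill.
#' @return Object of class `monthly_field`.
#' @export
monthly_field <- function(grid, years, values, variable = "tas", units = "degC") {
  stopifnot(inherits(grid, "grid_spec"))
  years <- as.integer(years)
  if (length(years) > 1 && any(diff(years) != 1L))
    stop("years must be contiguous ascending")
  if (length(values) == 1)
    values <- array(values, dim = c(length(years), 12L, grid$n_lat, grid$n_lon))
  stopifnot(identical(dim(values), c(length(years), 12L, grid$n_lat, grid$n_lon)))
  if (grepl("^pr", variable) && any(values < 0, na.rm = TRUE))
    stop("precipitation values must be non-negative")
  structure(list(grid = grid, years = years, values = values,
                 variable = variable, units = units),
            class = "monthly_field")
}

#' @export
print.annual_field <- function(x, ...) {
  cat(sprintf("annual_field '%s' [%s]: years %d-%d on %dx%d grid (%.0f%% missing)\n",
              x$variable, x$units, min(x$years), max(x$years),
              x$grid$n_lat, x$grid$n_lon,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
print.monthly_field <- function(x, ...) {
  cat(sprintf("monthly_field '%s' [%s]: years %d-%d x 12 months on %dx%d grid\n",
              x$variable, x$units, min(x$years), max(x$years),
              x$grid$n_lat, x$grid$n_lon))
  invisible(x)
}

# subset an annual field to a year range (inclusive); years must be covered
window_years <- function(field, from, to) {
  stopifnot(inherits(field, "annual_field"))
  idx <- match(from:to, field$years)
  if (anyNA(idx)) stop("requested years not covered by field")
  annual_field(field$grid, from:to,
               field$values[idx, , , drop = FALSE],
               field$variable, field$units)
}
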