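#' Write a gridded field to long-format CSV
#'
#' Plain-text serialization used throughout the pipeline: one row per
#' (year\[, month\], row, col) with cell-center coordinates, so files diff
#' cleanly and survive version control. Missing cell-years are omitted.
#'
#' @param field An `annual_field` or `monthly_field`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  ctr <- cell_centers(field$grid)
  if (inherits(field, "annual_field")) {
    d <- expand.grid(year = field$years, row = seq_len(field$grid$n_lat),
                     col = seq_len(field$grid$n_lon))
    d$value <- as.vector(field$values)
  } else if (inherits(field, "monthly_field")) {
    d <- expand.grid(year = field$years, month = 1:12,
                     row = seq_len(field$grid$n_lat),
                     col = seq_len(field$grid$n_lon))
    d$value <- as.vector(field$values)
  } else stop("not a gridded field")
  d$lat <- ctr$lat[d$row]
  d$lon <- ctr$lon[d$col]
  d <- d[!is.na(d$value), ]
  hdr <- sprintf("# variable=%s units=%s cell_size=%g lat_origin=%g lon_origin=%g n_lat=%d n_lon=%d years=%d:%d kind=%s",
                 field$variable, field$units, field$grid$cell_size,
                 field$grid$lat_origin, field$grid$lon_origin,
                 field$grid$n_lat, field$grid$n_lon,
                 min(field$years), max(field$years),
                 if (inherits(field, "monthly_field")) "monthly" else "annual")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(d, con, row.names = FALSE)
  invisible(path)
}

#' Read a gridded field from long-format CSV
#'
#' Inverse of [write_field_csv()]; reconstructs the grid from the header line.
#'
#' @param path File written by [write_field_csv()].
#' @return An `annual_field` or `monthly_field`.
#' @export
read_field_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "# ")) stop("missing field header line in ", path)
  kv <- strsplit(sub("^# ", "", hdr), " ")[[1]]
  kv <- strsplit(kv, "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  g <- grid_spec(cell_size = as.numeric(meta["cell_size"]),
                 lat_origin = as.numeric(meta["lat_origin"]),
                 lon_origin = as.numeric(meta["lon_origin"]),
                 n_lat = as.integer(meta["n_lat"]),
                 n_lon = as.integer(meta["n_lon"]))
  yr <- as.integer(strsplit(meta[["years"]], ":", fixed = TRUE)[[1]])
  years <- yr[1]:yr[2]
  d <- utils::read.csv(path, skip = 1L)
  if (identical(meta[["kind"]], "monthly")) {
    vals <- array(NA_real_, dim = c(length(years), 12L, g$n_lat, g$n_lon))
    vals[cbind(match(d$year, years), d$month, d$row, d$col)] <- d$value
    monthly_field(g, years, vals, meta[["variable"]], meta[["units"]])
  } else {
    vals <- array(NA_real_, dim = c(length(years), g$n_lat, g$n_lon))
    vals[cbind(match(d$year, years), d$row, d$col)] <- d$value
    annual_field(g, years, vals, meta[["variable"]], meta[["units"]])
  }
}

#' Write an annual field to NetCDF
#'
#' Optional CF-style NetCDF output (dimensions year, lat, lon with unit
#' attributes). Requires the `ncdf4` package.
#'
#' @inheritParams write_field_csv
#' @return `path`, invisibly.
#' @export
write_field_ncdf <- function(field, path) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("NetCDF output requires the 'ncdf4' package; use write_field_csv()")
  stopifnot(inherits(field, "annual_field"))
  ctr <- cell_centers(field$grid)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", ctr$lat)
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", ctr$lon)
  dyr <- ncdf4::ncdim_def("year", "year", as.double(field$years))
  var <- ncdf4::ncvar_def(field$variable, field$units,
                          list(dyr, dlat, dlon), missval = -9999,
                          prec = "double")
  nc <- ncdf4::nc_create(path, var)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, var, field$values + 0)  # copy: ncvar_put fills NA in place
  invisible(path)
}

#' Read an annual field from NetCDF
#'
#' @param path NetCDF file written by [write_field_ncdf()].
#' @param variable Variable name; default is the file's first variable.
#' @return An `annual_field`.
#' @export
read_field_ncdf <- function(path, variable = NULL) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("NetCDF input requires the 'ncdf4' package; use read_field_csv()")
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (is.null(variable)) variable <- names(nc$var)[1]
  lat <- ncdf4::ncvar_get(nc, "lat")
  lon <- ncdf4::ncvar_get(nc, "lon")
  years <- as.integer(ncdf4::ncvar_get(nc, "year"))
  vals <- ncdf4::ncvar_get(nc, variable, collapse_degen = FALSE)
  cell <- if (length(lat) > 1) lat[2] - lat[1] else if (length(lon) > 1) lon[2] - lon[1] else 2.81
  g <- grid_spec(cell_size = cell, lat_origin = lat[1] - cell / 2,
                 lon_origin = lon[1] - cell / 2,
                 n_lat = length(lat), n_lon = length(lon))
  units <- ncdf4::ncatt_get(nc, variable, "units")$value
  annual_field(g, years, vals, variable, if (is.character(units)) units else "1")
}
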