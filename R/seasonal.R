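#' Latitude-dependent summer month definition
#'
#' North of the Arctic circle (taken as exactly 67 degrees N, inclusive) the
#' growing season is short enough that only July counts as summer; between
#' 50 and 67 degrees N summer is June-July-August.
#'
#' @param latitude Latitude in degrees north (>= 50).
#' @return Integer vector of summer month numbers (`7L` or `6:8`).
#' @export
summer_months <- function(latitude) {
  stopifnot(length(latitude) == 1, is.finite(latitude))
  if (latitude < 50)
    stop("summer definition only covers latitudes >= 50 N (got ", latitude, ")")
  if (latitude >= 67) 7L else 6:8
}

#' Summer composite of a monthly field
#'
#' Per cell, the arithmetic mean of the cell's summer-month values each year,
#' using the month set for the cell-center latitude. This applies alike to
#' temperature, precipitation (mean of monthly totals, not their sum) and
#' monthly index fields. Years with any summer month missing are missing.
#'
#' @param field A [monthly_field()].
#' @return An [annual_field()] of summer means, with the per-row month sets
#'   in attribute `"months_used"`.
#' @export
summer_composite <- function(field) {
  stopifnot(inherits(field, "monthly_field"))
  g <- field$grid
  ctr <- cell_centers(g)
  ny <- length(field$years)
  out <- array(NA_real_, dim = c(ny, g$n_lat, g$n_lon))
  used <- vector("list", g$n_lat)
  for (i in seq_len(g$n_lat)) {
    sm <- summer_months(ctr$lat[i])
    used[[i]] <- sm
    sub <- field$values[, sm, , , drop = FALSE]
    # mean over the month dimension; any missing month -> NA (no na.rm)
    out[, i, ] <- apply(sub[, , i, , drop = FALSE], c(1, 4), mean)
  }
  res <- annual_field(g, field$years, out,
                      paste0(field$variable, "_summer"), field$units)
  attr(res, "months_used") <- used
  res
}

# seconds per month, 365-day (no-leap) or proleptic gregorian non-leap calendar
month_seconds <- function(calendar = c("noleap", "gregorian")) {
  calendar <- match.arg(calendar)
  days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  days * 86400
}

#' Annual total of a monthly NPP field
#'
#' Sums the twelve monthly values per cell-year. Model output stored as a
#' carbon flux (mass per area per second) is first converted to monthly
#' masses using true month lengths on a 365-day no-leap calendar, the common
#' convention of coupled-model archives.
#'
#' @param field A [monthly_field()] of NPP.
#' @param flux_per_second Is the input a per-second flux (kg C m-2 s-1 style)
#'   rather than a monthly mass?
#' @param calendar Calendar for month lengths when converting fluxes.
#' @return An [annual_field()] of annual totals; years with any month
#'   missing are missing.
#' @export
annual_npp_total <- function(field, flux_per_second = FALSE,
                             calendar = "noleap") {
  stopifnot(inherits(field, "monthly_field"))
  vals <- field$values
  units <- field$units
  if (flux_per_second) {
    secs <- month_seconds(calendar)
    vals <- sweep(vals, 2, secs, `*`)
    units <- sub("s-1", "month-1", units, fixed = TRUE)
  }
  tot <- apply(vals, c(1, 3, 4), sum)   # NA if any month missing
  annual_field(field$grid, field$years, tot,
               paste0(field$variable, "_annual"),
               sub("month-1", "yr-1", units, fixed = TRUE))
}

#' Element-wise ensemble mean of monthly fields
#'
#' @param realizations List of [monthly_field()]s on identical grids/years.
#' @return A [monthly_field()] of element-wise arithmetic means.
#' @export
ensemble_mean <- function(realizations) {
  stopifnot(length(realizations) >= 1)
  ref <- realizations[[1]]
  for (f in realizations) {
    stopifnot(inherits(f, "monthly_field"))
    if (!identical(dim(f$values), dim(ref$values)) ||
        !identical(f$years, ref$years))
      stop("ensemble members must share grid and years")
  }
  avg <- Reduce(`+`, lapply(realizations, `[[`, "values")) / length(realizations)
  monthly_field(ref$grid, ref$years, avg, ref$variable, ref$units)
}
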