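#' Aggregate site chronologies onto the consistent grid
#'
#' Each cell-year value is the unweighted mean of the index values of all
#' retained sites falling in that cell and having data that year; cell-years
#' with no contributing site are missing. Each site belongs to exactly one
#' cell (half-open cell membership). The per-cell last year with data is
#' recorded for trailing-window analyses.
#'
#' @param chronologies List of `site_chronology` objects.
#' @param metas Site metadata data.frame (`site_id`, `latitude`,
#'   `longitude`).
#' @param grid Target [grid_spec()].
#' @param years Year range of the output field (default: union of chronology
#'   years).
#' @return An [annual_field()] with attributes `"n_sites"` (per-cell site
#'   counts) and `"assignment"` (site-to-cell table).
#' @export
aggregate_points_to_grid <- function(chronologies, metas, grid, years = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  ids <- vapply(chronologies, `[[`, "", "site_id")
  m <- metas[match(ids, metas$site_id), ]
  if (anyNA(m$site_id)) stop("metadata missing for some chronologies")
  cells <- cell_index(grid, m$latitude, m$longitude)
  if (is.null(years)) {
    rng <- range(unlist(lapply(chronologies, function(x) x$data$year)))
    years <- rng[1]:rng[2]
  }
  ny <- length(years)
  sums <- array(0, dim = c(ny, grid$n_lat, grid$n_lon))
  cnts <- array(0L, dim = c(ny, grid$n_lat, grid$n_lon))
  nsites <- matrix(0L, grid$n_lat, grid$n_lon)
  for (k in seq_along(chronologies)) {
    if (is.na(cells$row[k])) next
    i <- cells$row[k]; j <- cells$col[k]
    nsites[i, j] <- nsites[i, j] + 1L
    d <- chronologies[[k]]$data
    d <- d[!is.na(d$index) & d$year %in% years, ]
    t <- match(d$year, years)
    sums[cbind(t, i, j)] <- sums[cbind(t, i, j)] + d$index
    cnts[cbind(t, i, j)] <- cnts[cbind(t, i, j)] + 1L
  }
  vals <- ifelse(cnts > 0, sums / cnts, NA_real_)
  dim(vals) <- dim(sums)
  out <- annual_field(grid, years, vals, "rwi", "1")
  attr(out, "n_sites") <- nsites
  attr(out, "assignment") <- data.frame(site_id = ids, row = cells$row,
                                        col = cells$col)
  out
}

#' Average a fine-resolution annual field onto the consistent grid
#'
#' A coarse cell's value is the mean of all fine cells whose centers fall
#' inside it (half-open membership), per year; missing fine cell-years are
#' excluded, and a coarse cell with no contributing fine cell is missing.
#'
#' @param fine An [annual_field()] on a finer grid.
#' @param grid Target [grid_spec()] with `cell_size` larger than the fine
#'   field's.
#' @return An [annual_field()] on `grid`.
#' @export
aggregate_fine_to_grid <- function(fine, grid) {
  stopifnot(inherits(fine, "annual_field"), inherits(grid, "grid_spec"))
  if (fine$grid$cell_size >= grid$cell_size)
    stop("fine field cell size must be smaller than target cell size")
  ctr <- cell_centers(fine$grid)
  pts <- expand.grid(i = seq_len(fine$grid$n_lat), j = seq_len(fine$grid$n_lon))
  cells <- cell_index(grid, ctr$lat[pts$i], ctr$lon[pts$j])
  ny <- length(fine$years)
  sums <- array(0, dim = c(ny, grid$n_lat, grid$n_lon))
  cnts <- array(0L, dim = c(ny, grid$n_lat, grid$n_lon))
  for (k in seq_len(nrow(pts))) {
    if (is.na(cells$row[k])) next
    v <- fine$values[, pts$i[k], pts$j[k]]
    ok <- !is.na(v)
    if (!any(ok)) next
    t <- which(ok)
    sums[cbind(t, cells$row[k], cells$col[k])] <-
      sums[cbind(t, cells$row[k], cells$col[k])] + v[ok]
    cnts[cbind(t, cells$row[k], cells$col[k])] <-
      cnts[cbind(t, cells$row[k], cells$col[k])] + 1L
  }
  vals <- ifelse(cnts > 0, sums / cnts, NA_real_)
  dim(vals) <- dim(sums)
  annual_field(grid, fine$years, vals, fine$variable, fine$units)
}

#' Re-sample a model field onto the consistent grid
#'
#' Regular lat-lon model output is harmonized to the consistent grid by
#' center membership: finer native cells are averaged within each target cell
#' (as [aggregate_fine_to_grid()]); for native grids as coarse as or coarser
#' than the target, each target cell takes the value of the native cell
#' containing its center (nearest-cell sampling).
#'
#' @param model An [annual_field()] on its native regular grid.
#' @param grid Target [grid_spec()].
#' @return An [annual_field()] on `grid`.
#' @export
regrid_model_to_grid <- function(model, grid) {
  stopifnot(inherits(model, "annual_field"), inherits(grid, "grid_spec"))
  if (model$grid$cell_size < grid$cell_size)
    return(annual_field(grid, model$years,
                        aggregate_fine_to_grid(model, grid)$values,
                        model$variable, model$units))
  ctr <- cell_centers(grid)
  tgt <- expand.grid(i = seq_len(grid$n_lat), j = seq_len(grid$n_lon))
  src <- cell_index(model$grid, ctr$lat[tgt$i], ctr$lon[tgt$j])
  ny <- length(model$years)
  vals <- array(NA_real_, dim = c(ny, grid$n_lat, grid$n_lon))
  for (k in seq_len(nrow(tgt))) {
    if (is.na(src$row[k])) next
    vals[, tgt$i[k], tgt$j[k]] <- model$values[, src$row[k], src$col[k]]
  }
  annual_field(grid, model$years, vals, model$variable, model$units)
}
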