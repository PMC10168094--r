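#' Configuration for the synthetic boreal dataset generator
#'
#' Bundles every knob of the generator: grid extent, time span, site/tree
#' replication, the monthly climate model, per-target sensitivity
#' coefficients on standardized summer anomalies, the negative-exponential
#' age trend, and noise levels. With coefficients `b` on independent
#' standardized anomalies and additive noise of standard deviation `sigma`,
#' a target's theoretical correlation with one climate variable is
#' `b / sqrt(sum(b^2) + sigma^2)`, which is what makes generated data usable
#' as a parameter-recovery oracle.
#'
#' @param grid A [grid_spec()]; its southern edge must be at or north of
#'   50 degrees N (the generator models boreal conditions only).
#' @param n_years Number of index years (>= 30, so a 25-year window plus the
#'   lag year always fits).
#' @param first_year First index calendar year; climate is generated from
#'   `first_year - 1` so lag-1 predictors exist.
#' @param sites_per_cell,trees_per_site Replication of the tree-ring network.
#' @param climate_params List: `temp_mean` (annual mean, degC),
#'   `temp_seasonal_amp` (seasonal half-range, degC), `temp_anom_sd`
#'   (interannual summer anomaly SD, degC), `temp_month_sd` (non-summer
#'   month noise, degC); `prec_mean`, `prec_seasonal_amp`, `prec_anom_sd`,
#'   `prec_month_sd` (all mm/month, anomalies truncated at zero).
#' @param sensitivity Named list of coefficient vectors
#'   `c(b_T0, b_T1, b_P0, b_P1)` per target (`rwi`, `ndvi`, `npp`):
#'   dimensionless responses to standardized current/previous summer
#'   temperature/precipitation anomalies.
#' @param age_trend List `a`, `tau`, `c`: widths follow
#'   `a*exp(-age/tau) + c` in 0.01 mm.
#' @param noise_sd List: `tree` (lognormal growth noise SD per tree),
#'   `field` (additive noise SD on index/NPP fields, on the standardized
#'   anomaly scale).
#' @param ar1 Optional AR(1) coefficient for summer anomalies (default 0,
#'   i.e. independent years, under which the closed-form correlation holds).
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(grid = grid_spec(n_lat = 3, n_lon = 4),
                             n_years = 30, first_year = 1977,
                             sites_per_cell = 2, trees_per_site = 8,
                             climate_params = list(
                               temp_mean = -5, temp_seasonal_amp = 18,
                               temp_anom_sd = 1.5, temp_month_sd = 0.8,
                               prec_mean = 60, prec_seasonal_amp = 25,
                               prec_anom_sd = 12, prec_month_sd = 8),
                             sensitivity = list(
                               rwi = c(b_T0 = 0, b_T1 = -0.6, b_P0 = 0, b_P1 = 0.6),
                               ndvi = c(b_T0 = 0.3, b_T1 = -0.15, b_P0 = 0.1, b_P1 = 0.1),
                               npp = c(b_T0 = 0.6, b_T1 = 0, b_P0 = 0.6, b_P1 = 0)),
                             age_trend = list(a = 150, tau = 80, c = 50),
                             noise_sd = list(tree = 0.3, field = sqrt(0.28)),
                             ar1 = 0, seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"))
  if (grid$lat_origin < 50)
    stop("synthetic grid extent must lie north of 50 N (boreal domain)")
  if (n_years < 30)
    stop("n_years must be >= 30 (25-year analysis window plus lag year, with margin)")
  stopifnot(sites_per_cell >= 1, trees_per_site >= 1,
            climate_params$prec_mean >= 0, abs(ar1) < 1)
  for (s in sensitivity)
    stopifnot(length(s) == 4)
  structure(list(grid = grid, n_years = as.integer(n_years),
                 first_year = as.integer(first_year),
                 sites_per_cell = as.integer(sites_per_cell),
                 trees_per_site = as.integer(trees_per_site),
                 climate_params = climate_params, sensitivity = sensitivity,
                 age_trend = age_trend, noise_sd = noise_sd,
                 ar1 = ar1, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Additive noise SD giving a target theoretical correlation
#'
#' Inverts `r = b / sqrt(b^2 + sum(b_other^2) + sigma^2)` for `sigma`: the
#' noise level at which a generated index correlates with one standardized
#' climate anomaly at exactly `r` in the population.
#'
#' @param b Coefficient on the anomaly of interest.
#' @param r Desired theoretical Pearson correlation (same sign as `b`).
#' @param b_other Coefficients on the remaining anomalies (default none).
#' @return Noise standard deviation.
#' @export
noise_sd_for_r <- function(b, r, b_other = 0) {
  stopifnot(abs(r) > 0, abs(r) <= 1, sign(b) == sign(r))
  v <- b^2 / r^2 - b^2 - sum(b_other^2)
  if (v < 0) stop("requested |r| unattainable with these coefficients")
  sqrt(v)
}

#' Generate gridded monthly temperature and precipitation
#'
#' Per cell, monthly values are a fixed seasonal cycle (July warmest/wettest)
#' plus interannual anomalies. The summer months of each year (per the
#' latitude-dependent summer definition, see [summer_months()]) all share one
#' standardized anomaly draw, so the summer composite of the output has an
#' exactly known z-score; non-summer months get independent month noise.
#' Precipitation anomalies are truncated at zero (parameters keep truncation
#' negligible so z-scores stay meaningful).
#'
#' @param config A [synthetic_config()].
#' @return Object of class `synthetic_climate`: list with `temperature` and
#'   `precipitation` ([monthly_field()]s covering `first_year - 1` onward)
#'   and the standardized summer anomaly arrays `z_temp`, `z_prec`
#'   (`[year, row, col]`).
#' @export
generate_monthly_climate <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  g <- config$grid
  cp <- config$climate_params
  years <- (config$first_year - 1L):(config$first_year + config$n_years - 1L)
  ny <- length(years)
  ctr <- cell_centers(g)
  months <- 1:12
  t_clim <- cp$temp_mean + cp$temp_seasonal_amp * cos(2 * pi * (months - 7) / 12)
  p_clim <- pmax(cp$prec_mean + cp$prec_seasonal_amp * cos(2 * pi * (months - 7) / 12), 0)

  set.seed(config$seed)
  z_t <- array(stats::rnorm(ny * g$n_lat * g$n_lon), dim = c(ny, g$n_lat, g$n_lon))
  z_p <- array(stats::rnorm(ny * g$n_lat * g$n_lon), dim = c(ny, g$n_lat, g$n_lon))
  if (config$ar1 != 0) {
    for (t in 2:ny) {
      z_t[t, , ] <- config$ar1 * z_t[t - 1, , ] + sqrt(1 - config$ar1^2) * z_t[t, , ]
      z_p[t, , ] <- config$ar1 * z_p[t - 1, , ] + sqrt(1 - config$ar1^2) * z_p[t, , ]
    }
  }
  tv <- array(NA_real_, dim = c(ny, 12, g$n_lat, g$n_lon))
  pv <- array(NA_real_, dim = c(ny, 12, g$n_lat, g$n_lon))
  for (i in seq_len(g$n_lat)) {
    sm <- summer_months(ctr$lat[i])
    for (j in seq_len(g$n_lon)) {
      tn <- matrix(stats::rnorm(ny * 12, sd = cp$temp_month_sd), ny, 12)
      pn <- matrix(stats::rnorm(ny * 12, sd = cp$prec_month_sd), ny, 12)
      tm <- sweep(tn, 2, t_clim, `+`)
      pm <- sweep(pn, 2, p_clim, `+`)
      # summer months share the year's anomaly draw (month noise replaced)
      for (m in sm) {
        tm[, m] <- t_clim[m] + cp$temp_anom_sd * z_t[, i, j]
        pm[, m] <- p_clim[m] + cp$prec_anom_sd * z_p[, i, j]
      }
      tv[, , i, j] <- tm
      pv[, , i, j] <- pmax(pm, 0)
    }
  }
  structure(list(
    temperature = monthly_field(g, years, tv, "tas", "degC"),
    precipitation = monthly_field(g, years, pv, "pr", "mm/month"),
    z_temp = z_t, z_prec = z_p, years = years),
    class = "synthetic_climate")
}

# lagged signal on standardized summer anomalies, for index years
# (all years after the first climate year)
planted_signal <- function(climate, b, i, j) {
  ny <- length(climate$years)
  idx <- 2:ny
  # coefficient order: b_T0, b_T1, b_P0, b_P1
  b[[1]] * climate$z_temp[idx, i, j] +
    b[[2]] * climate$z_temp[idx - 1, i, j] +
    b[[3]] * climate$z_prec[idx, i, j] +
    b[[4]] * climate$z_prec[idx - 1, i, j]
}

truth_row <- function(row, col, target, b) {
  # ties broken toward lag 0 first, then temperature (b order: T0, T1, P0, P1)
  k <- which.max(abs(b) + c(3, 1, 2, 0) * 1e-9 * max(abs(b)))
  data.frame(row = row, col = col, target = target,
             b_T0 = b[[1]], b_T1 = b[[2]], b_P0 = b[[3]], b_P1 = b[[4]],
             expected_variable = c("temperature", "temperature",
                                   "precipitation", "precipitation")[k],
             expected_lag = c(0L, 1L, 0L, 1L)[k],
             expected_sign = sign(b[[k]]))
}

#' Generate a ring-width site network with planted climate signal
#'
#' Every grid cell receives `sites_per_cell` sites of `trees_per_site` trees.
#' A tree's width in year t is the negative-exponential age curve times a
#' lognormal factor `exp(signal_t + eps)`, where `signal_t` combines the
#' cell's standardized summer anomalies at lag 0 and lag 1 through the `rwi`
#' sensitivity coefficients and `eps` is per-tree growth noise. Widths are
#' quantized to 0.01 mm and floored at that unit, matching Tucson-format
#' precision. Ratio detrending of the multiplicative model recovers
#' `exp(signal)` exactly, so chronology-level correlations have a known
#' structure.
#'
#' @param climate A `synthetic_climate` from [generate_monthly_climate()].
#' @param config The same [synthetic_config()].
#' @return List with `series` (list of [ring_width_series()]), `meta`
#'   (site metadata data.frame), and `truth` (per-cell generating
#'   coefficients and expected dominant variable/lag).
#' @export
generate_ring_width_sites <- function(climate, config) {
  stopifnot(inherits(climate, "synthetic_climate"),
            inherits(config, "synthetic_config"))
  g <- config$grid
  if (climate$years[1] > config$first_year - 1L)
    stop("climate must cover first_year - 1 (lag-1 predictor year)")
  b <- config$sensitivity$rwi
  at <- config$age_trend
  years <- config$first_year:(config$first_year + config$n_years - 1L)
  ctr <- cell_centers(g)
  set.seed(config$seed + 1L)
  series <- list()
  meta <- list()
  truth <- list()
  for (i in seq_len(g$n_lat)) {
    for (j in seq_len(g$n_lon)) {
      sig <- planted_signal(climate, b, i, j)
      truth[[length(truth) + 1L]] <- truth_row(i, j, "rwi", b)
      for (s in seq_len(config$sites_per_cell)) {
        site_id <- sprintf("%02d%02d%01d", i, j, s)
        lat <- ctr$lat[i] + stats::runif(1, -0.45, 0.45) * g$cell_size
        lon <- ctr$lon[j] + stats::runif(1, -0.45, 0.45) * g$cell_size
        elev <- round(stats::runif(1, 100, 800))
        for (k in seq_len(config$trees_per_site)) {
          age0 <- sample.int(30, 1)
          age <- age0 + seq_along(years) - 1
          curve <- at$a * exp(-age / at$tau) + at$c
          eps <- stats::rnorm(length(years), sd = config$noise_sd$tree)
          w <- pmax(round(curve * exp(sig + eps)), 1)
          series[[length(series) + 1L]] <-
            ring_width_series(sprintf("%s%02d", site_id, k), years, w,
                              site_id = site_id)
        }
        meta[[length(meta) + 1L]] <- data.frame(
          site_id = site_id, latitude = lat, longitude = lon,
          elevation = elev, first_year = years[1],
          last_year = years[length(years)])
      }
    }
  }
  list(series = series, meta = do.call(rbind, meta),
       truth = do.call(rbind, truth))
}

#' Generate an annual greenness-like index field
#'
#' Per cell, the index in year t is
#' `base + scale * (b_T0*zT_t + b_T1*zT_(t-1) + b_P0*zP_t + b_P1*zP_(t-1) + noise)`,
#' clipped to (0, 1) for NDVI-like use. Because the transform is linear,
#' per-cell correlations with any one standardized anomaly equal
#' `b / sqrt(sum(b^2) + noise_sd^2)` in the population.
#'
#' @param climate A `synthetic_climate`.
#' @param sensitivity Coefficients `c(b_T0, b_T1, b_P0, b_P1)`.
#' @param noise_sd Additive noise SD on the standardized-anomaly scale.
#' @param seed Integer seed.
#' @param base,scale Affine placement of the index inside (0, 1).
#' @param variable,units Labels for the output field.
#' @return An [annual_field()] for the index years, with the per-cell truth
#'   table in attribute `"truth"`.
#' @export
generate_annual_index_field <- function(climate, sensitivity, noise_sd,
                                        seed = 1L, base = 0.5, scale = 0.08,
                                        variable = "ndvi", units = "1") {
  stopifnot(inherits(climate, "synthetic_climate"), length(sensitivity) == 4)
  g <- climate$temperature$grid
  years <- climate$years[-1]
  ny <- length(years)
  set.seed(seed)
  vals <- array(NA_real_, dim = c(ny, g$n_lat, g$n_lon))
  truth <- list()
  for (i in seq_len(g$n_lat)) {
    for (j in seq_len(g$n_lon)) {
      sig <- planted_signal(climate, sensitivity, i, j)
      vals[, i, j] <- base + scale * (sig + stats::rnorm(ny, sd = noise_sd))
      truth[[length(truth) + 1L]] <- truth_row(i, j, variable, sensitivity)
    }
  }
  vals <- pmin(pmax(vals, 1e-6), 1 - 1e-6)
  out <- annual_field(g, years, vals, variable, units)
  attr(out, "truth") <- do.call(rbind, truth)
  out
}

#' Generate a monthly NPP-like field
#'
#' Annual totals follow
#' `base_annual * (1 + scale * (signal_t + noise))` with the planted lagged
#' sensitivity structure; each year's total is spread over months by a fixed
#' Gaussian phenology centred on July, so winter months carry a negligible
#' share and annual sums reproduce the configured (typically
#' current-year-dominated, positive) sensitivity exactly.
#'
#' @inheritParams generate_annual_index_field
#' @param base_annual Mean annual NPP (g C m-2 yr-1).
#' @param scale Relative interannual amplitude per unit standardized signal.
#' @param phenology_sd Width (months) of the Gaussian monthly allocation.
#' @return A [monthly_field()] (g C m-2 month-1) for the index years, truth
#'   table in attribute `"truth"`.
#' @export
generate_monthly_npp <- function(climate, sensitivity, noise_sd, seed = 1L,
                                 base_annual = 500, scale = 0.08,
                                 phenology_sd = 1.3) {
  stopifnot(inherits(climate, "synthetic_climate"), length(sensitivity) == 4)
  g <- climate$temperature$grid
  years <- climate$years[-1]
  ny <- length(years)
  w <- stats::dnorm(1:12, mean = 7, sd = phenology_sd)
  w <- w / sum(w)
  set.seed(seed)
  vals <- array(NA_real_, dim = c(ny, 12, g$n_lat, g$n_lon))
  truth <- list()
  for (i in seq_len(g$n_lat)) {
    for (j in seq_len(g$n_lon)) {
      sig <- planted_signal(climate, sensitivity, i, j)
      annual <- base_annual * pmax(1 + scale * (sig + stats::rnorm(ny, sd = noise_sd)), 0)
      vals[, , i, j] <- outer(annual, w)
      truth[[length(truth) + 1L]] <- truth_row(i, j, "npp", sensitivity)
    }
  }
  out <- monthly_field(g, years, vals, "npp", "gC m-2 month-1")
  attr(out, "truth") <- do.call(rbind, truth)
  out
}
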