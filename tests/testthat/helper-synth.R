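# Shared fixtures built in code.

small_grid <- function(n_lat = 3, n_lon = 4) grid_spec(n_lat = n_lat, n_lon = n_lon)

small_config <- function(seed = 1L, ...) {
  synthetic_config(grid = small_grid(), seed = seed, ...)
}

# grid covering ~200 cells for recovery runs
recovery_grid <- function() grid_spec(cell_size = 2.81, n_lat = 10, n_lon = 20)

# empirical amplitude gain of the detrending filter at a given period,
# measured by regressing the fitted curve on the input sinusoid over the
# series interior (edge-effect-free), independent of the solver internals
measure_spline_gain <- function(period, n = 1280, cutoff = 128) {
  t <- seq_len(n)
  y <- 100 + sin(2 * pi * t / period)
  curve <- fit_detrending_curve(y, cutoff_wavelength = cutoff) - 100
  int <- 200:(n - 200)
  fit <- stats::lm(curve[int] ~ sin(2 * pi * t[int] / period) +
                     cos(2 * pi * t[int] / period))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}

# naive independent recomputation of a whole correlation field via cor.test
naive_correlation_field <- function(index, climate, lag, window) {
  g <- index$grid
  r <- p <- matrix(NA_real_, g$n_lat, g$n_lon)
  for (i in seq_len(g$n_lat)) for (j in seq_len(g$n_lon)) {
    if (is.na(window$start[i, j])) next
    yrs <- window$start[i, j]:window$end[i, j]
    x <- index$values[match(yrs, index$years), i, j]
    y <- climate$values[match(yrs - lag, climate$years), i, j]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 20) next
    ct <- stats::cor.test(x[ok], y[ok])
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  list(r = r, p = p)
}
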