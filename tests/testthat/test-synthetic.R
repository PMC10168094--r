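test_that("identical seed and config give bit-identical outputs", {
  a <- generate_monthly_climate(small_config(seed = 3))
  b <- generate_monthly_climate(small_config(seed = 3))
  expect_identical(a$temperature$values, b$temperature$values)
  expect_identical(a$precipitation$values, b$precipitation$values)
  na <- generate_ring_width_sites(a, small_config(seed = 3))
  nb <- generate_ring_width_sites(b, small_config(seed = 3))
  expect_identical(lapply(na$series, `[[`, "widths"),
                   lapply(nb$series, `[[`, "widths"))
  expect_identical(na$meta, nb$meta)
  fa <- generate_annual_index_field(a, c(0.3, 0, 0.1, 0), 0.4, seed = 9)
  fb <- generate_annual_index_field(b, c(0.3, 0, 0.1, 0), 0.4, seed = 9)
  expect_identical(fa$values, fb$values)
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(grid = grid_spec(lat_origin = 45, n_lat = 3,
                                                 n_lon = 3)),
               "north of 50")
  expect_error(small_config(n_years = 28), "n_years")
  cl <- generate_monthly_climate(small_config())
  expect_true(all(cl$precipitation$values >= 0))
})

test_that("summer composite of generated climate has the configured anomaly SD", {
  cfg <- synthetic_config(grid = small_grid(), n_years = 200,
                          first_year = 1807, seed = 12)
  cl <- generate_monthly_climate(cfg)
  comp <- summer_composite(cl$temperature)
  sds <- apply(comp$values, c(2, 3), sd)
  # per-cell sample SD over 200 years within 15% of the configured 1.5 degC
  expect_true(all(abs(sds - 1.5) / 1.5 < 0.15))
  # and the composite z-scores are exactly the stored anomaly draws
  i <- 2; j <- 3
  z_hat <- (comp$values[, i, j] - mean(comp$values[, i, j])) /
    sd(comp$values[, i, j])
  expect_gt(cor(z_hat, cl$z_temp[, i, j]), 0.999)
})

test_that("zero anomaly SD gives identical summer composites every year", {
  cfg <- small_config()
  cfg$climate_params$temp_anom_sd <- 0
  cfg$climate_params$prec_anom_sd <- 0
  cl <- generate_monthly_climate(cfg)
  tc <- summer_composite(cl$temperature)
  pc <- summer_composite(cl$precipitation)
  for (i in 1:3) for (j in 1:4) {
    expect_equal(diff(range(tc$values[, i, j])), 0)
    expect_equal(diff(range(pc$values[, i, j])), 0)
  }
})

test_that("null signal and zero noise reduce trees to the rounded age curve", {
  cfg <- small_config()
  cfg$sensitivity$rwi <- c(b_T0 = 0, b_T1 = 0, b_P0 = 0, b_P1 = 0)
  cfg$noise_sd$tree <- 0
  cl <- generate_monthly_climate(cfg)
  net <- generate_ring_width_sites(cl, cfg)
  at <- cfg$age_trend
  for (s in net$series[1:10]) {
    # recover the tree's pith offset from its first width, then match exactly
    cand <- vapply(1:30, function(o)
      abs(s$widths[1] - round(at$a * exp(-o / at$tau) + at$c)), 0)
    o <- which.min(cand)
    age <- o + seq_along(s$years) - 1
    expect_equal(s$widths, pmax(round(at$a * exp(-age / at$tau) + at$c), 1))
    expect_true(all(diff(s$widths) <= 0))
  }
})

test_that("a single strong lag-1 coefficient is recovered per tree", {
  cfg <- small_config(seed = 6)
  cfg$sensitivity$rwi <- c(b_T0 = 0, b_T1 = -0.5, b_P0 = 0, b_P1 = 0)
  cfg$noise_sd$tree <- 0.02
  cl <- generate_monthly_climate(cfg)
  net <- generate_ring_width_sites(cl, cfg)
  s <- net$series[[1]]
  cell <- cell_index(cfg$grid, net$meta$latitude[1], net$meta$longitude[1])
  z_lag1 <- cl$z_temp[match(s$years, cl$years) - 1, cell$row, cell$col]
  idx <- compute_ratio_index(s, fit_detrending_curve(s))
  expect_lt(cor(log(idx$index), z_lag1), -0.95)
})

test_that("site and tree bookkeeping is consistent", {
  cfg <- synthetic_config(grid = small_grid(), sites_per_cell = 3,
                          trees_per_site = 10, seed = 2)
  cl <- generate_monthly_climate(cfg)
  net <- generate_ring_width_sites(cl, cfg)
  n_cells <- cfg$grid$n_lat * cfg$grid$n_lon
  expect_equal(nrow(net$meta), n_cells * 3)
  expect_equal(length(net$series), n_cells * 3 * 10)
  expect_equal(unname(table(vapply(net$series, `[[`, "", "site_id"))[net$meta$site_id]),
               rep(10L, nrow(net$meta)), ignore_attr = TRUE)
  expect_equal(nrow(net$truth), n_cells)
  # every site's coordinates map back to its generating cell
  cells <- cell_index(cfg$grid, net$meta$latitude, net$meta$longitude)
  expect_true(all(!is.na(cells$row)))
  # lag-1 year missing from climate is an error
  cl_short <- cl
  cl_short$years <- cl$years[-1]
  expect_error(generate_ring_width_sites(cl_short, cfg), "lag-1")
})

test_that("annual index field honours the closed-form correlation", {
  cfg <- synthetic_config(grid = recovery_grid(), seed = 8)
  cl <- generate_monthly_climate(cfg)
  # zero coefficients, zero noise -> constant field at the base value
  f0 <- generate_annual_index_field(cl, c(0, 0, 0, 0), 0, seed = 1)
  expect_equal(diff(range(f0$values)), 0)
  # single strong coefficient, vanishing noise -> near-perfect correlation
  f1 <- generate_annual_index_field(cl, c(0.6, 0, 0, 0), 1e-6, seed = 1)
  i <- 4; j <- 7
  expect_gt(cor(f1$values[, i, j], cl$z_temp[-1, i, j]), 0.9999)
  # noise set for theoretical r = 0.6: mean per-cell sample r within 0.05
  sd6 <- noise_sd_for_r(0.6, 0.6)
  f2 <- generate_annual_index_field(cl, c(0.6, 0, 0, 0), sd6, seed = 2)
  rs <- sapply(seq_len(cfg$grid$n_lat), function(i)
    sapply(seq_len(cfg$grid$n_lon), function(j)
      cor(f2$values[, i, j], cl$z_temp[-1, i, j])))
  expect_equal(mean(rs), 0.6, tolerance = 0.05)
  expect_true(all(f2$values > 0 & f2$values < 1))
})

test_that("monthly NPP has summer-concentrated phenology and exact annual sums", {
  cfg <- small_config(seed = 10)
  cl <- generate_monthly_climate(cfg)
  npp <- generate_monthly_npp(cl, cfg$sensitivity$npp, noise_sd = 0.5, seed = 3)
  expect_true(all(npp$values >= 0))
  tot <- annual_npp_total(npp)
  # conservation: annual value is exactly the sum of the 12 months
  expect_equal(tot$values[3, 2, 2], sum(npp$values[3, , 2, 2]))
  # winter months carry under 5% of the annual sum
  winter <- apply(npp$values[, c(12, 1, 2), , ], c(1, 3, 4), sum)
  expect_true(all(winter / tot$values < 0.05))
  # zero sensitivity and zero noise -> identical annual sums every year
  npp0 <- generate_monthly_npp(cl, c(0, 0, 0, 0), noise_sd = 0, seed = 3)
  tot0 <- annual_npp_total(npp0)
  expect_equal(diff(range(tot0$values)), 0)
})

test_that("planted lag and sign are recovered through the full tree-ring pipeline", {
  # default coefficients (lag-1: negative T, positive P), 8 trees/site:
  # effective cell-level |r| well above 0.6, so best-of-lags should pick
  # lag 1 with the right sign in at least 80% of cells per variable
  cfg <- synthetic_config(grid = grid_spec(n_lat = 4, n_lon = 6),
                          sites_per_cell = 1, trees_per_site = 8, seed = 31)
  cl <- generate_monthly_climate(cfg)
  net <- generate_ring_width_sites(cl, cfg)
  # (curve-floor warnings possible on short series with strong excursions)
  chrons <- suppressWarnings(
    lapply(split(seq_along(net$series),
                 vapply(net$series, `[[`, "", "site_id")),
           function(ix) build_site_chronology(net$series[ix])))
  rwi <- aggregate_points_to_grid(chrons, net$meta, cfg$grid)
  win <- analysis_window(rwi, "trailing", span = 25)
  tas <- summer_composite(cl$temperature)
  pr <- summer_composite(cl$precipitation)
  bt <- best_of_lags(correlation_field(rwi, tas, 0, win),
                     correlation_field(rwi, tas, 1, win))
  bp <- best_of_lags(correlation_field(rwi, pr, 0, win),
                     correlation_field(rwi, pr, 1, win))
  ok_t <- bt$lag == 1L & bt$r < 0
  ok_p <- bp$lag == 1L & bp$r > 0
  expect_gte(mean(ok_t, na.rm = TRUE), 0.8)
  expect_gte(mean(ok_p, na.rm = TRUE), 0.8)
})
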