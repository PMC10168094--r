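# build paired vectors whose sample correlation is exactly r
make_pair_with_r <- function(r, n = 25, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(cbind(rnorm(n), rnorm(n))))
  u1 <- scale(q[, 1] - mean(q[, 1]))[, 1]
  u2raw <- q[, 2] - mean(q[, 2])
  u2raw <- u2raw - u1 * sum(u2raw * u1) / sum(u1 * u1)
  u2 <- scale(u2raw)[, 1]
  list(x = u1, y = r * u1 + sqrt(1 - r^2) * u2)
}

test_that("pearson_r_p matches cor.test and flags degenerate input", {
  x <- rnorm(30); y <- 0.4 * x + rnorm(30)
  res <- pearson_r_p(x, y)
  ct <- cor.test(x, y)
  expect_equal(res[["r"]], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res[["p"]], ct$p.value, tolerance = 1e-12)
  expect_equal(pearson_r_p(x, x)[["r"]], 1)
  expect_equal(pearson_r_p(x, -x)[["r"]], -1)
  expect_true(is.na(pearson_r_p(x, rep(1, 30))[["r"]]))
  expect_true(is.na(pearson_r_p(x[1:4], y[1:4])[["r"]]))
})

test_that("the significance boundary at n = 25 sits between |r| = 0.39 and 0.40", {
  p_40 <- pearson_r_p(make_pair_with_r(0.40)$x, make_pair_with_r(0.40)$y)[["p"]]
  p_39 <- pearson_r_p(make_pair_with_r(0.39)$x, make_pair_with_r(0.39)$y)[["p"]]
  expect_lt(p_40, 0.05)
  expect_gt(p_39, 0.05)
  # t-distribution oracle for the critical r itself
  t_crit <- qt(0.975, df = 23)
  r_crit <- t_crit / sqrt(23 + t_crit^2)
  expect_gt(0.40, r_crit)
  expect_lt(0.39, r_crit)
})

test_that("analysis windows are fixed for satellite/model cells and trailing for tree-ring cells", {
  g <- grid_spec(n_lat = 1, n_lon = 3)
  vals <- array(NA_real_, c(57, 1, 3))
  vals[, 1, 1] <- rnorm(57)                       # full 1950-2006
  vals[1:45, 1, 2] <- rnorm(45)                   # ends 1994
  vals[1:20, 1, 3] <- rnorm(20)                   # too short
  f <- annual_field(g, 1950:2006, vals)
  wf <- analysis_window(f, "fixed")
  expect_equal(unname(c(wf$start[1, 1], wf$end[1, 1])), c(1982, 2006))
  wt <- analysis_window(f, "trailing")
  expect_equal(unname(c(wt$start[1, 2], wt$end[1, 2])), c(1970, 1994))
  expect_true(is.na(wt$start[1, 3]))
  expect_true(is.na(wf$start[1, 3]))   # 20 years < span in fixed window too
})

test_that("a lag-1 construction correlates perfectly at lag 1 and not at lag 0", {
  g <- grid_spec(n_lat = 2, n_lon = 2)
  set.seed(14)
  clim_years <- 1975:2006
  zv <- array(rnorm(length(clim_years) * 4), c(length(clim_years), 2, 2))
  climate <- annual_field(g, clim_years, zv, "tas_summer")
  # index is an exact copy of the previous year's climate
  idx_years <- 1982:2006
  iv <- zv[match(idx_years, clim_years) - 1, , , drop = FALSE]
  index <- annual_field(g, idx_years, iv)
  win <- analysis_window(index, "fixed")
  cf1 <- correlation_field(index, climate, 1, win)
  cf0 <- correlation_field(index, climate, 0, win)
  expect_true(all(abs(cf1$r - 1) < 1e-12))
  expect_true(all(abs(cf0$r) < 0.5))   # independent draws, finite sample
})

test_that("whole-field correlations equal a naive per-cell recomputation", {
  cfg <- synthetic_config(grid = grid_spec(n_lat = 10, n_lon = 10), seed = 17)
  cl <- generate_monthly_climate(cfg)
  idx <- generate_annual_index_field(cl, cfg$sensitivity$rwi,
                                     noise_sd = cfg$noise_sd$field, seed = 5)
  tas <- summer_composite(cl$temperature)
  win <- analysis_window(idx, "fixed")
  for (lag in 0:1) {
    cf <- correlation_field(idx, tas, lag, win)
    ref <- naive_correlation_field(idx, tas, lag, win)
    expect_equal(cf$r, ref$r, tolerance = 1e-12)
    expect_equal(cf$p, ref$p, tolerance = 1e-12)
  }
})

test_that("classification is an exhaustive, exclusive partition", {
  expect_equal(classify_correlation(0.6, 0.01), "positive-significant")
  expect_equal(classify_correlation(-0.6, 0.01), "negative-significant")
  expect_equal(classify_correlation(0.3, 0.14), "non-significant")
  expect_equal(classify_correlation(NA, NA), "non-significant")
  set.seed(3)
  r <- runif(200, -1, 1); p <- runif(200)
  cls <- classify_correlation(r, p)
  expect_true(all(cls %in% c("positive-significant", "negative-significant",
                             "non-significant")))
  expect_equal(sum(cls == "positive-significant") +
                 sum(cls == "negative-significant") +
                 sum(cls == "non-significant"), 200)
})

test_that("summary counts and percentages recount exactly", {
  g <- grid_spec(n_lat = 2, n_lon = 5)
  mk_cf <- function(r, p, lag, var) {
    structure(list(r = matrix(r, 2, 5), p = matrix(p, 2, 5), n = matrix(25L, 2, 5),
                   lag = lag, variable = var, grid = g, window = NULL),
              class = "correlation_field")
  }
  r_t <- c(0.6, 0.7, rep(0.1, 8)); p_t <- c(0.01, 0.02, rep(0.5, 8))
  r_p <- rep(-0.1, 10); p_p <- rep(0.6, 10)
  s <- summarize_counts(mk_cf(r_t, p_t, 0L, "tas"), mk_cf(r_p, p_p, 0L, "pr"))
  expect_equal(s$count[s$class == "Positive_t"], 2L)
  expect_equal(s$percentage[s$class == "Positive_t"], 20)
  expect_equal(s$total_cells[1], 10L)
  expect_true(all(s$count[s$class != "Positive_t"] == 0L))
  # restricted universe changes the denominator
  uni <- matrix(FALSE, 2, 5); uni[1, ] <- TRUE
  s2 <- summarize_counts(mk_cf(r_t, p_t, 0L, "tas"), mk_cf(r_p, p_p, 0L, "pr"),
                         universe = uni)
  expect_equal(s2$total_cells[1], 5L)
  expect_error(summarize_counts(mk_cf(r_t, p_t, 0L, "tas"),
                                mk_cf(r_p, p_p, 0L, "pr"),
                                universe = matrix(FALSE, 2, 5)),
               "empty")
})

test_that("best-of-lags takes the larger absolute r with ties to lag 0", {
  g <- grid_spec(n_lat = 1, n_lon = 3)
  mk <- function(r, lag) structure(
    list(r = matrix(r, 1, 3), p = matrix(0.01, 1, 3), n = matrix(25L, 1, 3),
         lag = lag, variable = "tas", grid = g, window = NULL),
    class = "correlation_field")
  b <- best_of_lags(mk(c(0.3, 0.5, NA), 0L), mk(c(-0.5, 0.5, -0.4), 1L))
  expect_equal(unname(b$lag[1, ]), c(1L, 0L, 1L))
  expect_equal(unname(b$r[1, ]), c(-0.5, 0.5, -0.4))
  # full-field argmax agrees with a brute-force per-cell loop
  set.seed(8)
  r0 <- matrix(runif(3, -1, 1), 1, 3); r1 <- matrix(runif(3, -1, 1), 1, 3)
  bb <- best_of_lags(mk(r0, 0L), mk(r1, 1L))
  for (j in 1:3) {
    expected <- if (abs(r1[1, j]) > abs(r0[1, j])) r1[1, j] else r0[1, j]
    expect_equal(bb$r[1, j], expected)
  }
})

test_that("variable dominance records the stronger variable and its response", {
  bt <- list(lag = matrix(1L, 1, 2), r = matrix(c(-0.6, 0.2), 1, 2),
             p = matrix(c(0.004, 0.34), 1, 2), variable = "tas")
  bp <- list(lag = matrix(0L, 1, 2), r = matrix(c(0.4, 0.55), 1, 2),
             p = matrix(c(0.06, 0.004), 1, 2), variable = "pr")
  d <- variable_dominance(bt, bp)
  expect_equal(unname(d$variable[1, ]), c("temperature", "precipitation"))
  expect_equal(unname(d$r[1, ]), c(-0.6, 0.55))
  cnt <- dominance_counts(d)
  expect_equal(cnt$count[cnt$class == "Negative_t"], 1L)
  expect_equal(cnt$count[cnt$class == "Positive_p"], 1L)
  # undefined side: the other dominates, flagged
  bt$r[1, 2] <- NA; bt$p[1, 2] <- NA
  d2 <- variable_dominance(bt, bp)
  expect_equal(d2$variable[1, 2], "precipitation")
  expect_true(d2$flagged[1, 2])
})

test_that("histogram bins are fixed width 0.1 with closed outer edges", {
  h <- correlation_histogram(c(0.05, -1, 1, 0.95, -0.95))
  expect_equal(nrow(h), 20)
  expect_equal(h$count[h$lower == 0.0], 1L)     # 0.05 in [0, 0.1)
  expect_equal(h$count[h$lower == -1], 2L)      # -1 and -0.95 in the lowest bin
  expect_equal(h$count[h$lower == 0.9], 2L)     # 0.95 and 1.0 in the top bin
  expect_equal(sum(h$count), 5L)
  set.seed(10)
  v <- runif(500, -1, 1)
  expect_equal(sum(correlation_histogram(v)$count), 500L)
})

test_that("kernel density is symmetric, normalized, and resolves planted bimodality", {
  d <- max_correlation_density(rep(c(-0.5, 0.5), 40))
  expect_equal(d$density, rev(d$density), tolerance = 1e-9)
  trap <- sum(diff(d$x) * (head(d$density, -1) + tail(d$density, -1)) / 2)
  expect_gt(trap, 0.99); expect_lt(trap, 1.01)
  expect_error(max_correlation_density(c(0.1, 0.2)), "at least 5")
  # two planted populations of opposite sign give two opposite-sign modes
  set.seed(12)
  vals <- c(rnorm(100, 0.6, 0.08), rnorm(100, -0.55, 0.08))
  pk <- borealsens:::density_peaks(max_correlation_density(vals))
  expect_equal(length(pk), 2)
  expect_lt(pk[1], 0); expect_gt(pk[2], 0)
})
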