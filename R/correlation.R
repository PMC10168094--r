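#' Pearson correlation with two-sided p-value
#'
#' Complete-case Pearson correlation with significance from the t
#' distribution on n - 2 degrees of freedom. Pairs with fewer than 5
#' complete observations or a constant input give an undefined (`NA`)
#' result rather than an error, so whole-field sweeps degrade gracefully.
#'
#' @param x,y Paired numeric series.
#' @return Named numeric vector `c(r, p, n)`; `r` and `p` are `NA` when
#'   undefined.
#' @export
pearson_r_p <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 5) return(c(r = NA_real_, p = NA_real_, n = n))
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(c(r = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  c(r = r, p = p, n = n)
}

#' Per-cell analysis windows
#'
#' The fixed window is the same span for every cell (default 1982-2006, 25
#' years, the satellite/model overlap period). The trailing window ends at
#' each cell's last year with data and extends `span` years back, matching
#' the treatment of tree-ring cells whose chronologies end at different
#' dates. Cells with fewer than `span` years of coverage are excluded
#' (`NA` window).
#'
#' @param index An [annual_field()].
#' @param kind `"fixed"` or `"trailing"`.
#' @param span Window length in years (default 25).
#' @param fixed_range Length-2 year range for the fixed window.
#' @return List of matrices `start`, `end` (`n_lat` x `n_lon`), `NA` where a
#'   cell is excluded.
#' @export
analysis_window <- function(index, kind = c("fixed", "trailing"), span = 25,
                            fixed_range = c(1982, 2006)) {
  kind <- match.arg(kind)
  stopifnot(inherits(index, "annual_field"))
  g <- index$grid
  start <- end <- matrix(NA_integer_, g$n_lat, g$n_lon)
  for (i in seq_len(g$n_lat)) {
    for (j in seq_len(g$n_lon)) {
      yrs <- index$years[!is.na(index$values[, i, j])]
      if (length(yrs) == 0) next
      if (kind == "fixed") {
        w <- c(fixed_range[1], fixed_range[2])
        cov <- sum(yrs >= w[1] & yrs <= w[2])
      } else {
        w <- c(max(yrs) - span + 1L, max(yrs))
        cov <- sum(yrs >= w[1] & yrs <= w[2])
      }
      if (cov < span) next   # excluded: insufficient years
      start[i, j] <- w[1]
      end[i, j] <- w[2]
    }
  }
  list(start = start, end = end, kind = kind, span = span)
}

#' Per-cell lagged correlation field
#'
#' For every cell with a defined window, correlates the index with the
#' climate composite shifted back by `lag` years (lag 0 = current summer,
#' lag 1 = previous summer) over that cell's window. Cells with fewer than
#' `min_years` complete pairs in the window are undefined.
#'
#' @param index An [annual_field()] (productivity index).
#' @param climate An [annual_field()] (summer climate composite) covering
#'   the window shifted by `lag`.
#' @param lag Integer lag in years (0 or 1).
#' @param window Output of [analysis_window()] on `index`.
#' @param min_years Minimum complete pairs per cell (default 20 of 25).
#' @return Object of class `correlation_field`: list with matrices `r`, `p`,
#'   `n`, plus `lag`, `variable`, `grid`, `window`.
#' @export
correlation_field <- function(index, climate, lag, window, min_years = 20) {
  stopifnot(inherits(index, "annual_field"), inherits(climate, "annual_field"),
            lag %in% c(0L, 1L))
  g <- index$grid
  stopifnot(g$n_lat == climate$grid$n_lat, g$n_lon == climate$grid$n_lon)
  r <- p <- matrix(NA_real_, g$n_lat, g$n_lon)
  n <- matrix(0L, g$n_lat, g$n_lon)
  for (i in seq_len(g$n_lat)) {
    for (j in seq_len(g$n_lon)) {
      if (is.na(window$start[i, j])) next
      yrs <- window$start[i, j]:window$end[i, j]
      ix <- match(yrs, index$years)
      cx <- match(yrs - lag, climate$years)
      if (anyNA(ix) || anyNA(cx)) next   # insufficient overlap
      res <- pearson_r_p(index$values[cbind(ix, i, j)],
                         climate$values[cbind(cx, i, j)])
      if (res[["n"]] < min_years) next
      r[i, j] <- res[["r"]]
      p[i, j] <- res[["p"]]
      n[i, j] <- as.integer(res[["n"]])
    }
  }
  structure(list(r = r, p = p, n = n, lag = as.integer(lag),
                 variable = climate$variable, grid = g, window = window),
            class = "correlation_field")
}

#' @export
print.correlation_field <- function(x, ...) {
  cat(sprintf("correlation_field vs %s, lag %d: %d cells defined, median r %.3f\n",
              x$variable, x$lag, sum(!is.na(x$r)),
              stats::median(x$r, na.rm = TRUE)))
  invisible(x)
}

#' Classify correlations by sign and significance
#'
#' Exhaustive three-way partition at level `alpha`: significant positive,
#' significant negative, or non-significant. Undefined correlations are
#' classed non-significant (flagged `NA` input is preserved nowhere else).
#'
#' @param r,p Correlation coefficients and two-sided p-values (vectors or
#'   matrices).
#' @param alpha Significance level (default 0.05, applied per cell with no
#'   multiple-testing correction, as in classical response-function maps).
#' @return Character array (same shape): `"positive-significant"`,
#'   `"negative-significant"` or `"non-significant"`.
#' @export
classify_correlation <- function(r, p, alpha = 0.05) {
  out <- array("non-significant", dim = if (is.null(dim(r))) length(r) else dim(r))
  sig <- !is.na(r) & !is.na(p) & p < alpha
  out[sig & r > 0] <- "positive-significant"
  out[sig & r < 0] <- "negative-significant"
  if (is.null(dim(r))) out <- as.vector(out)
  out
}

#' Count significant responses over the analyzed cells
#'
#' Builds one row of the response-count table for a given index and lag:
#' numbers and percentages of cells with significant positive/negative
#' correlations with summer temperature (`Positive_t`, `Negative_t`) and
#' precipitation (`Positive_p`, `Negative_p`). The denominator is the cell
#' universe: by default the cells where the index correlation is defined,
#' but for cross-index comparisons pass the tree-ring data mask so all
#' indices share a universe.
#'
#' @param cf_temp,cf_prec `correlation_field`s of one index against summer
#'   temperature and precipitation at one lag.
#' @param universe Logical matrix of analyzed cells (default: cells defined
#'   in `cf_temp` or `cf_prec`).
#' @param alpha Significance level.
#' @return data.frame with columns `class`, `count`, `percentage`,
#'   `total_cells`.
#' @export
summarize_counts <- function(cf_temp, cf_prec, universe = NULL, alpha = 0.05) {
  stopifnot(inherits(cf_temp, "correlation_field"),
            inherits(cf_prec, "correlation_field"))
  if (is.null(universe)) universe <- !is.na(cf_temp$r) | !is.na(cf_prec$r)
  total <- sum(universe)
  if (total == 0) stop("empty cell universe")
  cls_t <- classify_correlation(cf_temp$r, cf_temp$p, alpha)
  cls_p <- classify_correlation(cf_prec$r, cf_prec$p, alpha)
  cnt <- c(Positive_t = sum(universe & cls_t == "positive-significant"),
           Negative_t = sum(universe & cls_t == "negative-significant"),
           Positive_p = sum(universe & cls_p == "positive-significant"),
           Negative_p = sum(universe & cls_p == "negative-significant"))
  data.frame(class = names(cnt), count = as.integer(cnt),
             percentage = 100 * as.integer(cnt) / total,
             total_cells = total, row.names = NULL)
}

#' Select the stronger of the lag-0 and lag-1 correlations per cell
#'
#' "Strongest" means largest absolute r (the only reading under which a
#' negative response can be the highest); exact ties go to lag 0.
#'
#' @param cf0,cf1 `correlation_field`s at lag 0 and lag 1 for one variable.
#' @return List of matrices `lag`, `r`, `p`; all `NA` where both inputs are
#'   undefined.
#' @export
best_of_lags <- function(cf0, cf1) {
  stopifnot(inherits(cf0, "correlation_field"),
            inherits(cf1, "correlation_field"),
            cf0$lag == 0L, cf1$lag == 1L)
  a0 <- abs(cf0$r); a1 <- abs(cf1$r)
  take1 <- !is.na(a1) & (is.na(a0) | a1 > a0)
  lag <- ifelse(is.na(a0) & is.na(a1), NA_integer_, ifelse(take1, 1L, 0L))
  r <- ifelse(take1, cf1$r, cf0$r)
  p <- ifelse(take1, cf1$p, cf0$p)
  list(lag = lag, r = r, p = p, variable = cf0$variable)
}

#' Per-cell dominant climate variable
#'
#' Compares each cell's best (largest-|r|) temperature and precipitation
#' correlations and records which variable dominates, with the sign,
#' p-value and lag of the dominant correlation. Exact ties go to
#' temperature; if one side is undefined the other dominates (flagged).
#'
#' @param best_temp,best_prec Outputs of [best_of_lags()] for temperature
#'   and precipitation.
#' @return List of matrices `variable` (`"temperature"`/`"precipitation"`),
#'   `r`, `p`, `lag`, `flagged` (one side undefined).
#' @export
variable_dominance <- function(best_temp, best_prec) {
  at <- abs(best_temp$r); ap <- abs(best_prec$r)
  take_p <- !is.na(ap) & (is.na(at) | ap > at)
  none <- is.na(at) & is.na(ap)
  variable <- ifelse(none, NA_character_,
                     ifelse(take_p, "precipitation", "temperature"))
  pick <- function(f_t, f_p) ifelse(take_p, f_p, f_t)
  list(variable = variable,
       r = pick(best_temp$r, best_prec$r),
       p = pick(best_temp$p, best_prec$p),
       lag = pick(best_temp$lag, best_prec$lag),
       flagged = xor(is.na(at), is.na(ap)))
}

#' Count cells by dominant variable and response sign
#'
#' The intensity-of-effects table: among cells where temperature correlates
#' more strongly than precipitation, the number with significant positive
#' (`Positive_t`) and negative (`Negative_t`) dominant correlations, and
#' likewise `Positive_p`/`Negative_p` for precipitation-dominant cells.
#'
#' @param dominance Output of [variable_dominance()].
#' @param alpha Significance level.
#' @return data.frame with columns `class`, `count`.
#' @export
dominance_counts <- function(dominance, alpha = 0.05) {
  cls <- classify_correlation(dominance$r, dominance$p, alpha)
  is_t <- !is.na(dominance$variable) & dominance$variable == "temperature"
  is_p <- !is.na(dominance$variable) & dominance$variable == "precipitation"
  cnt <- c(Positive_t = sum(is_t & cls == "positive-significant"),
           Negative_t = sum(is_t & cls == "negative-significant"),
           Positive_p = sum(is_p & cls == "positive-significant"),
           Negative_p = sum(is_p & cls == "negative-significant"))
  data.frame(class = names(cnt), count = as.integer(cnt), row.names = NULL)
}

#' Histogram of correlation coefficients
#'
#' Fixed bins of width 0.1 spanning \[-1, 1\], half-open on the right except
#' the last bin, which is closed so r = 1 is counted.
#'
#' @param values Correlation coefficients in \[-1, 1\] (`NA` dropped).
#' @return data.frame with `lower`, `upper`, `count`.
#' @export
correlation_histogram <- function(values) {
  values <- values[!is.na(values)]
  stopifnot(all(values >= -1 & values <= 1))
  breaks <- round(seq(-1, 1, by = 0.1), 10)   # exact decimal edges
  bin <- cut(values, breaks, right = FALSE, include.lowest = TRUE)
  cnt <- as.integer(table(bin))
  data.frame(lower = breaks[-length(breaks)], upper = breaks[-1], count = cnt)
}

#' Kernel density of per-cell strongest correlations
#'
#' Gaussian-kernel density with Silverman's rule-of-thumb bandwidth,
#' evaluated on a fixed regular grid over \[-1, 1\]; the smoothed analogue
#' of [correlation_histogram()] used to compare the shapes of correlation
#' distributions across indices.
#'
#' @param values Per-cell best correlation coefficients (>= 5 required).
#' @param n_grid Number of evaluation points.
#' @return data.frame with `x` and `density`.
#' @export
max_correlation_density <- function(values, n_grid = 401) {
  values <- values[!is.na(values)]
  if (length(values) < 5)
    stop("kernel density needs at least 5 values (got ", length(values), ")")
  d <- stats::density(values, bw = "nrd0", kernel = "gaussian",
                      from = -1, to = 1, n = n_grid)
  data.frame(x = d$x, density = d$y)
}

# locations of local maxima of a sampled density curve; maxima below
# `min_frac` of the global maximum are treated as numerical wiggle
density_peaks <- function(dens, min_frac = 0.1) {
  y <- dens$density
  k <- which(diff(sign(diff(y))) == -2) + 1L
  k <- k[y[k] >= min_frac * max(y)]
  dens$x[k]
}
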