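#' Screen site metadata against the boreal study-design criteria
#'
#' A site enters the analysis only if it (a) lies strictly north of 50
#' degrees N (southern limit of the boreal zone), (b) sits below 2000 m
#' elevation (avoiding purely temperature-limited high-altitude stands), and
#' (c) has a chronology ending in 1990 or later, so the recent warming period
#' is covered. Rejections are labelled with the first criterion failed.
#'
#' @param metas data.frame with columns `site_id`, `latitude`, `longitude`,
#'   `elevation`, `last_year`.
#' @param min_lat,max_elev,min_last_year Selection thresholds. Latitude is
#'   strict (`>`), elevation strict (`<`), last year inclusive (`>=`).
#' @return `metas` with added logical `retained` and character `reason`
#'   (`NA` for retained sites).
#' @export
select_sites <- function(metas, min_lat = 50, max_elev = 2000,
                         min_last_year = 1990) {
  need <- c("site_id", "latitude", "elevation", "last_year")
  miss <- setdiff(need, names(metas))
  if (length(miss))
    stop("site metadata missing fields: ", paste(miss, collapse = ", "))
  for (f in setdiff(need, "site_id")) {
    if (anyNA(metas[[f]]))
      stop("missing ", f, " for site ",
           metas$site_id[which(is.na(metas[[f]]))[1]])
  }
  reason <- rep(NA_character_, nrow(metas))
  reason[metas$latitude <= min_lat] <- sprintf("latitude not farther north than %g N", min_lat)
  sel <- is.na(reason) & metas$elevation >= max_elev
  reason[sel] <- sprintf("elevation not lower than %g m", max_elev)
  sel <- is.na(reason) & metas$last_year < min_last_year
  reason[sel] <- sprintf("chronology ends before %d", min_last_year)
  metas$retained <- is.na(reason)
  metas$reason <- reason
  metas
}

# Penalty weight for the discrete cubic smoothing spline whose equivalent
# low-pass filter has amplitude response `gain` at period `wavelength` (years).
# Transfer function of the second-difference penalized smoother on a unit
# annual grid: H(f) = 1 / (1 + 16 lambda sin^4(pi f)).
spline_lambda <- function(wavelength, gain = 0.5) {
  stopifnot(wavelength > 2, gain > 0, gain < 1)
  (1 / gain - 1) / (16 * sin(pi / wavelength)^4)
}

#' Fit a frequency-cutoff smoothing-spline growth curve
#'
#' Fits the age/size trend of a raw ring-width series with a cubic smoothing
#' spline parameterized by its frequency response: the spline, viewed as a
#' low-pass filter, transmits 50% of the amplitude of a sinusoid at the
#' cutoff wavelength (default 128 years), passing slower growth trends nearly
#' unchanged while leaving interannual climate variance in the residual
#' index. Implemented as the discrete second-difference penalized smoother
#' (the equally spaced form of the cubic smoothing spline), whose transfer
#' function 1/(1 + 16*lambda*sin^4(pi*f)) is solved exactly for the cutoff
#' criterion.
#'
#' The fitted curve is floored at 5% of the series mean so the later ratio
#' index cannot blow up on near-zero fits; a warning is issued if the floor
#' engages.
#'
#' @param series A [ring_width_series()] (or any numeric vector of widths).
#' @param cutoff_wavelength Period in years at which the filter gain is 0.5.
#' @return Numeric vector of fitted curve values, same length as the series.
#' @export
fit_detrending_curve <- function(series, cutoff_wavelength = 128) {
  y <- if (inherits(series, "ring_width_series")) series$widths else as.numeric(series)
  n <- length(y)
  if (n < 10) stop("series too short to detrend (need >= 10 years, got ", n, ")")
  lambda <- spline_lambda(cutoff_wavelength)
  # (I + lambda D'D) x = y with D the (n-2) x n second-difference operator
  D <- diff(diag(n), differences = 2)
  curve <- as.numeric(solve(diag(n) + lambda * crossprod(D), y))
  floor_val <- 0.05 * mean(y)
  if (any(curve <= 0))
    warning("non-positive fitted values clamped to curve floor")
  pmax(curve, floor_val)
}

#' Ratio detrending index
#'
#' Divides measured widths by the fitted growth curve, giving a dimensionless
#' index with mean near 1; under a multiplicative (lognormal) growth model
#' this exactly inverts the age trend.
#'
#' @param series A [ring_width_series()].
#' @param curve Fitted curve from [fit_detrending_curve()], same years.
#' @return data.frame with columns `year`, `index`.
#' @export
compute_ratio_index <- function(series, curve) {
  stopifnot(inherits(series, "ring_width_series"),
            length(curve) == length(series$widths))
  if (any(curve <= 0)) stop("detrending curve must be strictly positive")
  data.frame(year = series$years, index = series$widths / curve)
}

#' Average per-tree indices into a site chronology
#'
#' @param indices List of per-tree data.frames with columns `year`, `index`.
#' @param robust Use Tukey's biweight robust mean instead of the arithmetic
#'   mean (default `FALSE`; the arithmetic mean is the literal reading of
#'   "averaging the standardized ring widths").
#' @return data.frame with columns `year`, `index`, `sample_depth`.
#' @export
build_standard_chronology <- function(indices, robust = FALSE) {
  if (length(indices) == 0) stop("no tree indices supplied")
  years <- sort(unique(unlist(lapply(indices, `[[`, "year"))))
  mat <- matrix(NA_real_, length(years), length(indices))
  for (j in seq_along(indices)) {
    mat[match(indices[[j]]$year, years), j] <- indices[[j]]$index
  }
  avg <- if (robust) apply(mat, 1, biweight_mean) else rowMeans(mat, na.rm = TRUE)
  depth <- rowSums(!is.na(mat))
  avg[depth == 0] <- NA_real_
  data.frame(year = years, index = avg, sample_depth = depth)
}

# Tukey's biweight robust mean (c = 9, as used in dendro chronology software)
biweight_mean <- function(x, c = 9, tol = 1e-8, max_iter = 50) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  if (length(x) < 3) return(mean(x))
  m <- stats::median(x)
  for (i in seq_len(max_iter)) {
    s <- stats::median(abs(x - m))
    if (s < tol) return(m)
    u <- (x - m) / (c * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    m_new <- sum(w * x) / sum(w)
    if (abs(m_new - m) < tol) return(m_new)
    m <- m_new
  }
  m
}

#' Mean interseries correlation (rbar)
#'
#' Average Pearson correlation over all tree pairs at a site, each computed
#' on the pair's overlapping years within `period`; pairs overlapping fewer
#' than `min_overlap` years are excluded.
#'
#' @param indices List of per-tree data.frames (`year`, `index`).
#' @param period Optional length-2 year range `c(first, last)` restricting
#'   the years used.
#' @param min_overlap Minimum overlapping years for a pair to count.
#' @return Mean pairwise correlation, or `NA` if fewer than one usable pair.
#' @export
compute_rbar <- function(indices, period = NULL, min_overlap = 10) {
  k <- length(indices)
  if (k < 2) return(NA_real_)
  rs <- numeric()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      a <- indices[[i]]; b <- indices[[j]]
      yrs <- intersect(a$year, b$year)
      if (!is.null(period)) yrs <- yrs[yrs >= period[1] & yrs <= period[2]]
      if (length(yrs) < min_overlap) next
      xa <- a$index[match(yrs, a$year)]
      xb <- b$index[match(yrs, b$year)]
      if (stats::sd(xa) == 0 || stats::sd(xb) == 0) next
      rs <- c(rs, stats::cor(xa, xb))
    }
  }
  if (length(rs) == 0) NA_real_ else mean(rs)
}

#' Expressed population signal (EPS)
#'
#' Quantifies how well a finite sample of `n` trees with mean interseries
#' correlation `rbar` represents the infinite population chronology:
#' `eps = n*rbar / (n*rbar + (1 - rbar))`. Values above 0.85 are the
#' conventional threshold of acceptable chronology quality. Non-positive
#' `rbar` (no common signal) is reported as 0.
#'
#' @param n_trees Number of trees (>= 1).
#' @param rbar Mean interseries correlation in (-1, 1\].
#' @return EPS in \[0, 1\] (`NA` if `rbar` is `NA`).
#' @export
compute_eps <- function(n_trees, rbar) {
  stopifnot(all(n_trees >= 1))
  if (any(rbar > 1, na.rm = TRUE)) stop("rbar cannot exceed 1")
  eps <- n_trees * rbar / (n_trees * rbar + (1 - rbar))
  eps[!is.na(rbar) & rbar <= 0] <- 0
  eps
}

#' Build a full site chronology with quality statistics
#'
#' Convenience wrapper: detrends every tree at a site, averages the ratio
#' indices, and attaches rbar/EPS computed over the common quality period
#' (years >= `eps_start`).
#'
#' @param series List of [ring_width_series()] for one site.
#' @param site_id Site identifier.
#' @param cutoff_wavelength Spline cutoff passed to [fit_detrending_curve()].
#' @param robust Passed to [build_standard_chronology()].
#' @param eps_start First year of the period over which rbar/EPS are computed.
#' @return Object of class `site_chronology`: list with `site_id`, `data`
#'   (year/index/sample_depth data.frame), `rbar`, `eps`, `n_trees`,
#'   `last_year`.
#' @export
build_site_chronology <- function(series, site_id = series[[1]]$site_id,
                                  cutoff_wavelength = 128, robust = FALSE,
                                  eps_start = 1950) {
  if (length(series) == 0) stop("no series for site ", site_id)
  indices <- lapply(series, function(s) {
    compute_ratio_index(s, fit_detrending_curve(s, cutoff_wavelength))
  })
  chron <- build_standard_chronology(indices, robust = robust)
  # trees contributing to the quality period
  in_period <- vapply(indices, function(d) sum(d$year >= eps_start) >= 10, TRUE)
  n_eff <- sum(in_period)
  rbar <- compute_rbar(indices, period = c(eps_start, max(chron$year)))
  eps <- if (is.na(rbar) || n_eff < 2) NA_real_ else compute_eps(n_eff, rbar)
  structure(list(site_id = site_id, data = chron, rbar = rbar, eps = eps,
                 n_trees = length(series),
                 last_year = max(chron$year[!is.na(chron$index)])),
            class = "site_chronology")
}

#' @export
print.site_chronology <- function(x, ...) {
  cat(sprintf("site_chronology %s: %d trees, %d-%d, rbar=%.3f, EPS=%.3f\n",
              x$site_id, x$n_trees, min(x$data$year), x$last_year,
              x$rbar, x$eps))
  invisible(x)
}

#' Screen chronologies by EPS
#'
#' Retains chronologies whose expressed population signal strictly exceeds
#' `threshold`; chronologies with undefined EPS (e.g. single-tree sites) are
#' rejected with reason "insufficient replication".
#'
#' @param chronologies List of `site_chronology` objects.
#' @param threshold EPS screening threshold (default 0.85).
#' @return data.frame with `site_id`, `eps`, `retained`, `reason`.
#' @export
screen_chronologies <- function(chronologies, threshold = 0.85) {
  eps <- vapply(chronologies, function(x) if (is.null(x$eps)) NA_real_ else x$eps, 0)
  ids <- vapply(chronologies, `[[`, "", "site_id")
  retained <- !is.na(eps) & eps > threshold
  reason <- rep(NA_character_, length(eps))
  reason[is.na(eps)] <- "insufficient replication"
  reason[!is.na(eps) & eps <= threshold] <-
    sprintf("EPS not greater than %g", threshold)
  data.frame(site_id = ids, eps = eps, retained = retained, reason = reason)
}
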