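#' Default end-to-end run configuration
#'
#' Flat key-value configuration for [run_pipeline()]. Unknown keys in a user
#' config are errors (fail fast rather than silently ignoring a typo).
#'
#' @return Named list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    cell_size = 2.81, grid_lat_origin = 50, grid_lon_origin = -180,
    grid_n_lat = 4L, grid_n_lon = 6L,
    n_years = 30L, first_year = 1977L,
    sites_per_cell = 2L, trees_per_site = 8L,
    cutoff_wavelength = 128,
    eps_threshold = 0.85, eps_start = 1950L,
    alpha = 0.05, window_span = 25L,
    fixed_window_start = 1982L, fixed_window_end = 2006L,
    robust_mean = FALSE, calendar = "noleap",
    universe = "rwi"
  )
}

#' Load and validate a run configuration
#'
#' @param config Path to a YAML file, a named list of overrides, or `NULL`
#'   for pure defaults.
#' @return Validated configuration list.
#' @export
load_run_config <- function(config = NULL) {
  base <- default_run_config()
  if (is.null(config)) return(base)
  user <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else if (is.list(config)) config
  else stop("config must be a file path or a named list")
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  base[names(user)] <- user
  stopifnot(base$alpha > 0, base$alpha < 1, base$window_span >= 5,
            base$eps_threshold > 0, base$eps_threshold < 1)
  base
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full synthetic comparison pipeline
#'
#' Executes, in dependency order: data simulation (climate, ring-width site
#' network, greenness-like and NPP-like fields), chronology building and EPS
#' screening, point-to-grid aggregation, seasonal compositing, lagged
#' correlation analysis, and summary-table/density generation. Every
#' artifact is a plain-text file under `out`; a manifest with MD5 checksums
#' is written last, so a rerun with the same config and seed can be checked
#' for bit-identical outputs.
#'
#' @param config Passed to [load_run_config()].
#' @param out Output directory (created if needed).
#' @return Invisibly, a list with the key in-memory results and the manifest
#'   data.frame.
#' @export
run_pipeline <- function(config = NULL, out) {
  cfg <- load_run_config(config)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(out, "run_config.yaml"))

  grid <- grid_spec(cfg$cell_size, cfg$grid_lat_origin, cfg$grid_lon_origin,
                    cfg$grid_n_lat, cfg$grid_n_lon)
  scfg <- synthetic_config(grid = grid, n_years = cfg$n_years,
                           first_year = cfg$first_year,
                           sites_per_cell = cfg$sites_per_cell,
                           trees_per_site = cfg$trees_per_site,
                           seed = cfg$seed)

  # --- simulate -------------------------------------------------------------
  sim <- run_stage("simulate", {
    climate <- generate_monthly_climate(scfg)
    net <- generate_ring_width_sites(climate, scfg)
    ndvi <- generate_annual_index_field(climate, scfg$sensitivity$ndvi,
                                        noise_sd = scfg$noise_sd$field,
                                        seed = scfg$seed + 2L)
    npp <- generate_monthly_npp(climate, scfg$sensitivity$npp,
                                noise_sd = scfg$noise_sd$field,
                                seed = scfg$seed + 3L)
    rwl_dir <- file.path(out, "rwl")
    dir.create(rwl_dir, showWarnings = FALSE)
    for (sid in unique(net$meta$site_id)) {
      write_rwl(Filter(function(s) s$site_id == sid, net$series),
                file.path(rwl_dir, paste0(sid, ".rwl")))
    }
    utils::write.csv(net$meta, file.path(out, "site_meta.csv"), row.names = FALSE)
    utils::write.csv(net$truth, file.path(out, "truth.csv"), row.names = FALSE)
    write_field_csv(climate$temperature, file.path(out, "climate_tas.csv"))
    write_field_csv(climate$precipitation, file.path(out, "climate_pr.csv"))
    write_field_csv(ndvi, file.path(out, "ndvi_annual.csv"))
    write_field_csv(npp, file.path(out, "npp_monthly.csv"))
    list(climate = climate, net = net, ndvi = ndvi, npp = npp)
  })

  # --- chronologies ---------------------------------------------------------
  chr <- run_stage("chronologies", {
    meta <- select_sites(sim$net$meta)
    keep <- meta$site_id[meta$retained]
    chrons <- lapply(keep, function(sid) {
      build_site_chronology(Filter(function(s) s$site_id == sid, sim$net$series),
                            site_id = sid,
                            cutoff_wavelength = cfg$cutoff_wavelength,
                            robust = cfg$robust_mean,
                            eps_start = cfg$eps_start)
    })
    scr <- screen_chronologies(chrons, threshold = cfg$eps_threshold)
    utils::write.csv(scr, file.path(out, "screening.csv"), row.names = FALSE)
    chrons <- chrons[scr$retained]
    tab <- do.call(rbind, lapply(chrons, function(x)
      cbind(site_id = x$site_id, x$data)))
    utils::write.csv(tab, file.path(out, "chronologies.csv"), row.names = FALSE)
    chrons
  })

  # --- regrid ---------------------------------------------------------------
  rwi <- run_stage("regrid", {
    f <- aggregate_points_to_grid(chr, sim$net$meta, grid)
    write_field_csv(f, file.path(out, "rwi_grid.csv"))
    utils::write.csv(attr(f, "assignment"),
                     file.path(out, "site_cell_assignment.csv"),
                     row.names = FALSE)
    f
  })

  # --- composite ------------------------------------------------------------
  comp <- run_stage("composite", {
    tas <- summer_composite(sim$climate$temperature)
    pr <- summer_composite(sim$climate$precipitation)
    npp_a <- annual_npp_total(sim$npp, flux_per_second = FALSE,
                              calendar = cfg$calendar)
    write_field_csv(tas, file.path(out, "tas_summer.csv"))
    write_field_csv(pr, file.path(out, "pr_summer.csv"))
    write_field_csv(npp_a, file.path(out, "npp_annual.csv"))
    list(tas = tas, pr = pr, npp_a = npp_a)
  })

  # --- correlate + summarize ------------------------------------------------
  res <- run_stage("correlate", {
    fixed <- c(cfg$fixed_window_start, cfg$fixed_window_end)
    indices <- list(rwi = list(field = rwi, kind = "trailing"),
                    ndvi = list(field = sim$ndvi, kind = "fixed"),
                    npp = list(field = comp$npp_a, kind = "fixed"))
    universe <- NULL
    all_cf <- list()
    summary_rows <- list()
    dom_rows <- list()
    hist_rows <- list()
    dens_rows <- list()
    for (nm in names(indices)) {
      fld <- indices[[nm]]$field
      win <- analysis_window(fld, indices[[nm]]$kind, span = cfg$window_span,
                             fixed_range = fixed)
      cf <- list()
      for (lag in 0:1) {
        cf[[paste0("t", lag)]] <- correlation_field(fld, comp$tas, lag, win)
        cf[[paste0("p", lag)]] <- correlation_field(fld, comp$pr, lag, win)
      }
      if (nm == "rwi" && identical(cfg$universe, "rwi"))
        universe <- !is.na(cf$t0$r) | !is.na(cf$t1$r)
      all_cf[[nm]] <- cf
      for (lag in 0:1) {
        s <- summarize_counts(cf[[paste0("t", lag)]], cf[[paste0("p", lag)]],
                              universe = universe, alpha = cfg$alpha)
        summary_rows[[paste(nm, lag)]] <- cbind(index = nm, lag = lag, s)
        ht <- correlation_histogram(cf[[paste0("t", lag)]]$r)
        hp <- correlation_histogram(cf[[paste0("p", lag)]]$r)
        hist_rows[[paste(nm, "t", lag)]] <-
          cbind(index = nm, variable = "temperature", lag = lag, ht)
        hist_rows[[paste(nm, "p", lag)]] <-
          cbind(index = nm, variable = "precipitation", lag = lag, hp)
      }
      bt <- best_of_lags(cf$t0, cf$t1)
      bp <- best_of_lags(cf$p0, cf$p1)
      dom <- variable_dominance(bt, bp)
      dom_rows[[nm]] <- cbind(index = nm, dominance_counts(dom, cfg$alpha))
      best_all <- ifelse(!is.na(dom$r), dom$r, NA_real_)
      vals <- best_all[!is.na(best_all)]
      if (length(vals) >= 5) {
        dens <- max_correlation_density(vals)
        dens_rows[[nm]] <- cbind(index = nm, dens)
      }
    }
    utils::write.csv(do.call(rbind, summary_rows),
                     file.path(out, "summary_counts.csv"), row.names = FALSE)
    utils::write.csv(do.call(rbind, dom_rows),
                     file.path(out, "dominance_counts.csv"), row.names = FALSE)
    utils::write.csv(do.call(rbind, hist_rows),
                     file.path(out, "histograms.csv"), row.names = FALSE)
    if (length(dens_rows))
      utils::write.csv(do.call(rbind, dens_rows),
                       file.path(out, "density.csv"), row.names = FALSE)
    # long-format correlation table
    corr_long <- do.call(rbind, lapply(names(all_cf), function(nm) {
      do.call(rbind, lapply(all_cf[[nm]], function(cf) {
        idx <- which(!is.na(cf$r), arr.ind = TRUE)
        if (nrow(idx) == 0) return(NULL)
        data.frame(index = nm, variable = cf$variable, lag = cf$lag,
                   row = idx[, 1], col = idx[, 2],
                   r = cf$r[idx], p = cf$p[idx], n = cf$n[idx])
      }))
    }))
    utils::write.csv(corr_long, file.path(out, "correlations.csv"),
                     row.names = FALSE)
    all_cf
  })

  manifest <- run_stage("manifest", {
    files <- sort(setdiff(list.files(out, recursive = TRUE), "manifest.csv"))
    md5 <- tools::md5sum(file.path(out, files))
    m <- data.frame(file = files, md5 = unname(md5),
                    size = file.size(file.path(out, files)))
    con <- file(file.path(out, "manifest.csv"), "w")
    writeLines(sprintf("# borealsens %s seed=%d",
                       as.character(utils::packageVersion("borealsens")),
                       cfg$seed), con)
    utils::write.csv(m, con, row.names = FALSE)
    close(con)
    m
  })

  invisible(list(config = cfg, rwi = rwi, correlations = res,
                 manifest = manifest, out = out))
}

#' Print a human-readable report of a pipeline run
#'
#' Reads the summary artifacts of a [run_pipeline()] output directory and
#' prints the response-count tables (per index and lag), the dominant-
#' variable table, and the locations of the density peaks per index.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return Invisibly, a list of the tables printed.
#' @export
report_summary <- function(run_dir) {
  sf <- file.path(run_dir, "summary_counts.csv")
  if (!file.exists(sf))
    stop("missing output of stage 'correlate' in ", run_dir,
         " (summary_counts.csv)")
  summary <- utils::read.csv(sf)
  dom <- utils::read.csv(file.path(run_dir, "dominance_counts.csv"))
  if (nrow(summary) == 0 || all(summary$total_cells == 0)) {
    cat("no analyzable cells\n")
    return(invisible(NULL))
  }
  cat("== Significant responses per index and lag (count / % of universe) ==\n")
  for (nm in unique(summary$index)) {
    for (lag in unique(summary$lag)) {
      s <- summary[summary$index == nm & summary$lag == lag, ]
      cat(sprintf("%-5s lag %d (n=%d): %s\n", nm, lag, s$total_cells[1],
                  paste(sprintf("%s %d (%.1f%%)", s$class, s$count,
                                s$percentage), collapse = ", ")))
    }
  }
  cat("\n== Dominant-variable counts ==\n")
  for (nm in unique(dom$index)) {
    s <- dom[dom$index == nm, ]
    cat(sprintf("%-5s: %s\n", nm,
                paste(sprintf("%s %d", s$class, s$count), collapse = ", ")))
  }
  peaks <- NULL
  df <- file.path(run_dir, "density.csv")
  if (file.exists(df)) {
    dens <- utils::read.csv(df)
    cat("\n== Density peaks of strongest correlations ==\n")
    peaks <- lapply(split(dens, dens$index), function(d)
      density_peaks(d[order(d$x), ]))
    for (nm in names(peaks))
      cat(sprintf("%-5s: peaks at %s\n", nm,
                  paste(sprintf("%.2f", peaks[[nm]]), collapse = ", ")))
    # dominant class per index, from summary at the dominant lag
  }
  invisible(list(summary = summary, dominance = dom, peaks = peaks))
}
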