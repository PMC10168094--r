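#' One tree's annual ring-width series
#'
#' @param series_id Measurement series identifier (max 8 characters for
#'   round-tripping through the Tucson format).
#' @param years Contiguous ascending calendar years.
#' @param widths Positive ring widths in units of 0.01 mm.
#' @param site_id Optional site identifier.
#' @return Object of class `ring_width_series`.
#' @export
ring_width_series <- function(series_id, years, widths, site_id = NA_character_) {
  years <- as.integer(years)
  stopifnot(length(years) == length(widths), length(years) >= 1)
  if (length(years) > 1 && any(diff(years) != 1L))
    stop("years must be strictly consecutive in series ", series_id)
  if (any(!is.finite(widths)) || any(widths <= 0))
    stop("widths must be positive in series ", series_id)
  structure(list(series_id = as.character(series_id), site_id = site_id,
                 years = years, widths = as.numeric(widths)),
            class = "ring_width_series")
}

#' @export
print.ring_width_series <- function(x, ...) {
  cat(sprintf("ring_width_series %s (site %s): %d years %d-%d, mean width %.1f (0.01 mm)\n",
              x$series_id, x$site_id, length(x$years), min(x$years),
              max(x$years), mean(x$widths)))
  invisible(x)
}

#' Read a Tucson decadal ring-width (.rwl) file
#'
#' Parses the ITRDB interchange format: series id in columns 1-8, then the
#' decade start year and up to ten values per line. A terminator of `999`
#' marks a series measured to 0.01 mm precision; `-9999` marks 0.001 mm
#' precision, in which case values are rescaled to the internal 0.01 mm unit.
#'
#' @param path Path to a .rwl file.
#' @param site_id Site identifier attached to every series (defaults to the
#'   file name without extension).
#' @return A list of [ring_width_series()] objects (empty, with a warning,
#'   for an empty file).
#' @export
read_rwl <- function(path, site_id = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty rwl file: ", path)
    return(list())
  }
  acc <- list()   # per series id: list(years=, vals=, done=, prec=)
  order_ids <- character()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    id <- trimws(substr(ln, 1, 8))
    rest <- substr(ln, 9, nchar(ln))
    toks <- strsplit(trimws(rest), "\\s+")[[1]]
    if (!nzchar(id) || length(toks) < 2)
      stop(sprintf("malformed rwl line %d in %s", i, path))
    num <- suppressWarnings(as.numeric(toks))
    if (anyNA(num))
      stop(sprintf("malformed rwl line %d in %s: non-numeric field", i, path))
    year0 <- as.integer(num[1])
    vals <- num[-1]
    if (is.null(acc[[id]])) {
      acc[[id]] <- list(years = integer(), vals = numeric(),
                        done = FALSE, prec = NA_real_)
      order_ids <- c(order_ids, id)
    }
    s <- acc[[id]]
    term <- NA_real_
    if (any(vals == 999)) {
      k <- which(vals == 999)[1]
      term <- 0.01
      vals <- vals[seq_len(k - 1)]
    } else if (any(vals == -9999)) {
      k <- which(vals == -9999)[1]
      term <- 0.001
      vals <- vals[seq_len(k - 1)]
    }
    yrs <- seq(year0, length.out = length(vals))
    if (any(yrs %in% s$years))
      stop(sprintf("duplicate (series, year) for '%s' at line %d in %s", id, i, path))
    s$years <- c(s$years, yrs)
    s$vals <- c(s$vals, vals)
    if (!is.na(term)) {
      s$done <- TRUE
      s$prec <- term
    }
    acc[[id]] <- s
  }
  out <- lapply(order_ids, function(id) {
    s <- acc[[id]]
    prec <- if (is.na(s$prec)) 0.01 else s$prec   # unterminated: assume 0.01 mm
    w <- if (prec == 0.001) s$vals / 10 else s$vals
    ring_width_series(id, s$years, w, site_id = site_id)
  })
  out
}

#' Write ring-width series to a Tucson decadal (.rwl) file
#'
#' Values are written as integers in 0.01 mm with the `999` terminator, so a
#' write/read round trip is lossless for widths quantized to 0.01 mm.
#'
#' @param series A list of [ring_width_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rwl <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in series) {
    if (nchar(s$series_id) > 8)
      stop("series_id longer than 8 characters: ", s$series_id)
    vals <- round(s$widths)
    yrs <- s$years
    i <- 1L
    while (i <= length(yrs)) {
      y <- yrs[i]
      decade_end <- (y %/% 10) * 10 + 9
      j <- min(which(yrs > decade_end)[1] - 1L, length(yrs), na.rm = TRUE)
      chunk <- vals[i:j]
      line <- sprintf("%-8s%4d%s", s$series_id, y,
                      paste0(sprintf("%6d", chunk), collapse = ""))
      if (j == length(yrs)) line <- paste0(line, sprintf("%6d", 999L))
      writeLines(line, con)
      i <- j + 1L
    }
  }
  invisible(path)
}
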