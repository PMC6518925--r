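#' Daily water temperature series
#'
#' Constructs a `temp_series`: a data frame of consecutive calendar days and
#' daily mean water temperatures (degrees C), the sole environmental driver of
#' embryo development in this package. Dates must be strictly increasing with
#' no duplicates; days missing from the input are inserted with `NA`
#' temperature so that downstream accumulation can flag them explicitly
#' (see [fill_gaps()]).
#'
#' @param dates `Date` vector (or ISO-8601 strings), one per observation.
#' @param temp_c numeric daily mean temperatures in degrees C.
#' @param site_id short text label for the site/tank the series describes.
#' @return a data frame of class `temp_series` with columns `date`, `temp_c`
#'   and attribute `site_id`.
#' @examples
#' ts <- temperature_series(as.Date("2016-11-01") + 0:9, rep(5.3, 10))
#' @export
temperature_series <- function(dates, temp_c, site_id = "site") {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("dates contain NA or unparseable values")
  if (length(dates) != length(temp_c)) {
    stop("dates and temp_c must have equal length")
  }
  if (is.unsorted(dates, strictly = TRUE)) {
    stop("dates must be strictly increasing with no duplicates")
  }
  temp_c <- as.numeric(temp_c)
  if (any(is.infinite(temp_c))) stop("temperatures must be finite (or NA)")
  full <- seq(dates[1L], dates[length(dates)], by = "day")
  tmp <- rep(NA_real_, length(full))
  tmp[match(dates, full)] <- temp_c
  out <- data.frame(date = full, temp_c = tmp)
  attr(out, "site_id") <- site_id
  class(out) <- c("temp_series", "data.frame")
  out
}

#' @export
print.temp_series <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf(
    "<temp_series> site '%s': %d days, %s to %s\n",
    attr(x, "site_id") %||% "?", n,
    format(x$date[1L]), format(x$date[n])
  ))
  ok <- !is.na(x$temp_c)
  if (any(ok)) {
    cat(sprintf(
      "  temp_c: mean %.2f, range %.2f..%.2f, %d missing day(s)\n",
      mean(x$temp_c[ok]), min(x$temp_c[ok]), max(x$temp_c[ok]), sum(!ok)
    ))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_temp_series <- function(x, site_id = attr(x, "site_id") %||% "site") {
  if (inherits(x, "temp_series")) return(x)
  stopifnot(is.data.frame(x), all(c("date", "temp_c") %in% names(x)))
  temperature_series(x$date, x$temp_c, site_id = site_id)
}

#' Read / write a temperature series as CSV
#'
#' The on-disk dialect is a two-column CSV with header `date,temp_c`,
#' ISO-8601 dates, one row per day.
#'
#' @param path file path.
#' @param site_id site label attached to the series (defaults to the file
#'   name without extension).
#' @return `read_temperature_csv()` returns a `temp_series`;
#'   `write_temperature_csv()` invisibly returns `path`.
#' @export
read_temperature_csv <- function(path, site_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || !all(c("date", "temp_c") %in% names(df))) {
    stop(sprintf("'%s': expected non-empty CSV with header date,temp_c", path))
  }
  bad <- which(is.na(suppressWarnings(as.numeric(df$temp_c))) & !is.na(df$temp_c) &
                 df$temp_c != "")
  if (length(bad)) {
    stop(sprintf("'%s': line %d, column temp_c: not a number ('%s')",
                 path, bad[1L] + 1L, df$temp_c[bad[1L]]))
  }
  d <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(d)) {
    stop(sprintf("'%s': line %d, column date: not an ISO-8601 date ('%s')",
                 path, which(is.na(d))[1L] + 1L, df$date[which(is.na(d))[1L]]))
  }
  temperature_series(d, as.numeric(df$temp_c),
                     site_id = site_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_temperature_csv
#' @param series a `temp_series`.
#' @export
write_temperature_csv <- function(series, path) {
  series <- as_temp_series(series)
  utils::write.csv(
    data.frame(date = format(series$date), temp_c = series$temp_c),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

# Daily temperatures used for thermal-unit (ATU) sums: negative daily means
# are clamped to 0 (thermal units are non-negative). Configurable.
atu_temps <- function(temps, clamp_negative_atu = TRUE) {
  if (clamp_negative_atu) pmax(temps, 0) else temps
}

#' Accumulated thermal units between two points of a series
#'
#' ATU is the running sum of daily mean water temperatures (degree C days)
#' from a start date. The end point may be fractional: whole days contribute
#' their full daily mean and the final partial day is pro-rated.
#'
#' @param series a `temp_series` (or data frame with `date`, `temp_c`).
#' @param start_date first day of the span (counted as day 0, contributing
#'   its full daily mean once one day has elapsed).
#' @param end_point elapsed time in days from the start of `start_date`
#'   (may be fractional; 0 gives 0 ATU).
#' @param clamp_negative_atu clamp sub-zero daily means to 0 before summing?
#' @return ATU accumulated over the span (degrees C x days).
#' @examples
#' s <- temperature_series(as.Date("2017-01-01") + 0:2, c(2, 4, 6))
#' atu_between(s, as.Date("2017-01-01"), 2.5) # 2 + 4 + 3 = 9
#' @export
atu_between <- function(series, start_date, end_point,
                        clamp_negative_atu = TRUE) {
  series <- as_temp_series(series)
  start_date <- as.Date(start_date)
  if (!is.finite(end_point) || end_point < 0) {
    stop("end_point must be a non-negative number of days")
  }
  i0 <- match(start_date, series$date)
  if (is.na(i0)) stop("start_date is not within the series")
  whole <- floor(end_point)
  frac <- end_point - whole
  if (i0 + whole + (frac > 0) - 1 > nrow(series)) {
    stop("span extends beyond the end of the series")
  }
  temps <- atu_temps(series$temp_c[seq(i0, length.out = whole + (frac > 0))],
                     clamp_negative_atu)
  if (anyNA(temps)) stop("span contains missing temperatures; fill gaps first")
  s <- if (whole > 0) sum(temps[seq_len(whole)]) else 0
  if (frac > 0) s <- s + frac * temps[whole + 1L]
  s
}

#' Fill short gaps in a temperature series
#'
#' Runs of missing days no longer than `max_gap_days` are filled by linear
#' interpolation between the bracketing observed days. Longer gaps are left
#' missing and recorded on the returned object so that any accumulation that
#' crosses them is flagged (never silently extrapolated). Optionally clamps
#' sub-zero logger readings at 0.1 degrees C, the rate-evaluation floor used
#' by the development models.
#'
#' @param series a `temp_series`.
#' @param max_gap_days longest gap (in days) that will be interpolated.
#'   Default 3.
#' @param clamp_low_c if non-`NULL`, observed temperatures below this value
#'   are raised to it (default `NULL`: leave readings untouched).
#' @return a `temp_series` with attribute `gaps`: a data frame of all gaps
#'   (columns `start`, `end`, `days`, `filled`).
#' @examples
#' s <- temperature_series(as.Date("2017-01-01") + c(0, 2), c(4, 6))
#' fill_gaps(s)$temp_c # 4, 5, 6
#' @export
fill_gaps <- function(series, max_gap_days = 3, clamp_low_c = NULL) {
  series <- as_temp_series(series)
  miss <- is.na(series$temp_c)
  gaps <- data.frame(start = as.Date(character()), end = as.Date(character()),
                     days = integer(), filled = logical())
  if (any(miss)) {
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i <- starts[k]; j <- ends[k]
      len <- j - i + 1L
      fill <- len <= max_gap_days && i > 1L && j < nrow(series)
      if (fill) {
        lo <- series$temp_c[i - 1L]; hi <- series$temp_c[j + 1L]
        series$temp_c[i:j] <- lo + (hi - lo) * seq_len(len) / (len + 1L)
      }
      gaps <- rbind(gaps, data.frame(
        start = series$date[i], end = series$date[j],
        days = len, filled = fill
      ))
    }
  }
  if (!is.null(clamp_low_c)) {
    series$temp_c <- ifelse(!is.na(series$temp_c) & series$temp_c < clamp_low_c,
                            clamp_low_c, series$temp_c)
  }
  attr(gaps, "row.names") <- seq_len(nrow(gaps))
  attr(series, "gaps") <- gaps
  series
}
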