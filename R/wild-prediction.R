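#' Spawning window
#'
#' Calendar interval of assumed egg deposition. The default window,
#' 24 October - 7 November, is the two-week spawning period assumed for the
#' emulated wild population; both endpoints are configuration options.
#'
#' @param start,end dates (or `"MM-DD"` strings combined with `year`).
#' @param year spawn year used when `start`/`end` are month-day strings.
#' @return object of class `spawn_window` (list with `start`, `end`).
#' @export
spawn_window <- function(start = "10-24", end = "11-07", year = NULL) {
  to_date <- function(x) {
    if (inherits(x, "Date")) return(x)
    if (grepl("^\\d{4}-", x)) return(as.Date(x))
    if (is.null(year)) stop("month-day endpoints need a year")
    as.Date(sprintf("%d-%s", year, x))
  }
  start <- to_date(start); end <- to_date(end)
  if (start > end) stop("spawn window start must not be after its end")
  structure(list(start = start, end = end), class = "spawn_window")
}

#' Predict hatch and emergence windows for one spawning season
#'
#' Runs development accumulation from each boundary spawn date (optionally a
#' daily grid across the window): the hatch window spans the 50%-hatch dates
#' predicted from the earliest and latest spawn dates, the emergence window
#' likewise at the emergence threshold (models without an emergence
#' threshold yield `NA` emergence columns). Seasons whose accumulation runs
#' into an unfilled gap or off the end of the series are flagged and their
#' windows left absent.
#'
#' @param series a `temp_series` covering the window through the following
#'   summer (gap-fill first with [fill_gaps()]).
#' @param window a [spawn_window()] with concrete dates.
#' @param model a [dev_model()]; default the Gorodilov model, whose 315 /
#'   450 somite-unit thresholds give 50% hatch and emergence.
#' @param grid `"boundaries"` (default) accumulates from the two window
#'   endpoints; `"daily"` from every day in the window (windows then span
#'   the min/max event dates).
#' @return one-row data frame of class `prediction_window`: `site`,
#'   `season_year`, `hatch_start`, `hatch_end`, `emerge_start`,
#'   `emerge_end`, `hatch_dur_d`, `emerge_dur_d`, `status`.
#' @export
predict_windows <- function(series, window, model = dev_model("gorodilov"),
                            grid = c("boundaries", "daily")) {
  grid <- match.arg(grid)
  series <- as_temp_series(series)
  stopifnot(inherits(window, "spawn_window"))
  spawn_dates <- if (grid == "daily") {
    seq(window$start, window$end, by = "day")
  } else unique(c(window$start, window$end))
  has_emerge <- "emergence" %in% names(model$event_thresholds)

  hatch <- emerge <- as.Date(rep(NA, length(spawn_dates)))
  status <- "ok"
  for (j in seq_along(spawn_dates)) {
    if (!spawn_dates[j] %in% series$date) { status <- "spawn_outside_series"; break }
    tr <- accumulate_development(series, model, spawn_dates[j])
    ev <- tr$events
    h <- ev[ev$event %in% c("hatch50", "hatch90"), ][1L, ]
    if (!isTRUE(h$resolved)) {
      status <- if (tr$truncated_at_gap) "gap_unresolved" else "series_too_short"
      break
    }
    hatch[j] <- h$event_date
    if (has_emerge) {
      e <- ev[ev$event == "emergence", ]
      if (!isTRUE(e$resolved)) {
        status <- if (tr$truncated_at_gap) "gap_unresolved" else "series_too_short"
        break
      }
      emerge[j] <- e$event_date
    }
  }
  ok <- status == "ok"
  out <- data.frame(
    site = attr(series, "site_id") %||% "site",
    season_year = as.integer(format(window$start, "%Y")),
    hatch_start = if (ok) min(hatch) else as.Date(NA),
    hatch_end = if (ok) max(hatch) else as.Date(NA),
    emerge_start = if (ok && has_emerge) min(emerge) else as.Date(NA),
    emerge_end = if (ok && has_emerge) max(emerge) else as.Date(NA),
    status = status
  )
  out$hatch_dur_d <- as.numeric(out$hatch_end - out$hatch_start)
  out$emerge_dur_d <- as.numeric(out$emerge_end - out$emerge_start)
  class(out) <- c("prediction_window", "data.frame")
  out
}

#' Predict windows for every spawning season covered by a series
#'
#' Applies [predict_windows()] with the same month-day spawning window to
#' each year of the series (a season belongs to the year of its spawn
#' start).
#'
#' @param series a `temp_series` spanning one or more autumn-to-summer
#'   seasons.
#' @param start_md,end_md spawning window endpoints as `"MM-DD"`.
#' @param model,grid passed to [predict_windows()].
#' @return data frame with one row per season.
#' @export
predict_seasons <- function(series, start_md = "10-24", end_md = "11-07",
                            model = dev_model("gorodilov"),
                            grid = "boundaries") {
  series <- as_temp_series(series)
  years <- sort(unique(as.integer(format(series$date, "%Y"))))
  rows <- list()
  for (y in years) {
    w <- try(spawn_window(start_md, end_md, year = y), silent = TRUE)
    if (inherits(w, "try-error")) next
    if (w$start < series$date[1L] || w$end > series$date[nrow(series)]) next
    rows[[length(rows) + 1L]] <- predict_windows(series, w, model, grid)
  }
  if (!length(rows)) stop("series covers no complete spawning season")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize predicted windows across seasons and sites
#'
#' @param windows data frame of resolved [predict_windows()] rows (possibly
#'   several sites and years; unresolved rows are dropped with a message).
#' @return list with `per_site` and `pooled` summaries: across-year min/max
#'   hatch and emergence dates and mean +/- sample SD of window durations.
#' @export
summarize_windows <- function(windows) {
  ok <- windows$status == "ok"
  if (!any(ok)) stop("no resolved windows to summarize")
  if (any(!ok)) message(sum(!ok), " unresolved window(s) dropped")
  w <- windows[ok, , drop = FALSE]
  sd0 <- function(x) if (sum(!is.na(x)) < 2) 0 else stats::sd(x, na.rm = TRUE)
  summ <- function(d) {
    data.frame(
      n_windows = nrow(d),
      hatch_earliest = min(d$hatch_start), hatch_latest = max(d$hatch_end),
      emerge_earliest = suppressWarnings(min(d$emerge_start, na.rm = TRUE)),
      emerge_latest = suppressWarnings(max(d$emerge_end, na.rm = TRUE)),
      hatch_dur_mean = mean(d$hatch_dur_d),
      hatch_dur_sd = sd0(d$hatch_dur_d),
      emerge_dur_mean = mean(d$emerge_dur_d),
      emerge_dur_sd = sd0(d$emerge_dur_d)
    )
  }
  per_site <- do.call(rbind, lapply(split(w, w$site), summ))
  per_site <- cbind(site = rownames(per_site), per_site)
  rownames(per_site) <- NULL
  list(per_site = per_site, pooled = summ(w))
}
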