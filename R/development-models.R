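#' Closed-form thermal development models for Atlantic salmon embryos
#'
#' Four published temperature-driven models of embryonic development rate.
#' Three express development as days to a hatch event at a given temperature,
#' so that a day at temperature T contributes the developmental fraction
#' 1/D(T) and the event occurs when fractions sum to 1 (rate summation).
#' The fourth (Gorodilov) expresses relative developmental age in tau_s,
#' the minutes required to form one somite pair at temperature T; a day
#' contributes 1440/tau_s(T) somite-units and events occur at fixed
#' cumulative unit totals (peak/50% hatch at 315, emergence at 450).
#'
#' * **Crisp** (daily mean temperature, base-10 logs):
#'   `log10(D) = intercept - 2.6562 * log10(T + 11.0)`, D = days to 50%
#'   hatch. The default intercept 5.1908 is the original Atlantic salmon
#'   constant; it is an overridable parameter of [dev_model()].
#' * **Gorodilov** (daily mean temperature, base-10 logs, valid
#'   0.1-11.0 degrees C): `log10(tau_s) = 3.0984 - 0.0967*T + 0.00207*T^2`.
#' * **WinSIRP** (weekly mean temperature; temperature-only form):
#'   `D = 11248 / (T_wk + 5.3944)^2.0198`, D = days to 50% hatch.
#' * **Kane** (daily mean temperature, natural log):
#'   `ln(D) = 5.483 * exp(-0.0347*T)`, D = days to 90% hatch.
#'
#' All four are strictly decreasing in temperature over their validity
#' ranges. Temperatures below `clamp_low_c` (default 0.1 degrees C, the
#' Gorodilov lower validity bound) are clamped before rate evaluation.
#'
#' @param t_avg daily mean water temperature (degrees C).
#' @param t_wk weekly mean water temperature (degrees C).
#' @param intercept,slope,t_offset Crisp coefficients (base-10 form).
#' @param clamp_low_c lower clamp applied before evaluation; `NULL` disables
#'   clamping (Crisp then errors at or below -`t_offset` degrees C).
#' @return days to the event (`*_days_to_event`) or minutes per somite pair
#'   (`gorodilov_tau_s`), vectorised over temperature.
#' @examples
#' crisp_days_to_event(5.3)
#' gorodilov_tau_s(5.3)
#' winsirp_days_to_event(5.3)
#' kane_days_to_event(0) # exp(5.483)
#' @name development-models
NULL

clamp_temp <- function(t, clamp_low_c = 0.1, clamp_high_c = NULL) {
  if (!all(is.finite(t))) stop("temperature must be finite")
  if (!is.null(clamp_low_c)) t <- pmax(t, clamp_low_c)
  if (!is.null(clamp_high_c)) t <- pmin(t, clamp_high_c)
  t
}

#' @rdname development-models
#' @export
crisp_days_to_event <- function(t_avg, intercept = 5.1908, slope = -2.6562,
                                t_offset = 11.0, clamp_low_c = 0.1) {
  t_avg <- clamp_temp(t_avg, clamp_low_c)
  if (any(t_avg + t_offset <= 0)) {
    stop(sprintf("temperature at or below %.1f C is outside the Crisp domain",
                 -t_offset))
  }
  10^(intercept + slope * log10(t_avg + t_offset))
}

#' @rdname development-models
#' @export
gorodilov_tau_s <- function(t_avg, clamp_low_c = 0.1, clamp_high_c = 11.0) {
  t_avg <- clamp_temp(t_avg, clamp_low_c, clamp_high_c)
  10^(3.0984 - 0.0967 * t_avg + 0.00207 * t_avg^2)
}

#' @rdname development-models
#' @export
winsirp_days_to_event <- function(t_wk, clamp_low_c = 0.1) {
  t_wk <- clamp_temp(t_wk, clamp_low_c)
  if (any(t_wk <= -5.3944)) {
    stop("temperature at or below -5.3944 C is outside the WinSIRP domain")
  }
  11248 / (t_wk + 5.3944)^2.0198
}

#' @rdname development-models
#' @export
kane_days_to_event <- function(t_avg, clamp_low_c = 0.1) {
  t_avg <- clamp_temp(t_avg, clamp_low_c)
  exp(5.483 * exp(-0.0347 * t_avg))
}

#' Development model object
#'
#' Bundles a named development model with its printed coefficients, event
#' thresholds in model-native units, accumulation time step and clamping
#' policy. `crisp` and `winsirp` predict 50% hatch, `kane` predicts 90%
#' hatch (each: threshold 1 developmental fraction); `gorodilov` predicts
#' 50% hatch at 315 and emergence at 450 accumulated somite-units.
#'
#' @param name one of `"crisp"`, `"gorodilov"`, `"winsirp"`, `"kane"`.
#' @param event_thresholds named numeric vector of event -> threshold in
#'   model-native units; defaults to the model's published events.
#' @param clamp_low_c lower temperature clamp for rate evaluation (degrees C).
#' @param clamp_negative_atu clamp negative daily means to 0 in ATU sums?
#' @param ... model coefficient overrides (currently Crisp's `intercept`,
#'   `slope`, `t_offset`).
#' @return an object of class `dev_model`.
#' @examples
#' m <- dev_model("gorodilov")
#' m$event_thresholds
#' @export
dev_model <- function(name = c("crisp", "gorodilov", "winsirp", "kane"),
                      event_thresholds = NULL, clamp_low_c = 0.1,
                      clamp_negative_atu = TRUE, ...) {
  name <- match.arg(name)
  dots <- list(...)
  defaults <- switch(name,
    crisp = list(
      thresholds = c(hatch50 = 1), time_step = "daily", log_base = 10,
      parameters = list(intercept = 5.1908, slope = -2.6562, t_offset = 11.0)
    ),
    gorodilov = list(
      thresholds = c(hatch50 = 315, emergence = 450), time_step = "daily",
      log_base = 10,
      parameters = list(a = 3.0984, b = -0.0967, c = 0.00207,
                        clamp_high_c = 11.0)
    ),
    winsirp = list(
      thresholds = c(hatch50 = 1), time_step = "weekly", log_base = 10,
      parameters = list(numerator = 11248, t_offset = 5.3944,
                        exponent = 2.0198)
    ),
    kane = list(
      thresholds = c(hatch90 = 1), time_step = "daily", log_base = exp(1),
      parameters = list(a = 5.483, b = -0.0347)
    )
  )
  pars <- utils::modifyList(defaults$parameters, dots)
  thresholds <- event_thresholds %||% defaults$thresholds
  if (is.null(names(thresholds)) || any(!nzchar(names(thresholds)))) {
    stop("event_thresholds must be a named numeric vector")
  }
  if (any(thresholds < 0)) stop("event thresholds must be non-negative")
  structure(
    list(name = name, parameters = pars, event_thresholds = thresholds,
         time_step = defaults$time_step, log_base = defaults$log_base,
         clamp_low_c = clamp_low_c, clamp_negative_atu = clamp_negative_atu),
    class = "dev_model"
  )
}

#' @export
print.dev_model <- function(x, ...) {
  cat(sprintf("<dev_model> %s (%s time step)\n", x$name, x$time_step))
  cat("  events:", paste(sprintf("%s=%g", names(x$event_thresholds),
                                 x$event_thresholds), collapse = ", "), "\n")
  invisible(x)
}

# Daily development increment at (already clamped) temperature, in
# model-native units: somite-units/day for gorodilov, fraction/day otherwise.
daily_increment <- function(model, temps) {
  p <- model$parameters
  switch(model$name,
    crisp = 1 / crisp_days_to_event(temps, p$intercept, p$slope, p$t_offset,
                                    clamp_low_c = NULL),
    gorodilov = 1440 / gorodilov_tau_s(temps, clamp_low_c = NULL,
                                       clamp_high_c = NULL),
    winsirp = 1 / winsirp_days_to_event(temps, clamp_low_c = NULL),
    kane = 1 / kane_days_to_event(temps, clamp_low_c = NULL)
  )
}

#' Closed-form days to event at constant temperature
#'
#' @param model a [dev_model()].
#' @param t_c constant temperature (degrees C).
#' @param event event name; default the model's first event.
#' @return days until the event threshold is reached at constant `t_c`.
#' @export
days_to_event <- function(model, t_c, event = names(model$event_thresholds)[1L]) {
  stopifnot(inherits(model, "dev_model"))
  thr <- model$event_thresholds[[event]]
  t_c <- clamp_temp(t_c, model$clamp_low_c,
                    model$parameters$clamp_high_c %||% NULL)
  thr / daily_increment(model, t_c)
}

#' Accumulate development over a temperature series
#'
#' Discrete-time rate summation: each calendar day contributes a development
#' increment determined by the model evaluated at that day's (clamped) mean
#' temperature -- for WinSIRP, at the mean of the day's 7-day block counted
#' from `start_date` (trailing partial blocks use their own mean). An event
#' fires on the first day its cumulative threshold is reached; linear
#' interpolation within the crossing day gives the fractional offset. The
#' fertilization/spawn day is day 0 and contributes the first increment, so
#' under constant temperature the accumulated event time equals the model's
#' closed form. ATU at the event is the sum of daily means through the
#' fractional crossing point.
#'
#' If the series ends (or hits an unfilled gap) before a threshold is
#' reached, the event is returned unresolved (`resolved = FALSE`) -- never
#' silently extrapolated.
#'
#' @param series a `temp_series`.
#' @param model a [dev_model()].
#' @param start_date fertilization (or spawn) date; must lie in the series.
#' @param events named thresholds to resolve; defaults to the model's.
#' @return an object of class `dev_trajectory`: list with `daily` (per-day
#'   data frame: `date`, `temp_c`, `rate_temp_c`, `increment`,
#'   `cum_development`, `cum_atu`) and `events` (per-event data frame:
#'   `event`, `threshold`, `resolved`, `event_date`, `dpf`, `atu`).
#' @examples
#' s <- temperature_series(as.Date("2016-11-01") + 0:150, rep(5.3, 151))
#' tr <- accumulate_development(s, dev_model("gorodilov"), as.Date("2016-11-01"))
#' tr$events
#' @export
accumulate_development <- function(series, model, start_date,
                                   events = model$event_thresholds) {
  series <- as_temp_series(series)
  stopifnot(inherits(model, "dev_model"))
  start_date <- as.Date(start_date)
  i0 <- match(start_date, series$date)
  if (is.na(i0)) stop("start_date is not within the series")
  temps <- series$temp_c[i0:nrow(series)]
  # truncate at the first missing day: beyond it development is unknowable
  firstna <- which(is.na(temps))[1L]
  hit_gap <- !is.na(firstna)
  if (hit_gap) temps <- temps[seq_len(firstna - 1L)]
  n <- length(temps)
  if (n == 0L) stop("series has no usable days at start_date")

  rate_temp <- clamp_temp(temps, model$clamp_low_c,
                          model$parameters$clamp_high_c %||% NULL)
  if (model$time_step == "weekly") {
    block <- (seq_len(n) - 1L) %/% 7L
    rate_temp <- stats::ave(rate_temp, block, FUN = mean)
  }
  inc <- daily_increment(model, rate_temp)
  cum_dev <- cumsum(inc)
  cum_atu <- cumsum(atu_temps(temps, model$clamp_negative_atu))

  if (is.null(names(events))) stop("events must be named thresholds")
  ev <- lapply(names(events), function(e) {
    thr <- events[[e]]
    i <- which(cum_dev >= thr)[1L]
    if (is.na(i)) {
      return(data.frame(event = e, threshold = thr, resolved = FALSE,
                        event_date = as.Date(NA), dpf = NA_real_,
                        atu = NA_real_))
    }
    prev_dev <- if (i > 1L) cum_dev[i - 1L] else 0
    f <- if (inc[i] > 0) (thr - prev_dev) / inc[i] else 0
    prev_atu <- if (i > 1L) cum_atu[i - 1L] else 0
    data.frame(
      event = e, threshold = thr, resolved = TRUE,
      event_date = series$date[i0 + i - 1L],
      dpf = (i - 1L) + f,
      atu = prev_atu + f * atu_temps(temps[i], model$clamp_negative_atu)
    )
  })
  ev <- do.call(rbind, ev)
  structure(
    list(
      start_date = start_date, model = model$name,
      daily = data.frame(date = series$date[i0:(i0 + n - 1L)], temp_c = temps,
                         rate_temp_c = rate_temp, increment = inc,
                         cum_development = cum_dev, cum_atu = cum_atu),
      events = ev, truncated_at_gap = hit_gap
    ),
    class = "dev_trajectory"
  )
}

#' @export
print.dev_trajectory <- function(x, ...) {
  cat(sprintf("<dev_trajectory> %s from %s over %d day(s)%s\n",
              x$model, format(x$start_date), nrow(x$daily),
              if (x$truncated_at_gap) " (truncated at gap)" else ""))
  print(x$events, row.names = FALSE)
  invisible(x)
}
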