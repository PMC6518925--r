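#' Hatch count dataset
#'
#' Per-tube daily hatch observations from a split-brood incubation
#' experiment. One row per tube per inspection day, with counts of newly
#' hatched and newly dead (removed) eggs. Tubes start with `eggs_per_tube`
#' eggs (50 in the experimental design emulated here).
#'
#' @param records data frame with columns `tube_id`, `family_id`,
#'   `treatment`, `fert_date`, `obs_date`, `n_hatched_new`, `n_dead_new`.
#' @param eggs_per_tube initial egg count per tube (default 50).
#' @return data frame of class `hatch_dataset` with attribute
#'   `eggs_per_tube`.
#' @export
hatch_dataset <- function(records, eggs_per_tube = 50) {
  need <- c("tube_id", "family_id", "treatment", "fert_date", "obs_date",
            "n_hatched_new", "n_dead_new")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  records$fert_date <- as.Date(records$fert_date)
  records$obs_date <- as.Date(records$obs_date)
  if (any(records$n_hatched_new < 0) || any(records$n_dead_new < 0)) {
    stop("counts must be non-negative")
  }
  if (any(records$n_hatched_new %% 1 != 0) || any(records$n_dead_new %% 1 != 0)) {
    stop("counts must be integers")
  }
  tot <- stats::aggregate(cbind(n_hatched_new, n_dead_new) ~ tube_id,
                          records, sum)
  if (any(tot$n_hatched_new + tot$n_dead_new > eggs_per_tube)) {
    stop("cumulative hatched + dead exceeds eggs_per_tube in some tube")
  }
  records <- records[order(records$tube_id, records$obs_date), , drop = FALSE]
  rownames(records) <- NULL
  attr(records, "eggs_per_tube") <- eggs_per_tube
  class(records) <- c("hatch_dataset", "data.frame")
  records
}

#' Read / write hatch count CSVs
#'
#' Dialect: `tube_id,family_id,treatment,fert_date,obs_date,n_hatched_new,
#' n_dead_new` with ISO-8601 dates.
#'
#' @param path file path.
#' @param eggs_per_tube initial egg count per tube.
#' @export
read_hatch_csv <- function(path, eggs_per_tube = 50) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  hatch_dataset(df, eggs_per_tube = eggs_per_tube)
}

#' @rdname read_hatch_csv
#' @param dataset a `hatch_dataset`.
#' @export
write_hatch_csv <- function(dataset, path) {
  out <- as.data.frame(dataset)
  out$fert_date <- format(out$fert_date)
  out$obs_date <- format(out$obs_date)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Cumulative ATU through the end of each observation day (fert day = day 0).
obs_day_atu <- function(series, fert_date, obs_dates, clamp_negative_atu = TRUE) {
  dpf <- as.numeric(obs_dates - fert_date)
  if (any(dpf < 0)) stop("observation before fertilization date")
  vapply(dpf, function(d) atu_between(series, fert_date, d + 1,
                                      clamp_negative_atu = clamp_negative_atu),
         numeric(1))
}

#' Logistic estimation of hatch timing for one incubation tube
#'
#' Fits a binomial-logit model of the cumulative proportion hatched against
#' cumulative ATU, with the denominator equal to the number of eggs that
#' eventually hatched (dead eggs never enter the trials: hatch timing is
#' conditional on hatching). ATU at 50% hatch is `-intercept/slope`, at 90%
#' hatch `(logit(0.9) - intercept)/slope`; days post fertilization at 50%
#' hatch is obtained by inverting the series' cumulative ATU at `atu50`.
#'
#' Degenerate paths: if every hatched egg hatched on a single inspection
#' day, perfect separation makes the slope unidentifiable and `atu50` is set
#' to the midpoint between the ATU of the last fully-unhatched day and of
#' the hatch day (`flag = "single_day"`). A tube with zero hatch returns all
#' estimates `NA` (`flag = "no_hatch"`).
#'
#' @param tube data frame for one tube (columns `obs_date`,
#'   `n_hatched_new`, `n_dead_new`; metadata columns as in
#'   [hatch_dataset()]).
#' @param series the `temp_series` the tube experienced.
#' @param fert_date fertilization date; default taken from `tube$fert_date`.
#' @param eggs_per_tube initial egg count (for hatch success); default from
#'   the dataset attribute or 50.
#' @param covariate `"atu"` (default) regresses on cumulative ATU;
#'   `"days"` on days post fertilization (DPF_50 then maps back to ATU).
#' @return one-row data frame: `tube_id`, `family_id`, `treatment`,
#'   `fert_date`, `atu50`, `atu90`, `dpf50`, `slope`, `intercept`,
#'   `n_hatched`, `hatch_success`, `flag`.
#' @export
fit_hatch_logistic <- function(tube, series, fert_date = NULL,
                               eggs_per_tube = NULL,
                               covariate = c("atu", "days")) {
  covariate <- match.arg(covariate)
  series <- as_temp_series(series)
  fert_date <- as.Date(fert_date %||% tube$fert_date[1L])
  eggs_per_tube <- eggs_per_tube %||% attr(tube, "eggs_per_tube") %||% 50
  tube <- tube[order(tube$obs_date), , drop = FALSE]

  meta <- data.frame(
    tube_id = tube$tube_id[1L] %||% NA_character_,
    family_id = tube$family_id[1L] %||% NA_character_,
    treatment = tube$treatment[1L] %||% NA_character_,
    fert_date = fert_date
  )
  n_hatched <- sum(tube$n_hatched_new)
  res <- cbind(meta, data.frame(
    atu50 = NA_real_, atu90 = NA_real_, dpf50 = NA_real_,
    slope = NA_real_, intercept = NA_real_, n_hatched = n_hatched,
    hatch_success = n_hatched / eggs_per_tube, flag = "ok"
  ))
  if (n_hatched == 0L) {
    res$flag <- "no_hatch"
    return(res)
  }

  atu <- obs_day_atu(series, fert_date, tube$obs_date)
  # both covariates measure exposure through the END of the observation
  # day: elapsed ATU, or elapsed days (dpf + 1, fertilization day = day 0)
  x <- if (covariate == "atu") atu
       else as.numeric(tube$obs_date - fert_date) + 1
  cum_h <- cumsum(tube$n_hatched_new)
  hatch_days <- which(tube$n_hatched_new > 0)

  if (length(hatch_days) == 1L) {
    i <- hatch_days
    lo <- if (i > 1L) x[i - 1L] else {
      # no pre-hatch observation: previous calendar day stands in
      if (covariate == "atu") {
        atu_between(series, fert_date, as.numeric(tube$obs_date[i] - fert_date))
      } else as.numeric(tube$obs_date[i] - fert_date)
    }
    mid <- (lo + x[i]) / 2
    if (covariate == "atu") {
      res$atu50 <- mid
      res$dpf50 <- invert_cum_atu(series, fert_date, mid)
    } else {
      res$dpf50 <- mid
      res$atu50 <- atu_between(series, fert_date, mid)
    }
    res$atu90 <- res$atu50
    res$flag <- "single_day"
    return(res)
  }

  fit <- suppressWarnings(
    stats::glm(cbind(cum_h, n_hatched - cum_h) ~ x,
               family = stats::binomial())
  )
  b <- stats::coef(fit)
  x50 <- -b[[1L]] / b[[2L]]
  x90 <- (stats::qlogis(0.9) - b[[1L]]) / b[[2L]]
  res$slope <- b[[2L]]
  res$intercept <- b[[1L]]
  if (covariate == "atu") {
    res$atu50 <- x50
    res$atu90 <- x90
    res$dpf50 <- invert_cum_atu(series, fert_date, x50)
  } else {
    res$dpf50 <- x50
    res$atu50 <- atu_between(series, fert_date, x50)
    res$atu90 <- atu_between(series, fert_date, x90)
  }
  res
}

# Fractional days post fertilization at which cumulative ATU reaches `atu`
# (linear within the crossing day).
invert_cum_atu <- function(series, fert_date, atu, clamp_negative_atu = TRUE) {
  series <- as_temp_series(series)
  fert_date <- as.Date(fert_date)
  i0 <- match(fert_date, series$date)
  if (is.na(i0)) stop("fert_date is not within the series")
  temps <- atu_temps(series$temp_c[i0:nrow(series)], clamp_negative_atu)
  firstna <- which(is.na(temps))[1L]
  if (!is.na(firstna)) temps <- temps[seq_len(firstna - 1L)]
  cs <- cumsum(temps)
  i <- which(cs >= atu)[1L]
  if (is.na(i)) stop("series ends before the requested ATU is accumulated")
  prev <- if (i > 1L) cs[i - 1L] else 0
  (i - 1L) + if (temps[i] > 0) (atu - prev) / temps[i] else 0
}

#' Fit hatch timing for every tube in a dataset
#'
#' @param dataset a [hatch_dataset()].
#' @param regimes named list of `temp_series`, keyed by
#'   `"<treatment>|<fert_date>"` with fallback to `"<treatment>"`.
#' @param ... passed to [fit_hatch_logistic()].
#' @return data frame of per-tube estimates, one row per tube.
#' @export
fit_hatch_tubes <- function(dataset, regimes, ...) {
  stopifnot(inherits(dataset, "hatch_dataset"))
  eggs <- attr(dataset, "eggs_per_tube")
  out <- lapply(split(as.data.frame(dataset), dataset$tube_id), function(tb) {
    key <- paste(tb$treatment[1L], format(as.Date(tb$fert_date[1L])), sep = "|")
    series <- regimes[[key]] %||% regimes[[tb$treatment[1L]]]
    if (is.null(series)) stop("no temperature series for tube key ", key)
    fit_hatch_logistic(tb, series, eggs_per_tube = eggs, ...)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Remove maternal families with uniformly low hatch success
#'
#' Families whose every tube hatched fewer than `min_success` of its eggs
#' are dropped (the emulated experiment removed one family with 0-14%
#' success before analysis; the retained families ranged 34-78%).
#'
#' @param estimates per-tube estimate table from [fit_hatch_tubes()] (any
#'   data frame with `family_id` and `hatch_success` columns).
#' @param min_success exclusion threshold as a fraction (default 0.15).
#' @return the table without excluded families; attribute
#'   `excluded_families` records the removals.
#' @export
exclude_low_success <- function(estimates, min_success = 0.15) {
  if (nrow(estimates) == 0L) stop("empty estimate table")
  mx <- tapply(estimates$hatch_success, estimates$family_id, max)
  drop <- names(mx)[mx < min_success]
  out <- estimates[!(estimates$family_id %in% drop), , drop = FALSE]
  if (nrow(out) == 0L) stop("all families fall below min_success")
  rownames(out) <- NULL
  attr(out, "excluded_families") <- drop
  out
}
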