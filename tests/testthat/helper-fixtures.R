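# Shared in-code fixtures: tiny deterministic series and datasets.

const_series <- function(temp, n_days = 320, start = as.Date("2016-11-01"),
                         site_id = "const") {
  temperature_series(start + 0:(n_days - 1), rep(temp, n_days),
                     site_id = site_id)
}

# A seeded synthetic river series long enough to carry an autumn spawn
# through the following summer.
river_series <- function(seed = 42, start = as.Date("2018-09-01"),
                         n_days = 420) {
  make_regime(regime_spec("river", seed = seed), start, n_days,
              site_id = paste0("river", seed))
}

# Daily hatch counts for one tube given per-egg hatch ATUs on a series.
tube_from_egg_atus <- function(egg_atu, series, fert_date,
                               tube_id = "t1", family_id = "F01",
                               treatment = "A") {
  i0 <- match(as.Date(fert_date), series$date)
  cum <- cumsum(pmax(series$temp_c[i0:nrow(series)], 0))
  off <- findInterval(egg_atu, cum)
  stopifnot(all(off < length(cum)))
  days <- sort(unique(off))
  data.frame(
    tube_id = tube_id, family_id = family_id, treatment = treatment,
    fert_date = as.Date(fert_date), obs_date = as.Date(fert_date) + days,
    n_hatched_new = as.integer(tabulate(match(off, days), length(days))),
    n_dead_new = 0L
  )
}
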