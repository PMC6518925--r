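# Closed-form development models and rate-summation accumulation.

test_that("closed forms reproduce independently computed reference values", {
  # frozen from high-precision term-by-term evaluation of each printed form
  expect_equal(crisp_days_to_event(5.3), 93.5378288723367, tolerance = 1e-12)
  expect_equal(gorodilov_tau_s(5.3), 440.591688312238, tolerance = 1e-12)
  expect_equal(winsirp_days_to_event(5.3), 93.8393871325746, tolerance = 1e-12)
  expect_equal(kane_days_to_event(5.3), 95.7666560270161, tolerance = 1e-12)
})

test_that("models are strictly decreasing in temperature and obey identities", {
  tt <- seq(0.5, 10.5, by = 0.5)
  for (f in list(crisp_days_to_event, gorodilov_tau_s, winsirp_days_to_event,
                 kane_days_to_event)) {
    expect_true(all(diff(f(tt)) < 0))
  }
  # Crisp depends on temperature only through T + 11
  expect_identical(crisp_days_to_event(4), crisp_days_to_event(4))
  expect_gt(crisp_days_to_event(4), crisp_days_to_event(8))
  # WinSIRP power-law identity: (T + 5.3944)^2.0198 * D = 11248
  for (t in c(1, 5.3, 9.7)) {
    expect_equal((t + 5.3944)^2.0198 * winsirp_days_to_event(t), 11248,
                 tolerance = 1e-10)
  }
  # Kane at T = 0 clamps to 0.1; with clamping disabled the exponent is 1
  expect_equal(kane_days_to_event(0, clamp_low_c = NULL), exp(5.483),
               tolerance = 1e-12)
})

test_that("temperature clamping is idempotent at the validity bounds", {
  expect_identical(gorodilov_tau_s(0), gorodilov_tau_s(0.1))
  expect_identical(gorodilov_tau_s(-3), gorodilov_tau_s(0.1))
  expect_identical(gorodilov_tau_s(12), gorodilov_tau_s(11))
  expect_equal(gorodilov_tau_s(0.1), 1226.73484092912, tolerance = 1e-12)
  expect_error(gorodilov_tau_s(NaN), "finite")
  expect_error(crisp_days_to_event(-12, clamp_low_c = NULL), "Crisp domain")
  expect_error(winsirp_days_to_event(-6, clamp_low_c = NULL), "WinSIRP domain")
})

test_that("accumulation at constant temperature inverts every closed form", {
  for (name in c("crisp", "gorodilov", "winsirp", "kane")) {
    m <- dev_model(name)
    for (t in c(2.0, 5.3, 8.0)) {
      s <- const_series(t)
      tr <- accumulate_development(s, m, s$date[1])
      ev <- tr$events
      for (k in seq_len(nrow(ev))) {
        expect_equal(ev$dpf[k], days_to_event(m, t, ev$event[k]),
                     tolerance = 1e-6)
        expect_equal(ev$atu[k], days_to_event(m, t, ev$event[k]) * t,
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("gorodilov emergence never precedes 50% hatch", {
  m <- dev_model("gorodilov")
  for (s in list(const_series(4), river_series(7))) {
    start <- s$date[30]
    ev <- accumulate_development(s, m, start)$events
    if (all(ev$resolved)) {
      expect_gte(ev$dpf[ev$event == "emergence"],
                 ev$dpf[ev$event == "hatch50"])
    }
  }
})

test_that("a zero threshold fires at the start with zero ATU", {
  s <- const_series(5)
  tr <- accumulate_development(s, dev_model("gorodilov"), s$date[1],
                               events = c(hatch50 = 0))
  expect_true(tr$events$resolved)
  expect_identical(tr$events$event_date, s$date[1])
  expect_equal(tr$events$dpf, 0)
  expect_equal(tr$events$atu, 0)
})

test_that("an exhausted series yields an unresolved event, not extrapolation", {
  s <- const_series(5, n_days = 10)
  tr <- accumulate_development(s, dev_model("gorodilov"), s$date[1])
  expect_false(any(tr$events$resolved))
  expect_true(all(is.na(tr$events$atu)))
  expect_equal(max(tr$daily$cum_atu), 50) # ATU definition: 10 days at 5 C
})

test_that("later start dates never hatch earlier (order preservation)", {
  s <- river_series(11)
  m <- dev_model("gorodilov")
  starts <- s$date[c(40, 50, 60, 75)]
  dates <- vapply(starts, function(d) {
    ev <- accumulate_development(s, m, d)$events
    as.numeric(ev$event_date[ev$event == "hatch50"])
  }, numeric(1))
  expect_true(all(diff(dates) >= 0))
})

test_that("gorodilov ATU at hatch rises with constant temperature (compensation)", {
  atu <- vapply(seq(1, 5, by = 0.5), function(t) {
    s <- const_series(t, n_days = 400)
    ev <- accumulate_development(s, dev_model("gorodilov"), s$date[1])$events
    ev$atu[ev$event == "hatch50"]
  }, numeric(1))
  expect_true(all(diff(atu) > 0))
})

test_that("weekly block averaging drives the WinSIRP step", {
  # 7 days at 2 then 7 at 8: both weeks use their own block mean
  s <- temperature_series(as.Date("2017-01-01") + 0:13, rep(c(2, 8), each = 7))
  tr <- accumulate_development(s, dev_model("winsirp"), s$date[1])
  expect_equal(unique(tr$daily$rate_temp_c), c(2, 8))
  expect_equal(tr$daily$increment[1:7],
               rep(1 / winsirp_days_to_event(2), 7))
  # trailing partial block uses its own mean
  s2 <- temperature_series(as.Date("2017-01-01") + 0:9, c(rep(4, 7), 5, 6, 7))
  tr2 <- accumulate_development(s2, dev_model("winsirp"), s2$date[1])
  expect_equal(tr2$daily$rate_temp_c[8:10], rep(6, 3))
})

test_that("atu_between sums whole days and pro-rates the final fraction", {
  s <- temperature_series(as.Date("2017-01-01") + 0:2, c(2, 4, 6))
  expect_equal(atu_between(s, s$date[1], 2.5), 9) # 2 + 4 + 3
  expect_equal(atu_between(s, s$date[1], 0), 0)
  expect_equal(atu_between(const_series(5), as.Date("2016-11-01"), 10), 50)
  expect_error(atu_between(s, s$date[1], 5), "beyond the end")
  expect_error(atu_between(s, as.Date("2016-12-31"), 1), "not within")
  # negative daily means clamp to zero by default
  s3 <- temperature_series(as.Date("2017-01-01") + 0:1, c(-2, 4))
  expect_equal(atu_between(s3, s3$date[1], 2), 4)
  expect_equal(atu_between(s3, s3$date[1], 2, clamp_negative_atu = FALSE), 2)
})

test_that("dev_model validates thresholds and exposes overrides", {
  expect_error(dev_model("gorodilov", event_thresholds = c(315, 450)), "named")
  m <- dev_model("crisp", intercept = 5.25)
  expect_equal(m$parameters$intercept, 5.25)
  expect_equal(dev_model("gorodilov")$event_thresholds,
               c(hatch50 = 315, emergence = 450))
})
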