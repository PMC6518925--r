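# Repeatability statistics and observed-vs-predicted model evaluation.

test_that("ICC is 1 with zero within-group variance and matches a hand table", {
  r <- icc_oneway(c(1, 1, 2, 2, 3, 3), rep(1:3, each = 2))
  expect_equal(r$icc, 1)
  # fixed 4 x 3 table: oracle is the hand-computed ANOVA mean-square ratio
  vals <- c(10, 12, 11, 20, 19, 21, 30, 31, 29, 40, 42, 41)
  grp <- rep(1:4, each = 3)
  r2 <- icc_oneway(vals, grp)
  means <- tapply(vals, grp, mean)
  msb <- 3 * sum((means - mean(vals))^2) / 3
  msw <- sum((vals - rep(means, each = 3))^2) / 8
  expect_equal(r2$icc, (msb - msw) / (msb + 2 * msw), tolerance = 1e-12)
  expect_lte(r2$ci_low, r2$icc)
  expect_gte(r2$ci_high, r2$icc)
  expect_identical(r2$n_groups, 4L)
  expect_equal(r2$mean_group_size, 3)
})

test_that("ICC is near zero (possibly negative) without a group effect", {
  set.seed(5)
  vals <- rnorm(60)
  r <- icc_oneway(vals, rep(1:12, each = 5))
  expect_lt(abs(r$icc), 0.3)
  expect_error(icc_oneway(1:5, rep(1, 5)), "2 groups")
  expect_error(icc_oneway(1:3, 1:3), "2\\+ observations")
})

test_that("family mixed model recovers variance components and handles nulls", {
  make_design <- function(family_sd, resid_sd, seed) {
    set.seed(seed)
    fam <- sprintf("F%02d", 1:17)
    date <- rep(as.Date("2016-11-01") + c(0, 3, 7, 10), length.out = 17)
    d <- expand.grid(family_id = fam, tube = 1:5)
    d$fert_date <- date[match(d$family_id, fam)]
    d$atu50 <- 527 + rnorm(17, 0, family_sd)[match(d$family_id, fam)] +
      rnorm(nrow(d), 0, resid_sd)
    d
  }
  # no family effect: LRT statistic should be small
  null_fit <- fit_family_model(make_design(0, 10, 1))
  expect_lt(null_fit$lrt_chi2, 3.84)
  expect_gt(null_fit$lrt_p, 0.05)

  # strong family effect (sd 10 vs residual 4): variance components recovered
  # within 30% of truth when averaged over replicates
  reps <- vapply(1:100, function(i) {
    f <- fit_family_model(make_design(10, 4, 100 + i))
    c(f$random_intercept_variance, f$residual_variance)
  }, numeric(2))
  expect_lt(abs(mean(reps[1, ]) - 100) / 100, 0.3)
  expect_lt(abs(mean(reps[2, ]) - 16) / 16, 0.3)

  # translation invariance: only the intercept moves
  d <- make_design(10, 4, 77)
  d2 <- d; d2$atu50 <- d2$atu50 + 100
  f1 <- fit_family_model(d); f2 <- fit_family_model(d2)
  expect_equal(f2$random_intercept_variance, f1$random_intercept_variance,
               tolerance = 1e-6)
  expect_equal(f2$residual_variance, f1$residual_variance, tolerance = 1e-6)
  expect_equal(f2$fixed_effects[["(Intercept)"]],
               f1$fixed_effects[["(Intercept)"]] + 100, tolerance = 1e-6)
  # LRT invariant to affine rescaling of the response
  d3 <- d; d3$atu50 <- 3 * d3$atu50 - 50
  f3 <- fit_family_model(d3)
  expect_equal(f3$lrt_chi2, f1$lrt_chi2, tolerance = 1e-4)
  # boundary-corrected p is half the plain chi-square p
  expect_equal(f1$lrt_p_boundary, f1$lrt_p / 2)
})

test_that("treatment model pre-averages replicates and fits the factorial", {
  set.seed(9)
  fam <- sprintf("F%02d", 1:8)
  date <- rep(as.Date("2016-11-01") + c(0, 7), length.out = 8)
  rows <- list()
  for (f in seq_along(fam)) {
    for (trt in c("A", "B", "C")) {
      n <- if (trt == "A") 4 else 1
      rows[[length(rows) + 1]] <- data.frame(
        family_id = fam[f], treatment = trt, fert_date = date[f],
        atu50 = 520 + (trt == "C") * -40 + rnorm(1, 0, 6) + rnorm(n, 0, 3)
      )
    }
  }
  est <- do.call(rbind, rows)
  fit <- fit_treatment_model(est)
  expect_s3_class(fit, "mixed_model_result")
  expect_true(all(c("treatment", "fert_date", "treatment:fert_date") %in%
                    fit$fixed_test$term))
  expect_gte(fit$random_intercept_variance, 0)
  expect_gte(fit$lrt_chi2, 0)
})

test_that("model evaluation matches constructed observed-minus-predicted pairs", {
  s <- const_series(5.3, n_days = 200)
  m <- dev_model("gorodilov")
  dates <- s$date[c(1, 4, 8, 11)]
  pred <- vapply(dates, function(d) {
    ev <- accumulate_development(s, m, d)$events
    ev$atu[ev$event == "hatch50"]
  }, numeric(1))

  # predicted == observed: zero mean difference, t undefined
  obs0 <- data.frame(treatment = "A", fert_date = dates, atu50 = pred)
  ev0 <- evaluate_models(obs0, list(A = s), models = list(m))
  expect_equal(ev0$tests$mean_difference, 0, tolerance = 1e-9)
  expect_true(is.na(ev0$tests$t_stat))

  # constant -7 offset with tiny jitter: mean difference about -7
  jit <- c(0.01, -0.02, 0.015, -0.005)
  obs7 <- data.frame(treatment = "A", fert_date = dates,
                     atu50 = pred + 7 + jit)
  ev7 <- evaluate_models(obs7, list(A = s), models = list(m))
  expect_equal(ev7$tests$mean_difference, -7 - mean(jit), tolerance = 1e-9)
  expect_lt(abs(ev7$tests$mean_difference + 7), 0.05)

  # paired t matches the textbook formula on a 12-pair fixture,
  # and swapping pair order negates t
  obs12 <- data.frame(
    treatment = rep(c("A", "B", "C"), each = 4),
    fert_date = rep(dates, 3),
    atu50 = rep(pred, 3) + c(-9, -4, -6, -8, -2, -5, -7, -3, -6, -4, -8, -5)
  )
  ev12 <- evaluate_models(obs12, list(A = s, B = s, C = s), models = list(m))
  d <- ev12$pairs$diff_atu
  expect_identical(ev12$tests$df, 11L)
  expect_equal(ev12$tests$t_stat, mean(d) / (sd(d) / sqrt(12)),
               tolerance = 1e-9)
  flipped <- t.test(-d)
  expect_equal(unname(flipped$statistic), -ev12$tests$t_stat,
               tolerance = 1e-12)
})

test_that("evaluation refuses unresolved accumulations and missing columns", {
  short <- const_series(5.3, n_days = 20)
  obs <- data.frame(treatment = "A", fert_date = short$date[1], atu50 = 520)
  expect_error(evaluate_models(obs, list(A = short), models = list("gorodilov")),
               "unresolved")
  expect_error(evaluate_models(obs, list(A = const_series(5.3)),
                               models = list("kane")), "atu90")
})

test_that("relative variability reproduces the reported percentage scale", {
  expect_equal(relative_variability(28, 527), 100 * 28 / 527)
  expect_error(relative_variability(5, 0), "positive")
  rc <- reported_contrasts()
  expect_identical(nrow(rc), 2L)
  expect_true(all(c("delta_atu", "total_atu") %in% names(rc)))
})
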