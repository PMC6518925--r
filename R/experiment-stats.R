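#' One-way intraclass correlation (repeatability)
#'
#' Random-effects one-way ANOVA estimator of the intraclass correlation:
#' `ICC = (MSB - MSW) / (MSB + (k0 - 1) * MSW)` where MSB and MSW are the
#' between- and within-group mean squares and `k0` is the unbalanced-design
#' average group size `(N - sum(n_i^2)/N) / (k - 1)`. The 95% confidence
#' interval follows the classical F-distribution bounds (Searle 1971), the
#' standard interval for this estimator. Slightly negative point estimates
#' (no group effect) are reported as computed.
#'
#' @param values numeric response (e.g. per-tube ATU at 50% hatch).
#' @param groups grouping factor (e.g. maternal family).
#' @param conf confidence level (default 0.95).
#' @return object of class `icc_oneway`: list with `icc`, `ci_low`,
#'   `ci_high`, `n_groups`, `mean_group_size` (k0), `msb`, `msw`.
#' @examples
#' icc_oneway(c(1, 1, 2, 2, 3, 3), rep(1:3, each = 2))$icc # 1
#' @export
icc_oneway <- function(values, groups, conf = 0.95) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  n_i <- tabulate(groups)
  k <- nlevels(groups)
  N <- length(values)
  if (k < 2L) stop("need at least 2 groups")
  if (all(n_i < 2L)) stop("need at least one group with 2+ observations")
  k0 <- (N - sum(n_i^2) / N) / (k - 1)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ssb <- sum(n_i * (means - gm)^2)
  ssw <- sum((values - means[as.integer(groups)])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  icc <- (msb - msw) / (msb + (k0 - 1) * msw)
  a <- 1 - conf
  Fobs <- msb / msw
  FL <- Fobs / stats::qf(1 - a / 2, k - 1, N - k)
  FU <- Fobs * stats::qf(1 - a / 2, N - k, k - 1)
  structure(
    list(icc = icc,
         ci_low = (FL - 1) / (FL + k0 - 1),
         ci_high = (FU - 1) / (FU + k0 - 1),
         n_groups = k, mean_group_size = k0, msb = msb, msw = msw,
         conf = conf),
    class = "icc_oneway"
  )
}

#' @export
print.icc_oneway <- function(x, ...) {
  cat(sprintf("One-way ICC = %.3f (%d%% CI: %.3f-%.3f), %d groups, k0 = %.2f\n",
              x$icc, round(100 * x$conf), x$ci_low, x$ci_high,
              x$n_groups, x$mean_group_size))
  invisible(x)
}

# Shared machinery for the two random-intercept models. REML fit via
# lmerTest (Satterthwaite denominator df for the fixed effects); the random
# intercept is tested with a REML likelihood-ratio test on 1 df.
fit_random_intercept <- function(formula, data) {
  fit <- lmerTest::lmer(formula, data = data,
                        control = lme4::lmerControl(check.conv.singular =
                          lme4::.makeCC(action = "ignore", tol = 1e-4)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  fam_var <- vc$vcov[vc$grp != "Residual"][1L]
  res_var <- vc$vcov[vc$grp == "Residual"][1L]
  lrt <- as.data.frame(lmerTest::ranova(fit))
  # ranova: first row is the full model, second the reduced (intercept dropped)
  chi2 <- max(lrt$LRT[2L], 0)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  aov_tab <- stats::anova(fit, type = 3)
  structure(
    list(
      fit = fit,
      fixed_effects = lme4::fixef(fit),
      random_intercept_variance = fam_var,
      residual_variance = res_var,
      lrt_chi2 = chi2,
      lrt_p = p,                 # plain chi-square(1) reference, as printed
      lrt_p_boundary = p / 2,    # boundary-corrected (variance >= 0) p
      fixed_test = data.frame(
        term = rownames(aov_tab),
        F = aov_tab$`F value`,
        df_num = aov_tab$NumDF,
        df_den = aov_tab$DenDF,
        p = aov_tab$`Pr(>F)`
      )
    ),
    class = "mixed_model_result"
  )
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf(
    "Random-intercept model: family variance %.2f, residual %.2f\n",
    x$random_intercept_variance, x$residual_variance))
  cat(sprintf("  LRT for random intercept: chi2(1) = %.2f, p = %.3g\n",
              x$lrt_chi2, x$lrt_p))
  print(x$fixed_test, row.names = FALSE)
  invisible(x)
}

#' Repeatability of hatch timing among maternal families
#'
#' `fit_family_model()` fits the constant-treatment replicate design:
#' response (per-tube ATU at 50% hatch) with fertilization date as a fixed
#' effect and maternal family as a random intercept. A significant family
#' intercept indicates hatch-timing differences among families fertilized
#' on the same day.
#'
#' `fit_treatment_model()` fits one value per family x treatment (replicate
#' tubes in the constant treatment are pre-averaged to a single value per
#' family first) with treatment, fertilization date and their interaction
#' as fixed effects and family as a random intercept.
#'
#' @param estimates per-tube estimate table (columns `atu50` -- or the
#'   response named by `response` --, `family_id`, `fert_date`, and
#'   `treatment` for the treatment model).
#' @param response name of the response column (default `"atu50"`).
#' @return object of class `mixed_model_result`: fixed-effect estimates,
#'   variance components, REML likelihood-ratio test for the random
#'   intercept (`lrt_chi2`, `lrt_p`, plus the boundary-corrected
#'   `lrt_p_boundary`), and Satterthwaite F tests of the fixed effects.
#' @export
fit_family_model <- function(estimates, response = "atu50") {
  d <- data.frame(
    y = estimates[[response]],
    fert_date = factor(estimates$fert_date),
    family_id = factor(estimates$family_id)
  )
  d <- d[stats::complete.cases(d), , drop = FALSE]
  per_date <- table(unique(d[c("fert_date", "family_id")])$fert_date)
  if (any(per_date < 2L)) {
    stop("need at least 2 families per fertilization date")
  }
  fit_random_intercept(y ~ fert_date + (1 | family_id), d)
}

#' @rdname fit_family_model
#' @param average_treatment treatment whose replicate tubes are averaged to
#'   one value per family before fitting (default `"A"`; `NULL` disables).
#' @export
fit_treatment_model <- function(estimates, response = "atu50",
                                average_treatment = "A") {
  d <- data.frame(
    y = estimates[[response]],
    treatment = factor(estimates$treatment),
    fert_date = factor(estimates$fert_date),
    family_id = factor(estimates$family_id)
  )
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (!is.null(average_treatment) && average_treatment %in% levels(d$treatment)) {
    d <- stats::aggregate(y ~ treatment + fert_date + family_id, d, mean)
  }
  fit_random_intercept(y ~ treatment * fert_date + (1 | family_id), d)
}

#' Paired evaluation of observed versus model-predicted ATU at hatch
#'
#' For each development model and each treatment x fertilization-date pair,
#' runs rate-summation accumulation over that pair's temperature regime and
#' compares the predicted ATU at the model's hatch event against the
#' observed value. `crisp`, `gorodilov` and `winsirp` predict (and are
#' compared against) ATU at 50% hatch; `kane` predicts ATU at 90% hatch and
#' requires an `atu90` column. Differences are predicted minus observed, so
#' a negative mean difference means the model under-estimates the thermal
#' units required to hatch. A two-sided paired t test (df = n_pairs - 1) is
#' reported per model; if all pairs share an identical difference the t
#' statistic is undefined and reported `NA`.
#'
#' @param observed data frame with one row per pair: `treatment`,
#'   `fert_date`, `atu50`, optionally `dpf50` and `atu90`.
#' @param regimes named list of `temp_series` keyed
#'   `"<treatment>|<fert_date>"` (fallback key `"<treatment>"`).
#' @param models list of [dev_model()] objects (or model names).
#' @return object of class `model_evaluation`: list with `pairs` (long data
#'   frame of per-pair observed, predicted ATU and days, and differences)
#'   and `tests` (per model: `mean_difference`, `t_stat`, `df`, `p`,
#'   `mean_abs_day_diff`).
#' @export
evaluate_models <- function(observed, regimes,
                            models = list("crisp", "gorodilov", "winsirp")) {
  models <- lapply(models, function(m) if (inherits(m, "dev_model")) m
                   else dev_model(m))
  observed$fert_date <- as.Date(observed$fert_date)
  rows <- list()
  for (m in models) {
    ev <- if (m$name == "kane") "hatch90" else "hatch50"
    obs_col <- if (m$name == "kane") "atu90" else "atu50"
    if (!obs_col %in% names(observed)) {
      stop(sprintf("model '%s' needs observed column '%s'", m$name, obs_col))
    }
    for (i in seq_len(nrow(observed))) {
      key <- paste(observed$treatment[i], format(observed$fert_date[i]),
                   sep = "|")
      series <- regimes[[key]] %||% regimes[[observed$treatment[i]]]
      if (is.null(series)) stop("no regime for pair ", key)
      tr <- accumulate_development(series, m, observed$fert_date[i])
      e <- tr$events[tr$events$event == ev, ]
      if (!isTRUE(e$resolved)) {
        stop(sprintf(
          "unresolved %s event for model '%s', pair %s: series too short",
          ev, m$name, key))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        model = m$name, treatment = observed$treatment[i],
        fert_date = observed$fert_date[i],
        observed_atu = observed[[obs_col]][i], predicted_atu = e$atu,
        observed_dpf = if ("dpf50" %in% names(observed) && ev == "hatch50")
          observed$dpf50[i] else NA_real_,
        predicted_dpf = e$dpf
      )
    }
  }
  pairs <- do.call(rbind, rows)
  pairs$diff_atu <- pairs$predicted_atu - pairs$observed_atu
  pairs$diff_dpf <- pairs$predicted_dpf - pairs$observed_dpf
  tests <- do.call(rbind, lapply(split(pairs, pairs$model), function(p) {
    d <- p$diff_atu
    tt <- if (stats::sd(d) > 0) stats::t.test(d) else NULL
    data.frame(
      model = p$model[1L], n_pairs = length(d), mean_difference = mean(d),
      t_stat = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      df = length(d) - 1L,
      p = if (is.null(tt)) NA_real_ else tt$p.value,
      mean_abs_day_diff = if (all(is.na(p$diff_dpf))) NA_real_
        else mean(abs(p$diff_dpf), na.rm = TRUE)
    )
  }))
  rownames(tests) <- NULL
  structure(list(pairs = pairs, tests = tests), class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf("<model_evaluation> %d pairs per model\n",
              nrow(x$pairs) / nrow(x$tests)))
  print(x$tests, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Relative variability of a hatch-timing contrast
#'
#' Expresses a difference in ATU between groups as a percentage of the
#' average total ATU of the incubation period -- the scale on which the
#' biological relevance of family and fertilization-date effects is judged.
#'
#' @param delta_atu contrast in ATU (e.g. maximum between-family difference).
#' @param total_atu average total ATU at 50% hatch of the reference group.
#' @return percentage, `100 * delta_atu / total_atu`.
#' @examples
#' relative_variability(28, 527) # ~5.3%
#' @export
relative_variability <- function(delta_atu, total_atu) {
  if (any(total_atu <= 0)) stop("total_atu must be positive")
  100 * delta_atu / total_atu
}

#' Reported hatch-timing contrasts of the emulated experiment
#'
#' Bundled numerator/denominator pairs of the key between-group contrasts
#' of the laboratory experiment: the maximum between-family ATU difference
#' against the constant-treatment average total ATU, and the maximum
#' fertilization-date ATU difference against the warm-spike-treatment
#' average total ATU. Feed these to [relative_variability()].
#'
#' @return data frame with columns `contrast`, `delta_atu`, `total_atu`.
#' @export
reported_contrasts <- function() {
  utils::read.csv(system.file("extdata", "reported_contrasts.csv",
                              package = "hatchphen", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
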