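test_that("exponential fit equals the events/exposure closed-form MLE", {
  spec <- true_survival_spec("exponential", c(rate = 0.08), 400,
                             max_followup = 40, censor_rate = 0.2, seed = 2)
  ipd <- generate_ipd(spec)
  fit <- fit_parametric(ipd, "exponential")
  rate_closed <- sum(ipd$event) / sum(ipd$time)
  expect_equal(unname(fit$params[["rate"]]), rate_closed, tolerance = 1e-6)
  # log-likelihood at the closed-form MLE matches the reported maximum
  ll_closed <- sum(ipd$event) * log(rate_closed) - rate_closed * sum(ipd$time)
  expect_equal(fit$loglik, ll_closed, tolerance = 1e-6)
})

test_that("parameters are recovered from a censored Weibull truth", {
  spec <- true_survival_spec("weibull", c(shape = 1.5, scale = 10), 2000,
                             max_followup = 40, censor_rate = 0.2, seed = 5)
  fit <- fit_parametric(generate_ipd(spec), "weibull")
  expect_equal(unname(fit$params[["shape"]]), 1.5, tolerance = 0.10)
  expect_equal(unname(fit$params[["scale"]]), 10, tolerance = 0.10)
})

test_that("parameter bias is small at n = 5000 without censoring", {
  truths <- list(
    exponential = c(rate = 0.05),
    weibull     = c(shape = 1.5, scale = 20),
    gompertz    = c(shape = 0.05, rate = 0.02),
    loglogistic = c(shape = 2, scale = 15),
    lognormal   = c(meanlog = 2.5, sdlog = 0.8),
    gengamma    = c(mu = 2.5, sigma = 0.8, Q = 0.5)
  )
  for (fam in names(truths)) {
    # the three-parameter gengamma has noisy single-sample estimates of Q,
    # so its bias is estimated by averaging replicates
    reps <- if (fam == "gengamma") 5 else 1
    est <- vapply(seq_len(reps), function(i) {
      spec <- true_survival_spec(fam, truths[[fam]], 5000, seed = 60 + i)
      fit <- fit_parametric(generate_ipd(spec), fam)
      expect_true(fit$converged, info = fam)
      fit$params
    }, numeric(length(truths[[fam]])))
    mean_est <- if (reps == 1) est else rowMeans(est)
    rel <- abs(mean_est - truths[[fam]]) / abs(truths[[fam]])
    expect_lt(max(rel), 0.05, label = paste(fam, "max relative bias"))
  }
})

test_that("the more flexible family attains at least the nested likelihood", {
  spec <- true_survival_spec("lognormal", c(meanlog = 3, sdlog = 0.6), 2000,
                             max_followup = 80, censor_rate = 0.1, seed = 9)
  ipd <- generate_ipd(spec)
  expect_gte(fit_parametric(ipd, "lognormal")$loglik,
             fit_parametric(ipd, "exponential")$loglik)
  # gengamma nests lognormal (Q = 0): must do at least as well up to tolerance
  expect_gte(fit_parametric(ipd, "gengamma")$loglik + 1e-4,
             fit_parametric(ipd, "lognormal")$loglik)
})

test_that("information criteria bookkeeping is self-consistent", {
  spec <- true_survival_spec("weibull", c(shape = 1.2, scale = 12), 300, seed = 4)
  ipd <- generate_ipd(spec)
  for (fam in surv_families()) {
    fit <- fit_parametric(ipd, fam)
    k <- length(fit$params)
    expect_identical(fit$aic, 2 * k - 2 * fit$loglik)
    expect_identical(fit$bic, k * log(fit$n) - 2 * fit$loglik)
  }
})

test_that("selection takes the lowest criterion with a fewer-parameter tie-break", {
  mk <- function(fam, aic, bic, k) {
    f <- make_fit(fam, stats::setNames(rep(1, k), paste0("p", seq_len(k))))
    f$aic <- aic; f$bic <- bic
    f
  }
  fits <- list(mk("weibull", 100, 101, 2), mk("gengamma", 95, 99, 3),
               mk("exponential", 99, 98, 1))
  expect_equal(select_best(fits, "aic")$family, "gengamma")
  expect_equal(select_best(fits, "bic")$family, "exponential")

  tie <- list(mk("gengamma", 95, 95, 3), mk("weibull", 95, 95, 2))
  expect_equal(select_best(tie, "aic")$family, "weibull")

  ov <- select_best(fits, "aic", override = "weibull")
  expect_equal(ov$family, "weibull")
  expect_true(ov$override)
  expect_error(select_best(fits, "aic", override = "gamma"), "not among fits")
  expect_error(select_best(list(), "aic"), "empty")
})

test_that("survival functions evaluate to their closed forms", {
  for (fam in surv_families()) {
    pars <- switch(fam, exponential = c(rate = 0.05),
                   weibull = c(shape = 1.5, scale = 10),
                   gompertz = c(shape = 0.05, rate = 0.02),
                   loglogistic = c(shape = 2, scale = 10),
                   lognormal = c(meanlog = 2, sdlog = 1),
                   gengamma = c(mu = 2, sigma = 1, Q = 0.5))
    expect_equal(survival_at(fam, 0, params = pars), 1, info = fam)
    s <- survival_at(fam, seq(0, 200, by = 5), params = pars)
    expect_true(all(diff(s) <= 0), info = fam)
    expect_lt(s[length(s)], 0.1)
  }
  expect_equal(survival_at("exponential", log(2) / 0.05, params = c(rate = 0.05)),
               0.5)
  # gompertz closed form, including the calibrated median
  pars <- calibrate_to_median("gompertz", 17.70, fixed = c(shape = 0.05))
  expect_equal(survival_at("gompertz", 17.70, params = pars), 0.5,
               tolerance = 1e-9)
  a <- pars[["shape"]]; b <- pars[["rate"]]
  expect_equal(survival_at("gompertz", 30, params = pars),
               exp(-(b / a) * (exp(a * 30) - 1)))
  # defective gompertz (negative shape) plateaus above zero
  s_inf <- survival_at("gompertz", 1e6, params = c(shape = -0.05, rate = 0.01))
  expect_gt(s_inf, 0)
  expect_equal(fit_quantile("gompertz", p = s_inf * 0.9,
                            params = c(shape = -0.05, rate = 0.01)), Inf)
})

test_that("weekly death probabilities telescope back to the survival curve", {
  # memoryless: constant weekly probability 1 - exp(-rate)
  p <- weekly_death_prob("exponential", 0:49, params = c(rate = 0.03))
  expect_equal(p, rep(1 - exp(-0.03), 50))

  # increasing hazard gives strictly increasing weekly probabilities
  pg <- weekly_death_prob("gompertz", 0:99, params = c(shape = 0.05, rate = 0.001))
  expect_true(all(diff(pg) > 0))

  # telescoping identity over 100 weeks for every family
  for (fam in c("exponential", "gompertz", "gengamma")) {
    pars <- switch(fam, exponential = c(rate = 0.02),
                   gompertz = c(shape = 0.03, rate = 0.01),
                   gengamma = c(mu = 3, sigma = 1, Q = 0.5))
    pv <- death_prob_vector(fam, 100, params = pars)
    expect_equal(prod(1 - pv), survival_at(fam, 100, params = pars),
                 tolerance = 1e-9, info = fam)
  }
})

test_that("median calibration solves S(median) = 0.5 in every family", {
  expect_equal(unname(calibrate_to_median("exponential", 10)[["rate"]]),
               log(2) / 10)
  b <- calibrate_to_median("gompertz", 17.70, fixed = c(shape = 0.05))[["rate"]]
  expect_equal(b, 0.05 * log(2) / (exp(0.05 * 17.70) - 1), tolerance = 1e-12)

  cases <- list(
    weibull = c(shape = 1.4), loglogistic = c(shape = 2),
    lognormal = c(sdlog = 0.9), gengamma = c(sigma = 1, Q = 1),
    gompertz = c(shape = 0.05)
  )
  for (fam in names(cases)) {
    pars <- calibrate_to_median(fam, 66.27, fixed = cases[[fam]])
    expect_equal(survival_at(fam, 66.27, params = pars), 0.5,
                 tolerance = 1e-8, info = fam)
    expect_equal(fit_quantile(fam, 0.5, params = pars), 66.27,
                 tolerance = 1e-6, info = fam)
  }
  expect_error(calibrate_to_median("weibull", 10), "requires fixed")
})

test_that("fits serialize to JSON and back", {
  spec <- true_survival_spec("gompertz", c(shape = 0.05, rate = 0.02), 200,
                             seed = 15)
  fit <- fit_parametric(generate_ipd(spec), "gompertz")
  f <- withr::local_tempfile(fileext = ".json")
  write_fit(fit, f)
  fit2 <- read_fit(f)
  expect_equal(fit2$params, fit$params)
  expect_equal(fit2$loglik, fit$loglik)
  expect_equal(survival_at(fit2, 25), survival_at(fit, 25))
})

test_that("degenerate inputs are flagged rather than silently fitted", {
  expect_error(fit_parametric(data.frame(time = c(1, 2, 3),
                                         event = c(TRUE, FALSE, FALSE)),
                              "weibull"), "at least 2 events")
  expect_error(fit_parametric(tiny_ipd(), "gamma2"), "unknown survival family")
})
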