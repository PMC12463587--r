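# Parametric survival distributions, MLE fitting and model selection.

test_that("survival functions honour their analytic anchors", {
  ll <- parametric_survival("loglogistic", shape = 2.309, scale = 13.051)
  ln <- parametric_survival("lognormal", meanlog = 2.376, sdlog = 0.805)
  expect_equal(surv_prob(ll, 0), 1)
  expect_equal(surv_prob(ln, 0), 1)
  # under S(t) = 1/(1 + (t/scale)^shape) the scale is the median
  expect_equal(surv_prob(ll, 13.051), 0.5)
  # log-normal median is exp(meanlog)
  expect_equal(surv_prob(ln, exp(2.376)), 0.5)
})

test_that("every family yields a proper, monotone survival function", {
  models <- list(
    parametric_survival("exponential", rate = 0.08),
    parametric_survival("weibull", shape = 1.3, scale = 12),
    parametric_survival("gompertz", shape = 0.12, rate = 0.05),
    parametric_survival("gompertz", shape = -0.05, rate = 0.04),
    parametric_survival("loglogistic", shape = 2.061, scale = 6.767),
    parametric_survival("lognormal", meanlog = 1.802, sdlog = 0.856)
  )
  tt <- seq(0, 600, by = 0.5)
  for (m in models) {
    s <- surv_prob(m, tt)
    expect_equal(s[1], 1)
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
    if (!(m$family == "gompertz" && m$params$shape < 0)) {
      expect_lt(surv_prob(m, 1e5), 1e-3)
    }
  }
  # negative-shape gompertz plateaus at exp(rate/shape)
  neg <- parametric_survival("gompertz", shape = -0.05, rate = 0.04)
  expect_equal(surv_prob(neg, 1e6), exp(0.04 / -0.05), tolerance = 1e-8)
})

test_that("invalid parameters and negative times are rejected", {
  expect_error(parametric_survival("weibull", shape = -1, scale = 2), "> 0")
  expect_error(parametric_survival("loglogistic", shape = 2), "requires parameters")
  expect_error(parametric_survival("exponential", rate = 0), "> 0")
  m <- parametric_survival("exponential", rate = 0.1)
  expect_error(surv_prob(m, -1), ">= 0")
})

test_that("exponential MLE matches the closed form d/T and its log-likelihood", {
  set.seed(11)
  n <- 400
  t_ev <- rexp(n, 0.07)
  cens <- runif(n, 0, 30)
  ipd <- data.frame(time = pmin(t_ev, cens), event = as.integer(t_ev <= cens))
  d <- sum(ipd$event); Tfu <- sum(ipd$time)
  fit <- fit_mle(ipd, "exponential")
  expect_true(fit$converged)
  expect_equal(fit$model$params$rate, d / Tfu, tolerance = 1e-6)
  expect_equal(fit$loglik, d * log(d / Tfu) - (d / Tfu) * Tfu, tolerance = 1e-8)
  # information-criteria identities, k = 1 free parameter
  expect_identical(fit$aic, 2 * 1 - 2 * fit$loglik)
  expect_identical(fit$bic, 1 * log(n) - 2 * fit$loglik)
})

test_that("fitting recovers log-logistic parameters from large uncensored samples", {
  set.seed(5)
  gen <- parametric_survival("loglogistic", shape = 2.309, scale = 13.051)
  ipd <- data.frame(time = rsurv(gen, 2000), event = 1)
  fit <- fit_mle(ipd, "loglogistic")
  expect_true(fit$converged)
  expect_lt(abs(fit$model$params$shape - 2.309) / 2.309, 0.05)
  expect_lt(abs(fit$model$params$scale - 13.051) / 13.051, 0.05)
})

test_that("AIC selection identifies the generating family at large n", {
  set.seed(17)
  gen <- parametric_survival("loglogistic", shape = 2.309, scale = 13.051)
  ipd <- data.frame(time = rsurv(gen, 2000), event = 1)
  fits <- lapply(names(psmcea:::SURV_FAMILIES), function(f) fit_mle(ipd, f))
  best <- select_model(fits)
  expect_identical(best$family, "loglogistic")
  rep <- attr(best, "report")
  expect_s3_class(rep, "data.frame")
  expect_setequal(rep$family, names(psmcea:::SURV_FAMILIES))
})

test_that("selection tie-breaks: single candidate, equal AIC, convergence", {
  single <- fake_fit("weibull", aic = 100, bic = 104)
  expect_identical(select_model(list(single))$family, "weibull")
  a <- fake_fit("weibull", aic = 100, bic = 108)
  b <- fake_fit("lognormal", aic = 100, bic = 104)
  expect_identical(select_model(list(a, b))$family, "lognormal")
  bad <- fake_fit("gompertz", aic = 1, bic = 1, converged = FALSE)
  expect_identical(select_model(list(a, bad))$family, "weibull")
  expect_error(select_model(list()), "no candidate")
})

test_that("degenerate IPD is rejected up front", {
  expect_error(fit_mle(data.frame(time = c(1, 2, 3), event = c(0, 0, 0)), "weibull"),
               "at least 2 events")
  expect_error(fit_mle(data.frame(time = c(0, 1, 2), event = c(1, 1, 1)), "lognormal"),
               "positive times")
})
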