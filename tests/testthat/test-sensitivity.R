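# One-way (tornado) analysis, PSA, CEAC, scenarios and threshold price.

test_that("tornado output is sorted and a non-entering parameter has zero spread", {
  cfg <- china_cfg()
  # silence the hypertension pathway entirely, then its management cost is inert
  cfg <- config_set(cfg, "ae_profile.hypertension.incidence_switch", 0)
  tw <- one_way(cfg)
  expect_true(all(diff(tw$spread) <= 1e-9))
  expect_equal(tw$spread[tw$path == "ae_profile.hypertension.cost"], 0)
  expect_error(one_way(cfg, data.frame(name = "x", path = "prices.nonexistent",
                                       base = 1, low = 0, high = 2, dist = "gamma")),
               "no parameter")
})

test_that("the ICER is affine in the ramucirumab unit price", {
  cfg <- china_cfg()
  icers <- vapply(c(0.25, 0.625, 1), function(m) scenario_price(cfg, m)$icer, numeric(1))
  # three-point collinearity: the midpoint multiplier gives the mean ICER
  expect_equal(icers[2], (icers[1] + icers[3]) / 2, tolerance = 1e-6)
  expect_equal(scenario_price(cfg, 1)$icer,
               evaluate_strategies(cfg)$comparison$icer)
})

test_that("PSA is bit-reproducible under a fixed seed and collapses when all fixed", {
  cfg <- china_cfg()
  a <- sample_psa(cfg, n = 40, seed = 123)
  b <- sample_psa(cfg, n = 40, seed = 123)
  expect_identical(a$draws, b$draws)
  expect_identical(a$param_draws, b$param_draws)
  # all-fixed specs: every draw equals the deterministic base case
  specs <- param_specs(cfg)
  specs$dist <- "fixed"
  fx <- sample_psa(cfg, specs = specs, n = 5, seed = 1)
  base <- evaluate_strategies(cfg)$comparison
  expect_true(all(abs(fx$draws$delta_cost - base$delta_cost) < 1e-9))
  expect_true(all(abs(fx$draws$delta_qaly - base$delta_qaly) < 1e-9))
})

test_that("sampled parameter means sit within Monte-Carlo error of their baselines", {
  cfg <- china_cfg()
  specs <- param_specs(cfg)
  set.seed(99)
  draws <- psmcea:::psa_draw_matrix(specs, 2000)
  # 3 standard errors per parameter: the check runs jointly over ~30
  # parameters, where a 2-SE band would flag a sampler-correct run
  for (i in which(specs$dist != "fixed")) {
    s <- (specs$high[i] - specs$low[i]) / (2 * 1.96)
    expect_lt(abs(mean(draws[, i]) - specs$base[i]), 3 * s / sqrt(2000),
              label = specs$name[i])
  }
  # fixed parameters are never perturbed
  fixed <- which(specs$dist == "fixed")
  expect_true(all(draws[, fixed] == specs$base[fixed]))
})

test_that("infeasible beta moment matching errors at configuration time", {
  spec <- data.frame(name = "bad", path = "utilities.pfs", base = 0.02,
                     low = -0.5, high = 0.54, dist = "beta")
  expect_error(psmcea:::psa_distribution(spec[1, ]), "infeasible")
})

test_that("CEAC limits match their analytic forms", {
  draws <- data.frame(delta_cost = c(-5, 10, 20, -1), delta_qaly = c(0.1, -0.2, 0.3, -0.4))
  cc <- ceac(draws, c(0, 1e12))
  # lambda = 0: fraction of cost-saving draws
  expect_equal(cc$probability[1], mean(draws$delta_cost < 0))
  # lambda -> infinity: fraction of QALY-gaining draws
  expect_equal(cc$probability[2], mean(draws$delta_qaly > 0))
  # degenerate draws, all costlier than the threshold justifies -> probability 0
  degen <- data.frame(delta_cost = rep(100, 4), delta_qaly = rep(0.001, 4))
  expect_equal(ceac(degen, 38042.49)$probability, 0)
})

test_that("acceptance probability is non-increasing in the price multiplier (CRN)", {
  cfg <- china_cfg()
  st <- scenario_table(cfg, multipliers = c(1, 0.5, 0.2, 0.1, 0.05),
                       n_psa = 100, seed = 7)
  expect_true(all(diff(st$acceptance) >= 0))  # multipliers are descending
  expect_true(all(diff(st$icer) <= 0))
})

test_that("threshold search brackets the target acceptance probability", {
  cfg <- china_cfg()
  tp <- threshold_price(cfg, target = 0.5, n = 200, seed = 11)
  expect_false(tp$no_solution)
  expect_true(tp$multiplier > 0 && tp$multiplier < 1)
  expect_lt(abs(tp$probability - 0.5), 0.05)
  # a strategy that stays unaffordable even with free ramucirumab reports
  # no solution instead of a fake price
  cfg_bad <- config_set(cfg, "prices.paclitaxel", 1e6)
  tp0 <- threshold_price(cfg_bad, target = 0.5, n = 50, seed = 11)
  expect_true(tp0$no_solution)
})
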