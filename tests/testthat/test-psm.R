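# Partitioned-survival trace construction, accumulation and comparison.

test_that("trace conserves state and is monotone every cycle, for all four cells", {
  for (persp in c("china", "us")) for (pop in c("overall", "cps_ge5")) {
    cfg <- default_config(persp, pop)
    traces <- suppressWarnings(build_traces(cfg))
    for (tr in traces) {
      expect_equal(nrow(tr), 130)
      expect_true(all(abs(tr$pfs + tr$pd + tr$dead - 1) < 1e-12))
      expect_true(all(tr$pfs >= 0 & tr$pfs <= 1))
      expect_true(all(tr$pd >= -1e-15 & tr$pd <= 1))
      expect_true(all(diff(tr$dead) >= -1e-12))
      expect_true(all(diff(tr$pfs) <= 1e-12))
      expect_true(all(tr$new_deaths >= 0))
    }
  }
})

test_that("the cohort starts progression-free and dies at the OS median", {
  cfg <- china_cfg()
  tr <- build_traces(cfg)$switch
  # the first cycle's boundary values are S(0) = 1
  expect_equal(tr$pfs[1] + tr$pd[1], (1 + surv_prob(cfg$survival$switch$os, tr$t_end[1])) / 2,
               tolerance = 1e-12)
  expect_lt(tr$dead[1], 0.05)
  # at t = 13.051 months (the log-logistic OS scale) half the cohort has died
  k <- which(tr$t_start <= 13.051 & tr$t_end >= 13.051)
  expect_equal(tr$dead[k], 0.5, tolerance = 0.05)
})

test_that("a PFS curve above OS is clamped, with the clamping counted", {
  os <- parametric_survival("exponential", rate = 0.3)
  pfs <- parametric_survival("exponential", rate = 0.1)  # "progression-free" above OS
  expect_warning(tr <- build_trace(os, pfs), "clamped")
  expect_true(attr(tr, "clamp_events") > 0)
  expect_true(all(tr$pd == 0))
  expect_true(all(abs(tr$pfs + tr$dead - 1) < 1e-12))
})

test_that("accumulate matches hand-worked arithmetic on a two-cycle toy trace", {
  tr <- manual_trace(pfs = c(1, 0.5), pd = c(0, 0.25))
  cyc_years <- 28 / 365.25
  out <- accumulate(tr, zero_costing(2), utilities = list(pfs = 0.8, pd = 0.5),
                    discount_rate = 0)
  expect_equal(out$total_qaly,
               (1 * 0.8 + (0.5 * 0.8 + 0.25 * 0.5)) * cyc_years, tolerance = 1e-12)
  expect_equal(out$life_years, (1 + 0.75) * cyc_years, tolerance = 1e-12)
  # with utilities of 1 and no discounting, QALYs equal life years
  out1 <- accumulate(tr, zero_costing(2), list(pfs = 1, pd = 1), 0)
  expect_equal(out1$total_qaly, out1$life_years)
})

test_that("positive discount rates strictly shrink discounted totals", {
  cfg <- china_cfg()
  r0 <- evaluate_strategies(config_set(cfg, "discount_rate", 0))
  r5 <- evaluate_strategies(cfg)
  for (arm in c("switch", "control")) {
    expect_lt(r5[[arm]]$total_cost, r0[[arm]]$total_cost)
    expect_lt(r5[[arm]]$total_qaly, r0[[arm]]$total_qaly)
    # life-years are reported undiscounted
    expect_equal(r5[[arm]]$life_years, r0[[arm]]$life_years)
  }
  expect_error(accumulate(build_traces(cfg)$switch,
                          zero_costing(130), list(pfs = 0.8, pd = 0.5), 0.2),
               "discount_rate")
})

test_that("refining the cycle length from 28 to 7 days moves QALYs by < 1%", {
  cfg <- china_cfg()
  q_of <- function(cycle_days) {
    tr <- build_trace(cfg$survival$switch$os, cfg$survival$switch$pfs,
                      cfg$horizon_years, cycle_days)
    accumulate(tr, zero_costing(nrow(tr)), cfg$utilities, cfg$discount_rate)$total_qaly
  }
  expect_lt(abs(q_of(7) - q_of(28)) / q_of(28), 0.01)
})

test_that("zeroing drug prices removes the drug component from both arms", {
  cfg <- china_cfg()
  for (p in names(cfg$prices)) cfg$prices[[p]] <- 0
  for (ae in names(cfg$ae_profile)) {
    cfg$ae_profile[[ae]]$incidence_control <- cfg$ae_profile[[ae]]$incidence_switch
  }
  res <- evaluate_strategies(cfg)
  expect_equal(res$switch$breakdown[["drug"]], 0)
  expect_equal(res$control$breakdown[["drug"]], 0)
  # with equalized AE profiles the AE component cancels too
  expect_equal(res$switch$breakdown[["ae_management"]],
               res$control$breakdown[["ae_management"]])
})

test_that("compare is antisymmetric and flags dominance correctly", {
  mk <- function(cost, qaly) structure(
    list(arm = "x", total_cost = cost, total_qaly = qaly, life_years = qaly,
         breakdown = c(drug = cost)), class = "strategy_outcome")
  cmp <- compare(mk(300, 1.5), mk(200, 1.0), wtp = 500)
  expect_equal(cmp$icer, 200)
  expect_true(cmp$cost_effective)
  expect_equal(cmp$icer * cmp$delta_qaly, cmp$delta_cost, tolerance = 1e-9)
  # swap negates the deltas and mirrors dominance
  fwd <- compare(mk(190, 1.5), mk(200, 1.0), wtp = 500)
  rev <- compare(mk(200, 1.0), mk(190, 1.5), wtp = 500)
  expect_equal(rev$delta_cost, -fwd$delta_cost)
  expect_equal(rev$delta_qaly, -fwd$delta_qaly)
  expect_identical(fwd$dominance, "dominant")
  expect_identical(rev$dominance, "dominated")
  # equal effect: no division, dominance by cost
  eq <- compare(mk(100, 1), mk(200, 1), wtp = 500)
  expect_true(is.na(eq$icer))
  expect_identical(eq$dominance, "cheaper")
  expect_true(eq$cost_effective)
})
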