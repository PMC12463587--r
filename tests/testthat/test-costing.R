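# Dosing arithmetic, per-cycle drug costs and adverse-event burden.

test_that("dose_mg follows its basis: per kg, per m2, flat", {
  pat <- patient(weight = 69, bsa = 1.74)
  ram <- regimen_component("ramucirumab", "per_kg", 8, c(1, 8), 28, "intravenous")
  pac <- regimen_component("paclitaxel", "per_m2", 80, c(1, 8, 15), 28, "intravenous")
  flat <- regimen_component("x", "flat", 100)
  expect_equal(dose_mg(ram, pat), 552)
  expect_equal(dose_mg(pac, pat), 139.2)
  expect_equal(dose_mg(flat, pat), 100)
  # linear in weight / BSA
  pat2 <- patient(weight = 138, bsa = 3.48)
  expect_equal(dose_mg(ram, pat2), 2 * dose_mg(ram, pat))
  expect_equal(dose_mg(pac, pat2), 2 * dose_mg(pac, pat))
})

test_that("per-model-cycle drug cost matches hand arithmetic for the maintenance drugs", {
  pat <- patient(weight = 69, bsa = 1.74)
  prices <- list(ramucirumab = 5.2322, paclitaxel = 0.280, zero = 0)
  care <- list(intravenous_injection = 0, injection_administration = 0)
  ram <- list(regimen_component("ramucirumab", "per_kg", 8, c(1, 8), 28, "intravenous"))
  expect_equal(model_cycle_drug_cost(ram, prices, care, pat)[["drug"]],
               552 * 2 * 5.2322, tolerance = 1e-10)  # $5,776.35
  pac <- list(regimen_component("paclitaxel", "per_m2", 80, c(1, 8, 15), 28, "intravenous"))
  expect_equal(model_cycle_drug_cost(pac, prices, care, pat)[["drug"]],
               139.2 * 3 * 0.280, tolerance = 1e-10)  # $116.93
  free <- list(regimen_component("zero", "flat", 10, 1, 28, "intravenous"))
  expect_equal(model_cycle_drug_cost(free, prices, care, pat)[["drug"]], 0)
  expect_error(model_cycle_drug_cost(
    list(regimen_component("unknown", "flat", 1)), prices, care, pat), "unknown")
})

test_that("regimen-to-model cycle alignment scales by cycle-length ratio and caps", {
  pat <- patient(weight = 70, bsa = 1.8)
  prices <- list(irinotecan = 1)
  care <- list(intravenous_injection = 0, injection_administration = 0)
  # 21-day regimen on 28-day model cycles accrues 4/3 regimen cycles per cycle
  iri <- list(regimen_component("irinotecan", "per_m2", 150, 1, 21, "intravenous"))
  expect_equal(model_cycle_drug_cost(iri, prices, care, pat)[["drug"]],
               150 * 1.8 * 28 / 21)
  # a 168-day cap ends exactly after model cycle 6
  capped <- list(regimen_component("irinotecan", "per_m2", 150, 1, 21, "intravenous",
                                   max_days = 168))
  expect_gt(model_cycle_drug_cost(capped, prices, care, pat, cycle_index = 6)[["total"]], 0)
  expect_equal(model_cycle_drug_cost(capped, prices, care, pat, cycle_index = 7)[["total"]], 0)
})

test_that("expected AE burden matches the published China maintenance-arm arithmetic", {
  expect_equal(ae_burden(NULL), list(cost = 0, qaly_loss = 0))
  one <- data.frame(incidence = 1, cost = 123.4, disutility = 0.2)
  expect_equal(ae_burden(one)$cost, 123.4)
  profile <- data.frame(
    incidence = c(0.2624, 0.06, 0.06),
    cost = c(136.792, 1097.008, 17.824),
    disutility = c(0.2, 0.16, 0.04))
  b <- ae_burden(profile)
  expect_equal(b$cost, 0.2624 * 136.792 + 0.06 * 1097.008 + 0.06 * 17.824,
               tolerance = 1e-12)  # $102.79
  expect_equal(b$qaly_loss,
               (0.2624 * 0.2 + 0.06 * 0.16 + 0.06 * 0.04) * 28 / 365.25)
})

test_that("costs are homogeneous of degree one in unit prices", {
  cfg <- china_cfg()
  cfg2 <- cfg
  for (p in names(cfg2$prices)) cfg2$prices[[p]] <- 2 * cfg2$prices[[p]]
  for (p in names(cfg2$care_costs)) cfg2$care_costs[[p]] <- 2 * cfg2$care_costs[[p]]
  for (ae in names(cfg2$ae_profile)) {
    cfg2$ae_profile[[ae]]$cost <- 2 * cfg2$ae_profile[[ae]]$cost
  }
  r1 <- evaluate_strategies(cfg)
  r2 <- evaluate_strategies(cfg2)
  for (arm in c("switch", "control")) {
    expect_equal(r2[[arm]]$total_cost, 2 * r1[[arm]]$total_cost, tolerance = 1e-12)
    expect_true(all(r1[[arm]]$breakdown >= 0))
    expect_equal(r1[[arm]]$total_cost, sum(r1[[arm]]$breakdown))
    # QALYs are price-free
    expect_identical(r2[[arm]]$total_qaly, r1[[arm]]$total_qaly)
  }
})
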