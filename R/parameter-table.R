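# Machine-readable copy of the shipped base-case parameters: baseline value,
# uncertainty range and sampling distribution for every uncertain model input,
# per payer perspective. This single table drives the default configuration,
# the tornado analysis and the PSA, so defaults cannot drift apart.

#' Uncertain-parameter reference table
#'
#' One row per uncertain model parameter for the given payer perspective:
#' dotted configuration path, baseline value, low/high range and sampling
#' distribution (`gamma` for costs and body size, `beta` for utilities and
#' probabilities, `fixed` for the discount rate). Ranges are the published
#' ones where available; where a source prints a range inconsistent with its
#' baseline it is kept as printed.
#'
#' @param perspective `"china"` or `"us"`.
#' @return data frame with columns `name`, `path`, `base`, `low`, `high`,
#'   `dist`.
#' @export
reference_parameters <- function(perspective = c("china", "us")) {
  perspective <- match.arg(perspective)
  row <- function(name, path, base, low, high, dist) {
    data.frame(name = name, path = path, base = base, low = low, high = high,
               dist = dist, stringsAsFactors = FALSE)
  }
  g <- function(name, path, base, low, high) row(name, path, base, low, high, "gamma")
  b <- function(name, path, base, low, high) row(name, path, base, low, high, "beta")

  if (perspective == "china") {
    country <- rbind(
      g("Enhanced CT per unit",      "care_costs.enhanced_ct",              23.693,  10.659, 106.647),
      g("Blood biochemistry per unit","care_costs.blood_biochemistry",      63.814,  33.253,  93.564),
      g("Blood routine per unit",    "care_costs.blood_routine",             1.930,   1.425,   3.622),
      g("Urine routine per unit",    "care_costs.urine_routine",             0.594,   0.287,   2.553),
      g("Injection administration",  "care_costs.injection_administration",  0.802,   0.158,   0.643),
      g("Intravenous injection",     "care_costs.intravenous_injection",     0.713,   0.356,   1.564),
      g("Cost of terminal care",     "care_costs.terminal_care",          1506.51, 1205.21, 1807.81),
      g("Cost of BSC per cycle",     "care_costs.bsc_per_cycle",           267.78,  214.22,  321.34),
      g("Ramucirumab per mg",        "prices.ramucirumab",                   5.2322,  4.186,   6.279),
      g("Paclitaxel per mg",         "prices.paclitaxel",                    0.280,   0.224,   0.335),
      g("Ondansetron per mg",        "prices.ondansetron",                   0.360,   0.288,   0.433),
      g("Dexamethasone per mg",      "prices.dexamethasone",                 0.018,   0.0148,  0.0221),
      g("Diphenhydramine per mg",    "prices.diphenhydramine",               0.103,   0.0823,  0.123),
      g("Capecitabine per mg",       "prices.capecitabine",                  0.000653, 0.000522, 0.000783),
      g("Calcium folinate per mg",   "prices.calcium_folinate",              0.0355,  0.0284,  0.0426),
      g("Oxaliplatin per mg",        "prices.oxaliplatin",                   0.881,   0.705,   1.058),
      g("5-Fluorouracil per mg",     "prices.fluorouracil",                  0.0183,  0.0146,  0.0220),
      g("Irinotecan per mg",         "prices.irinotecan",                    0.0955,  0.0764,  0.115),
      g("Neutropenia management cost","ae_profile.neutropenia.cost",       136.792, 109.418, 164.147),
      g("Peripheral neuropathy management cost",
        "ae_profile.peripheral_neuropathy.cost",                          1097.008, 877.607, 1316.410),
      g("Hypertension management cost","ae_profile.hypertension.cost",      17.824,  14.261,  21.387),
      g("Patient weight (kg)",       "patient.weight",                      69,      55.2,    82.88),
      g("Patient BSA (m2)",          "patient.bsa",                          1.74,    1.392,   2.088),
      row("Discount rate",           "discount_rate",                        0.05,    0,       0.08, "fixed")
    )
  } else {
    country <- rbind(
      g("Enhanced CT per unit",      "care_costs.enhanced_ct",             530.79,  424.63,  636.95),
      g("Blood biochemistry per unit","care_costs.blood_biochemistry",      10.56,    8.45,   12.67),
      g("Blood routine per unit",    "care_costs.blood_routine",             7.77,    6.22,    9.32),
      g("Urine routine per unit",    "care_costs.urine_routine",             3.17,    2.54,    3.80),
      g("Injection administration",  "care_costs.injection_administration", 13.91,   11.13,   16.69),
      g("Intravenous injection",     "care_costs.intravenous_injection",   223.30,  178.64,  267.96),
      g("Cost of terminal care",     "care_costs.terminal_care",         19247.03, 15397.62, 23096.44),
      g("Cost of BSC per cycle",     "care_costs.bsc_per_cycle",          2262.59, 1810.07, 2715.11),
      g("Ramucirumab per mg",        "prices.ramucirumab",                  15,      12,      18),
      g("Paclitaxel per mg",         "prices.paclitaxel",                    0.2882,  0.23056, 0.34584),
      g("Ondansetron per mg",        "prices.ondansetron",                   0.1056,  0.08448, 0.12672),
      g("Dexamethasone per mg",      "prices.dexamethasone",                 0.02255, 0.01804, 0.02706),
      g("Diphenhydramine per mg",    "prices.diphenhydramine",               0.0602,  0.04816, 0.07224),
      g("Capecitabine per mg",       "prices.capecitabine",                  0.002,   0.0016,  0.0024),
      g("Calcium folinate per mg",   "prices.calcium_folinate",              0.07026, 0.056208, 0.084312),
      g("Oxaliplatin per mg",        "prices.oxaliplatin",                   0.6,     0.48,    0.72),
      g("5-Fluorouracil per mg",     "prices.fluorouracil",                  0.01027, 0.008216, 0.012324),
      g("Irinotecan per mg",         "prices.irinotecan",                    0.3,     0.24,    0.36),
      g("Neutropenia management cost","ae_profile.neutropenia.cost",     18360.82, 14688.66, 22032.98),
      g("Peripheral neuropathy management cost",
        "ae_profile.peripheral_neuropathy.cost",                         14184.2, 11347.36, 17021.04),
      g("Hypertension management cost","ae_profile.hypertension.cost",   19272.01, 15417.61, 23126.41),
      g("Patient weight (kg)",       "patient.weight",                      75,      60,      90),
      g("Patient BSA (m2)",          "patient.bsa",                          1.8,     1.44,    2.16),
      row("Discount rate",           "discount_rate",                        0.03,    0,       0.08, "fixed")
    )
  }
  shared <- rbind(
    b("Utility of PFS",              "utilities.pfs",                        0.797,   0.64,    0.96),
    b("Utility of PD",               "utilities.pd",                         0.577,   0.46,    0.69),
    b("Disutility of neutropenia",   "ae_profile.neutropenia.disutility",    0.2,     0.16,    0.24),
    b("Disutility of peripheral neuropathy",
      "ae_profile.peripheral_neuropathy.disutility",                         0.16,    0.128,   0.192),
    b("Disutility of hypertension",  "ae_profile.hypertension.disutility",   0.04,    0.032,   0.048),
    b("Neutropenia risk, maintenance arm",
      "ae_profile.neutropenia.incidence_switch",                             0.2624,  0.2099,  0.3149),
    b("Neutropenia risk, control arm",
      "ae_profile.neutropenia.incidence_control",                            0.0963,  0.0770,  0.1156),
    b("Peripheral neuropathy risk, maintenance arm",
      "ae_profile.peripheral_neuropathy.incidence_switch",                   0.06,    0.048,   0.072),
    b("Peripheral neuropathy risk, control arm",
      "ae_profile.peripheral_neuropathy.incidence_control",                  0.07,    0.056,   0.084),
    b("Hypertension risk, maintenance arm",
      "ae_profile.hypertension.incidence_switch",                            0.06,    0.048,   0.072)
  )
  rbind(country, shared)
}

#' Baseline survival models per population
#'
#' The fitted OS/PFS extrapolation models used in the base case: log-logistic
#' for all four overall-population curves; for the PD-L1 CPS >= 5 subgroup,
#' log-logistic OS in the maintenance arm and log-normal elsewhere. Time in
#' months.
#'
#' @param population `"overall"` or `"cps_ge5"`.
#' @return nested list: `$switch`/`$control`, each with `$os` and `$pfs`
#'   [parametric_survival()] models.
#' @export
reference_survival <- function(population = c("overall", "cps_ge5")) {
  population <- match.arg(population)
  if (population == "overall") {
    list(
      switch = list(
        os  = parametric_survival("loglogistic", shape = 2.309, scale = 13.051),
        pfs = parametric_survival("loglogistic", shape = 2.061, scale = 6.767)),
      control = list(
        os  = parametric_survival("loglogistic", shape = 1.891, scale = 9.593),
        pfs = parametric_survival("loglogistic", shape = 1.697, scale = 3.579))
    )
  } else {
    list(
      switch = list(
        os  = parametric_survival("loglogistic", shape = 2.386, scale = 15.518),
        pfs = parametric_survival("lognormal", meanlog = 2.0989, sdlog = 0.7146)),
      control = list(
        os  = parametric_survival("lognormal", meanlog = 2.376, sdlog = 0.805),
        pfs = parametric_survival("lognormal", meanlog = 1.802, sdlog = 0.856))
    )
  }
}
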