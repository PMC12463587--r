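# Regimen- and body-size-based costing: unit prices, dosing schedules and
# care costs turned into per-model-cycle cost streams for each strategy.
#
# Regimens run on their own cycle length (28-day maintenance, 21-day CAPOX,
# 14-day FOLFOX, 21-day irinotecan); costs are aligned onto 28-day model
# cycles by continuous accrual, i.e. a model cycle accrues
# (overlap days / regimen cycle days) regimen cycles' worth of cost.
# Fractional milligrams are priced exactly (no vial rounding).

#' Patient anthropometrics
#'
#' @param weight body weight in kg.
#' @param bsa body surface area in m^2.
#' @return a `patient` object.
#' @export
patient <- function(weight, bsa) {
  assert_number(weight, "weight", lower = 1e-6)
  assert_number(bsa, "bsa", lower = 1e-6)
  structure(list(weight = weight, bsa = bsa), class = "patient")
}

#' One drug component of a treatment regimen
#'
#' @param drug drug name; must match a unit-price entry.
#' @param dose_basis `"per_kg"`, `"per_m2"` or `"flat"`.
#' @param dose_value dose in mg per basis unit, per administration day.
#' @param administration_days day indices (1-based) within the regimen cycle.
#' @param regimen_cycle_days regimen cycle length in days.
#' @param admin_class `"intravenous"`, `"injection"` or `"oral"`; selects the
#'   per-administration fee (oral incurs none).
#' @param weight mixing weight (e.g. 0.5 when half the cohort receives this
#'   regimen).
#' @param start_day model day the component becomes available (0 = outset).
#' @param max_days model days after `start_day` during which the component is
#'   given (`Inf` = for as long as the patient remains in the paying state).
#' @return a `regimen_component`.
#' @export
regimen_component <- function(drug, dose_basis = c("per_kg", "per_m2", "flat"),
                              dose_value, administration_days = 1,
                              regimen_cycle_days = 28,
                              admin_class = c("intravenous", "injection", "oral"),
                              weight = 1, start_day = 0, max_days = Inf) {
  dose_basis <- match.arg(dose_basis)
  admin_class <- match.arg(admin_class)
  assert_number(dose_value, "dose_value", lower = 1e-12)
  if (any(administration_days < 1) || any(administration_days > regimen_cycle_days)) {
    stop_config("administration days must lie within the regimen cycle")
  }
  structure(list(drug = drug, dose_basis = dose_basis, dose_value = dose_value,
                 administration_days = administration_days,
                 regimen_cycle_days = regimen_cycle_days,
                 admin_class = admin_class, weight = weight,
                 start_day = start_day, max_days = max_days),
            class = "regimen_component")
}

#' Administered dose in mg
#'
#' Dose for one administration day: `dose_value * weight` (per_kg),
#' `dose_value * bsa` (per_m2) or `dose_value` (flat).
#'
#' @param component a [regimen_component()].
#' @param patient a [patient()].
#' @return dose in mg.
#' @export
dose_mg <- function(component, patient) {
  switch(component$dose_basis,
    per_kg = component$dose_value * patient$weight,
    per_m2 = component$dose_value * patient$bsa,
    flat   = component$dose_value)
}

admin_fee <- function(admin_class, care_costs) {
  switch(admin_class,
    intravenous = care_costs$intravenous_injection,
    injection   = care_costs$injection_administration,
    oral        = 0)
}

# Cost of one component per full regimen cycle, split into drug acquisition
# and administration fees.
component_regimen_cycle_cost <- function(component, prices, care_costs, patient) {
  price <- prices[[component$drug]]
  if (is.null(price)) stop_config("no unit price configured for drug '", component$drug, "'")
  price <- unname(price)
  n_admin <- length(component$administration_days)
  c(drug = dose_mg(component, patient) * n_admin * price,
    administration = n_admin * admin_fee(component$admin_class, care_costs))
}

#' Expected drug and administration cost in one model cycle
#'
#' Accrues each component's regimen-cycle cost into the model cycle in
#' proportion to the calendar overlap between the model cycle and the
#' component's active window (`start_day` to `start_day + max_days`), so
#' treatment caps are respected.
#'
#' @param components list of [regimen_component()]s.
#' @param prices named list of USD-per-mg unit prices.
#' @param care_costs named list of care costs (supplies administration fees).
#' @param patient a [patient()].
#' @param model_cycle_days model cycle length in days (28).
#' @param cycle_index 1-based model cycle number.
#' @return named vector `c(drug, administration, total)` in USD.
#' @export
model_cycle_drug_cost <- function(components, prices, care_costs, patient,
                                  model_cycle_days = 28, cycle_index = 1) {
  out <- c(drug = 0, administration = 0)
  win_lo <- (cycle_index - 1) * model_cycle_days
  win_hi <- cycle_index * model_cycle_days
  for (comp in components) {
    overlap <- max(0, min(win_hi, comp$start_day + comp$max_days) - max(win_lo, comp$start_day))
    if (overlap <= 0) next
    per_cycle <- component_regimen_cycle_cost(comp, prices, care_costs, patient)
    out <- out + comp$weight * per_cycle * overlap / comp$regimen_cycle_days
  }
  c(out, total = sum(out))
}

#' Expected adverse-event cost and QALY decrement
#'
#' Expected over the incidence of each grade >= 3 event: cost
#' `sum(incidence * management cost)`; QALY decrement
#' `sum(incidence * disutility) * duration_years`.
#'
#' @param profile data frame with columns `incidence`, `cost`, `disutility`.
#' @param duration_years duration of each event's utility decrement in years
#'   (default: one 28-day model cycle).
#' @return list with `cost` (USD) and `qaly_loss` (QALYs).
#' @export
ae_burden <- function(profile, duration_years = 28 / 365.25) {
  if (is.null(profile) || nrow(profile) == 0) return(list(cost = 0, qaly_loss = 0))
  stopifnot(all(c("incidence", "cost", "disutility") %in% names(profile)))
  if (any(profile$incidence < 0 | profile$incidence > 1)) stop_config("AE incidences must be in [0, 1]")
  if (any(profile$cost < 0)) stop_config("AE management costs must be >= 0")
  list(cost = sum(profile$incidence * profile$cost),
       qaly_loss = sum(profile$incidence * profile$disutility) * duration_years)
}

#' Treatment regimen for one strategy arm
#'
#' Maintenance arm: ramucirumab 8 mg/kg days 1 and 8 plus paclitaxel 80 mg/m^2
#' days 1, 8 and 15 of a 28-day cycle, with antiemetic/antihistamine
#' premedication at each paclitaxel administration, continued while
#' progression-free. Control arm: a configurable CAPOX/FOLFOX mix for the
#' first 24 weeks, then fluoropyrimidine monotherapy at the same
#' fluoropyrimidine dose while progression-free.
#'
#' @param config a `cea_config`.
#' @param arm `"switch"` or `"control"`.
#' @return list of [regimen_component()]s.
#' @export
build_regimen <- function(config, arm = c("switch", "control")) {
  arm <- match.arg(arm)
  opts <- config$regimen_options
  if (arm == "switch") {
    pre <- opts$premedication
    return(list(
      regimen_component("ramucirumab", "per_kg", 8, c(1, 8), 28, "intravenous"),
      regimen_component("paclitaxel", "per_m2", 80, c(1, 8, 15), 28, "intravenous"),
      regimen_component("ondansetron", "flat", pre$ondansetron_mg, c(1, 8, 15), 28, "injection"),
      regimen_component("dexamethasone", "flat", pre$dexamethasone_mg, c(1, 8, 15), 28, "injection"),
      regimen_component("diphenhydramine", "flat", pre$diphenhydramine_mg, c(1, 8, 15), 28, "injection")
    ))
  }
  f <- opts$capox_fraction
  cap_days <- opts$oxaliplatin_max_weeks * 7
  comps <- list(
    # CAPOX: oxaliplatin 130 mg/m2 day 1 + capecitabine 1000 mg/m2 twice daily
    # days 1-14, every 21 days
    regimen_component("oxaliplatin", "per_m2", 130, 1, 21, "intravenous",
                      weight = f, max_days = cap_days),
    regimen_component("capecitabine", "per_m2", 2000, 1:14, 21, "oral",
                      weight = f, max_days = cap_days),
    # FOLFOX: oxaliplatin 85 mg/m2 + folinate 400 mg/m2 + 5-FU 400 mg/m2 bolus
    # and 2400 mg/m2 infusion, every 14 days
    regimen_component("oxaliplatin", "per_m2", 85, 1, 14, "intravenous",
                      weight = 1 - f, max_days = cap_days),
    regimen_component("calcium_folinate", "per_m2", 400, 1, 14, "intravenous",
                      weight = 1 - f, max_days = cap_days),
    regimen_component("fluorouracil", "per_m2", 2800, 1, 14, "intravenous",
                      weight = 1 - f, max_days = cap_days),
    # fluoropyrimidine monotherapy beyond the oxaliplatin cap
    regimen_component("capecitabine", "per_m2", 2000, 1:14, 21, "oral",
                      weight = f, start_day = cap_days),
    regimen_component("fluorouracil", "per_m2", 2800, 1, 14, "intravenous",
                      weight = 1 - f, start_day = cap_days)
  )
  comps
}

ae_profile_for_arm <- function(config, arm) {
  inc_field <- if (arm == "switch") "incidence_switch" else "incidence_control"
  do.call(rbind, lapply(names(config$ae_profile), function(nm) {
    item <- config$ae_profile[[nm]]
    data.frame(name = nm, incidence = item[[inc_field]], cost = item$cost,
               disutility = item$disutility, stringsAsFactors = FALSE)
  }))
}

#' Per-cycle cost streams for one strategy
#'
#' Assembles everything [accumulate()] needs: a cycles x {drug,
#' administration, tests} matrix of on-treatment (PFS) costs, per-cycle
#' progressed-disease costs (subsequent active therapy for the treated
#' fraction, best supportive care for the rest), the first-cycle AE cost and
#' QALY decrement, and the terminal-care cost attached to death.
#'
#' @param config a `cea_config`.
#' @param arm `"switch"` or `"control"`.
#' @param n_cycles number of model cycles.
#' @return a `strategy_costing` list.
#' @export
strategy_costing <- function(config, arm = c("switch", "control"), n_cycles) {
  arm <- match.arg(arm)
  pat <- patient(config$patient$weight, config$patient$bsa)
  comps <- build_regimen(config, arm)
  mcd <- config$cycle_days

  pfs_cost <- matrix(0, nrow = n_cycles, ncol = 3,
                     dimnames = list(NULL, c("drug", "administration", "tests")))
  # vectorized equivalent of model_cycle_drug_cost() over all cycles
  win_lo <- (seq_len(n_cycles) - 1) * mcd
  win_hi <- win_lo + mcd
  for (comp in comps) {
    overlap <- pmax(0, pmin(win_hi, comp$start_day + comp$max_days) -
                       pmax(win_lo, comp$start_day))
    if (all(overlap == 0)) next
    per_cycle <- component_regimen_cycle_cost(comp, config$prices, config$care_costs, pat)
    frac <- comp$weight * overlap / comp$regimen_cycle_days
    pfs_cost[, "drug"] <- pfs_cost[, "drug"] + per_cycle[["drug"]] * frac
    pfs_cost[, "administration"] <- pfs_cost[, "administration"] +
      per_cycle[["administration"]] * frac
  }
  tests <- with(config$care_costs,
                config$monitoring$blood_biochemistry * blood_biochemistry +
                config$monitoring$blood_routine * blood_routine +
                config$monitoring$urine_routine * urine_routine +
                config$monitoring$enhanced_ct * enhanced_ct)
  pfs_cost[, "tests"] <- tests

  active <- if (arm == "switch") config$subsequent$active_fraction_switch else
    config$subsequent$active_fraction_control
  iri <- regimen_component("irinotecan", "per_m2", 150, 1, 21, "intravenous")
  iri_cost <- component_regimen_cycle_cost(iri, config$prices, config$care_costs, pat)
  pd_subsequent <- active * sum(iri_cost) * mcd / iri$regimen_cycle_days
  pd_bsc <- (1 - active) * config$care_costs$bsc_per_cycle

  ae <- ae_burden(ae_profile_for_arm(config, arm),
                  duration_years = config$regimen_options$ae_disutility_cycles *
                    mcd / 365.25)

  structure(list(arm = arm, n_cycles = n_cycles, pfs_cost = pfs_cost,
                 pd_subsequent = pd_subsequent, pd_bsc = pd_bsc,
                 ae_cost = ae$cost, ae_qaly_loss = ae$qaly_loss,
                 terminal = config$care_costs$terminal_care),
            class = "strategy_costing")
}
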