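# Analysis configuration: one object holding every model input for a given
# payer perspective (china / us) and population (overall / PD-L1 CPS >= 5),
# with shipped defaults taken from the reference parameter table.

#' Default analysis configuration
#'
#' Builds the complete model configuration for one perspective x population
#' cell: survival models, unit prices, dosing regimens, care and adverse-event
#' costs, utilities, discounting and willingness-to-pay. Every uncertain value
#' defaults to the reference table ([reference_parameters()]); structural
#' choices (monitoring schedule, regimen composition, premedication doses) are
#' exposed under `regimen_options` and `monitoring`.
#'
#' @param perspective `"china"` or `"us"`.
#' @param population `"overall"` or `"cps_ge5"`.
#' @return a `cea_config` object (nested named list).
#' @examples
#' cfg <- default_config("china", "overall")
#' cfg$wtp
#' @export
default_config <- function(perspective = c("china", "us"),
                           population = c("overall", "cps_ge5")) {
  perspective <- match.arg(perspective)
  population <- match.arg(population)
  ref <- reference_parameters(perspective)

  config <- list(
    perspective = perspective,
    population = population,
    horizon_years = 10,
    cycle_days = 28,
    discount_rate = NA_real_,
    wtp = if (perspective == "china") 38042.49 else 150000,
    patient = list(weight = NA_real_, bsa = NA_real_),
    utilities = list(pfs = NA_real_, pd = NA_real_),
    survival = reference_survival(population),
    prices = list(ramucirumab = NA_real_, paclitaxel = NA_real_,
                  ondansetron = NA_real_, dexamethasone = NA_real_,
                  diphenhydramine = NA_real_, capecitabine = NA_real_,
                  calcium_folinate = NA_real_, oxaliplatin = NA_real_,
                  fluorouracil = NA_real_, irinotecan = NA_real_),
    care_costs = list(enhanced_ct = NA_real_, blood_biochemistry = NA_real_,
                      blood_routine = NA_real_, urine_routine = NA_real_,
                      injection_administration = NA_real_,
                      intravenous_injection = NA_real_,
                      bsc_per_cycle = NA_real_, terminal_care = NA_real_),
    # units of each test charged per 28-day model cycle while on treatment
    monitoring = list(blood_biochemistry = 1, blood_routine = 1,
                      urine_routine = 1, enhanced_ct = 0.5),
    ae_profile = list(
      neutropenia = list(cost = NA_real_, disutility = NA_real_,
                         incidence_switch = NA_real_, incidence_control = NA_real_),
      peripheral_neuropathy = list(cost = NA_real_, disutility = NA_real_,
                                   incidence_switch = NA_real_, incidence_control = NA_real_),
      hypertension = list(cost = NA_real_, disutility = NA_real_,
                          incidence_switch = NA_real_, incidence_control = 0)
    ),
    subsequent = list(active_fraction_switch = 0.58, active_fraction_control = 0.56),
    regimen_options = list(
      capox_fraction = 0.5,            # CAPOX vs FOLFOX mix in the control arm
      oxaliplatin_max_weeks = 24,      # oxaliplatin-based treatment cap
      premedication = list(ondansetron_mg = 8, dexamethasone_mg = 10,
                           diphenhydramine_mg = 25),
      ae_disutility_cycles = 1         # duration of AE QALY decrement, model cycles
    )
  )
  for (i in seq_len(nrow(ref))) {
    config <- config_set(config, ref$path[i], ref$base[i])
  }
  structure(config, class = c("cea_config", "list"))
}

#' Validate an analysis configuration
#'
#' Schema and range checks: probabilities in `[0, 1]`, non-negative costs,
#' positive body size, discount rate within the 0-8% range used for its
#' sensitivity bounds.
#'
#' @param config a `cea_config`.
#' @return the configuration, invisibly, or an error naming the offending
#'   entry.
#' @export
validate_config <- function(config) {
  assert_number(config$horizon_years, "horizon_years", lower = 1e-6)
  assert_number(config$cycle_days, "cycle_days", lower = 1)
  assert_number(config$discount_rate, "discount_rate", lower = 0, upper = 0.08)
  assert_number(config$wtp, "wtp", lower = 0)
  assert_number(config$patient$weight, "patient.weight", lower = 1e-6)
  assert_number(config$patient$bsa, "patient.bsa", lower = 1e-6)
  assert_number(config$utilities$pfs, "utilities.pfs", lower = 0, upper = 1)
  assert_number(config$utilities$pd, "utilities.pd", lower = 0, upper = 1)
  for (p in names(config$prices)) assert_number(config$prices[[p]], paste0("prices.", p), lower = 0)
  for (p in names(config$care_costs)) assert_number(config$care_costs[[p]], paste0("care_costs.", p), lower = 0)
  for (p in names(config$monitoring)) assert_number(config$monitoring[[p]], paste0("monitoring.", p), lower = 0)
  for (ae in names(config$ae_profile)) {
    item <- config$ae_profile[[ae]]
    assert_number(item$cost, paste0("ae_profile.", ae, ".cost"), lower = 0)
    assert_number(item$disutility, paste0("ae_profile.", ae, ".disutility"), lower = 0, upper = 1)
    assert_number(item$incidence_switch, paste0("ae_profile.", ae, ".incidence_switch"), lower = 0, upper = 1)
    assert_number(item$incidence_control, paste0("ae_profile.", ae, ".incidence_control"), lower = 0, upper = 1)
  }
  assert_number(config$subsequent$active_fraction_switch, "subsequent.active_fraction_switch", 0, 1)
  assert_number(config$subsequent$active_fraction_control, "subsequent.active_fraction_control", 0, 1)
  assert_number(config$regimen_options$capox_fraction, "regimen_options.capox_fraction", 0, 1)
  for (arm in c("switch", "control")) for (ep in c("os", "pfs")) {
    m <- config$survival[[arm]][[ep]]
    if (!inherits(m, "parametric_survival")) {
      stop_config("survival.", arm, ".", ep, " must be a parametric_survival model")
    }
  }
  invisible(config)
}

#' Read / write a configuration as YAML
#'
#' Survival models are stored as `{family, <parameters...>}` mappings and
#' reconstructed on read; the round trip `read_config(write_config(x))` is the
#' identity.
#'
#' @param config a `cea_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  plain <- unclass(config)
  for (arm in c("switch", "control")) for (ep in c("os", "pfs")) {
    m <- plain$survival[[arm]][[ep]]
    plain$survival[[arm]][[ep]] <- c(list(family = m$family), m$params)
  }
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @return `read_config`: a validated `cea_config`.
#' @export
read_config <- function(path) {
  plain <- yaml::read_yaml(path)
  for (arm in c("switch", "control")) for (ep in c("os", "pfs")) {
    m <- plain$survival[[arm]][[ep]]
    plain$survival[[arm]][[ep]] <- do.call(parametric_survival, m)
  }
  config <- structure(plain, class = c("cea_config", "list"))
  validate_config(config)
  config
}
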