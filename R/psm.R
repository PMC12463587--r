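# Three-state partitioned survival model: progression-free (PFS), progressed
# disease (PD) and death. State occupancy is read directly off the OS and PFS
# curves (PD = OS - PFS), with half-cycle correction: the occupancy credited
# to a cycle is the average of the survival values at its two boundaries.

#' Build a partitioned-survival cohort trace
#'
#' One row per 28-day model cycle out to the time horizon. Occupancy is the
#' half-cycle-corrected (boundary-averaged) value of `S_PFS` and `S_OS`;
#' `pd = max(0, S_OS - S_PFS)` with any clamping counted in the
#' `clamp_events` attribute; `new_deaths` is the drop in `S_OS` across the
#' cycle, used to attach one-off dying costs.
#'
#' @param os,pfs [parametric_survival()] models for overall and
#'   progression-free survival (time in months).
#' @param horizon_years model time horizon (default 10 years).
#' @param cycle_days model cycle length in days (default 28).
#' @return a `cohort_trace` data frame with columns `cycle`, `t_start`,
#'   `t_end` (months), `pfs`, `pd`, `dead`, `new_deaths`.
#' @export
build_trace <- function(os, pfs, horizon_years = 10, cycle_days = 28) {
  stopifnot(inherits(os, "parametric_survival"), inherits(pfs, "parametric_survival"))
  assert_number(horizon_years, "horizon_years", lower = 1e-6)
  cycle_months <- cycle_days / DAYS_PER_MONTH
  n_cycles <- round(horizon_years * 12 / cycle_months)
  tb <- (0:n_cycles) * cycle_months

  s_os <- surv_prob(os, tb)
  s_pfs <- surv_prob(pfs, tb)
  excess <- pmax(s_pfs - s_os, 0)
  clamp_events <- sum(excess[-1] > 1e-12)
  if (clamp_events > 0) {
    warning(sprintf("PFS exceeded OS in %d of %d cycles (max excess %.4f); PD clamped to 0",
                    clamp_events, n_cycles, max(excess)), call. = FALSE)
  }
  s_pfs <- pmin(s_pfs, s_os)

  os_occ <- (s_os[-1] + s_os[-(n_cycles + 1)]) / 2
  pfs_occ <- (s_pfs[-1] + s_pfs[-(n_cycles + 1)]) / 2
  trace <- data.frame(
    cycle = seq_len(n_cycles),
    t_start = tb[-(n_cycles + 1)],
    t_end = tb[-1],
    pfs = pfs_occ,
    pd = os_occ - pfs_occ,
    dead = 1 - os_occ,
    new_deaths = s_os[-(n_cycles + 1)] - s_os[-1]
  )
  structure(trace, class = c("cohort_trace", "data.frame"),
            clamp_events = clamp_events, cycle_days = cycle_days)
}

#' Accumulate discounted costs and QALYs over a cohort trace
#'
#' Per cycle: QALYs accrue as `(pfs * u_pfs + pd * u_pd) * cycle_years`;
#' on-treatment costs accrue against PFS occupancy, subsequent-therapy and BSC
#' costs against PD occupancy, and terminal care against new deaths.
#' Adverse-event cost and QALY decrement are applied in the first cycle only.
#' Discounting uses `(1 + r)^(-t)` at the cycle midpoint.
#'
#' @param trace a [build_trace()] result.
#' @param costing a [strategy_costing()] for the same cycle structure.
#' @param utilities list with `pfs` and `pd` health-state utilities.
#' @param discount_rate annual discount rate (0 to 0.08).
#' @return a `strategy_outcome`: `total_cost`, `total_qaly` (discounted),
#'   `life_years` (undiscounted) and a cost `breakdown` by component.
#' @export
accumulate <- function(trace, costing, utilities, discount_rate) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(costing, "strategy_costing"))
  if (nrow(trace) != costing$n_cycles) {
    stop_config("trace and costing cover different numbers of cycles")
  }
  assert_number(utilities$pfs, "utilities.pfs", 0, 1)
  assert_number(utilities$pd, "utilities.pd", 0, 1)
  assert_number(discount_rate, "discount_rate", 0, 0.08)

  cycle_years <- attr(trace, "cycle_days") / 365.25
  t_mid_years <- (trace$t_start + trace$t_end) / 2 / 12
  disc <- (1 + discount_rate)^(-t_mid_years)

  breakdown <- c(
    drug = sum(trace$pfs * costing$pfs_cost[, "drug"] * disc),
    administration = sum(trace$pfs * costing$pfs_cost[, "administration"] * disc),
    tests = sum(trace$pfs * costing$pfs_cost[, "tests"] * disc),
    ae_management = costing$ae_cost * disc[1],
    subsequent_therapy = sum(trace$pd * costing$pd_subsequent * disc),
    bsc = sum(trace$pd * costing$pd_bsc * disc),
    terminal_care = sum(trace$new_deaths * disc) * costing$terminal
  )
  qaly <- sum((trace$pfs * utilities$pfs + trace$pd * utilities$pd) * cycle_years * disc) -
    costing$ae_qaly_loss * disc[1]
  ly <- sum((trace$pfs + trace$pd) * cycle_years)

  structure(list(arm = costing$arm, total_cost = sum(breakdown),
                 total_qaly = qaly, life_years = ly, breakdown = breakdown),
            class = "strategy_outcome")
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("<strategy_outcome> %s: cost $%.2f, %.4f QALYs, %.4f LYs\n",
              x$arm, x$total_cost, x$total_qaly, x$life_years))
  invisible(x)
}

#' Incremental cost-effectiveness comparison
#'
#' @param a,b `strategy_outcome`s (a vs b).
#' @param wtp willingness-to-pay threshold in USD/QALY.
#' @return a `ce_comparison` with `delta_cost`, `delta_qaly`, `icer` (NA when
#'   dominance applies), a `dominance` label (`"none"`, `"dominant"`,
#'   `"dominated"`, `"cheaper"`, `"costlier"`) and `cost_effective` flag.
#' @export
compare <- function(a, b, wtp) {
  stopifnot(inherits(a, "strategy_outcome"), inherits(b, "strategy_outcome"))
  assert_number(wtp, "wtp", lower = 0)
  dc <- a$total_cost - b$total_cost
  de <- a$total_qaly - b$total_qaly
  if (de == 0) {
    dominance <- if (dc < 0) "cheaper" else if (dc > 0) "costlier" else "none"
    icer <- NA_real_
    ce <- dc <= 0
  } else if (de > 0 && dc <= 0) {
    dominance <- "dominant"; icer <- NA_real_; ce <- TRUE
  } else if (de < 0 && dc >= 0) {
    dominance <- "dominated"; icer <- NA_real_; ce <- FALSE
  } else {
    dominance <- "none"
    icer <- dc / de
    ce <- de > 0 && icer <= wtp
  }
  structure(list(delta_cost = dc, delta_qaly = de, icer = icer, wtp = wtp,
                 dominance = dominance, cost_effective = ce),
            class = "ce_comparison")
}

#' @export
print.ce_comparison <- function(x, ...) {
  cat(sprintf("<ce_comparison> dCost $%.2f, dQALY %.4f, ICER %s (WTP $%.2f)%s\n",
              x$delta_cost, x$delta_qaly,
              if (is.na(x$icer)) x$dominance else sprintf("$%.2f/QALY", x$icer),
              x$wtp, if (x$cost_effective) " [cost-effective]" else ""))
  invisible(x)
}

#' Write a cohort trace as CSV
#'
#' @param trace a `cohort_trace`.
#' @param path output file.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
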