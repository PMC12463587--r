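# Synthetic two-arm trial data with known ground truth: per-patient survival
# times drawn from specified parametric curves with administrative and random
# censoring, and an emulated "digitized KM curve + numbers-at-risk table"
# representation of the resulting Kaplan-Meier estimates.

#' Specification of a synthetic two-arm trial
#'
#' Defaults emulate the source trial's scale: 144 vs 142 patients, OS and PFS
#' generated from the shipped base-case extrapolation models, administrative
#' cutoff at 36 months of follow-up and a small exponential dropout rate.
#'
#' @param n_per_arm named vector: patients per arm.
#' @param survival nested list as in [reference_survival()] (per arm: `os`,
#'   `pfs` models).
#' @param cutoff administrative censoring time, months.
#' @param dropout_rate exponential dropout hazard per month (0 = none).
#' @param seed RNG seed used by [gen_ipd()].
#' @return a `trial_spec`.
#' @export
trial_spec <- function(n_per_arm = c(switch = 144, control = 142),
                       survival = reference_survival("overall"),
                       cutoff = 36, dropout_rate = 0.01, seed = 1) {
  stopifnot(all(n_per_arm >= 2), cutoff > 0, dropout_rate >= 0)
  structure(list(n_per_arm = n_per_arm, survival = survival, cutoff = cutoff,
                 dropout_rate = dropout_rate, seed = seed),
            class = "trial_spec")
}

#' Generate per-patient trial data
#'
#' Per patient: the overall-survival time is drawn from the arm's OS model and
#' a progression time independently from its PFS model; the progression-free
#' time is the minimum of the two, so PFS <= OS holds record by record.
#' Censoring is the minimum of the administrative cutoff and an exponential
#' dropout time. Deterministic under the spec's seed.
#'
#' @param spec a [trial_spec()].
#' @return named list `<arm>$<endpoint>` (`os`, `pfs`) of IPD data frames
#'   (`time`, `event`, `arm`).
#' @export
gen_ipd <- function(spec) {
  stopifnot(inherits(spec, "trial_spec"))
  set.seed(spec$seed)
  out <- list()
  for (arm in names(spec$n_per_arm)) {
    n <- spec$n_per_arm[[arm]]
    os_t <- rsurv(spec$survival[[arm]]$os, n)
    prog_t <- rsurv(spec$survival[[arm]]$pfs, n)
    pfs_t <- pmin(os_t, prog_t)
    drop_t <- if (spec$dropout_rate > 0) stats::rexp(n, spec$dropout_rate) else rep(Inf, n)
    cens <- pmin(spec$cutoff, drop_t)
    out[[arm]] <- list(
      os = data.frame(time = pmin(os_t, cens), event = as.integer(os_t <= cens), arm = arm),
      pfs = data.frame(time = pmin(pfs_t, cens), event = as.integer(pfs_t <= cens), arm = arm)
    )
  }
  out
}

#' Emulate plot digitization of a KM curve
#'
#' Computes the exact KM estimate of the IPD, samples it at `n_points` evenly
#' spaced times (plus `t = 0`), optionally adds uniform jitter on the survival
#' axis (clipped back to monotonicity) to mimic pixel-extraction error, and
#' tabulates the exact number at risk at `risk_times`.
#'
#' @param ipd IPD data frame (`time`, `event`).
#' @param n_points number of digitized points (>= 5).
#' @param risk_times times for the at-risk table (default: 6 evenly spaced,
#'   starting at 0).
#' @param jitter half-width of the uniform survival-axis error (e.g. 0.005;
#'   0 = exact digitization).
#' @return list with `curve` ([digitized_curve()]) and `risk`
#'   ([risk_table()]).
#' @export
emulate_digitization <- function(ipd, n_points = 100, risk_times = NULL, jitter = 0) {
  ipd <- validate_ipd(ipd)
  stopifnot(n_points >= 5, jitter >= 0)
  km <- km_estimate(ipd)
  t_max <- max(ipd$time)
  times <- unique(c(0, seq(t_max / n_points, t_max, length.out = n_points)))
  surv <- curve_at(km, times)
  if (jitter > 0) {
    surv <- surv + stats::runif(length(surv), -jitter, jitter)
    surv[1] <- 1
    surv <- cummin(pmin(pmax(surv, 0), 1))
  }
  risk_times <- risk_times %||% seq(0, t_max * 5 / 6, length.out = 6)
  stopifnot(risk_times[1] == 0)
  n_risk <- vapply(risk_times, function(t) sum(ipd$time >= t), integer(1))
  list(curve = digitized_curve(times, surv),
       risk = risk_table(risk_times, n_risk))
}

#' Write a ready-to-run synthetic fixture bundle
#'
#' Generates a complete input set for the pipeline: per-arm, per-endpoint IPD
#' CSVs, digitized-curve and risk-table CSVs, and the analysis configuration
#' as YAML.
#'
#' @param spec a [trial_spec()].
#' @param outdir output directory.
#' @param config configuration to ship alongside (default China/overall).
#' @return (invisibly) vector of written file paths.
#' @export
gen_fixtures <- function(spec, outdir, config = default_config("china", "overall")) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ipd <- gen_ipd(spec)
  paths <- character(0)
  for (arm in names(ipd)) for (ep in names(ipd[[arm]])) {
    p <- file.path(outdir, sprintf("ipd_%s_%s.csv", arm, ep))
    write_ipd(ipd[[arm]][[ep]], p)
    dig <- emulate_digitization(ipd[[arm]][[ep]])
    pc <- file.path(outdir, sprintf("digitized_%s_%s.csv", arm, ep))
    pr <- file.path(outdir, sprintf("risk_%s_%s.csv", arm, ep))
    utils::write.csv(as.data.frame(dig$curve), pc, row.names = FALSE)
    utils::write.csv(as.data.frame(dig$risk), pr, row.names = FALSE)
    paths <- c(paths, p, pc, pr)
  }
  cfg_path <- file.path(outdir, "config.yaml")
  write_config(config, cfg_path)
  invisible(c(paths, cfg_path))
}
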