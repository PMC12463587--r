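# Strategy evaluation and result orchestration.

#' Build the cohort traces for both strategies
#'
#' @param config a `cea_config`.
#' @return list with `switch` and `control` [build_trace()] results.
#' @export
build_traces <- function(config) {
  list(
    switch = build_trace(config$survival$switch$os, config$survival$switch$pfs,
                         config$horizon_years, config$cycle_days),
    control = build_trace(config$survival$control$os, config$survival$control$pfs,
                          config$horizon_years, config$cycle_days)
  )
}

#' Evaluate both strategies under a configuration
#'
#' Runs the partitioned survival model for the switch-maintenance and control
#' strategies and compares them.
#'
#' @param config a `cea_config`.
#' @param traces optional precomputed [build_traces()] result; the traces
#'   depend only on the survival models, so sensitivity analyses that vary
#'   cost/utility parameters can reuse them.
#' @param validate run [validate_config()] first (disable inside tight
#'   sampling loops).
#' @return list with `switch` and `control` `strategy_outcome`s and a
#'   `comparison` (`ce_comparison`).
#' @export
evaluate_strategies <- function(config, traces = NULL, validate = TRUE) {
  if (validate) validate_config(config)
  traces <- traces %||% build_traces(config)
  n <- nrow(traces$switch)
  out <- lapply(c(switch = "switch", control = "control"), function(arm) {
    accumulate(traces[[arm]], strategy_costing(config, arm, n),
               config$utilities, config$discount_rate)
  })
  out$comparison <- compare(out$switch, out$control, config$wtp)
  out
}

#' Base-case report
#'
#' Deterministic base-case evaluation producing the headline table: total and
#' incremental discounted costs and QALYs per strategy and the ICER, plus the
#' per-component cost breakdown.
#'
#' @param config a `cea_config`.
#' @param outdir optional directory; when given, `base_case.csv` and
#'   `cost_breakdown.csv` are written there.
#' @return a `base_case_report` list with elements `summary` (data frame),
#'   `breakdown` (data frame), `outcomes` and `comparison`.
#' @export
run_base <- function(config, outdir = NULL) {
  res <- evaluate_strategies(config)
  cmp <- res$comparison
  summary <- data.frame(
    perspective = config$perspective,
    population = config$population,
    arm = c("switch_maintenance", "control"),
    total_cost = c(res$switch$total_cost, res$control$total_cost),
    total_qaly = c(res$switch$total_qaly, res$control$total_qaly),
    life_years = c(res$switch$life_years, res$control$life_years),
    incremental_cost = c(cmp$delta_cost, NA),
    incremental_qaly = c(cmp$delta_qaly, NA),
    icer = c(cmp$icer, NA),
    dominance = c(cmp$dominance, NA),
    cost_effective = c(cmp$cost_effective, NA),
    stringsAsFactors = FALSE
  )
  breakdown <- do.call(rbind, lapply(c("switch", "control"), function(arm) {
    b <- res[[arm]]$breakdown
    data.frame(arm = arm, component = names(b), cost = unname(b),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary, file.path(outdir, "base_case.csv"), row.names = FALSE)
    utils::write.csv(breakdown, file.path(outdir, "cost_breakdown.csv"), row.names = FALSE)
  }
  structure(list(summary = summary, breakdown = breakdown,
                 outcomes = res[c("switch", "control")], comparison = cmp),
            class = "base_case_report")
}

#' @export
print.base_case_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Base case: %s perspective, %s population\n", s$perspective[1], s$population[1]))
  cat(sprintf("  %-18s cost $%12.2f   %.4f QALYs\n", s$arm, s$total_cost, s$total_qaly), sep = "")
  cmp <- x$comparison
  cat(sprintf("  incremental: $%.2f / %.4f QALYs -> %s\n", cmp$delta_cost, cmp$delta_qaly,
              if (is.na(cmp$icer)) cmp$dominance else sprintf("ICER $%.2f/QALY", cmp$icer)))
  cat(sprintf("  %scost-effective at WTP $%.2f/QALY\n",
              if (cmp$cost_effective) "" else "NOT ", cmp$wtp))
  invisible(x)
}

#' Run the full analysis bundle
#'
#' For each perspective x population cell: base case, tornado (one-way)
#' analysis, PSA draws, CEAC, and the price-scenario table, all written as CSV
#' under `outdir` together with an md5 manifest. Deterministic given `seed`.
#'
#' @param outdir output directory.
#' @param n_psa PSA iterations per cell.
#' @param seed base RNG seed; each cell derives its own sub-seed from it.
#' @param cells optional list of `cea_config`s; defaults to all four shipped
#'   cells.
#' @return (invisibly) the manifest data frame (file, md5).
#' @export
run_all <- function(outdir, n_psa = 5000, seed = 1, cells = NULL) {
  if (is.null(cells)) {
    cells <- list()
    for (persp in c("china", "us")) for (pop in c("overall", "cps_ge5")) {
      cells[[paste(persp, pop, sep = "_")]] <- default_config(persp, pop)
    }
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wtp_grid_of <- function(config) seq(0, 4 * config$wtp, length.out = 81)
  for (i in seq_along(cells)) {
    config <- cells[[i]]
    cell <- names(cells)[i]
    cell_seed <- (seed + 1000L * i) %% .Machine$integer.max
    tag <- function(stem) file.path(outdir, paste0(stem, "_", cell, ".csv"))

    base <- run_base(config, outdir = NULL)
    utils::write.csv(base$summary, tag("base_case"), row.names = FALSE)

    torn <- one_way(config)
    utils::write.csv(torn, tag("tornado"), row.names = FALSE)

    psa <- sample_psa(config, n = n_psa, seed = cell_seed)
    utils::write.csv(cbind(psa$draws, seed = psa$seed), tag("psa_draws"), row.names = FALSE)
    utils::write.csv(ceac(psa$draws, wtp_grid_of(config)), tag("ceac"), row.names = FALSE)

    scen <- scenario_table(config, n_psa = n_psa, seed = cell_seed)
    utils::write.csv(scen, tag("scenario"), row.names = FALSE)

    files <- c(files, tag("base_case"), tag("tornado"), tag("psa_draws"),
               tag("ceac"), tag("scenario"))
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
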