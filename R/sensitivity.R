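# Deterministic and probabilistic sensitivity analysis: tornado (one-way),
# Monte-Carlo PSA with gamma/beta sampling, cost-effectiveness acceptability
# curves, price scenarios and the threshold-price search.
#
# Distribution moment matching treats each parameter's published range as a
# 95% interval: mean = baseline, sd = (high - low) / (2 * 1.96); gamma via
# shape = mean^2/sd^2, rate = mean/sd^2; beta by matching mean and sd.

#' Uncertain-parameter specifications for a configuration
#'
#' The reference table for the configuration's perspective, with baselines
#' re-read from the configuration itself: if a value has been rescaled (e.g. a
#' ramucirumab price multiplier), its range is rescaled proportionally so the
#' relative uncertainty is preserved.
#'
#' @param config a `cea_config`.
#' @return data frame with `name`, `path`, `base`, `low`, `high`, `dist`.
#' @export
param_specs <- function(config) {
  specs <- reference_parameters(config$perspective)
  for (i in seq_len(nrow(specs))) {
    current <- config_get(config, specs$path[i])
    if (!isTRUE(all.equal(current, specs$base[i])) && specs$base[i] != 0) {
      scale <- current / specs$base[i]
      specs$low[i] <- specs$low[i] * scale
      specs$high[i] <- specs$high[i] * scale
      specs$base[i] <- current
    } else {
      specs$base[i] <- current
    }
  }
  specs
}

icer_of <- function(config, traces) {
  evaluate_strategies(config, traces = traces, validate = FALSE)$comparison$icer
}

#' One-way (tornado) sensitivity analysis
#'
#' Each parameter is set to its low and high bound in turn, all others held at
#' baseline, and the ICER recomputed. The result is sorted by spread
#' (|ICER_high - ICER_low|), descending — the tornado ordering.
#'
#' @param config a `cea_config`.
#' @param specs parameter specifications (default [param_specs()]).
#' @return data frame: `name`, `path`, `low`, `high`, `icer_low`, `icer_high`,
#'   `spread`, plus the baseline ICER as attribute `"base_icer"`.
#' @export
one_way <- function(config, specs = param_specs(config)) {
  validate_config(config)
  traces <- build_traces(config)
  base_icer <- icer_of(config, traces)
  res <- lapply(seq_len(nrow(specs)), function(i) {
    lo <- icer_of(config_set(config, specs$path[i], specs$low[i]), traces)
    hi <- icer_of(config_set(config, specs$path[i], specs$high[i]), traces)
    data.frame(name = specs$name[i], path = specs$path[i],
               low = specs$low[i], high = specs$high[i],
               icer_low = lo, icer_high = hi, spread = abs(hi - lo),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  out
}

# Moment-matched sampling parameters; errors at configuration time when a
# beta spec's sd is infeasible for its mean.
psa_distribution <- function(spec) {
  m <- spec$base
  s <- (spec$high - spec$low) / (2 * 1.96)
  if (spec$dist == "fixed" || s == 0) return(list(kind = "fixed", value = m))
  if (spec$dist == "gamma") {
    if (m <= 0) stop_config("gamma parameter '", spec$name, "' needs a positive mean")
    return(list(kind = "gamma", shape = m^2 / s^2, rate = m / s^2))
  }
  if (spec$dist == "beta") {
    if (m <= 0 || m >= 1) stop_config("beta parameter '", spec$name, "' needs a mean in (0, 1)")
    if (s^2 >= m * (1 - m)) {
      stop_config("beta parameter '", spec$name, "': sd ", signif(s, 4),
                  " infeasible for mean ", signif(m, 4))
    }
    nu <- m * (1 - m) / s^2 - 1
    return(list(kind = "beta", shape1 = m * nu, shape2 = (1 - m) * nu))
  }
  stop_config("unknown distribution '", spec$dist, "'")
}

# n x p matrix of sampled parameter values (columns follow specs rows)
psa_draw_matrix <- function(specs, n) {
  draws <- matrix(NA_real_, nrow = n, ncol = nrow(specs),
                  dimnames = list(NULL, specs$path))
  for (i in seq_len(nrow(specs))) {
    d <- psa_distribution(specs[i, ])
    draws[, i] <- switch(d$kind,
      fixed = rep(d$value, n),
      gamma = stats::rgamma(n, shape = d$shape, rate = d$rate),
      beta  = stats::rbeta(n, shape1 = d$shape1, shape2 = d$shape2))
  }
  draws
}

# Evaluate (delta_cost, delta_qaly) for every row of a draw matrix.
psa_evaluate_draws <- function(config, specs, draws, traces) {
  n <- nrow(draws)
  dc <- de <- numeric(n)
  for (r in seq_len(n)) {
    cfg <- config
    for (i in seq_len(ncol(draws))) {
      cfg <- config_set(cfg, specs$path[i], unname(draws[r, i]))
    }
    res <- evaluate_strategies(cfg, traces = traces, validate = FALSE)
    dc[r] <- res$comparison$delta_cost
    de[r] <- res$comparison$delta_qaly
  }
  data.frame(delta_cost = dc, delta_qaly = de)
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo resampling of every non-fixed parameter from its
#' moment-matched gamma/beta distribution, with the model evaluated for both
#' strategies per draw. The survival models carry no published uncertainty
#' ranges and are held fixed, so the cohort traces are computed once and
#' reused.
#'
#' @param config a `cea_config`.
#' @param specs parameter specifications (default [param_specs()]).
#' @param n number of iterations (the base analysis uses 5000).
#' @param seed RNG seed; identical seeds give identical draws.
#' @return a `psa_result`: `draws` (data frame of `delta_cost`,
#'   `delta_qaly`), `param_draws` (the sampled parameter matrix), `seed`,
#'   `n`, `wtp` and `acceptance` (probability cost-effective at the
#'   configuration's WTP).
#' @export
sample_psa <- function(config, specs = param_specs(config), n = 5000, seed = 1) {
  validate_config(config)
  stopifnot(n >= 1)
  set.seed(seed)
  draws <- psa_draw_matrix(specs, n)
  traces <- build_traces(config)
  d <- psa_evaluate_draws(config, specs, draws, traces)
  structure(list(draws = d, param_draws = draws, seed = seed, n = n,
                 wtp = config$wtp,
                 acceptance = mean(config$wtp * d$delta_qaly - d$delta_cost > 0)),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws (seed %d): mean dCost $%.2f, mean dQALY %.4f, P(CE at $%.0f) = %.3f\n",
              x$n, x$seed, mean(x$draws$delta_cost), mean(x$draws$delta_qaly),
              x$wtp, x$acceptance))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with positive
#' incremental net monetary benefit `wtp * dQALY - dCost`.
#'
#' @param draws PSA draws (data frame with `delta_cost`, `delta_qaly`), or a
#'   `psa_result`.
#' @param wtp_grid vector of WTP thresholds (USD/QALY).
#' @return data frame with columns `wtp`, `probability`.
#' @export
ceac <- function(draws, wtp_grid) {
  if (inherits(draws, "psa_result")) draws <- draws$draws
  stopifnot(nrow(draws) > 0)
  data.frame(
    wtp = wtp_grid,
    probability = vapply(wtp_grid, function(l) {
      mean(l * draws$delta_qaly - draws$delta_cost > 0)
    }, numeric(1))
  )
}

#' Price-scenario evaluation
#'
#' Deterministic base case with the ramucirumab unit price scaled by
#' `multiplier`.
#'
#' @param config a `cea_config`.
#' @param multiplier positive price multiplier (the published scenarios use
#'   1, 0.75, 0.5 and 0.25).
#' @return a `ce_comparison` with attributes `multiplier`, `price`,
#'   `switch_cost`, `switch_qaly`.
#' @export
scenario_price <- function(config, multiplier) {
  assert_number(multiplier, "multiplier", lower = 1e-12)
  cfg <- config_set(config, "prices.ramucirumab",
                    config$prices$ramucirumab * multiplier)
  res <- evaluate_strategies(cfg)
  cmp <- res$comparison
  attr(cmp, "multiplier") <- multiplier
  attr(cmp, "price") <- cfg$prices$ramucirumab
  attr(cmp, "switch_cost") <- res$switch$total_cost
  attr(cmp, "switch_qaly") <- res$switch$total_qaly
  cmp
}

#' Price-scenario table
#'
#' Deterministic ICERs at a set of ramucirumab price multipliers, optionally
#' with the PSA acceptance probability at each price (common random numbers
#' across prices: one parameter sample is drawn and the ramucirumab price
#' column rescaled per scenario).
#'
#' @param config a `cea_config`.
#' @param multipliers price multipliers.
#' @param n_psa PSA iterations for the acceptance column (0 to skip).
#' @param seed RNG seed for the PSA sample.
#' @return data frame mirroring the published scenario table: multiplier,
#'   price per mg, switch-arm total cost and QALYs, ICER and (optionally)
#'   acceptance probability.
#' @export
scenario_table <- function(config, multipliers = c(1, 0.75, 0.5, 0.25),
                           n_psa = 0, seed = 1) {
  rows <- lapply(multipliers, function(m) {
    cmp <- scenario_price(config, m)
    data.frame(multiplier = m, price_per_mg = attr(cmp, "price"),
               total_cost = attr(cmp, "switch_cost"),
               total_qaly = attr(cmp, "switch_qaly"),
               icer = cmp$icer, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (n_psa > 0) {
    specs <- param_specs(config)
    set.seed(seed)
    draws <- psa_draw_matrix(specs, n_psa)
    traces <- build_traces(config)
    ram_col <- which(specs$path == "prices.ramucirumab")
    out$acceptance <- vapply(multipliers, function(m) {
      dm <- draws
      dm[, ram_col] <- dm[, ram_col] * m
      d <- psa_evaluate_draws(config, specs, dm, traces)
      mean(config$wtp * d$delta_qaly - d$delta_cost > 0)
    }, numeric(1))
  }
  out
}

#' Threshold-price search
#'
#' Bisection on the ramucirumab price multiplier for the price at which the
#' probability of cost-effectiveness at `wtp` reaches `target`. Common random
#' numbers: one PSA parameter sample is drawn (fixed seed) and reused at every
#' candidate price, with the ramucirumab price column rescaled, so the
#' acceptance probability is monotone non-increasing in the multiplier and the
#' bisection is well behaved.
#'
#' @param config a `cea_config`.
#' @param target target acceptance probability (0.5 for the published
#'   threshold).
#' @param wtp willingness-to-pay threshold (defaults to the configuration's).
#' @param n PSA iterations per evaluation.
#' @param seed RNG seed.
#' @param tol stop once the acceptance probability is within `tol` of
#'   `target` (1 percentage point by default).
#' @return list with `multiplier`, `price` (USD/mg), `probability`, `wtp`,
#'   `n`, `seed`; or, when even a near-zero price cannot reach `target`, the
#'   same shape with `no_solution = TRUE`.
#' @export
threshold_price <- function(config, target = 0.5, wtp = config$wtp,
                            n = 5000, seed = 1, tol = 0.01) {
  validate_config(config)
  assert_number(target, "target", 0, 1)
  specs <- param_specs(config)
  set.seed(seed)
  draws <- psa_draw_matrix(specs, n)
  traces <- build_traces(config)
  ram_col <- which(specs$path == "prices.ramucirumab")
  base_price <- config$prices$ramucirumab
  cfg_wtp <- config_set(config, "wtp", wtp)

  prob_at <- function(m) {
    dm <- draws
    dm[, ram_col] <- dm[, ram_col] * m
    cfg <- config_set(cfg_wtp, "prices.ramucirumab", base_price * m)
    d <- psa_evaluate_draws(cfg, specs, dm, traces)
    mean(wtp * d$delta_qaly - d$delta_cost > 0)
  }

  result <- function(m, p, no_solution = FALSE) {
    list(multiplier = m, price = base_price * m, probability = p, wtp = wtp,
         n = n, seed = seed, no_solution = no_solution)
  }
  p_hi <- prob_at(1)
  if (p_hi >= target) return(result(1, p_hi))
  lo <- 1e-6
  p_lo <- prob_at(lo)
  if (p_lo < target) return(result(lo, p_lo, no_solution = TRUE))
  hi <- 1
  p_mid <- p_lo; mid <- lo
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    p_mid <- prob_at(mid)
    if (abs(p_mid - target) <= tol || (hi - lo) < 1e-4) break
    if (p_mid > target) lo <- mid else hi <- mid
  }
  result(mid, p_mid)
}
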