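# Shared fixtures: tiny configs, traces and costing objects built in code.

china_cfg <- function() default_config("china", "overall")

# a costing object with every cost zeroed, for QALY-only checks
zero_costing <- function(n_cycles, arm = "switch") {
  structure(list(
    arm = arm, n_cycles = n_cycles,
    pfs_cost = matrix(0, n_cycles, 3,
                      dimnames = list(NULL, c("drug", "administration", "tests"))),
    pd_subsequent = 0, pd_bsc = 0, ae_cost = 0, ae_qaly_loss = 0, terminal = 0
  ), class = "strategy_costing")
}

# hand-built cohort trace (for oracle arithmetic independent of build_trace)
manual_trace <- function(pfs, pd, cycle_days = 28) {
  n <- length(pfs)
  cycle_months <- cycle_days / (365.25 / 12)
  dead <- 1 - pfs - pd
  structure(data.frame(
    cycle = seq_len(n),
    t_start = (seq_len(n) - 1) * cycle_months,
    t_end = seq_len(n) * cycle_months,
    pfs = pfs, pd = pd, dead = dead,
    new_deaths = diff(c(0, dead))
  ), class = c("cohort_trace", "data.frame"), clamp_events = 0L,
  cycle_days = cycle_days)
}

# synthetic fit_result for select_model tie-break tests
fake_fit <- function(family, aic, bic, k = 2, converged = TRUE) {
  structure(list(model = parametric_survival("exponential", rate = 1),
                 family = family, loglik = -aic / 2, aic = aic, bic = bic,
                 n = 100, k = k, converged = converged),
            class = "fit_result")
}
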