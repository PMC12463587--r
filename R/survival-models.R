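# Parametric survival distributions, MLE fitting and AIC/BIC model selection.
#
# Five families are supported, under the parameterizations used by the
# flexsurv package (the dominant convention in survival extrapolation):
#   exponential  S(t) = exp(-rate * t)
#   weibull      S(t) = exp(-(t/scale)^shape)
#   gompertz     S(t) = exp(-rate/shape * (exp(shape*t) - 1)), shape may be < 0
#   loglogistic  S(t) = 1 / (1 + (t/scale)^shape)
#   lognormal    S(t) = 1 - Phi((log t - meanlog)/sdlog)
# Time is measured in months throughout.

SURV_FAMILIES <- list(
  exponential = c("rate"),
  weibull     = c("shape", "scale"),
  gompertz    = c("shape", "rate"),
  loglogistic = c("shape", "scale"),
  lognormal   = c("meanlog", "sdlog")
)

# parameters that must be strictly positive (gompertz shape and lognormal
# meanlog are unrestricted reals)
.positive_params <- list(
  exponential = "rate", weibull = c("shape", "scale"), gompertz = "rate",
  loglogistic = c("shape", "scale"), lognormal = "sdlog"
)

#' Construct a parametric survival model
#'
#' @param family one of `"exponential"`, `"weibull"`, `"gompertz"`,
#'   `"loglogistic"`, `"lognormal"`.
#' @param ... named parameters for the family (e.g. `shape`, `scale` for the
#'   log-logistic; `meanlog`, `sdlog` for the log-normal). Time unit is months.
#' @return an object of class `parametric_survival`.
#' @examples
#' os <- parametric_survival("loglogistic", shape = 2.309, scale = 13.051)
#' surv_prob(os, 13.051)  # 0.5: the scale is the median under this convention
#' @export
parametric_survival <- function(family, ...) {
  family <- match.arg(family, names(SURV_FAMILIES))
  params <- list(...)
  wanted <- SURV_FAMILIES[[family]]
  if (!setequal(names(params), wanted)) {
    stop_config(sprintf("family '%s' requires parameters {%s}", family,
                        paste(wanted, collapse = ", ")))
  }
  params <- params[wanted]
  for (p in wanted) assert_number(params[[p]], p)
  for (p in .positive_params[[family]]) {
    if (params[[p]] <= 0) stop_config(sprintf("'%s' must be > 0 for the %s family", p, family))
  }
  structure(list(family = family, params = params, time_unit = "months"),
            class = "parametric_survival")
}

#' @export
print.parametric_survival <- function(x, ...) {
  cat(sprintf("<parametric_survival> %s(%s), time in %s\n", x$family,
              paste(sprintf("%s = %g", names(x$params), unlist(x$params)),
                    collapse = ", "), x$time_unit))
  invisible(x)
}

#' Survival function of a parametric model
#'
#' @param model a [parametric_survival()] object.
#' @param t vector of non-negative times (months).
#' @return `S(t)`, a probability vector in `[0, 1]`.
#' @export
surv_prob <- function(model, t) {
  stopifnot(inherits(model, "parametric_survival"))
  if (any(!is.finite(t)) || any(t < 0)) stop_config("times must be finite and >= 0")
  p <- model$params
  switch(model$family,
    exponential = stats::pexp(t, rate = p$rate, lower.tail = FALSE),
    weibull     = stats::pweibull(t, shape = p$shape, scale = p$scale, lower.tail = FALSE),
    gompertz    = flexsurv::pgompertz(t, shape = p$shape, rate = p$rate, lower.tail = FALSE),
    loglogistic = flexsurv::pllogis(t, shape = p$shape, scale = p$scale, lower.tail = FALSE),
    lognormal   = stats::plnorm(t, meanlog = p$meanlog, sdlog = p$sdlog, lower.tail = FALSE)
  )
}

#' Random survival times from a parametric model
#'
#' @inheritParams surv_prob
#' @param n number of variates.
#' @return vector of `n` event times (months). Driven by the R RNG, so results
#'   are reproducible under `set.seed()`.
#' @export
rsurv <- function(model, n) {
  stopifnot(inherits(model, "parametric_survival"))
  p <- model$params
  switch(model$family,
    exponential = stats::rexp(n, rate = p$rate),
    weibull     = stats::rweibull(n, shape = p$shape, scale = p$scale),
    gompertz    = flexsurv::rgompertz(n, shape = p$shape, rate = p$rate),
    loglogistic = flexsurv::rllogis(n, shape = p$shape, scale = p$scale),
    lognormal   = stats::rlnorm(n, meanlog = p$meanlog, sdlog = p$sdlog)
  )
}

#' Fit a parametric survival family to individual patient data
#'
#' Maximum-likelihood fit of one family to right-censored IPD, via
#' [flexsurv::flexsurvreg()]. The log-likelihood maximized is
#' `sum over events of log f(t_i) + sum over censored of log S(t_i)`.
#'
#' @param ipd data frame with columns `time` (> 0) and `event` (1 = event,
#'   0 = censored).
#' @param family survival family name (see [parametric_survival()]).
#' @return a `fit_result` with elements `model`, `loglik`, `aic`, `bic`,
#'   `n`, `k` (free parameters) and `converged`. A failed optimization is
#'   returned with `converged = FALSE` and infinite AIC/BIC rather than
#'   raising an error.
#' @export
fit_mle <- function(ipd, family) {
  family <- match.arg(family, names(SURV_FAMILIES))
  ipd <- validate_ipd(ipd)
  if (sum(ipd$event) < 2) stop_config("need at least 2 events to fit a survival model")
  if (family %in% c("loglogistic", "lognormal") && any(ipd$time <= 0)) {
    stop_config("strictly positive times required for the ", family, " family")
  }
  dist <- switch(family, exponential = "exp", weibull = "weibull",
                 gompertz = "gompertz", loglogistic = "llogis", lognormal = "lnorm")
  k <- length(SURV_FAMILIES[[family]])
  n <- nrow(ipd)
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = ipd, dist = dist),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(structure(list(model = NULL, family = family, loglik = NA_real_,
                          aic = Inf, bic = Inf, n = n, k = k, converged = FALSE),
                     class = "fit_result"))
  }
  est <- stats::setNames(fit$res[, "est"], rownames(fit$res))
  params <- as.list(est[SURV_FAMILIES[[family]]])
  model <- do.call(parametric_survival, c(list(family = family), params))
  ll <- fit$loglik
  structure(list(model = model, family = family, loglik = ll,
                 aic = 2 * k - 2 * ll, bic = k * log(n) - 2 * ll,
                 n = n, k = k,
                 converged = isTRUE(fit$opt$convergence == 0)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: loglik = %.3f, AIC = %.3f, BIC = %.3f (n = %d%s)\n",
              x$family, x$loglik, x$aic, x$bic, x$n,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Select the best-fitting survival model by AIC
#'
#' Minimal AIC wins; ties are broken by minimal BIC, then by fewer free
#' parameters. Non-converged fits are excluded. The full AIC/BIC table is
#' attached as attribute `"report"`.
#'
#' @param fits list of `fit_result` objects over the same IPD.
#' @return the selected `fit_result`.
#' @export
select_model <- function(fits) {
  if (length(fits) == 0) stop_config("no candidate fits supplied")
  stopifnot(all(vapply(fits, inherits, logical(1), "fit_result")))
  report <- fit_report(fits)
  ok <- fits[vapply(fits, function(f) isTRUE(f$converged), logical(1))]
  if (length(ok) == 0) stop_config("no candidate fit converged")
  o <- order(vapply(ok, `[[`, numeric(1), "aic"),
             vapply(ok, `[[`, numeric(1), "bic"),
             vapply(ok, `[[`, numeric(1), "k"))
  best <- ok[[o[1]]]
  attr(best, "report") <- report
  best
}

#' AIC/BIC comparison table for a list of fits
#'
#' @param fits list of `fit_result` objects.
#' @return data frame with one row per family: parameters, log-likelihood,
#'   AIC, BIC, convergence flag.
#' @export
fit_report <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(
      family = f$family,
      params = if (is.null(f$model)) NA_character_ else
        paste(sprintf("%s=%.6g", names(f$model$params), unlist(f$model$params)),
              collapse = "; "),
      loglik = f$loglik, aic = f$aic, bic = f$bic, n = f$n,
      converged = f$converged,
      stringsAsFactors = FALSE
    )
  }))
}

validate_ipd <- function(ipd) {
  if (!is.data.frame(ipd) || !all(c("time", "event") %in% names(ipd))) {
    stop_config("IPD must be a data frame with columns 'time' and 'event'")
  }
  if (nrow(ipd) == 0) stop_config("IPD is empty")
  if (any(ipd$time < 0) || any(!is.finite(ipd$time))) stop_config("IPD times must be finite and >= 0")
  if (!all(ipd$event %in% c(0, 1))) stop_config("IPD event flags must be 0 or 1")
  ipd
}

#' Read / write individual patient data CSV
#'
#' The on-disk dialect has columns `time`, `event` (1 = event, 0 = censored)
#' and optionally `arm`.
#'
#' @param path CSV file path.
#' @return `read_ipd`: a validated IPD data frame.
#' @export
read_ipd <- function(path) {
  validate_ipd(utils::read.csv(path))
}

#' @rdname read_ipd
#' @param ipd IPD data frame.
#' @export
write_ipd <- function(ipd, path) {
  utils::write.csv(validate_ipd(ipd), path, row.names = FALSE)
  invisible(path)
}
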