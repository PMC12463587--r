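# Pseudo individual-patient data from digitized Kaplan-Meier curves.
#
# Implements the Guyot iterative reconstruction: within each numbers-at-risk
# interval, solve for event and censoring counts consistent with the digitized
# survival drops and the next at-risk count, spreading censoring uniformly
# over the interval.

#' Digitized Kaplan-Meier curve
#'
#' An ordered set of (time, survival) coordinates as produced by plot
#' digitization. The curve must start at (0, 1). Tiny monotonicity violations
#' (digitization jitter, rises <= 0.02) are repaired by clamping to the
#' running minimum, with a warning; larger rises are rejected.
#'
#' @param time strictly increasing times (months), starting at 0.
#' @param surv survival probabilities in `[0, 1]`, starting at 1.
#' @return a `digitized_curve` data frame with columns `time`, `surv`.
#' @export
digitized_curve <- function(time, surv) {
  if (length(time) != length(surv) || length(time) < 1) {
    stop_config("time and surv must be non-empty vectors of equal length")
  }
  if (any(diff(time) <= 0)) stop_config("digitized times must be strictly increasing")
  if (time[1] != 0 || abs(surv[1] - 1) > 1e-9) {
    stop_config("digitized curve must start at (0, 1)")
  }
  if (any(surv < -1e-9 | surv > 1 + 1e-9)) stop_config("survival probabilities must lie in [0, 1]")
  surv <- pmin(pmax(surv, 0), 1)
  rises <- diff(surv)
  if (any(rises > 0.02)) {
    bad <- which(rises > 0.02)[1]
    stop_config(sprintf(
      "survival rises by %.3f between t = %g and t = %g: not a digitization artefact",
      rises[bad], time[bad], time[bad + 1]))
  }
  if (any(rises > 0)) {
    warning("repairing small digitization jitter: survival clamped to running minimum",
            call. = FALSE)
    surv <- cummin(surv)
  }
  structure(data.frame(time = time, surv = surv),
            class = c("digitized_curve", "data.frame"))
}

#' Numbers-at-risk table
#'
#' @param time at-risk reporting times; the first must be 0.
#' @param n_risk non-increasing, non-negative patient counts.
#' @return a `risk_table` data frame.
#' @export
risk_table <- function(time, n_risk) {
  if (length(time) != length(n_risk) || length(time) < 1) {
    stop_config("time and n_risk must be non-empty vectors of equal length")
  }
  if (time[1] != 0) stop_config("risk table must start at time 0")
  if (any(diff(time) <= 0)) stop_config("risk-table times must be strictly increasing")
  if (any(n_risk < 0) || any(n_risk != round(n_risk))) {
    stop_config("numbers at risk must be non-negative integers")
  }
  if (any(diff(n_risk) > 0)) {
    bad <- which(diff(n_risk) > 0)[1]
    stop_config(sprintf("number at risk increases between t = %g and t = %g",
                        time[bad], time[bad + 1]))
  }
  structure(data.frame(time = time, n_risk = as.integer(n_risk)),
            class = c("risk_table", "data.frame"))
}

# One full forward pass of the Guyot recursion, given per-interval censoring
# counts. Returns event counts per digitized point, the censoring times
# actually placed, the implied number at risk before each point, and the
# running KM estimate. Censoring times within an interval are binned between
# that interval's digitized points (the first point absorbing any times before
# it), so every placed censoring is deducted from the at-risk count.
guyot_pass <- function(tS, S, t_risk, n_risk, lower, upper, n_censor) {
  n_int <- length(n_risk)
  n_t <- length(tS)
  d <- integer(n_t)
  cen_times <- vector("list", n_int)
  n_hat <- numeric(n_t + 1)
  n_hat[1] <- n_risk[1]
  KM_hat <- rep(1, n_t)
  last <- 0L  # index of last point where an event occurred (0 = baseline, KM = 1)
  for (j in seq_len(n_int)) {
    t_next <- if (j < n_int) t_risk[j + 1] else max(tS[n_t], t_risk[n_int])
    cj <- n_censor[j]
    ct <- if (cj > 0) t_risk[j] + seq_len(cj) * (t_next - t_risk[j]) / (cj + 1) else numeric(0)
    if (lower[j] > upper[j]) {
      cen_times[[j]] <- numeric(0)  # no digitized points: nothing to anchor to
      next
    }
    ks <- lower[j]:upper[j]
    breaks <- c(-Inf, if (length(ks) > 1) tS[ks[-1]], Inf)
    ct_bins <- if (length(ct)) findInterval(ct, breaks) else integer(0)
    kept <- numeric(0)
    for (b in seq_along(ks)) {
      k <- ks[b]
      km_prev <- if (last == 0L) 1 else KM_hat[last]
      dk <- if (n_hat[k] > 0 && km_prev > 0) round(n_hat[k] * (1 - S[k] / km_prev)) else 0
      dk <- max(0L, min(dk, floor(n_hat[k])))
      d[k] <- dk
      KM_hat[k] <- if (n_hat[k] > 0) km_prev * (1 - dk / n_hat[k]) else km_prev
      ct_k <- ct[ct_bins == b]
      # never censor more patients than remain at risk
      keep <- min(length(ct_k), max(0, floor(n_hat[k] - dk)))
      ct_k <- ct_k[seq_len(keep)]
      kept <- c(kept, ct_k)
      n_hat[k + 1] <- n_hat[k] - dk - length(ct_k)
      if (dk > 0) last <- k
    }
    cen_times[[j]] <- kept
  }
  list(d = d, cen_times = cen_times, n_hat = n_hat, KM_hat = KM_hat)
}

#' Reconstruct individual patient data from a digitized KM curve
#'
#' Guyot's iterative algorithm: for each at-risk interval, the number censored
#' is adjusted until the implied number at risk at the next reporting time
#' matches the published count, with censoring assumed uniform within the
#' interval and events placed at the digitized drop times. Patients still at
#' risk after the last digitized point are administratively censored there.
#'
#' @param curve a [digitized_curve()].
#' @param risk a [risk_table()] on the same time axis.
#' @param total_events optional total event count; when supplied, censoring in
#'   the final interval is adjusted so the reconstructed events match it.
#' @param arm optional arm label attached to the output.
#' @return an IPD data frame with columns `time`, `event` (and `arm` if given),
#'   one row per initially at-risk patient.
#' @export
reconstruct_ipd <- function(curve, risk, total_events = NULL, arm = NULL) {
  if (!inherits(curve, "digitized_curve")) curve <- digitized_curve(curve$time, curve$surv)
  if (!inherits(risk, "risk_table")) risk <- risk_table(risk$time, risk$n_risk)
  tS <- curve$time; S <- curve$surv
  t_risk <- risk$time; n_risk <- risk$n_risk
  n_int <- length(n_risk)
  if (max(t_risk) > max(tS) + 1e-9) {
    # the at-risk table extends past the last digitized point: carry the curve
    # forward flat so survivors can be censored at the right time
    tS <- c(tS, max(t_risk))
    S <- c(S, S[length(S)])
  }
  n_t <- length(tS)
  lower <- upper <- integer(n_int)
  for (j in seq_len(n_int)) {
    t_next <- if (j < n_int) t_risk[j + 1] else Inf
    idx <- which(tS >= t_risk[j] - 1e-9 & tS < t_next - 1e-9)
    if (j == n_int) idx <- which(tS >= t_risk[j] - 1e-9)
    lower[j] <- if (length(idx)) min(idx) else 1L
    upper[j] <- if (length(idx)) max(idx) else 0L
  }
  # n_hat index at which the cohort enters interval j+1: the first digitized
  # point at/after the boundary, or the slot after interval j's last point
  bidx <- integer(n_int)
  for (j in seq_len(n_int - 1)) {
    w <- which(tS >= t_risk[j + 1] - 1e-9)
    bidx[j] <- if (length(w)) min(w) else upper[j] + 1L
  }

  n_censor <- integer(n_int)
  for (j in seq_len(n_int)) {
    if (j < n_int) {
      s0 <- if (upper[j] >= lower[j]) S[lower[j]] else 1
      s1 <- S[min(bidx[j], n_t)]
      n_censor[j] <- if (s0 > 0) round(n_risk[j] * s1 / s0 - n_risk[j + 1]) else 0L
      n_censor[j] <- max(0L, n_censor[j])
      seen <- integer(0)
      repeat {
        pass <- guyot_pass(tS, S, t_risk, n_risk, lower, upper, n_censor)
        gap <- pass$n_hat[bidx[j]] - n_risk[j + 1]
        if (gap == 0 || n_censor[j] %in% seen) break
        seen <- c(seen, n_censor[j])
        n_censor[j] <- max(0L, n_censor[j] + round(gap))
        if (length(seen) > 200) break
      }
    } else if (!is.null(total_events)) {
      seen <- integer(0)
      repeat {
        pass <- guyot_pass(tS, S, t_risk, n_risk, lower, upper, n_censor)
        gap <- sum(pass$d) - total_events
        if (gap == 0 || n_censor[j] %in% seen) break
        seen <- c(seen, n_censor[j])
        n_censor[j] <- max(0L, n_censor[j] + round(gap))
        if (length(seen) > 200) break
      }
    }
  }
  pass <- guyot_pass(tS, S, t_risk, n_risk, lower, upper, n_censor)

  times <- rep(tS, pass$d)
  events <- rep(1, length(times))
  cen_t <- unlist(pass$cen_times)
  times <- c(times, cen_t)
  events <- c(events, rep(0, length(cen_t)))
  leftover <- pass$n_hat[length(tS) + 1]
  if (leftover > 0) {
    times <- c(times, rep(max(tS), leftover))
    events <- c(events, rep(0, leftover))
  }
  o <- order(times, -events)
  ipd <- data.frame(time = times[o], event = events[o])
  if (!is.null(arm)) ipd$arm <- arm
  validate_ipd(ipd)
}

#' Kaplan-Meier estimate of an IPD set
#'
#' Standard product-limit estimator (via [survival::survfit()]), returned in
#' the same representation as a digitized curve: the step-function value at
#' `t = 0` and after each observed time.
#'
#' @param ipd IPD data frame with `time` and `event` columns.
#' @return a [digitized_curve()].
#' @export
km_estimate <- function(ipd) {
  ipd <- validate_ipd(ipd)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  digitized_curve(c(0, fit$time), c(1, fit$surv))
}

#' Evaluate a step curve at arbitrary times
#'
#' Right-continuous step interpolation of a digitized / KM curve.
#'
#' @param curve a [digitized_curve()].
#' @param t times at which to read the curve.
#' @return survival values at `t`.
#' @export
curve_at <- function(curve, t) {
  stats::approx(curve$time, curve$surv, xout = t, method = "constant",
                f = 0, rule = 2)$y
}

#' Read digitized-curve / risk-table CSVs
#'
#' Column dialects: `time`, `surv` for curves; `time`, `n_risk` for risk
#' tables.
#'
#' @param path CSV file path.
#' @return the validated object.
#' @export
read_digitized_curve <- function(path) {
  x <- utils::read.csv(path)
  digitized_curve(x$time, x$surv)
}

#' @rdname read_digitized_curve
#' @export
read_risk_table <- function(path) {
  x <- utils::read.csv(path)
  risk_table(x$time, x$n_risk)
}
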