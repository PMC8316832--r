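#' Kaplan-Meier product-limit fit for one arm
#'
#' Estimates the survival function of a single treatment arm from
#' subject-level time-to-event records by the product-limit method, with
#' Greenwood variance at every step. Censored subjects leave the risk set
#' without producing a step.
#'
#' @param time numeric vector of follow-up times in months; strictly positive
#'   and finite. Alternatively a data frame with columns `time_months` (or
#'   `time`) and `event`, in which case `event` is taken from the data frame.
#' @param event integer/logical vector, 1 = event (death or progression)
#'   observed, 0 = censored.
#' @return An object of class `kmCurve`: a list with components
#'   `times` (distinct event times, increasing), `survival` (S(t) at each
#'   event time), `at_risk` (number at risk just before each event time),
#'   `events` (deaths at each time), `variance` (Greenwood variance of S(t)),
#'   `n_total` (arm size) and `max_time` (last observed time, event or
#'   censoring — the follow-up horizon).
#' @seealso [milestoneRate()], [rmst()], [coxHR()]
#' @examples
#' km <- kmFit(c(2, 4, 5, 7), c(1, 0, 1, 1))
#' km$survival  # 0.75, 0.375, 0
#' @export
kmFit <- function(time, event) {
  if (is.data.frame(time)) {
    df <- time
    tcol <- if ("time_months" %in% names(df)) "time_months" else "time"
    time <- df[[tcol]]
    event <- df[["event"]]
  }
  if (length(time) == 0L) stop("no records")
  if (!is.numeric(time) || anyNA(time) || any(!is.finite(time)) || any(time <= 0))
    stop("invalid time: times must be positive and finite")
  event <- as.integer(event)
  if (length(event) != length(time) || anyNA(event) || !all(event %in% c(0L, 1L)))
    stop("event must be a 0/1 vector matching time")

  n <- length(time)
  et <- sort(unique(time[event == 1L]))
  if (length(et) == 0L) {
    out <- list(times = numeric(0), survival = numeric(0),
                at_risk = integer(0), events = integer(0),
                variance = numeric(0), n_total = n, max_time = max(time))
    class(out) <- "kmCurve"
    return(out)
  }
  at_risk <- vapply(et, function(t) sum(time >= t), integer(1))
  d <- vapply(et, function(t) sum(time == t & event == 1L), integer(1))
  surv <- cumprod(1 - d / at_risk)
  # Greenwood: var S(t) = S(t)^2 * sum_{tj<=t} d_j / (n_j (n_j - d_j))
  gterm <- ifelse(at_risk > d, d / (as.numeric(at_risk) * (at_risk - d)), 0)
  variance <- surv^2 * cumsum(gterm)
  out <- list(times = et, survival = surv, at_risk = at_risk, events = d,
              variance = variance, n_total = n, max_time = max(time))
  class(out) <- "kmCurve"
  out
}

#' @export
print.kmCurve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n_total, ",", length(x$times),
      "event times, follow-up", format(x$max_time, digits = 4), "months\n")
  if (length(x$times)) {
    tab <- data.frame(time = x$times, at_risk = x$at_risk, events = x$events,
                      survival = round(x$survival, 4),
                      se = round(sqrt(x$variance), 4))
    print(utils::head(tab, 10), row.names = FALSE)
    if (length(x$times) > 10) cat("... (", length(x$times) - 10, " more rows)\n", sep = "")
  }
  invisible(x)
}

# right-continuous step lookup of S(tau) on a kmCurve; idx 0 => before first event
.kmStepIndex <- function(curve, tau) findInterval(tau, curve$times)

#' Milestone survival rate
#'
#' The Kaplan-Meier survival probability at a prespecified clinically
#' meaningful time point (e.g. 12 months), the cross-sectional complement to
#' the hazard ratio under non-proportional hazards. The estimate is the
#' right-continuous step value of S at `tau`; for subject-level fits the 95%
#' interval comes from the Greenwood standard error, by default on the
#' complementary log-log scale (the standard transformation keeping the
#' interval inside \[0, 1\]).
#'
#' @param curve a [kmFit()] curve or a [cleanCurve()] from digitized
#'   coordinates.
#' @param tau milestone time in months, > 0.
#' @param ... passed to methods.
#' @return An object of class `milestoneEstimate`: list with `tau`, `rate`,
#'   `se`, `ci_low`, `ci_high` (SE and CI are `NA` for curve-derived
#'   estimates, which carry no variance information).
#' @export
milestoneRate <- function(curve, tau, ...) UseMethod("milestoneRate")

#' @rdname milestoneRate
#' @param conf_level confidence level, default 0.95.
#' @param conf_scale `"cloglog"` (default) applies the Greenwood SE on the
#'   log(-log S) scale; `"plain"` uses a symmetric Wald interval clipped to
#'   \[0, 1\].
#' @param extrapolate if `FALSE` (default), `tau` beyond the last observed
#'   time is an error; if `TRUE`, the last survival value is carried forward
#'   with a warning.
#' @export
milestoneRate.kmCurve <- function(curve, tau, conf_level = 0.95,
                                  conf_scale = c("cloglog", "plain"),
                                  extrapolate = FALSE, ...) {
  conf_scale <- match.arg(conf_scale)
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("tau must be a single positive number")
  if (tau > curve$max_time) {
    if (!extrapolate) stop("milestone beyond follow-up")
    warning("milestone beyond follow-up: carrying last survival value forward")
  }
  idx <- .kmStepIndex(curve, tau)
  rate <- if (idx == 0L) 1 else curve$survival[idx]
  v <- if (idx == 0L) 0 else curve$variance[idx]
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (se == 0 || rate <= 0 || rate >= 1) {
    ci <- c(rate, rate)
  } else if (conf_scale == "cloglog") {
    # theta = log(-log S); se_theta = se_S / (S |log S|)
    se_theta <- se / (rate * abs(log(rate)))
    ci <- sort(rate^exp(c(z, -z) * se_theta))
  } else {
    ci <- pmin(1, pmax(0, rate + c(-z, z) * se))
  }
  structure(list(tau = tau, rate = rate, se = se,
                 ci_low = ci[1], ci_high = ci[2]),
            class = "milestoneEstimate")
}

#' @export
print.milestoneEstimate <- function(x, ...) {
  cat(sprintf("Milestone survival at %g months: %.3f", x$tau, x$rate))
  if (!is.na(x$se))
    cat(sprintf(" (SE %.4f, 95%% CI %.3f-%.3f)", x$se, x$ci_low, x$ci_high))
  cat("\n")
  invisible(x)
}

#' Restricted mean survival time
#'
#' The area under the survival curve from 0 to the horizon `tau` — the mean
#' survival time truncated at `tau`, a model-free summary that remains
#' interpretable when hazards are non-proportional. For subject-level
#' Kaplan-Meier fits the standard error uses the standard
#' integrated-Kaplan-Meier variance; curve-derived estimates (digitized
#' coordinates) carry no SE.
#'
#' @param curve a [kmFit()] curve or a [cleanCurve()].
#' @param tau horizon in months, > 0 and within follow-up.
#' @param ... passed to methods.
#' @return An object of class `rmstEstimate`: list with `tau`, `value`
#'   (months, in (0, tau\]) and `se` (`NA` when unavailable).
#' @export
rmst <- function(curve, tau, ...) UseMethod("rmst")

#' @rdname rmst
#' @param extrapolate if `FALSE` (default), `tau` beyond follow-up errors;
#'   if `TRUE`, the last survival value is carried forward with a warning.
#' @export
rmst.kmCurve <- function(curve, tau, extrapolate = FALSE, ...) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("tau must be a single positive number")
  if (tau > curve$max_time) {
    if (!extrapolate) stop("rmst horizon beyond follow-up")
    warning("rmst horizon beyond follow-up: carrying last survival value forward")
  }
  keep <- curve$times < tau
  et <- curve$times[keep]
  sv <- curve$survival[keep]
  knots <- c(0, et, tau)
  segS <- c(1, sv)                      # S on [knot_i, knot_{i+1})
  value <- sum(segS * diff(knots))
  # var = sum_j A_j^2 d_j / (n_j (n_j - d_j)), A_j = integral_{t_j}^{tau} S du
  if (length(et)) {
    widths <- diff(knots)               # length(et) + 1 segments
    # area from each event time t_j to tau: drop segments before t_j
    cumArea <- rev(cumsum(rev(segS * widths)))  # area from knot_i to tau
    A <- cumArea[-1]                    # from each event time onward
    nj <- curve$at_risk[keep]
    dj <- curve$events[keep]
    vterm <- ifelse(nj > dj, dj / (as.numeric(nj) * (nj - dj)), 0)
    se <- sqrt(sum(A^2 * vterm))
  } else {
    se <- 0
  }
  structure(list(tau = tau, value = value, se = se), class = "rmstEstimate")
}

#' @export
print.rmstEstimate <- function(x, ...) {
  cat(sprintf("RMST over 0-%g months: %.3f months", x$tau, x$value))
  if (!is.na(x$se)) cat(sprintf(" (SE %.4f)", x$se))
  cat("\n")
  invisible(x)
}

#' Two-group Cox proportional-hazards estimate
#'
#' Maximum partial likelihood estimate of the hazard ratio for a single
#' binary treatment contrast, with Efron handling of tied event times and a
#' Newton-Raphson solver (relative tolerance 1e-8). Supplies hazard ratios
#' for simulated trials, mirroring the HRs that published trials report.
#'
#' @param time follow-up times in months (both arms pooled).
#' @param event 0/1 event indicators.
#' @param treat 0/1 treatment indicator (1 = experimental arm).
#' @param conf_level confidence level for the Wald interval on the log scale.
#' @param tol relative convergence tolerance for Newton-Raphson.
#' @param max_iter maximum Newton iterations before aborting.
#' @return An object of class `hrEstimate`: list with `hr`, `log_hr`,
#'   `log_hr_se`, `ci_low`, `ci_high`, `n`, `n_events`, `iterations`.
#' @examples
#' set.seed(1)
#' t0 <- rexp(100, 0.1); t1 <- rexp(100, 0.07)
#' coxHR(c(t0, t1), rep(1, 200), rep(0:1, each = 100))$hr
#' @export
coxHR <- function(time, event, treat, conf_level = 0.95,
                  tol = 1e-8, max_iter = 100L) {
  if (length(time) == 0L) stop("no records")
  if (any(!is.finite(time)) || any(time <= 0)) stop("invalid time")
  event <- as.integer(event)
  treat <- as.integer(treat)
  if (!all(event %in% 0:1) || !all(treat %in% 0:1))
    stop("event and treat must be 0/1 vectors")
  if (sum(event) == 0L) stop("no events")

  et <- sort(unique(time[event == 1L]))
  # per event time: risk-set membership and death-set tallies
  beta <- 0
  info <- NA_real_
  for (iter in seq_len(max_iter)) {
    U <- 0; I <- 0
    eb <- exp(beta)
    for (t in et) {
      R <- time >= t
      D <- event == 1L & time == t
      d <- sum(D)
      s1 <- sum(treat[D])
      n1R <- sum(treat[R]); n0R <- sum(R) - n1R
      r0 <- n0R + n1R * eb
      r1 <- n1R * eb
      n1D <- s1; n0D <- d - s1
      d0 <- n0D + n1D * eb
      d1 <- n1D * eb
      l <- seq_len(d) - 1
      f0 <- r0 - (l / d) * d0
      f1 <- r1 - (l / d) * d1
      rat <- f1 / f0
      U <- U + s1 - sum(rat)
      I <- I + sum(rat - rat^2)   # x binary: second moment equals first
    }
    if (I <= 0) stop("cox fit failed: non-positive information (iteration ",
                     iter, ", beta = ", format(beta), ")")
    step <- U / I
    beta <- beta + step
    info <- I
    if (abs(step) < tol * max(1, abs(beta))) {
      z <- stats::qnorm(1 - (1 - conf_level) / 2)
      se <- 1 / sqrt(info)
      out <- list(hr = exp(beta), log_hr = beta, log_hr_se = se,
                  ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
                  n = length(time), n_events = sum(event), iterations = iter)
      class(out) <- "hrEstimate"
      return(out)
    }
  }
  stop("cox fit did not converge in ", max_iter,
       " iterations (beta = ", format(beta), ", last step = ", format(step), ")")
}

#' @export
print.hrEstimate <- function(x, ...) {
  cat(sprintf("HR = %.4f (95%% CI %.4f-%.4f), %d events / %d subjects\n",
              x$hr, x$ci_low, x$ci_high, x$n_events, x$n))
  invisible(x)
}
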