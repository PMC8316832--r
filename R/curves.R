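#' Raw digitized survival-curve coordinates
#'
#' Container for (time, survival) pairs read off a published Kaplan-Meier
#' figure with a digitizing tool. Raw coordinates may be slightly
#' non-monotone or stray just outside \[0, 1\] because of digitization
#' noise; [cleanCurve()] normalizes them.
#'
#' @param time coordinate times in months, finite and >= 0.
#' @param survival survival proportions as read off the figure.
#' @param n_arm reported arm size (optional, used as regression weight
#'   metadata downstream).
#' @param max_follow_up reported maximum follow-up in months (optional).
#' @return An object of class `digitizedCurve`: data frame with columns
#'   `time`, `survival` and attributes `n_arm`, `max_follow_up`.
#' @export
digitizedCurve <- function(time, survival, n_arm = NA_integer_,
                           max_follow_up = NA_real_) {
  if (length(time) != length(survival)) stop("time and survival lengths differ")
  if (length(time) < 2L) stop("a digitized curve needs at least 2 points")
  if (any(!is.finite(time)) || any(!is.finite(survival)))
    stop("coordinates must be finite")
  if (any(time < 0)) stop("negative time in digitized coordinates")
  out <- data.frame(time = as.numeric(time), survival = as.numeric(survival))
  attr(out, "n_arm") <- n_arm
  attr(out, "max_follow_up") <- max_follow_up
  class(out) <- c("digitizedCurve", "data.frame")
  out
}

#' Normalize digitized coordinates into a monotone step curve
#'
#' Turns raw digitized coordinates into a valid survival step function:
#' points are sorted by time, duplicate times are collapsed to their minimum
#' survival (a drop at that time, matching Kaplan-Meier step semantics),
#' survival is clamped to \[0, 1\], monotonicity is enforced by a running
#' minimum, and the curve is anchored at (0, 1). A digitized point at time 0
#' with survival below 1 is treated as noise and reset to 1. The operation
#' is idempotent.
#'
#' @param raw a [digitizedCurve()], or any data frame / 2-column matrix of
#'   (time, survival) pairs.
#' @return An object of class `cleanCurve`: data frame with strictly
#'   increasing `time`, non-increasing `survival` in \[0, 1\], first row
#'   (0, 1); attributes `n_arm` and `max_follow_up` carried over.
#' @export
cleanCurve <- function(raw) {
  if (is.matrix(raw)) raw <- data.frame(time = raw[, 1], survival = raw[, 2])
  if (!is.data.frame(raw)) stop("raw must be a digitizedCurve, data frame or matrix")
  tm <- as.numeric(raw[[1]])
  sv <- as.numeric(raw[[2]])
  if (length(tm) < 2L) stop("a digitized curve needs at least 2 points")
  if (any(!is.finite(tm)) || any(!is.finite(sv))) stop("coordinates must be finite")
  if (any(tm < 0)) stop("negative time in digitized coordinates")

  sv <- pmin(1, pmax(0, sv))
  ord <- order(tm, sv)                  # duplicate times: smaller survival last kept
  tm <- tm[ord]; sv <- sv[ord]
  keepMin <- vapply(unique(tm), function(t) min(sv[tm == t]), numeric(1))
  tm <- unique(tm); sv <- keepMin
  nonzero <- tm > 0
  tm <- c(0, tm[nonzero]); sv <- c(1, sv[nonzero])
  sv <- cummin(sv)
  out <- data.frame(time = tm, survival = sv)
  attr(out, "n_arm") <- attr(raw, "n_arm")
  attr(out, "max_follow_up") <- attr(raw, "max_follow_up")
  class(out) <- c("cleanCurve", "data.frame")
  out
}

#' @export
print.cleanCurve <- function(x, ...) {
  cat("Clean survival curve:", nrow(x), "points over 0-",
      format(max(x$time), digits = 4), "months\n")
  print.data.frame(utils::head(x, 8), row.names = FALSE)
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}

#' @rdname rmst
#' @param mode integration rule for curve-derived estimates: `"step"`
#'   (default) treats the coordinates as corners of a right-continuous step
#'   function — what a Kaplan-Meier curve is; `"trapezoid"` interpolates
#'   linearly between coordinates, a sensitivity option for digitizers that
#'   sample slanted segments. On a non-increasing curve the step value is
#'   always >= the trapezoid value (each segment uses its left, larger,
#'   survival value).
#' @export
rmst.cleanCurve <- function(curve, tau, mode = c("step", "trapezoid"), ...) {
  mode <- match.arg(mode)
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("tau must be a single positive number")
  tmax <- max(curve$time)
  if (tau > tmax + 1e-9) stop("horizon beyond digitized range")
  tm <- curve$time; sv <- curve$survival
  if (mode == "step") {
    keep <- tm < tau
    knots <- c(tm[keep], tau)
    value <- sum(sv[keep] * diff(knots))
  } else {
    stau <- stats::approx(tm, sv, xout = min(tau, tmax), rule = 2)$y
    keep <- tm < tau
    xs <- c(tm[keep], tau)
    ys <- c(sv[keep], stau)
    value <- sum((utils::head(ys, -1) + ys[-1]) / 2 * diff(xs))
  }
  structure(list(tau = tau, value = value, se = NA_real_), class = "rmstEstimate")
}

#' @rdname milestoneRate
#' @export
milestoneRate.cleanCurve <- function(curve, tau, ...) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0)
    stop("tau must be a single non-negative number")
  if (tau > max(curve$time) + 1e-9) stop("milestone beyond digitized range")
  idx <- findInterval(tau, curve$time)   # last coordinate time <= tau
  rate <- curve$survival[max(idx, 1L)]
  structure(list(tau = tau, rate = rate, se = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_),
            class = "milestoneEstimate")
}
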