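#' Ratio of arm-level effect values
#'
#' Experimental-over-control ratio used to express treatment effect on
#' milestone survival rates and RMSTs, the same direction convention as a
#' hazard ratio's experimental-vs-control contrast.
#'
#' @param value_experimental,value_control strictly positive effect values
#'   (rates, RMSTs, proportions).
#' @return `value_experimental / value_control`.
#' @export
effectRatio <- function(value_experimental, value_control) {
  if (!is.finite(value_experimental) || !is.finite(value_control) ||
      value_experimental <= 0 || value_control <= 0)
    stop("non-positive effect value")
  value_experimental / value_control
}

#' Relative risk from responder counts
#'
#' Ratio of response proportions (ORR or DCR) between experimental and
#' control arms. A zero control proportion leaves the relative risk
#' undefined and errors; a zero experimental proportion gives 0 with a
#' warning.
#'
#' @param responders_exp,n_exp responders and arm size, experimental arm.
#' @param responders_ctrl,n_ctrl responders and arm size, control arm.
#' @return the relative risk, `(responders_exp/n_exp)/(responders_ctrl/n_ctrl)`.
#' @export
rrFromCounts <- function(responders_exp, n_exp, responders_ctrl, n_ctrl) {
  counts <- c(responders_exp, n_exp, responders_ctrl, n_ctrl)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (n_exp <= 0 || n_ctrl <= 0) stop("arm size must be positive")
  if (responders_exp > n_exp || responders_ctrl > n_ctrl)
    stop("responders exceed arm size")
  if (responders_ctrl == 0) stop("undefined relative risk: zero responders in control arm")
  if (responders_exp == 0) {
    warning("zero responders in experimental arm: relative risk is 0")
    return(0)
  }
  (responders_exp / n_exp) / (responders_ctrl / n_ctrl)
}

# all permutations of 1..n as an n! x n matrix (n small)
.permMatrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permMatrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Spearman rank correlation with a two-sided test
#'
#' Pearson correlation of average ranks (ties averaged). The default p-value
#' is the two-sided t approximation with n - 2 degrees of freedom; for
#' n <= 10 an exact permutation p-value is available.
#'
#' @param x,y numeric vectors of equal length >= 3, no missing values.
#' @param method `"t"` (default) or `"exact"` (permutation enumeration,
#'   n <= 10).
#' @return list with components `r` and `p`.
#' @examples
#' spearmanCorr(1:5, c(2, 4, 8, 16, 32))$r  # +1: rank-invariant
#' @export
spearmanCorr <- function(x, y, method = c("t", "exact")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y lengths differ")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) stop("zero rank variance")
  r <- stats::cor(rx, ry)
  if (method == "t") {
    if (abs(r) >= 1 - 1e-12) {
      p <- 0
    } else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  } else {
    if (n > 10L) stop("exact permutation p only for n <= 10")
    # |r_perm| >= |r_obs|  <=>  |S - n*mx*my| >= |r_obs| (n-1) sx sy,
    # with S = sum(rx * permuted ry); enumerate by first element to cap memory
    mx <- mean(rx); my <- mean(ry)
    sx <- stats::sd(rx); sy <- stats::sd(ry)
    thr <- abs(r) * (n - 1) * sx * sy - 1e-9
    c0 <- n * mx * my
    count <- 0; total <- 0
    if (n <= 8L) {
      P <- .permMatrix(n)
      S <- as.vector(matrix(ry[P], nrow = nrow(P)) %*% rx)
      count <- sum(abs(S - c0) >= thr)
      total <- nrow(P)
    } else {
      sub <- .permMatrix(n - 1L)
      for (i in seq_len(n)) {
        rest <- seq_len(n)[-i]
        P <- cbind(i, matrix(rest[sub], nrow(sub)))
        S <- as.vector(matrix(ry[P], nrow = nrow(P)) %*% rx)
        count <- count + sum(abs(S - c0) >= thr)
        total <- total + nrow(P)
      }
    }
    p <- count / total
  }
  list(r = r, p = p)
}

#' Weighted log-log least-squares surrogacy fit
#'
#' The trial-level surrogacy model: regress the log hazard ratio for overall
#' survival on the log of a candidate surrogate's treatment effect across
#' experimental-vs-control comparisons, weighting each comparison by its
#' combined randomized sample size,
#' \deqn{\min_{a,b} \sum_i w_i (\log \mathrm{HR}_{OS,i} - a - b \log s_i)^2.}
#' Reported alongside are the weighted coefficient of determination
#' (1 - weighted residual SS / weighted total SS about the weighted mean),
#' the two-sided t test of slope = 0 (identical to the overall F test in a
#' single-regressor model), and the Spearman rank correlation of the
#' untransformed pairs. Slope and R-squared do not depend on the log base as
#' long as both axes share it; the intercept does (default base 10, the
#' convention in trial-level surrogacy plots).
#'
#' @param comparisons data frame of comparison records: one row per
#'   experimental-vs-control contrast with columns `hr_os`, the candidate
#'   surrogate column, and the weight column (see [pairComparisons()]).
#' @param surrogate name of the surrogate effect column, e.g.
#'   `"ratio_rmst_24"`, `"ratio_milestone_12"`, `"hr_pfs"`, `"rr_orr"`.
#' @param weight_col weight column, default `"n_total"`.
#' @param log_base base for both log transforms, default 10.
#' @return An object of class `surrogacyResult`: list with
#'   `surrogate_name`, `n_comparisons`, `spearman_r`, `spearman_p`,
#'   `intercept`, `slope`, `slope_se`, `r_squared`, `regression_p`,
#'   `log_base`.
#' @export
wlsLogLogFit <- function(comparisons, surrogate, weight_col = "n_total",
                         log_base = 10) {
  for (col in c("hr_os", surrogate, weight_col))
    if (!col %in% names(comparisons)) stop("missing column: ", col)
  s <- comparisons[[surrogate]]
  h <- comparisons$hr_os
  w <- comparisons[[weight_col]]
  use <- !is.na(s) & !is.na(h) & !is.na(w)
  if (any(use & (s <= 0 | h <= 0)))
    stop("non-positive effect value in ", surrogate, " or hr_os")
  if (sum(use) < 3L) stop("insufficient comparisons: need >= 3 with both hr_os and ", surrogate)
  s <- s[use]; h <- h[use]; w <- w[use]
  if (any(w <= 0)) stop("weights must be positive")
  x <- log(s, base = log_base)
  y <- log(h, base = log_base)
  fit <- stats::lm(y ~ x, weights = w)
  sm <- summary(fit)
  coefs <- sm$coefficients
  sp <- spearmanCorr(s, h)
  structure(list(surrogate_name = surrogate,
                 n_comparisons = sum(use),
                 spearman_r = sp$r, spearman_p = sp$p,
                 intercept = unname(coefs["(Intercept)", "Estimate"]),
                 slope = unname(coefs["x", "Estimate"]),
                 slope_se = unname(coefs["x", "Std. Error"]),
                 r_squared = sm$r.squared,
                 regression_p = unname(coefs["x", "Pr(>|t|)"]),
                 log_base = log_base),
            class = "surrogacyResult")
}

#' @export
print.surrogacyResult <- function(x, ...) {
  cat(formatEquation(x), "\n", sep = "")
  cat(sprintf("  n = %d, Spearman r = %.3f (P = %.4g), R^2 = %.3f (P = %.4g)\n",
              x$n_comparisons, x$spearman_r, x$spearman_p,
              x$r_squared, x$regression_p))
  invisible(x)
}

#' Format a surrogacy regression equation
#'
#' Renders a fitted surrogacy line in the conventional report form, e.g.
#' `Log (HR_OS) = -0.099 - 0.567 x Log (ratio_milestone_12)`.
#'
#' @param result a [wlsLogLogFit()] result.
#' @param digits decimals for the coefficients.
#' @return a character string.
#' @export
formatEquation <- function(result, digits = 3) {
  a <- round(result$intercept, digits)
  b <- round(result$slope, digits)
  sprintf("Log (HR_OS) = %s %s %s x Log (%s)",
          format(a), if (b < 0) "-" else "+", format(abs(b)),
          result$surrogate_name)
}

#' Fit every candidate surrogate
#'
#' Runs the weighted log-log surrogacy regression for each candidate
#' surrogate having at least 3 comparisons with both the surrogate and the
#' OS hazard ratio observed (per-surrogate complete-case analysis, so each
#' fit can use a different n). Surrogates with fewer usable comparisons are
#' silently dropped from the summary.
#'
#' @param comparisons data frame of comparison records.
#' @param surrogates candidate surrogate columns; defaults to the six
#'   standard candidates (12-month milestone-rate ratio, 12- and 24-month
#'   RMST ratios, PFS hazard ratio, ORR and DCR relative risks).
#' @param weight_col,log_base passed to [wlsLogLogFit()].
#' @return An object of class `surrogacySummary`: data frame with one row
#'   per fitted surrogate (columns `surrogate`, `n`, `spearman_r`,
#'   `spearman_p`, `intercept`, `slope`, `r_squared`, `regression_p`);
#'   the full `surrogacyResult` objects are attached as attribute
#'   `"results"`.
#' @export
evaluateAll <- function(comparisons,
                        surrogates = c("ratio_milestone_12", "ratio_rmst_12",
                                       "ratio_rmst_24", "hr_pfs",
                                       "rr_orr", "rr_dcr"),
                        weight_col = "n_total", log_base = 10) {
  present <- intersect(surrogates, names(comparisons))
  results <- list()
  for (sg in present) {
    usable <- sum(!is.na(comparisons[[sg]]) & !is.na(comparisons$hr_os))
    if (usable >= 3L)
      results[[sg]] <- wlsLogLogFit(comparisons, sg,
                                    weight_col = weight_col,
                                    log_base = log_base)
  }
  if (!length(results)) stop("insufficient comparisons: no surrogate has >= 3 usable comparisons")
  tab <- do.call(rbind, lapply(results, function(r)
    data.frame(surrogate = r$surrogate_name, n = r$n_comparisons,
               spearman_r = r$spearman_r, spearman_p = r$spearman_p,
               intercept = r$intercept, slope = r$slope,
               r_squared = r$r_squared, regression_p = r$regression_p,
               stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  attr(tab, "results") <- results
  class(tab) <- c("surrogacySummary", "data.frame")
  tab
}

#' @export
print.surrogacySummary <- function(x, digits = 3, ...) {
  cat("Trial-level surrogacy of treatment effects for the OS hazard ratio\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  print(df, row.names = FALSE)
  invisible(x)
}
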