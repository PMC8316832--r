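# ---- piecewise-constant hazard machinery -----------------------------------
# A hazard spec is list(breaks = increasing interior breakpoints (months),
# rates = per-month rates, length(rates) == length(breaks) + 1).

.checkHazard <- function(hz) {
  if (!is.list(hz) || !all(c("breaks", "rates") %in% names(hz)))
    stop("hazard spec must be list(breaks=, rates=)")
  if (length(hz$rates) != length(hz$breaks) + 1L)
    stop("hazard spec: need one more rate than breakpoints")
  if (is.unsorted(hz$breaks, strictly = TRUE) && length(hz$breaks) > 1L)
    stop("hazard breakpoints must be strictly increasing")
  if (any(hz$breaks <= 0)) stop("hazard breakpoints must be positive")
  if (any(hz$rates < 0) || all(hz$rates == 0)) stop("hazard rates invalid")
  hz
}

# cumulative hazard H(t) of a piecewise-constant hazard, vectorized in t
.pwexpCumHaz <- function(t, hz) {
  lo <- c(0, hz$breaks)
  hi <- c(hz$breaks, Inf)
  vapply(t, function(ti) sum(hz$rates * pmax(0, pmin(ti, hi) - lo)), numeric(1))
}

# inverse cumulative hazard: smallest t with H(t) = h
.pwexpInvCumHaz <- function(h, hz) {
  lo <- c(0, hz$breaks)
  widths <- diff(c(lo, Inf))
  segH <- hz$rates * widths                      # hazard mass per segment
  cumH <- c(0, cumsum(segH))                     # H at segment starts
  vapply(h, function(hi) {
    k <- findInterval(hi, cumH, left.open = TRUE)
    k <- max(1L, min(k, length(hz$rates)))
    if (hz$rates[k] == 0) {
      # no mass here; advance to next segment with positive rate
      while (k < length(hz$rates) && hz$rates[k] == 0) k <- k + 1L
      if (hz$rates[k] == 0) return(Inf)
    }
    lo[k] + (hi - cumH[k]) / hz$rates[k]
  }, numeric(1))
}

# draw n piecewise-exponential times (inverse transform of S(t) = exp(-H(t)))
.pwexpDraw <- function(n, hz) .pwexpInvCumHaz(stats::rexp(n), hz)

# hazard of an arm: control hazard, with rates multiplied by hr for t >= delay
.armHazard <- function(control_hz, delay, hr) {
  if (hr == 1) return(control_hz)
  if (delay <= 0) return(list(breaks = control_hz$breaks,
                              rates = control_hz$rates * hr))
  breaks <- sort(unique(c(control_hz$breaks, delay)))
  starts <- c(0, breaks)
  base <- control_hz$rates[findInterval(starts, control_hz$breaks) + 1L]
  rates <- ifelse(starts >= delay, base * hr, base)
  list(breaks = breaks, rates = rates)
}

# ---- scenario ---------------------------------------------------------------

#' Generative parameters for one simulated randomized trial
#'
#' Describes an ES-SCLC-like randomized trial with the survival kinetics of
#' first-line chemo-immunotherapy: an exponential-like control arm (default
#' single hazard giving a 10-month median OS), experimental arms whose
#' hazard is reduced by `hr_post_delay` only after `delay_months` (survival
#' curves overlap early and separate around 6 months), an optional cure
#' fraction producing a long-term survivor plateau, uniform accrual with an
#' administrative cutoff, exponential dropout, PFS coupled to OS through a
#' hazard multiplier, and per-arm response probabilities.
#'
#' @param n_per_arm subjects randomized per arm.
#' @param n_experimental_arms 1 or 2 experimental arms (2- or 3-arm trial).
#' @param control_hazard piecewise-constant hazard spec,
#'   `list(breaks=, rates=)` in events per month; default a single rate
#'   `log(2)/10` (median OS 10 months).
#' @param delay_months months before the treatment effect switches on
#'   (default 6).
#' @param hr_post_delay hazard ratio applied to the control hazard after the
#'   delay, one value per experimental arm (< 1 is benefit).
#' @param cure_fraction proportion of long-term survivors in experimental
#'   arms (mixture model: cured subjects never have the event and are
#'   censored at cutoff); requires a finite `admin_cutoff_months`.
#' @param accrual_months uniform accrual window.
#' @param admin_cutoff_months administrative cutoff from start of accrual
#'   (may be `Inf` when `cure_fraction` is 0 and dropout handles censoring).
#' @param dropout_rate exponential dropout (censoring) hazard per month.
#' @param orr_control,orr_experimental overall response probabilities.
#' @param dcr_control,dcr_experimental disease control probabilities
#'   (>= the corresponding ORR).
#' @param pfs_hazard_mult multiplier turning the OS hazard into the PFS
#'   hazard (> 1; progression precedes death); simulated PFS is clipped to
#'   be <= OS.
#' @param seed default seed used by the simulator when none is passed.
#' @return An object of class `trialScenario` (validated list).
#' @export
trialScenario <- function(n_per_arm = 200,
                          n_experimental_arms = 1,
                          control_hazard = list(breaks = numeric(0),
                                                rates = log(2) / 10),
                          delay_months = 6,
                          hr_post_delay = 0.7,
                          cure_fraction = 0,
                          accrual_months = 14,
                          admin_cutoff_months = 40,
                          dropout_rate = 0.005,
                          orr_control = 0.58, orr_experimental = 0.62,
                          dcr_control = 0.80, dcr_experimental = 0.85,
                          pfs_hazard_mult = 2,
                          seed = NULL) {
  sc <- list(n_per_arm = n_per_arm,
             n_experimental_arms = as.integer(n_experimental_arms),
             control_hazard = .checkHazard(control_hazard),
             delay_months = delay_months,
             hr_post_delay = hr_post_delay,
             cure_fraction = cure_fraction,
             accrual_months = accrual_months,
             admin_cutoff_months = admin_cutoff_months,
             dropout_rate = dropout_rate,
             orr_control = orr_control, orr_experimental = orr_experimental,
             dcr_control = dcr_control, dcr_experimental = dcr_experimental,
             pfs_hazard_mult = pfs_hazard_mult,
             seed = seed)
  if (sc$n_per_arm < 1) stop("n_per_arm must be >= 1")
  if (!sc$n_experimental_arms %in% 1:2)
    stop("n_experimental_arms must be 1 or 2")
  if (sc$delay_months < 0) stop("delay_months must be >= 0")
  if (any(sc$hr_post_delay <= 0)) stop("hr_post_delay must be > 0")
  if (length(sc$hr_post_delay) == 1L)
    sc$hr_post_delay <- rep(sc$hr_post_delay, sc$n_experimental_arms)
  if (length(sc$hr_post_delay) != sc$n_experimental_arms)
    stop("hr_post_delay must have one value per experimental arm")
  if (sc$cure_fraction < 0 || sc$cure_fraction >= 1)
    stop("cure_fraction must be in [0, 1)")
  if (sc$cure_fraction > 0 && !is.finite(sc$admin_cutoff_months))
    stop("cure_fraction > 0 requires a finite admin_cutoff_months")
  if (sc$accrual_months < 0) stop("accrual_months must be >= 0")
  if (is.finite(sc$admin_cutoff_months) &&
      sc$admin_cutoff_months <= sc$accrual_months)
    stop("admin_cutoff_months must exceed accrual_months")
  if (sc$dropout_rate < 0) stop("dropout_rate must be >= 0")
  probs <- c(sc$orr_control, sc$orr_experimental,
             sc$dcr_control, sc$dcr_experimental)
  if (any(probs < 0 | probs > 1)) stop("response probabilities must be in [0, 1]")
  if (sc$dcr_control < sc$orr_control || sc$dcr_experimental < sc$orr_experimental)
    stop("DCR probability must be >= ORR probability")
  if (sc$pfs_hazard_mult <= 1) stop("pfs_hazard_mult must be > 1")
  class(sc) <- "trialScenario"
  sc
}

#' @export
print.trialScenario <- function(x, ...) {
  cat("Trial scenario:", 1 + x$n_experimental_arms, "arms x", x$n_per_arm,
      "subjects\n")
  cat(sprintf("  control median OS %.1f mo; effect delay %g mo; post-delay HR %s; cure %g\n",
              log(2) / x$control_hazard$rates[1], x$delay_months,
              paste(x$hr_post_delay, collapse = "/"), x$cure_fraction))
  invisible(x)
}

# hazard spec of a named arm of the scenario ("control", "E1", "E2")
.scenarioArmHazard <- function(scenario, arm) {
  if (arm == "control") return(scenario$control_hazard)
  k <- if (arm %in% c("E1", "experimental")) 1L else if (arm == "E2") 2L else
    stop("unknown arm label: ", arm)
  if (k > scenario$n_experimental_arms) stop("scenario has no arm ", arm)
  .armHazard(scenario$control_hazard, scenario$delay_months,
             scenario$hr_post_delay[k])
}

#' Analytic survival and RMST of a scenario arm
#'
#' The exact survival function and restricted mean implied by a scenario's
#' generative law (piecewise-exponential with delayed effect, mixed with a
#' cure fraction for experimental arms):
#' \eqn{S(t) = c + (1 - c) e^{-H(t)}}. Used as ground truth in parameter
#' recovery checks.
#'
#' @param scenario a [trialScenario()].
#' @param t,tau evaluation times / horizon in months.
#' @param arm `"control"`, `"E1"` or `"E2"`.
#' @return `scenarioSurvival`: S(t) values; `scenarioRmst`: the integral of
#'   S over \[0, tau\] in months.
#' @export
scenarioSurvival <- function(scenario, t, arm = "control") {
  hz <- .scenarioArmHazard(scenario, arm)
  cf <- if (arm == "control") 0 else scenario$cure_fraction
  cf + (1 - cf) * exp(-.pwexpCumHaz(t, hz))
}

#' @rdname scenarioSurvival
#' @export
scenarioRmst <- function(scenario, tau, arm = "control") {
  hz <- .scenarioArmHazard(scenario, arm)
  cf <- if (arm == "control") 0 else scenario$cure_fraction
  lo <- c(0, hz$breaks)
  hi <- pmin(c(hz$breaks, Inf), tau)
  area <- 0
  H <- 0
  for (k in seq_along(hz$rates)) {
    if (hi[k] <= lo[k]) break
    w <- hi[k] - lo[k]
    r <- hz$rates[k]
    seg <- if (r == 0) exp(-H) * w else exp(-H) * (1 - exp(-r * w)) / r
    area <- area + seg
    H <- H + r * w
  }
  cf * tau + (1 - cf) * area
}

# ---- arm simulation ---------------------------------------------------------

#' Simulate one arm of a trial scenario
#'
#' Draws OS times by inverse-transform sampling of the arm's
#' piecewise-exponential survival law (control hazard, scaled by the
#' post-delay hazard ratio for experimental arms), marks a cure fraction as
#' never-event, generates PFS from the OS hazard times `pfs_hazard_mult`
#' clipped to PFS <= OS, applies administrative (uniform accrual + cutoff)
#' and dropout censoring, and draws ORR/DCR responder counts with
#' DCR >= ORR by construction.
#'
#' @param scenario a [trialScenario()].
#' @param arm `"control"`, `"E1"` or `"E2"`.
#' @param seed integer seed; defaults to the scenario's seed. Identical
#'   (scenario, arm, seed) give identical output.
#' @return data frame with one row per subject: `arm`, `os_time`,
#'   `os_event`, `pfs_time`, `pfs_event` (times in months); attribute
#'   `"responses"` is a list with `n`, `orr_responders`, `dcr_responders`.
#' @export
simulateArm <- function(scenario, arm = "control", seed = scenario$seed) {
  stopifnot(inherits(scenario, "trialScenario"))
  if (!is.null(seed)) set.seed(seed)
  n <- scenario$n_per_arm
  hz <- .scenarioArmHazard(scenario, arm)
  t_os <- .pwexpDraw(n, hz)
  if (arm != "control" && scenario$cure_fraction > 0) {
    cured <- stats::runif(n) < scenario$cure_fraction
    t_os[cured] <- Inf
  }
  pfs_hz <- list(breaks = hz$breaks, rates = hz$rates * scenario$pfs_hazard_mult)
  t_pfs <- pmin(.pwexpDraw(n, pfs_hz), t_os)
  entry <- stats::runif(n, 0, scenario$accrual_months)
  cens_admin <- scenario$admin_cutoff_months - entry
  cens_drop <- if (scenario$dropout_rate > 0)
    stats::rexp(n, scenario$dropout_rate) else rep(Inf, n)
  cens <- pmin(cens_admin, cens_drop)
  if (any(!is.finite(pmin(t_os, cens))))
    stop("simulated subject with infinite observed time; check censoring settings")
  os_time <- pmin(t_os, cens)
  os_event <- as.integer(t_os <= cens)
  pfs_time <- pmin(t_pfs, cens)
  pfs_event <- as.integer(t_pfs <= cens)

  is_exp <- arm != "control"
  p_orr <- if (is_exp) scenario$orr_experimental else scenario$orr_control
  p_dcr <- if (is_exp) scenario$dcr_experimental else scenario$dcr_control
  orr_resp <- stats::rbinom(1, n, p_orr)
  p_extra <- if (p_orr < 1) (p_dcr - p_orr) / (1 - p_orr) else 0
  dcr_resp <- orr_resp + stats::rbinom(1, n - orr_resp, p_extra)

  out <- data.frame(arm = arm, os_time = os_time, os_event = os_event,
                    pfs_time = pfs_time, pfs_event = pfs_event,
                    stringsAsFactors = FALSE)
  attr(out, "responses") <- list(n = n, orr_responders = orr_resp,
                                 dcr_responders = dcr_resp)
  out
}

# ---- trial suite ------------------------------------------------------------

#' Simulate a suite of trials and assemble comparison records
#'
#' Simulates `k_trials` randomized trials from a common scenario template,
#' sweeping the post-delay hazard ratio across experimental arms, then runs
#' the full analysis on each: Kaplan-Meier fits per arm, milestone rate at
#' 12 months, RMST at 12 and 24 months, Cox hazard ratios for OS and PFS,
#' and ORR/DCR relative risks — one comparison record per experimental arm
#' against its trial's shared control arm (so a 3-arm trial contributes two
#' comparisons). True generative effect values (post-delay HR, analytic
#' milestone and RMST ratios) are attached for recovery checks.
#'
#' Reproducibility: `set.seed(seed)` draws one sub-seed per trial via
#' `sample.int(2^31 - 1, k_trials)`; each trial is then simulated under its
#' sub-seed with arms drawn sequentially, so the whole suite is reproducible
#' from the single seed.
#'
#' @param k_trials number of trials, >= 3.
#' @param hr_grid post-delay hazard ratios, recycled across the suite's
#'   experimental arms in order.
#' @param template a [trialScenario()] used for every other parameter.
#' @param n_arms arms per trial (2 or 3), recycled to `k_trials`.
#' @param seed suite seed (integer).
#' @return list with `comparisons` (data frame, one row per comparison:
#'   ids, `n_total`, `hr_os`, `hr_pfs`, `rr_orr`, `rr_dcr`,
#'   `ratio_milestone_12`, `ratio_rmst_12`, `ratio_rmst_24`, plus
#'   `true_hr_post_delay`, `true_ratio_milestone_12`, `true_ratio_rmst_12`,
#'   `true_ratio_rmst_24`) and `subjects` (long data frame:
#'   `trial_id`, `arm_id`, `time_months`, `event`, `endpoint`).
#' @export
simulateTrialSuite <- function(k_trials, hr_grid, template = trialScenario(),
                               n_arms = 2, seed = 20201231) {
  if (k_trials < 3) stop("k_trials must be >= 3")
  n_arms <- rep_len(n_arms, k_trials)
  if (!all(n_arms %in% 2:3)) stop("n_arms values must be 2 or 3")
  n_exp_total <- sum(n_arms - 1L)
  hrs <- rep_len(hr_grid, n_exp_total)
  set.seed(seed)
  trial_seeds <- sample.int(2147483646L, k_trials)

  comp_rows <- list()
  subj_rows <- list()
  hr_idx <- 1L
  for (i in seq_len(k_trials)) {
    trial_id <- sprintf("SIM%02d", i)
    n_exp <- n_arms[i] - 1L
    hrs_i <- hrs[hr_idx:(hr_idx + n_exp - 1L)]
    hr_idx <- hr_idx + n_exp
    sc <- template
    sc$n_experimental_arms <- n_exp
    sc$hr_post_delay <- hrs_i
    set.seed(trial_seeds[i])
    ctrl <- simulateArm(sc, "control", seed = NULL)
    km_c <- kmFit(ctrl$os_time, ctrl$os_event)
    ms_c <- milestoneRate(km_c, 12)$rate
    r12_c <- rmst(km_c, 12)$value
    r24_c <- rmst(km_c, 24)$value
    resp_c <- attr(ctrl, "responses")
    subj_rows[[length(subj_rows) + 1L]] <- .armLong(trial_id, "control", ctrl)
    for (k in seq_len(n_exp)) {
      arm_id <- paste0("E", k)
      exp_arm <- simulateArm(sc, arm_id, seed = NULL)
      km_e <- kmFit(exp_arm$os_time, exp_arm$os_event)
      resp_e <- attr(exp_arm, "responses")
      os_hr <- coxHR(c(exp_arm$os_time, ctrl$os_time),
                     c(exp_arm$os_event, ctrl$os_event),
                     rep(1:0, times = c(nrow(exp_arm), nrow(ctrl))))
      pfs_hr <- coxHR(c(exp_arm$pfs_time, ctrl$pfs_time),
                      c(exp_arm$pfs_event, ctrl$pfs_event),
                      rep(1:0, times = c(nrow(exp_arm), nrow(ctrl))))
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        trial_id = trial_id, experimental_arm_id = arm_id,
        control_arm_id = "control",
        n_total = nrow(exp_arm) + nrow(ctrl),
        hr_os = os_hr$hr, hr_pfs = pfs_hr$hr,
        rr_orr = rrFromCounts(resp_e$orr_responders, resp_e$n,
                              resp_c$orr_responders, resp_c$n),
        rr_dcr = rrFromCounts(resp_e$dcr_responders, resp_e$n,
                              resp_c$dcr_responders, resp_c$n),
        ratio_milestone_12 = effectRatio(milestoneRate(km_e, 12)$rate, ms_c),
        ratio_rmst_12 = effectRatio(rmst(km_e, 12)$value, r12_c),
        ratio_rmst_24 = effectRatio(rmst(km_e, 24)$value, r24_c),
        true_hr_post_delay = hrs_i[k],
        true_ratio_milestone_12 =
          scenarioSurvival(sc, 12, arm_id) / scenarioSurvival(sc, 12, "control"),
        true_ratio_rmst_12 =
          scenarioRmst(sc, 12, arm_id) / scenarioRmst(sc, 12, "control"),
        true_ratio_rmst_24 =
          scenarioRmst(sc, 24, arm_id) / scenarioRmst(sc, 24, "control"),
        stringsAsFactors = FALSE)
      subj_rows[[length(subj_rows) + 1L]] <- .armLong(trial_id, arm_id, exp_arm)
    }
  }
  list(comparisons = do.call(rbind, comp_rows),
       subjects = do.call(rbind, subj_rows))
}

# wide arm data frame -> long subject records (OS + PFS endpoints)
.armLong <- function(trial_id, arm_id, arm_df) {
  rbind(
    data.frame(trial_id = trial_id, arm_id = arm_id,
               time_months = arm_df$os_time, event = arm_df$os_event,
               endpoint = "OS", stringsAsFactors = FALSE),
    data.frame(trial_id = trial_id, arm_id = arm_id,
               time_months = arm_df$pfs_time, event = arm_df$pfs_event,
               endpoint = "PFS", stringsAsFactors = FALSE))
}

# ---- digitization emulator --------------------------------------------------

#' Emulate figure digitization of a Kaplan-Meier curve
#'
#' Produces the kind of raw coordinates a human digitizing a published
#' figure would: points on a uniform time grid over the curve's support (or
#' exactly at the step corners), survival values perturbed by truncated
#' Gaussian noise, and a few adjacent points swapped so the cleaning step is
#' exercised.
#'
#' @param curve a [kmFit()] curve.
#' @param n_points number of coordinates, >= 2.
#' @param jitter_sd SD of the additive Gaussian noise on the survival scale
#'   (values are truncated to \[0, 1\]).
#' @param seed integer seed (optional).
#' @param at `"grid"` (default) samples a uniform time grid; `"corners"`
#'   samples the exact step corners (plus the follow-up end), which makes
#'   the round trip lossless when `jitter_sd = 0`.
#' @return a [digitizedCurve()].
#' @export
digitizeEmulator <- function(curve, n_points, jitter_sd = 0.005, seed = NULL,
                             at = c("grid", "corners")) {
  at <- match.arg(at)
  stopifnot(inherits(curve, "kmCurve"))
  if (n_points < 2L) stop("n_points must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  if (at == "corners") {
    tm <- c(0, curve$times, curve$max_time)
    sv <- c(1, curve$survival, if (length(curve$survival))
      curve$survival[length(curve$survival)] else 1)
    dup <- duplicated(tm)
    tm <- tm[!dup]; sv <- sv[!dup]
  } else {
    tm <- seq(0, curve$max_time, length.out = n_points)
    idx <- findInterval(tm, curve$times)
    sv <- ifelse(idx == 0L, 1, curve$survival[pmax(idx, 1L)])
  }
  if (jitter_sd > 0)
    sv <- pmin(1, pmax(0, sv + stats::rnorm(length(sv), 0, jitter_sd)))
  # shuffle a few adjacent pairs to emulate out-of-order extraction
  if (length(tm) > 3L) {
    nswap <- max(1L, length(tm) %/% 20L)
    pos <- sample(seq_len(length(tm) - 1L), nswap)
    for (p in pos) {
      tm[c(p, p + 1L)] <- tm[c(p + 1L, p)]
      sv[c(p, p + 1L)] <- sv[c(p + 1L, p)]
    }
  }
  digitizedCurve(tm, sv, n_arm = curve$n_total,
                 max_follow_up = curve$max_time)
}
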