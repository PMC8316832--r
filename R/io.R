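# ---- trial metadata ---------------------------------------------------------

#' Load a trial metadata table
#'
#' Reads the CSV of included trials (one row per trial: id, phase, arm
#' labels, primary endpoint, randomized n, response-classification system,
#' number of arms) and validates it. A copy of the seven-trial ES-SCLC
#' first-line immunotherapy table ships with the package
#' (`system.file("extdata", "sclc_trials_table.csv", package = "milesurv")`).
#'
#' @param path CSV file with header columns `trial_id`, `phase`,
#'   `experimental_arms` (labels separated by `;`), `control_arm`,
#'   `primary_endpoint`, `n_patients`, `response_system`, `n_arms`.
#' @return An object of class `trialMeta` (validated data frame).
#' @export
loadTrials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("trial_id", "phase", "experimental_arms", "control_arm",
           "primary_endpoint", "n_patients", "response_system", "n_arms")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing column: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("no trials")
  if (anyDuplicated(df$trial_id))
    stop("duplicate trial_id: ",
         paste(unique(df$trial_id[duplicated(df$trial_id)]), collapse = ", "))
  for (col in c("n_patients", "n_arms")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      stop("non-numeric ", col, " in row ", bad[1])
    df[[col]] <- as.numeric(df[[col]])
  }
  if (any(df$n_patients <= 0)) stop("n_patients must be positive")
  if (any(df$n_arms < 2)) stop("n_arms must be >= 2")
  class(df) <- c("trialMeta", "data.frame")
  df
}

#' Totals over a trial metadata table
#'
#' @param trials a [loadTrials()] table.
#' @return list with `n_trials`, `n_patients` (sum of randomized patients),
#'   `n_arms` (sum of arms) and `n_comparisons` (each experimental arm vs
#'   its trial's shared control: `sum(n_arms - 1)`).
#' @export
trialTotals <- function(trials) {
  list(n_trials = nrow(trials),
       n_patients = sum(trials$n_patients),
       n_arms = sum(trials$n_arms),
       n_comparisons = sum(trials$n_arms - 1))
}

# ---- subject-level and curve tables ----------------------------------------

#' Read and write subject-level records
#'
#' Long-format CSV with columns `trial_id`, `arm_id`, `time_months`,
#' `event`, `endpoint` (`OS` or `PFS`).
#'
#' @param path CSV path.
#' @return `readSubjects`: the validated data frame.
#' @export
readSubjects <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("trial_id", "arm_id", "time_months", "event", "endpoint")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing column: ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$time_months)) || any(df$time_months <= 0))
    stop("invalid time")
  if (!all(df$event %in% 0:1)) stop("event must be 0/1")
  if (!all(df$endpoint %in% c("OS", "PFS"))) stop("endpoint must be OS or PFS")
  df
}

#' @rdname readSubjects
#' @param subjects long-format subject records as returned by
#'   [simulateTrialSuite()]`$subjects`.
#' @export
writeSubjects <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE)
  invisible(path)
}

#' Export a Kaplan-Meier curve as a step table
#'
#' @param curve a [kmFit()] curve.
#' @param path CSV path; columns `time`, `survival`, `at_risk`, `events`.
#' @export
writeCurve <- function(curve, path) {
  stopifnot(inherits(curve, "kmCurve"))
  utils::write.csv(data.frame(time = curve$times, survival = curve$survival,
                              at_risk = curve$at_risk, events = curve$events),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read digitized survival-curve coordinates
#'
#' Two-column CSV with header `time_months`, `survival` — one file per arm,
#' as produced by a figure digitizer.
#'
#' @param path CSV path.
#' @param n_arm,max_follow_up optional metadata attached to the curve.
#' @return a [digitizedCurve()].
#' @export
readDigitizedCurve <- function(path, n_arm = NA_integer_,
                               max_follow_up = NA_real_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_months", "survival") %in% names(df)))
    stop("coordinate file needs columns time_months, survival: ", path)
  digitizedCurve(df$time_months, df$survival, n_arm = n_arm,
                 max_follow_up = max_follow_up)
}

# ---- arm-level effect tables and pairing -----------------------------------

#' Pair an arm-level effect table into comparison records
#'
#' Takes an arm-level table (one row per arm with its size, milestone rate,
#' RMSTs and responder counts; hazard ratios recorded on the experimental
#' rows) and forms one comparison per experimental arm against its trial's
#' control arm — so a 3-arm trial contributes two comparisons sharing the
#' control. Ratios use the uniform experimental/control direction. Missing
#' arm values propagate to `NA` in the comparison (per-surrogate
#' complete-case handling happens in [evaluateAll()]).
#'
#' @param arm_table data frame with columns `trial_id`, `arm_id`, `role`
#'   (`"experimental"`/`"control"`), `n`, and optionally `hr_os`, `hr_pfs`
#'   (experimental rows), `os_milestone_12`, `os_rmst_12`, `os_rmst_24`,
#'   `orr_responders`, `dcr_responders`.
#' @return comparison data frame as consumed by [evaluateAll()].
#' @export
pairComparisons <- function(arm_table) {
  req <- c("trial_id", "arm_id", "role", "n")
  miss <- setdiff(req, names(arm_table))
  if (length(miss)) stop("missing column: ", paste(miss, collapse = ", "))
  if (!all(arm_table$role %in% c("experimental", "control")))
    stop("role must be experimental or control")
  opt <- function(row, col) if (col %in% names(arm_table)) row[[col]] else NA_real_
  ratioNA <- function(a, b) if (is.na(a) || is.na(b)) NA_real_ else effectRatio(a, b)
  rrNA <- function(re, ne, rc, nc) {
    if (anyNA(c(re, ne, rc, nc))) return(NA_real_)
    rrFromCounts(re, ne, rc, nc)
  }
  rows <- list()
  for (tid in unique(arm_table$trial_id)) {
    sub <- arm_table[arm_table$trial_id == tid, , drop = FALSE]
    ctrl <- sub[sub$role == "control", , drop = FALSE]
    if (nrow(ctrl) != 1L)
      stop("trial ", tid, " must have exactly one control arm")
    exps <- sub[sub$role == "experimental", , drop = FALSE]
    if (nrow(exps) == 0L) stop("trial ", tid, " has no experimental arm")
    for (j in seq_len(nrow(exps))) {
      e <- exps[j, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        trial_id = tid,
        experimental_arm_id = e$arm_id,
        control_arm_id = ctrl$arm_id,
        n_total = e$n + ctrl$n,
        hr_os = opt(e, "hr_os"),
        hr_pfs = opt(e, "hr_pfs"),
        rr_orr = rrNA(opt(e, "orr_responders"), e$n,
                      opt(ctrl, "orr_responders"), ctrl$n),
        rr_dcr = rrNA(opt(e, "dcr_responders"), e$n,
                      opt(ctrl, "dcr_responders"), ctrl$n),
        ratio_milestone_12 = ratioNA(opt(e, "os_milestone_12"),
                                     opt(ctrl, "os_milestone_12")),
        ratio_rmst_12 = ratioNA(opt(e, "os_rmst_12"), opt(ctrl, "os_rmst_12")),
        ratio_rmst_24 = ratioNA(opt(e, "os_rmst_24"), opt(ctrl, "os_rmst_24")),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (any(!is.na(out$hr_os) & out$hr_os <= 0)) stop("non-positive hr_os")
  out
}

#' Load an arm-level effect table
#'
#' @param path CSV in the arm-level schema of [pairComparisons()].
#' @return the validated arm-level data frame.
#' @export
loadArmTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("trial_id", "arm_id", "role", "n")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing column: ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$n) | df$n <= 0)) stop("arm size n must be positive")
  df
}

# ---- pipeline ---------------------------------------------------------------

#' Analysis configuration
#'
#' Bundles the tunable analysis settings: milestone and RMST horizons, the
#' shared log base of the surrogacy regression, the weight column, the
#' integration rule for curve-derived RMSTs, the confidence level and the
#' seed.
#'
#' @param tau_milestone milestone horizon in months (default 12).
#' @param taus_rmst RMST horizons in months (default `c(12, 24)`).
#' @param log_base shared log base (default 10).
#' @param weight_col regression weight column (default `"n_total"`).
#' @param integration `"step"` or `"trapezoid"` for curve-derived RMSTs.
#' @param conf_level confidence level in (0, 1).
#' @param seed integer seed for any stochastic step.
#' @return An object of class `runConfig` (validated list).
#' @export
runConfig <- function(tau_milestone = 12, taus_rmst = c(12, 24),
                      log_base = 10, weight_col = "n_total",
                      integration = c("step", "trapezoid"),
                      conf_level = 0.95, seed = 1L) {
  integration <- match.arg(integration)
  if (any(c(tau_milestone, taus_rmst) <= 0)) stop("taus must be positive")
  if (conf_level <= 0 || conf_level >= 1) stop("conf_level must be in (0, 1)")
  structure(list(tau_milestone = tau_milestone, taus_rmst = taus_rmst,
                 log_base = log_base, weight_col = weight_col,
                 integration = integration, conf_level = conf_level,
                 seed = as.integer(seed)),
            class = "runConfig")
}

#' Run the digitized-curve surrogacy pipeline
#'
#' End-to-end analysis of a set of trials whose survival curves were
#' digitized from published figures: per arm, read and clean the coordinate
#' file, extract the milestone rate and RMSTs; pair experimental arms with
#' their control; fit every candidate surrogate with
#' [evaluateAll()]; and (optionally) write the comparison table, the
#' results table, a plain-text report with the fitted regression equations,
#' and a log line for every decision (integration mode, exclusions and
#' why). An RMST horizon not covered by an arm's digitized range yields
#' `NA` for that comparison only (logged); a horizon beyond every curve's
#' range aborts. On error, partial output files are removed.
#'
#' @param manifest data frame or CSV path mapping arms to coordinate files:
#'   columns `trial_id`, `arm_id`, `role`, `n`, `curve_file`, and
#'   optionally `hr_os`, `hr_pfs`, `orr_responders`, `dcr_responders`.
#'   Relative `curve_file` paths are resolved against the manifest's
#'   directory when `manifest` is a path.
#' @param config a [runConfig()].
#' @param out_dir output directory; `NULL` (default) writes nothing.
#' @return list with `arms` (per-arm extracted estimates), `comparisons`,
#'   `results` (a [evaluateAll()] summary) and `log` (character vector);
#'   invisibly when `out_dir` is given.
#' @export
runPipeline <- function(manifest, config = runConfig(), out_dir = NULL) {
  stopifnot(inherits(config, "runConfig"))
  base_dir <- "."
  if (is.character(manifest)) {
    base_dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  req <- c("trial_id", "arm_id", "role", "n", "curve_file")
  miss <- setdiff(req, names(manifest))
  if (length(miss))
    stop("[manifest] missing column: ", paste(miss, collapse = ", "))
  logs <- character(0)
  note <- function(...) logs <<- c(logs, sprintf(...))
  note("integration mode: %s; log base: %g; weights: %s",
       config$integration, config$log_base, config$weight_col)

  arm_rows <- list()
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, , drop = FALSE]
    f <- m$curve_file
    if (!file.exists(f)) f <- file.path(base_dir, m$curve_file)
    if (!file.exists(f))
      stop("[curves] coordinate file not found: ", m$curve_file)
    cc <- cleanCurve(readDigitizedCurve(f, n_arm = m$n))
    row <- data.frame(trial_id = m$trial_id, arm_id = m$arm_id,
                      role = m$role, n = m$n, stringsAsFactors = FALSE)
    tmax <- max(cc$time)
    if (config$tau_milestone <= tmax) {
      row$os_milestone_12 <- milestoneRate(cc, config$tau_milestone)$rate
    } else {
      row$os_milestone_12 <- NA_real_
      note("excluded: %s/%s milestone %g mo beyond digitized range (%.1f mo)",
           m$trial_id, m$arm_id, config$tau_milestone, tmax)
    }
    for (k in seq_along(config$taus_rmst)) {
      tau <- config$taus_rmst[k]
      col <- paste0("os_rmst_", tau)
      if (tau <= tmax) {
        row[[col]] <- rmst(cc, tau, mode = config$integration)$value
      } else {
        row[[col]] <- NA_real_
        note("excluded: %s/%s RMST horizon %g mo beyond digitized range (%.1f mo)",
             m$trial_id, m$arm_id, tau, tmax)
      }
    }
    for (col in c("hr_os", "hr_pfs", "orr_responders", "dcr_responders"))
      row[[col]] <- if (col %in% names(manifest)) m[[col]] else NA_real_
    arm_rows[[i]] <- row
  }
  arms <- do.call(rbind, arm_rows)
  for (col in c("os_milestone_12", paste0("os_rmst_", config$taus_rmst)))
    if (all(is.na(arms[[col]])))
      stop("[curves] horizon beyond digitized range for every curve (", col, ")")

  comparisons <- pairComparisons(arms)
  # surrogate columns must match the configured RMST horizons
  surrogates <- c("ratio_milestone_12",
                  paste0("ratio_rmst_", config$taus_rmst),
                  "hr_pfs", "rr_orr", "rr_dcr")
  results <- evaluateAll(comparisons, surrogates = intersect(surrogates,
                                                             names(comparisons)),
                         weight_col = config$weight_col,
                         log_base = config$log_base)
  for (sg in setdiff(surrogates, results$surrogate))
    note("surrogate %s: fewer than 3 usable comparisons, not fitted", sg)
  for (i in seq_len(nrow(results)))
    note("surrogate %s: n = %d complete-case comparisons",
         results$surrogate[i], results$n[i])

  out <- list(arms = arms, comparisons = comparisons, results = results,
              log = logs)
  if (is.null(out_dir)) return(out)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("comparisons.csv", "surrogacy_results.csv",
                                "report.txt", "run_log.txt"))
  ok <- FALSE
  on.exit(if (!ok) unlink(paths), add = TRUE)
  utils::write.csv(comparisons, paths[1], row.names = FALSE)
  utils::write.csv(as.data.frame(results), paths[2], row.names = FALSE)
  rpt <- c("Trial-level surrogacy of treatment effects for the OS hazard ratio",
           "",
           unlist(lapply(attr(results, "results"), function(r)
             c(formatEquation(r),
               sprintf("  n = %d, Spearman r = %.3f (P = %.4g), R^2 = %.3f (P = %.4g)",
                       r$n_comparisons, r$spearman_r, r$spearman_p,
                       r$r_squared, r$regression_p), ""))))
  writeLines(rpt, paths[3])
  writeLines(logs, paths[4])
  ok <- TRUE
  invisible(out)
}
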