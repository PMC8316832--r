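# Independent oracles and fixture builders used across the suite.

# Empirical survival function at time t for uncensored data: P(T > t).
empiricalSurvival <- function(times, t) mean(times > t)

# Brute-force weighted least squares via the normal equations, independent
# of lm(): minimizes sum w (y - a - b x)^2.
bfWls <- function(x, y, w) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  e <- y - X %*% beta
  ybar <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * e^2) / sum(w * (y - ybar)^2)
  list(intercept = beta[1], slope = beta[2], r_squared = r2)
}

# Weighted Pearson correlation (for the R^2 == squared-correlation check).
weightedCor <- function(x, y, w) {
  mx <- sum(w * x) / sum(w); my <- sum(w * y) / sum(w)
  sxy <- sum(w * (x - mx) * (y - my))
  sxy / sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
}

# The hand-derived censored worked example: events at 2, 5, 7 with one
# censoring at 4 (n = 4). S steps: 0.75, 0.375, 0; RMST to 8 is 5.0.
censoredExample <- function() data.frame(time = c(2, 4, 5, 7),
                                         event = c(1, 0, 1, 1))

# Arm-level effect table in the ST2-style schema, entirely synthetic:
# 7 trials (two 3-arm), with the missingness pattern of the published
# analysis — 24-month RMST unavailable for one 2-arm trial, ORR for one
# 2-arm trial, DCR for one 3-arm and one 2-arm trial — so the per-surrogate
# complete-case counts are 9, 9, 8, 9, 8, 6.
syntheticArmTable <- function(seed = 404) {
  set.seed(seed)
  n_arms <- c(2, 2, 2, 3, 3, 2, 2)
  rows <- list()
  for (i in seq_along(n_arms)) {
    tid <- sprintf("T%02d", i)
    n <- sample(60:450, 1)
    ctrl <- data.frame(trial_id = tid, arm_id = "C", role = "control", n = n,
                       os_milestone_12 = runif(1, 0.3, 0.5),
                       os_rmst_12 = runif(1, 7, 9),
                       os_rmst_24 = runif(1, 9, 12),
                       orr_responders = rbinom(1, n, 0.58),
                       dcr_responders = rbinom(1, n, 0.8),
                       hr_os = NA_real_, hr_pfs = NA_real_,
                       stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- ctrl
    for (k in seq_len(n_arms[i] - 1)) {
      rows[[length(rows) + 1L]] <- data.frame(
        trial_id = tid, arm_id = paste0("E", k), role = "experimental", n = n,
        os_milestone_12 = runif(1, 0.35, 0.6),
        os_rmst_12 = runif(1, 7.5, 9.5),
        os_rmst_24 = runif(1, 10, 14),
        orr_responders = rbinom(1, n, 0.62),
        dcr_responders = rbinom(1, n, 0.85),
        hr_os = runif(1, 0.6, 1.05), hr_pfs = runif(1, 0.6, 1.1),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$os_rmst_24[tab$trial_id == "T03"] <- NA          # 2-arm: 9 -> 8
  tab$orr_responders[tab$trial_id == "T06"] <- NA      # 2-arm: 9 -> 8
  tab$dcr_responders[tab$trial_id %in% c("T04", "T07")] <- NA  # 3-arm + 2-arm: 9 -> 6
  tab
}

# Small random survival datasets (with ties and censoring) for oracle sweeps.
randomSurvData <- function(n, tie_pool = 6, cens_prob = 0.3) {
  data.frame(time = sample(seq_len(tie_pool), n, replace = TRUE) +
               sample(c(0, 0.5), n, replace = TRUE),
             event = rbinom(n, 1, 1 - cens_prob))
}
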