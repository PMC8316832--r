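test_that("scenario validation rejects invalid generative parameters", {
  expect_error(trialScenario(hr_post_delay = -0.5), "hr_post_delay")
  expect_error(trialScenario(cure_fraction = 1), "cure_fraction")
  expect_error(trialScenario(cure_fraction = 0.1, admin_cutoff_months = Inf),
               "finite admin_cutoff")
  expect_error(trialScenario(delay_months = -1), "delay_months")
  expect_error(trialScenario(dcr_control = 0.4, orr_control = 0.6), "DCR")
  expect_error(trialScenario(admin_cutoff_months = 10, accrual_months = 12),
               "exceed")
  expect_error(trialScenario(n_experimental_arms = 3), "1 or 2")
})

test_that("same seed and scenario give identical output; nothing censors when nothing can", {
  sc <- trialScenario(n_per_arm = 50, seed = 99)
  a1 <- simulateArm(sc, "E1")
  a2 <- simulateArm(sc, "E1")
  expect_identical(a1, a2)

  sc0 <- trialScenario(n_per_arm = 200, dropout_rate = 0,
                       admin_cutoff_months = Inf, cure_fraction = 0)
  a <- simulateArm(sc0, "control", seed = 1)
  expect_true(all(a$os_event == 1))
  expect_true(all(a$pfs_event == 1))
  expect_true(all(a$pfs_time <= a$os_time))
  expect_true(all(a$os_time > 0))
})

test_that("exponential control arm matches the closed-form law within 1%", {
  sc <- trialScenario(n_per_arm = 100000, dropout_rate = 0,
                      admin_cutoff_months = Inf)
  a <- simulateArm(sc, "control", seed = 12)
  lam <- log(2) / 10
  expect_lt(abs(median(a$os_time) - 10) / 10, 0.01)
  expect_lt(abs(mean(a$os_time > 12) - exp(-12 * lam)) / exp(-12 * lam), 0.01)
})

test_that("inverse-transform sampler matches the analytic piecewise law (KS < 0.01)", {
  sc <- trialScenario(n_per_arm = 100000,
                      control_hazard = list(breaks = c(4, 9),
                                            rates = c(0.04, 0.09, 0.06)),
                      delay_months = 6, hr_post_delay = 0.6,
                      cure_fraction = 0.1, dropout_rate = 0,
                      admin_cutoff_months = 200, accrual_months = 1)
  a <- simulateArm(sc, "E1", seed = 13)
  grid <- seq(0.5, 60, by = 0.5)
  emp <- vapply(grid, function(t) mean(a$os_time > t), numeric(1))
  ana <- scenarioSurvival(sc, grid, "E1")
  expect_lt(max(abs(emp - ana)), 0.01)
})

test_that("arms coincide before the effect delay and separate after", {
  sc <- trialScenario(n_per_arm = 50000, delay_months = 6, hr_post_delay = 0.6,
                      dropout_rate = 0, admin_cutoff_months = Inf)
  # analytic curves are identical on [0, delay]
  tt <- seq(0.5, 6, by = 0.5)
  expect_equal(scenarioSurvival(sc, tt, "E1"), scenarioSurvival(sc, tt, "control"))
  expect_lt(scenarioSurvival(sc, 24, "control"), scenarioSurvival(sc, 24, "E1"))
  # simulated KM curves overlap there within Monte-Carlo noise
  e <- simulateArm(sc, "E1", seed = 14)
  c0 <- simulateArm(sc, "control", seed = 15)
  sup <- max(abs(vapply(tt, function(t) mean(e$os_time > t) - mean(c0$os_time > t),
                        numeric(1))))
  expect_lt(sup, 0.015)
})

test_that("estimates recover the generative parameters", {
  # delay = 0: Cox recovers the hazard ratio within 10% at n = 1000/arm
  sc <- trialScenario(n_per_arm = 1000, delay_months = 0, hr_post_delay = 0.7,
                      dropout_rate = 0, admin_cutoff_months = Inf)
  set.seed(16)
  e <- simulateArm(sc, "E1", seed = NULL)
  c0 <- simulateArm(sc, "control", seed = NULL)
  fit <- coxHR(c(e$os_time, c0$os_time), c(e$os_event, c0$os_event),
               rep(1:0, each = 1000))
  expect_lt(abs(fit$hr - 0.7) / 0.7, 0.10)

  # RMST ratio from simulation matches the analytic ratio within 2% at n = 50000
  sc2 <- trialScenario(n_per_arm = 50000, delay_months = 6, hr_post_delay = 0.65,
                       dropout_rate = 0, admin_cutoff_months = Inf)
  e2 <- simulateArm(sc2, "E1", seed = 17)
  c2 <- simulateArm(sc2, "control", seed = 18)
  est <- rmst(kmFit(e2$os_time, e2$os_event), 24)$value /
    rmst(kmFit(c2$os_time, c2$os_event), 24)$value
  truth <- scenarioRmst(sc2, 24, "E1") / scenarioRmst(sc2, 24, "control")
  expect_lt(abs(est - truth) / truth, 0.02)
})

test_that("suite bookkeeping mirrors the 7-trial/16-arm/9-comparison design", {
  suite <- simulateTrialSuite(7, c(0.7, 0.8, 0.9), trialScenario(n_per_arm = 40),
                              n_arms = c(2, 2, 2, 3, 3, 2, 2), seed = 19)
  expect_equal(nrow(suite$comparisons), 9)
  arms <- unique(suite$subjects[c("trial_id", "arm_id")])
  expect_equal(nrow(arms), 16)
  expect_true(all(c("true_hr_post_delay", "true_ratio_rmst_24") %in%
                    names(suite$comparisons)))
  # suites are reproducible as a whole from the single seed
  suite2 <- simulateTrialSuite(7, c(0.7, 0.8, 0.9), trialScenario(n_per_arm = 40),
                               n_arms = c(2, 2, 2, 3, 3, 2, 2), seed = 19)
  expect_identical(suite$comparisons, suite2$comparisons)
})

test_that("beneficial effects produce ratios above 1 and OS hazard ratios below 1", {
  suite <- simulateTrialSuite(6, 0.55, trialScenario(n_per_arm = 400), seed = 20)
  cmp <- suite$comparisons
  # the generative law itself has the sign structure
  expect_true(all(cmp$true_ratio_rmst_24 > 1))
  expect_true(all(cmp$true_ratio_milestone_12 > 1))
  # estimates carry it on average, and comparison-wise wherever the
  # estimated benefit is clear (noisy near-null trials may straddle 1)
  expect_true(all(cmp$hr_os < 1))
  expect_gt(mean(cmp$ratio_rmst_24), 1)
  expect_gt(mean(cmp$ratio_milestone_12), 1)
  clear <- cmp$hr_os < 0.85
  expect_true(all(cmp$ratio_rmst_24[clear] > 1))
  # and the fitted relation has the right sign
  fit <- wlsLogLogFit(cmp, "ratio_rmst_24")
  expect_lt(fit$slope, 0)
  expect_lt(fit$spearman_r, 0)
})

test_that("digitize emulator produces valid raw curves at the boundary", {
  sc <- trialScenario(n_per_arm = 60)
  km <- kmFit(simulateArm(sc, "control", seed = 21)$os_time,
              simulateArm(sc, "control", seed = 21)$os_event)
  d <- digitizeEmulator(km, 2, jitter_sd = 0, seed = 22)
  expect_s3_class(cleanCurve(d), "cleanCurve")
  expect_error(digitizeEmulator(km, 1), "n_points")
})
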