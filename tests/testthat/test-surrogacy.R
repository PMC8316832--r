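test_that("effect ratios follow the experimental/control convention", {
  expect_equal(effectRatio(0.5, 0.5), 1)
  expect_equal(effectRatio(6, 4), 1.5)
  set.seed(1)
  for (rep in 1:20) {
    a <- runif(1, 0.01, 10); b <- runif(1, 0.01, 10)
    expect_equal(effectRatio(a, b) * effectRatio(b, a), 1, tolerance = 1e-12)
  }
  expect_error(effectRatio(0, 1), "non-positive")
  expect_error(effectRatio(1, -2), "non-positive")
})

test_that("relative risk from counts handles zeros by policy", {
  expect_equal(rrFromCounts(30, 50, 20, 50), 1.5)
  expect_equal(rrFromCounts(10, 40, 10, 40), 1)
  expect_warning(rr <- rrFromCounts(0, 50, 10, 50), "zero responders")
  expect_equal(rr, 0)
  expect_error(rrFromCounts(10, 50, 0, 50), "undefined relative risk")
  expect_error(rrFromCounts(60, 50, 10, 50), "exceed")
})

test_that("Spearman correlation is a rank statistic with sensible p-values", {
  expect_equal(spearmanCorr(1:3, 3:1)$r, -1)
  expect_equal(spearmanCorr(1:5, exp(1:5))$r, 1)
  expect_equal(spearmanCorr(1:5, exp(1:5))$p, 0)

  set.seed(2)
  for (rep in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    r0 <- spearmanCorr(x, y)$r
    # matches the standard implementation
    expect_equal(r0, cor(x, y, method = "spearman"), tolerance = 1e-12)
    # invariant under strictly monotone transforms; sign flips under negation
    expect_equal(spearmanCorr(exp(x), y^3 * 2 + y)$r, r0, tolerance = 1e-12)
    expect_equal(spearmanCorr(-x, y)$r, -r0, tolerance = 1e-12)
  }
  expect_error(spearmanCorr(rep(1, 5), 1:5), "zero rank variance")
  expect_error(spearmanCorr(1:2, 2:1), "at least 3")
})

test_that("exact permutation p agrees with the exact reference for untied data", {
  set.seed(3)
  for (n in c(5, 6, 7)) {
    x <- rnorm(n); y <- rnorm(n)
    mine <- spearmanCorr(x, y, method = "exact")
    ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
    expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  }
  expect_error(spearmanCorr(rnorm(11), rnorm(11), method = "exact"), "n <= 10")
})

test_that("weighted log-log fit matches the normal-equation oracle to 1e-10", {
  set.seed(4)
  for (rep in 1:25) {
    k <- sample(3:12, 1)
    comp <- data.frame(hr_os = exp(rnorm(k, -0.2, 0.3)),
                       ratio_rmst_24 = exp(rnorm(k, 0.1, 0.2)),
                       n_total = sample(60:900, k))
    fit <- wlsLogLogFit(comp, "ratio_rmst_24")
    oracle <- bfWls(log10(comp$ratio_rmst_24), log10(comp$hr_os), comp$n_total)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-10)
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
    expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-10)
    # single-regressor WLS: R^2 is the squared weighted correlation
    expect_equal(fit$r_squared,
                 weightedCor(log10(comp$ratio_rmst_24), log10(comp$hr_os),
                             comp$n_total)^2,
                 tolerance = 1e-10)
  }
})

test_that("weighted fit is invariant to weight scale and recovers exact linear data", {
  comp <- data.frame(hr_os = 10^c(0, -0.5, -1), ratio_rmst_24 = 10^c(0, 1, 2),
                     n_total = c(100, 100, 100))
  fit <- wlsLogLogFit(comp, "ratio_rmst_24")
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$slope, -0.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  set.seed(5)
  comp <- data.frame(hr_os = exp(rnorm(8, -0.2, 0.3)),
                     ratio_rmst_24 = exp(rnorm(8, 0.1, 0.2)),
                     n_total = sample(60:900, 8))
  f1 <- wlsLogLogFit(comp, "ratio_rmst_24")
  comp10 <- comp; comp10$n_total <- comp10$n_total * 10
  f2 <- wlsLogLogFit(comp10, "ratio_rmst_24")
  for (fld in c("intercept", "slope", "r_squared", "regression_p"))
    expect_equal(f1[[fld]], f2[[fld]], tolerance = 1e-12)

  # slope and R^2 are log-base invariant; the intercept is not
  fe <- wlsLogLogFit(comp, "ratio_rmst_24", log_base = exp(1))
  expect_equal(fe$slope, f1$slope, tolerance = 1e-12)
  expect_equal(fe$r_squared, f1$r_squared, tolerance = 1e-12)

  expect_error(wlsLogLogFit(comp[1:2, ], "ratio_rmst_24"), "insufficient comparisons")
  compbad <- comp; compbad$hr_os[1] <- -1
  expect_error(wlsLogLogFit(compbad, "ratio_rmst_24"), "non-positive")
})

test_that("evaluateAll fits per-surrogate complete cases and detects exact relations", {
  set.seed(6)
  k <- 9
  comp <- data.frame(hr_os = exp(rnorm(k, -0.2, 0.3)),
                     ratio_milestone_12 = exp(rnorm(k, 0.1, 0.2)),
                     hr_pfs = exp(rnorm(k, -0.1, 0.3)),
                     n_total = sample(100:900, k))
  # induce an exact power law for one surrogate: log hr_os = c + d log ratio
  comp$ratio_rmst_24 <- 10^((log10(comp$hr_os) + 0.05) / -1.8)
  res <- evaluateAll(comp)
  expect_equal(res$r_squared[res$surrogate == "ratio_rmst_24"], 1, tolerance = 1e-10)
  expect_equal(res$slope[res$surrogate == "ratio_rmst_24"], -1.8, tolerance = 1e-10)

  # permuting one surrogate's values destroys its fit and leaves others alone
  set.seed(7)
  comp2 <- comp
  comp2$ratio_rmst_24 <- comp2$ratio_rmst_24[sample(k)]
  res2 <- evaluateAll(comp2)
  expect_lt(res2$r_squared[res2$surrogate == "ratio_rmst_24"], 0.5)
  expect_equal(res2$r_squared[res2$surrogate == "ratio_milestone_12"],
               res$r_squared[res$surrogate == "ratio_milestone_12"])

  # missing values: per-surrogate complete case with varying n
  comp$ratio_milestone_12[1:7] <- NA    # only 2 usable -> dropped
  comp$hr_pfs[1:3] <- NA                # 6 usable -> fitted with n = 6
  res3 <- evaluateAll(comp)
  expect_false("ratio_milestone_12" %in% res3$surrogate)
  expect_equal(res3$n[res3$surrogate == "hr_pfs"], 6)
})

test_that("regression equations render in the conventional report form", {
  fit <- wlsLogLogFit(data.frame(hr_os = 10^c(0, -0.5, -1),
                                 ratio_rmst_24 = 10^c(0, 1, 2),
                                 n_total = rep(100, 3)), "ratio_rmst_24")
  expect_match(formatEquation(fit), "^Log \\(HR_OS\\) = 0 - 0\\.5 x Log \\(ratio_rmst_24\\)$")
})
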