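test_that("mode coefficient patterns carry the designed sparse structure", {
  m1 <- modeCoefficients(1, 20)
  expect_equal(m1$alpha[1:12],
               c(0.30, 0.36, 0.45, 0.48, 0.60, 0.72, 0.90, 1.20,
                 0, 0, 1.20, 1.20))
  expect_equal(m1$beta[1:12],
               c(0.20, 0.24, 0.30, 0.32, 0.40, 0.48, 0.60, 0.80,
                 0.80, 0.80, 0, 0))
  expect_equal(m1$alpha[1:8] * m1$beta[1:8],
               c(0.0600, 0.0864, 0.1350, 0.1536, 0.2400, 0.3456,
                 0.5400, 0.9600))
  m2 <- modeCoefficients(2, 15)
  expect_equal(m2$alpha[1:8],
               c(0.25, 0.30, 0.375, 0.40, 0.50, 0.60, 0.75, 1.00))
  expect_equal(m2$alpha[1:8], m2$beta[1:8])
  m3 <- modeCoefficients(3, 12)
  expect_equal(m3$beta[1:8],
               c(0.30, 0.36, 0.45, 0.48, 0.60, 0.72, 0.90, 1.20))
  for (m in list(m1, m2, m3)) {
    expect_equal(sum(m$alpha * m$beta != 0), 8L)
    expect_true(all(m$alpha[9:10] == 0) && all(m$beta[11:12] == 0))
    if (length(m$alpha) > 12)
      expect_true(all(m$alpha[13:length(m$alpha)] == 0) &&
                  all(m$beta[13:length(m$beta)] == 0))
  }
  expect_error(modeCoefficients(4, 20), "mode")
  expect_error(modeCoefficients(1, 10), "at least 12")
})

test_that("confounder generator matches its stated distribution", {
  expect_equal(dim(generateConfounders(0)), c(0L, 10L))
  expect_error(generateConfounders(-1), "non-negative")
  Z <- generateConfounders(50000, seed = 101)
  expect_true(all(Z[, 1:5] %in% c(0, 1)))
  expect_true(all(abs(colMeans(Z[, 1:5]) - 0.3) < 0.01))
  expect_true(abs(cor(Z[, 6], Z[, 7]) - 0.3) < 0.02)
  expect_true(all(abs(apply(Z[, 6:10], 2, sd) - 1) < 0.02))
})

test_that("exposure assignment follows the logistic model", {
  Z <- generateConfounders(10000, seed = 5)
  # all-zero coefficients: every assignment probability is 1/2
  X0 <- generateExposure(Z, l = rep(0, 10), l0 = 0, seed = 6)
  expect_true(abs(mean(X0) - 0.5) < 0.02)
  # overwhelming intercept forces treatment
  X1 <- generateExposure(Z[1:100, ], l = rep(0, 10), l0 = 20, seed = 7)
  expect_true(all(X1 == 1))
  expect_error(generateExposure(Z, l = rep(0, 3)), "length")
})

test_that("datasets are reproducible and follow the generating model", {
  cfg <- simulationConfig(n = 150, p = 40, mode = 1, seed = 99)
  d1 <- generateDataset(cfg)
  d2 <- generateDataset(cfg)
  expect_identical(mediators(d1), mediators(d2))
  expect_identical(outcome(d1), outcome(d2))
  expect_identical(exposure(d1), exposure(d2))

  # degenerate noiseless model: Y = c + gamma X exactly
  cfg0 <- simulationConfig(n = 50, p = 12, seed = 1, sigmaE = 0, sigmaXi = 0,
                           Theta = rep(0, 10), Phi = rep(0, 10),
                           alpha = rep(0, 12), beta = rep(0, 12))
  d0 <- generateDataset(cfg0)
  expect_equal(outcome(d0), 0.5 + 0.5 * exposure(d0))

  # per-mediator regression recovers alpha1 = 0.30 at large n
  db <- generateDataset(simulationConfig(n = 20000, p = 12, seed = 17))
  f <- lm(mediators(db)[, 1] ~ exposure(db) + confounders(db))
  a1 <- summary(f)$coefficients[2, ]
  expect_lt(abs(a1["Estimate"] - 0.30) / a1["Std. Error"], 3)
})

test_that("confounding is real: the naive direct-effect estimate is biased", {
  ds <- generateDataset(simulationConfig(n = 5000, p = 12, seed = 23))
  f <- summary(lm(outcome(ds) ~ exposure(ds)))$coefficients
  # true gamma = 0.5 plus the full mediated effect; even against the total
  # effect the unadjusted contrast is off by many SEs
  cf <- modeCoefficients(1, 12)
  totalEffect <- 0.5 + sum(cf$alpha * cf$beta)
  expect_gt(abs(f[2, 1] - totalEffect) / f[2, 2], 3)
})

test_that("MediationDataset validates its inputs", {
  M <- matrix(rnorm(20), 5, 4)
  expect_error(MediationDataset(X = c(0, 1, 2, 0, 1), Y = rnorm(5), M = M),
               "binary")
  expect_error(MediationDataset(X = c(0, 1, 1, 0), Y = rnorm(4), M = M),
               "agree")
  ds <- MediationDataset(X = c(0, 1, 1, 0, 1), Y = rnorm(5), M = M)
  expect_s4_class(ds, "MediationDataset")
  expect_equal(ncol(confounders(ds)), 0L)
})
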