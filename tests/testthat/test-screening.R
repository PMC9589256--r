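test_that("screening dimension follows 2n/ln(n), capped at p", {
  expect_identical(sisDimension(300, 1000), 106L)
  expect_identical(sisDimension(500, 10000), 161L)
  expect_identical(sisDimension(300, 50), 50L)
  expect_error(sisDimension(1, 100), "at least 2")
})

test_that("marginal estimators agree with explicit normal-equations oracles", {
  set.seed(77)
  n <- 24
  X <- rbinom(n, 1, 0.5)
  S <- plogis(rnorm(n))
  Z <- matrix(rnorm(n * 3), n, 3)
  m <- rnorm(n)
  Y <- 1 + 0.5 * X + 2 * m + rnorm(n)

  ps <- marginalBetaPS(Y, X, m, S)
  oPS <- normalEquationsOracle(Y, cbind(1, X, S, m))
  expect_equal(ps$beta, oPS$coef[4], tolerance = 1e-10)
  expect_equal(ps$se, oPS$se[4], tolerance = 1e-10)

  cv <- marginalBetaCov(Y, X, m, Z)
  oCV <- normalEquationsOracle(Y, cbind(1, X, Z, m))
  expect_equal(cv$beta, oCV$coef[6], tolerance = 1e-10)
  expect_equal(cv$se, oCV$se[6], tolerance = 1e-10)

  # zero-column Z reduces to the unadjusted model
  cv0 <- marginalBetaCov(Y, X, m, NULL)
  o0 <- normalEquationsOracle(Y, cbind(1, X, m))
  expect_equal(cv0$beta, o0$coef[3], tolerance = 1e-10)
})

test_that("two-step weighted estimator matches its brute-force oracle", {
  set.seed(11)
  n <- 8
  X <- c(1, 0, 1, 1, 0, 0, 1, 0)
  m <- rnorm(n)
  Y <- 0.3 + 0.8 * X + 1.5 * m + rnorm(n, sd = 0.3)
  w <- runif(n, 0.8, 4)
  est <- marginalBetaTwoStep(Y, X, m, w)
  oracle <- twoStepOracle(Y, X, m, w)
  expect_equal(est$beta, oracle$beta, tolerance = 1e-6)
  expect_equal(est$se, oracle$se, tolerance = 1e-6)
  expect_error(marginalBetaTwoStep(Y, X, m, c(w[-1], 0)), "positive")
})

test_that("two-step reduces to plain least squares with unit weights", {
  set.seed(12)
  n <- 60
  X <- rep(c(0, 1), each = n / 2) - 0.5      # centered exposure
  m <- rnorm(n)
  m <- resid(lm(m ~ X))                       # orthogonal to X
  Y <- 2 * m + rnorm(n, sd = 0.1)
  est <- marginalBetaTwoStep(Y, X, m, rep(1, n))
  ols <- coef(lm(Y ~ m))[2]
  expect_equal(est$beta, unname(ols), tolerance = 1e-8)
})

test_that("noiseless signals are recovered exactly", {
  n <- 30
  X <- rep(c(0, 1), length.out = n)
  S <- rep(0.5, n) + seq(-0.1, 0.1, length.out = n)
  m <- rnorm(n)
  m <- resid(lm(m ~ X + S))
  Y <- 3 * m
  expect_equal(marginalBetaPS(Y, X, m, S)$beta, 3, tolerance = 1e-8)
  # constant mediator columns are flagged, not ranked
  res <- marginalBetaPS(Y, X, cbind(m, rep(1, n)), S)
  expect_false(res$ok[2])
  expect_identical(res$beta[2], 0)
})

test_that("screening ranks by absolute marginal coefficient", {
  ds <- smallDataset(n = 100, p = 30, seed = 3)
  ps <- fitPropensity(exposure(ds), confounders(ds))
  scr <- screenMediators(ds, "PSU", ps, dOverride = 10)
  # brute-force rank on standardized mediators
  M <- scale(mediators(ds))
  bb <- abs(marginalBetaPS(outcome(ds), exposure(ds), M, psScores(ps))$beta)
  expect_identical(keptMediators(scr), order(-bb, seq_along(bb))[1:10])
  # p <= d keeps everything
  scrAll <- screenMediators(ds, "PSU", ps)
  expect_identical(sort(keptMediators(scrAll)), 1:30)
  # reported coefficients are on the original mediator scale
  k1 <- keptMediators(scr)[1]
  direct <- marginalBetaPS(outcome(ds), exposure(ds), mediators(ds)[, k1],
                           psScores(ps))
  expect_equal(unname(marginalBeta(scr)[1]), direct$beta, tolerance = 1e-10)
})

test_that("the strongest mediator is always screened across replicates", {
  for (s in 1:20) {
    ds <- generateDataset(simulationConfig(n = 500, p = 600, seed = s))
    ps <- fitPropensity(exposure(ds), confounders(ds))
    expect_true(8 %in% keptMediators(screenMediators(ds, "PSU", ps)))
  }
})

test_that("sure screening retains the true mediators at realistic rates", {
  ret <- matrix(FALSE, 50, 8)
  for (s in 1:50) {
    ds <- generateDataset(simulationConfig(n = 500, p = 1000, seed = s))
    ps <- fitPropensity(exposure(ds), confounders(ds))
    kept <- keptMediators(screenMediators(ds, "PSU", ps))
    ret[s, ] <- (1:8) %in% kept
  }
  # moderate-to-strong effects are essentially never lost; the weakest
  # two (indirect effects 0.06, 0.0864) survive most of the time
  expect_true(all(colMeans(ret)[3:8] >= 0.95))
  expect_gt(mean(rowSums(ret) == 8), 0.5)
  expect_gt(mean(ret[, 1]), 0.6)
})
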