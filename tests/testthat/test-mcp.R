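test_that("MCP penalty evaluates the tapered form with continuous saturation", {
  expect_identical(mcpPenalty(0, 1, 3), 0)
  expect_equal(mcpPenalty(0.5, 1, 3), 0.5 - 0.25 / 6)
  expect_equal(mcpPenalty(5, 1, 3), 1.5)      # delta * lambda^2 / 2
  # continuity at the knee |b| = delta * lambda
  eps <- 1e-9
  expect_equal(mcpPenalty(3 - eps, 1, 3), mcpPenalty(3 + eps, 1, 3),
               tolerance = 1e-6)
  expect_error(mcpPenalty(1, -0.1, 3), "non-negative")
})

test_that("firm threshold is the closed-form minimizer of its objective", {
  expect_identical(firmThreshold(0.8, 1, 3), 0)
  expect_equal(firmThreshold(2, 1, 3), 1.5)
  expect_equal(firmThreshold(4, 1, 3), 4)
  expect_error(firmThreshold(1, 1, 0.9), "delta")
  # brute-force 1-D minimization across regimes and signs
  for (z in c(-2.5, -1.3, -0.4, 0.7, 1.1, 2.2, 3.8)) {
    for (lam in c(0.5, 1)) {
      expect_equal(firmThreshold(z, lam, 3), firmOracle(z, lam, 3),
                   tolerance = 1e-3)
    }
  }
})

test_that("the unpenalized limit of the path is ordinary least squares", {
  set.seed(21)
  n <- 60
  X <- rbinom(n, 1, 0.5)
  M <- matrix(rnorm(n * 4), n, 4)
  Y <- 1 + 0.5 * X + M %*% c(1, -0.5, 0, 0.8) + rnorm(n)
  path <- fitMcpPath(Y, X, M, lambda = c(0.5, 0.1, 0))
  ols <- coef(lm(Y ~ X + M))
  expect_equal(unname(path$beta[path$penalized, 3]), unname(ols[3:6]),
               tolerance = 1e-6)
  expect_equal(unname(path$beta[1, 3]), unname(ols[2]), tolerance = 1e-6)
  expect_equal(unname(path$intercepts[3]), unname(ols[1]), tolerance = 1e-6)
})

test_that("orthonormal-design solutions are coordinate-wise firm thresholds", {
  set.seed(22)
  n <- 80
  q <- 5
  M0 <- matrix(rnorm(n * q), n, q)
  M0 <- sweep(M0, 2, colMeans(M0))      # centered, so Q's columns stay centered
  M <- qr.Q(qr(M0)) * sqrt(n)           # M'M/n = I exactly
  X <- resid(lm(rnorm(n) ~ M))          # X orthogonal to M, centered
  b <- c(1.6, -0.9, 0.25, 0, 2.4)
  Y <- drop(M %*% b)                    # noiseless, mean zero
  lam <- 0.4
  path <- fitMcpPath(Y, X, M, lambda = c(1.2, lam))
  z <- drop(crossprod(M, Y)) / n        # marginal coordinates equal b here
  expect_equal(unname(path$beta[path$penalized, 2]),
               unname(firmThreshold(z, lam, 3)), tolerance = 1e-4)
  # delta -> infinity approaches the soft-thresholding (lasso) solution
  pathBig <- fitMcpPath(Y, X, M, lambda = c(1.2, lam), delta = 1e6)
  soft <- sign(z) * pmax(abs(z) - lam, 0)
  expect_equal(unname(pathBig$beta[pathBig$penalized, 2]), unname(soft),
               tolerance = 1e-3)
})

test_that("the solver beats an exhaustive 2-D grid on the penalized objective", {
  set.seed(23)
  n <- 40
  X <- rbinom(n, 1, 0.5)
  M <- matrix(rnorm(n * 2), n, 2)
  M[, 2] <- 0.6 * M[, 1] + 0.8 * M[, 2]     # correlated pair
  Y <- 0.4 * X + 1.2 * M[, 1] - 0.7 * M[, 2] + rnorm(n, sd = 0.8)
  lam <- 0.15
  path <- fitMcpPath(Y, X, M, lambda = c(0.6, lam), trace = TRUE)
  solverObj <- tail(path$objective[[2]], 1)

  # profiled objective on the solver's standardized scale: for each grid
  # point (b1, b2) the unpenalized exposure coefficient is optimized out
  D <- cbind(X, M)
  Dc <- sweep(D, 2, colMeans(D))
  Ds <- sweep(Dc, 2, sqrt(colMeans(Dc^2)), "/")
  yc <- Y - mean(Y)
  g <- seq(-2, 2, by = 0.01)
  grid <- expand.grid(b1 = g, b2 = g)
  R2 <- outer(drop(yc), rep(1, nrow(grid))) -
    Ds[, 2] %*% t(grid$b1) - Ds[, 3] %*% t(grid$b2)
  gOpt <- drop(crossprod(Ds[, 1], R2)) / n
  rss <- colSums(R2^2) / n - gOpt^2
  obj <- rss / 2 + mcpPenalty(grid$b1, lam, 3) + mcpPenalty(grid$b2, lam, 3)
  expect_lte(solverObj, min(obj) + 1e-8)
})

test_that("the penalized objective never increases across sweeps", {
  set.seed(24)
  n <- 50
  X <- rbinom(n, 1, 0.5)
  M <- matrix(rnorm(n * 8), n, 8)
  Y <- 0.5 * X + M %*% c(1, -1, 0.5, rep(0, 5)) + rnorm(n)
  path <- fitMcpPath(Y, X, M, trace = TRUE)
  for (objs in path$objective)
    expect_true(all(diff(objs) <= 1e-10))
})

test_that("information-criterion selection is consistent under null and signal", {
  nullSizes <- integer(50)
  hitCount <- 0
  for (s in 1:50) {
    set.seed(700 + s)
    n <- 300
    X <- rbinom(n, 1, 0.5)
    M <- matrix(rnorm(n * 20), n, 20)
    Ynull <- 0.5 * X + rnorm(n)
    fitN <- selectLambda(fitMcpPath(Ynull, X, M))
    nullSizes[s] <- length(mcpSupport(fitN))
    Ysig <- 0.5 * X + 2 * M[, 7] + rnorm(n)
    fitS <- selectLambda(fitMcpPath(Ysig, X, M))
    if (7L %in% mcpSupport(fitS)) hitCount <- hitCount + 1
  }
  # BIC keeps the null support essentially empty (a stray coordinate can
  # clear the log(n)/n bar at this sample size, but never more than a few)
  expect_gte(mean(nullSizes == 0), 0.5)
  expect_gte(mean(nullSizes <= 2), 0.9)
  expect_gte(hitCount, 48)     # >= 95% recovery of a strong planted signal
})

test_that("single-lambda paths select that lambda", {
  set.seed(25)
  n <- 40
  X <- rbinom(n, 1, 0.5)
  M <- matrix(rnorm(n * 3), n, 3)
  Y <- X + M[, 1] + rnorm(n)
  path <- fitMcpPath(Y, X, M, lambda = 0.2)
  fit <- selectLambda(path)
  expect_equal(fit@lambda, 0.2)
})

test_that("oracle refit reproduces closed-form least-squares standard errors", {
  set.seed(26)
  n <- 35
  X <- rbinom(n, 1, 0.5)
  S <- plogis(rnorm(n))
  M <- matrix(rnorm(n * 2), n, 2)
  Y <- 0.3 + 0.5 * X + 0.8 * S + M %*% c(1, -2) + rnorm(n)
  refit <- oracleRefit(Y, X, M, covariates = S)
  oracle <- normalEquationsOracle(Y, cbind(1, X, S, M))
  expect_equal(refit$beta, oracle$coef[4:5], tolerance = 1e-10)
  expect_equal(refit$betaSE, oracle$se[4:5], tolerance = 1e-10)
  expect_equal(refit$gamma, oracle$coef[2], tolerance = 1e-10)
  # empty support: no mediator SEs, not an error
  r0 <- oracleRefit(Y, X, M[, integer(0), drop = FALSE], covariates = S)
  expect_length(r0$betaSE, 0)
  # vanishing noise drives the SEs to zero
  Yexact <- 0.3 + 0.5 * X + M %*% c(1, -2)
  rX <- oracleRefit(Yexact, X, M)
  expect_true(all(rX$betaSE < 1e-8))
})

test_that("support size grows along the warm-started path", {
  set.seed(27)
  n <- 60
  X <- rbinom(n, 1, 0.5)
  M <- matrix(rnorm(n * 10), n, 10)
  Y <- 0.5 * X + M %*% c(2, -1.5, 1, 0.5, rep(0, 6)) + rnorm(n)
  path <- fitMcpPath(Y, X, M)
  sizes <- lengths(path$supports)
  # non-monotonicity can occur for MCP but should be rare on a clean design
  expect_lte(sum(diff(sizes) < 0), 2)
  expect_lt(sizes[1], sizes[length(sizes)])
})
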