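# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check: grid refinement instead of IRLS, explicit
# normal equations instead of QR shortcuts, hand-rolled step-up instead of
# p.adjust.

# Maximize the Bernoulli log-likelihood of logit(P(X=1)) = b0 + b1 * z by
# nested grid refinement.
gridLogisticOracle <- function(X, z, lower = c(-5, -5), upper = c(5, 5),
                               stages = 6L, pts = 41L) {
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * z
    sum(X * eta - log1p(exp(eta)))
  }
  for (s in seq_len(stages)) {
    g0 <- seq(lower[1], upper[1], length.out = pts)
    g1 <- seq(lower[2], upper[2], length.out = pts)
    ll <- outer(g0, g1, Vectorize(loglik))
    ix <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    b <- c(g0[ix[1]], g1[ix[2]])
    span <- c(diff(range(g0)), diff(range(g1))) / (pts - 1) * 2
    lower <- b - span
    upper <- b + span
  }
  b
}

# Weighted least squares of y on cbind(1, X, m) by explicit normal
# equations, then the two-step residual pathway.
twoStepOracle <- function(y, X, m, w) {
  D <- cbind(1, X, m)
  A <- t(D) %*% (w * D)
  b <- solve(A, t(D) %*% (w * y))
  gammaW <- b[2]
  e <- y - gammaW * X
  D2 <- cbind(1, m)
  b2 <- solve(t(D2) %*% D2, t(D2) %*% e)
  r <- e - D2 %*% b2
  s2 <- sum(r^2) / (length(y) - 2)
  se <- sqrt(s2 * solve(t(D2) %*% D2)[2, 2])
  list(gammaW = gammaW, beta = b2[2], se = se)
}

# Ordinary least squares of y on D by explicit inversion, with SEs.
normalEquationsOracle <- function(y, D) {
  A <- solve(t(D) %*% D)
  b <- A %*% t(D) %*% y
  r <- y - D %*% b
  s2 <- sum(r^2) / (length(y) - ncol(D))
  list(coef = unname(drop(b)), se = unname(sqrt(s2 * diag(A))))
}

# Hand-rolled BH step-up adjustment over m hypotheses (untested ones at 1).
bhStepUpOracle <- function(p, m = length(p)) {
  k <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(k)
  for (i in seq(k - 1, 1)) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# 1-D brute-force minimizer of 0.5*(b - z)^2 + MCP penalty on a fine grid.
firmOracle <- function(z, lambda, delta, width = 3, step = 1e-4) {
  grid <- seq(z - width, z + width, by = step)
  obj <- 0.5 * (grid - z)^2 + mcpPenalty(grid, lambda, delta)
  grid[which.min(obj)]
}

smallDataset <- function(n = 120, p = 40, seed = 42, ...) {
  generateDataset(simulationConfig(n = n, p = p, seed = seed, ...))
}
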