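# Step 3: minimax concave penalty (MCP) selection over the screened
# mediators. The exposure (and the propensity score for PSR, or the
# confounders for COV) stay unpenalized; only mediator coefficients are
# shrunk.

#' MCP penalty value
#'
#' \deqn{p(b) = \lambda\left(|b| - \frac{b^2}{2\delta\lambda}\right)
#'   \quad\text{for } |b| < \delta\lambda, \qquad
#'   p(b) = \frac{\delta\lambda^2}{2} \quad\text{for } |b| \ge
#'   \delta\lambda,}
#' the unique continuous completion of the quadratically tapered absolute
#' penalty: it matches the lasso near zero and flattens beyond
#' \eqn{\delta\lambda}, leaving large coefficients unbiased.
#'
#' @param b coefficient value(s).
#' @param lambda regularization parameter, non-negative.
#' @param delta concavity parameter, greater than 1 (default 3).
#' @return penalty value(s).
#' @examples
#' mcpPenalty(0.5, 1, 3)  # 0.5 - 0.25/6
#' mcpPenalty(5, 1, 3)    # saturated at delta * lambda^2 / 2 = 1.5
#' @export
mcpPenalty <- function(b, lambda, delta = 3) {
  if (lambda < 0) stop("lambda must be non-negative")
  if (delta <= 1) stop("delta must exceed 1")
  ab <- abs(b)
  sat <- delta * lambda^2 / 2
  inner <- ab < delta * lambda
  out <- rep(sat, length(ab))
  if (lambda > 0)
    out[inner] <- lambda * (ab[inner] - ab[inner]^2 / (2 * delta * lambda))
  else
    out[inner] <- 0
  out
}

#' Firm-thresholding operator
#'
#' The closed-form minimizer of \eqn{\tfrac12 (b - z)^2 +
#' p(b; \lambda, \delta)} with the MCP penalty: zero inside the threshold,
#' a rescaled soft threshold in the concave region, and the identity beyond
#' \eqn{\delta\lambda}. This is the exact coordinate update of the solver
#' on unit-scale columns.
#'
#' @param z unpenalized (marginal least-squares) coordinate value(s).
#' @inheritParams mcpPenalty
#' @return thresholded value(s).
#' @examples
#' firmThreshold(c(0.8, 2, 4), lambda = 1, delta = 3)  # 0, 1.5, 4
#' @export
firmThreshold <- function(z, lambda, delta = 3) {
  if (lambda < 0) stop("lambda must be non-negative")
  if (delta <= 1) stop("delta must exceed 1: the coordinate update is not defined")
  az <- abs(z)
  out <- numeric(length(z))
  mid <- az > lambda & az <= delta * lambda
  out[mid] <- sign(z[mid]) * (az[mid] - lambda) / (1 - 1 / delta)
  big <- az > delta * lambda
  out[big] <- z[big]
  out
}

#' Fit the MCP regularization path
#'
#' Coordinate descent over a decreasing lambda grid with warm starts. The
#' design is `cbind(X, covariates, M)`; `X` and the covariates are never
#' penalized. All columns are centered and scaled to unit quadratic mean
#' internally; coefficients are returned on the original scale. When no
#' grid is supplied, 50 log-spaced values from \eqn{\lambda_{max}} (the
#' smallest lambda with an empty mediator support) down to
#' \eqn{0.01\,\lambda_{max}} are used.
#'
#' @param Y outcome vector.
#' @param X exposure vector (unpenalized).
#' @param M screened mediator matrix (penalized columns).
#' @param covariates optional unpenalized adjustment columns (propensity
#'   score for PSR, confounder matrix for COV).
#' @param lambda optional strictly decreasing, non-negative grid.
#' @param nlambda,lambdaMinRatio grid size and lower endpoint ratio used
#'   when `lambda` is `NULL`.
#' @param delta MCP concavity parameter (> 1).
#' @param tol convergence tolerance on the maximum absolute coefficient
#'   change per sweep.
#' @param maxSweeps sweep budget per lambda.
#' @param trace record the penalized objective after every sweep.
#' @return an object of class `"McpPath"`: a list with the lambda grid,
#'   per-lambda coefficients (original scale), intercepts, residual sums
#'   of squares, support sizes, convergence flags, and the inputs needed
#'   for post-selection refits.
#' @seealso [selectLambda()], [firmThreshold()]
#' @export
fitMcpPath <- function(Y, X, M, covariates = NULL, lambda = NULL,
                       nlambda = 50L, lambdaMinRatio = 0.01, delta = 3,
                       tol = 1e-7, maxSweeps = 10000L, trace = FALSE) {
  if (delta <= 1) stop("delta must exceed 1")
  Y <- as.numeric(Y)
  M <- as.matrix(M)
  n <- length(Y)
  if (nrow(M) != n) stop("nrow(M) must equal length(Y)")
  if (is.null(colnames(M))) colnames(M) <- paste0("M", seq_len(ncol(M)))
  unpen <- cbind(X = as.numeric(X))
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("C", seq_len(ncol(covariates)))
    unpen <- cbind(unpen, covariates)
  }
  D <- cbind(unpen, M)
  penalized <- c(rep(FALSE, ncol(unpen)), rep(TRUE, ncol(M)))
  mu <- colMeans(D)
  Dc <- sweep(D, 2L, mu)
  sc <- sqrt(colMeans(Dc^2))
  if (any(sc == 0))
    stop("zero-variance column in the MCP design: ",
         paste(colnames(D)[sc == 0], collapse = ", "))
  Ds <- sweep(Dc, 2L, sc, "/")
  ybar <- mean(Y)
  yc <- Y - ybar

  # warm start: unpenalized block at its joint least-squares solution
  f0 <- lm.fit(Ds[, !penalized, drop = FALSE], yc)
  init <- numeric(ncol(Ds))
  init[!penalized] <- f0$coefficients

  if (is.null(lambda)) {
    lamMax <- max(abs(crossprod(Ds[, penalized, drop = FALSE],
                                f0$residuals)) / n)
    if (!is.finite(lamMax) || lamMax <= 0) lamMax <- 1e-3
    # keep the first grid point strictly above the activation boundary:
    # at exactly lambda_max one coordinate sits on the threshold and can
    # oscillate there indefinitely
    lamMax <- lamMax * (1 + 1e-5)
    lambda <- exp(seq(log(lamMax), log(lamMax * lambdaMinRatio),
                      length.out = nlambda))
  } else {
    lambda <- as.numeric(lambda)
    if (any(lambda < 0)) stop("lambda values must be non-negative")
    if (length(lambda) > 1L && any(diff(lambda) >= 0))
      stop("lambda grid must be strictly decreasing")
  }

  G <- crossprod(Ds) / n
  cvec <- drop(crossprod(Ds, yc)) / n
  fit <- .mcpCdPath(G, cvec, sum(yc^2), n, penalized, lambda, delta, tol,
                    as.integer(maxSweeps), trace, init)
  if (!all(fit$converged))
    stop("MCP coordinate descent did not converge at lambda index ",
         paste(which(!fit$converged), collapse = ", "))
  betaStd <- fit$beta
  betaOrig <- betaStd / sc
  fitted <- Ds %*% betaStd
  rss <- colSums((yc - fitted)^2)
  intercepts <- ybar - drop(crossprod(betaOrig, mu))
  supports <- lapply(seq_along(lambda), function(i)
    which(betaStd[penalized, i] != 0))
  structure(list(
    lambda = lambda, delta = delta,
    beta = betaOrig, penalized = penalized, n = n,
    nUnpenalized = ncol(unpen) + 1L,  # + intercept
    intercepts = intercepts, rss = rss, supports = supports,
    sweeps = fit$sweeps, converged = fit$converged,
    objective = if (trace) fit$objective else NULL,
    colnamesM = colnames(M),
    Y = Y, X = as.numeric(X), M = M, covariates = covariates
  ), class = "McpPath")
}

#' @export
print.McpPath <- function(x, ...) {
  cat("McpPath:", length(x$lambda), "lambda values, delta =", x$delta, "\n")
  cat("  support sizes:",
      paste(range(lengths(x$supports)), collapse = " .. "), "\n")
  invisible(x)
}

#' Select lambda by information criterion
#'
#' Chooses the path solution minimizing
#' \eqn{n \ln(\mathrm{RSS}/n) + \mathrm{df}\,\ln n} (BIC, default) or
#' \eqn{n \ln(\mathrm{RSS}/n) + 2\,\mathrm{df}} (AIC), where df is the
#' mediator support size plus the number of unpenalized terms. Standard
#' errors for the selected support come from the unpenalized
#' post-selection least-squares refit (the oracle property of MCP).
#'
#' @param path an `"McpPath"` from [fitMcpPath()].
#' @param criterion `"BIC"` or `"AIC"`.
#' @return an [McpFit-class]; its `beta` are the penalized coefficients at
#'   the selected lambda, its `se` the oracle-refit standard errors.
#' @export
selectLambda <- function(path, criterion = c("BIC", "AIC")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(path, "McpPath"))
  n <- path$n
  df <- lengths(path$supports) + path$nUnpenalized
  ll <- n * log(pmax(path$rss, 1e-300) / n)
  ic <- if (criterion == "BIC") ll + df * log(n) else ll + 2 * df
  best <- which.min(ic)
  support <- path$supports[[best]]
  pen <- path$penalized
  betaAll <- path$beta[, best]
  betaMed <- betaAll[pen]
  names(betaMed) <- path$colnamesM
  refit <- oracleRefit(path$Y, path$X,
                       path$M[, support, drop = FALSE], path$covariates)
  psc <- betaAll[!pen][-1]
  new("McpFit",
      beta = betaMed,
      gammaHat = unname(betaAll[!pen][1]),
      psCoef = psc,
      intercept = unname(path$intercepts[best]),
      support = as.integer(support),
      lambda = path$lambda[best], delta = path$delta,
      se = setNames(refit$betaSE, path$colnamesM[support]),
      icPath = data.frame(lambda = path$lambda, df = df, criterion = ic,
                          supportSize = lengths(path$supports)),
      converged = path$converged)
}

#' Post-selection least-squares refit
#'
#' Unpenalized least squares of the outcome on the intercept, the
#' exposure, the adjustment covariates and the selected mediators. By the
#' oracle property of MCP the refit on the selected support behaves
#' asymptotically like least squares on the true support, so its standard
#' errors are valid for post-selection inference.
#'
#' @param Y,X outcome and exposure vectors.
#' @param Msupport mediator matrix restricted to the support (may have
#'   zero columns).
#' @param covariates optional adjustment columns.
#' @param weights optional observation weights (weighted refit).
#' @return list with `gamma`, `gammaSE`, `beta`, `betaSE` (both empty for
#'   an empty support), `coef` (all coefficients) and `sigma2`.
#' @export
oracleRefit <- function(Y, X, Msupport, covariates = NULL, weights = NULL) {
  Msupport <- as.matrix(Msupport)
  D <- cbind(`(Intercept)` = 1, X = as.numeric(X))
  if (!is.null(covariates) && NCOL(covariates) > 0)
    D <- cbind(D, as.matrix(covariates))
  if (ncol(Msupport) > 0) D <- cbind(D, Msupport)
  if (qr(D)$rank < ncol(D)) stop("refit design is rank deficient")
  fit <- if (is.null(weights)) lm.fit(D, as.numeric(Y))
         else lm.wfit(D, as.numeric(Y), as.numeric(weights))
  dfres <- length(Y) - ncol(D)
  if (dfres <= 0) stop("not enough samples for the refit")
  r <- fit$residuals
  rss <- if (is.null(weights)) sum(r^2) else sum(weights * r^2)
  sigma2 <- rss / dfres
  R <- qr.R(fit$qr)
  XtXinv <- chol2inv(R)
  ses <- sqrt(sigma2 * diag(XtXinv))
  # lm.fit pivots columns; restore original order
  ses <- ses[order(fit$qr$pivot)]
  k <- ncol(D) - ncol(Msupport)
  list(gamma = unname(fit$coefficients["X"]),
       gammaSE = unname(ses[2L]),
       beta = unname(fit$coefficients[seq_len(ncol(Msupport)) + k]),
       betaSE = unname(ses[seq_len(ncol(Msupport)) + k]),
       coef = fit$coefficients, sigma2 = sigma2)
}

#' @rdname psmediation-accessors
#' @export
setMethod("mcpSupport", "McpFit", function(x) x@support)

setMethod("show", "McpFit", function(object) {
  cat("McpFit: |support| =", length(object@support),
      "at lambda =", signif(object@lambda, 4),
      "(delta =", object@delta, ")\n")
  cat("  gammaHat =", signif(object@gammaHat, 4), "\n")
})
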