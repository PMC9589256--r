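# Step 2: sure independence screening. Each method ranks mediators by the
# absolute marginal mediator-outcome coefficient computed under its own
# confounder adjustment, then keeps the top d = ceiling(2n / ln n).
#
# All three marginal estimators accept a single mediator vector or an n x p
# matrix; the matrix forms are closed-form vectorized least squares so that
# screening 10,000 mediators costs a handful of O(np) passes.

#' Screening dimension
#'
#' The number of mediators retained by sure independence screening,
#' \eqn{d = \lceil 2n / \ln n \rceil}, capped at the mediator dimension.
#' This is the usual order \eqn{O(n/\log n)} screening size for
#' ultra-high-dimensional mediator selection.
#'
#' @param n sample size (at least 2).
#' @param p mediator dimension.
#' @return integer screening dimension.
#' @examples
#' sisDimension(300, 1000)   # 106
#' sisDimension(500, 10000)  # 161
#' @export
sisDimension <- function(n, p) {
  if (n < 2) stop("n must be at least 2")
  as.integer(min(p, ceiling(2 * n / log(n))))
}

# Least squares of y on cbind(A, m) for every column m of M at once, via
# Frisch-Waugh: residualize y and each mediator on A, then the coefficient
# of m is <m~, y~>/<m~, m~>. Returns beta, se and a validity flag.
.marginalAdjusted <- function(Y, M, A) {
  M <- as.matrix(M)
  n <- nrow(M)
  qrA <- qr(A)
  if (qrA$rank < ncol(A))
    stop("adjustment design is rank deficient")
  Yt <- qr.resid(qrA, Y)
  Mt <- qr.resid(qrA, M)
  smm <- colSums(Mt^2)
  smy <- drop(crossprod(Mt, Yt))
  ok <- smm > n * 1e-12 * pmax(colMeans(M^2), 1)
  beta <- ifelse(ok, smy / smm, 0)
  rss <- sum(Yt^2) - beta^2 * smm
  dfres <- n - ncol(A) - 1L
  if (dfres <= 0) stop("not enough samples for the marginal fit")
  sigma2 <- pmax(rss, 0) / dfres
  se <- ifelse(ok, sqrt(sigma2 / smm), NA_real_)
  list(beta = unname(beta), se = unname(se), ok = unname(ok))
}

#' Marginal mediator coefficient with the propensity score as covariate
#'
#' For each mediator column, the least-squares coefficient of the mediator
#' in the outcome model `Y ~ 1 + X + Mk + S`, with its standard error.
#' Used by the PSR screening stage.
#'
#' @param Y outcome vector.
#' @param X binary exposure vector.
#' @param M mediator vector or n x p matrix.
#' @param S propensity score vector.
#' @return list with numeric vectors `beta`, `se` and logical `ok` (FALSE
#'   for degenerate mediator columns, which get beta 0 and are excluded
#'   from ranking).
#' @export
marginalBetaPS <- function(Y, X, M, S) {
  .marginalAdjusted(Y, M, cbind(1, X, S))
}

#' Marginal mediator coefficient with direct covariate adjustment
#'
#' The least-squares coefficient of the mediator in
#' `Y ~ 1 + X + Mk + Z`. Used by the COV screening stage; with a
#' zero-column `Z` this reduces to `Y ~ 1 + X + Mk`.
#'
#' @inheritParams marginalBetaPS
#' @param Z confounder matrix (samples as rows), possibly zero columns.
#' @return as [marginalBetaPS()].
#' @export
marginalBetaCov <- function(Y, X, M, Z) {
  if (is.null(Z)) Z <- matrix(numeric(0), nrow = length(Y), ncol = 0)
  .marginalAdjusted(Y, M, cbind(1, X, as.matrix(Z)))
}

#' Marginal mediator coefficient by the two-step weighted estimator
#'
#' The inverse-probability-weighting analogue used by the PSW and PSU
#' screening stages. For each mediator: (1) weighted least squares of
#' `Y ~ 1 + X + Mk` with the IPW weights yields the weighted direct-effect
#' estimate \eqn{\hat\gamma_{k,w}}; (2) the residual
#' \eqn{e_k = Y - \hat\gamma_{k,w} X} removes the weighted exposure effect;
#' (3) unweighted least squares of `ek ~ 1 + Mk` gives \eqn{\hat\beta_k}
#' and its standard error.
#'
#' @inheritParams marginalBetaPS
#' @param weights strictly positive IPW weights.
#' @return as [marginalBetaPS()].
#' @export
marginalBetaTwoStep <- function(Y, X, M, weights) {
  M <- as.matrix(M)
  n <- nrow(M)
  w <- as.numeric(weights)
  if (length(w) != n) stop("weights length must equal the sample size")
  if (any(!is.finite(w)) || any(w <= 0))
    stop("weights must be strictly positive")
  X <- as.numeric(X)
  # Weighted 3x3 normal equations for (c, gamma, beta_k), vectorized over k
  sw <- sum(w); swx <- sum(w * X); swx2 <- sum(w * X^2)
  swy <- sum(w * Y); swxy <- sum(w * X * Y)
  swm <- drop(crossprod(M, w))
  swxm <- drop(crossprod(M, w * X))
  swm2 <- drop(crossprod(M^2, w))
  swmy <- drop(crossprod(M, w * Y))
  # Cramer's rule on [sw swx swm; swx swx2 swxm; swm swxm swm2] b = rhs
  det3 <- function(a11, a12, a13, a21, a22, a23, a31, a32, a33)
    a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
      a13 * (a21 * a32 - a22 * a31)
  D0 <- det3(sw, swx, swm, swx, swx2, swxm, swm, swxm, swm2)
  Dg <- det3(sw, swy, swm, swx, swxy, swxm, swm, swmy, swm2)
  scale0 <- sw * swx2 * pmax(swm2, sw)
  ok <- abs(D0) > 1e-12 * pmax(scale0, 1)
  gammaKW <- ifelse(ok, Dg / D0, NA_real_)
  # Step 2/3: residual e_k = Y - gammaKW * X, then OLS of e_k on (1, Mk)
  sy <- sum(Y); sx <- sum(X); sxy <- sum(X * Y); sx2 <- sum(X^2)
  sy2 <- sum(Y^2)
  sm <- colSums(M); sm2 <- colSums(M^2)
  smy <- drop(crossprod(M, Y)); smx <- drop(crossprod(M, X))
  sek <- sy - gammaKW * sx                      # sum of residuals
  smek <- smy - gammaKW * smx                   # <Mk, ek>
  sek2 <- sy2 - 2 * gammaKW * sxy + gammaKW^2 * sx2
  Smm <- sm2 - sm^2 / n
  Sme <- smek - sm * sek / n
  See <- sek2 - sek^2 / n
  ok <- ok & (Smm > n * 1e-12 * pmax(sm2 / n, 1))
  beta <- ifelse(ok, Sme / Smm, 0)
  rss <- pmax(See - beta^2 * Smm, 0)
  se <- ifelse(ok, sqrt(rss / (n - 2L) / Smm), NA_real_)
  list(beta = unname(beta), se = unname(se), ok = unname(ok))
}

#' Sure independence screening of the mediator matrix
#'
#' Applies the method's marginal outcome-model estimator to every mediator
#' and keeps the `d` with the largest absolute coefficient (computed on
#' internally standardized mediator columns, so the ranking is scale-free;
#' reported coefficients are on the original scale). All three
#' propensity-score methods (PSR, PSW, PSU) screen with the score as a
#' covariate, so they share one screened set; COV adjusts for the
#' confounders directly. The inverse-probability two-step estimator is
#' available as an alternative screening rule via `estimator = "twoStep"`.
#'
#' @param dataset a [MediationDataset-class].
#' @param method one of `"PSR"`, `"PSW"`, `"PSU"`, `"COV"`.
#' @param propensity a [PropensityResult-class]; required for PSR, PSW and
#'   PSU.
#' @param dOverride optional screening dimension overriding
#'   [sisDimension()].
#' @param estimator marginal estimator: `"auto"` (the method's default),
#'   `"psCovariate"` ([marginalBetaPS()]), `"twoStep"`
#'   ([marginalBetaTwoStep()]) or `"covAdjust"` ([marginalBetaCov()]).
#' @return a [ScreenResult-class]; `keptMediators()` are ordered by
#'   decreasing marginal \eqn{|\hat\beta|} (standardized scale), ties
#'   broken by ascending index.
#' @export
screenMediators <- function(dataset, method = c("PSU", "PSR", "PSW", "COV"),
                            propensity = NULL, dOverride = NULL,
                            estimator = c("auto", "psCovariate", "twoStep",
                                          "covAdjust")) {
  method <- match.arg(method)
  estimator <- match.arg(estimator)
  if (estimator == "auto")
    estimator <- if (method == "COV") "covAdjust" else "psCovariate"
  Y <- outcome(dataset)
  X <- exposure(dataset)
  M <- mediators(dataset)
  n <- length(Y)
  p <- ncol(M)
  d <- if (is.null(dOverride)) sisDimension(n, p)
       else as.integer(min(p, dOverride))
  if (method != "COV" && is.null(propensity))
    stop("PSR/PSW/PSU screening requires a fitted propensity model")
  sds <- apply(M, 2L, sd)
  sds[sds == 0] <- 1
  Ms <- sweep(sweep(M, 2L, colMeans(M)), 2L, sds, "/")
  res <- switch(estimator,
    psCovariate = marginalBetaPS(Y, X, Ms, psScores(propensity)),
    twoStep = marginalBetaTwoStep(Y, X, Ms, psWeights(propensity)),
    covAdjust = marginalBetaCov(Y, X, Ms, confounders(dataset)))
  score <- ifelse(res$ok, abs(res$beta), -Inf)
  ord <- order(-score, seq_len(p))
  kept <- ord[seq_len(min(d, sum(res$ok)))]
  new("ScreenResult",
      d = d, kept = as.integer(kept),
      marginalBeta = setNames(res$beta[kept] / unname(sds[kept]),
                              colnames(M)[kept]),
      marginalSE = setNames(res$se[kept] / unname(sds[kept]),
                            colnames(M)[kept]),
      method = method)
}

#' @rdname psmediation-accessors
#' @export
setMethod("keptMediators", "ScreenResult", function(x) x@kept)

#' @rdname psmediation-accessors
#' @export
setMethod("marginalBeta", "ScreenResult", function(x) x@marginalBeta)

setMethod("show", "ScreenResult", function(object) {
  cat("ScreenResult (", object@method, "): kept ",
      length(object@kept), " of d = ", object@d, "\n", sep = "")
  k <- head(object@kept, 5L)
  cat("  top mediators:", paste(k, collapse = ", "),
      if (length(object@kept) > 5L) "...", "\n")
})
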