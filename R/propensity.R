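# Step 1 of the pipeline: propensity score estimation and inverse
# probability weighting.

#' Fit the propensity score model
#'
#' Logistic regression of the binary exposure on the baseline confounders,
#' \eqn{\mathrm{logit}(S_i) = l_0 + l' Z_i}, fitted by iteratively
#' reweighted least squares (convergence tolerance 1e-8, at most 100
#' iterations). With no confounders the maximum-likelihood score is the
#' treated fraction for every sample.
#'
#' @param X binary 0/1 exposure vector; both groups must be non-empty.
#' @param Z confounder matrix (samples as rows); may have zero columns.
#' @param clipScores clip fitted scores to \[0.01, 0.99\] before weighting.
#'   Off by default: the plain inverse-probability formula is used as
#'   printed, the flag is a robustness valve for near-degenerate scores.
#' @return a [PropensityResult-class] with coefficients, scores and IPW
#'   weights.
#' @examples
#' Z <- generateConfounders(200, seed = 1)
#' X <- generateExposure(Z, seed = 2)
#' ps <- fitPropensity(X, Z)
#' all.equal(mean(psScores(ps)), mean(X))  # intercept score equation
#' @export
fitPropensity <- function(X, Z = NULL, clipScores = FALSE) {
  X <- as.numeric(X)
  if (anyNA(X) || !all(X %in% c(0, 1)))
    stop("X must be binary 0/1 without missing values")
  if (length(unique(X)) < 2L)
    stop("both exposure groups must be non-empty; X is constant")
  if (is.null(Z)) Z <- matrix(numeric(0), nrow = length(X), ncol = 0)
  Z <- as.matrix(Z)
  if (nrow(Z) != length(X)) stop("nrow(Z) must equal length(X)")
  D <- cbind(`(Intercept)` = 1, Z)
  if (qr(D)$rank < ncol(D))
    stop("confounder design is rank deficient after adding an intercept")
  fit <- suppressWarnings(
    glm.fit(D, X, family = binomial(),
            control = list(epsilon = 1e-8, maxit = 100L))
  )
  S <- fit$fitted.values
  if (any(S < 1e-10 | S > 1 - 1e-10))
    stop("propensity fit is (quasi-)separated: fitted scores reach 0/1")
  if (!fit$converged)
    stop("propensity IRLS did not converge in 100 iterations")
  clipped <- FALSE
  if (clipScores) {
    S <- pmin(pmax(S, 0.01), 0.99)
    clipped <- TRUE
  }
  new("PropensityResult",
      coef = setNames(fit$coefficients, colnames(D)),
      scores = as.numeric(S),
      weights = ipwWeights(X, S),
      converged = fit$converged, nIter = as.integer(fit$iter),
      clipped = clipped)
}

#' Inverse-probability-of-treatment weights
#'
#' \eqn{w_i = X_i / S_i + (1 - X_i) / (1 - S_i)}: treated samples are
#' weighted by the reciprocal of their propensity score, controls by the
#' reciprocal of its complement. No normalization is applied.
#'
#' @param X binary 0/1 exposure vector.
#' @param S propensity scores, strictly inside (0, 1).
#' @return numeric weight vector, every entry greater than 1.
#' @examples
#' ipwWeights(c(1, 0, 1), c(0.5, 0.2, 0.25))  # 2, 1.25, 4
#' @export
ipwWeights <- function(X, S) {
  X <- as.numeric(X)
  S <- as.numeric(S)
  if (length(X) != length(S)) stop("X and S lengths differ")
  if (any(S <= 0 | S >= 1)) stop("scores must lie strictly inside (0, 1)")
  X / S + (1 - X) / (1 - S)
}

#' @rdname psmediation-accessors
#' @export
setMethod("psScores", "PropensityResult", function(x) x@scores)

#' @rdname psmediation-accessors
#' @export
setMethod("psWeights", "PropensityResult", function(x) x@weights)

#' @rdname psmediation-accessors
#' @export
setMethod("psCoef", "PropensityResult", function(x) x@coef)

setMethod("show", "PropensityResult", function(object) {
  cat("PropensityResult:", length(object@scores), "samples;",
      length(object@coef) - 1L, "confounders\n")
  cat("  score range: [", signif(min(object@scores), 4), ", ",
      signif(max(object@scores), 4), "]",
      if (object@clipped) " (clipped)", "\n", sep = "")
  cat("  IRLS iterations:", object@nIter, "\n")
})
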