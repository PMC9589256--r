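# Step 4: per-candidate exposure-mediator effects, normal-approximation
# p-values, BH false-discovery-rate adjustment and the joint-significance
# decision.

#' Estimate the exposure-mediator path coefficient
#'
#' Method-specific estimate of \eqn{\alpha_k}, the effect of the exposure
#' on one mediator, with its standard error:
#' * PSR / PSU: least-squares coefficient of `X` in `Mk ~ 1 + X + S`;
#' * PSW: weighted least-squares coefficient of `X` in `Mk ~ 1 + X` using
#'   the IPW weights (weighted-least-squares standard error);
#' * COV: least-squares coefficient of `X` in `Mk ~ 1 + X + Z`.
#'
#' A constant adjustment column (for example a degenerate propensity
#' score) is dropped with a warning rather than failing the fit.
#'
#' @param Mk single mediator vector.
#' @param X binary exposure vector.
#' @param adjuster the propensity scores (PSR/PSU), the IPW weights (PSW),
#'   or the confounder matrix (COV); ignored columns may be `NULL`.
#' @param method one of `"PSR"`, `"PSW"`, `"PSU"`, `"COV"`.
#' @return list with `alpha` and `se`.
#' @export
estimateAlpha <- function(Mk, X, adjuster,
                          method = c("PSU", "PSR", "PSW", "COV")) {
  method <- match.arg(method)
  Mk <- as.numeric(Mk)
  X <- as.numeric(X)
  dropConstant <- function(A) {
    A <- as.matrix(A)
    keep <- apply(A, 2L, function(col) var(col) > 1e-12 * max(mean(col^2), 1))
    if (!all(keep))
      warning("dropping constant adjustment column(s) from the alpha model")
    A[, keep, drop = FALSE]
  }
  if (method == "PSW") {
    w <- as.numeric(adjuster)
    if (any(w <= 0)) stop("weights must be strictly positive")
    fit <- oracleRefit(Mk, X, matrix(numeric(0), length(X), 0),
                       weights = w)
  } else {
    A <- if (method == "COV") adjuster else as.matrix(as.numeric(adjuster))
    if (!is.null(A) && NCOL(A) > 0) A <- dropConstant(A)
    fit <- oracleRefit(Mk, X, matrix(numeric(0), length(X), 0),
                       covariates = A)
  }
  list(alpha = fit$gamma, se = fit$gammaSE)
}

#' Two-sided normal-approximation p-value
#'
#' \eqn{P = 2\{1 - \Phi(|\hat\theta| / \hat\sigma)\}}.
#'
#' @param estimate point estimate(s).
#' @param se strictly positive standard error(s).
#' @return p-value(s) in \[0, 1\].
#' @export
rawPvalue <- function(estimate, se) {
  if (any(se <= 0)) stop("standard errors must be strictly positive")
  2 * pnorm(abs(estimate) / se, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment: sort ascending, multiply by m/rank,
#' enforce monotonicity from the largest rank downwards and cap at 1.
#' Delegates to [stats::p.adjust()].
#'
#' When `m` exceeds the number of supplied p-values, the correction treats
#' the remaining hypotheses as untested (p-value 1); this is how the joint
#' test corrects the candidate set against the full screened dimension.
#'
#' @param p raw p-values in \[0, 1\].
#' @param m multiplicity universe (number of tests); at least `length(p)`.
#' @return adjusted p-values in the original order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bhAdjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("m must be at least length(p)")
  p.adjust(p, method = "BH", n = m)
}

#' Joint-significance decision
#'
#' A mediator is declared significant only when both the
#' exposure-mediator and the mediator-outcome null hypotheses are
#' rejected; the joint p-value is the larger of the two BH-adjusted
#' p-values.
#'
#' @param pBhAlpha,pBhBeta BH-adjusted p-values for the two paths.
#' @param level significance level (default 0.05).
#' @return list with `pJoint` and logical `significant`.
#' @export
jointDecision <- function(pBhAlpha, pBhBeta, level = 0.05) {
  if (any(c(pBhAlpha, pBhBeta) < 0 | c(pBhAlpha, pBhBeta) > 1))
    stop("p-values must lie in [0, 1]")
  pj <- pmax(pBhAlpha, pBhBeta)
  list(pJoint = pj, significant = pj <= level)
}

#' Percent of total effect mediated
#'
#' \eqn{\%TE_k = 100\,\hat\alpha_k\hat\beta_k / (\hat\gamma +
#' \sum_{j \in C} \hat\alpha_j\hat\beta_j)}: one candidate's indirect
#' effect as a share of the direct effect plus all selected indirect
#' effects. Negative values arise when an indirect effect opposes the
#' total.
#'
#' @param effect indirect effect(s) \eqn{\hat\alpha_k\hat\beta_k}.
#' @param gammaHat direct-effect estimate.
#' @param allEffects indirect effects of every selected candidate.
#' @return percentage(s); `NA` when the denominator is zero.
#' @export
percentTE <- function(effect, gammaHat, allEffects = effect) {
  den <- gammaHat + sum(allEffects)
  if (abs(den) < .Machine$double.eps) return(rep(NA_real_, length(effect)))
  100 * effect / den
}
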