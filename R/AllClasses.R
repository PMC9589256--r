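#' @import methods
#' @importFrom stats binomial glm.fit lm.fit lm.wfit pnorm p.adjust plogis
#'   rbinom rnorm runif sd var setNames qnorm
#' @importFrom utils head
#' @importFrom SummarizedExperiment SummarizedExperiment colData rowData assay
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @useDynLib psmediation, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Simulation configuration for the confounded mediation design
#'
#' Encodes one study's data-generating process: ten baseline confounders
#' (five independent Bernoulli(0.3), five exchangeable-correlation normals),
#' logistic exposure assignment, and linear mediator / outcome models with a
#' sparse mediation structure in which exactly eight mediators carry a
#' nonzero indirect effect and four decoys carry only one of the two path
#' coefficients.
#'
#' @slot n sample size.
#' @slot p mediator dimension.
#' @slot mode effect-size pattern 1, 2 or 3 (ignored when `alpha`/`beta`
#'   are supplied explicitly).
#' @slot seed integer seed driving all draws of one dataset.
#' @slot l0 exposure logistic intercept.
#' @slot l exposure logistic coefficients on the confounders (length w).
#' @slot Theta confounder-to-mediator coefficients, shared across mediators.
#' @slot Phi confounder-to-outcome coefficients.
#' @slot gamma direct exposure effect on the outcome.
#' @slot c outcome intercept.
#' @slot interceptRange support of the per-mediator uniform intercepts.
#' @slot sigmaE mediator noise standard deviation.
#' @slot sigmaXi outcome noise standard deviation.
#' @slot Sigma covariance of the five normal confounders.
#' @slot alpha,beta full length-p path coefficient vectors.
#'
#' @seealso [simulationConfig()], [generateDataset()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    n = "integer", p = "integer", mode = "integer", seed = "integer",
    l0 = "numeric", l = "numeric", Theta = "numeric", Phi = "numeric",
    gamma = "numeric", c = "numeric", interceptRange = "numeric",
    sigmaE = "numeric", sigmaXi = "numeric", Sigma = "matrix",
    alpha = "numeric", beta = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@n < 2L) msg <- c(msg, "n must be >= 2")
  if (object@p < 1L) msg <- c(msg, "p must be >= 1")
  if (length(object@l) != length(object@Theta) ||
      length(object@l) != length(object@Phi))
    msg <- c(msg, "l, Theta and Phi must have equal length (w)")
  if (length(object@alpha) != object@p || length(object@beta) != object@p)
    msg <- c(msg, "alpha and beta must have length p")
  S <- object@Sigma
  if (nrow(S) != ncol(S) || any(abs(S - t(S)) > 1e-12))
    msg <- c(msg, "Sigma must be symmetric")
  if (any(eigen(S, symmetric = TRUE, only.values = TRUE)$values <= 0))
    msg <- c(msg, "Sigma must be positive definite")
  if (length(object@interceptRange) != 2L ||
      diff(object@interceptRange) < 0)
    msg <- c(msg, "interceptRange must be an ordered pair")
  if (object@sigmaE < 0 || object@sigmaXi < 0)
    msg <- c(msg, "noise scales must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Container for one mediation study
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose assay holds the
#' mediator matrix (mediators as rows, samples as columns) and whose column
#' data carries the binary exposure, the continuous outcome and the baseline
#' confounders. Simulated datasets additionally store the true path
#' coefficients in the row data.
#'
#' @seealso [MediationDataset()], [exposure()], [outcome()], [mediators()],
#'   [confounders()]
#' @exportClass MediationDataset
setClass("MediationDataset", contains = "SummarizedExperiment")

setValidity("MediationDataset", function(object) {
  msg <- character()
  cd <- colData(object)
  if (!all(c("exposure", "outcome") %in% colnames(cd)))
    return("colData must contain 'exposure' and 'outcome'")
  x <- cd$exposure
  if (anyNA(x) || !all(x %in% c(0, 1)))
    msg <- c(msg, "exposure must be binary 0/1 without missing values")
  if (anyNA(cd$outcome))
    msg <- c(msg, "outcome contains missing values")
  if (anyNA(assay(object)))
    msg <- c(msg, "mediator matrix contains missing values")
  zn <- metadata(object)$confounderNames
  if (length(zn)) {
    if (!all(zn %in% colnames(cd)))
      msg <- c(msg, "confounder columns missing from colData")
    else if (anyNA(as.matrix(cd[, zn, drop = FALSE])))
      msg <- c(msg, "confounders contain missing values")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted propensity model and inverse probability weights
#'
#' @slot coef logistic coefficients (intercept first).
#' @slot scores fitted propensity scores, each strictly inside (0, 1).
#' @slot weights inverse-probability-of-treatment weights
#'   \eqn{w_i = X_i/S_i + (1-X_i)/(1-S_i)}.
#' @slot converged whether the IRLS fit converged.
#' @slot nIter number of IRLS iterations used.
#' @slot clipped whether scores were clipped to \[0.01, 0.99\] before
#'   weighting.
#'
#' @seealso [fitPropensity()], [ipwWeights()]
#' @exportClass PropensityResult
setClass("PropensityResult",
  representation(coef = "numeric", scores = "numeric", weights = "numeric",
                 converged = "logical", nIter = "integer",
                 clipped = "logical")
)

setValidity("PropensityResult", function(object) {
  msg <- character()
  if (any(object@scores <= 0 | object@scores >= 1))
    msg <- c(msg, "scores must lie strictly inside (0, 1)")
  if (length(object@weights) != length(object@scores))
    msg <- c(msg, "weights and scores lengths differ")
  if (any(object@weights <= 1))
    msg <- c(msg, "IPW weights must all exceed 1")
  if (length(msg)) msg else TRUE
})

#' Sure-independence-screening result
#'
#' @slot d screening dimension actually used.
#' @slot kept mediator indices retained, ordered by decreasing marginal
#'   \eqn{|\hat\beta|} (ties broken by ascending index).
#' @slot marginalBeta marginal outcome-model coefficient for each kept
#'   mediator, on the original mediator scale.
#' @slot marginalSE standard error paired with `marginalBeta`.
#' @slot method one of PSR, PSW, PSU, COV.
#'
#' @seealso [screenMediators()], [sisDimension()]
#' @exportClass ScreenResult
setClass("ScreenResult",
  representation(d = "integer", kept = "integer", marginalBeta = "numeric",
                 marginalSE = "numeric", method = "character")
)

setValidity("ScreenResult", function(object) {
  msg <- character()
  if (anyDuplicated(object@kept)) msg <- c(msg, "kept contains duplicates")
  if (length(object@kept) != length(object@marginalBeta) ||
      length(object@kept) != length(object@marginalSE))
    msg <- c(msg, "kept/marginalBeta/marginalSE lengths differ")
  if (!object@method %in% c("PSR", "PSW", "PSU", "COV"))
    msg <- c(msg, "unknown method")
  if (length(msg)) msg else TRUE
})

#' MCP-penalized fit over the screened mediators
#'
#' @slot beta penalized mediator coefficients on the original scale, named
#'   by mediator; zero outside the support.
#' @slot gammaHat unpenalized exposure coefficient at the selected lambda.
#' @slot psCoef unpenalized coefficient(s) of the adjustment covariates
#'   (propensity score for PSR, confounders for COV; length 0 otherwise).
#' @slot intercept model intercept on the original scale.
#' @slot support indices (into the screened set) with nonzero beta.
#' @slot lambda selected regularization parameter.
#' @slot delta MCP concavity parameter.
#' @slot se oracle-property standard errors for support members, from the
#'   unpenalized post-selection refit.
#' @slot icPath data.frame with the lambda grid, support sizes and the
#'   information criterion used for selection.
#' @slot converged convergence flag per lambda.
#'
#' @seealso [fitMcpPath()], [selectLambda()]
#' @exportClass McpFit
setClass("McpFit",
  representation(beta = "numeric", gammaHat = "numeric", psCoef = "numeric",
                 intercept = "numeric", support = "integer",
                 lambda = "numeric", delta = "numeric", se = "numeric",
                 icPath = "data.frame", converged = "logical")
)

setValidity("McpFit", function(object) {
  msg <- character()
  sup <- unname(which(object@beta != 0))
  if (!identical(sort(sup), sort(unname(as.integer(object@support)))))
    msg <- c(msg, "support must equal the nonzero positions of beta")
  if (length(object@se) != length(object@support))
    msg <- c(msg, "one SE per support member required")
  if (length(object@se) && any(object@se <= 0))
    msg <- c(msg, "oracle SEs must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' Per-mediator mediation inference table
#'
#' Holds, for every MCP-selected candidate, the exposure-mediator
#' coefficient \eqn{\hat\alpha_k}, the mediator-outcome coefficient
#' \eqn{\hat\beta_k}, their product (the indirect effect), the share of the
#' total effect, raw and BH-adjusted p-values on both paths, and the
#' joint-significance decision.
#'
#' @slot table the per-candidate data.frame (see [resultsTable()]).
#' @slot gammaHat direct-effect estimate from the method's final outcome
#'   refit on the support.
#' @slot method one of PSR, PSW, PSU, COV.
#' @slot d screening dimension used.
#' @slot lambda selected MCP regularization parameter.
#' @slot level significance level of the joint test.
#'
#' @seealso [runMediation()]
#' @exportClass MediationResult
setClass("MediationResult",
  representation(table = "data.frame", gammaHat = "numeric",
                 method = "character", d = "integer", lambda = "numeric",
                 level = "numeric")
)

setValidity("MediationResult", function(object) {
  tab <- object@table
  need <- c("mediator", "alpha", "alpha_se", "beta", "beta_se", "effect",
            "pct_te", "p_raw_alpha", "p_raw_beta", "p_bh_alpha",
            "p_bh_beta", "p_joint", "significant")
  if (!all(need %in% colnames(tab)))
    return(paste("table must contain columns:", paste(need, collapse = ", ")))
  pv <- unlist(tab[c("p_raw_alpha", "p_raw_beta", "p_bh_alpha",
                     "p_bh_beta", "p_joint")])
  if (length(pv) && (any(pv < 0 | pv > 1, na.rm = TRUE)))
    return("p-values must lie in [0, 1]")
  TRUE
})
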