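# Orchestration of the four-stage procedure per method, plus delimited-text
# dataset I/O.

#' Run the propensity-adjusted high-dimensional mediation pipeline
#'
#' Executes, for one dataset and one method: (1) propensity estimation and
#' inverse probability weighting (skipped for COV); (2) sure independence
#' screening with the method's marginal outcome model; (3) MCP-penalized
#' selection with information-criterion tuning and oracle-property
#' standard errors; (4) exposure-mediator estimation, two-sided normal
#' p-values, BH adjustment over the selected set on both paths, and the
#' joint-significance decision.
#'
#' Method dispatch:
#' * **PSR** — propensity score as an unpenalized covariate in the
#'   screening models and the MCP objective; alpha from `Mk ~ 1 + X + S`.
#' * **PSW** — S-covariate screening, MCP without adjustment terms,
#'   weighted alpha model `Mk ~ 1 + X` (IPW weights); direct effect from
#'   the weighted outcome refit.
#' * **PSU** — hybrid: PSW's mediator-outcome pathway (screening, MCP and
#'   beta inference identical to PSW) with PSR's exposure-mediator
#'   pathway.
#' * **COV** — confounders as covariates in every model.
#'
#' PSW and PSU share the entire mediator-outcome pathway, so their MCP
#' supports and beta p-values coincide on identical input; they differ
#' only on the exposure-mediator side.
#'
#' @param dataset a [MediationDataset-class].
#' @param method one of `"PSU"`, `"PSR"`, `"PSW"`, `"COV"`.
#' @param dOverride optional screening dimension (see [sisDimension()]).
#' @param delta MCP concavity parameter.
#' @param ic information criterion for lambda selection.
#' @param nlambda size of the lambda grid.
#' @param level joint-test significance level.
#' @param clipScores clip propensity scores to \[0.01, 0.99\].
#' @param bhUniverse multiplicity universe for the BH correction of both
#'   path p-values: `"support"` (default) corrects over the MCP support
#'   (the candidate set actually tested); `"screened"` corrects against
#'   all `d` screened mediators, treating the unselected ones as untested.
#' @param screenEstimator marginal screening estimator passed to
#'   [screenMediators()] (`"auto"` uses the method's default).
#' @return a [MediationResult-class]; the per-candidate table is available
#'   via [resultsTable()].
#' @examples
#' ds <- generateDataset(simulationConfig(n = 200, p = 100, seed = 11))
#' res <- runMediation(ds, method = "PSU")
#' head(resultsTable(res))
#' @export
runMediation <- function(dataset, method = c("PSU", "PSR", "PSW", "COV"),
                         dOverride = NULL, delta = 3,
                         ic = c("BIC", "AIC"), nlambda = 50L,
                         level = 0.05, clipScores = FALSE,
                         bhUniverse = c("support", "screened"),
                         screenEstimator = "auto") {
  method <- match.arg(method)
  ic <- match.arg(ic)
  bhUniverse <- match.arg(bhUniverse)
  stopifnot(is(dataset, "MediationDataset"))
  Y <- outcome(dataset)
  X <- exposure(dataset)
  M <- mediators(dataset)
  Z <- confounders(dataset)

  ps <- NULL
  if (method != "COV") {
    if (ncol(Z) == 0)
      stop(method, " requires confounders to fit the propensity model")
    ps <- fitPropensity(X, Z, clipScores = clipScores)
  }

  scr <- screenMediators(dataset, method = method, propensity = ps,
                         dOverride = dOverride, estimator = screenEstimator)
  kept <- keptMediators(scr)
  Mscr <- M[, kept, drop = FALSE]

  covariates <- switch(method,
    PSR = matrix(psScores(ps), ncol = 1, dimnames = list(NULL, "S")),
    COV = if (ncol(Z) > 0) Z else NULL,
    NULL)
  path <- fitMcpPath(Y, X, Mscr, covariates = covariates,
                     nlambda = nlambda, delta = delta)
  fit <- selectLambda(path, criterion = ic)
  sup <- mcpSupport(fit)
  candidates <- kept[sup]

  if (length(sup) == 0L) {
    tab <- data.frame(mediator = character(0), alpha = numeric(0),
                      alpha_se = numeric(0), beta = numeric(0),
                      beta_se = numeric(0), effect = numeric(0),
                      pct_te = numeric(0), p_raw_alpha = numeric(0),
                      p_raw_beta = numeric(0), p_bh_alpha = numeric(0),
                      p_bh_beta = numeric(0), p_joint = numeric(0),
                      significant = logical(0))
    gammaFinal <- .finalGamma(Y, X, Mscr[, integer(0), drop = FALSE],
                              method, ps, Z)
    return(new("MediationResult", table = tab, gammaHat = gammaFinal,
               method = method, d = scr@d, lambda = fit@lambda,
               level = level))
  }

  betaHat <- unname(fit@beta[sup])
  betaSE <- unname(fit@se)
  Msup <- Mscr[, sup, drop = FALSE]

  alphaAdj <- switch(method,
    PSR = , PSU = psScores(ps),
    PSW = psWeights(ps),
    COV = Z)
  am <- lapply(seq_along(sup), function(j)
    estimateAlpha(Msup[, j], X, alphaAdj, method = method))
  alphaHat <- vapply(am, `[[`, numeric(1), "alpha")
  alphaSE <- vapply(am, `[[`, numeric(1), "se")

  pRawB <- rawPvalue(betaHat, betaSE)
  pRawA <- rawPvalue(alphaHat, alphaSE)
  m <- if (bhUniverse == "screened") scr@d else length(sup)
  pBhB <- bhAdjust(pRawB, m = m)
  pBhA <- bhAdjust(pRawA, m = m)
  jd <- jointDecision(pBhA, pBhB, level = level)

  gammaFinal <- .finalGamma(Y, X, Msup, method, ps, Z)
  effect <- alphaHat * betaHat
  tab <- data.frame(
    mediator = colnames(M)[candidates],
    alpha = alphaHat, alpha_se = alphaSE,
    beta = betaHat, beta_se = betaSE,
    effect = effect,
    pct_te = percentTE(effect, gammaFinal, effect),
    p_raw_alpha = pRawA, p_raw_beta = pRawB,
    p_bh_alpha = pBhA, p_bh_beta = pBhB,
    p_joint = jd$pJoint, significant = jd$significant,
    row.names = NULL)
  tab <- tab[order(-abs(tab$effect)), , drop = FALSE]
  rownames(tab) <- NULL
  new("MediationResult", table = tab, gammaHat = gammaFinal,
      method = method, d = scr@d, lambda = fit@lambda, level = level)
}

# Direct-effect estimate for the %TE denominator: the method's final
# outcome refit on the support (weighted for PSW/PSU, S for PSR, Z for COV).
.finalGamma <- function(Y, X, Msup, method, ps, Z) {
  switch(method,
    PSR = oracleRefit(Y, X, Msup,
                      covariates = psScores(ps))$gamma,
    PSW = ,
    PSU = oracleRefit(Y, X, Msup, weights = psWeights(ps))$gamma,
    COV = oracleRefit(Y, X, Msup,
                      covariates = if (ncol(Z) > 0) Z else NULL)$gamma)
}

#' @rdname psmediation-accessors
#' @export
setMethod("resultsTable", "MediationResult", function(x) x@table)

#' @rdname psmediation-accessors
#' @export
setMethod("directEffect", "MediationResult", function(x) x@gammaHat)

#' @rdname psmediation-accessors
#' @export
setMethod("significantMediators", "MediationResult", function(x)
  x@table$mediator[x@table$significant])

setMethod("show", "MediationResult", function(object) {
  cat("MediationResult (", object@method, "): ",
      nrow(object@table), " candidates, ",
      sum(object@table$significant), " significant at level ",
      object@level, "\n", sep = "")
  cat("  d =", object@d, "| lambda =", signif(object@lambda, 4),
      "| gammaHat =", signif(object@gammaHat, 4), "\n")
  if (nrow(object@table))
    print(utils::head(object@table[, c("mediator", "alpha", "beta",
                                       "effect", "pct_te", "p_joint",
                                       "significant")], 10L))
})

# ---- dataset I/O -----------------------------------------------------------

.readTable <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) >= 1L && (is.character(dt[[1]]) || is.factor(dt[[1]]))) {
    rownames(dt) <- dt[[1]]
    dt <- dt[, -1, drop = FALSE]
  }
  bad <- which(is.na(as.matrix(dt)), arr.ind = TRUE)
  if (nrow(bad))
    stop("missing value in ", basename(path), " at row ", bad[1, 1],
         ", column ", colnames(dt)[bad[1, 2]])
  dt
}

#' Read a mediation dataset from delimited text files
#'
#' Expects `X.csv` (exposure, one column), `Y.csv` (outcome), `M.csv`
#' (mediators, samples as rows) and optionally `Z.csv` (confounders) in a
#' directory, or explicit paths. Comma- or tab-delimited with a header
#' row; a leading character column is treated as sample identifiers.
#'
#' @param dir directory containing the four files; or `NULL` when paths
#'   are given explicitly.
#' @param x,y,m,z explicit file paths overriding `dir`.
#' @return a validated [MediationDataset-class].
#' @export
readMediationDataset <- function(dir = NULL, x = NULL, y = NULL, m = NULL,
                                 z = NULL) {
  pick <- function(explicit, name) {
    if (!is.null(explicit)) return(explicit)
    if (is.null(dir)) stop("supply either dir or explicit paths")
    file.path(dir, name)
  }
  xf <- pick(x, "X.csv"); yf <- pick(y, "Y.csv"); mf <- pick(m, "M.csv")
  zf <- if (!is.null(z)) z
        else if (!is.null(dir) && file.exists(file.path(dir, "Z.csv")))
          file.path(dir, "Z.csv") else NULL
  for (f in c(xf, yf, mf, zf))
    if (!file.exists(f)) stop("file not found: ", f)
  X <- .readTable(xf)[[1]]
  Y <- .readTable(yf)[[1]]
  M <- as.matrix(.readTable(mf))
  Z <- if (!is.null(zf)) as.matrix(.readTable(zf)) else NULL
  if (length(X) != nrow(M) || length(Y) != nrow(M) ||
      (!is.null(Z) && nrow(Z) != nrow(M)))
    stop("row counts of X, Y, M", if (!is.null(Z)) ", Z",
         " are inconsistent")
  if (!all(X %in% c(0, 1)))
    stop("X must be coded 0/1 (found values ",
         paste(utils::head(setdiff(unique(X), c(0, 1)), 3), collapse = ", "),
         "); recode the exposure to 0 = control, 1 = treated")
  MediationDataset(X = X, Y = Y, M = M, Z = Z)
}

#' Write a mediation dataset as delimited text files
#'
#' Writes `X.csv`, `Y.csv`, `M.csv`, `Z.csv` (and `truth.csv` with the
#' true path coefficients when present) into a directory, comma-delimited
#' with headers, samples as rows.
#'
#' @param dataset a [MediationDataset-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeMediationDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(obj, name)
    data.table::fwrite(as.data.frame(obj), file.path(dir, name))
  wr(data.frame(X = exposure(dataset)), "X.csv")
  wr(data.frame(Y = outcome(dataset)), "Y.csv")
  wr(mediators(dataset), "M.csv")
  Z <- confounders(dataset)
  if (ncol(Z) > 0) wr(Z, "Z.csv")
  if (!is.null(trueAlpha(dataset)))
    wr(data.frame(mediator = rownames(dataset),
                  alpha = trueAlpha(dataset),
                  beta = trueBeta(dataset)), "truth.csv")
  invisible(dir)
}

#' Write a mediation results table
#'
#' Comma-delimited export of [resultsTable()] with six significant digits.
#'
#' @param result a [MediationResult-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeResults <- function(result, path) {
  tab <- resultsTable(result)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = 6L)
  data.table::fwrite(tab, path)
  invisible(path)
}
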