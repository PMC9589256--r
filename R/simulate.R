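# Synthetic-data generator for the confounded high-dimensional mediation
# design: 10 confounders (5 Bernoulli(0.3), 5 exchangeable-correlation
# normals), logistic exposure assignment, and linear mediator/outcome models
# with a sparse indirect-effect structure.

.defaultL <- c(0.1, 0.3, 0.4, 0.4, 0.6, 0.1, 0.3, 0.4, 0.4, 0.6)
.defaultTheta <- c(0.2, 0.3, 0.3, 0.5, 0.6, 0.2, 0.3, 0.3, 0.5, 0.6)
.defaultPhi <- c(0.1, 0.3, 0.4, 0.4, 0.6, 0.1, 0.3, 0.4, 0.4, 0.6)

.exchangeableSigma <- function(k = 5L, rho = 0.3) {
  S <- matrix(rho, k, k)
  diag(S) <- 1
  S
}

#' Effect-size patterns for the simulated mediation structure
#'
#' Returns the full length-`p` path coefficient vectors for one of the three
#' study modes. In each mode the first eight mediators carry a nonzero
#' indirect effect \eqn{\alpha_k \beta_k}; positions 9-10 are outcome-only
#' decoys (\eqn{\alpha = 0}), positions 11-12 are exposure-only decoys
#' (\eqn{\beta = 0}), and everything beyond position 12 is null. The base
#' effect vector is \eqn{t = (0.50, 0.60, 0.75, 0.80, 1.00, 1.20, 1.50,
#' 2.00)}; mode 1 uses \eqn{\alpha = 0.6t, \beta = 0.4t}, mode 2
#' \eqn{\alpha = \beta = 0.5t}, mode 3 \eqn{\alpha = 0.4t, \beta = 0.6t}.
#'
#' @param mode integer 1, 2 or 3.
#' @param p mediator dimension, at least 12.
#' @return list with numeric vectors `alpha` and `beta`, each of length `p`.
#' @examples
#' cf <- modeCoefficients(1, 20)
#' cf$alpha[1:12]
#' sum(cf$alpha * cf$beta != 0)  # exactly 8
#' @export
modeCoefficients <- function(mode, p) {
  if (!mode %in% 1:3) stop("mode must be 1, 2 or 3")
  if (p < 12L) stop("p must be at least 12")
  t8 <- c(0.50, 0.60, 0.75, 0.80, 1.00, 1.20, 1.50, 2.00)
  fac <- switch(as.character(mode),
                "1" = c(0.6, 0.4), "2" = c(0.5, 0.5), "3" = c(0.4, 0.6))
  decoy <- fac[1] * 2.00  # decoy strength matches the largest alpha/beta
  alpha <- numeric(p)
  beta <- numeric(p)
  alpha[1:8] <- fac[1] * t8
  beta[1:8] <- fac[2] * t8
  alpha[11:12] <- decoy
  beta[9:10] <- fac[2] * 2.00
  list(alpha = alpha, beta = beta)
}

#' Construct a simulation configuration
#'
#' Bundles every parameter of the data-generating process. Defaults
#' reproduce the reference design: logistic exposure coefficients
#' `l = (0.1, 0.3, 0.4, 0.4, 0.6, 0.1, 0.3, 0.4, 0.4, 0.6)` with intercept
#' 0, confounder effects `Theta` shared across mediators, outcome confounder
#' effects `Phi = l`, per-mediator intercepts drawn from U(0, 2), direct
#' effect 0.5, outcome intercept 0.5, mediator noise SD 1.2 and outcome
#' noise SD 1.
#'
#' @param n sample size.
#' @param p mediator dimension.
#' @param mode effect-size pattern (1, 2 or 3); ignored when `alpha` and
#'   `beta` are supplied.
#' @param seed integer seed; one seeded generator drives all draws of a
#'   dataset in a fixed order (confounders, exposure, intercepts, mediator
#'   noise, outcome noise).
#' @param l0,l exposure logistic intercept and confounder coefficients.
#' @param Theta,Phi confounder effects on mediators / outcome.
#' @param gamma,c direct effect and outcome intercept.
#' @param interceptRange support of the uniform per-mediator intercepts.
#' @param sigmaE,sigmaXi mediator and outcome noise standard deviations.
#' @param Sigma covariance of the five normal confounders.
#' @param alpha,beta optional explicit path coefficient vectors (length
#'   `p`), overriding `mode`; use these for null designs.
#' @return a [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(n = 100, p = 50, mode = 1, seed = 7)
#' @export
simulationConfig <- function(n, p, mode = 1L, seed = 1L,
                             l0 = 0, l = .defaultL,
                             Theta = .defaultTheta, Phi = .defaultPhi,
                             gamma = 0.5, c = 0.5,
                             interceptRange = c(0, 2),
                             sigmaE = 1.2, sigmaXi = 1,
                             Sigma = .exchangeableSigma(),
                             alpha = NULL, beta = NULL) {
  if (is.null(alpha) != is.null(beta))
    stop("supply both alpha and beta, or neither")
  if (is.null(alpha)) {
    cf <- modeCoefficients(mode, p)
    alpha <- cf$alpha
    beta <- cf$beta
  }
  new("SimulationConfig",
      n = as.integer(n), p = as.integer(p), mode = as.integer(mode),
      seed = as.integer(seed), l0 = as.numeric(l0), l = as.numeric(l),
      Theta = as.numeric(Theta), Phi = as.numeric(Phi),
      gamma = as.numeric(gamma), c = as.numeric(c),
      interceptRange = as.numeric(interceptRange),
      sigmaE = as.numeric(sigmaE), sigmaXi = as.numeric(sigmaXi),
      Sigma = Sigma, alpha = as.numeric(alpha), beta = as.numeric(beta))
}

#' Draw the baseline confounder matrix
#'
#' Columns 1-5 are independent Bernoulli(0.3); columns 6-10 are jointly
#' normal with mean zero, unit variances and exchangeable correlation 0.3.
#'
#' @param n number of samples (rows); may be zero.
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @param Sigma covariance matrix of the normal block.
#' @return numeric matrix with `n` rows and 10 columns named `Z1`..`Z10`.
#' @export
generateConfounders <- function(n, seed = NULL,
                                Sigma = .exchangeableSigma()) {
  if (length(n) != 1L || is.na(n) || n < 0)
    stop("n must be a non-negative count")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(Sigma)
  Zb <- matrix(rbinom(n * 5L, 1L, 0.3), nrow = n, ncol = 5L)
  Zn <- matrix(rnorm(n * k), nrow = n, ncol = k) %*% chol(Sigma)
  Z <- cbind(Zb, Zn)
  colnames(Z) <- paste0("Z", seq_len(ncol(Z)))
  Z
}

#' Assign the binary exposure from the logistic model
#'
#' Each sample is treated with probability
#' \eqn{\mathrm{logit}^{-1}(l_0 + l' Z_i)}, independently.
#'
#' @param Z confounder matrix (samples as rows).
#' @param l logistic coefficients on the confounder columns.
#' @param l0 logistic intercept.
#' @param seed optional seed.
#' @return integer 0/1 vector of length `nrow(Z)`.
#' @export
generateExposure <- function(Z, l = .defaultL, l0 = 0, seed = NULL) {
  Z <- as.matrix(Z)
  if (length(l) != ncol(Z))
    stop("length(l) must equal ncol(Z)")
  if (!is.null(seed)) set.seed(seed)
  pz <- plogis(l0 + drop(Z %*% l))
  rbinom(nrow(Z), 1L, pz)
}

#' Generate one mediation dataset from a configuration
#'
#' Draws, in order: confounders, exposure, per-mediator intercepts
#' \eqn{c_k \sim U(0,2)}, mediator noise, outcome noise; then assembles
#' \deqn{M_{ik} = c_k + \alpha_k X_i + \Theta' Z_i + e_{ik}, \qquad
#'       Y_i = c + \gamma X_i + \beta' M_i + \Phi' Z_i + \xi_i.}
#' Identical configurations (including the seed) yield bit-identical data.
#'
#' @param config a [SimulationConfig-class] from [simulationConfig()].
#' @return a [MediationDataset-class] carrying the true `alpha`/`beta` in
#'   its row data.
#' @examples
#' ds <- generateDataset(simulationConfig(n = 80, p = 30, seed = 3))
#' table(exposure(ds))
#' @export
generateDataset <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  n <- config@n
  p <- config@p
  set.seed(config@seed)
  Z <- generateConfounders(n, seed = NULL, Sigma = config@Sigma)
  X <- generateExposure(Z, l = config@l, l0 = config@l0, seed = NULL)
  ck <- runif(p, config@interceptRange[1], config@interceptRange[2])
  E <- matrix(rnorm(n * p, sd = config@sigmaE), nrow = n, ncol = p)
  xi <- rnorm(n, sd = config@sigmaXi)
  zTheta <- drop(Z %*% config@Theta)
  # M = 1 ck' + X alpha' + (Z Theta) 1' + E, built without an n x p outer loop
  M <- E + outer(X, config@alpha) + zTheta
  M <- sweep(M, 2L, ck, "+")
  Y <- config@c + config@gamma * X + drop(M %*% config@beta) +
    drop(Z %*% config@Phi) + xi
  colnames(M) <- paste0("M", seq_len(p))
  MediationDataset(X = X, Y = Y, M = M, Z = Z,
                   trueAlpha = config@alpha, trueBeta = config@beta)
}

#' Construct a MediationDataset
#'
#' Validates and packs one study's variables into a
#' [SummarizedExperiment::SummarizedExperiment]-derived container: the
#' mediator matrix is stored transposed (mediators as rows), exposure,
#' outcome and confounders live in the column data.
#'
#' @param X binary 0/1 exposure vector of length n.
#' @param Y continuous outcome vector of length n.
#' @param M numeric mediator matrix, samples as rows (n x p).
#' @param Z optional confounder matrix, samples as rows (n x w).
#' @param trueAlpha,trueBeta optional true path coefficients (simulations).
#' @return a [MediationDataset-class].
#' @export
MediationDataset <- function(X, Y, M, Z = NULL,
                             trueAlpha = NULL, trueBeta = NULL) {
  M <- as.matrix(M)
  n <- nrow(M)
  if (length(X) != n || length(Y) != n)
    stop("X, Y and nrow(M) must agree")
  if (is.null(colnames(M))) colnames(M) <- paste0("M", seq_len(ncol(M)))
  cd <- DataFrame(exposure = as.numeric(X), outcome = as.numeric(Y))
  zn <- character()
  if (!is.null(Z) && NCOL(Z) > 0) {
    Z <- as.matrix(Z)
    if (nrow(Z) != n) stop("nrow(Z) must equal nrow(M)")
    if (is.null(colnames(Z))) colnames(Z) <- paste0("Z", seq_len(ncol(Z)))
    zn <- colnames(Z)
    for (j in seq_along(zn)) cd[[zn[j]]] <- Z[, j]
  }
  rd <- DataFrame(row.names = colnames(M))
  if (!is.null(trueAlpha)) rd$trueAlpha <- trueAlpha
  if (!is.null(trueBeta)) rd$trueBeta <- trueBeta
  se <- SummarizedExperiment(assays = list(mediators = t(M)),
                             colData = cd, rowData = rd)
  obj <- new("MediationDataset", se)
  metadata(obj)$confounderNames <- zn
  validObject(obj)
  obj
}

#' @rdname psmediation-accessors
#' @export
setMethod("exposure", "MediationDataset",
          function(x) colData(x)$exposure)

#' @rdname psmediation-accessors
#' @export
setMethod("outcome", "MediationDataset",
          function(x) colData(x)$outcome)

#' @rdname psmediation-accessors
#' @export
setMethod("mediators", "MediationDataset",
          function(x) t(assay(x, "mediators")))

#' @rdname psmediation-accessors
#' @export
setMethod("confounders", "MediationDataset", function(x) {
  zn <- metadata(x)$confounderNames
  if (!length(zn))
    return(matrix(numeric(0), nrow = ncol(x), ncol = 0))
  as.matrix(colData(x)[, zn, drop = FALSE])
})

#' @rdname psmediation-accessors
#' @export
setMethod("trueAlpha", "MediationDataset",
          function(x) rowData(x)$trueAlpha)

#' @rdname psmediation-accessors
#' @export
setMethod("trueBeta", "MediationDataset",
          function(x) rowData(x)$trueBeta)

setMethod("show", "MediationDataset", function(object) {
  cat("MediationDataset:", ncol(object), "samples,",
      nrow(object), "mediators,",
      length(metadata(object)$confounderNames), "confounders\n")
  x <- exposure(object)
  cat("  exposure: ", sum(x == 1), " treated / ", sum(x == 0),
      " control\n", sep = "")
  if (!is.null(trueAlpha(object)))
    cat("  true nonzero indirect effects:",
        sum(trueAlpha(object) * trueBeta(object) != 0), "\n")
})
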