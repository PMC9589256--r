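# Replication-study driver: many seeded replicates of the generating
# process, each pushed through the full pipeline, summarized into
# selection counts, power, false positives and conditional effect
# estimates.

#' Operating characteristics of one study cell
#'
#' @slot perMediator data.frame over the eight true mediators:
#'   `trueEffect`, `selectionCount` (MCP support membership across
#'   replicates), `TPR` (joint-test detection rate), `estimate` (mean
#'   indirect effect conditional on MCP selection), `MSE` (mean squared
#'   deviation from the true effect among those replicates) and `empSE`
#'   (empirical standard deviation of the conditional estimates).
#' @slot fp mean count of falsely declared mediators per replicate.
#' @slot fdr mean per-replicate false-discovery proportion (0 when a
#'   replicate declares nothing).
#' @slot fpSE,fdrSE Monte-Carlo standard errors of `fp` and `fdr`.
#' @slot nReplicates number of successful replicates summarized.
#' @slot method,mode,n,p the study cell.
#'
#' @exportClass StudyMetrics
setClass("StudyMetrics",
  representation(perMediator = "data.frame", fp = "numeric",
                 fdr = "numeric", fpSE = "numeric", fdrSE = "numeric",
                 nReplicates = "integer",
                 method = "character", mode = "integer", n = "integer",
                 p = "integer")
)

setMethod("show", "StudyMetrics", function(object) {
  cat("StudyMetrics (", object@method, "): mode ", object@mode,
      ", n = ", object@n, ", p = ", object@p, ", R = ",
      object@nReplicates, "\n", sep = "")
  cat("  FP =", signif(object@fp, 4), "| FDR =", signif(object@fdr, 4), "\n")
  pm <- object@perMediator
  num <- vapply(pm, is.numeric, logical(1))
  pm[num] <- lapply(pm[num], signif, digits = 4L)
  print(pm)
})

#' Run one simulation replicate through the pipeline
#'
#' Generates one dataset from the study design and runs every requested
#' method on it. The record per method keeps the MCP support, the set of
#' jointly significant mediators, and the estimated indirect effect for
#' every supported candidate (all as original mediator indices).
#'
#' @param n,p,mode study cell parameters.
#' @param seed replicate seed.
#' @param methods character vector of methods to run.
#' @param alpha,beta optional explicit truth vectors (null designs).
#' @param ... further arguments to [runMediation()].
#' @return named list (per method) of records: `support`, `significant`,
#'   `effect` (named by support index), `seed`.
#' @export
runReplicate <- function(n, p, mode = 1L, seed = 1L,
                         methods = "PSU", alpha = NULL, beta = NULL, ...) {
  cfg <- simulationConfig(n = n, p = p, mode = mode, seed = seed,
                          alpha = alpha, beta = beta)
  ds <- generateDataset(cfg)
  out <- lapply(methods, function(m) {
    res <- runMediation(ds, method = m, ...)
    tab <- resultsTable(res)
    idx <- match(tab$mediator, rownames(ds))
    list(seed = seed, method = m,
         support = idx,
         significant = idx[tab$significant],
         effect = setNames(tab$effect, idx))
  })
  names(out) <- methods
  out
}

#' Summarize replicate records into study metrics
#'
#' @param records list of per-replicate records for one method (each as
#'   produced by [runReplicate()]).
#' @param trueIdx indices of the mediators with a true indirect effect.
#' @param trueEffects their true indirect effects \eqn{\alpha_k\beta_k}.
#' @param method,mode,n,p cell labels carried into the result.
#' @return a [StudyMetrics-class].
#' @export
summarizeStudy <- function(records, trueIdx = 1:8, trueEffects,
                           method = "PSU", mode = 1L, n = NA_integer_,
                           p = NA_integer_) {
  if (!length(records)) stop("no successful replicates to summarize")
  R <- length(records)
  sel <- vapply(trueIdx, function(k)
    sum(vapply(records, function(r) k %in% r$support, logical(1))), numeric(1))
  tpr <- vapply(trueIdx, function(k)
    mean(vapply(records, function(r) k %in% r$significant, logical(1))),
    numeric(1))
  est <- mse <- empse <- rep(NA_real_, length(trueIdx))
  for (i in seq_along(trueIdx)) {
    k <- trueIdx[i]
    e <- unlist(lapply(records, function(r)
      if (k %in% r$support) unname(r$effect[as.character(k)]) else NULL))
    if (length(e)) {
      est[i] <- mean(e)
      mse[i] <- mean((e - trueEffects[i])^2)
      empse[i] <- sd(e)
    }
  }
  fpCounts <- vapply(records, function(r)
    sum(!r$significant %in% trueIdx), numeric(1))
  fdrRep <- vapply(records, function(r) {
    npos <- length(r$significant)
    if (npos == 0L) 0 else sum(!r$significant %in% trueIdx) / npos
  }, numeric(1))
  pm <- data.frame(
    mediator = paste0("M", trueIdx),
    trueEffect = trueEffects,
    selectionCount = as.integer(sel),
    TPR = tpr, estimate = est, MSE = mse, empSE = empse,
    row.names = NULL)
  new("StudyMetrics", perMediator = pm, fp = mean(fpCounts),
      fdr = mean(fdrRep),
      fpSE = sd(fpCounts) / sqrt(R), fdrSE = sd(fdrRep) / sqrt(R),
      nReplicates = as.integer(R),
      method = method, mode = as.integer(mode), n = as.integer(n),
      p = as.integer(p))
}

#' Run a full replication study cell
#'
#' Repeats the generating process `reps` times (replicate r uses seed
#' `seedOffset + r`, so the default offset reproduces seeds 1..R), runs
#' every requested method on each dataset, and summarizes the operating
#' characteristics per method. Replicates are independent, so results are
#' invariant to the worker count.
#'
#' @param mode,n,p study cell.
#' @param methods methods to run on each replicate.
#' @param reps number of replicates.
#' @param seedOffset added to the replicate index to form its seed.
#' @param workers parallel workers (forked; 1 = sequential).
#' @param ... further arguments to [runMediation()].
#' @return named list of [StudyMetrics-class], one per method. Failed
#'   replicates are dropped with a warning.
#' @export
runStudy <- function(mode = 1L, n = 300L, p = 1000L,
                     methods = c("PSU"), reps = 500L, seedOffset = 0L,
                     workers = 1L, ...) {
  cf <- modeCoefficients(mode, max(p, 12L))
  trueEffects <- (cf$alpha * cf$beta)[1:8]
  one <- function(r) {
    tryCatch(runReplicate(n = n, p = p, mode = mode,
                          seed = seedOffset + r, methods = methods, ...),
             error = function(e) structure(conditionMessage(e),
                                           class = "replicateError"))
  }
  recs <- if (workers > 1L)
    parallel::mclapply(seq_len(reps), one, mc.cores = workers)
  else lapply(seq_len(reps), one)
  failed <- vapply(recs, inherits, logical(1), "replicateError")
  if (any(failed)) {
    warning(sum(failed), " replicate(s) failed and were excluded; first: ",
            recs[[which(failed)[1]]])
    recs <- recs[!failed]
  }
  if (!length(recs)) stop("all replicates failed")
  out <- lapply(methods, function(m)
    summarizeStudy(lapply(recs, `[[`, m), trueIdx = 1:8,
                   trueEffects = trueEffects, method = m, mode = mode,
                   n = n, p = p))
  names(out) <- methods
  out
}

#' Export study metrics as delimited tables
#'
#' Writes one CSV per method (per-mediator metrics plus the study-level
#' FP/FDR columns) and a JSON bundle of all metrics.
#'
#' @param metrics named list of [StudyMetrics-class] from [runStudy()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeStudyMetrics <- function(metrics, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list()
  for (m in names(metrics)) {
    s <- metrics[[m]]
    tab <- s@perMediator
    tab$FP <- s@fp
    tab$FDR <- s@fdr
    data.table::fwrite(tab, file.path(dir, paste0("metrics_", m, ".csv")))
    bundle[[m]] <- list(perMediator = s@perMediator, FP = s@fp,
                        FDR = s@fdr, R = s@nReplicates,
                        cell = list(mode = s@mode, n = s@n, p = s@p))
  }
  jsonlite::write_json(bundle, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
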