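# Replication studies shared by the acceptance checks. Cached so that
# several test blocks can interrogate one study without re-running it.
.studyCache <- new.env(parent = emptyenv())

cachedStudy <- function(n, p, methods, reps) {
  key <- paste(n, p, paste(methods, collapse = "+"), reps, sep = "_")
  if (is.null(.studyCache[[key]]))
    .studyCache[[key]] <- runStudy(mode = 1, n = n, p = p,
                                   methods = methods, reps = reps)
  .studyCache[[key]]
}

# Monte-Carlo standard error of a mean over replicates.
mcSE <- function(x) sd(x) / sqrt(length(x))
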