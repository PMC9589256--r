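test_that("replicates are reproducible and distinguish decoys from truth", {
  r1 <- runReplicate(n = 250, p = 100, mode = 1, seed = 6,
                     methods = c("PSU", "COV"))
  r2 <- runReplicate(n = 250, p = 100, mode = 1, seed = 6,
                     methods = c("PSU", "COV"))
  expect_identical(r1, r2)
  expect_named(r1, c("PSU", "COV"))
  # the outcome-only decoys (9, 10) may enter the MCP support, but can
  # never be counted as true positives by the summarizer
  rec <- list(list(seed = 1, method = "PSU", support = c(8L, 9L, 11L),
                   significant = c(8L, 11L),
                   effect = c(`8` = 0.9, `9` = 0.1, `11` = 0.2)))
  s <- summarizeStudy(rec, trueIdx = 1:8,
                      trueEffects = modeCoefficients(1, 12)$alpha[1:8] *
                                    modeCoefficients(1, 12)$beta[1:8])
  expect_equal(s@fp, 1)            # mediator 11 declared but not true
  expect_equal(s@fdr, 0.5)
})

test_that("summaries match a manual tally on hand-built records", {
  trueEff <- c(0.06, 0.0864, 0.135, 0.1536, 0.24, 0.3456, 0.54, 0.96)
  recs <- list(
    list(seed = 1, method = "PSU", support = c(1L, 5L, 8L, 20L),
         significant = c(5L, 8L),
         effect = c(`1` = 0.05, `5` = 0.30, `8` = 1.00, `20` = 0.10)),
    list(seed = 2, method = "PSU", support = c(5L, 8L),
         significant = c(5L, 8L),
         effect = c(`5` = 0.20, `8` = 0.90)),
    list(seed = 3, method = "PSU", support = c(8L, 33L),
         significant = c(8L, 33L),
         effect = c(`8` = 0.98, `33` = -0.20))
  )
  s <- summarizeStudy(recs, trueIdx = 1:8, trueEffects = trueEff)
  pm <- s@perMediator
  expect_equal(pm$selectionCount, c(1, 0, 0, 0, 2, 0, 0, 3))
  expect_equal(pm$TPR, c(0, 0, 0, 0, 2 / 3, 0, 0, 1))
  expect_equal(pm$estimate[5], mean(c(0.30, 0.20)))
  expect_equal(pm$estimate[8], mean(c(1.00, 0.90, 0.98)))
  expect_equal(pm$MSE[8], mean((c(1.00, 0.90, 0.98) - 0.96)^2))
  expect_true(is.na(pm$estimate[2]))
  # replicate 3 declares one false of two positives; others none
  expect_equal(s@fp, mean(c(0, 0, 1)))
  expect_equal(s@fdr, mean(c(0, 0, 0.5)))
  expect_error(summarizeStudy(list(), trueIdx = 1:8, trueEffects = trueEff),
               "no successful")
})

test_that("a per-replicate false discovery with nine hits contributes 0.1", {
  trueEff <- rep(0.1, 8)
  rec <- list(list(seed = 1, method = "PSU",
                   support = c(1:8, 50L), significant = c(1:8, 50L),
                   effect = setNames(rep(0.1, 9), c(1:8, 50))))
  s <- summarizeStudy(rec, trueIdx = 1:8, trueEffects = trueEff)
  expect_equal(s@fdr, 1 / 9)
  expect_equal(s@fp, 1)
})

test_that("study cells run end-to-end for every method and stay seed-stable", {
  st <- runStudy(mode = 1, n = 300, p = 200,
                 methods = c("PSR", "PSW", "PSU", "COV"), reps = 2)
  expect_named(st, c("PSR", "PSW", "PSU", "COV"))
  for (s in st) {
    expect_s4_class(s, "StudyMetrics")
    expect_equal(s@nReplicates, 2L)
    expect_true(all(s@perMediator$TPR >= 0 & s@perMediator$TPR <= 1))
    expect_true(all(s@perMediator$selectionCount <= 2))
  }
  # worker count must not change results (per-replicate seeding)
  st1 <- runStudy(mode = 1, n = 200, p = 100, methods = "PSU", reps = 3,
                  workers = 1)
  st2 <- runStudy(mode = 1, n = 200, p = 100, methods = "PSU", reps = 3,
                  workers = 2)
  expect_equal(st1$PSU@perMediator, st2$PSU@perMediator)
  # the joint test can only discard MCP-selected mediators
  expect_true(all(st1$PSU@perMediator$TPR * 3 <=
                  st1$PSU@perMediator$selectionCount))
})

test_that("study metrics export to delimited tables and JSON", {
  st <- runStudy(mode = 1, n = 200, p = 100, methods = "PSU", reps = 2)
  dir <- withr::local_tempdir()
  writeStudyMetrics(st, dir)
  expect_true(file.exists(file.path(dir, "metrics_PSU.csv")))
  bundle <- jsonlite::read_json(file.path(dir, "metrics.json"))
  expect_equal(bundle$PSU$R, 2L)
  expect_equal(bundle$PSU$cell$p, 100L)
})
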