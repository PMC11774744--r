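# small searchable cohort: planted genes G1..G3 among a pool of 12
smallSearchData <- function(seed = 1, n = 140, nGenes = 12,
                            effects = c(1.2, 1.0, 0.8)) {
  sim <- simulateCohort(cohortSpec(
    nPatients = n, nGenes = nGenes,
    signatureGenes = paste0("G", seq_along(effects)),
    effects = effects, seed = seed))
  out <- outcomeFromStatus(sim$cohort)
  labeledCohort(sim$expr[, names(out)], out, "train")
}

test_that("beam-step candidate expansion deduplicates gene sets", {
  lc <- smallSearchData(seed = 3)
  cfg <- searchConfig(seed = 3, keepFraction = 1, pNew = 1 - 1e-9,
                      pRetained = 1 - 1e-9)
  survivors <- list(list(genes = "G1"), list(genes = "G2"))
  out <- beamStep(survivors, c("G1", "G2", "G3"), lc, cfg)
  counts <- attr(out, "counts")
  expect_equal(counts$candidatesRaw, 4)     # {G1}+G2, {G1}+G3, {G2}+G1, {G2}+G3
  expect_equal(counts$candidatesUnique, 3)  # {G1,G2} reached twice
  keys <- sort(vapply(out, function(m) paste(sort(m@genes), collapse = "."),
                      ""))
  expect_identical(keys, c("G1.G2", "G1.G3", "G2.G3"))
})

test_that("gate failures drop candidates and an empty pool errors", {
  lc <- smallSearchData(seed = 5)
  # impossible gate: nothing can pass
  cfgStrict <- searchConfig(seed = 5, pNew = 1e-12, pRetained = 1e-12)
  out <- beamStep(list(list(genes = "G1")), paste0("G", 1:6), lc, cfgStrict)
  expect_length(out, 0)
  expect_error(searchSignatures(lc, character(0)), "empty")
  expect_error(searchSignatures(lc, "nope"), "nope")
})

test_that("every registry model satisfies its gates when refit from scratch", {
  lc <- smallSearchData(seed = 7)
  cfg <- searchConfig(seed = 7, maxSize = 5)
  reg <- searchSignatures(lc, paste0("G", 1:12), cfg)
  expect_gt(length(reg$models), 0)
  keys <- vapply(reg$models, function(m)
    paste(sort(m@genes), collapse = "."), "")
  expect_false(any(duplicated(keys)))
  for (m in reg$models) {
    refit <- fitLogistic(m@genes, lc)
    p <- refit@pValues
    k <- length(p)
    expect_lt(p[[k]], if (k == 1) cfg$pRetained else cfg$pNew)
    if (k > 1) expect_true(all(p[-k] < cfg$pRetained))
    expect_equal(unname(refit@coefficients), unname(m@coefficients),
                 tolerance = 1e-8)
  }
})

test_that("the search is bit-reproducible and respects maxSize", {
  lc <- smallSearchData(seed = 11)
  cfg <- searchConfig(seed = 11, maxSize = 4)
  r1 <- searchSignatures(lc, paste0("G", 1:12), cfg)
  r2 <- searchSignatures(lc, paste0("G", 1:12), cfg)
  expect_identical(lapply(r1$models, function(m) m@genes),
                   lapply(r2$models, function(m) m@genes))
  expect_identical(vapply(r1$models, function(m) m@cvAuc, numeric(1)),
                   vapply(r2$models, function(m) m@cvAuc, numeric(1)))
  expect_lte(max(lengths(lapply(r1$models, function(m) m@genes))), 4)

  one <- searchSignatures(lc, paste0("G", 1:12),
                          searchConfig(seed = 11, maxSize = 1))
  expect_true(all(vapply(one$models, function(m) length(m@genes), 1L) == 1L))
})

test_that("null gene pools leave the registry small", {
  sim <- simulateCohort(cohortSpec(nPatients = 60, nGenes = 10,
                                   signatureGenes = "G1", effects = 0,
                                   seed = 13))
  out <- outcomeFromStatus(sim$cohort)
  lc <- labeledCohort(sim$expr[, names(out)], out)
  reg <- searchSignatures(lc, paste0("G", 1:3),
                          searchConfig(seed = 13, maxSize = 3))
  # most size-1 null models fail the p < 0.05 gate
  expect_lte(sum(reg$counts$gated[1]), 2)
})

test_that("model selection applies the AUC threshold and CV tie-break rule", {
  lc <- smallSearchData(seed = 17)
  sim2 <- simulateCohort(cohortSpec(nPatients = 80, nGenes = 12,
                                    signatureGenes = paste0("G", 1:3),
                                    effects = c(1.2, 1.0, 0.8), seed = 18))
  out2 <- outcomeFromStatus(sim2$cohort)
  test <- labeledCohort(sim2$expr[, names(out2)], out2, "test")
  cfg <- searchConfig(seed = 17, maxSize = 4)
  reg <- searchSignatures(lc, paste0("G", 1:12), cfg)

  selNone <- selectBest(reg, lc, test, searchConfig(seed = 17,
                                                    aucThreshold = 0.999))
  expect_identical(selNone$status, "no model meets threshold")
  expect_null(selNone$model)

  selAll <- selectBest(reg, lc, test, searchConfig(seed = 17,
                                                   aucThreshold = 0.5))
  expect_identical(selAll$status, "ok")
  # the winner has the maximum CV AUC among eligible models
  evalAuc <- function(m) {
    sc <- m@intercept + as.numeric(test@x[, m@genes, drop = FALSE] %*%
                                     m@coefficients)
    rocAuc(sc, test@outcome)
  }
  eligible <- Filter(function(m) m@trainAuc > 0.5 && evalAuc(m) > 0.5,
                     reg$models)
  expect_equal(selAll$model@cvAuc,
               max(vapply(eligible, function(m) m@cvAuc, numeric(1))))
  expect_equal(selAll$model@testAuc, evalAuc(selAll$model),
               tolerance = 1e-12)
})

test_that("stratified splitting preserves class balance and sample identity", {
  sim <- simulateCohort(cohortSpec(seed = 19))
  out <- outcomeFromStatus(sim$cohort)
  sp <- splitCohort(sim$expr, out, fraction = 0.7, seed = 19)
  expect_setequal(c(rownames(sp$train@x), rownames(sp$test@x)), names(out))
  expect_equal(mean(sp$train@outcome), mean(out), tolerance = 0.05)
  expect_identical(sp$train@split, "train")
  sp2 <- splitCohort(sim$expr, out, fraction = 0.7, seed = 19)
  expect_identical(rownames(sp$train@x), rownames(sp2$train@x))
})
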