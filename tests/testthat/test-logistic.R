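makeCohort <- function(n = 80, p = 3, seed = 4, beta = c(1, -0.5, 0),
                       alpha = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("P", seq_len(n)), LETTERS[seq_len(p)]))
  y <- rbinom(n, 1, plogis(alpha + X %*% beta))
  em <- ExpressionMatrix(t(X), "external_normalized")
  labeledCohort(em, y)
}

test_that("logistic fits match stats::glm coefficients and Wald p-values", {
  lc <- makeCohort()
  m <- fitLogistic(c("A", "B", "C"), lc)
  g <- glm(lc@outcome ~ lc@x[, c("A", "B", "C")], family = binomial)
  expect_equal(unname(c(m@intercept, m@coefficients)), unname(coef(g)),
               tolerance = 1e-8)
  expect_equal(unname(m@pValues),
               unname(summary(g)$coefficients[-1, 4]), tolerance = 1e-6)
  expect_true(m@converged)
  expect_false(m@separation)
})

test_that("intercept-only fit recovers the log-odds of the prevalence", {
  lc <- makeCohort(n = 40)
  lc@outcome <- rep(c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L), 4)
  m <- fitLogistic(character(0), lc)
  expect_equal(m@intercept, log(0.1 / 0.9), tolerance = 1e-8)
  expect_equal(m@trainAuc, 0.5)  # all scores tied
})

test_that("separation and degenerate cohorts are flagged or rejected", {
  lc <- makeCohort()
  lc@outcome <- as.integer(lc@x[, "A"] > 0)  # perfect single-gene separation
  m <- fitLogistic("A", lc)
  expect_true(m@separation)

  lcOne <- makeCohort()
  lcOne@outcome <- rep(1L, nrow(lcOne@x))
  expect_error(fitLogistic("A", lcOne), "both outcome classes")
  expect_error(fitLogistic("ZZ", makeCohort()), "ZZ")
})

test_that("ROC AUC follows the Mann-Whitney pair-counting definition", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1.0)
  # 2 concordant of 4 pos-neg pairs
  expect_equal(rocAuc(c(0.9, 0.4, 0.6, 0.2), c(1, 0, 0, 1)), 0.5)
  expect_equal(rocAuc(rep(0.7, 6), c(1, 0, 1, 0, 1, 0)), 0.5)  # all tied
  expect_error(rocAuc(1:4, c(1, 1, 1, 1)), "both classes")

  set.seed(31)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    sc <- sample(seq(0, 1, 0.25), n, replace = TRUE)  # force ties
    lb <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(rocAuc(sc, lb), oracleAuc(sc, lb), tolerance = 1e-12)
    expect_equal(rocAuc(sc, lb) + rocAuc(-sc, lb), 1, tolerance = 1e-12)
  }
})

test_that("cross-validated AUC is deterministic and calibrated on null genes", {
  lc <- makeCohort(n = 120, seed = 8)
  cfg <- searchConfig(seed = 77)
  a1 <- cvAuc(c("A", "B"), lc, cfg)
  a2 <- cvAuc(c("A", "B"), lc, cfg)
  expect_identical(a1, a2)
  expect_false(identical(a1, cvAuc(c("A", "B"), lc, searchConfig(seed = 78))))

  # null gene: mean CV AUC near 0.5 over simulations
  aucs <- vapply(1:25, function(r) {
    lcn <- makeCohort(n = 150, seed = 100 + r, beta = c(0, 0, 0))
    cvAuc("A", lcn, searchConfig(seed = r))
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)

  # strong gene: high CV AUC with high probability
  hits <- vapply(1:15, function(r) {
    lcs <- makeCohort(n = 300, seed = 200 + r, beta = c(2, 0, 0))
    cvAuc("A", lcs, searchConfig(seed = r)) > 0.75
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  tiny <- makeCohort(n = 8)
  tiny@outcome <- c(1L, rep(0L, 7))
  expect_error(cvAuc("A", tiny, cfg), "too small")
})

test_that("Wald p-values of a null gene are uniform", {
  ps <- vapply(1:120, function(r) {
    lc <- makeCohort(n = 400, p = 1, seed = 300 + r, beta = 0)
    fitLogistic("A", lc)@pValues[["A"]]
  }, numeric(1))
  # fraction below 0.05 within 3 binomial SEs of 0.05
  expect_lt(abs(mean(ps < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 120))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("classification applies the strict probability threshold", {
  m <- new("GeneSignatureModel", genes = "A", intercept = 0,
           coefficients = c(A = 1), pValues = c(A = 0.01),
           trainAuc = NA_real_, cvAuc = NA_real_, testAuc = NA_real_,
           converged = TRUE, separation = FALSE)
  x <- matrix(c(0, 1, -1), 3, 1, dimnames = list(paste0("P", 1:3), "A"))
  out <- classifySamples(m, x)
  expect_equal(out$probability, plogis(c(0, 1, -1)))
  expect_identical(out$label, c("favorable", "unfavorable", "favorable"))

  mInt <- new("GeneSignatureModel", genes = character(0), intercept = 10,
              coefficients = numeric(0), pValues = numeric(0),
              trainAuc = NA_real_, cvAuc = NA_real_, testAuc = NA_real_,
              converged = TRUE, separation = FALSE)
  expect_true(all(classifySamples(mInt, x)$label == "unfavorable"))
  expect_error(classifySamples(m, matrix(1, 1, 1,
                                         dimnames = list("P1", "B"))), "A")
})

test_that("a model reapplied to its training cohort reproduces its train AUC", {
  lc <- makeCohort(n = 100, seed = 5)
  m <- fitLogistic(c("A", "B"), lc)
  em <- ExpressionMatrix(t(lc@x), "external_normalized")
  prob <- classifySamples(m, em)$probability
  expect_equal(rocAuc(prob, lc@outcome), m@trainAuc, tolerance = 1e-12)
})
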