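makeExprFromRows <- function(rows, samples) {
  ExpressionMatrix(matrix(unlist(rows), nrow = length(rows), byrow = TRUE,
                          dimnames = list(names(rows), samples)),
                   normalization = "external_normalized")
}

test_that("Spearman rho is invariant under monotone transforms and matches the rank formula", {
  s <- paste0("S", 1:7)
  ic <- setNames(c(0.5, 2, 8, 1, 30, 12, 4), s)
  em <- makeExprFromRows(list(up = exp(ic) + 1, down = -ic,
                              curved = log(ic)^1), s)
  tb <- screenTable(spearmanScreen(em, ic))
  expect_equal(tb$rho[tb$gene == "up"], 1)
  expect_equal(tb$rho[tb$gene == "down"], -1)
  expect_equal(tb$rho[tb$gene == "curved"], 1)

  # frozen fixture: ranks (1..5) vs (2,1,4,3,5): sum d^2 = 4 so
  # rho = 1 - 6*4/(5*24) = 0.8, confirmed by the brute-force rank formula
  s5 <- paste0("S", 1:5)
  em5 <- makeExprFromRows(list(g = c(1, 2, 3, 4, 5)), s5)
  ic5 <- setNames(c(2, 1, 4, 3, 5), s5)
  tb5 <- screenTable(spearmanScreen(em5, ic5))
  expect_equal(tb5$rho, 0.8)
  expect_equal(tb5$rho, oracleSpearman(c(1, 2, 3, 4, 5), ic5))
})

test_that("t-approximation p-values match the standard large-sample formula", {
  set.seed(21)
  s <- paste0("S", 1:15)
  ic <- setNames(exp(rnorm(15)), s)
  em <- makeExprFromRows(list(a = rnorm(15), b = rnorm(15) + log(ic)), s)
  tb <- screenTable(spearmanScreen(em, ic))
  for (i in 1:2) {
    ct <- suppressWarnings(
      cor.test(exprValues(em)[i, s], ic, method = "spearman",
               exact = FALSE))
    expect_equal(tb$rho[i], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(tb$p[i], ct$p.value, tolerance = 1e-9)
  }
})

test_that("exact permutation p-values agree with enumeration oracles", {
  # tie-free case: cor.test's exact distribution is the oracle
  set.seed(5)
  s <- paste0("S", 1:8)
  x <- sample(8); ic <- setNames(as.numeric(sample(8)), s)
  em <- makeExprFromRows(list(g = x), s)
  cfg <- screenConfig(pMethod = "exact_permutation")
  tb <- screenTable(spearmanScreen(em, ic, cfg))
  ct <- cor.test(x, unname(ic), method = "spearman", exact = TRUE)
  expect_equal(tb$p, ct$p.value, tolerance = 1e-12)

  # tied case: direct enumeration of all 720 permutations
  s6 <- paste0("S", 1:6)
  x6 <- c(1, 1, 2, 3, 3, 4); ic6 <- setNames(c(2, 1, 1, 4, 3, 5), s6)
  em6 <- makeExprFromRows(list(g = x6), s6)
  tb6 <- screenTable(spearmanScreen(em6, ic6, cfg))
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 6), ]
  obs <- oracleSpearman(x6, ic6)
  null <- apply(perms, 1, function(p) oracleSpearman(x6, ic6[p]))
  expect_equal(tb6$p, mean(abs(null) >= abs(obs) - 1e-12),
               tolerance = 1e-12)
  expect_error(spearmanScreen(makeExprFromRows(list(g = rnorm(12)),
                                               paste0("S", 1:12)),
                              setNames(rnorm(12), paste0("S", 1:12)), cfg),
               "n <= 10")
})

test_that("constant genes yield NaN rho without an exception and few samples error", {
  s <- paste0("S", 1:6)
  em <- makeExprFromRows(list(flat = rep(3, 6), ok = rnorm(6)), s)
  ic <- setNames(exp(rnorm(6)), s)
  tb <- screenTable(spearmanScreen(em, ic))
  expect_true(is.nan(tb$rho[tb$gene == "flat"]))
  expect_false(tb$significant[tb$gene == "flat"])
  expect_error(spearmanScreen(em[, 1:3], ic[1:3]), "at least 4")
})

test_that("missing IC50 values are dropped pairwise", {
  s <- paste0("S", 1:8)
  em <- makeExprFromRows(list(g = 1:8), s)
  ic <- setNames(c(1, 2, NA, 4, 5, 6, NA, 8), s)
  tb <- screenTable(spearmanScreen(em, ic))
  expect_equal(tb$n, 6)
  expect_equal(tb$rho, 1)
})

test_that("significance filtering applies strict thresholds on both gates", {
  mk <- function(rho, p) {
    tb <- data.frame(gene = paste0("g", seq_along(rho)), rho = rho, p = p,
                     n = 20,
                     significant = abs(rho) > 0.3 & p < 0.05,
                     direction = ifelse(abs(rho) > 0.3 & p < 0.05,
                                        ifelse(rho > 0, "+", "-"), "none"))
    new("CorrelationScreenResult", datasetId = "d", drug = "x", table = tb,
        config = unclass(screenConfig()))
  }
  res <- mk(c(0.30, -0.6, 0.9, 0.31), c(0.001, 0.01, 0.2, 0.049))
  fs <- filterSignificant(res)
  expect_false("g1" %in% c(fs$positive, fs$negative))  # rho == 0.30 excluded
  expect_identical(fs$negative, "g2")
  expect_false("g3" %in% fs$positive)                  # p gate
  expect_identical(fs$positive, "g4")
})

test_that("co-directional intersection follows set algebra and drops conflicting genes", {
  d1 <- list(positive = c("A", "C"), negative = "B")
  d2 <- list(positive = c("A", "D"), negative = "B")
  ix <- codirectionalIntersection(list(ds1 = d1, ds2 = d2), drug = "5-FU")
  expect_identical(ix$positive_genes, "A")
  expect_identical(ix$negative_genes, "B")
  expect_identical(ix$contributing_datasets, c("ds1", "ds2"))

  # significant + in one dataset, - in the other: excluded from both sets
  ix2 <- codirectionalIntersection(list(list(positive = "X", negative = character(0)),
                                        list(positive = character(0), negative = "X")))
  expect_length(ix2$positive_genes, 0)
  expect_length(ix2$negative_genes, 0)
  expect_error(codirectionalIntersection(list(d1)), "at least 2")
})

test_that("intersection equals a brute-force set oracle on random instances", {
  set.seed(99)
  genes <- paste0("G", 1:50)
  for (rep in 1:25) {
    nd <- sample(2:4, 1)
    sets <- lapply(seq_len(nd), function(i) {
      sig <- sample(genes, sample(0:25, 1))
      pos <- sample(sig, rbinom(1, length(sig), 0.5))
      list(positive = pos, negative = setdiff(sig, pos))
    })
    ix <- codirectionalIntersection(sets)
    oraclePos <- genes[vapply(genes, function(g)
      all(vapply(sets, function(s) g %in% s$positive, logical(1))),
      logical(1))]
    oracleNeg <- genes[vapply(genes, function(g)
      all(vapply(sets, function(s) g %in% s$negative, logical(1))),
      logical(1))]
    expect_setequal(ix$positive_genes, oraclePos)
    expect_setequal(ix$negative_genes, oracleNeg)
  }
})

test_that("cross-drug overlap reports pairwise/triple intersections and contradictions", {
  mkIx <- function(drug, pos, neg)
    structure(list(drug = drug, positive_genes = pos, negative_genes = neg,
                   contributing_datasets = "d"),
              class = "IntersectionResult")
  ov <- crossDrugOverlap(list(
    `5-FU` = mkIx("5-FU", c("X", "Z"), "N1"),
    OXA = mkIx("OXA", "X", c("N1", "Z")),
    `SN-38` = mkIx("SN-38", "Q", character(0))))
  pw <- ov$pairwise
  expect_equal(pw$positive[pw$drug1 == "5-FU" & pw$drug2 == "OXA"], "X")
  expect_equal(pw$negative[pw$drug1 == "5-FU" & pw$drug2 == "OXA"], "N1")
  expect_identical(ov$contradictions, "Z")   # + for 5-FU, - for OXA
  expect_length(ov$allDrugs$positive, 0)

  disjoint <- crossDrugOverlap(list(
    a = mkIx("a", "A", character(0)), b = mkIx("b", "B", character(0)),
    c = mkIx("c", "C", character(0))))
  expect_true(all(disjoint$pairwise$positive == ""))
  expect_length(disjoint$contradictions, 0)
})
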