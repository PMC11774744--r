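# shared fixtures built in code

# small named count matrix
makeCounts <- function(nGenes = 6, nSamples = 4, seed = 1, lambda = 100) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    m <- matrix(rpois(nGenes * nSamples, lambda), nGenes, nSamples,
                dimnames = list(paste0("G", seq_len(nGenes)),
                                paste0("S", seq_len(nSamples))))
    m
  })
}

# brute-force median-of-ratios size factors, straight from the definition
oracleSizeFactors <- function(counts) {
  ref <- exp(rowMeans(log(counts)))        # geometric mean per gene
  use <- apply(counts > 0, 1, all)         # genes without zeros
  apply(counts, 2, function(col) median((col / ref)[use]))
}

# brute-force TMM factor of `sample` against `ref` (doubly trimmed,
# precision-weighted mean of log ratios), straight from the definition
oracleTMMFactor <- function(counts, sample, ref, trimM = 0.30,
                            trimA = 0.05) {
  yi <- counts[, sample]; yr <- counts[, ref]
  Ni <- sum(yi); Nr <- sum(yr)
  keep <- yi > 0 & yr > 0
  M <- log2((yi[keep] / Ni) / (yr[keep] / Nr))
  A <- 0.5 * log2((yi[keep] / Ni) * (yr[keep] / Nr))
  w <- (Ni - yi[keep]) / (Ni * yi[keep]) + (Nr - yr[keep]) / (Nr * yr[keep])
  n <- length(M)
  loM <- floor(n * trimM) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
  sel <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  2^(sum((M / w)[sel]) / sum((1 / w)[sel]))
}

# exhaustive pairwise-concordance ROC AUC oracle
oracleAuc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# brute-force log-rank statistic: O-E/V over distinct event times
oracleLogrank <- function(times, events, groups) {
  groups <- as.character(groups)
  g1 <- unique(groups)[1]
  ts <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    atRisk <- times >= t
    n <- sum(atRisk); n1 <- sum(atRisk & groups == g1)
    d <- sum(events == 1 & times == t)
    d1 <- sum(events == 1 & times == t & groups == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# brute-force Spearman rho via the rank formula (mid-ranks)
oracleSpearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# named IC50 vector out of a one-drug panel dataset
panelIc50 <- function(dataset) {
  setNames(ic50Values(dataset$response)[, 1],
           rownames(ic50Values(dataset$response)))
}

writeTempTsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
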