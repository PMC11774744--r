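#' Median-of-ratios size-factor log transform
#'
#' Variance-flattening log transform for count matrices ahead of the
#' Spearman screen. Per-sample size factors are the median over genes of
#' the ratio count / geometric-mean-of-gene (genes containing any zero are
#' excluded from the reference set), and the output is
#' `log2(count / sizeFactor + pseudocount)`. Because the transform is
#' monotone within each sample it preserves the within-sample and
#' between-sample rank structure the screen depends on.
#'
#' @param expr an [ExpressionMatrix-class] with `normalization ==
#'   "raw_counts"`.
#' @param pseudocount positive stabilizing constant added after size-factor
#'   scaling (default 1).
#' @return An [ExpressionMatrix-class] tagged `"log_size_factor"`, with the
#'   size factors in `attr(, "sizeFactors")` via `metadata`.
#' @export
sizeFactorLogTransform <- function(expr, pseudocount = 1) {
  stopifnot(is(expr, "ExpressionMatrix"))
  if (normalization(expr) != "raw_counts")
    stop("sizeFactorLogTransform expects raw counts, got ",
         normalization(expr))
  if (!(pseudocount > 0)) stop("pseudocount must be positive")
  counts <- exprValues(expr)
  if (!any(rowSums(counts == 0) == 0))
    stop("no reference genes for size factors ",
         "(every gene contains at least one zero count)")
  sf <- DESeq2::estimateSizeFactorsForMatrix(counts)
  out <- log2(sweep(counts, 2L, sf, "/") + pseudocount)
  res <- ExpressionMatrix(out, normalization = "log_size_factor")
  S4Vectors::metadata(res)$sizeFactors <- sf
  res
}

#' TMM-normalized log2 counts per million
#'
#' Trimmed-mean-of-M-values normalization followed by log2 CPM, the
#' standard count normalization for cohort-level RNA-seq classifiers.
#' Scaling factors come from the doubly trimmed (by log-ratio M and
#' absolute-intensity A), precision-weighted mean of log ratios against a
#' reference sample, rescaled so their geometric mean is 1; effective
#' library size = raw library size x factor.
#'
#' @param expr an [ExpressionMatrix-class] with `normalization ==
#'   "raw_counts"`.
#' @param reference sample id to normalize against, or `"auto"` (sample
#'   whose upper quartile is closest to the mean upper quartile).
#' @param trimM trim fraction on log-ratios (default 0.30).
#' @param trimA trim fraction on average log intensity (default 0.05).
#' @param priorCount prior count for the log-CPM transform (default 0.5).
#' @return An [ExpressionMatrix-class] tagged `"tmm_logcpm"`, with the
#'   normalization factors stored in `metadata(.)$tmmFactors`.
#' @export
tmmLogCPM <- function(expr, reference = "auto", trimM = 0.30, trimA = 0.05,
                      priorCount = 0.5) {
  stopifnot(is(expr, "ExpressionMatrix"))
  if (normalization(expr) != "raw_counts")
    stop("tmmLogCPM expects raw counts, got ", normalization(expr))
  if (trimM < 0 || trimM >= 0.5 || trimA < 0 || trimA >= 0.5)
    stop("trim fractions must lie in [0, 0.5)")
  counts <- exprValues(expr)
  libs <- colSums(counts)
  if (any(libs == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[libs == 0], collapse = ", "))
  refCol <- NULL
  if (!identical(reference, "auto")) {
    refCol <- match(reference, colnames(counts))
    if (is.na(refCol)) stop("reference sample not found: ", reference)
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = refCol,
                              logratioTrim = trimM, sumTrim = trimA)
  dge <- edgeR::DGEList(counts = counts, norm.factors = f)
  out <- edgeR::cpm(dge, log = TRUE, prior.count = priorCount)
  res <- ExpressionMatrix(out, normalization = "tmm_logcpm")
  S4Vectors::metadata(res)$tmmFactors <- setNames(f, colnames(counts))
  res
}

#' Collapse replicate samples to one profile per culture
#'
#' Replicate expression profiles (e.g. three RNA-seq libraries per organoid
#' culture) are averaged on the normalized scale, since IC50 is a
#' per-culture quantity.
#'
#' @param expr a normalized [ExpressionMatrix-class].
#' @param groups factor/character of length `ncol(expr)` mapping each
#'   sample to its culture.
#' @return An [ExpressionMatrix-class] with one column per culture,
#'   carrying the input normalization tag.
#' @export
collapseReplicates <- function(expr, groups) {
  stopifnot(is(expr, "ExpressionMatrix"))
  if (normalization(expr) == "raw_counts")
    stop("collapse replicates on the normalized scale, not raw counts")
  groups <- as.character(groups)
  if (length(groups) != ncol(expr))
    stop("groups must have one entry per sample")
  v <- exprValues(expr)
  ug <- unique(groups)
  out <- vapply(ug, function(g) rowMeans(v[, groups == g, drop = FALSE]),
                numeric(nrow(v)))
  colnames(out) <- ug
  ExpressionMatrix(out, normalization = normalization(expr))
}
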