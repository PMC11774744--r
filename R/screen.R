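#' Configuration for the Spearman IC50 screen
#'
#' A gene is called significant when `|rho| > rhoThreshold` (strict) and
#' `p < alpha` (strict). The default thresholds (0.3, 0.05) reflect that
#' drug response is multifactorial, so individually modest but reproducible
#' correlations are retained and reliability is enforced through the
#' cross-dataset intersection instead of multiple-testing correction.
#'
#' @param rhoThreshold minimum absolute Spearman coefficient (default 0.3).
#' @param alpha p-value threshold (default 0.05).
#' @param pMethod `"t_approx"` (t-statistic approximation
#'   `t = rho * sqrt((n-2)/(1-rho^2))`) or `"exact_permutation"` (exact
#'   permutation null, available for n <= 10, where the approximation is
#'   weakest -- e.g. a 7-culture organoid panel).
#' @return A list with class `"ScreenConfig"`.
#' @export
screenConfig <- function(rhoThreshold = 0.3, alpha = 0.05,
                         pMethod = c("t_approx", "exact_permutation")) {
  pMethod <- match.arg(pMethod)
  if (!(rhoThreshold > 0 && rhoThreshold < 1))
    stop("rhoThreshold must lie in (0, 1)")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  structure(list(rhoThreshold = rhoThreshold, alpha = alpha,
                 pMethod = pMethod), class = "ScreenConfig")
}

# two-sided p for Spearman rho via the t approximation
spearmanPT <- function(rho, n) {
  p <- rep(NA_real_, length(rho))
  ok <- is.finite(rho)
  r <- pmin(pmax(rho[ok], -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p[ok] <- 2 * pt(-abs(tt), df = n - 2)
  p[ok][abs(r) >= 1 - 1e-15] <- 0
  p
}

# exact two-sided permutation p for one gene; distribution cached by the
# rank multisets (identical for all tie-free genes)
spearmanPExact <- function(ra, rb, rho, cache) {
  a2 <- as.integer(round(2 * ra)); b2 <- as.integer(round(2 * rb))
  key <- paste(c(sort(a2), -1L, sort(b2)), collapse = ",")
  dist <- cache[[key]]
  if (is.null(dist)) {
    dist <- cpp_spearman_perm_dist(a2, b2)
    cache[[key]] <- dist
  }
  n <- length(ra)
  tvals <- (seq_along(dist) - 1) / 4  # T = sum a_i * b_perm(i)
  rhoT <- (tvals - n * mean(ra) * mean(rb)) /
    ((n - 1) * stats::sd(ra) * stats::sd(rb))
  keep <- dist > 0
  sum(dist[keep][abs(rhoT[keep]) >= abs(rho) - 1e-12]) / sum(dist)
}

#' Spearman screen of gene expression against IC50
#'
#' Computes, for every gene, the Spearman correlation (mid-ranks for ties)
#' between its expression and the per-sample IC50 of one drug, restricted
#' to the samples shared by both inputs after pairwise removal of missing
#' IC50 values. Constant genes (all ranks tied) get `rho = NaN` and are
#' flagged non-significant.
#'
#' @param expr an [ExpressionMatrix-class] (any normalization; the ranks
#'   are what matter).
#' @param ic50 a named per-sample IC50 vector, or a
#'   [DrugResponseTable-class] (then `drug` selects the column).
#' @param config a [screenConfig()].
#' @param datasetId label for this dataset (e.g. `"ORGANOIDS"`, `"GDSC1"`).
#' @param drug drug name (required when `ic50` is a table).
#' @return A [CorrelationScreenResult-class].
#' @export
spearmanScreen <- function(expr, ic50, config = screenConfig(),
                           datasetId = "dataset", drug = "drug") {
  stopifnot(is(expr, "ExpressionMatrix"))
  if (is(ic50, "DrugResponseTable")) {
    if (!drug %in% drugNames(ic50)) stop("drug not in response table: ", drug)
    ic50 <- ic50Values(ic50)[, drug]
  }
  if (is.null(names(ic50))) stop("ic50 vector must be named by sample id")
  shared <- intersect(sampleIds(expr), names(ic50))
  y <- ic50[shared]
  shared <- shared[is.finite(y)]
  y <- ic50[shared]
  n <- length(shared)
  if (n < 4) stop("need at least 4 shared samples with IC50 values, got ", n)
  v <- exprValues(expr)[, shared, drop = FALSE]

  ry <- rank(y)
  rx <- t(apply(v, 1L, rank))
  sdx <- apply(rx, 1L, stats::sd)
  constant <- sdx == 0
  rho <- rep(NaN, nrow(v))
  if (any(!constant)) {
    rxc <- rx[!constant, , drop = FALSE]
    rho[!constant] <- as.numeric(
      stats::cor(t(rxc), ry, method = "pearson"))
  }

  if (config$pMethod == "t_approx") {
    p <- spearmanPT(rho, n)
  } else {
    if (n > 10)
      stop("exact permutation p-values are limited to n <= 10 samples")
    cache <- new.env(parent = emptyenv())
    p <- rep(NA_real_, nrow(v))
    for (i in which(!constant))
      p[i] <- spearmanPExact(rx[i, ], ry, rho[i], cache)
  }

  sig <- !is.na(rho) & is.finite(rho) & !is.na(p) &
    abs(rho) > config$rhoThreshold & p < config$alpha
  direction <- ifelse(sig, ifelse(rho > 0, "+", "-"), "none")
  tb <- data.frame(gene = rownames(v), rho = rho, p = p, n = n,
                   significant = sig, direction = direction,
                   stringsAsFactors = FALSE, row.names = NULL)
  new("CorrelationScreenResult", datasetId = datasetId, drug = drug,
      table = tb, config = unclass(config))
}

#' Split a screen result into positively / negatively correlated gene sets
#'
#' Applies the significance rule (strict `|rho| > rhoThreshold`, strict
#' `p < alpha`) and partitions the significant genes by the sign of rho.
#'
#' @param result a [CorrelationScreenResult-class].
#' @param config optional [screenConfig()] overriding the one stored in
#'   `result`.
#' @return list with character vectors `positive` and `negative`.
#' @export
filterSignificant <- function(result, config = NULL) {
  stopifnot(is(result, "CorrelationScreenResult"))
  cfg <- if (is.null(config)) result@config else unclass(config)
  tb <- result@table
  sig <- !is.na(tb$rho) & !is.na(tb$p) &
    abs(tb$rho) > cfg$rhoThreshold & tb$p < cfg$alpha
  list(positive = tb$gene[sig & tb$rho > 0],
       negative = tb$gene[sig & tb$rho < 0])
}

#' Co-directional intersection of screening hits across datasets
#'
#' A gene survives only if it is significant with the same direction in
#' every dataset: the positive set is the intersection of per-dataset
#' positive sets, likewise for negative. A gene significant positively in
#' one dataset and negatively in another appears in neither.
#'
#' @param screens list (one element per dataset, >= 2) of either
#'   [CorrelationScreenResult-class] objects or `list(positive=, negative=)`
#'   pairs as returned by [filterSignificant()]. Names, if set, label the
#'   contributing datasets.
#' @param drug drug label carried into the result.
#' @return list with class `"IntersectionResult"`: `drug`,
#'   `positive_genes`, `negative_genes`, `contributing_datasets`.
#' @export
codirectionalIntersection <- function(screens, drug = "drug") {
  if (length(screens) < 2) stop("need at least 2 datasets to intersect")
  sets <- lapply(screens, function(s) {
    if (is(s, "CorrelationScreenResult")) filterSignificant(s) else s
  })
  ids <- names(screens)
  if (is.null(ids)) ids <- paste0("dataset", seq_along(screens))
  pos <- Reduce(intersect, lapply(sets, `[[`, "positive"))
  neg <- Reduce(intersect, lapply(sets, `[[`, "negative"))
  structure(list(drug = drug,
                 positive_genes = sort(pos),
                 negative_genes = sort(neg),
                 contributing_datasets = ids),
            class = "IntersectionResult")
}

#' Cross-drug overlap of consistently correlated genes
#'
#' Compares the co-directional gene sets of two or more drugs: pairwise
#' and all-drug intersections by direction, plus a contradiction list of
#' genes consistently correlated in opposite directions for some drug pair.
#'
#' @param intersections named list (>= 2) of `"IntersectionResult"`
#'   objects, one per drug.
#' @return list with class `"CrossDrugOverlap"`: `pairwise` (data.frame of
#'   per-pair shared genes by direction), `allDrugs` (genes shared by every
#'   drug, by direction), `contradictions` (character vector).
#' @export
crossDrugOverlap <- function(intersections) {
  if (length(intersections) < 2) stop("need at least 2 drugs")
  drugs <- names(intersections)
  if (is.null(drugs)) drugs <- vapply(intersections, `[[`, "", "drug")
  pos <- lapply(intersections, `[[`, "positive_genes")
  neg <- lapply(intersections, `[[`, "negative_genes")
  names(pos) <- names(neg) <- drugs

  pairs <- utils::combn(drugs, 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    data.frame(drug1 = pr[1L], drug2 = pr[2L],
               positive = paste(intersect(pos[[pr[1L]]], pos[[pr[2L]]]),
                                collapse = ","),
               negative = paste(intersect(neg[[pr[1L]]], neg[[pr[2L]]]),
                                collapse = ","),
               stringsAsFactors = FALSE)
  }))
  contra <- unique(unlist(lapply(pairs, function(pr)
    c(intersect(pos[[pr[1L]]], neg[[pr[2L]]]),
      intersect(neg[[pr[1L]]], pos[[pr[2L]]])))))
  structure(list(
    pairwise = pw,
    allDrugs = list(positive = sort(Reduce(intersect, pos)),
                    negative = sort(Reduce(intersect, neg))),
    contradictions = sort(contra)),
    class = "CrossDrugOverlap")
}
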