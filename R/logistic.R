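#' Maximum-likelihood logistic fit of a gene signature
#'
#' Fits outcome ~ intercept + sum(coef * expression) by iteratively
#' reweighted least squares and reports per-coefficient two-sided Wald
#' p-values from the observed-information covariance. Non-convergence,
#' (quasi-)complete separation and singular designs are reported via
#' flags, never silently.
#'
#' @param genes character vector of gene ids (may be empty for an
#'   intercept-only fit).
#' @param cohort a [LabeledCohort-class].
#' @return A [GeneSignatureModel-class] with `trainAuc` filled in (0.5 for
#'   an intercept-only model, whose scores are all tied) and
#'   `cvAuc`/`testAuc` set to `NA` until computed.
#' @export
fitLogistic <- function(genes, cohort) {
  stopifnot(is(cohort, "LabeledCohort"))
  genes <- as.character(genes)
  miss <- setdiff(genes, colnames(cohort@x))
  if (length(miss))
    stop("genes absent from cohort matrix: ", paste(miss, collapse = ", "))
  y <- as.numeric(cohort@outcome)
  if (length(unique(y)) < 2)
    stop("cohort must contain both outcome classes")
  X <- cbind(1, cohort@x[, genes, drop = FALSE])
  fit <- cpp_fit_logistic(X, y)
  cf <- fit$coefficients
  se <- fit$se
  z <- cf / se
  p <- 2 * pnorm(-abs(z))
  k <- length(genes)
  scores <- as.numeric(X %*% cf)
  trainAuc <- cpp_auc(scores, y)
  new("GeneSignatureModel",
      genes = genes,
      intercept = cf[1L],
      coefficients = setNames(if (k) cf[-1L] else numeric(0), genes),
      pValues = setNames(if (k) p[-1L] else numeric(0), genes),
      trainAuc = trainAuc, cvAuc = NA_real_, testAuc = NA_real_,
      converged = isTRUE(fit$converged) && !isTRUE(fit$singular),
      separation = isTRUE(fit$separation) || isTRUE(fit$singular))
}

#' ROC AUC by the Mann-Whitney rank formulation
#'
#' `AUC = U / (n1 * n0)` where U counts concordant score pairs between the
#' positive and negative class, ties counted 1/2.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels binary labels (0/1 or logical).
#' @return AUC in `[0, 1]`.
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  if (sum(labels) == 0 || sum(labels) == length(labels))
    stop("both classes must be present")
  cpp_auc(as.numeric(scores), labels)
}

# stratified fold assignment: n x repeats matrix of fold ids in 1..k,
# class proportions preserved per fold; deterministic given the seed
makeStratifiedFolds <- function(y, k, repeats, seed) {
  y <- as.integer(y)
  if (min(table(y)) < k)
    stop("smallest outcome class (", min(table(y)),
         ") is too small for ", k, "-fold stratification")
  n <- length(y)
  withSeed(seed, {
    sapply(seq_len(repeats), function(r) {
      fid <- integer(n)
      for (cls in unique(y)) {
        idx <- which(y == cls)
        fid[sample(idx)] <- rep(seq_len(k), length.out = length(idx))
      }
      fid
    })
  })
}

#' Repeated stratified cross-validated AUC of a gene set
#'
#' Partitions the cohort into `cvFolds` stratified folds (class
#' proportions preserved), fits the logistic model on k-1 folds, scores
#' the held-out fold, and averages the per-fold AUC over all folds and
#' `cvRepeats` repeats. Fold assignment is a pure function of
#' `config$seed`, so two calls on the same data and config are identical
#' to full precision.
#'
#' @param genes character vector of gene ids.
#' @param cohort a [LabeledCohort-class].
#' @param config a [searchConfig()].
#' @return mean held-out AUC.
#' @export
cvAuc <- function(genes, cohort, config = searchConfig()) {
  stopifnot(is(cohort, "LabeledCohort"))
  genes <- as.character(genes)
  miss <- setdiff(genes, colnames(cohort@x))
  if (length(miss))
    stop("genes absent from cohort matrix: ", paste(miss, collapse = ", "))
  y <- as.numeric(cohort@outcome)
  folds <- makeStratifiedFolds(cohort@outcome, config$cvFolds,
                               config$cvRepeats, config$seed)
  cpp_cv_auc(cohort@x[, genes, drop = FALSE], y, folds)
}

#' Apply a gene signature classifier to expression data
#'
#' Computes `p = logistic(intercept + sum(coef * expression))` per sample
#' and labels a sample unfavorable when `p > threshold` (strict, so a
#' probability of exactly 0.5 at the default threshold is favorable).
#'
#' @param model a [GeneSignatureModel-class].
#' @param expr an [ExpressionMatrix-class] or a samples x genes matrix
#'   containing all model genes.
#' @param threshold classification threshold on the probability scale
#'   (default 0.5).
#' @return data.frame with `sample_id`, `probability`, `label`
#'   (`"favorable"`/`"unfavorable"`; unfavorable corresponds to outcome 1).
#' @export
classifySamples <- function(model, expr, threshold = 0.5) {
  stopifnot(is(model, "GeneSignatureModel"))
  x <- if (is(expr, "ExpressionMatrix")) t(exprValues(expr)) else as.matrix(expr)
  miss <- setdiff(model@genes, colnames(x))
  if (length(miss))
    stop("expression data is missing model genes: ",
         paste(miss, collapse = ", "))
  eta <- model@intercept +
    as.numeric(x[, model@genes, drop = FALSE] %*% model@coefficients)
  prob <- plogis(eta)
  data.frame(sample_id = rownames(x),
             probability = prob,
             label = ifelse(prob > threshold, "unfavorable", "favorable"),
             stringsAsFactors = FALSE, row.names = NULL)
}
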