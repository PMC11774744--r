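#' Configuration for the gated signature beam search
#'
#' @param maxSize maximum signature size (default 12 genes).
#' @param pNew Wald p-value gate for the newly added gene (default 0.15,
#'   "at least marginally significant").
#' @param pRetained Wald p-value gate for every previously included gene
#'   (default 0.05); also the gate a single-gene model must pass.
#' @param cvFolds folds for the per-step cross-validation (default 3).
#' @param cvRepeats number of CV repeats (default 5).
#' @param keepFraction fraction of gated candidates retained per step by
#'   mean CV AUC (default 0.5).
#' @param aucThreshold train/test AUC both must strictly exceed this for a
#'   model to be selectable (default 0.85; lower to 0.75 for harder
#'   cohorts when nothing passes).
#' @param classThreshold probability cutoff for classification
#'   (default 0.5).
#' @param seed integer seed controlling fold assignment and any other
#'   randomness; the whole search is bit-reproducible given (data, seed).
#' @return list with class `"SearchConfig"`.
#' @export
searchConfig <- function(maxSize = 12, pNew = 0.15, pRetained = 0.05,
                         cvFolds = 3, cvRepeats = 5, keepFraction = 0.5,
                         aucThreshold = 0.85, classThreshold = 0.5,
                         seed = 1L) {
  if (!(keepFraction > 0 && keepFraction <= 1))
    stop("keepFraction must lie in (0, 1]")
  if (cvFolds < 2) stop("cvFolds must be >= 2")
  if (pRetained > pNew) stop("pRetained must be <= pNew")
  if (maxSize < 1) stop("maxSize must be >= 1")
  structure(list(maxSize = as.integer(maxSize), pNew = pNew,
                 pRetained = pRetained, cvFolds = as.integer(cvFolds),
                 cvRepeats = as.integer(cvRepeats),
                 keepFraction = keepFraction,
                 aucThreshold = aucThreshold,
                 classThreshold = classThreshold,
                 seed = as.integer(seed)),
            class = "SearchConfig")
}

# fit a candidate given column indices into X (addition order preserved);
# returns coef/p/flags, or NULL when the design is singular
.fitCandidate <- function(X, y, idx) {
  f <- cpp_fit_logistic(cbind(1, X[, idx, drop = FALSE]), y)
  if (isTRUE(f$singular)) return(NULL)
  list(idx = idx,
       coef = f$coefficients,
       p = 2 * pnorm(-abs(f$coefficients / f$se)),
       converged = isTRUE(f$converged),
       separation = isTRUE(f$separation))
}

# gate: new gene (last index) at pNew, all earlier genes at pRetained;
# non-converged or separated fits fail the gate so the beam continues
.passesGate <- function(cand, config) {
  if (is.null(cand) || !cand$converged || cand$separation) return(FALSE)
  p <- cand$p[-1L]  # drop intercept
  k <- length(p)
  if (k == 1L) return(is.finite(p) && p < config$pRetained)
  all(is.finite(p)) && p[k] < config$pNew &&
    all(p[-k] < config$pRetained)
}

.candidateRecord <- function(cand, X, y, folds) {
  scores <- as.numeric(cbind(1, X[, cand$idx, drop = FALSE]) %*% cand$coef)
  cand$trainAuc <- cpp_auc(scores, y)
  cand$cvAuc <- cpp_cv_auc(X[, cand$idx, drop = FALSE], y, folds)
  cand$key <- paste(sort(cand$idx), collapse = ".")
  cand
}

# rank candidates: mean CV AUC desc, train AUC desc, then lexicographically
# smallest gene set; returns ordering permutation
.rankCandidates <- function(records) {
  cv <- vapply(records, `[[`, 0, "cvAuc")
  tr <- vapply(records, `[[`, 0, "trainAuc")
  key <- vapply(records, `[[`, "", "key")
  order(-cv, -tr, key)
}

#' One step of the gated beam search
#'
#' Extends every surviving model of size s by every pool gene it does not
#' already contain, collapses gene-set duplicates reached via different
#' orders, refits each candidate on the training cohort, applies the
#' significance gates (new gene `p < pNew`, all other genes
#' `p < pRetained`; singular, non-converged or separated fits fail), scores
#' the gated candidates by repeated-CV AUC and keeps the top
#' `keepFraction`.
#'
#' @param survivors list of models of equal size s as returned by a
#'   previous step (or [searchSignatures()] internals); each element needs
#'   a `genes` character vector.
#' @param genePool character vector of candidate genes.
#' @param train a [LabeledCohort-class].
#' @param config a [searchConfig()].
#' @return list of [GeneSignatureModel-class] of size s+1 (possibly empty
#'   when no candidate survives gating), with step counts in
#'   `attr(, "counts")`.
#' @export
beamStep <- function(survivors, genePool, train, config = searchConfig()) {
  stopifnot(is(train, "LabeledCohort"))
  genePool <- as.character(genePool)
  X <- train@x[, genePool, drop = FALSE]
  y <- as.numeric(train@outcome)
  folds <- makeStratifiedFolds(train@outcome, config$cvFolds,
                               config$cvRepeats, config$seed)
  survIdx <- lapply(survivors, function(m) {
    g <- if (is(m, "GeneSignatureModel")) m@genes else m$genes
    match(g, genePool)
  })
  step <- .beamStepIdx(survIdx, X, y, folds, config)
  out <- lapply(step$records, .recordToModel, genePool = genePool)
  attr(out, "counts") <- step$counts
  out
}

# Candidate expansion, gene-set deduplication, gating and CV scoring run
# in C++ (cpp_beam_step); the ranking and keep-fraction cut stay here.
# A gene set reached through different parent orders has one fit but a
# different "new" gene per order; it is kept as soon as one order passes.
.beamStepIdx <- function(survIdx, X, y, folds, config) {
  step <- cpp_beam_step(X, y, lapply(survIdx, as.integer), folds,
                        config$pNew, config$pRetained)
  nGated <- length(step$idx)
  records <- lapply(seq_len(nGated), function(i) {
    idx <- step$idx[[i]]
    list(idx = idx,
         coef = c(step$intercept[i], step$coef[[i]]),
         p = c(NA_real_, step$p[[i]]),
         converged = TRUE, separation = FALSE,
         trainAuc = step$trainAuc[i],
         cvAuc = step$cvAuc[i],
         key = paste(sort(idx), collapse = "."))
  })
  ord <- .rankCandidates(records)
  nKeep <- min(nGated, ceiling(config$keepFraction * nGated))
  records <- records[ord][seq_len(nKeep)]
  list(records = records,
       counts = data.frame(candidatesRaw = step$raw,
                           candidatesUnique = step$uniqueTried,
                           gated = nGated,
                           kept = nKeep))
}

.recordToModel <- function(rec, genePool) {
  genes <- genePool[rec$idx]
  k <- length(genes)
  new("GeneSignatureModel",
      genes = genes,
      intercept = rec$coef[1L],
      coefficients = setNames(rec$coef[-1L], genes),
      pValues = setNames(rec$p[-1L], genes),
      trainAuc = rec$trainAuc,
      cvAuc = if (is.null(rec$cvAuc)) NA_real_ else rec$cvAuc,
      testAuc = NA_real_,
      converged = rec$converged,
      separation = rec$separation)
}

#' Gated forward beam search over logistic gene signatures
#'
#' Builds single-gene logistic models from the gene pool (a single gene
#' must itself be significant at `pRetained`), prunes them to the top
#' `keepFraction` by repeated-CV AUC, then iterates [beamStep()] until
#' `maxSize` or until no candidate survives the gates. All retained models
#' of every size form the registry.
#'
#' @param train a [LabeledCohort-class].
#' @param genePool character vector of candidate genes, all present in
#'   `train`.
#' @param config a [searchConfig()].
#' @return list with class `"SignatureRegistry"`: `models` (list of
#'   [GeneSignatureModel-class]), `counts` (per-size data.frame with raw
#'   candidate, gated and kept counts), `config`.
#' @export
searchSignatures <- function(train, genePool, config = searchConfig()) {
  stopifnot(is(train, "LabeledCohort"))
  genePool <- as.character(genePool)
  if (length(genePool) == 0) stop("gene pool is empty")
  miss <- setdiff(genePool, colnames(train@x))
  if (length(miss))
    stop("gene pool not in training matrix: ", paste(miss, collapse = ", "))
  X <- train@x[, genePool, drop = FALSE]
  y <- as.numeric(train@outcome)
  if (length(unique(y)) < 2) stop("training cohort needs both classes")
  folds <- makeStratifiedFolds(train@outcome, config$cvFolds,
                               config$cvRepeats, config$seed)

  # size-1 models
  gated <- list()
  for (g in seq_along(genePool)) {
    cand <- .fitCandidate(X, y, g)
    if (.passesGate(cand, config)) gated[[length(gated) + 1L]] <- cand
  }
  records <- lapply(gated, function(cand) .candidateRecord(cand, X, y, folds))
  ord <- .rankCandidates(records)
  nKeep <- min(length(records), ceiling(config$keepFraction * length(records)))
  records <- records[ord][seq_len(nKeep)]
  counts <- data.frame(size = 1L, candidatesRaw = length(genePool),
                       candidatesUnique = length(genePool),
                       gated = length(gated), kept = nKeep)

  allRecords <- records
  survivors <- records
  s <- 1L
  while (s < config$maxSize && length(survivors) > 0) {
    step <- .beamStepIdx(lapply(survivors, `[[`, "idx"), X, y, folds, config)
    survivors <- step$records
    counts <- rbind(counts, cbind(size = s + 1L, step$counts))
    allRecords <- c(allRecords, survivors)
    s <- s + 1L
  }

  models <- lapply(allRecords, .recordToModel, genePool = genePool)
  structure(list(models = models, counts = counts, config = config),
            class = "SignatureRegistry")
}

#' @export
print.SignatureRegistry <- function(x, ...) {
  cat(sprintf("SignatureRegistry: %d retained models\n", length(x$models)))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Select the best signature by the train/test AUC threshold rule
#'
#' Evaluates every registry model on the held-out test cohort, keeps the
#' models whose train AUC and test AUC both strictly exceed
#' `config$aucThreshold`, and returns the one with the highest
#' cross-validated AUC (ties: higher train AUC, then lexicographically
#' smallest gene set). When no model passes, the result says so explicitly
#' so the caller can decide to lower the threshold.
#'
#' @param registry a `"SignatureRegistry"` from [searchSignatures()].
#' @param train,test [LabeledCohort-class] objects.
#' @param config a [searchConfig()]; `config$aucThreshold` is the gate.
#' @return list with class `"SignatureSelection"`: `status` (`"ok"` or
#'   `"no model meets threshold"`), `model` (a
#'   [GeneSignatureModel-class] with `testAuc` filled in, or `NULL`),
#'   `threshold`, `nEligible`.
#' @export
selectBest <- function(registry, train, test, config = registry$config) {
  if (!length(registry$models)) stop("registry is empty")
  stopifnot(is(train, "LabeledCohort"), is(test, "LabeledCohort"))
  thr <- config$aucThreshold
  evalModel <- function(m) {
    sc <- m@intercept + as.numeric(
      test@x[, m@genes, drop = FALSE] %*% m@coefficients)
    m@testAuc <- cpp_auc(sc, as.numeric(test@outcome))
    m
  }
  models <- lapply(registry$models, evalModel)
  pass <- vapply(models, function(m)
    is.finite(m@testAuc) && m@trainAuc > thr && m@testAuc > thr, logical(1))
  if (!any(pass)) {
    return(structure(list(status = "no model meets threshold", model = NULL,
                          threshold = thr, nEligible = 0L),
                     class = "SignatureSelection"))
  }
  eligible <- models[pass]
  cv <- vapply(eligible, function(m) m@cvAuc, numeric(1))
  tr <- vapply(eligible, function(m) m@trainAuc, numeric(1))
  key <- vapply(eligible, function(m) paste(sort(m@genes), collapse = "."), "")
  best <- eligible[[order(-cv, -tr, key)[1L]]]
  structure(list(status = "ok", model = best, threshold = thr,
                 nEligible = sum(pass)),
            class = "SignatureSelection")
}

#' @export
print.SignatureSelection <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("SignatureSelection: %d model(s) above AUC threshold %.2f\n",
                x$nEligible, x$threshold))
    show(x$model)
  } else {
    cat(sprintf("SignatureSelection: no model meets threshold %.2f\n",
                x$threshold))
  }
  invisible(x)
}

#' Derive the binary classifier outcome from prognostic status
#'
#' Unfavorable = 1, favorable = 0; patients with uncertain status are
#' excluded (they re-enter only in complete-dataset survival analyses).
#'
#' @param cohort a [CohortTable-class] with a `prognostic_status` column
#'   (see [definePrognosticStatus()]).
#' @return named 0/1 vector over the patients with definite status.
#' @export
outcomeFromStatus <- function(cohort) {
  stopifnot(is(cohort, "CohortTable"))
  d <- cohortData(cohort)
  if (!"prognostic_status" %in% names(d))
    stop("cohort has no prognostic_status; run definePrognosticStatus() first")
  keep <- d$prognostic_status != "uncertain"
  setNames(as.integer(d$prognostic_status[keep] == "unfavorable"),
           d$sample_id[keep])
}

#' Seeded stratified train/test split
#'
#' Splits samples into train and test [LabeledCohort-class]s preserving
#' the outcome proportions (default 70/30, mirroring a 112/47 split of a
#' 159-patient cohort).
#'
#' @param expr an [ExpressionMatrix-class] covering (at least) the labeled
#'   samples.
#' @param outcome named binary vector (1 = unfavorable), e.g. from
#'   [outcomeFromStatus()].
#' @param fraction training fraction (default 0.70).
#' @param seed integer seed.
#' @return list with `train` and `test` [LabeledCohort-class]s.
#' @export
splitCohort <- function(expr, outcome, fraction = 0.70, seed = 1L) {
  stopifnot(is(expr, "ExpressionMatrix"))
  if (is.null(names(outcome))) stop("outcome must be named by sample id")
  ids <- intersect(sampleIds(expr), names(outcome))
  if (!length(ids)) stop("no overlap between expression and outcome samples")
  outcome <- outcome[ids]
  trainIds <- withSeed(seed, {
    unlist(lapply(unique(outcome), function(cls) {
      idx <- ids[outcome == cls]
      sample(idx, round(fraction * length(idx)))
    }), use.names = FALSE)
  })
  testIds <- setdiff(ids, trainIds)
  list(train = labeledCohort(expr[, trainIds], outcome[trainIds], "train"),
       test = labeledCohort(expr[, testIds], outcome[testIds], "test"))
}
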