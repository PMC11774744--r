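#' @import methods
#' @importFrom stats median cor pnorm pchisq pt qt plogis rnorm runif rbinom
#'   uniroot sd quantile setNames complete.cases as.formula
#' @importFrom utils read.table write.table
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#' @importFrom S4Vectors metadata metadata<-
#' @useDynLib chemosig, .registration = TRUE
NULL

.NORMALIZATIONS <- c("raw_counts", "log_size_factor", "tmm_logcpm",
                     "external_normalized")

#' ExpressionMatrix: genes x samples expression values
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single genes-by-samples assay (`"exprs"`) plus a tag recording which
#' normalization the values carry. Raw counts must be non-negative; any
#' normalized matrix must be finite.
#'
#' @slot normalization one of `"raw_counts"`, `"log_size_factor"`,
#'   `"tmm_logcpm"`, `"external_normalized"`.
#' @export
setClass("ExpressionMatrix",
         contains = "SummarizedExperiment",
         representation(normalization = "character"))

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (length(object@normalization) != 1L ||
      !object@normalization %in% .NORMALIZATIONS)
    msg <- c(msg, sprintf("normalization must be one of: %s",
                          paste(.NORMALIZATIONS, collapse = ", ")))
  v <- SummarizedExperiment::assay(object, withDimnames = TRUE)
  if (!is.numeric(v))
    msg <- c(msg, "expression values must be numeric")
  gid <- rownames(v); sid <- colnames(v)
  if (is.null(gid) || is.null(sid))
    msg <- c(msg, "gene and sample identifiers are required (dimnames)")
  else {
    if (anyDuplicated(gid))
      msg <- c(msg, sprintf("duplicate gene identifiers: %s",
                            paste(unique(gid[duplicated(gid)]), collapse = ", ")))
    if (anyDuplicated(sid))
      msg <- c(msg, sprintf("duplicate sample identifiers: %s",
                            paste(unique(sid[duplicated(sid)]), collapse = ", ")))
  }
  if (identical(object@normalization, "raw_counts")) {
    if (any(!is.finite(v)) || any(v < 0))
      msg <- c(msg, "raw counts must be finite and non-negative")
  } else if (any(!is.finite(v))) {
    msg <- c(msg, "normalized expression values must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   unique row and column names.
#' @param normalization normalization tag for `values`; new count matrices
#'   are `"raw_counts"` (the default), pre-normalized external data (e.g.
#'   microarray intensities) should be tagged `"external_normalized"`.
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rpois(6, 50), 3, 2,
#'             dimnames = list(paste0("G", 1:3), c("S1", "S2")))
#' em <- ExpressionMatrix(m)
#' @export
ExpressionMatrix <- function(values,
                             normalization = c("raw_counts", "log_size_factor",
                                               "tmm_logcpm",
                                               "external_normalized")) {
  normalization <- match.arg(normalization)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values))
  new("ExpressionMatrix", se, normalization = normalization)
}

#' DrugResponseTable: per-sample, per-drug IC50 values
#'
#' Samples-by-drugs matrix of IC50 concentrations in micromolar. Values
#' must be strictly positive wherever present; `NA` marks drugs not
#' assayed for a sample (dropped pairwise downstream).
#'
#' @slot ic50 numeric matrix (samples x drugs) with dimnames.
#' @export
setClass("DrugResponseTable", representation(ic50 = "matrix"))

setValidity("DrugResponseTable", function(object) {
  v <- object@ic50
  msg <- character()
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "sample and drug names are required")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate sample ids")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate drug names")
  }
  if (any(v <= 0, na.rm = TRUE))
    msg <- c(msg, "IC50 values must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' Construct a DrugResponseTable
#'
#' @param ic50 numeric matrix of IC50 values (micromolar), samples in rows,
#'   drugs in columns, both named. `NA` entries mark missing measurements.
#' @return A [DrugResponseTable-class] object.
#' @export
DrugResponseTable <- function(ic50) {
  ic50 <- as.matrix(ic50)
  storage.mode(ic50) <- "double"
  new("DrugResponseTable", ic50 = ic50)
}

#' CohortTable: patient clinical table with survival follow-up
#'
#' Per-patient survival time (years), event indicator (1 = event observed),
#' optional clinical covariates, and the 5-year prognostic status once
#' assigned by [definePrognosticStatus()].
#'
#' @slot data data.frame with mandatory columns `sample_id`, `time_years`,
#'   `event`; an optional `prognostic_status` column; all other columns are
#'   treated as clinical covariates.
#' @export
setClass("CohortTable", representation(data = "data.frame"))

setValidity("CohortTable", function(object) {
  d <- object@data
  msg <- character()
  need <- c("sample_id", "time_years", "event")
  miss <- setdiff(need, names(d))
  if (length(miss))
    return(sprintf("missing mandatory columns: %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(d$sample_id)) msg <- c(msg, "duplicate sample ids")
  if (any(!is.finite(d$time_years)) || any(d$time_years < 0))
    msg <- c(msg, "time_years must be finite and >= 0")
  if (!all(d$event %in% c(0, 1)))
    msg <- c(msg, "event must be 0 or 1")
  if ("prognostic_status" %in% names(d) &&
      !all(d$prognostic_status %in% c("favorable", "unfavorable", "uncertain")))
    msg <- c(msg, "prognostic_status must be favorable/unfavorable/uncertain")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortTable
#'
#' @param data data.frame with columns `sample_id`, `time_years`, `event`
#'   plus any clinical covariates.
#' @return A [CohortTable-class] object.
#' @export
CohortTable <- function(data) {
  data <- as.data.frame(data)
  data$sample_id <- as.character(data$sample_id)
  new("CohortTable", data = data)
}

#' CorrelationScreenResult: per-gene Spearman screen against IC50
#'
#' One row per gene: Spearman rho, p-value, number of samples used,
#' significance flag and direction under the screen thresholds.
#'
#' @slot datasetId dataset label.
#' @slot drug drug name.
#' @slot table data.frame with columns `gene`, `rho`, `p`, `n`,
#'   `significant`, `direction`.
#' @slot config the [screenConfig()] used.
#' @export
setClass("CorrelationScreenResult",
         representation(datasetId = "character", drug = "character",
                        table = "data.frame", config = "list"))

setValidity("CorrelationScreenResult", function(object) {
  tb <- object@table
  need <- c("gene", "rho", "p", "n", "significant", "direction")
  if (!all(need %in% names(tb)))
    return(sprintf("screen table needs columns: %s", paste(need, collapse = ", ")))
  if (!all(tb$direction %in% c("+", "-", "none")))
    return("direction must be '+', '-' or 'none'")
  bad <- tb$significant & !(abs(tb$rho) > object@config$rhoThreshold &
                              tb$p < object@config$alpha)
  if (any(bad, na.rm = TRUE))
    return("significant flags inconsistent with thresholds")
  TRUE
})

#' GeneSignatureModel: a fitted logistic gene signature
#'
#' Ordered gene set (in order of addition by the beam search), logistic
#' intercept and per-gene coefficients on the expression scale, per-gene
#' two-sided Wald p-values, and train / cross-validation / test ROC AUC.
#' Outcome coding: unfavorable prognosis = 1.
#'
#' @slot genes character vector of gene ids, in addition order.
#' @slot intercept log-odds intercept.
#' @slot coefficients named per-gene log-odds per expression unit.
#' @slot pValues named per-gene two-sided Wald p-values.
#' @slot trainAuc,cvAuc,testAuc ROC AUC on the training data, mean over
#'   repeated CV folds, and on held-out data (`NA` until evaluated).
#' @slot converged,separation fit diagnostics.
#' @export
setClass("GeneSignatureModel",
         representation(genes = "character", intercept = "numeric",
                        coefficients = "numeric", pValues = "numeric",
                        trainAuc = "numeric", cvAuc = "numeric",
                        testAuc = "numeric", converged = "logical",
                        separation = "logical"))

setValidity("GeneSignatureModel", function(object) {
  k <- length(object@genes)
  if (length(object@coefficients) != k || length(object@pValues) != k)
    return("genes, coefficients and pValues must have equal length")
  if (anyDuplicated(object@genes)) return("genes must be unique")
  TRUE
})

#' DoseResponseFit: four-parameter log-logistic dose-response fit
#'
#' Parameters of f(x) = lower + (upper - lower) / (1 + (x/e)^slope) fitted
#' by least squares; `slope > 0` means viability decreases with dose.
#'
#' @slot lower,upper asymptotic viability fractions.
#' @slot slope Hill coefficient (sign convention: positive = decreasing).
#' @slot e inflection concentration in micromolar (the relative IC50).
#' @slot rss residual sum of squares.
#' @slot converged optimizer status; degenerate fits are flagged FALSE.
#' @export
setClass("DoseResponseFit",
         representation(lower = "numeric", upper = "numeric",
                        slope = "numeric", e = "numeric", rss = "numeric",
                        converged = "logical"))

setValidity("DoseResponseFit", function(object) {
  if (object@converged) {
    if (!(object@e > 0)) return("inflection e must be positive")
    if (!(object@upper > object@lower))
      return("upper asymptote must exceed lower for a converged fit")
  }
  TRUE
})

#' LabeledCohort: expression plus binary outcome for classifier fitting
#'
#' Samples-by-genes design matrix restricted to the candidate gene pool,
#' with a binary outcome vector (1 = unfavorable prognosis). Patients with
#' uncertain 5-year status must be excluded before construction.
#'
#' @slot x numeric matrix, samples x genes, dimnames set.
#' @slot outcome integer vector in \{0, 1\}, 1 = unfavorable.
#' @slot split `"train"`, `"test"` or `"unspecified"`.
#' @export
setClass("LabeledCohort",
         representation(x = "matrix", outcome = "integer", split = "character"))

setValidity("LabeledCohort", function(object) {
  msg <- character()
  if (nrow(object@x) != length(object@outcome))
    msg <- c(msg, "outcome length must equal number of samples")
  if (!all(object@outcome %in% c(0L, 1L)))
    msg <- c(msg, "outcome must be 0/1")
  if (is.null(colnames(object@x)) || is.null(rownames(object@x)))
    msg <- c(msg, "x must carry sample and gene names")
  if (length(msg)) msg else TRUE
})

#' Construct a LabeledCohort
#'
#' @param expr an [ExpressionMatrix-class] (genes x samples).
#' @param outcome binary vector (1 = unfavorable), one per sample of `expr`,
#'   or a named vector matched by sample id.
#' @param split `"train"`, `"test"` or `"unspecified"`.
#' @return A [LabeledCohort-class] object.
#' @export
labeledCohort <- function(expr, outcome, split = "unspecified") {
  stopifnot(is(expr, "ExpressionMatrix"))
  x <- t(exprValues(expr))
  if (!is.null(names(outcome))) {
    if (!all(rownames(x) %in% names(outcome)))
      stop("outcome is missing samples: ",
           paste(setdiff(rownames(x), names(outcome)), collapse = ", "))
    outcome <- outcome[rownames(x)]
  }
  new("LabeledCohort", x = x, outcome = as.integer(outcome),
      split = split)
}
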