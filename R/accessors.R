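#' Accessors for chemosig data classes
#'
#' `exprValues()` returns the genes x samples matrix, `geneIds()` and
#' `sampleIds()` the identifiers, `normalization()` the normalization tag.
#' `ic50Values()` and `drugNames()` access drug-response tables;
#' `cohortData()` the clinical data.frame; `signatureGenes()` the ordered
#' gene list of a signature model.
#'
#' @param x a chemosig object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x)
  SummarizedExperiment::assay(x, "exprs"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("sampleIds", "DrugResponseTable", function(x) rownames(x@ic50))

#' @rdname accessors
#' @export
setMethod("sampleIds", "CohortTable", function(x) x@data$sample_id)

#' @rdname accessors
#' @export
setGeneric("normalization", function(x) standardGeneric("normalization"))

#' @rdname accessors
#' @export
setMethod("normalization", "ExpressionMatrix", function(x) x@normalization)

#' @rdname accessors
#' @export
setGeneric("ic50Values", function(x) standardGeneric("ic50Values"))

#' @rdname accessors
#' @export
setMethod("ic50Values", "DrugResponseTable", function(x) x@ic50)

#' @rdname accessors
#' @export
setGeneric("drugNames", function(x) standardGeneric("drugNames"))

#' @rdname accessors
#' @export
setMethod("drugNames", "DrugResponseTable", function(x) colnames(x@ic50))

#' @rdname accessors
#' @export
setGeneric("cohortData", function(x) standardGeneric("cohortData"))

#' @rdname accessors
#' @export
setMethod("cohortData", "CohortTable", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("screenTable", function(x) standardGeneric("screenTable"))

#' @rdname accessors
#' @export
setMethod("screenTable", "CorrelationScreenResult", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("signatureGenes", function(x) standardGeneric("signatureGenes"))

#' @rdname accessors
#' @export
setMethod("signatureGenes", "GeneSignatureModel", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("modelAuc", function(x) standardGeneric("modelAuc"))

#' @rdname accessors
#' @export
setMethod("modelAuc", "GeneSignatureModel", function(x)
  c(train = x@trainAuc, cv = x@cvAuc, test = x@testAuc))

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
              nrow(object), ncol(object), object@normalization))
})

setMethod("show", "DrugResponseTable", function(object) {
  cat(sprintf("DrugResponseTable: %d samples x %d drugs (%d missing IC50)\n",
              nrow(object@ic50), ncol(object@ic50), sum(is.na(object@ic50))))
})

setMethod("show", "CohortTable", function(object) {
  d <- object@data
  cat(sprintf("CohortTable: %d patients, %d events", nrow(d), sum(d$event)))
  if ("prognostic_status" %in% names(d)) {
    tb <- table(d$prognostic_status)
    cat(" | status: ", paste(names(tb), tb, sep = "=", collapse = ", "))
  }
  cat("\n")
})

setMethod("show", "CorrelationScreenResult", function(object) {
  cat(sprintf(
    "CorrelationScreenResult [%s / %s]: %d genes, %d significant (+%d/-%d)\n",
    object@datasetId, object@drug, nrow(object@table),
    sum(object@table$significant, na.rm = TRUE),
    sum(object@table$direction == "+"), sum(object@table$direction == "-")))
})

setMethod("show", "GeneSignatureModel", function(object) {
  cat(sprintf("GeneSignatureModel: %d gene(s) [%s]\n", length(object@genes),
              paste(object@genes, collapse = ", ")))
  cat(sprintf("  AUC train=%.3f cv=%.3f test=%s\n", object@trainAuc,
              object@cvAuc,
              ifelse(is.na(object@testAuc), "NA",
                     sprintf("%.3f", object@testAuc))))
})

setMethod("show", "DoseResponseFit", function(object) {
  cat(sprintf(
    "DoseResponseFit: lower=%.4g upper=%.4g slope=%.4g e=%.4g uM (rss=%.4g, %s)\n",
    object@lower, object@upper, object@slope, object@e, object@rss,
    if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "LabeledCohort", function(object) {
  cat(sprintf("LabeledCohort [%s]: %d samples x %d genes, %d unfavorable\n",
              object@split, nrow(object@x), ncol(object@x),
              sum(object@outcome)))
})
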