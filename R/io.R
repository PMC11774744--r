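#' Read a gene expression matrix from TSV/CSV
#'
#' Expects identifiers in the first column and a header row of identifiers.
#' With `orientation = "genes_in_rows"` (the default dialect) rows are genes
#' and columns samples; with `"samples_in_rows"` the file is transposed on
#' read so the returned object is always genes x samples.
#'
#' @param path file path.
#' @param format `"tsv"` or `"csv"`.
#' @param orientation `"genes_in_rows"` or `"samples_in_rows"`.
#' @param normalization tag for the values (default `"raw_counts"`; use
#'   `"external_normalized"` for pre-normalized microarray data).
#' @return An [ExpressionMatrix-class].
#' @export
readExpressionMatrix <- function(path,
                                 format = c("tsv", "csv"),
                                 orientation = c("genes_in_rows",
                                                 "samples_in_rows"),
                                 normalization = "raw_counts") {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (format == "tsv") "\t" else ","
  raw <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", quote = "\"",
                    comment.char = "")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate identifiers in first column: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  hdr <- colnames(raw)[-1L]
  if (anyDuplicated(hdr))
    stop("duplicate identifiers in header: ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(num) && !all(is.na(body) == is.na(num))) {
    bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                 body[bad[1L], bad[2L]], ids[bad[1L]], hdr[bad[2L]]))
  }
  dimnames(num) <- list(ids, hdr)
  if (orientation == "samples_in_rows") num <- t(num)
  ExpressionMatrix(num, normalization = normalization)
}

#' Write an ExpressionMatrix to TSV/CSV
#'
#' Genes in rows, first column `gene_id`, header of sample ids. Values are
#' written with 15 significant digits so a write/read round trip preserves
#' them to full double precision.
#'
#' @param x an [ExpressionMatrix-class].
#' @param path output file path.
#' @param format `"tsv"` or `"csv"`.
#' @export
writeExpressionMatrix <- function(x, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  v <- exprValues(x)
  df <- data.frame(gene_id = rownames(v),
                   apply(v, 2L, function(col) formatC(col, digits = 15,
                                                      format = "g")),
                   check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a drug-response table (long TSV)
#'
#' Expects columns `sample_id`, `drug`, `ic50_um` (micromolar); reshapes to
#' a samples x drugs matrix with `NA` where a sample/drug pair is absent.
#'
#' @param path TSV file path.
#' @return A [DrugResponseTable-class].
#' @export
readDrugResponseTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  need <- c("sample_id", "drug", "ic50_um")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  samples <- unique(as.character(d$sample_id))
  drugs <- unique(as.character(d$drug))
  m <- matrix(NA_real_, length(samples), length(drugs),
              dimnames = list(samples, drugs))
  m[cbind(as.character(d$sample_id), as.character(d$drug))] <- d$ic50_um
  DrugResponseTable(m)
}

#' Write a drug-response table as long TSV
#'
#' @param x a [DrugResponseTable-class].
#' @param path output file path.
#' @export
writeDrugResponseTable <- function(x, path) {
  m <- ic50Values(x)
  d <- expand.grid(sample_id = rownames(m), drug = colnames(m),
                   stringsAsFactors = FALSE)
  d$ic50_um <- m[cbind(d$sample_id, d$drug)]
  d <- d[!is.na(d$ic50_um), ]
  d$ic50_um <- formatC(d$ic50_um, digits = 15, format = "g")
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical cohort table (TSV)
#'
#' Mandatory columns `sample_id`, `time_years`, `event`; all further
#' columns are carried along as clinical covariates.
#'
#' @param path TSV file path.
#' @param timeUnit `"years"` (default) or `"months"`; months are converted
#'   to years internally.
#' @return A [CohortTable-class].
#' @export
readClinicalTable <- function(path, timeUnit = c("years", "months")) {
  timeUnit <- match.arg(timeUnit)
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  miss <- setdiff(c("sample_id", "time_years", "event"), names(d))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (timeUnit == "months") d$time_years <- d$time_years / 12
  CohortTable(d)
}

#' Write a correlation screen result as TSV
#'
#' Columns `gene,rho,p,n,significant,direction`, numeric values at 15
#' significant digits.
#'
#' @param x a [CorrelationScreenResult-class].
#' @param path output file path.
#' @export
writeScreenResult <- function(x, path) {
  tb <- screenTable(x)
  tb$rho <- formatC(tb$rho, digits = 15, format = "g")
  tb$p <- formatC(tb$p, digits = 15, format = "g")
  write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
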