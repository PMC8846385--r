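#' Construct an M6ACohort
#'
#' Bundles an expression matrix with its clinical table and optional side
#' tables (gene sets, MAF, CNV, immunophenoscore, simulation ground truth)
#' into a single [M6ACohort-class] object.
#'
#' @param exprs numeric matrix, genes x samples, log2 scale.
#' @param clinical data.frame with `sample_id`, `os_time`, `os_event`
#'   (ordered/subset to the expression columns).
#' @param geneSets,maf,cnv,ips,truth optional side tables stored in
#'   `metadata()`.
#' @return an [M6ACohort-class].
#' @export
M6ACohort <- function(exprs, clinical = NULL, geneSets = NULL, maf = NULL,
                      cnv = NULL, ips = NULL, truth = NULL) {
  cd <- S4Vectors::DataFrame(row.names = colnames(exprs))
  if (!is.null(clinical)) {
    idx <- match(colnames(exprs), clinical$sample_id)
    if (anyNA(idx))
      stop("clinical table is missing sample(s): ",
           paste(colnames(exprs)[is.na(idx)][1:3], collapse = ", "))
    cd <- S4Vectors::DataFrame(clinical[idx, , drop = FALSE],
                               row.names = colnames(exprs))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs), colData = cd,
    metadata = list(geneSets = geneSets, maf = maf, cnv = cnv, ips = ips,
                    truth = truth))
  new("M6ACohort", se)
}

#' @describeIn M6ACohort-class expression assay as a plain matrix
#' @param x an `M6ACohort`
#' @export
exprsMatrix <- function(x) {
  if (is.matrix(x)) return(x)
  SummarizedExperiment::assay(x, "exprs")
}

#' @describeIn M6ACohort-class clinical columns as a data.frame
#' @export
clinicalData <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

#' @describeIn M6ACohort-class gene-set collection stored with the cohort
#' @export
cohortGeneSets <- function(x) S4Vectors::metadata(x)$geneSets

#' @describeIn M6ACohort-class somatic-mutation MAF table
#' @export
mafData <- function(x) S4Vectors::metadata(x)$maf

#' @describeIn M6ACohort-class copy-number call matrix
#' @export
cnvCalls <- function(x) S4Vectors::metadata(x)$cnv

#' @describeIn M6ACohort-class immunophenoscore table
#' @export
ipsTable <- function(x) S4Vectors::metadata(x)$ips

#' @describeIn M6ACohort-class simulation ground truth (or `NULL` for real data)
#' @export
groundTruth <- function(x) S4Vectors::metadata(x)$truth

#' @describeIn M6ACohort-class survival outcome (time, event) for the samples
#' @export
survivalOutcome <- function(x) {
  cl <- clinicalData(x)
  stopifnot(all(c("os_time", "os_event") %in% colnames(cl)))
  data.frame(sample_id = rownames(cl), time = cl$os_time, event = cl$os_event,
             stringsAsFactors = FALSE)
}

setMethod("show", "M6ACohort", function(object) {
  x <- exprsMatrix(object)
  cat("M6ACohort:", nrow(x), "genes x", ncol(x), "samples\n")
  md <- S4Vectors::metadata(object)
  have <- names(md)[!vapply(md, is.null, logical(1))]
  if (length(have)) cat("side tables:", paste(have, collapse = ", "), "\n")
  cd <- SummarizedExperiment::colData(object)
  if (ncol(cd)) cat("clinical columns:", paste(colnames(cd), collapse = ", "), "\n")
})
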