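#' @import methods
#' @importFrom stats approx aov ave cor cor.test cutree dist hclust kmeans
#'   kruskal.test median p.adjust pexp phyper pnorm prcomp pt qnorm quantile
#'   rbinom rexp rnorm rpois runif sd setNames var wilcox.test
#' @importFrom utils read.delim write.table head
#' @importFrom stats as.dist pchisq
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Catalog of m6A regulator genes
#'
#' Holds the canonical m6A regulator symbols together with their functional
#' role (writer = methyltransferase, eraser = demethylase, reader =
#' m6A-binding protein) and an alias map from alternate spellings to the
#' canonical symbol.
#'
#' @slot roles named character vector; names are canonical gene symbols,
#'   values are `"writer"`, `"eraser"` or `"reader"`.
#' @slot aliases named character vector mapping alternate symbol to canonical
#'   symbol.
#'
#' @seealso [defaultRegulatorCatalog()]
#' @export
setClass("RegulatorCatalog",
  representation(roles = "character", aliases = "character")
)

setValidity("RegulatorCatalog", function(object) {
  msg <- character()
  if (is.null(names(object@roles)) || anyDuplicated(names(object@roles)))
    msg <- c(msg, "roles must be named by unique gene symbols")
  if (!all(object@roles %in% c("writer", "eraser", "reader")))
    msg <- c(msg, "roles must be 'writer', 'eraser' or 'reader'")
  if (length(object@aliases)) {
    if (is.null(names(object@aliases)))
      msg <- c(msg, "aliases must be named")
    if (!all(object@aliases %in% names(object@roles)))
      msg <- c(msg, "every alias must resolve to a canonical symbol")
    if (any(names(object@aliases) %in% names(object@roles)))
      msg <- c(msg, "an alias may not shadow a canonical symbol")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic or assembled m6A analysis cohort
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one `"exprs"` assay
#' (genes x samples, log2 scale), clinical variables in `colData`, and the
#' remaining cohort tables (gene sets, MAF, CNV calls, immunophenoscore,
#' simulation ground truth) in `metadata`.
#'
#' @seealso [simulateM6ACohort()], [exprsMatrix()], [groundTruth()]
#' @export
setClass("M6ACohort", contains = "SummarizedExperiment")

setValidity("M6ACohort", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    x <- SummarizedExperiment::assay(object, "exprs")
    if (nrow(x) < 2L || ncol(x) < 2L)
      msg <- c(msg, "need >= 2 genes and >= 2 samples")
    if (any(!is.finite(x)))
      msg <- c(msg, "expression values must be finite (no NA/NaN/Inf)")
    if (anyDuplicated(rownames(x)))
      msg <- c(msg, "gene ids must be unique")
    if (anyDuplicated(colnames(x)))
      msg <- c(msg, "sample ids must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Result of resampling-based consensus clustering
#'
#' @slot kRange integer vector of candidate cluster numbers.
#' @slot consensus named list (one element per k) of samples x samples
#'   consensus matrices; entry (i, j) is the fraction of co-sampled
#'   resamples in which samples i and j fell in the same inner cluster.
#' @slot labels named list of integer label vectors per k, renumbered by
#'   descending cluster size.
#' @slot pac numeric vector per k: proportion of ambiguous clustering,
#'   CDF(0.9) - CDF(0.1) of the off-diagonal consensus entries.
#' @slot areaUnderCDF numeric vector per k (Monti CDF area).
#' @slot deltaArea numeric vector per k (relative area increase).
#' @slot chosenK integer, the selected number of clusters.
#' @slot reps,subsampleFraction,innerAlgorithm,seed run parameters.
#' @slot resamples list of stored per-rep resample assignments (possibly
#'   empty), used for oracle-style auditing on small inputs.
#'
#' @seealso [consensusCluster()], [selectK()], [clusterLabels()]
#' @export
setClass("ConsensusResult",
  representation(
    kRange = "integer", consensus = "list", labels = "list",
    pac = "numeric", areaUnderCDF = "numeric", deltaArea = "numeric",
    chosenK = "integer", reps = "integer", subsampleFraction = "numeric",
    innerAlgorithm = "character", seed = "integer", resamples = "list"
  )
)

setValidity("ConsensusResult", function(object) {
  msg <- character()
  for (k in as.character(object@kRange)) {
    m <- object@consensus[[k]]
    if (is.null(m)) { msg <- c(msg, paste("missing consensus matrix for k =", k)); next }
    if (!isSymmetric(unname(m))) msg <- c(msg, paste("consensus matrix not symmetric at k =", k))
    if (any(m < 0 | m > 1)) msg <- c(msg, paste("consensus entries outside [0,1] at k =", k))
    if (any(diag(m) != 1)) msg <- c(msg, paste("consensus diagonal != 1 at k =", k))
  }
  if (length(msg)) msg else TRUE
})

#' PCA-based m6A gene-signature model
#'
#' Stores everything needed to score a new sample: the prognostic signature
#' genes, their training-cohort centering means and scaling standard
#' deviations, and the (sign-oriented) loadings of principal components 1
#' and 2 of the z-scored training matrix.
#'
#' @slot genes character, signature gene symbols.
#' @slot center,scale named numeric, per-gene mean and standard deviation.
#' @slot loadings genes x 2 matrix of unit-norm PC loadings.
#' @slot varExplained length-2 numeric, variance fractions of PC1/PC2.
#' @slot degenerate logical, `TRUE` when the training matrix had effective
#'   rank 1 and the PC2 loadings were zeroed.
#' @slot trainingCohort character id of the training matrix.
#'
#' @seealso [buildSignature()], [m6aScore()]
#' @export
setClass("SignatureModel",
  representation(
    genes = "character", center = "numeric", scale = "numeric",
    loadings = "matrix", varExplained = "numeric", degenerate = "logical",
    trainingCohort = "character"
  )
)

setValidity("SignatureModel", function(object) {
  msg <- character()
  p <- length(object@genes)
  if (!all(dim(object@loadings) == c(p, 2L)))
    msg <- c(msg, "loadings must be genes x 2")
  if (length(object@center) != p || length(object@scale) != p)
    msg <- c(msg, "center/scale must match signature length")
  for (j in 1:2) {
    nrm <- sqrt(sum(object@loadings[, j]^2))
    if (nrm > 0 && abs(nrm - 1) > 1e-8)
      msg <- c(msg, paste0("PC", j, " loadings not unit norm"))
  }
  if (length(msg)) msg else TRUE
})

#' Maximally selected survival cutpoint
#'
#' @slot cutpoint numeric, the score value maximising the absolute
#'   standardized two-group log-rank statistic.
#' @slot statistic numeric, the standardized log-rank statistic at the
#'   cutpoint (sign: positive when the high group has more events than
#'   expected).
#' @slot scanTable data.frame of every candidate cutpoint and its statistic.
#' @slot minprop numeric, minimum proportion of samples per side.
#'
#' @seealso [optimalCutpoint()], [stratifyByScore()]
#' @export
setClass("CutpointResult",
  representation(
    cutpoint = "numeric", statistic = "numeric",
    scanTable = "data.frame", minprop = "numeric"
  )
)

setValidity("CutpointResult", function(object) {
  msg <- character()
  if (length(object@cutpoint) != 1L || !is.finite(object@cutpoint))
    msg <- c(msg, "cutpoint must be a single finite value")
  if (!all(c("cutpoint", "statistic") %in% names(object@scanTable)))
    msg <- c(msg, "scanTable needs 'cutpoint' and 'statistic' columns")
  if (length(msg)) msg else TRUE
})
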