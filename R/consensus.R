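## Resampling-based consensus clustering (Monti-style): repeatedly subsample
## the samples, cluster each subsample, and record for every sample pair the
## fraction of co-sampled resamples in which they co-cluster. Used twice in
## the workflow: on the 23 regulators (m6A clusters) and on the overlap DEGs
## (gene clusters).

.innerCluster <- function(x, k, algorithm) {
  # x: features x samples; returns integer labels per sample
  n <- ncol(x)
  if (k >= n) return(seq_len(n))
  if (algorithm == "hclust") {
    cc <- suppressWarnings(cor(x))
    cc[!is.finite(cc)] <- 0
    d <- as.dist(1 - cc)
    cutree(hclust(d, method = "average"), k = k)
  } else {
    xs <- scale(t(x))
    xs[!is.finite(xs)] <- 0
    kmeans(xs, centers = k, nstart = 1, iter.max = 30)$cluster
  }
}

#' Consensus clustering of samples on a feature panel
#'
#' For each candidate k, draws `reps` subsamples of the samples (without
#' replacement, fraction `subsampleFraction`), clusters each subsample with
#' the inner algorithm (average-linkage hierarchical clustering on
#' 1 - Pearson correlation by default, or k-means on z-scored features), and
#' assembles the consensus matrix: entry (i, j) = co-clustering count
#' divided by co-sampling count. Final per-k labels come from
#' average-linkage clustering of `1 - consensus` as a distance. Seed
#' deterministic.
#'
#' @param x expression matrix (genes x samples) or [M6ACohort-class].
#' @param features character vector of feature (gene) rows to cluster on;
#'   `NULL` uses all rows.
#' @param kRange candidate numbers of clusters (default 2:6).
#' @param reps number of resampling iterations (default 1000).
#' @param subsampleFraction fraction of samples drawn per rep (default 0.8).
#' @param innerAlgorithm `"hclust"` (default) or `"kmeans"`.
#' @param seed RNG seed.
#' @param selectMethod forwarded to [selectK()] for `chosenK`.
#' @param storeResamples keep every rep's subsample indices and labels
#'   (for auditing; memory-heavy, intended for small inputs).
#' @return a [ConsensusResult-class].
#' @examples
#' co <- simulateM6ACohort(simulationConfig(nSamples = 60, nGenes = 800,
#'                                          nDegPerCluster = 10, seed = 3))
#' cr <- consensusCluster(co, features = regulatorSymbols(defaultRegulatorCatalog()),
#'                        kRange = 2:4, reps = 25, seed = 3)
#' selectK(cr)
#' @export
consensusCluster <- function(x, features = NULL, kRange = 2:6, reps = 1000L,
                             subsampleFraction = 0.8,
                             innerAlgorithm = c("hclust", "kmeans"),
                             seed = 1L, selectMethod = c("delta_area", "pac"),
                             storeResamples = FALSE) {
  innerAlgorithm <- match.arg(innerAlgorithm)
  selectMethod <- match.arg(selectMethod)
  x <- exprsMatrix(x)
  if (!is.null(features)) {
    miss <- setdiff(features, rownames(x))
    if (length(miss) == length(features))
      stop("none of the requested features are in the matrix")
    if (length(miss))
      warning("dropping ", length(miss), " feature(s) absent from the matrix")
    x <- x[intersect(features, rownames(x)), , drop = FALSE]
  }
  if (nrow(x) < 2L) stop("need at least 2 features for clustering")
  n <- ncol(x)
  kRange <- sort(unique(as.integer(kRange)))
  if (any(kRange >= n)) stop("every k must be smaller than the sample count")
  if (any(kRange < 2L)) stop("k must be >= 2")
  reps <- as.integer(reps)
  if (reps < 1L) stop("reps must be >= 1")
  if (subsampleFraction <= 0 || subsampleFraction > 1)
    stop("subsampleFraction must be in (0, 1]")
  nSub <- max(2L, floor(subsampleFraction * n))

  set.seed(as.integer(seed))
  draws <- lapply(seq_len(reps), function(r) sort(sample.int(n, nSub)))

  coSample <- matrix(0, n, n)
  for (idx in draws) coSample[idx, idx] <- coSample[idx, idx] + 1

  consensus <- labels <- resamples <- setNames(
    vector("list", length(kRange)), as.character(kRange))
  anyZero <- FALSE
  for (k in kRange) {
    coCluster <- matrix(0, n, n)
    repLabels <- if (storeResamples) vector("list", reps) else NULL
    for (r in seq_len(reps)) {
      idx <- draws[[r]]
      lab <- .innerCluster(x[, idx, drop = FALSE], k, innerAlgorithm)
      for (g in split(idx, lab)) coCluster[g, g] <- coCluster[g, g] + 1
      if (storeResamples) repLabels[[r]] <- setNames(lab, colnames(x)[idx])
    }
    cons <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
    pos <- coSample > 0
    cons[pos] <- coCluster[pos] / coSample[pos]
    if (any(!pos)) anyZero <- TRUE
    diag(cons) <- 1
    consensus[[as.character(k)]] <- cons
    finalLab <- cutree(hclust(as.dist(1 - cons), method = "average"), k = k)
    labels[[as.character(k)]] <- .renumberLabels(finalLab)
    if (storeResamples) resamples[[as.character(k)]] <- repLabels
  }
  if (anyZero)
    warning("some sample pairs were never co-sampled; their consensus is 0")

  dg <- .consensusDiagnostics(consensus, kRange)
  res <- new("ConsensusResult",
    kRange = kRange, consensus = consensus, labels = labels,
    pac = dg$pac, areaUnderCDF = dg$auc, deltaArea = dg$delta,
    chosenK = NA_integer_, reps = reps,
    subsampleFraction = subsampleFraction, innerAlgorithm = innerAlgorithm,
    seed = as.integer(seed),
    resamples = if (storeResamples) list(draws = draws, labels = resamples)
                else list())
  res@chosenK <- selectK(res, method = selectMethod)
  res
}

# labels renumbered by descending cluster size, ties by the lexicographically
# first member id, so cluster "1" is always the largest
.renumberLabels <- function(lab) {
  nm <- names(lab)
  sizes <- table(lab)
  firstMember <- vapply(names(sizes), function(l)
    min(nm[lab == l]), character(1))
  ord <- order(-as.integer(sizes), firstMember)
  newLab <- setNames(seq_along(ord), names(sizes)[ord])
  setNames(as.integer(newLab[as.character(lab)]), nm)
}

.consensusDiagnostics <- function(consensus, kRange) {
  offdiag <- lapply(consensus, function(m) m[upper.tri(m)])
  cdfAt <- function(v, q) mean(v <= q)
  pac <- vapply(offdiag, function(v) cdfAt(v, 0.9) - cdfAt(v, 0.1), numeric(1))
  # Monti CDF area on a fixed grid
  grid <- seq(0, 1, by = 0.01)
  auc <- vapply(offdiag, function(v) {
    cdf <- vapply(grid, function(q) cdfAt(v, q), numeric(1))
    sum(diff(grid) * cdf[-1])
  }, numeric(1))
  delta <- numeric(length(kRange))
  delta[1] <- auc[1]
  if (length(kRange) > 1)
    delta[-1] <- diff(auc) / pmax(auc[-length(auc)], .Machine$double.eps)
  names(pac) <- names(auc) <- names(delta) <- as.character(kRange)
  list(pac = pac, auc = auc, delta = delta)
}

#' Select the number of clusters from a consensus run
#'
#' `"delta_area"` (default) applies the Monti CDF elbow: the smallest k
#' after which moving to the next candidate adds less than 0.1 to the area
#' under the consensus CDF (the area curve has flattened). `"pac"` picks the
#' k minimising the proportion of ambiguous clustering, PAC = CDF(0.9) -
#' CDF(0.1) of the off-diagonal consensus entries; low PAC means most pairs
#' are either always or never co-clustered. Ties resolve to the smallest k.
#' With a deterministic inner algorithm PAC degenerates to exact ties (0 at
#' every k that splits well-separated groups cleanly), which is why the
#' elbow rule is the default.
#'
#' @param result a [ConsensusResult-class].
#' @param method `"pac"` or `"delta_area"`.
#' @return the chosen k (integer).
#' @export
selectK <- function(result, method = c("delta_area", "pac")) {
  method <- match.arg(method)
  stopifnot(is(result, "ConsensusResult"))
  ks <- result@kRange
  if (length(ks) == 1L) return(ks)
  if (method == "pac") {
    pac <- result@pac
    ks[which.min(pac)]   # which.min takes the first (smallest k) on ties
  } else {
    # elbow on the consensus-CDF area curve: the smallest k after which the
    # area gains less than 0.1 going to the next candidate. Needs a candidate
    # beyond the true k to detect the flattening; if the curve never
    # flattens inside kRange there is no supported structure and the
    # smallest candidate is returned.
    aInc <- diff(result@areaUnderCDF)
    stable <- which(aInc < 0.1)
    if (!length(stable)) return(ks[1L])
    ks[min(stable)]
  }
}

#' Final consensus labels for a given k
#'
#' Deterministic labels from average-linkage clustering of `1 - consensus`,
#' renumbered by descending cluster size (largest cluster = 1, i.e.
#' pattern "A"), ties broken by the lexicographically first member id.
#'
#' @param result a [ConsensusResult-class].
#' @param k number of clusters; defaults to `chosenK`.
#' @return named integer vector of per-sample labels in `1..k`.
#' @export
clusterLabels <- function(result, k = NULL) {
  stopifnot(is(result, "ConsensusResult"))
  if (is.null(k)) k <- result@chosenK
  key <- as.character(k)
  if (!key %in% names(result@labels))
    stop("k = ", k, " was not part of the consensus run (kRange: ",
         paste(result@kRange, collapse = ", "), ")")
  result@labels[[key]]
}

#' Consensus matrix for a given k
#' @param result a [ConsensusResult-class].
#' @param k number of clusters; defaults to `chosenK`.
#' @return samples x samples numeric matrix with entries in \[0, 1\].
#' @export
consensusMatrix <- function(result, k = NULL) {
  stopifnot(is(result, "ConsensusResult"))
  if (is.null(k)) k <- result@chosenK
  key <- as.character(k)
  if (!key %in% names(result@consensus)) stop("k = ", k, " not available")
  result@consensus[[key]]
}

setMethod("show", "ConsensusResult", function(object) {
  cat("ConsensusResult over k = {", paste(object@kRange, collapse = ", "),
      "}, ", object@reps, " resamples of ",
      round(100 * object@subsampleFraction), "% (", object@innerAlgorithm,
      ")\n", sep = "")
  cat("PAC:", paste(sprintf("%s=%.3f", names(object@pac), object@pac),
                    collapse = "  "), "\n")
  cat("chosen k:", object@chosenK, "| cluster sizes:",
      paste(table(clusterLabels(object)), collapse = "/"), "\n")
})
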