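## Single-sample gene-set enrichment. Two statistics:
##  - ssgseaScores: the rank-weighted running-sum score (sum of the running
##    sum over all positions), in-set increments proportional to rank^alpha;
##  - gsvaScores: an ECDF-rank variant whose per-set score is the range of
##    the running sum (max deviation - min deviation).
## Plus moderated-t differential enrichment and hypergeometric ORA.

.restrictSets <- function(sets, genes, minSize) {
  kept <- lapply(sets, function(s) intersect(s, genes))
  sizes <- lengths(kept)
  drop <- sizes < minSize
  if (any(drop))
    warning(sum(drop), " gene set(s) dropped (< ", minSize,
            " members present): ", paste(names(sets)[drop], collapse = ", "))
  if (all(drop)) stop("all gene sets dropped after intersecting with matrix")
  kept[!drop]
}

# running-sum enrichment for one sample given precomputed ranks
# r: per-gene rank (higher = more expressed), ord: gene indices in
# descending-rank order, inSet: logical per gene
.runningSumScore <- function(r, ord, inSet, alpha, statistic) {
  w <- r[ord]^alpha
  w[!inSet[ord]] <- 0
  sumIn <- sum(w)
  nOut <- sum(!inSet)
  step <- ifelse(inSet[ord], w / sumIn, -1 / nOut)
  rs <- cumsum(step)
  if (statistic == "sum") sum(rs) else max(rs) - min(rs)
}

#' Single-sample GSEA enrichment scores
#'
#' For every sample, genes are ranked by expression (descending; ties get
#' average ranks). Walking down the ranked list, in-set genes add an
#' increment proportional to rank^`alpha` (increments normalized to sum 1)
#' and out-of-set genes subtract a uniform decrement; the set's score is the
#' sum of the running-sum deviations over all positions. Depends on ranks
#' only, so any strictly monotone transform of a sample's expression vector
#' leaves its scores unchanged. With `normalize = TRUE` all scores are
#' divided by the matrix-wide (max - min).
#'
#' @param x expression matrix (genes x samples) or [M6ACohort-class].
#' @param sets named list of gene-symbol vectors.
#' @param alpha rank-weight exponent (default 0.25, the method's published
#'   default).
#' @param normalize divide by matrix-wide score range (default TRUE).
#' @param minSize drop sets with fewer members present (default 2).
#' @return sets x samples numeric matrix with attributes `method` and
#'   `params`.
#' @export
ssgseaScores <- function(x, sets, alpha = 0.25, normalize = TRUE,
                         minSize = 2L) {
  x <- exprsMatrix(x)
  sets <- .restrictSets(sets, rownames(x), minSize)
  nGenes <- nrow(x)
  inSetM <- vapply(sets, function(s) rownames(x) %in% s,
                   logical(nGenes))    # genes x sets
  scores <- matrix(NA_real_, length(sets), ncol(x),
                   dimnames = list(names(sets), colnames(x)))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    r <- rank(v, ties.method = "average")
    ord <- order(v, decreasing = TRUE)
    for (s in seq_along(sets)) {
      inSet <- inSetM[, s]
      if (all(inSet)) stop("gene set '", names(sets)[s],
                           "' covers the whole matrix; score undefined")
      scores[s, j] <- .runningSumScore(r, ord, inSet, alpha, "sum")
    }
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  structure(scores, method = "ssgsea",
            params = list(alpha = alpha, normalize = normalize,
                          minSize = minSize))
}

#' GSVA-like enrichment scores
#'
#' Per gene, expression is first transformed to its cross-sample ECDF rank
#' (so a gene's value for a sample is its quantile position among all
#' samples); per sample, a KS-like running sum is then walked over genes
#' ordered by these ECDF ranks, with in-set increments proportional to
#' rank^`tau`. The score is the range of the running sum (maximum deviation
#' minus minimum deviation).
#'
#' @param x expression matrix (genes x samples) or [M6ACohort-class];
#'   needs >= 3 samples for a meaningful ECDF.
#' @param sets named list of gene-symbol vectors.
#' @param tau rank-weight exponent (default 1).
#' @param minSize drop sets with fewer members present (default 2).
#' @return sets x samples numeric matrix.
#' @export
gsvaScores <- function(x, sets, tau = 1, minSize = 2L) {
  x <- exprsMatrix(x)
  if (ncol(x) < 3L) stop("GSVA-like scoring needs >= 3 samples")
  sets <- .restrictSets(sets, rownames(x), minSize)
  # cross-sample ECDF rank per gene (ties -> average rank / n)
  ec <- t(apply(x, 1L, function(v) rank(v, ties.method = "average"))) / ncol(x)
  dimnames(ec) <- dimnames(x)
  inSetM <- vapply(sets, function(s) rownames(x) %in% s, logical(nrow(x)))
  scores <- matrix(NA_real_, length(sets), ncol(x),
                   dimnames = list(names(sets), colnames(x)))
  for (j in seq_len(ncol(x))) {
    v <- ec[, j]
    r <- rank(v, ties.method = "average")
    ord <- order(v, decreasing = TRUE)
    for (s in seq_along(sets)) {
      inSet <- inSetM[, s]
      if (all(inSet)) stop("gene set '", names(sets)[s],
                           "' covers the whole matrix; score undefined")
      scores[s, j] <- .runningSumScore(r, ord, inSet, tau, "range")
    }
  }
  structure(scores, method = "gsva_like",
            params = list(tau = tau, minSize = minSize))
}

#' Differential enrichment between two groups of samples
#'
#' Applies the moderated-t machinery of [moderatedTFit()] to the rows of an
#' enrichment matrix for one contrast pair, with Benjamini-Hochberg FDR and
#' an activated/inhibited direction column (sign of the score difference in
#' the first group relative to the second).
#'
#' @param E enrichment matrix (sets x samples).
#' @param labels per-sample group labels (named or aligned to columns).
#' @param contrast length-2 character: `c(groupA, groupB)`.
#' @return data.frame: set, scoreDiff, t, p, fdr, direction.
#' @export
pathwayDifferential <- function(E, labels, contrast) {
  stopifnot(length(contrast) == 2L)
  if (!is.null(names(labels))) labels <- labels[colnames(E)]
  keep <- labels %in% contrast
  if (sum(labels == contrast[1]) < 2L || sum(labels == contrast[2]) < 2L)
    stop("each side of the contrast needs >= 2 samples")
  sub <- E[, keep, drop = FALSE]
  g <- factor(ifelse(labels[keep] == contrast[1], "A", "B"), c("A", "B"))
  fit <- .moderatedTTwoGroup(sub, g == "A")
  data.frame(
    set = rownames(E),
    scoreDiff = fit$logFC,
    t = fit$t,
    p = fit$p,
    fdr = p.adjust(fit$p, "BH"),
    direction = ifelse(fit$logFC > 0, "activated",
                ifelse(fit$logFC < 0, "inhibited", "flat")),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Hypergeometric over-representation analysis
#'
#' One-sided hypergeometric tail test of query-gene overlap with each set,
#' with Benjamini-Hochberg FDR. Query genes outside the universe are
#' dropped with a warning; sets are intersected with the universe.
#'
#' @param queryGenes character vector of hit genes.
#' @param sets named list of gene-symbol vectors.
#' @param universe character vector, the assayed gene universe.
#' @return data.frame sorted by ascending p: set, setSize, overlap, p, fdr.
#' @export
oraEnrich <- function(queryGenes, sets, universe) {
  universe <- unique(canonicalizeSymbols(universe))
  queryGenes <- unique(canonicalizeSymbols(queryGenes))
  if (!length(universe)) stop("empty universe")
  out <- setdiff(queryGenes, universe)
  if (length(out)) {
    warning(length(out), " query gene(s) outside the universe dropped")
    queryGenes <- intersect(queryGenes, universe)
  }
  if (!length(queryGenes)) stop("empty query after universe restriction")
  N <- length(universe); q <- length(queryGenes)
  res <- lapply(names(sets), function(nm) {
    s <- intersect(unique(canonicalizeSymbols(sets[[nm]])), universe)
    m <- length(s)
    ov <- length(intersect(s, queryGenes))
    # P[X >= ov], X ~ Hypergeom(N, m, q)
    p <- phyper(ov - 1L, m, N - m, q, lower.tail = FALSE)
    data.frame(set = nm, setSize = m, overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$fdr <- p.adjust(res$p, "BH")
  res[order(res$p), , drop = FALSE]
}
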