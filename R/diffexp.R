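## Empirical-Bayes moderated two-group t statistics (Smyth-style variance
## shrinkage): per-gene residual variances are shrunk toward a prior
## estimated by moment matching of log s^2 via digamma/trigamma inversion,
## and the t statistic gains the prior degrees of freedom.

# Newton inversion of trigamma(y) = x, following the standard recurrence
.trigammaInverse <- function(x, tol = 1e-8, maxit = 50L) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in seq_len(maxit)) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif / y) < tol) break
    }
    y
  }, numeric(1))
}

# moment-matching fit of the scaled inverse-chisq prior (d0, s0^2) to the
# observed log variances; returns d0 = Inf when there is no excess spread
.fitVariancePrior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) stop("variance prior inestimable: too few positive variances")
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  eBar <- mean(e)
  excess <- mean((e - eBar)^2) * length(e) / (length(e) - 1) - trigamma(d / 2)
  if (excess <= 0) {
    d0 <- Inf
    s02 <- exp(eBar)
  } else {
    d0 <- 2 * .trigammaInverse(excess)
    s02 <- exp(eBar + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s02 = s02)
}

# two-group moderated t for rows of x; isA: logical per column
# d0 override: NULL = estimate, 0 = ordinary t, Inf = full shrinkage
.moderatedTTwoGroup <- function(x, isA, d0 = NULL, s02 = NULL) {
  nA <- sum(isA); nB <- sum(!isA)
  if (nA < 2L || nB < 2L) stop("each group needs >= 2 samples")
  a <- x[, isA, drop = FALSE]; b <- x[, !isA, drop = FALSE]
  mA <- rowMeans(a); mB <- rowMeans(b)
  logFC <- mA - mB
  ssA <- rowSums((a - mA)^2); ssB <- rowSums((b - mB)^2)
  d <- nA + nB - 2L
  s2 <- (ssA + ssB) / d
  cFac <- sqrt(1 / nA + 1 / nB)
  estimated <- FALSE
  if (is.null(d0)) {
    if (all(s2 == 0)) stop("all genes have zero residual variance; prior inestimable")
    if (sum(s2 > 0) < 10L) {
      warning("fewer than 10 positive variances; falling back to ordinary t")
      d0 <- 0
    } else {
      pr <- .fitVariancePrior(s2, d)
      d0 <- pr$d0; s02 <- pr$s02
      estimated <- TRUE
    }
  }
  if (d0 == 0) {
    s2post <- s2
    dfTotal <- d
  } else if (is.infinite(d0)) {
    if (is.null(s02)) stop("s02 required when d0 is infinite")
    s2post <- rep(s02, length(s2))
    dfTotal <- Inf
  } else {
    if (is.null(s02)) stop("s02 required when d0 is finite and fixed")
    s2post <- (d0 * s02 + d * s2) / (d0 + d)
    dfTotal <- d0 + d
  }
  se <- sqrt(s2post) * cFac
  t <- ifelse(se > 0, logFC / se, 0)
  p <- if (is.infinite(dfTotal)) 2 * pnorm(-abs(t)) else 2 * pt(-abs(t), dfTotal)
  p[logFC == 0 & se == 0] <- 1
  list(logFC = logFC, aveExpr = rowMeans(x), t = t, p = p, s2 = s2, d = d,
       d0 = d0, s02 = if (is.null(s02)) NA_real_ else s02,
       dfTotal = dfTotal, priorEstimated = estimated)
}

#' Moderated-t differential expression between modification patterns
#'
#' Fits per-gene two-group comparisons with empirical-Bayes variance
#' moderation. Residual variances follow a scaled inverse-chi-square prior
#' whose degrees of freedom `d0` and scale `s0^2` are estimated by moment
#' matching of log s^2 (digamma/trigamma inversion, Newton, tolerance 1e-8);
#' the posterior variance `(d0 s0^2 + d s^2) / (d0 + d)` enters the t
#' statistic, which is referred to a t distribution on `d0 + d` degrees of
#' freedom. Zero-variance genes are handled through the prior.
#'
#' @param x expression matrix (genes x samples) or [M6ACohort-class].
#' @param labels per-sample cluster labels (named or column-aligned).
#' @param scheme `"one-vs-rest"` (default; one contrast per cluster) or
#'   `"pairwise"` (all unordered pairs).
#' @param priorDf override for `d0`: `NULL` (estimate; default), `0`
#'   (ordinary pooled-variance t) or `Inf` (full shrinkage to `s0^2`, which
#'   must then be given via `priorVar`).
#' @param priorVar `s0^2` to use with a fixed `priorDf`.
#' @return named list of data.frames, one per contrast, each with columns
#'   gene, logFC, aveExpr, t, p, fdr, plus attributes `d0` and `s02`.
#' @export
moderatedTFit <- function(x, labels, scheme = c("one-vs-rest", "pairwise"),
                          priorDf = NULL, priorVar = NULL) {
  scheme <- match.arg(scheme)
  x <- exprsMatrix(x)
  if (!is.null(names(labels))) labels <- labels[colnames(x)]
  if (length(labels) != ncol(x)) stop("labels must cover every sample")
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  contrasts <- if (scheme == "one-vs-rest") {
    setNames(lapply(groups, function(g) list(A = g, B = setdiff(groups, g))),
             paste0(groups, "_vs_rest"))
  } else {
    prs <- utils::combn(groups, 2L, simplify = FALSE)
    setNames(lapply(prs, function(p) list(A = p[1], B = p[2])),
             vapply(prs, paste, character(1), collapse = "_vs_"))
  }
  out <- lapply(contrasts, function(ct) {
    isA <- labels %in% ct$A
    inContrast <- labels %in% c(ct$A, ct$B)
    fit <- .moderatedTTwoGroup(x[, inContrast, drop = FALSE],
                               isA[inContrast], d0 = priorDf, s02 = priorVar)
    tab <- data.frame(gene = rownames(x), logFC = fit$logFC,
                      aveExpr = fit$aveExpr, t = fit$t, p = fit$p,
                      fdr = p.adjust(fit$p, "BH"),
                      stringsAsFactors = FALSE, row.names = NULL)
    attr(tab, "d0") <- fit$d0
    attr(tab, "s02") <- fit$s02
    tab
  })
  out
}

#' Threshold a DEG table
#'
#' Keeps genes with `|logFC| >` the fold-change threshold (strict) AND
#' `p <` the p threshold (strict), matching the workflow's significance
#' standard of |logFC| > 1, p < 0.05 on raw p-values; an FDR gate is
#' available via `useAdjusted`. Output is ordered by descending |t|.
#'
#' @param degTable one contrast's data.frame from [moderatedTFit()].
#' @param lfcThreshold log2 fold-change threshold (default 1).
#' @param pThreshold p-value threshold (default 0.05).
#' @param useAdjusted gate on the BH-adjusted p instead of raw p.
#' @return character vector of gene symbols.
#' @export
selectDegs <- function(degTable, lfcThreshold = 1, pThreshold = 0.05,
                       useAdjusted = FALSE) {
  stopifnot(lfcThreshold > 0, pThreshold > 0)
  if (!nrow(degTable)) return(character())
  pcol <- if (useAdjusted) degTable$fdr else degTable$p
  keep <- abs(degTable$logFC) > lfcThreshold & pcol < pThreshold
  kept <- degTable[keep, , drop = FALSE]
  kept$gene[order(-abs(kept$t))]
}

#' Overlap (Venn core) of per-contrast DEG lists
#'
#' @param degLists named list (>= 2) of gene vectors.
#' @return list with `overlap` (intersection of all lists) and `regions`
#'   (named counts of every non-empty Venn region, names like `"1&2"`).
#' @export
overlapDegs <- function(degLists) {
  if (length(degLists) < 2L) stop("need at least 2 DEG lists")
  if (is.null(names(degLists)))
    names(degLists) <- seq_along(degLists)
  all <- unique(unlist(degLists))
  member <- vapply(degLists, function(l) all %in% l, logical(length(all)))
  if (length(all) == 1L) member <- matrix(member, nrow = 1L)
  key <- apply(member, 1L, function(row)
    paste(names(degLists)[row], collapse = "&"))
  regions <- table(key)
  list(overlap = Reduce(intersect, degLists),
       regions = setNames(as.integer(regions), names(regions)))
}
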