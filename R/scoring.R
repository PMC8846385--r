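## The m6A gene signature and per-sample score. Overlap DEGs are filtered to
## those prognostic in a univariate Cox screen, z-scored, and decomposed by
## PCA (SVD of the samples x genes matrix); a sample's m6Ascore is the sum
## of its projections onto the (sign-oriented) first two principal
## components.

#' Build the prognostic PCA signature
#'
#' Runs a univariate Cox screen over the overlap DEGs, keeps genes with
#' `p <` the threshold, z-scores the retained rows of the training matrix
#' (correlation-matrix PCA, so merged cohorts on different scales are
#' comparable), and stores the loadings of principal components 1 and 2.
#' SVD sign ambiguity is removed deterministically: each component is
#' flipped so its loading sum is >= 0, with a loading-sum tie resolved by
#' making the lexicographically first gene's loading non-negative.
#'
#' @param x training expression matrix (genes x samples) or
#'   [M6ACohort-class].
#' @param overlapGenes candidate genes (the overlap DEG list).
#' @param time,event survival outcome aligned to the samples.
#' @param coxPThreshold keep genes with Cox p below this (default 0.05);
#'   1.0 keeps every candidate.
#' @param trainingCohort id string recorded in the model.
#' @return a [SignatureModel-class].
#' @export
buildSignature <- function(x, overlapGenes, time, event,
                           coxPThreshold = 0.05, trainingCohort = "training") {
  x <- exprsMatrix(x)
  overlapGenes <- intersect(overlapGenes, rownames(x))
  if (length(overlapGenes) < 2L)
    stop("no signature genes: fewer than 2 overlap DEGs present in the matrix")
  screen <- uniCoxScreen(x[overlapGenes, , drop = FALSE], time, event)
  keep <- screen$gene[!is.na(screen$p) & screen$p < coxPThreshold]
  if (length(keep) < 2L)
    stop("no signature genes: fewer than 2 genes pass the Cox filter")
  xs <- x[keep, , drop = FALSE]
  ctr <- rowMeans(xs)
  scl <- apply(xs, 1L, sd)
  if (any(scl == 0)) {
    keep <- keep[scl > 0]
    if (length(keep) < 2L) stop("no signature genes: survivors are constant")
    xs <- x[keep, , drop = FALSE]; ctr <- rowMeans(xs); scl <- apply(xs, 1L, sd)
  }
  z <- (xs - ctr) / scl
  pc <- prcomp(t(z), center = FALSE, scale. = FALSE)
  nPC <- ncol(pc$rotation)
  load1 <- pc$rotation[, 1L]
  varTot <- sum(pc$sdev^2)
  degenerate <- nPC < 2L || pc$sdev[2L]^2 / varTot < 1e-12
  load2 <- if (degenerate) rep(0, length(keep)) else pc$rotation[, 2L]
  orient <- function(v) {
    s <- sum(v)
    if (s < 0) return(-v)
    if (s == 0 && length(v) && v[order(names(v))][1L] < 0) return(-v)
    v
  }
  names(load1) <- names(load2) <- keep
  loadings <- cbind(PC1 = orient(load1), PC2 = orient(load2))
  varExp <- c(pc$sdev[1L]^2 / varTot,
              if (nPC >= 2L) pc$sdev[2L]^2 / varTot else 0)
  if (degenerate)
    warning("training matrix has effective rank 1; PC2 loadings zeroed")
  new("SignatureModel", genes = keep, center = ctr, scale = scl,
      loadings = loadings, varExplained = varExp, degenerate = degenerate,
      trainingCohort = trainingCohort)
}

#' Per-sample m6A signature score
#'
#' Centers and scales each sample's signature-gene vector with the model's
#' training means/sds and projects it onto the stored PC1 and PC2 loadings;
#' the m6Ascore is the sum of the two projections (each projection being the
#' sum over signature genes of loading x z-value). Scoring the training
#' cohort itself yields mean zero by the PCA centering identity.
#'
#' @param model a [SignatureModel-class].
#' @param x expression matrix or [M6ACohort-class] containing every
#'   signature gene (missing genes are an error listing them).
#' @return data.frame: sample_id, pc1, pc2, score.
#' @export
m6aScore <- function(model, x) {
  stopifnot(is(model, "SignatureModel"))
  x <- exprsMatrix(x)
  miss <- setdiff(model@genes, rownames(x))
  if (length(miss))
    stop("matrix is missing signature gene(s): ",
         paste(head(miss, 10), collapse = ", "))
  z <- (x[model@genes, , drop = FALSE] - model@center) / model@scale
  proj <- t(z) %*% model@loadings    # samples x 2
  data.frame(sample_id = colnames(x), pc1 = proj[, 1L], pc2 = proj[, 2L],
             score = proj[, 1L] + proj[, 2L],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Stratify samples by score at the survival-optimal cutpoint
#'
#' Finds the maximally selected cutpoint of the score against the outcome,
#' labels samples high (`score > cut`) / low (`score <= cut`), and reports
#' per-group Kaplan-Meier curves plus the two-group log-rank test.
#'
#' @param scores data.frame from [m6aScore()] (columns sample_id, score).
#' @param time,event survival outcome aligned to `scores$sample_id`.
#' @param minprop passed to [optimalCutpoint()].
#' @return list: `scores` (input plus `group`), `cutpoint`
#'   ([CutpointResult-class]), `km` (named list of KM curves), `logrank`
#'   (list statistic/df/p).
#' @export
stratifyByScore <- function(scores, time, event, minprop = 0.1) {
  cp <- optimalCutpoint(scores$score, time, event, minprop = minprop)
  group <- ifelse(scores$score > cp@cutpoint, "high", "low")
  scores$group <- group
  km <- lapply(split(seq_along(group), group), function(i)
    kmEstimate(time[i], event[i]))
  lr <- logrankTest(time, event, group)
  list(scores = scores, cutpoint = cp, km = km, logrank = lr)
}

#' Regulator correlation network and prognostic classes
#'
#' Pairwise correlations among the catalog regulators present in the matrix
#' (Spearman by default; Pearson available) plus a per-regulator univariate
#' Cox classification: "favorable" (HR < 1, p < 0.05), "risk" (HR > 1,
#' p < 0.05), otherwise "ns".
#'
#' @param x expression matrix or [M6ACohort-class].
#' @param time,event survival outcome.
#' @param catalog a [RegulatorCatalog-class].
#' @param method correlation method, `"spearman"` (default) or `"pearson"`.
#' @return list: `pairs` (data.frame a, b, rho, p), `prognosis` (data.frame
#'   gene, role, hr, p, class).
#' @export
regulatorNetwork <- function(x, time, event,
                             catalog = defaultRegulatorCatalog(),
                             method = c("spearman", "pearson")) {
  method <- match.arg(method)
  x <- exprsMatrix(x)
  if (ncol(x) < 3L) stop("need >= 3 samples")
  regs <- regulatorSymbols(catalog)
  absent <- setdiff(regs, rownames(x))
  if (length(absent) == length(regs)) stop("no catalog regulators in matrix")
  if (length(absent))
    warning("regulator(s) absent from matrix dropped: ",
            paste(absent, collapse = ", "))
  regs <- intersect(regs, rownames(x))
  xr <- x[regs, , drop = FALSE]
  prs <- utils::combn(regs, 2L, simplify = FALSE)
  pairs <- do.call(rbind, lapply(prs, function(p) {
    ct <- suppressWarnings(cor.test(xr[p[1], ], xr[p[2], ], method = method,
                                    exact = FALSE))
    data.frame(a = p[1], b = p[2], rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  }))
  screen <- uniCoxScreen(xr, time, event)
  class <- ifelse(is.na(screen$p) | screen$p >= 0.05, "ns",
                  ifelse(screen$hr < 1, "favorable", "risk"))
  prognosis <- data.frame(gene = screen$gene,
                          role = unname(regulatorRoles(catalog)[screen$gene]),
                          hr = screen$hr, p = screen$p, class = class,
                          stringsAsFactors = FALSE)
  list(pairs = pairs, prognosis = prognosis)
}

#' Associate the score with a phenotype
#'
#' Dispatches to the workflow's standard two-sided tests: Kruskal-Wallis or
#' one-way ANOVA for >= 2 groups, Wilcoxon rank-sum for two groups, Spearman
#' correlation for a continuous covariate.
#'
#' @param score numeric per-sample score.
#' @param covariate grouping factor (kruskal/anova/wilcoxon) or numeric
#'   vector (spearman).
#' @param kind `"kruskal"`, `"anova"`, `"wilcoxon"` or `"spearman"`.
#' @return list: `statistic`, `p`, and `estimate` (rho) for Spearman.
#' @export
associateScore <- function(score, covariate,
                           kind = c("kruskal", "anova", "wilcoxon",
                                    "spearman")) {
  kind <- match.arg(kind)
  if (length(score) != length(covariate))
    stop("score and covariate lengths differ")
  switch(kind,
    kruskal = {
      g <- as.factor(covariate)
      if (nlevels(droplevels(g)) < 2L) stop("need >= 2 groups")
      kt <- kruskal.test(score, g)
      list(statistic = unname(kt$statistic), p = kt$p.value)
    },
    anova = {
      g <- as.factor(covariate)
      if (nlevels(droplevels(g)) < 2L) stop("need >= 2 groups")
      av <- summary(aov(score ~ g))[[1L]]
      list(statistic = av[["F value"]][1L], p = av[["Pr(>F)"]][1L])
    },
    wilcoxon = {
      g <- as.factor(covariate)
      if (nlevels(droplevels(g)) != 2L) stop("wilcoxon needs exactly 2 groups")
      lv <- levels(droplevels(g))
      wt <- suppressWarnings(wilcox.test(score[g == lv[1]],
                                         score[g == lv[2]]))
      list(statistic = unname(wt$statistic), p = wt$p.value)
    },
    spearman = {
      ct <- suppressWarnings(cor.test(score, as.numeric(covariate),
                                      method = "spearman", exact = FALSE))
      list(statistic = unname(ct$statistic), p = ct$p.value,
           estimate = unname(ct$estimate))
    })
}

setMethod("show", "SignatureModel", function(object) {
  cat("SignatureModel:", length(object@genes), "prognostic genes,",
      "PC1/PC2 variance", paste(round(100 * object@varExplained, 1),
                                collapse = "/"), "%\n")
  if (object@degenerate) cat("note: rank-1 training matrix, PC2 zeroed\n")
  cat("training cohort:", object@trainingCohort, "\n")
})
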