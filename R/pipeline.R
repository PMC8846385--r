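#' Run the full m6A modification-pattern analysis
#'
#' Executes the workflow end to end on one cohort: consensus clustering of
#' samples on the regulator panel (m6A clusters) -> single-sample enrichment
#' of the cohort gene sets with per-cluster Kruskal-Wallis summaries ->
#' one-vs-rest moderated-t DEGs and their overlap (Venn core) -> consensus
#' clustering on the overlap DEGs (gene clusters) -> prognostic PCA
#' signature and per-sample m6Ascore -> survival-optimal cutpoint
#' stratification with KM/log-rank -> regulator correlation/prognosis
#' network -> TMB, CNV and IPS associations with the score. Any stage
#' failure aborts with the stage name; results of completed stages are kept
#' in the partially filled return value when `outdir` is set.
#'
#' @param cohort an [M6ACohort-class] (e.g. from [simulateM6ACohort()] or
#'   assembled from loaded files via [M6ACohort()]).
#' @param catalog regulator catalog (default the built-in 23).
#' @param kRange,reps,subsampleFraction consensus-clustering parameters
#'   (defaults 2:6, 100, 0.8).
#' @param lfcThreshold,pThreshold DEG gate (defaults 1 and 0.05 on raw p).
#' @param coxPThreshold prognostic filter for signature genes (default 0.05).
#' @param minprop cutpoint window (default 0.1).
#' @param enrichMethod `"ssgsea"` (default) or `"gsva"`.
#' @param seed master seed for all stochastic stages.
#' @param outdir optional directory: per-stage TSVs plus a
#'   `run_summary.json` are written there.
#' @return a list (`RunSummary`): stage outputs (`clusters`, `enrichment`,
#'   `degs`, `geneClusters`, `signature`, `scores`, `stratification`,
#'   `network`, `genomics`) and `headline` (chosen k, cluster sizes,
#'   overlap-DEG and signature-gene counts, cutpoint, log-rank p, score-TMB
#'   Spearman rho, ARI vs. planted truth when available).
#' @examples
#' \donttest{
#' co <- simulateM6ACohort(simulationConfig(nSamples = 60, nGenes = 800,
#'                                          nDegPerCluster = 10, seed = 5))
#' rs <- runPipeline(co, kRange = 2:4, reps = 25, seed = 5)
#' rs$headline
#' }
#' @export
runPipeline <- function(cohort, catalog = defaultRegulatorCatalog(),
                        kRange = 2:6, reps = 100L, subsampleFraction = 0.8,
                        lfcThreshold = 1, pThreshold = 0.05,
                        coxPThreshold = 0.05, minprop = 0.1,
                        enrichMethod = c("ssgsea", "gsva"), seed = 1L,
                        outdir = NULL) {
  enrichMethod <- match.arg(enrichMethod)
  stopifnot(is(cohort, "M6ACohort"))
  x <- exprsMatrix(cohort)
  outcome <- survivalOutcome(cohort)
  truth <- groundTruth(cohort)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out <- list()

  out$clusters <- stage("m6a_clusters", {
    cr <- consensusCluster(x, features = regulatorSymbols(catalog),
                           kRange = kRange, reps = reps,
                           subsampleFraction = subsampleFraction, seed = seed)
    list(result = cr, k = cr@chosenK, labels = clusterLabels(cr))
  })
  labels <- out$clusters$labels

  out$enrichment <- stage("enrichment", {
    sets <- cohortGeneSets(cohort)
    if (is.null(sets)) NULL else {
      E <- if (enrichMethod == "ssgsea") ssgseaScores(x, sets)
           else gsvaScores(x, sets)
      perSet <- lapply(rownames(E), function(s)
        associateScore(E[s, ], labels[colnames(E)], kind = "kruskal"))
      summary <- data.frame(
        set = rownames(E),
        kruskalH = vapply(perSet, `[[`, numeric(1), "statistic"),
        p = vapply(perSet, `[[`, numeric(1), "p"),
        stringsAsFactors = FALSE)
      summary$fdr <- p.adjust(summary$p, "BH")
      list(scores = E, byCluster = summary)
    }
  })

  out$degs <- stage("differential_expression", {
    fits <- moderatedTFit(x, labels, scheme = "one-vs-rest")
    lists <- lapply(fits, selectDegs, lfcThreshold = lfcThreshold,
                    pThreshold = pThreshold)
    ov <- overlapDegs(lists)
    list(tables = fits, lists = lists, overlap = ov$overlap,
         regions = ov$regions)
  })
  if (!length(out$degs$overlap))
    stop("pipeline stage 'differential_expression' failed: no signature genes",
         " (empty overlap DEG list)", call. = FALSE)

  out$geneClusters <- stage("gene_clusters", {
    cr <- consensusCluster(x, features = out$degs$overlap, kRange = kRange,
                           reps = reps, subsampleFraction = subsampleFraction,
                           seed = seed + 1L)
    list(result = cr, k = cr@chosenK, labels = clusterLabels(cr))
  })

  out$signature <- stage("signature", {
    buildSignature(x, out$degs$overlap, outcome$time, outcome$event,
                   coxPThreshold = coxPThreshold)
  })
  out$scores <- stage("scoring", m6aScore(out$signature, x))

  out$stratification <- stage("stratification", {
    stratifyByScore(out$scores, outcome$time, outcome$event,
                    minprop = minprop)
  })

  out$network <- stage("regulator_network", {
    regulatorNetwork(x, outcome$time, outcome$event, catalog = catalog)
  })

  out$genomics <- stage("genomics", {
    res <- list()
    maf <- mafData(cohort)
    if (!is.null(maf)) {
      tmb <- computeTmb(maf, sampleUniverse = colnames(x))
      rho <- associateScore(out$scores$score,
                            tmb$tmb[match(out$scores$sample_id,
                                          tmb$sample_id)],
                            kind = "spearman")
      grp <- setNames(out$stratification$scores$group, out$scores$sample_id)
      res$tmb <- tmb
      res$scoreTmb <- rho
      res$mutationFrequency <- mutationFrequency(
        maf, regulatorSymbols(catalog), grp)
    }
    cnv <- cnvCalls(cohort)
    if (!is.null(cnv))
      res$cnvFrequency <- cnvFrequency(cnv, regulatorSymbols(catalog))
    ips <- ipsTable(cohort)
    if (!is.null(ips)) {
      grp <- out$stratification$scores$group[
        match(ips$sample_id, out$scores$sample_id)]
      res$ips <- associateScore(ips$ips, grp, kind = "wilcoxon")
    }
    res
  })

  ari <- if (!is.null(truth)) truthReport(truth, labels)$ari else NA_real_
  out$headline <- list(
    chosenK = out$clusters$k,
    clusterSizes = as.integer(table(labels)),
    ariVsTruth = ari,
    nOverlapDegs = length(out$degs$overlap),
    nSignatureGenes = length(out$signature@genes),
    cutpoint = out$stratification$cutpoint@cutpoint,
    logrankP = out$stratification$logrank$p,
    scoreTmbRho = if (!is.null(out$genomics$scoreTmb))
      out$genomics$scoreTmb$estimate else NA_real_,
    scoreTmbP = if (!is.null(out$genomics$scoreTmb))
      out$genomics$scoreTmb$p else NA_real_,
    seed = as.integer(seed))

  if (!is.null(outdir)) .writeRunOutputs(out, outdir)
  out
}

.writeRunOutputs <- function(out, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, nm) {
    p <- file.path(outdir, nm)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    .writeManifest(p)
    p
  }
  files <- character()
  files["labels"] <- wtsv(data.frame(sample_id = names(out$clusters$labels),
                                     m6a_cluster = out$clusters$labels),
                          "m6a_clusters.tsv")
  if (!is.null(out$enrichment)) {
    files["enrichment"] <- wtsv(
      data.frame(set = rownames(out$enrichment$scores),
                 out$enrichment$scores, check.names = FALSE),
      "enrichment_scores.tsv")
    files["enrichment_summary"] <- wtsv(out$enrichment$byCluster,
                                        "enrichment_by_cluster.tsv")
  }
  for (nm in names(out$degs$tables))
    files[paste0("deg_", nm)] <- wtsv(out$degs$tables[[nm]],
                                      paste0("deg_", nm, ".tsv"))
  writeLines(out$degs$overlap, file.path(outdir, "overlap_degs.txt"))
  files["overlap"] <- file.path(outdir, "overlap_degs.txt")
  files["gene_clusters"] <- wtsv(
    data.frame(sample_id = names(out$geneClusters$labels),
               gene_cluster = out$geneClusters$labels), "gene_clusters.tsv")
  files["scores"] <- wtsv(out$stratification$scores, "m6a_scores.tsv")
  files["cutpoint_scan"] <- wtsv(out$stratification$cutpoint@scanTable,
                                 "cutpoint_scan.tsv")
  files["network_pairs"] <- wtsv(out$network$pairs, "regulator_pairs.tsv")
  files["network_prognosis"] <- wtsv(out$network$prognosis,
                                     "regulator_prognosis.tsv")
  if (!is.null(out$genomics$tmb))
    files["tmb"] <- wtsv(out$genomics$tmb, "tmb.tsv")
  if (!is.null(out$genomics$cnvFrequency))
    files["cnv"] <- wtsv(out$genomics$cnvFrequency, "cnv_frequency.tsv")
  summary <- c(out$headline, list(files = as.list(files)))
  jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(files)
}
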