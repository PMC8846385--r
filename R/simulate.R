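## Synthetic-cohort generator. Plants the statistical structure the analysis
## assumes (regulator-driven sample clusters, cluster-patterned DEGs,
## cluster-specific immune-set activity, a latent per-sample score driving
## survival and mutational burden, regulator CNV events) so every pipeline
## stage can be exercised against known truth without controlled-access data.

.stageSeed <- function(seed, stage) {
  # independent substreams: adding one output type never perturbs the others
  as.integer((as.numeric(seed) * 97L + stage * 1000003) %% 2147483647)
}

#' Simulation configuration
#'
#' Collects and validates the knobs of [simulateM6ACohort()]. Defaults are
#' the package's reference study conditions: 300 samples, 2000 genes, three
#' regulator-driven clusters separated by a 2 z-unit shift, 100 planted
#' cluster-patterned DEGs per cluster with log2 effect 2, a latent
#' per-sample score with cluster-dependent mean that drives survival
#' (log-hazard coefficient -0.8 per score SD; high score protective) and
#' mutational burden (target Spearman -0.4), and 30% censoring.
#'
#' @param nSamples,nGenes cohort dimensions.
#' @param nClusters number of planted modification patterns (>= 2).
#' @param regulatorShift cluster mean shift on regulator genes (z units).
#' @param nDegPerCluster planted DEGs whose "deviant" cluster is each cluster.
#' @param degEffect log2-unit scale of the planted DEG pattern.
#' @param clusterLogHazard per-cluster log-hazard offsets (default all 0;
#'   cluster-level survival differences arise through the score means).
#' @param scoreLogHazard hazard log-linear coefficient of the standardized
#'   latent score.
#' @param baselineHazard exponential baseline hazard (per day).
#' @param censoringRate expected fraction of censored subjects, in [0, 1).
#' @param tmbCorrelation target Spearman correlation between latent score
#'   and mutation count (negative by default).
#' @param clusterScoreMean per-cluster mean of the latent score.
#' @param immuneShift expression shift of a cluster's activated immune set.
#' @param scoreLoading expression loading of the within-cluster residual of
#'   the latent score on the planted prognostic genes.
#' @param scoreClusterLoading coherent loading of the latent score's
#'   cluster-mean component on the prognostic genes; large enough that PC1/2
#'   of the prognostic block carry the cluster-level score, small enough to
#'   only mildly perturb the planted fold changes.
#' @param regulatorMutationRate fraction of samples carrying a regulator
#'   mutation.
#' @param cnvGainGenes,cnvLossGenes,cnvGainRate,cnvLossRate planted
#'   copy-number events on regulator genes.
#' @param seed master RNG seed; fanned out to per-stage substreams.
#' @return a validated `list` of class `simConfig`.
#' @export
simulationConfig <- function(nSamples = 300L, nGenes = 2000L, nClusters = 3L,
                             regulatorShift = 2, nDegPerCluster = 100L,
                             degEffect = 2,
                             clusterLogHazard = rep(0, nClusters),
                             scoreLogHazard = -0.8,
                             baselineHazard = 1 / 1500,
                             censoringRate = 0.3,
                             tmbCorrelation = -0.4,
                             clusterScoreMean = NULL,
                             immuneShift = 1.5,
                             scoreLoading = 0.6,
                             scoreClusterLoading = 0.4,
                             regulatorMutationRate = 0.056,
                             cnvGainGenes = c("VIRMA", "YTHDF1", "YTHDF3",
                                              "IGF2BP1", "METTL3"),
                             cnvLossGenes = c("WTAP", "RBM15", "ZC3H13",
                                              "YTHDC2", "YTHDF2", "RBM15B"),
                             cnvGainRate = 0.3, cnvLossRate = 0.2,
                             seed = 1L) {
  if (nClusters < 2L) stop("nClusters must be >= 2")
  if (censoringRate < 0 || censoringRate >= 1)
    stop("censoringRate must be in [0, 1)")
  if (!all(is.finite(c(regulatorShift, degEffect, scoreLogHazard))))
    stop("shifts and coefficients must be finite")
  if (length(clusterLogHazard) != nClusters)
    stop("clusterLogHazard must have one entry per cluster")
  if (is.null(clusterScoreMean)) {
    # mirrors the reference pattern: one high-score cluster (best survival
    # under a negative score->hazard coefficient), one low, rest in between
    clusterScoreMean <- rep(0, nClusters)
    clusterScoreMean[min(2L, nClusters)] <- 1
    clusterScoreMean[nClusters] <- -1
  }
  if (length(clusterScoreMean) != nClusters)
    stop("clusterScoreMean must have one entry per cluster")
  nImmuneGenes <- 30L * nClusters
  nProcessGenes <- 25L * 12L
  reserved <- 23L + nClusters * nDegPerCluster + nImmuneGenes + nProcessGenes
  if (reserved > nGenes)
    stop("nGenes too small: need at least ", reserved,
         " for regulators + planted DEGs + gene-set blocks")
  cfg <- mget(names(formals(simulationConfig)))
  structure(cfg, class = "simConfig")
}

#' Simulate a complete m6A analysis cohort
#'
#' Generates expression (gene-wise Gaussian noise, sd 1, plus planted
#' cluster structure), a clinical table with exponential survival times and
#' independent exponential censoring, immune-cell and biological-process
#' gene sets, a somatic-mutation MAF whose per-sample nonsynonymous count is
#' Poisson with log-mean linear in the negated latent score, regulator
#' copy-number calls, and an immunophenoscore table. Fully reproducible from
#' the config seed.
#'
#' Planted DEGs use a zero-sum per-cluster mean pattern (the "deviant"
#' cluster shifted by \eqn{-e(K-1)/2}, all others by \eqn{+e/2}) so that every
#' one-vs-rest contrast is non-null and the overlap (Venn-core) DEG set is
#' well defined.
#'
#' @param config a [simulationConfig()] (or arguments passed to it via `...`).
#' @param ... used to build a config when `config` is missing.
#' @return an [M6ACohort-class]; [groundTruth()] returns the planted truth
#'   (cluster labels, DEG/prognostic gene lists, latent score, expected TMB).
#' @examples
#' cohort <- simulateM6ACohort(simulationConfig(nSamples = 40, nGenes = 800,
#'                                              nDegPerCluster = 10, seed = 1))
#' table(groundTruth(cohort)$cluster)
#' @export
simulateM6ACohort <- function(config = NULL, ...) {
  if (is.null(config)) config <- simulationConfig(...)
  stopifnot(inherits(config, "simConfig"))
  cf <- config
  n <- as.integer(cf$nSamples); p <- as.integer(cf$nGenes)
  K <- as.integer(cf$nClusters)
  regs <- regulatorSymbols(defaultRegulatorCatalog())

  sampleIds <- sprintf("S%04d", seq_len(n))
  cluster <- rep(seq_len(K), length.out = n)
  names(cluster) <- sampleIds

  nDeg <- as.integer(cf$nDegPerCluster) * K
  degGenes <- sprintf("DEG%04d", seq_len(nDeg))
  immuneGenes <- sprintf("IMM%04d", seq_len(30L * K))
  processGenes <- sprintf("BP%04d", seq_len(25L * 12L))
  nBg <- p - 23L - nDeg - length(immuneGenes) - length(processGenes)
  bgGenes <- sprintf("G%05d", seq_len(nBg))
  genes <- c(regs, degGenes, immuneGenes, processGenes, bgGenes)

  ## latent per-sample score (drives survival, TMB, prognostic genes)
  set.seed(.stageSeed(cf$seed, 1L))
  latent <- cf$clusterScoreMean[cluster] + rnorm(n, sd = 0.75)
  names(latent) <- sampleIds
  latentStd <- as.numeric(scale(latent))

  ## expression: baseline log2 ~ N(6, 1), planted shifts on top
  set.seed(.stageSeed(cf$seed, 2L))
  x <- matrix(rnorm(p * n, mean = 6, sd = 1), nrow = p,
              dimnames = list(genes, sampleIds))
  regPattern <- matrix(rnorm(23L * K), nrow = 23L,
                       dimnames = list(regs, NULL))
  x[regs, ] <- x[regs, ] + cf$regulatorShift * regPattern[, cluster]

  degCluster <- rep(seq_len(K), each = cf$nDegPerCluster)
  degSign <- rep(c(1, -1), length.out = nDeg)
  degPattern <- matrix(cf$degEffect / 2, nrow = nDeg, ncol = K)
  degPattern[cbind(seq_len(nDeg), degCluster)] <- -cf$degEffect * (K - 1) / 2
  degPattern <- degPattern * degSign
  x[degGenes, ] <- x[degGenes, ] + degPattern[, cluster]

  # prognostic genes carry the latent score in two parts: the within-cluster
  # residual (weight scoreLoading; leaves the planted DEG contrasts intact)
  # plus a weaker coherent cluster-mean component (weight
  # scoreClusterLoading; lets a 2-component PCA of these genes see the
  # cluster-level part of the score, at the cost of mildly perturbing their
  # fold-change geometry)
  prognosticGenes <- degGenes[seq(1L, nDeg, by = 2L)]
  latentResid <- latentStd - ave(latentStd, cluster)
  latentClusterMean <- ave(latentStd, cluster)
  progSignal <- cf$scoreLoading * latentResid +
    cf$scoreClusterLoading * latentClusterMean
  x[prognosticGenes, ] <- x[prognosticGenes, ] +
    matrix(progSignal, nrow = length(prognosticGenes), ncol = n, byrow = TRUE)

  ## immune-cell sets: set k activated (+immuneShift) in cluster k's samples
  immuneSetNames <- paste0("Immune.", c("Activated.CD8.T.cell", "Macrophage",
                                        "Regulatory.T.cell", "NK.cell",
                                        "Dendritic.cell", "Monocyte"))
  immuneSetNames <- rep(immuneSetNames, length.out = K)
  if (anyDuplicated(immuneSetNames))
    immuneSetNames <- paste0(immuneSetNames, ".", seq_len(K))
  immuneSets <- split(immuneGenes, rep(seq_len(K), each = 30L))
  names(immuneSets) <- immuneSetNames
  for (k in seq_len(K))
    x[immuneSets[[k]], cluster == k] <-
      x[immuneSets[[k]], cluster == k] + cf$immuneShift

  processSetNames <- c("EMT1", "EMT2", "EMT3", "Immune_Checkpoint",
                       "CD8_T_effector", "Mismatch_Repair",
                       "Antigen_Processing", "Wnt_Targets",
                       "DNA_Damage_Repair", "Pan_F_TBRS", "DNA_Replication",
                       "Angiogenesis")
  processSets <- split(processGenes, rep(seq_len(12L), each = 25L))
  names(processSets) <- processSetNames
  geneSets <- c(immuneSets, processSets)
  attr(geneSets, "category") <- setNames(
    c(rep("immune-cell", K), rep("biological-process", 12L)), names(geneSets))

  ## survival: exponential with log-hazard = cluster offset + beta * score
  set.seed(.stageSeed(cf$seed, 3L))
  hazard <- cf$baselineHazard *
    exp(cf$clusterLogHazard[cluster] + cf$scoreLogHazard * latentStd)
  tEvent <- rexp(n, rate = hazard)
  if (cf$censoringRate > 0) {
    cRate <- mean(hazard) * cf$censoringRate / (1 - cf$censoringRate)
    tCens <- rexp(n, rate = cRate)
  } else tCens <- rep(Inf, n)
  osTime <- pmin(tEvent, tCens)
  osEvent <- as.integer(tEvent <= tCens)

  age <- pmin(pmax(round(rnorm(n, 58, 12)), 25), 90)
  stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                  prob = c(0.25, 0.4, 0.25, 0.1))
  # basal enriched at low latent score, luminal A at high (reference pattern)
  subtypeProb <- function(s) {
    w <- c(basal = exp(-1.2 * s), her2 = 1, lumA = exp(1.2 * s), lumB = 1,
           normal = 0.4)
    w / sum(w)
  }
  subtype <- vapply(latentStd, function(s)
    sample(names(subtypeProb(0)), 1L, prob = subtypeProb(s)), character(1))

  clinical <- data.frame(
    sample_id = sampleIds, os_time = osTime, os_event = osEvent, age = age,
    tumor_stage = stage, molecular_subtype = subtype,
    stringsAsFactors = FALSE)

  ## mutations: Poisson counts, log-mean linear in -latent score
  set.seed(.stageSeed(cf$seed, 4L))
  # slope from the target correlation by inverting the small-b Poisson
  # log-linear relation corr = lambda0*b / sqrt(lambda0 + lambda0^2 b^2)
  lambda0 <- 20
  rhoT <- cf$tmbCorrelation
  bTmb <- abs(rhoT) / sqrt(lambda0 * (1 - min(rhoT^2, 0.99)))
  lambda <- exp(log(lambda0) + sign(rhoT) * bTmb * latentStd)
  nMut <- rpois(n, lambda)
  classes <- nonsynonymousClasses()
  classProb <- c(0.66, 0.08, 0.06, 0.05, 0.03, 0.03, 0.05, 0.02, 0.02)
  # background mutations avoid the regulator panel so that regulator
  # alteration stays as sparse as the planted carrier rate dictates
  backgroundGenes <- setdiff(genes, regs)
  mafRows <- lapply(seq_len(n), function(i) {
    cnt <- nMut[i]
    nSilent <- rpois(1L, 0.3 * lambda[i])
    if (cnt + nSilent == 0L) return(NULL)
    cls <- c(sample(classes, cnt, replace = TRUE, prob = classProb),
             rep("Silent", nSilent))
    data.frame(
      Hugo_Symbol = sample(backgroundGenes, cnt + nSilent, replace = TRUE),
      Tumor_Sample_Barcode = sampleIds[i],
      Variant_Classification = cls,
      Variant_Type = ifelse(grepl("Ins", cls), "INS",
                     ifelse(grepl("Del", cls), "DEL", "SNP")),
      Chromosome = sample(as.character(1:22), cnt + nSilent, replace = TRUE),
      Start_Position = sample.int(1e8, cnt + nSilent, replace = TRUE),
      stringsAsFactors = FALSE)
  })
  # sparse regulator mutations on a small fraction of samples
  mutCarriers <- which(runif(n) < cf$regulatorMutationRate)
  mutableRegs <- c("LRPPRC", "YTHDF1", "FMR1", "WTAP", "YTHDC1", "YTHDF3",
                   "HNRNPA2B1")
  if (length(mutCarriers)) {
    mafRows <- c(mafRows, list(data.frame(
      Hugo_Symbol = sample(mutableRegs, length(mutCarriers), replace = TRUE),
      Tumor_Sample_Barcode = sampleIds[mutCarriers],
      Variant_Classification = "Missense_Mutation",
      Variant_Type = "SNP",
      Chromosome = sample(as.character(1:22), length(mutCarriers),
                          replace = TRUE),
      Start_Position = sample.int(1e8, length(mutCarriers), replace = TRUE),
      stringsAsFactors = FALSE)))
  }
  mafRaw <- do.call(rbind, mafRows)
  maf <- data.frame(sample = mafRaw$Tumor_Sample_Barcode,
                    gene = mafRaw$Hugo_Symbol,
                    classification = mafRaw$Variant_Classification,
                    type = mafRaw$Variant_Type, chrom = mafRaw$Chromosome,
                    pos = mafRaw$Start_Position, stringsAsFactors = FALSE)

  ## CNV calls on the 23 regulators
  set.seed(.stageSeed(cf$seed, 5L))
  cnv <- matrix(0L, nrow = 23L, ncol = n, dimnames = list(regs, sampleIds))
  background <- matrix(rbinom(23L * n, 1L, 0.02) *
                         sample(c(-1L, 1L), 23L * n, replace = TRUE), 23L, n)
  cnv <- cnv + background
  for (g in intersect(cf$cnvGainGenes, regs)) {
    hit <- runif(n) < cf$cnvGainRate
    cnv[g, hit] <- sample(c(1L, 2L), sum(hit), replace = TRUE,
                          prob = c(0.7, 0.3))
  }
  for (g in intersect(cf$cnvLossGenes, regs)) {
    hit <- runif(n) < cf$cnvLossRate
    cnv[g, hit] <- sample(c(-1L, -2L), sum(hit), replace = TRUE,
                          prob = c(0.7, 0.3))
  }

  ## immunophenoscore: noisy positive function of the latent score
  set.seed(.stageSeed(cf$seed, 6L))
  ips <- data.frame(sample_id = sampleIds,
                    ips = 5 + 0.5 * latentStd + rnorm(n, sd = 1),
                    stringsAsFactors = FALSE)

  perContrast <- lapply(seq_len(K), function(k) degGenes)
  names(perContrast) <- paste0("cluster", seq_len(K), "_vs_rest")
  truth <- list(
    cluster = cluster,
    degGenes = degGenes,
    degGenesPerContrast = perContrast,
    prognosticGenes = prognosticGenes,
    latentScore = latent,
    expectedTmb = setNames(lambda, sampleIds),
    immuneActivation = setNames(names(immuneSets), paste0("cluster", 1:K)),
    config = cf)

  M6ACohort(x, clinical = clinical, geneSets = geneSets, maf = maf,
            cnv = cnv, ips = ips, truth = truth)
}

#' Concordance between planted and recovered partitions
#'
#' @param truth a ground-truth list from [groundTruth()] (or a label vector).
#' @param predicted predicted labels, named by sample or aligned to truth.
#' @return list with `ari` (adjusted Rand index, permutation-invariant in
#'   label names) and `recall` (per true cluster, the largest fraction of its
#'   members sharing one predicted label).
#' @export
truthReport <- function(truth, predicted) {
  trueLab <- if (is.list(truth)) truth$cluster else truth
  if (!is.null(names(predicted)) && !is.null(names(trueLab))) {
    if (!setequal(names(predicted), names(trueLab)))
      stop("sample universes differ between truth and prediction")
    predicted <- predicted[names(trueLab)]
  }
  if (length(predicted) != length(trueLab))
    stop("label vectors have different lengths")
  ari <- mclust::adjustedRandIndex(trueLab, predicted)
  recall <- vapply(split(as.character(predicted), trueLab),
                   function(v) max(table(v)) / length(v), numeric(1))
  list(ari = ari, recall = recall)
}

#' Write a simulated cohort as a file bundle
#'
#' Emits the full plain-text bundle (expression TSV, clinical TSV, gene-set
#' GMT, MAF, CNV TSV, IPS TSV) plus a `truth.json` with the planted ground
#' truth, each with a sidecar manifest.
#'
#' @param cohort an [M6ACohort-class] from [simulateM6ACohort()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
writeCohortBundle <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    maf = file.path(dir, "mutations.maf"),
    cnv = file.path(dir, "cnv.tsv"),
    ips = file.path(dir, "ips.tsv"),
    truth = file.path(dir, "truth.json"))
  writeExpression(exprsMatrix(cohort), paths["expression"])
  cl <- clinicalData(cohort)
  cl <- data.frame(sample_id = rownames(cl), cl[setdiff(colnames(cl), "sample_id")],
                   stringsAsFactors = FALSE, check.names = FALSE)
  write.table(cl, paths["clinical"], sep = "\t", quote = FALSE, row.names = FALSE)
  .writeManifest(paths[["clinical"]])
  writeGeneSets(cohortGeneSets(cohort), paths["gene_sets"])
  maf <- mafData(cohort)
  mafOut <- data.frame(Hugo_Symbol = maf$gene,
                       Tumor_Sample_Barcode = maf$sample,
                       Variant_Classification = maf$classification,
                       Variant_Type = maf$type, Chromosome = maf$chrom,
                       Start_Position = maf$pos, stringsAsFactors = FALSE)
  write.table(mafOut, paths["maf"], sep = "\t", quote = FALSE, row.names = FALSE)
  .writeManifest(paths[["maf"]])
  writeExpression(cnvCalls(cohort), paths["cnv"])
  write.table(ipsTable(cohort), paths["ips"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  .writeManifest(paths[["ips"]])
  tr <- groundTruth(cohort)
  jsonlite::write_json(
    list(cluster = as.list(tr$cluster), degGenes = tr$degGenes,
         prognosticGenes = tr$prognosticGenes,
         latentScore = as.list(round(tr$latentScore, 10))),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
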