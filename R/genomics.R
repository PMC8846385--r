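## Somatic-mutation and copy-number summaries: per-sample tumor mutational
## burden from a MAF, per-group mutated-sample fractions (the tabular
## content of a waterfall plot), and per-gene CNV gain/loss frequencies.

#' Tumor mutational burden per sample
#'
#' Counts each sample's MAF records whose variant classification is in the
#' nonsynonymous set ([nonsynonymousClasses()]). Because a sample absent
#' from a MAF is ambiguous (not sequenced vs. mutation-free), an explicit
#' sample universe is required; universe samples without records get 0.
#'
#' @param maf MAF data.frame from [loadMAF()] (columns `sample`, `gene`,
#'   `classification`).
#' @param sampleUniverse character vector of all sequenced samples.
#' @param exomeSizeMb exome footprint for the per-megabase rate
#'   (default 38).
#' @param unknownClassification `"ignore"` (default; warn and skip records
#'   with a classification outside the MAF vocabulary) or `"error"`.
#' @return data.frame: sample_id, tmb (count), tmbPerMb.
#' @export
computeTmb <- function(maf, sampleUniverse, exomeSizeMb = 38,
                       unknownClassification = c("ignore", "error")) {
  unknownClassification <- match.arg(unknownClassification)
  if (!length(sampleUniverse)) stop("empty sample universe")
  if (anyDuplicated(sampleUniverse)) stop("duplicate samples in universe")
  unknown <- !maf$classification %in% .mafVocabulary()
  if (any(unknown)) {
    if (unknownClassification == "error")
      stop("unknown variant classification(s): ",
           paste(unique(maf$classification[unknown]), collapse = ", "))
    warning(sum(unknown), " record(s) with unknown classification ignored")
    maf <- maf[!unknown, , drop = FALSE]
  }
  nonsyn <- maf[maf$classification %in% nonsynonymousClasses(), , drop = FALSE]
  counts <- table(factor(nonsyn$sample, levels = sampleUniverse))
  data.frame(sample_id = sampleUniverse, tmb = as.integer(counts),
             tmbPerMb = as.integer(counts) / exomeSizeMb,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-gene, per-group mutation frequency
#'
#' Sample-level frequencies: a sample counts once per gene no matter how
#' many records it carries. Only nonsilent (nonsynonymous) records count.
#'
#' @param maf MAF data.frame.
#' @param genes genes to summarize.
#' @param groups named character vector sample -> group label (e.g. the
#'   high/low score groups); must have no empty group.
#' @return list: `byGene` (data.frame gene x group fractions), `altered`
#'   (list: per-group and overall altered-sample counts and fractions,
#'   where altered = carrying >= 1 nonsilent record in any of `genes`).
#' @export
mutationFrequency <- function(maf, genes, groups) {
  if (is.null(names(groups))) stop("groups must be named by sample id")
  lv <- unique(groups)
  sizes <- table(factor(groups, lv))
  if (any(sizes == 0L)) stop("empty group")
  nonsyn <- maf[maf$classification %in% nonsynonymousClasses() &
                  maf$sample %in% names(groups), , drop = FALSE]
  byGene <- do.call(rbind, lapply(genes, function(g) {
    carriers <- unique(nonsyn$sample[nonsyn$gene == g])
    row <- data.frame(gene = g, stringsAsFactors = FALSE)
    for (l in lv) {
      inGroup <- names(groups)[groups == l]
      row[[paste0("freq_", l)]] <- length(intersect(carriers, inGroup)) /
        length(inGroup)
    }
    row
  }))
  carriersAny <- unique(nonsyn$sample[nonsyn$gene %in% genes])
  perGroup <- lapply(lv, function(l) {
    inGroup <- names(groups)[groups == l]
    nAlt <- length(intersect(carriersAny, inGroup))
    list(n = length(inGroup), altered = nAlt,
         fraction = nAlt / length(inGroup))
  })
  names(perGroup) <- lv
  altered <- list(
    perGroup = perGroup,
    overall = list(n = length(groups), altered = length(carriersAny),
                   fraction = length(carriersAny) / length(groups)))
  list(byGene = byGene, altered = altered)
}

#' Copy-number gain/loss frequency per gene
#'
#' Gain = fraction of samples with call >= `threshold`; loss = fraction
#' with call <= `-threshold`. Continuous input is thresholded the same way.
#'
#' @param cnv gene x sample call matrix.
#' @param genes genes to summarize (absent genes dropped with a warning).
#' @param threshold call threshold (default 1).
#' @return data.frame: gene, gainFreq, lossFreq.
#' @export
cnvFrequency <- function(cnv, genes = rownames(cnv), threshold = 1) {
  absent <- setdiff(genes, rownames(cnv))
  if (length(absent))
    warning("gene(s) absent from CNV matrix dropped: ",
            paste(absent, collapse = ", "))
  genes <- intersect(genes, rownames(cnv))
  if (!length(genes)) stop("no requested genes in CNV matrix")
  sub <- cnv[genes, , drop = FALSE]
  data.frame(gene = genes,
             gainFreq = rowMeans(sub >= threshold),
             lossFreq = rowMeans(sub <= -threshold),
             stringsAsFactors = FALSE, row.names = NULL)
}
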