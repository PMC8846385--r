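## Readers / writers for the plain-text formats the pipeline touches:
## expression / CNV / clinical TSV, GMT gene sets, MAF mutation tables.
## All writers drop a sidecar JSON manifest (md5, parameters) next to the file.

#' Load a gene x sample expression matrix from TSV
#'
#' Expects gene symbols in the first column and sample ids in the header.
#' Symbols are canonicalized (uppercase, alias-resolved) and duplicate rows
#' are collapsed by their per-sample mean. A log2(x+1) transform is applied
#' according to `logTransform`:
#' \describe{
#'   \item{auto}{transform when the matrix maximum exceeds 50, the usual
#'     signature of linear-scale FPKM/TPM input (log2 data rarely exceed ~20);}
#'   \item{force}{always transform;}
#'   \item{never}{never transform.}
#' }
#' The decision is recorded in `attr(x, "loadReport")` for auditability.
#'
#' @param path TSV file path.
#' @param logTransform `"auto"` (default), `"force"` or `"never"`.
#' @param catalog [RegulatorCatalog-class] used for symbol aliases.
#' @return numeric matrix (genes x samples) with a `loadReport` attribute
#'   (list: `transformed`, `reason`, `nDuplicatesCollapsed`).
#' @export
loadExpression <- function(path, logTransform = c("auto", "force", "never"),
                           catalog = defaultRegulatorCatalog()) {
  logTransform <- match.arg(logTransform)
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression TSV needs a gene column plus >= 1 sample")
  genes <- canonicalizeSymbols(raw[[1L]], catalog)
  sampleIds <- colnames(raw)[-1L]
  if (anyDuplicated(sampleIds))
    stop("duplicate sample id(s): ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
  body <- raw[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      if (length(bad))
        stop("non-numeric value in column '", sampleIds[j], "', row ", bad[1L],
             " (gene ", genes[bad[1L]], ")")
      body[[j]] <- as.numeric(v)
    }
  }
  x <- as.matrix(body)
  if (anyNA(x)) stop("missing values in expression matrix are not allowed")
  nDup <- sum(duplicated(genes))
  if (nDup > 0L) {
    x <- rowsum(x, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, unique(genes))))
    genes <- unique(genes)
  }
  rownames(x) <- genes
  colnames(x) <- sampleIds
  doTransform <- switch(logTransform,
    force = TRUE, never = FALSE, auto = max(x) > 50)
  reason <- switch(logTransform,
    force = "forced by caller",
    never = "disabled by caller",
    auto = if (doTransform) "auto: max > 50, linear scale assumed"
           else "auto: max <= 50, already log scale")
  if (doTransform) {
    if (any(x < -1)) stop("cannot log2(x+1)-transform values below -1")
    x <- log2(x + 1)
  }
  if (any(!is.finite(x))) stop("non-finite expression values after loading")
  structure(x, loadReport = list(transformed = doTransform, reason = reason,
                                 nDuplicatesCollapsed = nDup))
}

.writeManifest <- function(path, params = list()) {
  manifest <- list(
    file = basename(path),
    md5 = unname(tools::md5sum(path)),
    params = params,
    written = "m6Apattern"
  )
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Write an expression (or CNV / score) matrix to TSV
#'
#' Genes in rows, tab separated, `.` decimal; a sidecar
#' `<path>.manifest.json` records the file hash.
#'
#' @param x numeric matrix with row and column names.
#' @param path output path.
#' @param idColumn name of the first (id) column.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path, idColumn = "gene") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- idColumn
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  .writeManifest(path, list(rows = nrow(x), cols = ncol(x)))
  invisible(path)
}

#' Load gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>member...`.
#'
#' @param path GMT file.
#' @param catalog [RegulatorCatalog-class] for symbol canonicalization.
#' @return named list of character vectors (the gene-set collection), with a
#'   `category` attribute when descriptions carry a
#'   `immune-cell|pathway|biological-process` tag.
#' @export
loadGeneSets <- function(path, catalog = defaultRegulatorCatalog()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  categ <- character(length(lines))
  known <- c("immune-cell", "pathway", "biological-process")
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("malformed GMT line ", i, ": fewer than 3 fields")
    nm[i] <- fields[1L]
    categ[i] <- if (fields[2L] %in% known) fields[2L] else NA_character_
    members <- unique(canonicalizeSymbols(fields[-(1:2)], catalog))
    members <- members[nzchar(members)]
    if (!length(members)) stop("GMT line ", i, " has no members")
    sets[[i]] <- members
  }
  if (anyDuplicated(nm))
    stop("duplicate gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(sets) <- nm
  names(categ) <- nm
  attr(sets, "category") <- categ
  sets
}

#' Write gene sets to GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional per-set description column.
#' @return `path`, invisibly.
#' @export
writeGeneSets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "category")
    if (is.null(descriptions)) descriptions <- rep("na", length(sets))
    descriptions[is.na(descriptions)] <- "na"
  }
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  .writeManifest(path, list(nSets = length(sets)))
  invisible(path)
}

#' Standard MAF nonsynonymous variant classifications
#'
#' The maftools convention for which variant classes count as
#' protein-altering (and hence toward mutational burden).
#' @return character vector.
#' @export
nonsynonymousClasses <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
    "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins", "Splice_Site",
    "Translation_Start_Site", "Nonstop_Mutation")
}

.mafVocabulary <- function() {
  c(nonsynonymousClasses(),
    "Silent", "Intron", "3'UTR", "5'UTR", "3'Flank", "5'Flank", "RNA", "IGR",
    "Targeted_Region", "De_novo_Start_InFrame", "De_novo_Start_OutOfFrame")
}

#' Load a somatic-mutation MAF table
#'
#' Requires at least `Hugo_Symbol`, `Tumor_Sample_Barcode` and
#' `Variant_Classification`; `Variant_Type`, `Chromosome` and
#' `Start_Position` are carried along when present. Coordinates stay 1-based
#' (the MAF standard).
#'
#' @param path tab-separated MAF file (comment lines starting `#` skipped).
#' @return data.frame with columns `sample`, `gene`, `classification`,
#'   `type`, `chrom`, `pos`.
#' @export
loadMAF <- function(path) {
  maf <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  miss <- setdiff(need, colnames(maf))
  if (length(miss))
    stop("MAF is missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (any(!nzchar(maf$Tumor_Sample_Barcode)))
    stop("empty Tumor_Sample_Barcode in MAF")
  getcol <- function(nm, default) {
    if (nm %in% colnames(maf)) maf[[nm]] else rep(default, nrow(maf))
  }
  data.frame(
    sample = as.character(maf$Tumor_Sample_Barcode),
    gene = canonicalizeSymbols(maf$Hugo_Symbol),
    classification = as.character(maf$Variant_Classification),
    type = as.character(getcol("Variant_Type", NA_character_)),
    chrom = as.character(getcol("Chromosome", NA_character_)),
    pos = as.integer(getcol("Start_Position", NA_integer_)),
    stringsAsFactors = FALSE
  )
}

#' Load a clinical table
#'
#' Requires `sample_id`, `os_time`, `os_event`. `os_event` is coerced from
#' `{0, 1, "Alive", "Dead"}` to a 0/1 indicator (1 = death observed).
#' Optional columns (age, stage, molecular subtype, IPS, ...) pass through.
#'
#' @param path TSV file.
#' @return data.frame with at least `sample_id`, `os_time`, `os_event`.
#' @export
loadClinical <- function(path) {
  cl <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(need, colnames(cl))
  if (length(miss))
    stop("clinical table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(cl$sample_id))
    stop("duplicate sample_id in clinical table")
  if (any(is.na(cl$os_time)) || any(cl$os_time < 0))
    stop("os_time must be non-negative and non-missing")
  ev <- cl$os_event
  ev <- ifelse(ev %in% c("Dead", "dead", "1", 1), 1L,
        ifelse(ev %in% c("Alive", "alive", "0", 0), 0L, NA_integer_))
  if (anyNA(ev))
    stop("os_event values must be in {0, 1, Alive, Dead}")
  cl$os_event <- ev
  cl$os_time <- as.numeric(cl$os_time)
  cl
}

#' Load gene x sample copy-number calls
#'
#' Integer GISTIC-style calls in \{-2, -1, 0, 1, 2\}, or continuous values to
#' be thresholded later by [cnvFrequency()].
#'
#' @param path TSV, genes in rows (first column), samples in header.
#' @return numeric matrix.
#' @export
loadCNV <- function(path) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  x <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(x) <- canonicalizeSymbols(raw[[1L]])
  if (anyNA(x)) stop("missing values in CNV matrix")
  x
}

#' Merge expression cohorts on their shared genes
#'
#' Restricts all matrices to the intersection of gene symbols, then removes
#' cohort-scale differences either by per-cohort gene-wise z-scoring
#' (population sd; the default) or by quantile normalization of every sample
#' to the pooled mean reference distribution.
#'
#' @param matrices list of gene x sample matrices (or a single matrix).
#' @param method `"zscore"` or `"quantile"`.
#' @param cohortIds optional character names for the cohorts; defaults to
#'   list names or `cohort1..N`.
#' @return merged matrix with a `cohort` attribute (per-sample cohort label).
#' @export
mergeCohorts <- function(matrices, method = c("zscore", "quantile"),
                         cohortIds = NULL) {
  method <- match.arg(method)
  if (is.matrix(matrices)) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1L)
  if (is.null(cohortIds)) {
    cohortIds <- names(matrices)
    if (is.null(cohortIds) || any(!nzchar(cohortIds)))
      cohortIds <- paste0("cohort", seq_along(matrices))
  }
  shared <- Reduce(intersect, lapply(matrices, rownames))
  if (!length(shared)) stop("no genes shared across cohorts")
  matrices <- lapply(matrices, function(m) m[shared, , drop = FALSE])
  if (method == "zscore") {
    norm <- lapply(matrices, function(m) {
      mu <- rowMeans(m)
      sdev <- sqrt(rowMeans((m - mu)^2))   # population sd
      sdev[sdev == 0] <- 1
      (m - mu) / sdev
    })
  } else {
    pooled <- do.call(cbind, matrices)
    n <- nrow(pooled)
    ref <- rowMeans(apply(pooled, 2L, sort))
    norm <- lapply(matrices, function(m) {
      apply(m, 2L, function(v) {
        out <- numeric(n)
        r <- rank(v, ties.method = "average")
        # average ref values for tied ranks via interpolation on rank grid
        out <- approx(seq_len(n), ref, xout = r)$y
        out
      })
    })
    norm <- lapply(seq_along(norm), function(i) {
      m <- norm[[i]]; rownames(m) <- shared
      colnames(m) <- colnames(matrices[[i]]); m
    })
  }
  merged <- do.call(cbind, norm)
  lab <- rep(cohortIds, vapply(matrices, ncol, integer(1)))
  names(lab) <- colnames(merged)
  structure(merged, cohort = lab)
}
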