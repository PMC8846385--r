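# m6Apattern

Tools for dissecting **N6-methyladenosine (m6A) regulator biology in bulk
tumour transcriptomes** — written for computational biologists who want the
complete m6A modification-pattern workflow (consensus subtyping → immune and
pathway enrichment → pattern-associated genes → prognostic signature score →
survival stratification → mutation-burden correlates) as tested, reusable R
functions rather than a one-off script collection.

## What it computes

Starting from a log2 gene × sample expression matrix with survival
follow-up, the pipeline:

1. clusters samples on the **23 canonical m6A regulators** (8 writers,
   2 erasers, 13 readers; built in via `defaultRegulatorCatalog()`) with
   Monti-style resampling **consensus clustering**: the consensus matrix
   entry *(i, j)* is the fraction of co-sampled resamples in which samples
   *i* and *j* co-cluster, and k is chosen from the consensus-CDF elbow
   (PAC also available);
2. quantifies per-sample immune-cell and pathway activity with the
   rank-based **ssGSEA** running-sum statistic (and a GSVA-like ECDF
   variant);
3. derives pattern-associated genes by empirical-Bayes **moderated-t**
   one-vs-rest contrasts (variances shrunk toward a scaled
   inverse-chi-square prior; gate |log2FC| > 1, p < 0.05) and intersects
   the per-contrast lists into the **overlap DEG** set;
4. filters overlap DEGs through a univariate **Cox** screen, z-scores the
   survivors and builds a 2-component PCA signature; the per-sample
   **m6Ascore** is

   score(s) = Σᵢ w1ᵢ zᵢ(s) + Σᵢ w2ᵢ zᵢ(s),

   the sum of the sample's projections onto principal components 1 and 2
   over the signature genes *i*;
5. splits the cohort at the **maximally selected log-rank cutpoint**
   (argmax over candidate thresholds of |O−E|/√V, high = score > cut) and
   reports Kaplan–Meier curves and the log-rank test;
6. relates the score to **tumor mutational burden** (nonsynonymous MAF
   records per sample), regulator **CNV** gain/loss frequencies, mutation
   frequencies by score group, and a precomputed immunophenoscore.

A first-class synthetic-cohort generator (`simulateM6ACohort()`) plants all
of this structure — three regulator-driven clusters, cluster-patterned
DEGs, cluster-specific immune-set activation, a latent score driving
exponential survival and Poisson mutation counts, regulator CNV events —
with byte-reproducible seeding, so the entire pipeline is testable without
access to controlled patient data. `cohortManifest()` lists the public
accessions (TCGA-BRCA plus six GEO series) a user would fetch to run the
workflow on real cohorts; the package itself downloads nothing.

## Worked example

```r
library(m6Apattern)

cohort <- simulateM6ACohort(simulationConfig(seed = 42))
cohort
#> M6ACohort: 2000 genes x 300 samples
#> side tables: geneSets, maf, cnv, ips, truth
#> clinical columns: sample_id, os_time, os_event, age, tumor_stage, molecular_subtype

run <- runPipeline(cohort, seed = 42)
str(run$headline)
#> List of 10
#>  $ chosenK        : int 3
#>  $ clusterSizes   : int [1:3] 100 100 100
#>  $ ariVsTruth     : num 1
#>  $ nOverlapDegs   : int 248
#>  $ nSignatureGenes: int 170
#>  $ cutpoint       : num -9.25
#>  $ logrankP       : num 4.01e-14
#>  $ scoreTmbRho    : num -0.346
#>  $ scoreTmbP      : num 7.05e-10
#>  $ seed           : int 42

run$stratification$cutpoint
#> CutpointResult: cutpoint = -9.247945 | standardized log-rank = -7.561
#> 240 candidates scanned, minprop = 0.1 ; high group = score > cutpoint
```

Reading the headline: the consensus run picked k = 3 and recovered the
planted subtypes exactly (adjusted Rand index 1); 248 genes were
differentially expressed in *every* one-vs-rest contrast, 170 of them
survived the prognostic Cox filter into the signature; splitting the
m6Ascore at its survival-optimal cutpoint separates overall survival
(log-rank p ≈ 4e-14, the high-score group surviving longer — the planted
direction), and the score is negatively correlated with mutational burden
(Spearman ρ ≈ −0.35). Pass `outdir =` to write every stage table as TSV
plus a `run_summary.json`.

Individual stages are exported on their own (`consensusCluster()`,
`ssgseaScores()`, `moderatedTFit()`, `buildSignature()`, `m6aScore()`,
`optimalCutpoint()`, `computeTmb()`, ...) and accept plain matrices, so any
step can be swapped into an existing analysis. File-based workflows go
through `loadExpression()` / `loadClinical()` / `loadGeneSets()` /
`loadMAF()` / `loadCNV()` and `writeCohortBundle()`.

## Package layout

- `R/` — S4 classes (`M6ACohort` extending SummarizedExperiment,
  `ConsensusResult`, `SignatureModel`, `CutpointResult`,
  `RegulatorCatalog`) and the stage functions.
- `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles in `helper-oracles.R`.
- `vignettes/m6Apattern-methods.Rmd` — the methods vignette: model
  details, generator design, numerical conventions, limitations.
- `inst/extdata/cohort-manifest.tsv` — the public cohort accession list.
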