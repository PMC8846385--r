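---
title: "m6Apattern: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{m6Apattern: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6Apattern)
```

# The analysis

N6-methyladenosine (m6A) is the most common internal mRNA modification,
deposited by *writer* methyltransferases (METTL3/METTL14/WTAP/VIRMA/
RBM15/RBM15B/ZC3H13/CBLL1), removed by the *erasers* FTO and ALKBH5, and
interpreted by thirteen *reader* proteins. Tumours differ systematically in
the expression of these 23 regulators, and those differences track immune
microenvironment composition, prognosis and mutational burden. m6Apattern
implements the full analytical chain used to dissect this in bulk
breast-cancer transcriptomes:

1. **Modification patterns.** Samples are clustered on the 23-regulator
   expression panel by resampling-based consensus clustering
   (`consensusCluster()`), and the number of patterns is chosen from the
   consensus-CDF diagnostics (`selectK()`).
2. **Microenvironment and pathway profiles.** Per-sample gene-set activity
   is quantified with a rank-based single-sample enrichment statistic
   (`ssgseaScores()`, `gsvaScores()`); differences between patterns use the
   moderated-t machinery (`pathwayDifferential()`) and Kruskal–Wallis tests.
3. **Pattern-associated genes.** One-vs-rest moderated-t fits
   (`moderatedTFit()`) are thresholded at |log~2~FC| > 1 and p < 0.05
   (`selectDegs()`); the intersection over all contrasts — the Venn core —
   is the overlap DEG list (`overlapDegs()`).
4. **The m6Ascore.** Overlap DEGs are filtered to those prognostic in a
   univariate Cox screen, z-scored, and decomposed by PCA
   (`buildSignature()`); a sample's score is the sum of its projections on
   principal components 1 and 2 (`m6aScore()`), in the style of the genome
   grading index. The cohort is split at the maximally selected log-rank
   cutpoint (`optimalCutpoint()`, `stratifyByScore()`).
5. **Genomic correlates.** Tumor mutational burden from a MAF
   (`computeTmb()`), per-group mutation frequencies
   (`mutationFrequency()`), regulator copy-number gain/loss rates
   (`cnvFrequency()`), and score associations (`associateScore()`).

`runPipeline()` executes the chain end to end and reports a headline
summary (chosen k, cluster sizes, overlap-DEG and signature-gene counts,
cutpoint, log-rank p, score–TMB correlation).

The score formula deserves one note. The construction "sum of PC1 and PC2"
is interpreted as *per-sample PC1 projection plus PC2 projection*, each
projection being the sum over signature genes of loading × z-scored
expression. The literal alternative — summing loadings over genes into a
cohort-wide constant — carries no per-patient information and was rejected.

# Statistical components

## Consensus clustering

For each candidate k, `reps` subsamples of the samples are drawn without
replacement (fraction 0.8 by default; features are never subsampled) and
clustered by average-linkage hierarchical clustering on 1 − Pearson
correlation. The consensus matrix entry (i, j) is the number of resamples
in which i and j co-clustered divided by the number in which both were
drawn; pairs never co-drawn get consensus 0 with a warning. Final labels
cluster `1 − consensus` as a distance and are renumbered by descending
cluster size (largest = pattern 1/"A"), with size ties broken by the
lexicographically first member id.

Two k-selection rules are provided. The *delta-area* rule (default) walks
the area under the consensus CDF and picks the smallest k after which the
next candidate adds < 0.1 area — the classic elbow. The *PAC* rule
minimises CDF(0.9) − CDF(0.1), ties resolving to the smallest k. PAC is not
the default for a structural reason: with a deterministic inner algorithm,
any k that splits well-separated groups cleanly has PAC exactly 0 — on a
crisp three-cluster cohort both k = 2 and k = 3 score 0, and the smallest-k
tie rule then under-selects. The elbow rule sees the large CDF-area jump
from k = 2 to 3 and the flat step beyond it. Note the elbow needs one
candidate beyond the true k inside `kRange` to detect the flattening.

## Single-sample enrichment

`ssgseaScores()` ranks each sample's genes (average ranks on ties), walks
the ranked list, adds rank^α-proportional increments (normalized to sum 1)
for in-set genes and uniform decrements otherwise, and scores the set as
the sum of the running-sum deviations; α = 0.25 is the statistic's
published default, and matrix-wide (max − min) normalization is applied
when requested. Because only ranks enter, scores are exactly invariant to
any strictly monotone per-sample transform — a property the tests assert
bitwise. `gsvaScores()` first replaces each gene's values by cross-sample
ECDF ranks so that between-sample spread calibrates the profile, then
scores each set by the range (max deviation − min deviation) of the
running sum.

## Moderated t

Per-gene two-group comparisons shrink residual variances toward a scaled
inverse-chi-square prior fitted by moment matching of log s²: the prior
degrees of freedom d₀ solve a trigamma equation (Newton inversion,
tolerance 1e-8) and the posterior variance (d₀s₀² + ds²)/(d₀ + d) enters a
t statistic on d₀ + d degrees of freedom. The implementation is checked
against its two closed-form limits (d₀ = 0 is the ordinary pooled t;
d₀ = ∞ fixes the denominator at s₀²) and, in the test suite, against the
independent empirical-Bayes implementation in limma. With fewer than 10
usable variances the prior is inestimable and the fit falls back to the
ordinary t with a warning.

## Survival statistics

Kaplan–Meier, log-rank and Cox fits delegate to the survival package
(product-limit estimator; O−E score test; Efron ties, convergence 1e-9,
50 iterations), with hand-computed fixtures and a brute-force
hypergeometric O−E oracle pinning the wrappers down. The maximally
selected cutpoint scans every distinct score value inside the
[q(minprop), q(1 − minprop)] window and maximises |O−E|/√V for the
high = score > cut split; ties take the smaller cutpoint. The scan is
vectorized over candidates (two indicator-matrix products), which also
makes the optional 999-permutation selection-corrected p affordable. The
maximal statistic is reported *uncorrected* by default — honest about
selection, with the permutation p available — and simulations in the test
suite show the naive reject rate is substantially inflated under the null
while the corrected rate is near nominal. One geometric caveat: on
perfectly separating data the standardized statistic peaks at, or one or
two samples inside, the early-death block rather than exactly between the
blocks, because V falls faster than O−E as the split unbalances; the same
behaviour is seen in maxstat-style implementations.

# The synthetic cohort generator

`simulateM6ACohort()` plants every statistical feature the pipeline is
meant to detect, in a fixed reference configuration chosen once:

* **Dimensions.** 300 samples × 2000 genes by default — desk scale, a few
  seconds end to end. Tests use smaller cohorts (stated per test);
  the acceptance run uses the reference size.
* **Clusters.** Three patterns, equal sizes; each regulator gets
  per-cluster mean shifts of 2 z-units times a standard-normal pattern.
* **Planted DEGs.** 100 genes per cluster with a zero-sum per-cluster mean
  pattern ((+e/2, +e/2, −e), rotated and sign-flipped per gene; e = 2), so
  *every* one-vs-rest contrast is non-null (expected log₂FC ±1.5/±1.5/∓3)
  and the Venn-core overlap list is well defined. A single-cluster shift
  would leave cross-contrast fold changes at exactly the |log₂FC| > 1
  boundary.
* **Latent score.** Per-sample score with cluster-dependent means
  (0, +1, −1; the second pattern is the high-score/good-prognosis one) and
  within-cluster noise (sd 0.75). Half of the planted DEGs are
  *prognostic*: they carry the score's within-cluster residual (weight
  0.6) plus a weaker coherent cluster-mean component (weight 0.4). The
  split is deliberate: the residual part leaves the planted fold-change
  contrasts intact, while the coherent part is what lets a two-component
  PCA of these genes see the cluster-level score at all. The weight 0.4 is
  the smallest value (on a 0.2/0.3/0.4 design grid) at which the rebuilt
  m6Ascore tracks the generative score with Spearman ≥ 0.7; the cost is
  that roughly a fifth of the prognostic half falls below the strict
  fold-change gate in some contrast, which the DEG tests account for.
* **Survival.** Exponential event times with log-hazard = cluster offset
  (0 by default) + (−0.8) × standardized score; independent exponential
  censoring calibrated to a 30% censoring fraction. Cluster-level survival
  differences therefore emerge through the score means rather than being
  specified twice.
* **Mutations.** Per-sample nonsynonymous counts are Poisson with log-mean
  linear in the negated score; the slope for a target Spearman ρ is the
  analytic inversion b = |ρ|/√(λ₀(1 − ρ²)) at base rate λ₀ = 20 (checked
  once by Monte Carlo: b = 0.10 gives ρ ≈ −0.40). Background mutations
  avoid the regulator panel; regulator mutations come from a separate
  sparse carrier process (5.6% of samples, hitting the seven regulators
  that are recurrently mutated in breast tumours) so that regulator
  alteration stays as rare as in real cohorts.
* **CNV and IPS.** Planted amplifications (30%) and deletions (20%) on
  configurable regulator subsets over a 2% background; an
  immunophenoscore table positively linked to the score.
* **Seeding.** One master seed fans out to fixed per-stage substreams, so
  adding or regenerating one output type never perturbs the others, and
  identical configs are byte-identical.

What the generator does *not* emulate: count-level RNA-seq noise (negative
binomial, library sizes), batch effects, microarray probe artefacts,
clonal structure in mutations, or realistic gene–gene correlation beyond
the planted blocks. Passing tests therefore demonstrate that the
implementation detects the structures it claims to detect at realistic
effect sizes — not that real cohorts contain those structures.

# Numerical conventions and edge cases

* Gene symbols are uppercased, trimmed, and passed through a small alias
  map (KIAA1429 → VIRMA; the frequent LRPPPRC misspelling → LRPPRC), since
  both spellings circulate. Duplicate rows collapse by mean.
* Expression loading auto-detects linear-scale input (matrix maximum
  above 50) and applies log₂(x+1); the decision is recorded in the load
  report. Missing values are a hard error everywhere — no imputation.
* PCA sign ambiguity is removed by flipping each component so its loading
  sum is ≥ 0 (loading-sum ties: the lexicographically first gene's loading
  is made non-negative). Rank-1 training matrices keep PC1 and zero PC2
  with a flag. Signature genes are z-scored before PCA so that merged
  cohorts on different scales are comparable.
* The DEG gate uses raw p (the workflow's stated standard) with strict
  inequalities; BH-adjusted values are always emitted alongside.
* Consensus pairs never co-sampled score 0 with a warning; k must satisfy
  2 ≤ k < n.
* TMB requires an explicit sample universe because absence from a MAF is
  ambiguous (unsequenced vs mutation-free); counts are reported raw and
  per megabase (38 Mb exome by default).
* The cutpoint "high" group is strictly greater than the cutpoint.

# Problem sizes

Unit tests run on 12–500-sample fixtures built in code; the acceptance
checks use the generator's reference conditions (n = 300, 2000 genes,
100 consensus resamples over k = 2..6; 20 replicates for calibration-style
checks at up to n = 400–500). The whole suite completes in under a minute
on one core.

# Known limitations

* The consensus elbow cannot flag structure at the top of `kRange`; widen
  the range if the chosen k hits its upper end.
* The naive cutpoint p-value is selection-optimistic by construction; use
  `permutationP` when the p-value itself matters.
* Univariate Cox screening across thousands of genes refits per gene;
  at whole-transcriptome scale this is the slowest step.
* The GSVA-like statistic is an ECDF-rank variant, not the kernel-density
  estimator of the original method; scores are comparable within a run,
  not across tools.
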