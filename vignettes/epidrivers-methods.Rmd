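---
title: "Methods: detecting gene-body UMR hypermethylation-driven gene activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting gene-body UMR hypermethylation-driven gene activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidrivers)
```

## The biological question and the model

In several cancers, most prominently esophageal squamous cell carcinoma,
a class of developmental transcription factors is re-activated in tumors
through an unusual epigenetic route: *gain* of DNA methylation inside
under-methylated regions (UMRs) located in their gene bodies. A UMR is a
run of CpGs whose average methylation is at or below 10% in normal
tissue; such regions are enriched for regulatory elements. The package
implements the discovery chain for genes with this signature:

1. call UMRs in normal samples and DMRs between tumor and normal;
2. call differential expression on the paired transcriptome and split a
   candidate gene list (homeobox genes) into activated (aHBG) and
   unactivated (uHBG) sets;
3. quantify the association between gene-body-UMR methylation change and
   expression change per gene set, and the overlap of activated genes
   with hypermethylated genes;
4. rank candidates with a multi-omics Gene Risk Score whose feature
   weights are derived from mutational-constraint correlations;
5. stratify patients by the activity of the resulting regulatory axis
   and test the survival difference.

Every stage is a pure function of tabular inputs, so the chain is
deterministic given its inputs.

## Coordinate conventions

Genomic intervals (genes, promoters, UMRs, DMRs) use BED-style 0-based
half-open coordinates. CpG sites are 1-based single-base positions, as
in CpG reports; a CpG at position $p$ lies in $[s, e)$ iff
$s \le p - 1 < e$. CpGs are assumed reported on one strand (pre-merged).
A per-sample observation with zero read total encodes *missing* and is
excluded from all means — never imputed.

## Methylome stages

**Coverage filter.** Observations with fewer than `min_cov = 4` reads
are masked; this mirrors the usual single-base accuracy requirement for
WGBS. Sites losing all observations are dropped.

**Region means.** The methylation of a region is the unweighted mean of
per-site $\beta$ values (methylated/total), each site first averaged
across the requested samples. Unweighted averaging matches the "average
methylation level" notion that defines UMRs; coverage-weighted
alternatives would let single deep sites dominate a region.

**UMR caller.** UMRs in this package are maximal runs of consecutive
covered CpGs with mean $\beta \le$ `umr_max_meth` (default 0.10),
containing at least `umr_min_cpgs = 10` CpGs, with no inter-CpG gap
above `max_gap_bp = 1000`. The 10% threshold *is* the UMR definition;
HMM-based segmenters used in the original analyses add smoothing on top
of it, which matters for noisy sparse data but not for the property the
definition states. The minimum CpG count is not part of the published
definition; 10 mirrors the DMR rule and is configurable. The gap cap
prevents runs from spanning CpG deserts; 1 kb is of the order of the
inter-island spacing and is likewise configurable.

**DMR caller.** Candidates are formed by merging consecutive CpGs whose
tumor-minus-normal mean difference shares sign and exceeds half the
final effect threshold (`min_diff / 2`); requiring the full threshold
per site would fragment true regions whose per-site noise straddles it.
Candidates with at least `min_cpgs = 10` CpGs are tested with a paired
two-sided Wilcoxon signed-rank test on per-sample region means
(requiring data from ≥ 3 pairs), p-values are Benjamini–Hochberg
adjusted across candidates, and regions pass at `q < 0.05` and
$|\Delta\beta| \ge 0.1$. These are the published thresholds; the
original analysis obtained its segmentation from metilene, whereas this
package substitutes a transparent statistic that preserves exactly the
stated criteria. One documented discrepancy in the source material: the
methods state a difference threshold of 0.1 while one figure caption
states ≥ 0.2; the package defaults to 0.1 and leaves the threshold as a
parameter rather than silently reconciling the two.

**Context annotation.** Promoters are strand-aware windows
`promoter_up = 1500` bp upstream to `promoter_down = 500` bp downstream
of the TSS — the source material never defines an annotation promoter,
and its experimental work targeted roughly 1–1.5 kb upstream of the
TSS, so this window brackets that with a conventional downstream
margin. Labels follow the precedence promoter > gene body > intergenic;
ties between genes are resolved by TSS distance, then lexicographic
gene id, making annotation deterministic.

## Transcriptome stages

Counts are filtered with the published rule (count strictly > 10 in at
least 5% of samples; with `min_frac = 0` the rule degenerates to "> 10
in at least one sample"). Sample QC computes each sample's network
connectivity — the sum of its Pearson correlations on
$\log_2(\text{count}+1)$ profiles with all other samples — standardizes
it and removes samples with $Z < -2$; a zero connectivity variance
(e.g. identical samples) defines all $Z = 0$. The pass is single-shot
by default, with an iterative option.

Differential expression uses median-of-ratios size factors (the
DESeq-style estimator, cross-checked against `DESeq2` in the test
suite) and, per gene, the mean over pairs of
$\log_2((t + 0.5)/(n + 0.5))$ with a paired Wilcoxon signed-rank
p-value and BH adjustment. The 0.5 pseudocount avoids logs of zero and
is configurable. The original analysis used DESeq2's negative-binomial
model; the package deliberately substitutes a distribution-free paired
test (exact DESeq2 emulation is a non-goal) and additionally accepts
externally produced DE tables via `read_de_table()`, so a DESeq2 run
can drive the downstream stages unchanged. Note the paired signed-rank
test is discrete: with $k$ pairs the smallest attainable p is about
$2/2^k$, so designs with fewer than ~15 pairs cannot clear a 5% FDR
over thousands of genes — the benchmark uses 30 pairs.

Status follows the published gates: `up` iff LFC ≥ 1 and q ≤ 0.05,
`down` iff LFC ≤ −1 and q ≤ 0.05. aHBGs are homeobox genes with status
`up`; everything else in the list (down *or unchanged*) is uHBG.

## Integration stages

Methylation–expression coupling uses the tumor−normal methylation
change over a region class per gene against the expression LFC, with a
Spearman correlation (midranks for ties; exact permutation p for
$n \le 9$, t-approximation otherwise). The `gene_body_umr` region class
intersects UMRs *called on normal samples* with gene bodies and then
averages both conditions over that fixed region — calling UMRs on
tumors would let the region itself shift under hypermethylation and
bias the delta toward zero. Genes without a qualifying region are
absent from the table, not zero-filled.

Set-overlap enrichment is the upper-tail hypergeometric probability
$P(X \ge k)$; SNV density divides SNV counts by region length in kb
(full gene-interval length — whether the original analysis used coding
length is unstated); the substitution spectrum strand-collapses
purine-reference SNVs onto the six pyrimidine classes, flagging CpG
context by a G immediately 3′ of the collapsed base.

## The Gene Risk Score

For gene $i$ and feature matrix $X$ with columns LFC, $|\Delta M|$,
MAF and network degree,
$$\mathrm{GRS}_i = \sum_{j=1}^{M} \rho_j \, Z(X_{ij}),$$
with $\rho_j$ the Spearman correlation of column $j$ with the genes'
missense-constraint Z scores. Design decisions taken here, where the
source formulation is silent:

* **Standardization.** Raw features mix scales (MAF $\sim 10^{-3}$,
  degree $\sim 10^{1}$); without standardization one column dominates
  numerically. Columns are z-scored by default (`standardize = FALSE`
  restores the raw sum). Because Spearman weights are rank-based and
  z-scoring is affine, the default score is equivariant to positive
  rescaling of any raw feature — a property the test suite asserts.
* **Weight population.** Weights are computed over all genes in the
  supplied feature table (restricting to aHBGs is possible by
  subsetting beforehand).
* **Aggregations.** Per-gene MAF is the mean allele frequency of the
  gene's SNVs (0 with none); connectivity is the count of distinct
  partners over deduplicated edges with combined score ≥ 700.

Genes with any missing feature are dropped with a warning; ranking is
by descending score with lexicographic tie-breaks; `missense_z ≥ 3.09`
flags constraint-intolerant genes. Ranks are a permutation of
$1..n$ and permuting input rows permutes scores identically (tested).

## Survival axis

PLAGE activity is the right singular vector of the largest singular
value of the per-gene z-scored $\log_2(\text{count}+1)$ expression of
the axis gene set. The SVD sign is arbitrary, so it is fixed to
correlate non-negatively with the set's mean z-scored expression —
"high activity" then means high axis expression, matching the direction
in which the axis is prognostic. Whether the original scores were
computed on counts or TPM is unstated; the package uses
$\log_2(\text{count}+1)$ and accepts any pre-logged matrix.

The cutpoint maximizes the absolute standardized log-rank statistic
$|O - E| / \sqrt{V}$ over midpoints between consecutive sorted unique
scores, keeping at least `min_prop = 0.1` of samples per side (the
usual maximally-selected-statistics convention; unspecified in the
source). Ties go to the smaller cutpoint. The reported p-value is the
*plain* log-rank p at the selected cutoff — no selection correction is
applied, since that is what the published p-values are; treat it as
descriptive rather than a calibrated type-I error.

The log-rank statistic accumulates, at each distinct event time, the
observed events in one group against the hypergeometric expectation and
variance given the risk sets; Kaplan–Meier estimation delegates to the
`survival` package (censored-at-event-time samples count as at risk).

## The synthetic benchmark

`generate_bundle()` emulates the study conditions end-to-end from one
root seed (independent substreams per data type, so regenerating one
block leaves the others identical):

* **Layout.** Genes of 2 kb on four chromosomes, 3 kb apart; CpGs every
  50 bp inside genes and every 500 bp between them — desk-scale density
  with realistic clustering.
* **Methylome.** Beta-binomial methylation (precision 30) around a 0.8
  background; every homeobox-like gene carries a centered gene-body UMR
  (40% of the body, ~16 CpGs) at $\beta = 0.05$ in normals. In tumors,
  driver UMRs gain `delta_meth` scaled by a per-driver multiplier
  $u_i \sim U(0.6, 1.4)$. Coverage is Poisson(30) with a 5% low-coverage
  admixture (mean 2, floored at 1 read) so the coverage filter has real
  work.
* **Expression.** Negative-binomial counts (dispersion 0.15) around
  log-normal baselines; driver tumor means scale by
  $2^{\mathrm{lfc} \cdot u_i}$. The same $u_i$ couples methylation gain,
  expression gain and constraint, producing the positive
  methylation–expression correlation among drivers that the method is
  designed to detect.
* **Variants, network, constraint.** SNV densities of 1/kb (2/kb for
  drivers) with a C>T-at-CpG-dominated spectrum presented on both
  strands; driver allele frequencies inflated 3×; edge probabilities
  0.06 (drivers) vs 0.006 with combined scores uniform on 400–1000;
  missense Z near $3 + u_i$ for drivers versus standard normal
  otherwise.
* **Survival.** A per-tumor-sample activity $a_s \sim N(0,1)$ shifts
  the axis genes' expression by $2^{0.5 a_s}$ and multiplies an
  exponential hazard (baseline 0.02/month) by $2^{a_s}$, with uniform
  administrative censoring on 30–60 months.

Default sizes — 2000 genes, 30 pairs, 40 drivers among 170
homeobox-like genes — keep a full pipeline run under a minute on one
CPU while leaving each statistical stage non-trivial. What the
generator does **not** emulate: genome-wide hypomethylation (it plants
only hypermethylation, so hypo-DMR dominance in real tumors is outside
what passing tests demonstrate), CpG-island structure, batch effects,
copy-number confounding of expression, linked variants, and realistic
network topology beyond degree inflation. Recovery results on the
benchmark therefore validate the machinery, not the biology of any
particular cohort.

## Numerical choices and degenerate inputs

* Wilcoxon tests use the normal approximation with continuity
  correction; zero differences are dropped per convention, and a test
  with no non-zero differences returns p = 1.
* Spearman p-values switch to exhaustive permutation at $n \le 9$
  ($9! \approx 3.6 \times 10^5$ permutations).
* Constant feature columns get weight 0 (with a warning) and contribute
  nothing after standardization; constant scores make cutpoint
  selection an error rather than an arbitrary split.
* Empty DMR sets yield `NA` fractions, not 0; empty UMR/DMR calls are
  empty tibbles with stable schemas.
* Ties: DMR/UMR runs break at chromosome boundaries and configured
  gaps; ranking and annotation ties resolve lexicographically so all
  outputs are reproducible.

## Limitations

* The DMR/UMR callers are threshold segmentations; they will fragment
  regions whose signal hovers at the threshold and have no smoothing
  across sparse CpGs.
* The paired Wilcoxon DE test is conservative at small pair counts and
  ignores count overdispersion structure; for production differential
  expression, import a DESeq2 table.
* The maximally selected log-rank p is not corrected for cutpoint
  selection and is anti-conservative as a hypothesis test.
* Dataset-scale published quantities (e.g. absolute DMR counts or
  global methylation averages from 150-pair cohorts) depend on data
  volumes outside a desk-scale benchmark; the package's checks target
  arithmetic identities, estimator correctness against oracles, null
  calibration and planted-truth recovery instead.
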