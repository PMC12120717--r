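# epidrivers

Discovery of epigenetically activated driver genes from paired
tumor/normal multi-omics data.

In esophageal squamous cell carcinoma (ESCC), a set of homeobox
transcription factors is switched on not by promoter demethylation but
by **hypermethylation of under-methylated regions (UMRs) inside their
gene bodies**. `epidrivers` implements the computational chain that
discovers such genes from whole-genome bisulfite (WGBS), RNA-seq,
variant, interaction-network and survival data, and ships a seeded
synthetic multi-omics generator with known ground truth so the entire
chain is testable end-to-end without any data downloads.

The package is aimed at computational biologists working on methylome /
transcriptome integration who want a transparent, fully tested
implementation of each step rather than a black-box workflow.

## What it computes

1. **Methylome** — CpG coverage filtering (≥ 4 reads), UMR calling
   (maximal runs of ≥ 10 CpGs with mean methylation β ≤ 10%), paired
   tumor-vs-normal DMR calling (sign-consistent CpG merging, paired
   Wilcoxon signed-rank on region means, Benjamini–Hochberg FDR < 0.05,
   |Δβ| ≥ 0.1, ≥ 10 CpGs), genomic-context annotation
   (promoter > gene body > intergenic) and gene-body metagene profiles.
2. **Transcriptome** — expression filtering (count > 10 in ≥ 5% of
   samples), sample QC by standardized network connectivity (drop
   Z < −2), paired nonparametric differential expression with
   median-of-ratios normalization (|log₂FC| ≥ 1, FDR ≤ 0.05), and
   classification of a homeobox list into activated (aHBG, up) versus
   unactivated (uHBG, down or unchanged) genes.
3. **Integration** — Spearman correlation of gene-body-UMR methylation
   change against expression change per gene set, hypergeometric
   set-overlap enrichment, SNV density per kb, and the
   pyrimidine-collapsed substitution spectrum with CpG-context flags.
4. **Gene Risk Score (GRS)** — for gene *i* with features
   *X*<sub>*ij*</sub> (log₂ fold change, |ΔM|, minor allele frequency,
   interaction-network degree at combined score ≥ 700):

   GRS<sub>*i*</sub> = Σ<sub>*j*</sub> ρ<sub>*j*</sub> · Z(X<sub>*ij*</sub>)

   where each weight ρ<sub>*j*</sub> is the Spearman correlation of
   feature *j* with the gene's missense-constraint Z score (Z ≥ 3.09
   flags intolerant genes), and Z(·) standardizes each feature column.
5. **Survival axis** — PLAGE pathway activity (leading right singular
   vector of the z-scored gene-set expression), maximally selected
   log-rank cutpoint, Kaplan–Meier curves and the two-group log-rank
   test.

## Worked example

```r
library(epidrivers)

bundle <- generate_bundle(synthetic_config(
  n_genes = 400, n_pairs = 25, n_drivers = 15, n_homeobox = 40, seed = 42
))
report <- run_pipeline(bundle, grs_k = 10)
report
#> <pipeline_report>
#>   UMRs: 40   DMRs: 15 (0.0% hypo)
#>   DE: 15 up / 0 down   aHBG: 15 / uHBG: 25
#>   aHBG x hyper overlap: 100.0% (p = 1.59e-27)
#>   GRS genes scored: 40 (top: G0169, G0097, G0313)
#>   survival: cutoff 0.133, log-rank p = 0.002628
```

All 40 planted gene-body UMRs are recovered, the 15 planted drivers are
called as hyper-DMRs and as upregulated (hence aHBGs), and every aHBG
overlaps the hypermethylated gene set (the generator plants only
tumor-hypermethylated regions, so 0% of DMRs are hypomethylated —
unlike real tumors, where global hypomethylation dominates).

```r
head(tidy(report$grs), 3)
#>   gene_id   grs  rank constrained
#> 1 G0169    4.75     1 TRUE
#> 2 G0097    4.72     2 TRUE
#> 3 G0313    4.31     3 TRUE

report$correlations
#>     rho      p_value     n gene_set
#> 1 0.760  0.0000000130    40 all
#> 2 0.929  0.000000587     15 aHBG
#> 3 0.0308 0.884           25 uHBG
```

Methylation gain in gene-body UMRs correlates strongly with
overexpression for activated genes (ρ = 0.93) and not at all for
unactivated ones — the signature the method is built to detect. Scoring
against the planted truth:

```r
truth_report(bundle$truth,
             rank_and_select(report$grs, 15)$gene_id,
             called_umrs = report$umrs, k = 15)
#>    k n_drivers n_hit precision_at_k recall_at_k umr_jaccard
#> 1 15        15    15              1           1       0.939
```

`autoplot(report$grs)`, `autoplot(report$survival)`,
`plot_delta_correlation(report$delta_umr)` and
`plot_gene_body_profile()` give ggplot views of each result.

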