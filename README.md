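# stoichcomp

Aneuploid tumors gain or lose whole chromosomes, which immediately
perturbs the dosage of hundreds of genes. For protein complexes this is a
stoichiometry problem: subunits encoded on the altered chromosome are
over- or under-produced relative to their partners on other chromosomes,
leaving orphan subunits that are prone to aggregation. `stoichcomp`
implements an analysis pipeline for studying how tumors compensate: it
detects recurrent cancer-type-specific whole-chromosome aneuploidies,
calls the transcripts and proteins that change with them, asks whether
the changes on *other* chromosomes are concentrated among co-complex
partners of the aneuploid proteins, attributes the regulation to
transcriptional vs post-translational layers, and scores each tumor's
residual stoichiometry imbalance against survival.

The package is aimed at computational cancer biologists working with
paired aneuploidy/transcriptome/proteome cohorts (TCGA/CPTAC-style).
Because the original data sources cannot be redistributed, `stoichcomp`
ships a fully parameterized synthetic multi-omics cohort generator with
recorded ground truth; every stage of the pipeline has a recovery test
against planted signal.

## Core statistics

* **Whole-chromosome calls** from arm-level scores s_p, s_q in
  {-1, 0, +1}: chromosomes 1-12 and 16-20 are called only when both arms
  agree; for the acrocentric chromosomes (13-15, 21, 22) the q arm is
  representative. Conflicting or missing arms give NA.
* **Recurrence and enrichment** use the 2x2 Pearson chi-square with the
  standard residual r = (O - E) / sqrt(E); a case is recurrent at
  Holm-adjusted p <= 0.05 with r >= 2, co-amplifications at adjusted
  p < 0.01.
* **Differential expression** is a two-sided Wilcoxon rank-sum test per
  feature: transcripts at BH-adjusted p < 0.1 (falling back to raw
  p < 0.05 when fewer than 250 protein-coding genes pass), proteins at
  raw p < 0.1.
* **Partner co-abundance** is the Spearman correlation of protein pairs
  per cancer type, pooled across types by the maximum correlation per
  pair.
* **PPI enrichment** compares the observed cross-set interaction count
  with a degree-preserving null that replaces each aneuploid protein by a
  random protein from its log2-degree bin; p = (1 + #{null >= obs}) /
  (n_iter + 1).
* **The stoichiometry deviation score** of a sample is the mean absolute
  residual over the top-30 partner-on-aneuploid-protein regressions;
  survival is stratified at the cutpoint maximizing the standardized
  log-rank statistic over the 10-90% score quantile window
  (Kaplan-Meier curves, log-rank p).

## Worked example

```r
library(stoichcomp)

cohort <- generate_cohort(cohort_config(seed = 1))
cohort
#> stoich_cohort: 300 samples (3 types), 1100 genes, 697 proteins,
#>   103 complexes, 2964 PPI edges, 56 compensated pairs

chrom <- chromosome_scores(cohort$arm_scores)
detect_recurrent(chrom, cohort$sample_info$cancer_type)
#>   cancer_type chromosome direction n_altered n_type   chi2_p std_residual    adj_p
#> 1         CT1          7         1        60     99 2.20e-27         7.85 2.77e-25
#> 2         CT2         10        -1        58     96 1.64e-29         8.30 2.09e-27
#> 3         CT3         12         1        60     97 1.23e-31         8.60 1.57e-29

report <- run_pipeline(cohort, list(ppi_iters = 200))
case <- report$cases[["CT1_chr7_+1"]]
case$ppi$value[c("observed", "p")]
#> $observed [1] 46      $p [1] 0.0199
report$comparisons$aggregation$value[c("median_in", "median_out", "p")]
#> $median_in [1] 0.092   $median_out [1] 0.019   $p [1] 2.7e-05
report$stoichiometry$value$survival$overall$value[c("cutpoint", "p")]
#> $cutpoint [1] 0.325    $p [1] 1.1e-19
```

Reading the numbers: the three planted aneuploidies (chr7 gain in CT1,
chr10 loss in CT2, chr12 gain in CT3) are recovered with large standard
residuals. For the chr7 amplification, the 46 physical interactions
between differentially abundant aneuploid proteins and those on other
chromosomes exceed the degree-preserving null (p = 0.02); partner
correlations are higher when the aneuploid protein is aggregation-prone
(p = 2.7e-05), the planted compensation signature; and stratifying
samples at deviation score 0.325 separates survival strongly (log-rank
p = 1.1e-19, planted hazard ratio 3).

A cohort can be written to and read back from a directory of plain-text
files (`write_cohort()` / `read_cohort()`), and a thin CLI wraps the two
entry points (`inst/cli/stoichcomp.R simulate|run`).

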