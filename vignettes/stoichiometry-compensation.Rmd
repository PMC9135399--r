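---
title: "Methods: detecting stoichiometry compensation in aneuploid cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting stoichiometry compensation in aneuploid cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

Whole-chromosome aneuploidy changes the copy number of every gene on the
affected chromosome at once. At the transcript level this produces a dosage
effect roughly proportional to the copy-number ratio; at the protein level
the effect is attenuated, because complex-forming proteins are degraded when
their partners are missing. The package's working model has three layers:

1. **Dosage.** Genes on a chromosome with state $s \in \{-1, 0, +1\}$ shift
   their mean log2 expression by $\beta s$ (transcripts) and
   $\alpha \beta s$ (proteins), with attenuation $\alpha \in [0, 1]$.
2. **Compensation.** For an aneuploid protein $x$ whose unpaired excess
   would aggregate, the abundance of its co-complex partner $y$ on another
   chromosome tracks $x$: across samples,
   $y = \rho\, z_x + \sqrt{1-\rho^2}\,\varepsilon$ on the standardized
   scale, so partner pairs reach a co-abundance correlation near $\rho$.
   The residual noise $\varepsilon$ is the biologically interesting part:
   samples that fail to compensate have larger residuals.
3. **Consequence.** The per-sample *stoichiometry deviation score* is the
   mean absolute residual over the strongest partner regressions; it feeds
   a survival stratification and a correlation analysis against
   degradation-machinery abundance.

Every analysis stage is a separate module with its own statistics; the
pipeline (`run_pipeline()`) wires them in order and records per-stage skip
reasons instead of failing.

# Stage-by-stage procedure and numerical choices

## Whole-chromosome calls

Arm-level calls in $\{-1, 0, +1, \mathrm{missing}\}$ collapse to
whole-chromosome states: both arms must agree for chromosomes 1--12 and
16--20; the q arm is representative for the acrocentric 13--15, 21 and 22;
anything else is NA, and NA samples are excluded per chromosome, not
globally. Autosomes only. Cancer-type labels are caller-supplied, so
merging types (e.g. treating colon and rectal cohorts as one) is a label
remapping before detection.

## Recurrent-aneuploidy detection

Each (type, chromosome, direction) is tested one-vs-rest: a 2x2 table of
{this type, other types} x {altered in this direction, not}, Pearson
chi-square, Holm correction across all tests, and the selection rule
adjusted p <= 0.05 with standard residual >= 2. The one-vs-rest table is
the minimal reading of testing "within each cancer type against random
expectation"; amplifications and deletions are tested separately because
they are reported as separate case lists.

A numerical point that matters: the *standard residual*
$(O-E)/\sqrt{E}$ is always the raw Pearson component, but the uncorrected
chi-square tail is anticonservative on 2x2 tables at Holm-level thresholds
(measured family-wise error 0.08--0.10 on null cohorts). The p-value
therefore uses the Yates continuity correction by default
(`correct = TRUE`; measured family-wise error 0.02--0.04), which leaves
the residuals untouched. The uncorrected p remains available for exact
comparison against textbook Pearson components.

Co-amplifications are tested within each amplification case's type
(chi-square on co-occurrence with every other chromosome, Holm, adjusted
p strictly below 0.01), and each chromosome's contribution to
dysregulation is the fraction of its genes that are differentially
expressed; co-amplified and other chromosomes are compared with a paired
Wilcoxon test across cases.

## Differential expression

Transcripts arrive as TPM (conversion normalizes each sample to $10^6$;
all-zero features are dropped, and an exclusion list hook covers
mitochondrial genes). Proteomic spectral counts can be quantile-normalized
onto the mean order-statistic profile followed by log2; ties map through
average ranks with linear interpolation of the reference.

The test is a two-sided Wilcoxon rank-sum per feature (`stats::wilcox.test`:
exact for small tie-free samples, normal approximation with tie and
continuity correction otherwise). Transcript significance is BH-adjusted
p < 0.1; when fewer than 250 protein-coding genes pass, the call falls back
to raw p < 0.05 so downstream enrichment tests retain power. Proteins use
raw p < 0.1 with no adjustment and no fallback -- the relaxed cutoff *is*
the protein rule. Missing protein values are excluded pairwise (never
imputed); features with fewer than 3 observed values per group are
skipped; constant features get p = 1 and a flag. Direction is the sign of
the median group difference.

## Complex and partner analyses

The complex database is a GMT-shaped container (subunit sets plus
functional-term labels). Partner enrichment crosses DA status with
partner status over the universe of *quantified other-chromosome
proteins* -- the most conservative universe consistent with the analysis;
in particular, proteins in no complex stay in the universe (they are the
baseline the partner signal is judged against). Only direction-consistent
aneuploid proteins seed the pair set: increased for amplifications,
decreased for deletions.

Correlations are Spearman with average-rank ties, computed per cancer
type over pairwise-complete samples (>= 3, constant vectors dropped), and
pooled by keeping the maximum *signed* rho per unordered pair; an
absolute-maximum variant exists for sensitivity checks, since "strongest"
is ambiguous for negative correlations. Promiscuity is a strict
more-than-five-complexes rule, co-occurrence frequency is
|complexes with both| / |complexes with either|, and group contrasts
(co-complex vs non-complex, aggregation-prone vs not, promiscuous vs not,
correlation classes at the $\pm 0.2$ band) are rank-sum tests.

## PPI randomization

The interaction network is a simple undirected edge list (self-loops
rejected, duplicates collapsed). The null preserves degree structure:
each aneuploid protein is replaced by a distinct protein drawn uniformly
from its log2-degree bin, widening to adjacent bins when a bin is
exhausted -- "similar degree" needs a concrete definition and logarithmic
bins keep relative degree error bounded. Replacements may hit other
members of the original set (only self-replacement is forbidden); the
fixed partner set stays fixed. The p-value uses the pseudocount form
$(1 + \#\{null \ge obs\})/(n_{iter}+1)$, bounded away from zero, with the
raw $k/n$ variant available.

## Regulatory layers

Methylation: each gene maps to its most upstream promoter (resolved at
cohort-generation time); per-gene mean beta values in aneuploid vs
diploid samples are compared with a *paired* Wilcoxon by default (each
gene is its own control; a pooled variant exists), separately for up- and
downregulated genes. The TF-target test counts targets of differentially
expressed aneuploid-chromosome TFs among other-chromosome DE genes
against size-matched random TF sets (100 iterations by default,
configurable upward for stability). Its two-tailed empirical p uses a
mid-p convention -- the observed value counts half in each tail -- because
doubling tails that both fully include the observed point mass is visibly
conservative on a discrete null (mean p ~0.56, failing uniformity
checks); the conservative formula remains as `p_method = "conservative"`.
Ubiquitination-site totals are compared across {all proteins, complex
subunits, top-positive partners (rho >= 0.4), top-negative partners
(rho <= -0.4)}, proteins absent from the ubiquitination data removed.

## Functional enrichment

Per aneuploidy case (selection is per case, before pooling), the top 20
positive and 20 negative correlation pairs stand against the
non-correlated background band $[-0.2, 0.2]$ (top pairs removed from the
background so the groups are disjoint; boundary ties break by pair ID).
The complexes containing the partner proteins enter a per-term 2x2
chi-square, and the enrichment score is $(O-E)/\sqrt{E}$ of the
(top, annotated) cell. No multiple-testing correction across terms by
default (significance is p < 0.05), with a BH option. Sensitivity
re-runs drop ribosomal genes or complexes with more than 10 subunits.

## Deviation score and survival

The top 30 amplification-case pairs by absolute rho (signed-positive
optional) are fitted by OLS (partner on aneuploid protein, all
pairwise-complete samples; residuals are in-sample, matching the score's
construction; an out-of-fold option exists). The deviation score of a
sample is the mean absolute residual over models where both proteins are
measured (>= 50% of models required). Survival stratification scans every
observed score in the 10--90% quantile window for the cutpoint maximizing
the standardized log-rank statistic, assigns score <= cutpoint to the low
group, and reports Kaplan-Meier curves with the naive log-rank p. The
naive p ignores cutpoint selection and is anti-conservative; a
permutation-adjusted p (default 1000 permutations of scores against
survival) is available and recommended for confirmatory use.
Degradation-machinery coupling is the rank-sum comparison of the
degradation set's abundance-vs-score Spearman correlations against all
proteins, repeated within amplification- and deletion-carrier subsets.

# The synthetic cohort generator

`generate_cohort()` draws, deterministically per seed (each block has its
own derived seed, so editing one block never reshuffles another):

* arm scores with planted whole-chromosome events (both arms set) on top
  of a background alteration rate, plus measurement noise: missing arm
  calls (1%) and single-arm discordances (1%) that exercise the NA rules;
* log-normal transcripts rescaled to TPM, dosage effect log2(1.5) -- the
  3:2 copy ratio of a single-chromosome gain -- with noise SD 0.5;
* proteins at attenuation 0.5 with noise SD 0.5 and 10% missingness
  completely at random, quantifying 70% of coding genes;
* a complex database of 100 random complexes (sizes 3--8) plus a few
  large ribosomal complexes, with recurring promiscuous hub subunits (one
  forced onto each planted chromosome so promiscuity analyses always have
  material) and semicolon-term annotations;
* compensated pairs: aggregation-prone, non-promiscuous aneuploid
  complex proteins coupled to up to three other-chromosome partners at
  target Spearman rho 0.6; the partner residual noise is scaled by the
  planted per-sample deviation state (multiplier 1 or 2, normalized so
  the marginal correlation still hits the target);
* a PPI edge list with compensated-pair edges, intra-module
  cross-wiring, 30% of co-complex pairs, and random background edges;
* promoter methylation (one promoter per gene, beta values), a random
  TF-target map, Poisson ubiquitination counts (rate 6 for compensated
  partners vs 2 background), degradation-machinery proteins whose
  abundance increases with the deviation state, and exponential survival
  with hazard ratio 3 per deviation unit, administratively censored.

Default study conditions: 3 cancer types x 100 samples, 1100 genes on 22
chromosomes, one planted aneuploidy per type (chr7+, chr10-, chr12+) at
carrier fraction 0.6 over a background alteration rate of 0.05.

What the generator does **not** emulate: copy-number segmentation noise,
batch or platform effects, correlated gene-gene expression structure
beyond the planted pairs, realistic complex-size or degree distributions,
GO-DAG term structure, or competing risks in survival. Passing recovery
tests therefore demonstrates that the statistics recover their own
planted signal at realistic sizes -- not that real-tumor effect sizes
would be detected; on real data the dosage and compensation effects are
weaker and noisier than the defaults here, and detected fractions will
differ accordingly.

# Test design and problem sizes

Oracle tests check each statistic against an independent brute-force
implementation (residuals from marginals, Pearson-on-handmade-ranks
Spearman, normal-equation OLS, enumeration partner/co-occurrence lookups)
on 100+ random small instances at 1e-8. Null calibration uses 200
simulated null cohorts (4 types x 100 samples) for family-wise error, 200
repetitions for the randomization-test uniformity checks (399/400
iterations), and 2000 null features for the differential-test
false-positive rate. Recovery runs 25 seeds for detection sensitivity,
200 samples/type for correlation recovery, and 50 seeds for the
Kaplan-Meier ordering. These sizes keep the full suite deterministic and
fast while leaving the binomial error of each estimate well inside the
asserted bounds.

# Known limitations

* The chi-square machinery assumes adequate expected counts; cases with
  an expected cell below 1 are skipped outright rather than approximated.
* The naive survival p after cutpoint optimization is reported because it
  is the field's common convention, but only the permutation-adjusted p
  controls size.
* Pooling by maximum correlation biases pooled rho upward for pairs
  measured in several cohorts; recovery checks therefore measure each
  pair in its own cohort.
* The <250-gene fallback couples the transcript significance rule to the
  annotation's protein-coding flag; cohorts without that flag treat all
  genes as coding.
* No GO-DAG propagation: functional terms are flat labels, and term
  enrichment inherits whatever redundancy the annotation carries.
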