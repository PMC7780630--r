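---
title: "Methods and design notes for epiclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for epiclass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`epiclass` implements an integrative methylome + mutation subtyping
workflow for urothelial tumor cohorts: consensus epi-clustering of
methylation-array β values with an explicit hypermethylation signature
rule, promoter methylation gene calling, mutational load / exclusivity /
signature-exposure analysis, and survival association — together with a
synthetic cohort generator that plants ground truth for recovery testing.
This vignette records the models, the defaults, and the design decisions
taken where the methodology left room.

## The methylome model

A cohort is a probes × samples matrix of β values, β = M/(M + U) ∈ [0, 1].
Probe QC removes sex-chromosome probes, probes with any missing value and
(optionally) probes failing a detection-p matrix at 0.05, mirroring
standard array practice. Statistical testing runs on M-values,
M = log2(β/(1 − β)) with β clipped to [10⁻³, 1 − 10⁻³]: β values are
heteroskedastic near the bounds and the logit transform stabilizes the
variance; effect sizes (Δβ) are always reported on the β scale where they
are interpretable. The per-probe test is Welch's unequal-variance t; the
pipeline the signature rule descends from uses moderated statistics, but
the rule itself only consumes group means and an FDR, and Welch is the
assumption-light default (a β-space option exists for sensitivity checks).
BH adjustment is applied once across all tested probes.

**Hypermethylation signature rule.** Probe *k* is significantly
hypermethylated in cluster C1 when mean β(C1) ≥ 0.4, mean β(C2) ≤ 0.2 and
FDR < 0.05; the rule is applied symmetrically for C2. The rule is
deliberately mean-threshold-based (not Δβ-based): it selects probes that
are near-unmethylated in one subtype and clearly methylated in the other,
which is what makes the signature transferable across cohorts and
platforms.

**Consensus clustering.** `n_runs` (default 500) resampling runs each
draw 80% of samples and 80% of features without replacement, cluster the
subsample hierarchically and cut at *k*. The consensus entry for a pair is
its co-cluster count divided by its co-sample count — the standard
consensus definition; "average of connectivity matrices over all runs"
is ambiguous for pairs never drawn together, so those get consensus 0
plus a warning rather than a silent denominator of n_runs. Final labels
cut a hierarchical tree built on the consensus matrix rows (default
1 − Pearson distance, Ward.D2 linkage). Supervised transfer of a probe
signature onto an external cohort restricts to the intersected probes and
uses Manhattan/Ward.D2 base runs, the protocol named for supervised
450k clustering; unsupervised discovery of the primary cohort defaults to
Euclidean/Ward on the top-1% most variable probes. The "top 1%" metric is
not pinned down by the source methodology; variance is the default
(sd and MAD selectable), the count is floor(0.01 · n), and ties break
lexicographically by probe id so runs are platform-reproducible.

**Ward variants.** `ward_d` applies the Lance-Williams Ward update to the
dissimilarities as given; `ward_d2` squares them first and reports
square-rooted heights. Both are exposed because both appear in practice
(hclust's `ward.D` and `ward.D2`), and both are verified in the test suite
against a naive O(n³) agglomeration oracle.

**DMRs.** Kernel-smoothed DMR calling is out of scope; the package ships
a declared gap-merge caller: significant same-direction probes on one
chromosome merge while consecutive gaps are ≤ 1 kb, and regions need ≥ 2
probes. The rule is stamped into the output's `caller` attribute so its
results cannot be mistaken for smoothed-DMR output. Annotation input is
1-based (array-manifest convention); emitted region spans are BED-style
0-based half-open, converted in exactly one place.

**Promoter methylation genes.** Promoter probes are TSS1500, TSS200,
5'UTR and 1stExon; a gene's per-sample promoter methylation is the median
β over its promoter probes. Genes likely methylated in normal tissue are
excluded first (more than 50% of normals with β ≥ 0.2, or normal median
β ≥ 0.2); a tumor is called methylated at β ≥ 0.3 and a gene is reported
when its tumor frequency is strictly greater than 10%.

**MeTIL-style score.** The published lymphocyte-infiltration score's
exact formula is not restated in the methodology this package follows, so
`metil_score()` is a declared stand-in: the first principal component of
the z-scored β values of a small configurable CpG set, sign-oriented by an
explicit orientation vector. It reproduces the qualitative behavior
(group separation along a methylation axis) and is labelled as such.

## Mutations and signatures

Mutational load is total mutations / 50 Mb; the capture size is a
parameter because it is assay-specific. Mutual exclusivity and
co-occurrence use one-sided Fisher exact tests ("less" for exclusivity,
"greater" for co-occurrence) on the 2×2 of joint mutation status, BH
adjusted within each direction; the reported log2 odds ratio is the
sample OR with Haldane 0.5 correction on zero cells (keeps it finite;
the raw table is always in the output). The two-sided Fisher p is the
probability-mass definition with 1e-7 relative slack — the convention of
R's `fisher.test`, which the package calls.

Catalogs use the 96 pyrimidine-centric channels (C>A, C>G, C>T, T>A,
T>C, T>G × 16 contexts, alphabetical within substitution); purine-
reference records are reverse-complemented before binning, and only
coding single-base substitutions (missense, silent, nonsense) enter the
catalog. Exposure fitting is forward selection with non-negative least
squares refits: each step adds the signature with the largest
sum-of-squares reduction on the (optionally re-weighted, then
renormalized) channel-frequency vector and stops when the improvement
drops below 1e-4; weights under the 0.2 cutoff are zeroed and the
remainder refit once, then re-thresholded without a second refit, so
every reported weight is ≥ 0.2. The residual 1 − Σw is the "unknown"
share and is excluded from downstream clustering — the reading adopted
for discarding unknown signatures (the alternative reading,
signatures-of-unknown-etiology, is not applicable to a synthetic basis).
The exome-to-genome trinucleotide re-weighting requires genome and exome
context frequencies that are assay- and genome-build-specific, so the
normalization is an injectable 96-vector, identity by default in
synthetic mode.

NMF clustering interprets "lee" as Lee–Seung multiplicative updates under
squared Frobenius loss. The best of 30 random restarts by final loss is
kept, the loss trace is non-increasing within every run (asserted in
tests), samples are assigned to the factor with the maximal `H`
coefficient, and contributors are extracted per signature as the factor
with the maximal `W` loading, ties to the lowest index.

## Survival

Kaplan-Meier, log-rank and univariate Cox go through the survival
package (the de-facto standard, and the one the original analyses used),
with Breslow tie handling by default (Efron behind a flag) and Wald 95%
intervals exp(logHR ± 1.96·se). Monotone partial likelihood (complete
separation) is detected and flagged instead of reporting a divergent
estimate. Only univariate fits are provided: the source forest plot does
not specify which covariates entered jointly, so a multivariable model
would be guesswork.

## The synthetic cohort generator

The generator encodes the study conditions the analysis assumes, and its
defaults are fixed once:

* 60 tumors split 60/40 into two latent clusters, 8 normals, 5,000
  probes, a 200-probe planted block at mean β 0.65 in cluster 1 versus
  0.10 elsewhere. The per-cluster effect sizes are not published values;
  0.65/0.10 were chosen so a correctly recovered block satisfies the
  0.4/0.2 signature thresholds with realistic array noise.
* β noise is Beta-distributed, parameterized by mean and precision
  (shapes μφ and (1−μ)φ, φ = 15): array β values are bounded and bimodal,
  and a two-parameter bounded distribution is the simplest generator with
  the right support. Background probes get a per-probe bimodal baseline
  shared by all samples — variable across probes, non-differential across
  samples.
* `na_rate` defaults to 0: the missing-value filter is exercised by
  dedicated tests with nonzero rates, and a clean default keeps the
  planted block's recovery measurable against the full 200 probes. Sex
  probes default to 2% of the array.
* Background mutation counts are negative binomial with mean 145 and
  size 0.7 — mean 2.9 per Mb under the 50 Mb convention with the heavy
  right tail real exomes show. Trinucleotide contexts are i.i.d. draws
  from the cluster's signature mixture; genomic position carries no
  signal, which is sufficient for exposure-recovery testing but not for
  regional analyses. Driver frequencies default to the familiar UTUC
  drivers (FGFR3 enriched in the low-methylation cluster, SWI/SNF-type
  mutations in the high cluster).
* Survival times are exponential (constant hazard) with a true
  high-vs-low hazard ratio of 6.57 and baseline hazard 0.02/month;
  censoring is an independent exponential whose rate is set so the
  expected censored fraction on the baseline arm equals `censoring_rate`
  (default 0.2). `censoring_rate = 1` degenerates to administrative
  all-censoring and is flagged. PFS times are a scaled copy of OS times —
  no attempt at distinct progression biology.
* One global seed; each stage derives a substream by hashing the stage
  name, so adding a stage never perturbs another stage's draws.

What passing recovery tests on these cohorts shows: the pipeline finds
exactly the structure it is designed for, at effect sizes the thresholds
were built around. What it does not show: performance under probe-type
artefacts, batch effects, cellular contamination gradients, copy-number
driven β shifts, or positionally clustered mutational processes — none of
which the generator emulates.

## Numerical choices and degenerate inputs

* Constant probes in both groups get p = 1 by convention.
* Probes never co-sampled in a consensus run get consensus 0 + warning;
  runs drawing fewer than k samples are skipped, counted, and logged.
* Mann-Whitney uses exact enumeration (tie-aware) when both samples have
  ≤ 8 observations, otherwise the tie-corrected normal approximation.
* Zero-mutation samples are skipped by the exposure fitter with a
  warning; zero cells in odds ratios get Haldane 0.5.
* Expression preprocessing defaults to filter → log2(x+1) → median-center
  rows then columns. The order "filter → median-center → log2" appears in
  the source description but is numerically invalid (median-centering
  produces negatives a plain log cannot take); the center-first variant is
  selectable and uses a signed log so it stays defined.
* Tie-breaks everywhere (variable ranking, argmax cluster assignment,
  contributor extraction) resolve to the lexicographically or index-wise
  lowest candidate, for cross-platform reproducibility.

## Problem sizes

The default test and acceptance runs use 60-tumor / 5,000-probe cohorts,
500-run consensus, 2,000-probe permutation nulls (50–100 replicates),
5,000-mutation exposure fits and 20-replicate Cox calibrations at n = 500
— sizes chosen so the full suite completes in well under an hour on a
single core while keeping every recovery margin comfortable.

## Known limitations

* No IDAT parsing, background correction, or probe-type normalization:
  the β matrix is the entry point.
* The DMR caller is proximity-based, not kernel-smoothed.
* No de-novo signature discovery; exposures are fit against a supplied
  basis. The packaged basis generator is synthetic and labelled as such.
* Single-sample enrichment scoring is a generic scorer (mean-z or a
  rank-based running-sum), not a re-implementation of any published
  coefficient set.
* Nearest-centroid subtype calls require user-supplied centroids.
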