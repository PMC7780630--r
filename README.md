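# epiclass

Integrative methylome and mutation subtyping of urothelial tumor cohorts.

Upper-tract urothelial carcinoma (UTUC) cohorts split into two reproducible
DNA-methylation subtypes — a hypermethylated, immune-infiltrated
"EpiC-high" group and an *FGFR3*-mutation-enriched "EpiC-low" group — with
sharply different survival. `epiclass` re-implements the full analysis
behind that kind of study as a tested, reusable R toolchain, aimed at
researchers who want to run (or stress-test) the same pipeline on their own
methylation-array and whole-exome cohorts:

* **Methylome**: probe QC (sex chromosomes, missing values, detection p),
  top-variable-probe selection, hierarchical and resampled **consensus
  clustering** (n runs at 80%/80% sample/feature resampling; consensus
  `C_ij` = co-cluster count / co-sample count), per-probe Welch tests on
  M-values with BH correction, and the explicit hypermethylation signature
  rule: probe *k* is significantly hypermethylated in cluster 1 when
  mean β<sup>C1</sup><sub>k</sub> ≥ 0.4, mean β<sup>C2</sup><sub>k</sub> ≤ 0.2
  and FDR < 0.05. Plus gap-merge DMR calling, promoter-gene methylation
  calls (median promoter β, 0.3 call cutoff, >10% frequency, normal-tissue
  exclusion), signature transfer to external cohorts, genomic-context
  enrichment, and a MeTIL-style infiltration score.
* **Mutations**: MAF parsing with dialect mapping, mutational load
  (mutations / 50 Mb), gene and gene-family frequencies, one-sided Fisher
  mutual exclusivity / co-occurrence with Haldane-corrected log2 odds
  ratios, and mutation–phenotype association.
* **Signatures**: 96-channel trinucleotide catalogs (pyrimidine-strand
  convention), per-sample exposure fitting by forward selection +
  non-negative least squares with a 0.2 reporting cutoff, and Lee–Seung
  NMF clustering of exposures with "max" contributor extraction.
* **Survival**: Kaplan-Meier / log-rank and univariate Cox (Breslow ties)
  via the survival package, wrapped with separation handling.
* **Synthetic cohorts**: a first-class generator that plants ground truth
  (epi-cluster labels, a hypermethylated probe block, driver frequencies,
  signature mixtures, cluster-dependent hazards) so every stage of the
  pipeline can be tested for *recovery*, not just for running.

## Worked example

```r
library(epiclass)

cfg    <- sim_config(seed = 7)        # 60 tumors, 200-probe planted block
cohort <- simulate_beta(cfg)
tumors <- cohort$sample_info$sample_id[cohort$sample_info$type == "tumor"]

beta <- filter_probes(cohort$beta[, tumors], cohort$annotation)
top  <- select_variable_probes(beta, fraction = 0.01)
cc   <- consensus_cluster(beta[top, ],
          consensus_params(n_runs = 500, base_distance = "euclidean",
                           base_linkage = "ward_d", k = 2, seed = 11))
cc
#> Consensus clustering result
#>   samples: 60  k: 2  runs: 500 ( 0 skipped )
#>   cluster sizes: 36 / 24

dmps <- call_dmps(beta, cc$labels)
sig  <- derive_hyper_signature(dmps)    # the 0.4 / 0.2 / FDR<0.05 rule
length(sig$hyper_in_g1)                 #> 200  (the planted block, exactly)
length(sig$hyper_in_g2)                 #> 0

basis <- synthetic_signature_basis(5)
muts  <- simulate_mutations(cfg, basis, cohort$truth)
round(mutational_load(muts$records, muts$sample_universe)$summary, 2)
#>   mean     sd median    min    max
#>   2.07   2.10   1.22   0.04   8.46

clin <- simulate_clinical(cfg, cohort$truth)
grp  <- factor(cohort$truth$cluster[clin$sample_id],
               levels = c(2, 1), labels = c("low", "high"))
cox_univariate(clin, grp, "os")
#> HR = 6.68 (95% CI 3.14-14.20), p = 8e-07
```

The consensus split recovers the two planted epi-clusters (36/24, adjusted
Rand index 1), the signature rule returns exactly the planted
hypermethylated block, and the Cox fit recovers the simulated high-vs-low
hazard ratio (true value 6.57) within its confidence interval.

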