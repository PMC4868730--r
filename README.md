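# mutexpress

Somatic mutations can reshape a tumor's transcriptome, but their
expression effects are entangled with two stronger genetic determinants:
somatic copy-number alteration (SCNA) and promoter methylation.
`mutexpress` implements a complete oncogenomic analysis pipeline for
tumor cohorts — built around expression-associated single-nucleotide
variants (eSNVs) — for researchers who want to go from multi-omic
matrices to prioritized, drug-mappable mutational candidates:

1. **Two-step association scan.** Per gene *i*, relative transcript
   abundance is residualized on the genetic determinants,

   RT<sub>i</sub> = SCNA<sub>i</sub> + M<sub>i</sub> + ε<sub>i</sub>,

   with an ANOVA decomposition of each determinant's variance share; then
   every residual/SNV pair is tested with a simple regression,

   ε<sub>i</sub> = SNV<sub>j</sub> + γ<sub>j</sub>,

   with Bonferroni control over all tested pairs, a genomic-control
   inflation factor λ<sub>GC</sub> = median(χ²)/0.4549 as the calibration
   diagnostic, and cis/trans classification by whether the SNV lies
   inside the associated gene.
2. **Driver prioritization.** Per patient, mutated genes are ranked by a
   network-propagation impact score (personalized restart on the
   patient's differential expression, damping 0.85) and split into
   drivers and passengers by a maximally selected rank statistic;
   significant eSNVs are restricted to driver loci.
3. **Mutational clustering.** Spherical k-means (cosine similarity on
   L2-normalized binary profiles, best of 20 restarts) groups patients by
   their driver-eSNV profiles; cluster–clinical associations are tested
   with Fisher's exact test.
4. **Survival machinery.** Cox proportional hazards (Efron ties),
   Kaplan–Meier curves, 10-year cumulative/dynamic time-dependent ROC,
   and Uno's censoring-adjusted (IPCW) concordance.
5. **Evidence integration.** Seven boolean criteria per eSNV — missense,
   nonsense, cis-acting, prognostic (per-variant Cox p < 0.05), cluster-
   related (Fisher p < 0.05), consensus-clustered co-occurrence
   (Bonferroni p < 0.05, odds ratio > 1, ≥ 10 shared associated genes,
   same consensus cluster), and synthetic-lethality nomination (carrier
   enrichment in one mode of a bimodal gene) — are summed into a score;
   score ≥ 2 flags a biological risk eSNV.
6. **Drug repurposing.** Risk loci plus their correlated genes are tested
   for hypergeometric enrichment in solid- versus hematologic-tumor
   drug-target profiles split by indication keywords.

A first-class synthetic cohort generator (`generate_cohort()`) emits all
layers with implanted ground truth — effect pairs, cluster labels,
prognostic hazards, synthetic-lethal pairs — so the whole pipeline is
testable without any external download.

## Worked example

```r
library(mutexpress)

cfg <- pipeline_config(seed = 1)   # 200 samples, 150 genes, 100 SNVs
res <- run_pipeline(cfg)
print(res$summary)
#> eSNV association scan
#>   pairs tested:       15000
#>   significant pairs:  14 (0.093%)
#>   lambda_GC:          0.989
#>   eSNVs / genes:      14 / 14
#>   mean R2 cis/trans:  0.236 / 0.300
```

The scan tested 15,000 SNV–gene pairs and flagged 14 at the Bonferroni
level — about 0.09% of pairs, driven by the generator's 20 implanted
effects (those diluted across the grid; several have too few carriers or
too small a β to survive family-wise control). λ<sub>GC</sub> ≈ 0.99
says the remaining ~15k null tests are well calibrated. Downstream:

```r
res$prioritized$counts$n_esnvs          # 12 driver eSNVs
sum(res$evidence$risk)                  # 10 risk eSNVs with score >= 2
res$survival$uno_c                      # 0.597 cluster concordance
res$repurposing$solid$p                 # 0.0164 drug-target enrichment
```

The enrichment p-value is small because half the synthetic drug targets
are drawn from implanted effect genes. Cluster-level truth recovery is
checked on the full mutation profile (the implanted cluster markers are
passengers, so they are deliberately absent from the prioritized panel):

```r
g <- generate_cohort(simulation_config(seed = 7))
cl <- spherical_kmeans(t(g$cohort$mutation_matrix), k = 3, seed = 1)
adjusted_rand_index(cl$labels, g$truth$cluster_labels[names(cl$labels)])
#> [1] 0.985
```

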