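---
title: "Methods: mutation-expression association and driver eSNV prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation-expression association and driver eSNV prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutexpress)
```

## The model

`mutexpress` asks which somatic single-nucleotide variants leave a
detectable trace on the tumor transcriptome once the two dominant
genetic determinants of expression — somatic copy number and promoter
methylation — are accounted for. The model is deliberately a two-step
linear one:

* **Step 1 (residualization).** For every gene $i$, ordinary least
  squares of the relative transcript abundance on an intercept, the
  GISTIC copy-number score and the gene-level methylation beta value:
  $RT_i = \alpha + \beta_s\,\mathrm{SCNA}_i + \beta_m M_i +
  \varepsilon_i$. Sequential (type-I) ANOVA sums of squares, with SCNA
  entered first, give each determinant's variance fraction; F-test
  p-values are Benjamini–Hochberg adjusted *across genes* per
  determinant, so "SCNA-regulated" and "methylation-regulated" gene
  counts are FDR-controlled statements.
* **Step 2 (scan).** Each SNV $j$'s binary carrier vector is regressed
  against every gene's residual: $\varepsilon_i = \beta\,\mathrm{SNV}_j
  + \gamma_j$. The report per pair is the OLS $\hat\beta$, its Wald
  $t$-interval with residual degrees of freedom, a two-sided $t$-test
  p-value and the $R^2$ (variance explained). Family-wise control is
  Bonferroni at family size equal to the number of pairs *actually
  tested* — pairs skipped by the carrier filter produce no p-value, so
  they do not count.

Running the scan on residuals rather than jointly fitting all three
determinants is a deliberate choice, not an approximation made for
convenience alone: it keeps the pair scan a rank-one update that
vectorizes over all genes at once (tens of millions of pairs are
feasible), and it matches the interpretation of the downstream effect
sizes as *perturbations of determinant-adjusted expression*. The cost is
that an SNV correlated with a gene's copy number will have part of its
effect absorbed in step 1; the null calibration below shows this is not
a source of inflation under independence.

Calibration is monitored with the genomic-control inflation factor:
two-sided p-values are converted to 1-df $\chi^2$ quantiles and
$\lambda_{GC}$ is their median divided by $\mathrm{median}(\chi^2_1)
\approx 0.4549$. Values near 1 indicate a well-calibrated scan; values
clearly above 1 suggest relatedness or confounding.

An association is **cis-acting** when the SNV's position falls inside
the associated gene's interval (1-based, both boundaries inclusive, same
chromosome), otherwise **trans-acting**. Genes without an interval are
classified trans with a warning, keeping the partition exhaustive.

## Tunable parameters

| Parameter | Default | Units / domain | Why |
|---|---|---|---|
| scan `alpha` | 0.05 | family-wise level | conventional FWER target |
| `min_carriers` | 2 | samples | a 1-carrier regressor is a 0-df contrast; singletons are also removed upstream as "sole SNVs" |
| Bonferroni `family` | global | global / per_gene | one family over all tested pairs is the conservative reading; the per-gene alternative is exposed as a flag |
| signature `alpha` | 0.05 | per-test level | selection level of the prognostic and cluster evidence layers |
| co-occurrence `min_overlap` | 10 | shared associated genes | pairs sharing fewer associated genes are too unstable to call co-occurrent |
| `risk_cutoff` | 2 | criteria (0–7) | two independent lines of evidence define a risk eSNV |
| ROC horizon | 10 | years | progression-free survival is evaluated on a 10-year window |
| propagation `damping` | 0.85 | 0–1 | standard PageRank-family default; the ranking principle, not the constant, carries the method |
| `quantile_bound` | 0.95 | quantile | candidate maxstat cutpoints restricted to the central 90% of order statistics |
| bimodality `delta_bic` / `min_weight` / `min_separation` | 10 / 0.1 / 2 | BIC units / proportion / pooled SD | a decisive BIC margin, non-degenerate modes, and clearly separated means |

## What the synthetic cohort emulates

`generate_cohort()` is the package's study-conditions generator, not a
test fixture: every default was fixed once, before any downstream
result was inspected, and the tests and the acceptance script consume it
as-is.

* **Expression** is linear in the three determinant layers per gene —
  exactly the generative structure step 1 + step 2 assume — with
  Gaussian noise (`noise_sd`, default 1 in standardized expression
  units). Implanted SNV effects are drawn from `beta_range` (default
  0.3–2.3 per mutant allele, the magnitude range typical of prioritized
  cis-acting variants); a quarter of effect SNVs are placed inside their
  target gene (cis), the rest elsewhere.
* **Copy number** is discrete GISTIC calls $\{-2,\dots,2\}$ with
  marginal probabilities (0.05, 0.15, 0.6, 0.15, 0.05); **methylation**
  is Beta(2,2) per gene and sample.
* **Mutations** are sparse binary with background rate 0.04 per
  SNV/sample; each of the 3 clusters gets 5 marker SNVs at within-cluster
  rate 0.7, which makes the implanted partition recoverable by spherical
  k-means; effect SNVs carry at carrier rate 0.15 so the scan sees
  roughly 30 carriers at the default 200 samples.
* **Survival** is exponential with log-hazard proportional to carriage
  of the prognostic SNVs (default hazard ratio 3), administratively
  censored at 10 years plus independent exponential censoring targeting
  a 30% censored fraction. The constant baseline hazard (median 5 years)
  gives closed-form recovery checks; a Weibull baseline was considered
  and rejected for the default because it buys realism the tests do not
  need.
* **Bimodal genes** are two-component log2-normal mixtures whose high
  mode excludes carriers of a paired SNV — the synthetic-lethality
  signal the BEEM test is designed to find.

What it does **not** emulate: linkage between nearby SNVs, mutational
signatures and trinucleotide context, copy-number segments (calls are
i.i.d. across genes), methylation–expression confounding structure,
subclonality, or realistic TCGA barcode grammar. Passing the recovery
tests therefore demonstrates the estimators work when their model holds
and stays calibrated under independence — not that real-cohort effect
estimates are unbiased under every violation.

One consequence worth stating: the cluster-marker SNVs are deliberately
*passengers* (no expression effect), so they are absent from the
pipeline's prioritized eSNV panel, and the end-to-end pipeline run does
not recover the implanted clusters from that panel. Cluster-structure
recovery is a property of `spherical_kmeans()` on the full mutation
profile and is tested there.

## Numerical choices

* **Propagation** iterates $r \leftarrow (1-d)f + dTr$ to an
  $L_\infty$ change below $10^{-9}$ (cap 1,000 iterations, error on
  non-convergence). $T$ splits each target gene's mass equally among its
  regulators, so impact flows *upstream*: a mutated gene collects score
  from the differentially expressed genes it can reach.
* **Maxstat** evaluates the standardized Wilcoxon-type statistic (with
  tie correction) at every admissible cutpoint and takes the maximum;
  cutpoints between tied scores are inadmissible. All-equal scores yield
  a zero-driver split with a warning rather than an arbitrary cut.
* **Spherical k-means** breaks assignment ties by lowest cluster index
  and holds out all-zero rows (a zero vector has no direction); the
  returned solution is the best cosine objective over 20 seeded
  restarts.
* **Cox fits** use the Efron tie approximation throughout. A covariate
  with no variation is reported with coefficient 0 (HR 1) rather than
  an error; suspected monotone likelihood (explosive standard errors)
  is an error suggesting penalization.
* **Time-dependent ROC** uses the Kaplan–Meier redistribution method:
  within-cutoff-group KM curves estimate sensitivity/specificity at each
  horizon, and the ROC is traversed in threshold order (highest cutoff
  at (0,0) to lowest at (1,1)) before trapezoid integration — coordinate
  sorting is numerically unsafe when distinct cutoffs give equal rates.
* **Uno's concordance** weights usable pairs by $1/G(t_i^-)^2$ with $G$
  the KM estimate of the censoring distribution, truncated at the
  horizon; without censoring all weights are 1 and the statistic equals
  Harrell's C exactly (asserted in tests, alongside a cross-check
  against `survival::concordance(timewt = "n/G2")`).
* **Fisher tests** on large cluster-by-category tables fall back to a
  seeded Monte-Carlo p-value ($10^5$ draws) with the method recorded in
  the output.
* **Bimodality** floors expression at 0.1 before log2 — the reading of
  "values below 0.1 are rounded up" that avoids $-\infty$ — and fits
  1- versus 2-component Gaussian mixtures by EM (`mclust`).

## Open design decisions

Where the analysis design was genuinely open, the package commits to one
reading and exposes the alternative:

* **Bonferroni family**: one global family over all tested pairs;
  `family = "per_gene"` available.
* **Maxstat "cutoff of 0.95"**: read as the quantile window bounding
  candidate cutpoints — the standard maximally-selected-statistics usage
  — not as a score threshold.
* **Adjusted time-dependent analyses**: a nominal 3-level cluster label
  has no intrinsic order, so clusters enter ROC/concordance through the
  Cox linear predictor fitted on cluster indicators; the adjusted
  variant uses the joint linear predictor including clinical covariates.
* **Co-occurrence universe**: the genes entering the step-2 scan, since
  the associated-gene sets are defined over exactly that space;
  criterion 6 requires membership in at least one retained pair.
* **Co-occurrence direction**: "co-occurred" is read as positive
  association, so retained pairs need odds ratio > 1 on top of adjusted
  significance.
* **"Sole SNVs"**: variants carried by exactly one sample; the carrier
  threshold is configurable (default 2).
* **MHC exclusion**: defaults to chr6:28,477,797–33,448,354 (hg19
  convention) and is configurable, since only the region, not its
  coordinates, is conventionally fixed.

## Problem sizes

The shipped tests and the acceptance script run at sizes chosen so the
whole suite completes in well under a minute on one core while keeping
every statistical check meaningful: the standard cohort is 200 samples,
150 genes, 100 SNVs and 20 implanted effects (15,000 scan pairs); the
null-calibration cohort is 128 samples with 14,000+ tested pairs; Cox
recovery uses 2,000 uncensored subjects; oracle comparisons use 20–50
random instances each. These are the package's own verification sizes —
the estimators themselves are vectorized and scale to cohort-scale
grids (tens of millions of pairs) without structural change.

## Known limitations

* The two-step scan does not model linkage between SNVs, covariates
  beyond SCNA and methylation, or permutation-based significance.
* The driver ranking is a transparent propagation ranking in the spirit
  of network-impact methods, with a fixed damping factor and a
  plain edge-list network; it is not a bit-exact reimplementation of any
  published package, and its output should be read as a pluggable
  prioritizer.
* Synthetic-lethality nomination is statistical (mutation exclusivity
  with an expression mode); it carries no essentiality or perturbation
  evidence.
* Drug-target enrichment depends on the declared gene universe, which is
  a required, logged parameter (default: genes in the analyzed
  expression profile); enrichment p-values move with that choice and
  should be compared only within a fixed universe.
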