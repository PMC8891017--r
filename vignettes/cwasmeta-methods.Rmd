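---
title: "Methods: cross-biobank coding-variant meta-analysis at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-biobank coding-variant meta-analysis at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwasmeta)
```

## The study design this package emulates

`cwasmeta` implements, end to end and at desk scale, the statistical machinery
of a coding-wide association study (CWAS) run across two population biobanks
of unequal size: a large reference cohort genotyped by exome sequencing and a
smaller founder-population cohort in which many rare alleles are enriched by
one to two orders of magnitude. The scientific payoff of that design is power:
an allele rare in the reference population but enriched in the founder
population contributes far more association information than its reference
frequency suggests, and a fixed-effect meta-analysis inherits that gain.

Everything runs on synthetic data generated inside the package; no biobank
download is required. The synthetic generators are first-class, tested code:
the point is that every downstream module can be exercised under a data
distribution whose truth is known.

## Synthetic cohorts

`generate_variant_panel()` lays out biallelic variants on one chromosome with
strictly increasing positions, partitioned into consecutive LD blocks. Each
variant gets a reference-cohort MAF (log-uniform over the configured range,
default 0.01%-1%, extensible to 50%) and an enrichment factor drawn from a
configurable set (default 1-50x), defining the second cohort's frequency as
`enrichment * maf`. A `causal_fraction` of variants receives a positive
log-odds effect drawn from an effect pool; the default pool
(`cwas_effect_pool`: 0.14-2.09) spans the range of per-allele log odds ratios
reported for coding disease associations, from modest common-variant effects
to large rare-variant effects. Effect sizes are sampled independently of MAF;
how real studies pair them is not identifiable from published summary tables,
and independence is the neutral choice.

`generate_cohort()` draws genotypes per LD block through a latent Gaussian
copula with equicorrelation `ld_rho`, thresholded at the allele frequency,
two haplotypes per individual — Hardy-Weinberg marginally, block-structured
LD jointly. Block-constant latent correlation is deliberately the simplest
LD structure that makes clumping testable; it does not reproduce real
haplotype mosaics, decaying LD with distance, or cross-block LD, so passing
clumping tests here says nothing about recombination-realistic data. Disease
status is Bernoulli from a logistic liability `alpha + sum(beta * dosage)`;
`alpha` is solved by root-finding so the expected prevalence over the realized
genotype distribution equals the target to 1e-6. Covariates (age terms, sex,
interactions, ten simulated PCs) mimic the standard association covariate
recipe; there is no relatedness or population structure beyond those simulated
covariates, which is exactly why plain covariate-adjusted regression (below)
stands in for whole-genome mixed-model machinery.

`simulate_summary_stats()` is the fast path: it draws effect estimates
directly from the asymptotic sampling law of the score estimator,
`beta_hat ~ N(beta, 1/v)` with `v = 2 n p (1-p) phi (1-phi)`. A
Kolmogorov-Smirnov test in the suite checks that the fast path and the
individual-level path produce indistinguishable Z-score distributions at
matched parameters; the fast path is what makes thousand-replicate power
grids affordable.

## Association testing

Per-cohort testing mirrors biobank practice: a logistic **score test** for
each variant against a null model with covariates, switching to **Firth
penalized regression** whenever the score p falls below 0.01. Inclusion
filters are strict-greater-than 100 cases, minor allele count at least 5
overall and at least 3 in both cases and controls, and INFO > 0.6; the filter
log names the first failing rule for every excluded variant, and nothing is
dropped silently.

Two numerical conventions matter:

* The reported effect is the one-step estimate `beta = U/V`, `se = 1/sqrt(V)`
  from the null-model score components, so `beta/se` reproduces the score Z
  exactly and the p-value is consistent with the reported effect by
  construction. The one-step estimate is mildly biased toward zero for large
  effects; the suite's recovery test (true beta 0.3, MAF 0.2, n = 20,000)
  bounds that bias within the +-10% band.
* The Firth likelihood-ratio test is a profile test: the constrained fit
  fixes the dosage coefficient at zero **under the full design's Jeffreys
  penalty**. Penalizing each model with its own information determinant would
  add an O(log n) artifact to the LRT statistic. The Firth standard error is
  recomputed from the effect size and the LRT p (`se = |beta|/z(p)`), the
  convention required for downstream inverse-variance weighting of Firth
  results. Newton iterations cap at 50 with tolerance 1e-8 on the score norm;
  non-convergent fits are flagged and excluded downstream.

## Meta-analysis and the enrichment power model

`harmonize_alleles()` aligns the two cohorts' records per variant: identical
alleles pass, swapped alleles flip the sign and frequency, unambiguous strand
complements are relabelled, and A/T / G/C pairs are dropped — frequency-based
rescue of ambiguous pairs is untestable against synthetic truth, and dropping
is the conservative choice. `ivw_meta()` is the fixed-effect inverse-variance
combination; Cochran's Q is reported as a diagnostic and never used to filter.
`genomic_inflation()` gives the usual median-chi-square lambda.

The **uplift** module carries the power model. With score information
`v_i = 2 N_i p_i (1-p_i) phi_i (1-phi_i)` and `p2 = e * p1`, the theoretical
ratio of the meta-analysed Z to the reference study's Z is

    U = sqrt(1 + v2/v1),

independent of the effect size to first order. `simulate_uplift_cell()`
validates it per MAF-by-enrichment cell: draw an effect from the pool,
simulate both cohorts, combine, record `Z_meta/Z_ref`, aggregate by the
median over replicates. The median (not the mean) is the default aggregate
because the ratio estimator is heavy-tailed at rare MAF; replicates with
|Z_ref| < 0.1 are resampled (capped at ten times the requested count) for the
same reason. The default cohort configuration is the two biobanks' scales —
392,814 and 260,405 individuals, prevalence 0.05 in both (the prevalence is a
package default; real analyses fixed cohort-specific estimates that are not
printed) — with a `scale` factor for desk runs. Grid agreement is summarized
by the median absolute relative error (MARE, %) over cells; at 200 replicates
per cell the default grid sits around 1-3%. The known residual structure:
at the rarest MAF (0.01%) combined with the largest enrichments the simulated
uplift falls below theory by 10-30%, because the reference Z is then so small
that the ratio's median shrinks toward zero. That bias is a property of the
ratio statistic in the ultra-rare corner, not an error in either surface, and
the MARE over the grid absorbs it; per-cell agreement claims in the tests are
restricted to the 0.1%-1% regime.

## Regions and significance tiers

Significance is tiered: genome-wide at 5e-8, and a conservative tier at 2e-9
(0.05 over ~26.8 million effective tests, reported at one significant figure)
that additionally demands concordant effect directions and p < 0.05 in each
cohort. Clumping is greedy: lowest meta-p lead first (ties broken
lexicographically by variant id — the tie-break makes reruns deterministic),
members within +-500 kb and r² > 0.1; the MHC (chr6:25.5-34.0 Mb, taken as
printed, build GRCh38 by config) is a single pseudo-clump regardless of LD.
Overlapping padded clumps merge into distinct regions, one sentinel per
annotated gene, regions shared across disease clusters merged once. Fold
enrichment between cohorts is `log2(af_enr/af_ref)` with a two-sided Fisher
test on allele counts reconstructed as `round(2 n af)` (exact counts accepted
when available), flagged at p < 5e-5.

## Phenotype harmonization and clustering

Phenotypes harmonize across cohorts by the Jaccard index of their ICD-10 code
sets, retained strictly above 0.7, with name-based exclusions (spontaneous
deliveries, abortions). Disease clusters come from cosine similarity on
binary ICD-10 indicator vectors over the union code universe, Ward
agglomeration (`ward.D2`) on `1 - similarity`, tree cut at 0.8. The
featurization is a package choice — case-overlap profiles are a plausible
alternative and available via the feature-matrix builder; neither is asserted
as what any particular study used. Identical feature rows are deduplicated
before agglomeration and share a cluster: Ward merge heights scale with
cluster mass, so feeding duplicates through the linkage would let redundant
phenotype definitions shift everyone else's clusters, which is the wrong
behaviour for a harmonization pipeline.

## Clustered Mendelian randomization

`ratio_estimate()` is the two-sample ratio `beta_y/beta_x` with leading-order
standard error `se(beta_y)/|beta_x|`. `mr_clust_em()` fits a mixture over the
per-variant ratios with three kinds of components:

* substantive clusters `N(mu_k, ratio_se_i^2)` — a cluster is a set of
  variants sharing **one** causal ratio, so clusters carry no free variance
  parameter; the only dispersion is the known per-variant sampling variance.
  Giving clusters a free variance lets a diffuse pseudo-cluster absorb
  scattered null ratios and destroys null calibration;
* a null component fixed at mean zero with the same known variances;
* a flat junk component spanning the observed ratio range (+-3 max se).

The number of substantive clusters is chosen by BIC over `0..max_k`; zero is
a first-class outcome, and is what permuted or signal-free data should —
and in the test suite does — select. Variants are assigned where the maximum
responsibility exceeds 0.7. Singleton clusters are allowed by default (no
minimum-size penalty in the likelihood), accommodating rare variants whose
large ratios are genuine; the ablation switch refits without components that
cannot hold two assigned variants. Initialization is k-means on the ratios
with ten restarts under a derived seed.

Counting *discovered mechanisms* is a separate, stricter act from assigning
variants: `n_substantive_clusters()` requires at least four assigned variants
and a cluster mean more than three inverse-variance standard errors from
zero, mirroring the reporting convention of published clustered-MR analyses.
Chance coincidences of two precise ratio estimates are common under any
permutation scheme; they are real likelihood structure but not reportable
mechanisms. The permutation null (`permute_outcome_null()`) permutes the
outcome (beta, se) pairs across variants and refits. One subtlety the test
suite respects: permuting outcomes only destroys cluster structure when the
panel contains variants with genuinely null outcome effects (as disease-locus
panels do); in a panel where every outcome beta is exactly proportional to
its exposure beta, the permuted ratios remain bimodal and no method should
be expected to report a clean null there.

## Enrichment statistics

`fisher_enrichment()` builds the 2x2 table in two modes. Background-inclusive
uses the margins as given — `(a, set-a, hits_bg, bg-hits_bg)` — and is the
default because it reproduces the worked drug-target example exactly
(26/482 vs 569/19,955 gives conditional-MLE OR 1.9, p 0.0024);
background-exclusive subtracts the set first and gives OR ~2.0 on the same
counts. Both are exposed. The two-sided p sums all tables with probability
at most the observed one, and the suite checks it against brute-force
hypergeometric tail summation.

## Orchestration, determinism, problem sizes

`run_pipeline()` chains simulate, per-cohort association, meta-analysis,
tiering, clumping and merging, writing each stage as TSV plus a JSON manifest
of seeds, thresholds, row counts and per-reason filter counters; reruns with
one configuration are byte-identical. All generators are pure functions of
their arguments and a seed, via a helper that derives per-stage child seeds
and restores the caller's RNG state. Coordinates are 1-based inclusive
everywhere except the BED export, which is 0-based half-open and says so in
its header.

The test suite's problem sizes are chosen to keep the default run fast while
leaving the Monte Carlo error well inside each asserted band: cohorts of
2,500-20,000 individuals, panels of 150-20,000 variants, 200-1,000 power
replicates per cell, 100-run permutation nulls. The acceptance script runs
the uplift grid at the full biobank sample sizes through the summary-level
engine, where cost is independent of n.

## Known limitations

* LD is block-constant; no decay with distance, no cross-block correlation.
* The one-step score effect estimate undershoots large effects; Firth
  results do not, and carry the se-from-LRT convention instead.
* The uplift simulation understates theory in the ultra-rare,
  high-enrichment corner (ratio-median shrinkage), documented above.
* The clustered-MR reading here — known-variance clusters, BIC with k = 0,
  size-4 reporting — is one consistent interpretation of "adjusted to
  accommodate rare variants"; the original algorithm's exact modifications
  are not published in reproducible detail.
* Phenotype featurization for clustering is a stated package choice, not a
  reconstruction.
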