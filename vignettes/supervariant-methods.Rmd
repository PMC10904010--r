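---
title: "Supervariant discovery and validation: model, design choices, and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervariant discovery and validation: model, design choices, and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supervariant)
```

## The method

A *supervariant* is an additive burden score over an adaptively selected
subset of SNPs within a predefined SNP set. For a continuous phenotype
$y$ and a set of $M$ minor-allele dosage vectors $g_1, \dots, g_M$, the
construction proceeds in four steps:

1. **Sets.** The genome is partitioned into non-overlapping 1-Mbp windows,
   indexed `Chr{c}_{k}` with $k = \lfloor \mathrm{pos} / 10^6 \rfloor + 1$
   (window 1 spans positions 1–999,999, window 2 spans
   1,000,000–1,999,999, and so on). Named sets — e.g. SNPs in a
   gene-ontology gene list — are supported and may span chromosomes.
2. **Ranking.** Each SNP's marginal effect is estimated by OLS of $y$ on
   its dosage plus covariates; the $t$ statistic of the dosage coefficient
   orders the set descendingly (direction "+") and ascendingly ("−"), so
   positive- and negative-effect variants are each given a ranking.
3. **Cutoff selection.** For every cutoff $k = 1, \dots, M$ the top-$k$
   dosages are summed into a burden score
   $s_i = \sum_{j \le k} g_{ij}$ and the score is regressed on the
   phenotype with covariate adjustment; the $k$ minimizing the two-sided
   association p-value is selected (ties go to the smaller $k$).
4. **Testing.** The selected score is the supervariant, named
   `{pheno}_{set}{+|-}`; its construction statistics are those of the
   minimizing regression.

Because step 3 minimizes over cutoffs of a data-driven ranking, the
construction p-value is an *optimized* statistic and is deliberately not
multiplicity-corrected. Reproducibility is instead enforced by a repeated
split-sample design: the cohort is randomly halved (sizes
$\lfloor fn \rfloor$ and $n - \lfloor fn \rfloor$, $f = 0.5$ by default);
supervariants are constructed on the first half and declared *discovered*
at the Bonferroni level $\alpha_d = 0.05/(n_\text{sets} \times 2 \times
n_\text{phenotypes})$; their SNP membership is then frozen, re-aggregated
on the second half, and *validated* at $\alpha_v = 0.05 /
n_\text{phenotypes}$ against a freshly fitted covariate design. The
procedure is repeated 10 times with independent splits; a supervariant
(identified by phenotype, set and direction — its $k$ and membership may
vary across replications) is *retained* when validated in at least 6 of
10 replications, and a SNP contributes to the frozen external-validation
list when selected in at least 3 of the replications in which the
supervariant was validated. Under a uniform null for the validation
p-value, the chance of retention is
`binomial_validation_probability(0.05/22, 10, 6)` $= 2.87 \times
10^{-14}$ for a 22-phenotype family.

External validation aggregates the frozen SNP list on independent
cohorts after *allele harmonization* — any SNP whose counted allele
differs from the discovery minor allele is complemented ($g \to 2 - g$);
SNPs absent from a cohort, or with irreconcilable allele labels, are
dropped and counted. Per-cohort association results are combined by
sample-size-weighted meta-analysis:
$Z_i = \mathrm{sign}(\hat\beta_i)\,\Phi^{-1}(1 - p_i/2)$ and
$Z = \sum_i \sqrt{n_i} Z_i \big/ \sqrt{\sum_i n_i}$, with two-sided
$p = 2\Phi(-|Z|)$. Equal-weight averaging of Z-scores is *not* an
acceptable substitute; the test suite asserts the $\sqrt{n}$ weighting
explicitly.

## Quality control

Variant and sample filters follow fixed boundary semantics:

| filter | rule | default |
|---|---|---|
| sample missingness | removed when **>** threshold | 0.10 |
| variant missingness | removed when **≥** threshold | 0.10 |
| minor allele frequency | removed when **≤** threshold | 0.01 |
| Hardy–Weinberg exact p | removed when **<** threshold | 1e-7 |

The Hardy–Weinberg test is the two-sided exact test conditioning on
allele counts: heterozygote counts sharing the parity of the minor-allele
count are enumerated and those no more probable than the observed
configuration are summed (computed in log space with max-subtraction; a
relative slack of 1e-10 treats analytically tied configurations as
equal). The three variant filters are evaluated on the input matrix, so
the retained set is order-independent by construction.

At a counted-allele frequency of exactly 0.5 the lexicographically
smaller allele label is declared minor, making orientation deterministic
and reproducible across cohorts.

## Covariate design

The design matrix contains an intercept, `age`, `age²`, `sex`,
`age×sex`, `age²×sex`, site indicator columns (first level dropped;
omitted entirely for single-site or site-free cohorts), and any `PC`
columns present — mirroring a typical imaging-genetics adjustment. The
derived columns are always formed from the raw `age`/`sex` columns at
design-build time and are never stored. Rank deficiency (e.g. constant
age making `age²` collinear) is an error naming the offending terms, not
a silent drop. Samples with missing covariates are dropped and counted.

Marginal scans residualize the phenotype and every dosage column against
the design once (Frisch–Waugh), which reproduces the joint fit
`y ~ covariates + g` exactly — the suite asserts agreement with per-SNP
`lm()` fits to 1e-8 — while using residual degrees of freedom
$n - p - 1$ of the joint fit. Two-sided p-values come from the $t$
distribution (not a normal approximation), which matters at the small
$n$ used in simulation studies. Missing dosages are mean-imputed per SNP
at regression/aggregation time only and never written back. Monomorphic
SNPs receive $t = 0$, $p = 1$ and a flag, keeping rankings total while
guaranteeing they never head one.

## The synthetic multi-cohort generator

No individual-level data ships with the package; every downstream stage
is exercised on synthetic cohorts whose defaults mirror the motivating
study design: a large discovery cohort of 30,842 samples and three
external cohorts of 1927, 4399 and 319; 22 continuous phenotypes; age,
sex, site (absent in the fourth, smallest cohort) and 10 principal
components as covariates with cohort-specific age ranges.

* **Genotypes.** Within each LD block, two independent latent AR(1)
  Gaussian haplotype processes with parameter $\rho \in [0, 1)$ are
  thresholded at each SNP's target MAF and summed. Marginally every SNP
  is in exact Hardy–Weinberg proportions; within-block genotype $r^2$
  increases monotonically in $\rho$, and blocks are independent. Target
  MAFs are drawn once per configuration and shared across cohorts, so
  cohorts differ only in their samples.
* **Phenotypes.** $y = \sum_j \beta_j g_j + 0.01\,\mathrm{age} +
  0.1\,\mathrm{sex} + \varepsilon$, $\varepsilon \sim N(0, 1)$ by
  default. The age and sex loadings are deliberately nonzero so that
  covariate adjustment is consequential in every test. The default
  genetic architecture is sparse: the first four phenotypes each carry a
  5-SNP additive block (β = 0.05 per minor allele), the rest are null.
* **Allele-swap fixture.** The second cohort stores a configurable SNP
  subset (the first five by default) under the complementary allele
  coding — the same haplotypes, relabelled — so that cross-cohort
  harmonization is permanently exercised; the suite asserts that
  harmonized scores and association statistics are *identical* to an
  unswapped twin cohort.

Everything is deterministic given the configuration seed; per-cohort and
per-phenotype streams are derived from it, and all draws restore the
caller's RNG state.

What the generator does **not** emulate: imputation dosages and INFO
scores, population structure beyond synthetic PC columns, relatedness,
realistic recombination maps, and non-Gaussian phenotypes. Passing tests
therefore demonstrate correctness of the pipeline's logic and its
statistical calibration under the stated generative model, not
robustness to the full messiness of real cohort data.

## Calibration of the split-replication design

A point worth stating precisely: because the construction p-value is a
minimum over cutoffs of a data-driven ranking, its null exceedance rate
at $\alpha_d$ is *higher* than $\alpha_d$ — a naive
expected-discoveries calculation of $\alpha_d \times
n_\text{candidates}$ understates discoveries under the global null. This
is intrinsic to adaptive SNP-set methods, and it is exactly why the
design validates frozen candidates on held-out data: for a frozen
membership the validation p-value is an ordinary regression p-value and
is uniform under the null. The null-calibration suite (50 sets × 2000
samples × 20 replications, no genetic effects) asserts all three layers:
discoveries are rare, validations among discoveries are binomially
consistent with $\alpha_v$ and uniform by a Kolmogorov–Smirnov check,
and nothing survives the ≥ 6-validation retention rule.

## Numerical and design choices

* **Cutoff sweep.** Exhaustive over every $k$ (no early stopping); the
  residualized score is maintained as a prefix sum, so a sweep costs one
  design projection of the dosage block plus $O(n)$ per cutoff. The
  suite checks exact equality (including tie handling) against a
  brute-force sweep that re-aggregates from scratch and fits `lm()` at
  every $k$.
* **Ties.** p-value ties at cutoff selection go to the smaller $k$
  (parsimony, determinism); ranking ties go to the earlier genomic
  position, then SNP id.
* **Internal validation** requires significance only; effect-sign
  concordance between halves is recorded and an optional
  `strict_sign` flag makes it a requirement. Direction candidates are
  always constructed for both signs, even when every marginal $t$ shares
  one sign — validation discards what construction should not.
* **Part-2 refitting.** The validation half refits its own covariate
  design and minor-allele orientation is fixed on part 1 and propagated,
  so both halves count the same allele.
* **Replication seeds** are `master_seed + replication`, keeping splits
  independent but the whole study reproducible from one integer.
* **SNP contribution counting** runs over the replications in which the
  supervariant was validated (retention's own evidence base), with the
  ≥ 3-selection rule configurable.
* **Meta-analysis with missing cohorts.** A supervariant whose frozen
  SNPs are all absent from one cohort is combined over the remaining
  cohorts; per-cohort dropped-SNP counts are carried into the report so
  attrition is visible. Underflowing per-cohort p-values are clamped at
  the smallest positive double and flagged.
* **Conditional analysis.** `conditional_test()` augments the design
  with previously reported GWAS dosages; a score collinear with the
  extension (e.g. conditioning on the supervariant's own SNPs) is
  flagged and reported with $p = 1$ rather than a spurious statistic.

## Problem sizes in the test suite

The simulation suites run at desk scale, chosen as the smallest sizes at
which the asserted behaviours are stable rather than borderline: null
calibration at 50 windows × 10 SNPs × 2000 samples × 20 replications;
signal recovery at 5 causal SNPs with aggregate $R^2 \approx 5\%$, 4000
discovery and 1500 external samples over 20 study seeds; cutoff-recovery
at 50 seeds × 4000 samples; oracle equivalences on 200-sample fixtures.
The full-scale arithmetic of the motivating design (thresholds
$0.05/(2723 \times 2 \times 22)$, $0.05/314$, split sizes
$15{,}421 + 15{,}421$, pooled external $n = 6645$) is checked exactly,
and a 30,842-sample cohort is split once to verify the even-split sizes.

## Known limitations

* Hard calls only; the TSV dosage dialect accepts 0/1/2/NA, not
  fractional imputed dosages, and an INFO-score filter is accepted in
  configuration but inert on hard calls.
* No relatedness handling (synthetic cohorts are unrelated by
  construction) and no mixed models or genomic-control adjustment.
* Phenotypes are analysed untransformed; an inverse-normal transform can
  be applied by the caller before fitting if desired.
* Only the additive (minor-allele count) coding is implemented;
  indicator codings and tree-based importance rankings are out of scope.
* Window sets never cross chromosomes; named sets may.
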