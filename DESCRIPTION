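Package: supervariant
Title: Supervariant Discovery, Validation and Meta-Analysis for SNP Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Adaptive ranking-and-aggregation of single-nucleotide
    polymorphisms (SNPs) into supervariants: within predefined SNP sets
    (1-Mbp genomic windows or user-named gene sets), SNPs are ranked by
    covariate-adjusted marginal t-statistics, an additive minor-allele
    burden score is formed at every possible cutoff, and the cutoff
    minimising the association p-value is selected. Reproducibility is
    assessed by repeated split-sample discovery/internal-validation with
    Bonferroni thresholds and retention rules, followed by allele-harmonised
    external validation on independent cohorts combined by sample-size
    weighted Z-score meta-analysis. Includes quality-control filters (call
    rate, minor allele frequency, Hardy-Weinberg exact test), PLINK
    bed/bim/fam and TSV-dosage input/output, and a multi-cohort synthetic
    genotype/phenotype generator with block-wise linkage disequilibrium for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
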