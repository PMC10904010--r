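#' Genotype matrix container
#'
#' Holds a samples x SNPs matrix of hard-call dosages in \{0, 1, 2\} (or `NA`
#' for missing calls) together with per-SNP metadata. The dosage of a SNP
#' counts copies of its `a1` allele; after [orient_to_minor()] the counted
#' allele is the minor allele, the coding assumed by all aggregation and
#' scanning functions.
#'
#' @param dosages integer/numeric matrix, samples in rows, SNPs in columns;
#'   values in \{0, 1, 2\} or `NA`.
#' @param snps `data.frame` with columns `id`, `chrom`, `pos`, `a1`, `a2`
#'   (one row per column of `dosages`). `a1` is the counted allele.
#' @param samples character vector of unique sample identifiers, one per row.
#' @return An object of class `sv_genotypes`: a list with elements `dosages`
#'   (matrix with dimnames), `snps` (metadata `data.frame` including a `maf`
#'   column recomputed from the non-missing calls), and `samples`.
#' @export
sv_genotypes <- function(dosages, snps, samples) {
  dosages <- as.matrix(dosages)
  if (nrow(snps) != ncol(dosages))
    stopf("snps has %d rows but dosages has %d columns", nrow(snps), ncol(dosages))
  if (length(samples) != nrow(dosages))
    stopf("%d sample ids for %d dosage rows", length(samples), nrow(dosages))
  if (anyDuplicated(samples))
    stopf("duplicate sample ids: %s",
          paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (anyDuplicated(snps$id))
    stopf("duplicate SNP ids: %s",
          paste(unique(snps$id[duplicated(snps$id)]), collapse = ", "))
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad))
    stopf("dosages must be 0/1/2/NA; found %s", paste(unique(dosages[bad]), collapse = ", "))
  same <- snps$a1 == snps$a2
  if (any(same))
    stopf("SNP(s) with identical allele labels: %s", paste(snps$id[same], collapse = ", "))
  if (any(snps$pos < 1)) stopf("SNP positions must be >= 1")
  rownames(dosages) <- samples
  colnames(dosages) <- snps$id
  snps <- snps[, c("id", "chrom", "pos", "a1", "a2")]
  rownames(snps) <- NULL
  gm <- structure(list(dosages = dosages, snps = snps, samples = samples),
                  class = "sv_genotypes")
  gm$snps$maf <- snp_maf(gm)
  gm
}

#' @export
print.sv_genotypes <- function(x, ...) {
  cat(sprintf("<sv_genotypes> %d samples x %d SNPs on chromosome(s) %s\n",
              length(x$samples), nrow(x$snps),
              paste(unique(x$snps$chrom), collapse = ", ")))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing calls: %.2f%%; MAF range [%.3f, %.3f]\n",
              100 * miss, min(x$snps$maf), max(x$snps$maf)))
  invisible(x)
}

# Frequency of the counted (a1) allele from non-missing calls.
allele1_freq <- function(gm) colMeans(gm$dosages, na.rm = TRUE) / 2

# Minor allele frequency (folded to [0, 0.5]).
snp_maf <- function(gm) {
  f <- allele1_freq(gm)
  f[is.nan(f)] <- 0  # all calls missing
  pmin(f, 1 - f)
}

# Per-SNP missing-call fraction.
snp_missing_rate <- function(gm) colMeans(is.na(gm$dosages))

# Per-sample missing-call fraction.
sample_missing_rate <- function(gm) rowMeans(is.na(gm$dosages))

# Subset helper keeping metadata consistent.
subset_genotypes <- function(gm, samples = NULL, snps = NULL) {
  d <- gm$dosages
  sm <- gm$samples
  info <- gm$snps
  if (!is.null(samples)) {
    idx <- if (is.character(samples)) match(samples, sm) else samples
    d <- d[idx, , drop = FALSE]
    sm <- sm[idx]
  }
  if (!is.null(snps)) {
    jdx <- if (is.character(snps)) match(snps, info$id) else snps
    d <- d[, jdx, drop = FALSE]
    info <- info[jdx, , drop = FALSE]
  }
  sv_genotypes(d, info, sm)
}

# Dosage matrix with per-SNP mean imputation of missing calls (never persisted
# back into the container; used only at aggregation/regression time).
impute_dosages <- function(gm, snp_ids = NULL) {
  d <- gm$dosages
  if (!is.null(snp_ids)) {
    jdx <- match(snp_ids, gm$snps$id)
    if (anyNA(jdx))
      stopf("SNP(s) absent from genotype matrix: %s",
            paste(snp_ids[is.na(jdx)], collapse = ", "))
    d <- d[, jdx, drop = FALSE]
  }
  d <- matrix(as.numeric(d), nrow = nrow(d), dimnames = dimnames(d))
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    na_idx <- which(is.na(d), arr.ind = TRUE)
    d[na_idx] <- mu[na_idx[, 2]]
  }
  d
}

#' Cohort container
#'
#' Bundles genotypes with covariate and phenotype tables that share the same
#' samples in the same order.
#'
#' @param label cohort name.
#' @param genotypes an [sv_genotypes] object.
#' @param covariates `data.frame` with a `IID` column plus covariate columns.
#' @param phenotypes `data.frame` with a `IID` column plus phenotype columns.
#' @return An object of class `sv_cohort`.
#' @export
sv_cohort <- function(label, genotypes, covariates, phenotypes) {
  stopifnot(inherits(genotypes, "sv_genotypes"))
  for (tab in list(covariates, phenotypes)) {
    if (!"IID" %in% names(tab)) stopf("covariate/phenotype tables need an IID column")
    if (!identical(as.character(tab$IID), as.character(genotypes$samples)))
      stopf("cohort '%s': table sample ids do not match genotype samples", label)
  }
  structure(list(label = label, genotypes = genotypes,
                 covariates = covariates, phenotypes = phenotypes),
            class = "sv_cohort")
}

#' @export
print.sv_cohort <- function(x, ...) {
  cat(sprintf("<sv_cohort> '%s': %d samples, %d SNPs, %d covariates, %d phenotypes\n",
              x$label, length(x$genotypes$samples), nrow(x$genotypes$snps),
              ncol(x$covariates) - 1L, ncol(x$phenotypes) - 1L))
  invisible(x)
}

# Subset a cohort's samples, keeping the three tables aligned.
subset_cohort <- function(cohort, samples) {
  idx <- if (is.character(samples)) match(samples, cohort$genotypes$samples) else samples
  sv_cohort(cohort$label,
            subset_genotypes(cohort$genotypes, samples = idx),
            cohort$covariates[idx, , drop = FALSE],
            cohort$phenotypes[idx, , drop = FALSE])
}
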