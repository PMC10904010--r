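# Quality control: sample/variant filters, Hardy-Weinberg exact test,
# minor-allele orientation and cross-cohort allele harmonization.

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditioning on the observed allele counts: the
#' p-value sums the conditional probabilities of all heterozygote counts
#' (which share the parity of the observed minor-allele count) that are no
#' more probable than the observed configuration.
#'
#' @param n_AA,n_Aa,n_aa non-negative integer genotype counts (hom, het, hom).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stopf("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stopf("at least one genotype required")
  m <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)  # minor allele count
  if (m == 0) return(1)
  hets <- seq(m %% 2, m, by = 2)
  # log conditional probability up to a constant:
  #   P(h) propto 2^h / ( ((m-h)/2)! * h! * ((2n-m-h)/2)! )
  logp <- hets * log(2) - lfactorial((m - hets) / 2) - lfactorial(hets) -
    lfactorial((2 * n - m - hets) / 2)
  logp <- logp - max(logp)
  pr <- exp(logp)
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

#' Remove samples with high genotype missingness
#'
#' Samples whose fraction of missing calls is strictly greater than
#' `max_missing` are removed (the boundary sample is retained).
#'
#' @param gm an [sv_genotypes].
#' @param max_missing missing-call fraction threshold in (0, 1].
#' @return Filtered [sv_genotypes], sample order preserved.
#' @export
filter_samples_by_missingness <- function(gm, max_missing = 0.10) {
  stopifnot(max_missing > 0, max_missing <= 1)
  keep <- which(sample_missing_rate(gm) <= max_missing)
  if (length(keep) == length(gm$samples)) return(gm)
  subset_genotypes(gm, samples = keep)
}

#' Variant quality-control filters
#'
#' Drops SNPs with minor allele frequency `<= maf_min`, missing-call rate
#' `>= max_missing`, or Hardy-Weinberg exact p `< hwe_alpha`. The three
#' filters are evaluated on the input matrix, so their outcome does not
#' depend on application order.
#'
#' @param gm an [sv_genotypes].
#' @param maf_min MAF at or below which a SNP is removed.
#' @param max_missing missing rate at or above which a SNP is removed.
#' @param hwe_alpha Hardy-Weinberg p-value below which a SNP is removed.
#' @return List with `genotypes` (retained matrix) and `exclusions`, a
#'   `data.frame` (`snp_id`, `reason`, `value`, `threshold`) with one row per
#'   failed filter per SNP (`reason` in `maf`, `missing`, `hwe`).
#' @export
filter_snps <- function(gm, maf_min = 0.01, max_missing = 0.10, hwe_alpha = 1e-7) {
  maf <- snp_maf(gm)
  miss <- snp_missing_rate(gm)
  hwe_p <- vapply(seq_len(nrow(gm$snps)), function(j) {
    d <- gm$dosages[, j]
    hwe_exact_test(sum(d == 2, na.rm = TRUE), sum(d == 1, na.rm = TRUE),
                   sum(d == 0, na.rm = TRUE))
  }, numeric(1))

  fail_rows <- function(keep, reason, value, threshold) {
    data.frame(snp_id = gm$snps$id[keep], reason = rep(reason, sum(keep)),
               value = value[keep], threshold = rep(threshold, sum(keep)),
               stringsAsFactors = FALSE)
  }
  ex <- rbind(fail_rows(maf <= maf_min, "maf", maf, maf_min),
              fail_rows(miss >= max_missing, "missing", miss, max_missing),
              fail_rows(hwe_p < hwe_alpha, "hwe", hwe_p, hwe_alpha))
  rownames(ex) <- NULL
  keep <- !(gm$snps$id %in% ex$snp_id)
  out <- if (all(keep)) gm else subset_genotypes(gm, snps = which(keep))
  list(genotypes = out, exclusions = ex)
}

#' Orient dosages to count the minor allele
#'
#' Flips any SNP whose counted allele has frequency above 0.5 (dosage
#' `g <- 2 - g`, allele labels swapped). At frequency exactly 0.5 the
#' lexicographically smaller allele label is taken as minor, so orientation
#' is deterministic across cohorts.
#'
#' @param gm an [sv_genotypes].
#' @return List with `genotypes` (minor-allele oriented) and `orientation`, a
#'   `data.frame` (`snp_id`, `minor_allele`, `major_allele`) reusable by
#'   [harmonize_to_reference()].
#' @export
orient_to_minor <- function(gm) {
  f <- allele1_freq(gm)
  f[is.nan(f)] <- 0
  flip <- f > 0.5 | (f == 0.5 & gm$snps$a1 > gm$snps$a2)
  if (any(flip)) {
    d <- gm$dosages
    d[, flip] <- 2 - d[, flip]
    snps <- gm$snps
    tmp <- snps$a1[flip]
    snps$a1[flip] <- snps$a2[flip]
    snps$a2[flip] <- tmp
    gm <- sv_genotypes(d, snps, gm$samples)
  }
  list(genotypes = gm,
       orientation = data.frame(snp_id = gm$snps$id,
                                minor_allele = gm$snps$a1,
                                major_allele = gm$snps$a2,
                                stringsAsFactors = FALSE))
}

#' Harmonize a cohort's allele coding to a reference orientation
#'
#' For each SNP in the reference orientation table, the cohort's dosage is
#' made to count the reference minor allele: SNPs already counting it are
#' untouched, SNPs counting the other allele are flipped (`g <- 2 - g`).
#' SNPs absent from the cohort, or whose allele labels match neither
#' reference allele, are excluded and reported rather than raising an error.
#'
#' @param gm cohort [sv_genotypes].
#' @param orientation orientation table from [orient_to_minor()] on the
#'   reference (discovery) cohort.
#' @return List with `genotypes` (restricted to usable SNPs, in reference
#'   table order) and `report`, a `data.frame` (`snp_id`, `status`) where
#'   status is `kept`, `flipped`, `absent`, or `allele_mismatch`.
#' @export
harmonize_to_reference <- function(gm, orientation) {
  idx <- match(orientation$snp_id, gm$snps$id)
  status <- character(nrow(orientation))
  status[is.na(idx)] <- "absent"
  present <- which(!is.na(idx))
  j <- idx[present]
  same <- gm$snps$a1[j] == orientation$minor_allele[present] &
    gm$snps$a2[j] == orientation$major_allele[present]
  flipped <- gm$snps$a1[j] == orientation$major_allele[present] &
    gm$snps$a2[j] == orientation$minor_allele[present]
  status[present[same]] <- "kept"
  status[present[flipped & !same]] <- "flipped"
  status[present[!same & !flipped]] <- "allele_mismatch"

  keep <- present[same | flipped]
  d <- gm$dosages[, idx[keep], drop = FALSE]
  snps <- gm$snps[idx[keep], , drop = FALSE]
  do_flip <- (flipped & !same)[match(keep, present)]
  if (any(do_flip)) {
    d[, do_flip] <- 2 - d[, do_flip]
    tmp <- snps$a1[do_flip]
    snps$a1[do_flip] <- snps$a2[do_flip]
    snps$a2[do_flip] <- tmp
  }
  list(genotypes = sv_genotypes(d, snps, gm$samples),
       report = data.frame(snp_id = orientation$snp_id, status = status,
                           stringsAsFactors = FALSE))
}
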