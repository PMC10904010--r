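# Multi-cohort synthetic data generator. Hard-call genotypes are produced
# under Hardy-Weinberg equilibrium from two latent AR(1) Gaussian haplotype
# processes per LD block (thresholded at each SNP's target MAF), phenotypes
# from sparse additive minor-allele effects plus covariate loadings and
# Gaussian noise, and covariates follow the imaging-study design (age, sex,
# acquisition site, 10 principal components).

#' Simulation configuration
#'
#' Defaults mirror the multi-cohort imaging-genetics design the pipeline is
#' built for: one large discovery cohort (n = 30,842) and three external
#' validation cohorts (n = 1927, 4399, 319); 22 continuous phenotypes of
#' which the first four carry sparse 5-SNP additive effects; block-wise LD;
#' age/sex/site/principal-component covariates with cohort-specific age
#' ranges and one site-free cohort.
#'
#' @param n_samples named integer vector of cohort sizes.
#' @param n_snps number of SNPs (shared map across cohorts).
#' @param chrom per-SNP chromosome labels (default: SNPs split over two
#'   chromosomes).
#' @param pos per-SNP 1-based base-pair positions, strictly increasing
#'   within a chromosome.
#' @param maf_range range the per-SNP target minor allele frequencies are
#'   drawn from, within (0.01, 0.5].
#' @param ld_block_lengths positive integers summing to `n_snps`.
#' @param rho within-block latent AR(1) correlation in [0, 1).
#' @param effects named list: phenotype -> `data.frame(snp_id, beta)` of
#'   additive effects per minor allele.
#' @param phenotypes phenotype names (defaults to `names(effects)` plus
#'   enough null phenotypes to reach 22 when `effects` is left at default).
#' @param covariate_scheme named list per cohort: `age_range` (length-2),
#'   `n_sites` (0 drops the site column), `n_pcs`.
#' @param covariate_loadings named numeric: fixed loadings for `age`, `sex`
#'   (nonzero by default so covariate adjustment is consequential).
#' @param noise_sd phenotype noise standard deviation.
#' @param swap_snps SNP ids whose allele labels are swapped (dosage
#'   complemented) in the second cohort, to keep harmonization exercised;
#'   `NULL` disables. Default: the first 5 SNPs when there are >= 2 cohorts.
#' @param seed integer master seed.
#' @return A validated list of class `sv_sim_config`.
#' @export
sim_config <- function(n_samples = c(UKB = 30842, UKBW = 1927, ABCD = 4399, HCP = 319),
                       n_snps = 1000,
                       chrom = NULL, pos = NULL,
                       maf_range = c(0.05, 0.5),
                       ld_block_lengths = NULL,
                       rho = 0.5,
                       effects = NULL,
                       phenotypes = NULL,
                       covariate_scheme = NULL,
                       covariate_loadings = c(age = 0.01, sex = 0.1),
                       noise_sd = 1,
                       swap_snps = NULL,
                       seed = 1L) {
  if (is.null(names(n_samples)) || anyDuplicated(names(n_samples)))
    stopf("n_samples must have unique cohort names")
  if (any(n_samples < 1)) stopf("cohort sizes must be positive")
  if (rho < 0 || rho >= 1) stopf("rho must lie in [0, 1)")
  if (maf_range[1] <= 0.01 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stopf("maf_range must lie within (0.01, 0.5]")
  if (noise_sd <= 0) stopf("noise_sd must be positive")

  if (is.null(chrom) || is.null(pos)) {
    half <- ceiling(n_snps / 2)
    chrom <- rep(c("1", "2"), c(half, n_snps - half))
    pos <- c(seq_len(half), seq_len(n_snps - half)) * 4000L
  }
  if (length(chrom) != n_snps || length(pos) != n_snps)
    stopf("chrom/pos must have length n_snps")
  for (cc in unique(chrom)) {
    pc <- pos[chrom == cc]
    if (any(diff(pc) <= 0))
      stopf("positions must be strictly increasing within chromosome %s", cc)
  }
  if (any(pos < 1)) stopf("positions must be >= 1")

  if (is.null(ld_block_lengths)) {
    nb <- n_snps %/% 10
    ld_block_lengths <- c(rep(10L, nb), if (n_snps %% 10) n_snps %% 10)
  }
  if (sum(ld_block_lengths) != n_snps || any(ld_block_lengths < 1))
    stopf("ld_block_lengths must be positive and sum to n_snps")

  snp_ids <- paste0("rs", seq_len(n_snps))
  default_effects <- is.null(effects)
  if (default_effects) {
    # sparse architecture: first four phenotypes each carry a 5-SNP block
    effects <- list()
    for (j in seq_len(min(4, n_snps %/% 5))) {
      idx <- (j - 1) * 250 + 1:5
      idx <- idx[idx <= n_snps]
      effects[[sprintf("FA%02d", j)]] <-
        data.frame(snp_id = snp_ids[idx], beta = 0.05)
    }
  }
  for (ph in names(effects)) {
    ef <- effects[[ph]]
    if (!all(c("snp_id", "beta") %in% names(ef)))
      stopf("effects[['%s']] needs snp_id and beta columns", ph)
    bad <- setdiff(ef$snp_id, snp_ids)
    if (length(bad))
      stopf("effect SNP(s) not in the map: %s", paste(bad, collapse = ", "))
  }
  if (is.null(phenotypes)) {
    phenotypes <- if (default_effects)
      sprintf("FA%02d", seq_len(22)) else names(effects)
  }
  if (!all(names(effects) %in% phenotypes))
    stopf("every effect phenotype must appear in `phenotypes`")

  if (is.null(covariate_scheme)) {
    labs <- names(n_samples)
    age_ranges <- list(c(45, 80), c(45, 80), c(9, 11), c(22, 37))
    n_sites <- c(3L, 3L, 4L, 0L)
    covariate_scheme <- lapply(seq_along(labs), function(i)
      list(age_range = age_ranges[[min(i, 4)]],
           n_sites = n_sites[min(i, 4)], n_pcs = 10L))
    names(covariate_scheme) <- labs
  }
  missing_scheme <- setdiff(names(n_samples), names(covariate_scheme))
  if (length(missing_scheme))
    stopf("no covariate scheme for cohort(s): %s",
          paste(missing_scheme, collapse = ", "))

  if (is.null(swap_snps) && length(n_samples) >= 2)
    swap_snps <- snp_ids[seq_len(min(5, n_snps))]

  structure(list(n_samples = n_samples, n_snps = n_snps,
                 snp_ids = snp_ids, chrom = chrom, pos = pos,
                 maf_range = maf_range, ld_block_lengths = ld_block_lengths,
                 rho = rho, effects = effects, phenotypes = phenotypes,
                 covariate_scheme = covariate_scheme,
                 covariate_loadings = covariate_loadings,
                 noise_sd = noise_sd, swap_snps = swap_snps,
                 seed = as.integer(seed)),
            class = "sv_sim_config")
}

# SNP-level attributes shared by all cohorts (MAFs, allele labels), drawn
# deterministically from the master seed.
shared_snp_attributes <- function(config) {
  with_seed(config$seed, {
    maf <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])
    alleles <- t(replicate(config$n_snps, sample(c("A", "C", "G", "T"), 2)))
    list(maf = maf, a1 = alleles[, 1], a2 = alleles[, 2])
  })
}

cohort_index <- function(config, cohort_label) {
  i <- match(cohort_label, names(config$n_samples))
  if (is.na(i)) stopf("unknown cohort label '%s'", cohort_label)
  i
}

#' Simulate hard-call genotypes for one cohort
#'
#' Within each LD block, two independent latent AR(1) Gaussian haplotype
#' processes with parameter `rho` are thresholded at each SNP's target minor
#' allele frequency and summed, giving hard calls in \{0, 1, 2\} that are in
#' Hardy-Weinberg proportions marginally and correlated within blocks;
#' blocks are mutually independent. Deterministic given the config seed and
#' cohort label.
#'
#' @param config an [sim_config()].
#' @param cohort_label which cohort's samples to draw (sizes and seeds are
#'   cohort-specific; MAFs and alleles are shared).
#' @return An [sv_genotypes] with minor-allele (`a1`) counted dosages.
#' @export
simulate_genotypes <- function(config, cohort_label = names(config$n_samples)[1]) {
  stopifnot(inherits(config, "sv_sim_config"))
  i <- cohort_index(config, cohort_label)
  att <- shared_snp_attributes(config)
  if (any(att$maf <= 0 | att$maf > 0.5)) stopf("target MAF outside (0, 0.5]")
  n <- config$n_samples[[i]]
  rho <- config$rho

  d <- with_seed(config$seed + 1000L * i, {
    out <- matrix(0L, nrow = n, ncol = config$n_snps)
    offset <- 0L
    for (len in config$ld_block_lengths) {
      cols <- offset + seq_len(len)
      tau <- stats::qnorm(1 - att$maf[cols])
      for (hap in 1:2) {
        z <- matrix(stats::rnorm(n * len), n, len)
        if (rho > 0 && len > 1) {
          w <- sqrt(1 - rho^2)
          for (j in 2:len) z[, j] <- rho * z[, j - 1] + w * z[, j]
        }
        out[, cols] <- out[, cols] + (z > rep(tau, each = n))
      }
      offset <- offset + len
    }
    out
  })
  snps <- data.frame(id = config$snp_ids, chrom = config$chrom,
                     pos = config$pos, a1 = att$a1, a2 = att$a2,
                     stringsAsFactors = FALSE)
  sv_genotypes(d, snps, paste0(cohort_label, "_", seq_len(n)))
}

#' Simulate a cohort's covariate table
#'
#' Emits raw covariates only: `age` (uniform over the cohort's range), `sex`
#' (Bernoulli 0/1), `site` (equiprobable categorical; omitted when the
#' scheme has no sites) and standard-normal `PC1..PCk`. Derived columns
#' (age squared and the interactions) are formed by [build_design()], never
#' stored.
#'
#' @param config an [sim_config()].
#' @param cohort_label cohort whose scheme to use.
#' @return `data.frame` with an `IID` column first.
#' @export
simulate_covariates <- function(config, cohort_label) {
  stopifnot(inherits(config, "sv_sim_config"))
  i <- cohort_index(config, cohort_label)
  sc <- config$covariate_scheme[[cohort_label]]
  n <- config$n_samples[[i]]
  with_seed(config$seed + 1000L * i + 500L, {
    tab <- data.frame(IID = paste0(cohort_label, "_", seq_len(n)),
                      age = stats::runif(n, sc$age_range[1], sc$age_range[2]),
                      sex = stats::rbinom(n, 1, 0.5))
    if (sc$n_sites >= 1)
      tab$site <- paste0("site", sample.int(sc$n_sites, n, replace = TRUE))
    for (k in seq_len(sc$n_pcs %||% 10L))
      tab[[paste0("PC", k)]] <- stats::rnorm(n)
    tab
  })
}

#' Simulate one phenotype column
#'
#' `y = sum_j beta_j g_j + loading_age * age + loading_sex * sex +
#' N(0, noise_sd^2)`; phenotypes without entries in `config$effects` are
#' pure covariate + noise.
#'
#' @param genotypes cohort [sv_genotypes].
#' @param covariates matching covariate table.
#' @param config an [sim_config()].
#' @param phenotype_name which phenotype to draw.
#' @param seed RNG seed for the noise draw (callers vary it per cohort).
#' @return Named numeric vector (names = sample ids).
#' @export
simulate_phenotype <- function(genotypes, covariates, config, phenotype_name,
                               seed = config$seed) {
  stopifnot(inherits(config, "sv_sim_config"))
  n <- length(genotypes$samples)
  y <- numeric(n)
  ef <- config$effects[[phenotype_name]]
  if (!is.null(ef) && nrow(ef) > 0) {
    miss <- setdiff(ef$snp_id, genotypes$snps$id)
    if (length(miss))
      stopf("effect SNP(s) absent from genotypes: %s", paste(miss, collapse = ", "))
    G <- impute_dosages(genotypes, ef$snp_id)
    y <- y + as.numeric(G %*% ef$beta)
  }
  lo <- config$covariate_loadings
  if (!is.na(lo["age"]) && "age" %in% names(covariates))
    y <- y + lo[["age"]] * as.numeric(covariates$age)
  if (!is.na(lo["sex"]) && "sex" %in% names(covariates))
    y <- y + lo[["sex"]] * as.numeric(covariates$sex)
  y <- y + with_seed(seed, stats::rnorm(n, 0, config$noise_sd))
  names(y) <- genotypes$samples
  y
}

#' Simulate every cohort of the study
#'
#' Cohorts share the SNP map, target allele frequencies and true effects but
#' have independent samples. When `config$swap_snps` is set and at least two
#' cohorts exist, the second cohort's listed SNPs are stored with swapped
#' allele labels (dosage complemented) — the same haplotypes under the
#' opposite coding convention — so allele harmonization is always exercised.
#'
#' @param config an [sim_config()].
#' @return Named list of [sv_cohort] objects.
#' @export
simulate_multi_cohort <- function(config) {
  stopifnot(inherits(config, "sv_sim_config"))
  labs <- names(config$n_samples)
  cohorts <- lapply(seq_along(labs), function(i) {
    lab <- labs[i]
    gm <- simulate_genotypes(config, lab)
    cov <- simulate_covariates(config, lab)
    ph <- data.frame(IID = gm$samples)
    for (j in seq_along(config$phenotypes)) {
      pn <- config$phenotypes[j]
      ph[[pn] ] <- as.numeric(simulate_phenotype(gm, cov, config, pn,
                                                 seed = config$seed + 1000L * i + j))
    }
    if (i == 2L && length(config$swap_snps)) {
      j <- match(config$swap_snps, gm$snps$id)
      j <- j[!is.na(j)]
      d <- gm$dosages
      d[, j] <- 2 - d[, j]
      snps <- gm$snps
      tmp <- snps$a1[j]
      snps$a1[j] <- snps$a2[j]
      snps$a2[j] <- tmp
      gm <- sv_genotypes(d, snps, gm$samples)
    }
    sv_cohort(lab, gm, cov, ph)
  })
  names(cohorts) <- labs
  cohorts
}
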