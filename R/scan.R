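# Covariate-adjusted per-SNP association scan. Computation residualizes the
# phenotype and every dosage column against the design (Frisch-Waugh), which
# reproduces the joint OLS fit y ~ covariates + g exactly while touching the
# design decomposition only once; degrees of freedom are those of the joint
# fit, n - p - 1.

# Regression of y on a single predictor after projecting the design out of
# both. `den0` short-circuits predictors with (numerically) zero residual
# variance: monomorphic or design-collinear columns get beta 0, t 0, p 1.
resid_assoc <- function(ry, rx, df, ryry = sum(ry^2)) {
  den <- sum(rx^2)
  if (den <= 1e-12 * max(1, length(rx))) {
    return(list(beta = 0, se = NA_real_, t = 0, p = 1, degenerate = TRUE))
  }
  num <- sum(rx * ry)
  beta <- num / den
  rss <- max(ryry - beta * num, 0)
  se <- sqrt(rss / df / den)
  tval <- if (se > 0) beta / se else sign(beta) * Inf
  p <- 2 * stats::pt(-abs(tval), df)
  list(beta = beta, se = se, t = tval, p = max(p, .Machine$double.xmin),
       degenerate = FALSE)
}

#' Per-SNP marginal association statistics
#'
#' For every SNP, fits (equivalently to the joint OLS
#' `y ~ covariates + g`) the covariate-adjusted marginal regression and
#' reports the dosage coefficient, its standard error, t-statistic and
#' two-sided p-value from the t distribution with `n - p - 1` degrees of
#' freedom. Missing dosages are mean-imputed per SNP for the fit only.
#' Monomorphic SNPs are reported with `t = 0`, `p = 1` and flagged, so the
#' ranking stays total but such SNPs never lead it.
#'
#' @param gm an [sv_genotypes] (minor-allele oriented).
#' @param phenotype numeric phenotype vector; either named by sample id or
#'   aligned with `gm$samples`.
#' @param design an [sv_design] built on the same cohort.
#' @return `data.frame` with columns `snp_id`, `chrom`, `pos`, `beta`, `se`,
#'   `t`, `p`, `n`, `monomorphic`.
#' @export
marginal_stats <- function(gm, phenotype, design) {
  al <- align_to_design(gm, phenotype, design)
  ry <- design_resid(design, al$y)
  RG <- design_resid(design, al$G)
  n <- nrow(al$G)
  df <- n - ncol(design$X) - 1
  ryry <- sum(ry^2)

  num <- as.numeric(crossprod(RG, ry))
  den <- colSums(RG^2)
  degen <- den <= 1e-12 * max(1, n)
  beta <- ifelse(degen, 0, num / den)
  rss <- pmax(ryry - beta * num, 0)
  se <- ifelse(degen, NA_real_, sqrt(rss / df / den))
  tval <- ifelse(degen, 0, beta / se)
  p <- ifelse(degen, 1, pmax(2 * stats::pt(-abs(tval), df), .Machine$double.xmin))

  data.frame(snp_id = gm$snps$id, chrom = gm$snps$chrom, pos = gm$snps$pos,
             beta = beta, se = se, t = tval, p = p, n = n,
             monomorphic = degen, stringsAsFactors = FALSE)
}

# Align genotype rows and phenotype values with the design's samples.
align_to_design <- function(gm, phenotype, design) {
  if (!is.null(names(phenotype))) {
    y <- as.numeric(phenotype[design$samples])
  } else {
    if (length(phenotype) != length(gm$samples))
      stopf("unnamed phenotype of length %d for %d samples",
            length(phenotype), length(gm$samples))
    y <- as.numeric(phenotype[match(design$samples, gm$samples)])
  }
  if (anyNA(y)) stopf("phenotype missing for %d design sample(s)", sum(is.na(y)))
  G <- impute_dosages(gm)[match(design$samples, gm$samples), , drop = FALSE]
  list(y = y, G = G)
}

#' Write a marginal scan to TSV
#'
#' Columns `snp_id chrom pos beta se t p n`.
#'
#' @param stats result of [marginal_stats()].
#' @param path output file.
#' @export
write_scan <- function(stats, path) {
  utils::write.table(stats[, c("snp_id", "chrom", "pos", "beta", "se", "t", "p", "n")],
                     path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
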