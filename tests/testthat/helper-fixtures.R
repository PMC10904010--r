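# Fixture builders and independent oracles used across the suite. All data
# are generated in code at test time; nothing is read from disk.

# Small hand-built genotype matrix.
tiny_gm <- function(dosages, chrom = "1", pos = NULL, a1 = NULL, a2 = NULL) {
  m <- ncol(dosages)
  snps <- data.frame(id = paste0("s", seq_len(m)),
                     chrom = rep_len(chrom, m),
                     pos = pos %||% seq_len(m) * 1000L,
                     a1 = a1 %||% rep("A", m),
                     a2 = a2 %||% rep("G", m),
                     stringsAsFactors = FALSE)
  sv_genotypes(dosages, snps, paste0("i", seq_len(nrow(dosages))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Config for a single-cohort study: n_windows 1-Mbp windows of
# snps_per_window SNPs each on one chromosome.
window_config <- function(n, n_windows, snps_per_window = 10, rho = 0,
                          effects = list(), phenotypes = names(effects),
                          seed = 1, n_samples = c(D = n), ...) {
  m <- n_windows * snps_per_window
  pos <- as.integer((seq_len(m) - 1) %/% snps_per_window) * 1000000L +
    ((seq_len(m) - 1) %% snps_per_window + 1L) * 1000L
  sim_config(n_samples = n_samples, n_snps = m,
             chrom = rep("1", m), pos = pos,
             ld_block_lengths = rep(snps_per_window, n_windows), rho = rho,
             effects = effects,
             phenotypes = if (length(phenotypes)) phenotypes else "FA01",
             swap_snps = character(0), seed = seed, ...)
}

# Cohort with minor-allele-oriented genotypes, ready for scanning.
oriented_cohort <- function(config, label = names(config$n_samples)[1]) {
  co <- simulate_multi_cohort(config)[[label]]
  co$genotypes <- orient_to_minor(co$genotypes)$genotypes
  co
}

pheno_vec <- function(cohort, name) {
  stats::setNames(as.numeric(cohort$phenotypes[[name]]), cohort$phenotypes$IID)
}

# --- independent oracles -------------------------------------------------

# Exact HWE p-value by direct enumeration of absolute conditional
# probabilities (no normalization shortcut; different route from the
# package implementation).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  m <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (m == 0) return(1)
  const <- lfactorial(n) + lfactorial(m) + lfactorial(2 * n - m) - lfactorial(2 * n)
  prob_of <- function(h) {
    exp(const + h * log(2) - lfactorial(h) - lfactorial((m - h) / 2) -
          lfactorial((2 * n - m - h) / 2))
  }
  hets <- seq(m %% 2, m, by = 2)
  probs <- vapply(hets, prob_of, numeric(1))
  obs <- probs[match(n_Aa, hets)]
  # conditional probability = mass ratio; normalizing also cancels the
  # lgamma rounding shared by every term
  min(1, sum(probs[probs <= obs * (1 + 1e-10)]) / sum(probs))
}

# Per-SNP joint OLS fit y ~ covariates + g via lm().
joint_ols_oracle <- function(gm, y, design) {
  G <- gm$dosages
  X <- design$X
  t(vapply(seq_len(ncol(G)), function(j) {
    g <- as.numeric(G[, j])
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    fit <- summary(stats::lm(y ~ 0 + X + g))
    co <- fit$coefficients["g", ]
    c(beta = co[[1]], se = co[[2]], t = co[[3]], p = co[[4]])
  }, c(beta = 0, se = 0, t = 0, p = 0)))
}

# From-scratch cutoff sweep: re-aggregates at every k and fits with lm().
cutoff_oracle <- function(gm, ranked, y, design) {
  X <- design$X
  G <- supervariant:::impute_dosages(gm, ranked)
  best_p <- Inf
  best_k <- NA_integer_
  p_path <- numeric(length(ranked))
  for (k in seq_along(ranked)) {
    score <- rowSums(G[, seq_len(k), drop = FALSE])
    fit <- summary(stats::lm(y ~ 0 + X + score))
    p <- fit$coefficients["score", 4]
    p_path[k] <- p
    if (p < best_p) {
      best_p <- p
      best_k <- k
    }
  }
  list(k = best_k, p = best_p, p_path = p_path)
}

# Independently coded sample-size-weighted Z combination.
meta_oracle <- function(ns, ps, signs) {
  zs <- signs * qnorm(1 - ps / 2)
  z <- sum(sqrt(ns) * zs) / sqrt(sum(ns))
  list(z = z, p = 2 * pnorm(-abs(z)))
}
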