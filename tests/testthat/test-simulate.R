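# Synthetic multi-cohort generator: allele-frequency targeting, LD
# structure, Hardy-Weinberg proportions, phenotype construction and
# determinism.

test_that("empirical MAF matches the target under independence", {
  cfg <- sim_config(n_samples = c(A = 50000), n_snps = 1,
                    chrom = "1", pos = 1000L, ld_block_lengths = 1L, rho = 0,
                    maf_range = c(0.3, 0.3) + c(-1e-9, 1e-9),
                    effects = list(), phenotypes = "y",
                    swap_snps = character(0), seed = 3)
  gm <- simulate_genotypes(cfg, "A")
  maf_hat <- mean(gm$dosages) / 2
  se <- sqrt(0.3 * 0.7 / (2 * 50000))  # binomial sampling of 2n alleles
  expect_lt(abs(maf_hat - 0.3), 3 * se)
  expect_true(all(gm$dosages %in% 0:2))
})

test_that("rho controls within-block LD; cross-block r2 is near zero", {
  r2_within <- numeric(0)
  r2_between <- numeric(0)
  for (s in 1:10) {
    cfg <- sim_config(n_samples = c(A = 2000), n_snps = 20,
                      ld_block_lengths = rep(5, 4), rho = 0.9,
                      effects = list(), phenotypes = "y",
                      swap_snps = character(0), seed = 100 + s)
    gm <- simulate_genotypes(cfg, "A")
    d <- gm$dosages
    for (b in 0:3) {
      j <- b * 5 + 1:5
      r2_within <- c(r2_within, cor(d[, j[1]], d[, j[2]])^2)
    }
    r2_between <- c(r2_between, cor(d[, 5], d[, 6])^2,
                    cor(d[, 10], d[, 11])^2)
  }
  expect_gt(mean(r2_within), mean(r2_between) + 0.2)
  expect_lt(mean(r2_between), 0.02)
})

test_that("degenerate single-SNP configuration yields hard calls", {
  cfg <- sim_config(n_samples = c(A = 30), n_snps = 1, chrom = "1",
                    pos = 5L, ld_block_lengths = 1L, rho = 0.5,
                    effects = list(), phenotypes = "y",
                    swap_snps = character(0), seed = 2)
  gm <- simulate_genotypes(cfg, "A")
  expect_equal(dim(gm$dosages), c(30L, 1L))
  expect_true(all(gm$dosages %in% 0:2))
})

test_that("simulated genotypes are in Hardy-Weinberg proportions", {
  cfg <- window_config(1000, n_windows = 200, snps_per_window = 10,
                       rho = 0, seed = 42)
  gm <- simulate_genotypes(cfg, "D")
  pv <- vapply(seq_len(ncol(gm$dosages)), function(j) {
    d <- gm$dosages[, j]
    hwe_exact_test(sum(d == 2), sum(d == 1), sum(d == 0))
  }, numeric(1))
  se <- sqrt(0.05 * 0.95 / length(pv))
  expect_lt(abs(mean(pv < 0.05) - 0.05), 3 * se)
})

test_that("covariate tables follow the cohort scheme and are deterministic", {
  cfg <- sim_config(n_samples = c(A = 200, B = 100, C = 150, H = 80),
                    n_snps = 10, ld_block_lengths = rep(5, 2),
                    effects = list(), phenotypes = "y", seed = 5)
  cov_a <- simulate_covariates(cfg, "A")
  expect_equal(length(unique(cov_a$site)), 3L)
  expect_identical(cov_a, simulate_covariates(cfg, "A"))
  expect_true(all(paste0("PC", 1:10) %in% names(cov_a)))
  # fourth cohort is site-free (HCP-like); the design drops site terms
  cov_h <- simulate_covariates(cfg, "H")
  expect_false("site" %in% names(cov_h))
  d <- build_design(cov_h)
  expect_false(any(grepl("^site", d$terms)))
  expect_error(simulate_covariates(cfg, "nope"), "unknown cohort")
})

test_that("null phenotypes give uniform marginal p-values", {
  cfg <- window_config(500, n_windows = 200, snps_per_window = 10, rho = 0,
                       seed = 9, covariate_loadings = c(age = 0, sex = 0))
  co <- oriented_cohort(cfg)
  design <- build_design(co$covariates, terms = character(0))  # intercept only
  y <- pheno_vec(co, "FA01")
  st <- marginal_stats(co$genotypes, y, design)
  se <- sqrt(0.05 * 0.95 / nrow(st))
  expect_lt(abs(mean(st$p < 0.05) - 0.05), 3 * se)
})

test_that("a planted effect is recovered in the noiseless limit", {
  cfg <- window_config(500, n_windows = 1, snps_per_window = 5,
                       effects = list(y = data.frame(snp_id = "rs3", beta = 1)),
                       phenotypes = "y", seed = 11,
                       covariate_loadings = c(age = 0, sex = 0),
                       noise_sd = 1e-8)
  co <- oriented_cohort(cfg)
  design <- build_design(co$covariates, terms = character(0))
  st <- marginal_stats(co$genotypes, pheno_vec(co, "y"), design)
  expect_equal(st$beta[st$snp_id == "rs3"], 1, tolerance = 1e-6)
})

test_that("planted block effects carry the designed power", {
  # 10 SNPs explaining ~2% of variance at n = 4000: the joint F-test
  # should reject at 0.05 essentially always (non-central F power ~ 1)
  n <- 4000
  target_r2 <- 0.02
  ncp <- n * target_r2 / (1 - target_r2)
  power <- 1 - pf(qf(0.95, 10, n - 11), 10, n - 11, ncp = ncp)
  expect_gt(power, 0.999)  # analytic oracle for the chosen conditions

  rej <- 0
  n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    cfg <- window_config(n, n_windows = 1, snps_per_window = 10, rho = 0,
                         effects = list(y = data.frame(
                           snp_id = paste0("rs", 1:10),
                           beta = sqrt(target_r2 / (1 - target_r2) / 10 / 0.37))),
                         phenotypes = "y", seed = 5000 + s,
                         covariate_loadings = c(age = 0, sex = 0))
    co <- simulate_multi_cohort(cfg)$D
    G <- co$genotypes$dosages[, 1:10]
    y <- co$phenotypes$y
    f <- summary(lm(y ~ G))$fstatistic
    if (pf(f[1], f[2], f[3], lower.tail = FALSE) < 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_seeds, 0.95)
})

test_that("phenotype variance decomposes into genetic, covariate and noise parts", {
  betas <- c(0.3, 0.2, 0.25)
  cfg <- window_config(20000, n_windows = 1, snps_per_window = 10, rho = 0,
                       effects = list(y = data.frame(
                         snp_id = paste0("rs", 1:3), beta = betas)),
                       phenotypes = "y", seed = 21,
                       covariate_loadings = c(age = 0, sex = 0.5),
                       noise_sd = 1)
  co <- simulate_multi_cohort(cfg)$D
  maf <- co$genotypes$snps$maf[1:3]
  expected <- sum(betas^2 * 2 * maf * (1 - maf)) + 0.5^2 * 0.25 + 1
  expect_equal(var(co$phenotypes$y), expected, tolerance = 0.05)
})

test_that("multi-cohort simulation shares the map, swaps alleles in cohort 2", {
  eff <- list(FA01 = data.frame(snp_id = paste0("rs", 1:3), beta = 0.2))
  base <- list(n_samples = c(D = 300, V = 200), n_snps = 20,
               ld_block_lengths = rep(5, 4), effects = eff,
               phenotypes = "FA01", seed = 31)
  cfg_swap <- do.call(sim_config, c(base, list(swap_snps = paste0("rs", 1:5))))
  cfg_none <- do.call(sim_config, c(base, list(swap_snps = character(0))))
  cs <- simulate_multi_cohort(cfg_swap)
  cn <- simulate_multi_cohort(cfg_none)
  expect_identical(names(cs), c("D", "V"))
  expect_identical(cs$D$genotypes$snps, cn$D$genotypes$snps)
  # swapped SNPs: same haplotypes under the complementary coding
  expect_equal(cs$V$genotypes$dosages[, 1:5], 2 - cn$V$genotypes$dosages[, 1:5])
  expect_equal(cs$V$genotypes$dosages[, 6:20], cn$V$genotypes$dosages[, 6:20])
  expect_identical(cs$V$genotypes$snps$a1[1:5], cn$V$genotypes$snps$a2[1:5])
  # phenotypes are unaffected by the storage coding
  expect_identical(cs$V$phenotypes, cn$V$phenotypes)
  # byte-identical on rerun
  expect_identical(cs, simulate_multi_cohort(cfg_swap))
  # single cohort config
  one <- simulate_multi_cohort(window_config(50, 2, 5, seed = 1))
  expect_length(one, 1L)
  expect_error(sim_config(n_samples = c(A = 10, A = 10), n_snps = 10,
                          ld_block_lengths = 10),
               "unique cohort names")
})

test_that("configuration errors are caught", {
  expect_error(window_config(10, 2, 5, rho = 1), "rho")
  expect_error(window_config(10, 2, 5, maf_range = c(0.001, 0.4)), "maf_range")
  expect_error(sim_config(n_samples = c(A = 10), n_snps = 10,
                          ld_block_lengths = c(4, 4)), "sum to n_snps")
  expect_error(window_config(10, 2, 5, effects = list(
    y = data.frame(snp_id = "rs999", beta = 1)), phenotypes = "y"),
    "rs999")
  cfg <- window_config(50, 1, 5,
                       effects = list(y = data.frame(snp_id = "rs2", beta = 1)),
                       phenotypes = "y", seed = 2)
  co <- simulate_multi_cohort(cfg)$D
  gm_sub <- supervariant:::subset_genotypes(co$genotypes, snps = c(1L, 3L))
  expect_error(simulate_phenotype(gm_sub, co$covariates, cfg, "y"), "rs2")
})
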