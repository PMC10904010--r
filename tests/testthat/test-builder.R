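# Ranking, additive aggregation, adaptive cutoff selection and candidate
# construction, checked against a from-scratch brute-force sweep.

fake_stats <- function(t, chrom = "1", pos = seq_along(t) * 100L,
                       ids = paste0("s", seq_along(t))) {
  data.frame(snp_id = ids, chrom = chrom, pos = pos, beta = t, se = 1,
             t = t, p = 2 * pnorm(-abs(t)), n = 100L, monomorphic = FALSE,
             stringsAsFactors = FALSE)
}

test_that("ranking is directional, antisymmetric and tie-broken by position", {
  st <- fake_stats(c(2.1, -0.3, 5.0))
  expect_identical(rank_snps(st, st$snp_id, "+"), c("s3", "s1", "s2"))
  expect_identical(rank_snps(st, st$snp_id, "-"), c("s2", "s1", "s3"))
  tied <- fake_stats(c(1.5, 1.5), pos = c(200L, 100L))
  expect_identical(rank_snps(tied, tied$snp_id, "+"), c("s2", "s1"))
  expect_error(rank_snps(st, "missing_snp"), "missing_snp")
})

test_that("additive scores sum minor-allele dosages with mean imputation", {
  set.seed(5)
  gm <- tiny_gm(rbind(c(0L, 1L, 2L), c(2L, 2L, 2L), c(0L, 0L, 0L)))
  s <- aggregate_score(gm, c("s1", "s2", "s3"))
  expect_equal(unname(s), c(3, 6, 0))
  expect_error(aggregate_score(gm, c("s1", "ghost")), "ghost")
  gm2 <- tiny_gm(rbind(c(0L, NA), c(2L, 2L), c(1L, 0L)))
  expect_equal(unname(aggregate_score(gm2, c("s1", "s2"))), c(1, 4, 1))
})

test_that("cutoff selection matches the brute-force re-aggregation oracle", {
  set.seed(30)
  for (s in 1:5) {
    cfg <- window_config(250, 1, 25, rho = 0.3, seed = 40 + s,
                         effects = list(y = data.frame(
                           snp_id = paste0("rs", sample(1:25, 3)), beta = 0.25)),
                         phenotypes = "y")
    co <- oriented_cohort(cfg)
    design <- build_design(co$covariates)
    y <- pheno_vec(co, "y")
    st <- marginal_stats(co$genotypes, y, design)
    for (dir in c("+", "-")) {
      ranked <- rank_snps(st, co$genotypes$snps$id, dir)
      sel <- select_cutoff(co$genotypes, ranked, y, design)
      ora <- cutoff_oracle(co$genotypes, ranked, as.numeric(y), design)
      expect_identical(sel$k, ora$k)
      expect_equal(sel$assoc$p, ora$p, tolerance = 1e-10)
      expect_equal(sel$p_path, ora$p_path, tolerance = 1e-10)
    }
  }
})

test_that("exact p ties resolve to the smaller cutoff", {
  set.seed(6)
  # duplicated dosage column: the k = 2 score is exactly twice the k = 1
  # score, so both cutoffs give identical statistics
  g <- rbinom(120, 2, 0.3)
  gm <- tiny_gm(cbind(g, g), pos = c(100L, 200L))
  design <- build_design(data.frame(IID = paste0("i", 1:120)), terms = character(0))
  y <- stats::setNames(0.4 * g + rnorm(120), gm$samples)
  sel <- select_cutoff(gm, c("s1", "s2"), y, design)
  expect_identical(sel$p_path[1], sel$p_path[2])
  expect_identical(sel$k, 1L)
})

test_that("single-SNP sets force k = 1", {
  set.seed(7)
  gm <- tiny_gm(matrix(rbinom(80, 2, 0.4), ncol = 1))
  design <- build_design(data.frame(IID = paste0("i", 1:80)), terms = character(0))
  sel <- select_cutoff(gm, "s1", stats::setNames(rnorm(80), gm$samples), design)
  expect_identical(sel$k, 1L)
})

test_that("the selected cutoff brackets a planted equal-effect prefix", {
  hits <- 0
  n_seeds <- 50
  for (s in seq_len(n_seeds)) {
    cfg <- window_config(4000, 1, 50, rho = 0, seed = 700 + s,
                         effects = list(y = data.frame(
                           snp_id = paste0("rs", 1:5), beta = 0.22)),
                         phenotypes = "y")
    co <- oriented_cohort(cfg)
    design <- build_design(co$covariates)
    y <- pheno_vec(co, "y")
    st <- marginal_stats(co$genotypes, y, design)
    ranked <- rank_snps(st, co$genotypes$snps$id, "+")
    sel <- select_cutoff(co$genotypes, ranked, y, design)
    if (sel$k >= 4 && sel$k <= 6) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("candidate construction is total, deterministic and prefix-consistent", {
  cfg <- window_config(300, 1, 12, seed = 51,
                       effects = list(y = data.frame(snp_id = paste0("rs", 1:2),
                                                     beta = 0.4)),
                       phenotypes = "y")
  co <- oriented_cohort(cfg)
  design <- build_design(co$covariates)
  y <- pheno_vec(co, "y")
  set <- partition_genome(co$genotypes$snps)[[1]]
  cands <- build_supervariants(co$genotypes, set, y, design, "y")
  expect_named(cands, c("+", "-"))
  expect_identical(cands$`+`$name, paste0("y_", set$set_id, "+"))
  expect_identical(cands$`-`$name, paste0("y_", set$set_id, "-"))
  for (cd in cands) {
    expect_identical(cd$selected_snps, cd$ranked_snps[seq_len(cd$k)])
    expect_lte(cd$k, length(cd$ranked_snps))
  }
  # permutation invariance of input SNP order within the set
  set2 <- set
  set2$snp_ids <- rev(set2$snp_ids)
  cands2 <- build_supervariants(co$genotypes, set2, y, design, "y")
  expect_identical(cands$`+`$selected_snps, cands2$`+`$selected_snps)
  expect_identical(cands$`+`$assoc, cands2$`+`$assoc)
  # rerun determinism
  cands3 <- build_supervariants(co$genotypes, set, y, design, "y")
  expect_identical(cands, cands3)
  # sign consistency: "+" with a positive top t has positive k=1 beta
  st <- marginal_stats(co$genotypes, y, design)
  if (any(st$t > 0)) {
    top <- rank_snps(st, set$snp_ids, "+")[1]
    a <- test_score(aggregate_score(co$genotypes, top), y, design)
    expect_gt(a$beta, 0)
  }
})

test_that("an all-positive set still yields a negative-direction candidate", {
  set.seed(8)
  g <- sapply(1:4, function(j) rbinom(200, 2, 0.3))
  gm <- tiny_gm(g)
  y <- stats::setNames(rowSums(g) * 0.5 + rnorm(200), gm$samples)
  design <- build_design(data.frame(IID = gm$samples), terms = character(0))
  set <- define_named_set("allpos", gm$snps$id, gm)
  cands <- build_supervariants(gm, set, y, design, "y")
  st <- marginal_stats(gm, y, design)
  expect_true(all(st$t > 0))
  expect_s3_class(cands$`-`, "sv_candidate")
  expect_identical(cands$`-`$ranked_snps, rev(rank_snps(st, set$snp_ids, "+")))
})

test_that("conditional tests reduce, flag collinearity, and absorb signal", {
  cfg <- window_config(500, 1, 10, seed = 61,
                       effects = list(y = data.frame(snp_id = "rs1", beta = 0.5)),
                       phenotypes = "y")
  co <- oriented_cohort(cfg)
  design <- build_design(co$covariates)
  y <- pheno_vec(co, "y")
  score <- aggregate_score(co$genotypes, paste0("rs", 1:3))
  plain <- test_score(score, y, design)
  none <- conditional_test(score, y, design, NULL)
  expect_equal(none[c("beta", "se", "t", "p")], plain[c("beta", "se", "t", "p")])
  # conditioning on the supervariant's own SNPs is collinear
  G <- supervariant:::impute_dosages(co$genotypes, paste0("rs", 1:3))
  self <- conditional_test(score, y, design, G)
  expect_true(self$collinear)
  expect_identical(self$p, 1)
  # signal wholly carried by the conditioned-on SNP: p rises
  g1 <- supervariant:::impute_dosages(co$genotypes, "rs1")
  cond <- conditional_test(score, y, design, g1)
  expect_gt(cond$p, plain$p)
})
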