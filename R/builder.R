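# Supervariant construction: rank SNPs within a set by marginal t, sweep
# every cutoff k, aggregate the top-k minor-allele dosages additively, and
# keep the cutoff whose burden-score association attains the lowest p-value.

#' Rank a SNP set by marginal t-statistic
#'
#' Direction `"+"` sorts descending in t (positive effects first), `"-"`
#' ascending. Ties are broken by chromosome, position, then SNP id, so the
#' order is total and reproducible.
#'
#' @param stats [marginal_stats()] output covering the set.
#' @param snp_ids SNP ids of the set.
#' @param direction `"+"` or `"-"`.
#' @return Character vector of SNP ids, best-ranked first.
#' @export
rank_snps <- function(stats, snp_ids, direction = c("+", "-")) {
  direction <- match.arg(direction)
  idx <- match(snp_ids, stats$snp_id)
  if (length(idx) == 0 || anyNA(idx))
    stopf("marginal statistics missing for SNP(s): %s",
          paste(snp_ids[is.na(idx)], collapse = ", "))
  s <- stats[idx, , drop = FALSE]
  key <- if (direction == "+") -s$t else s$t
  s$snp_id[order(key, s$chrom, s$pos, s$snp_id)]
}

#' Additive burden score
#'
#' Per-sample sum of minor-allele dosages over the given SNPs; missing calls
#' are mean-imputed per SNP before summation.
#'
#' @param gm an [sv_genotypes] (minor-allele oriented).
#' @param snp_ids SNPs to aggregate; all must be present in `gm`.
#' @return Named numeric vector of scores, one per sample.
#' @export
aggregate_score <- function(gm, snp_ids) {
  rowSums(impute_dosages(gm, snp_ids))
}

#' Test a burden score against a phenotype
#'
#' Covariate-adjusted OLS of the phenotype on the score; reports the score
#' coefficient with t-based two-sided p at `n - p - 1` degrees of freedom.
#'
#' @param score per-sample score (named by sample id or aligned to the design).
#' @param phenotype phenotype vector (same conventions).
#' @param design an [sv_design].
#' @return List with `beta`, `se`, `t`, `p`, `n`, `sign` (+1/-1) and
#'   `degenerate` (constant or design-collinear score).
#' @export
test_score <- function(score, phenotype, design) {
  y <- align_vector(phenotype, design)
  x <- align_vector(score, design)
  ry <- design_resid(design, y)
  rx <- design_resid(design, x)
  df <- length(y) - ncol(design$X) - 1
  a <- resid_assoc(ry, rx, df)
  a$n <- length(y)
  a$sign <- if (a$beta < 0) -1 else 1
  a
}

align_vector <- function(v, design) {
  if (!is.null(names(v))) v <- v[design$samples]
  if (length(v) != length(design$samples))
    stopf("vector of length %d for %d design samples", length(v),
          length(design$samples))
  if (anyNA(v)) stopf("missing values after sample alignment")
  as.numeric(v)
}

#' Adaptive cutoff selection
#'
#' Sweeps every cutoff `k = 1..length(ranked_snps)`; at each k the top-k
#' SNPs are aggregated and the burden score regressed on the phenotype with
#' covariate adjustment. Returns the k attaining the lowest p-value, ties
#' resolved in favour of the smaller k. The sweep maintains the residualized
#' score as a prefix sum, so the full search costs one design projection of
#' the dosage block plus O(n) work per cutoff.
#'
#' @param gm an [sv_genotypes].
#' @param ranked_snps output of [rank_snps()].
#' @param phenotype phenotype vector.
#' @param design an [sv_design].
#' @return List with `k`, `assoc` (as [test_score()]) and `p_path`, the
#'   p-value at every cutoff.
#' @export
select_cutoff <- function(gm, ranked_snps, phenotype, design) {
  stopifnot(length(ranked_snps) >= 1)
  y <- align_vector(phenotype, design)
  G <- impute_dosages(gm, ranked_snps)[match(design$samples, gm$samples), ,
                                       drop = FALSE]
  ry <- design_resid(design, y)
  RG <- design_resid(design, G)
  n <- length(y)
  df <- n - ncol(design$X) - 1
  ryry <- sum(ry^2)

  M <- length(ranked_snps)
  p_path <- numeric(M)
  best <- NULL
  best_k <- 1L
  rs <- numeric(n)
  for (k in seq_len(M)) {
    rs <- rs + RG[, k]
    a <- resid_assoc(ry, rs, df, ryry)
    p_path[k] <- a$p
    if (is.null(best) || a$p < best$p) {
      best <- a
      best_k <- k
    }
  }
  best$n <- n
  best$sign <- if (best$beta < 0) -1 else 1
  list(k = best_k, assoc = best, p_path = p_path)
}

#' Construct the two supervariant candidates of a SNP set
#'
#' Ranks the set's SNPs in both directions and runs cutoff selection for
#' each, always producing one positive- and one negative-direction candidate
#' named `"{phenotype}_{set_id}{+|-}"` (construction totality: a direction
#' with no matching-sign SNP still yields a candidate, which downstream
#' validation will discard).
#'
#' @param gm an [sv_genotypes].
#' @param snp_set an `sv_snp_set`.
#' @param phenotype phenotype vector.
#' @param design an [sv_design].
#' @param phenotype_name label used in candidate names.
#' @param stats optional precomputed [marginal_stats()] covering the set
#'   (recomputed on the set's SNPs when omitted).
#' @return Named list of two `sv_candidate` objects (`"+"`, `"-"`), each with
#'   `name`, `phenotype`, `set_id`, `direction`, `ranked_snps`, `k`,
#'   `selected_snps` (the top-k prefix) and `assoc` (construction statistics).
#' @export
build_supervariants <- function(gm, snp_set, phenotype, design,
                                phenotype_name = "pheno", stats = NULL) {
  if (is.null(stats)) {
    sub <- subset_genotypes(gm, snps = match(snp_set$snp_ids, gm$snps$id))
    stats <- marginal_stats(sub, phenotype, design)
  }
  out <- lapply(c("+", "-"), function(dir) {
    ranked <- rank_snps(stats, snp_set$snp_ids, dir)
    sel <- select_cutoff(gm, ranked, phenotype, design)
    structure(list(name = paste0(phenotype_name, "_", snp_set$set_id, dir),
                   phenotype = phenotype_name, set_id = snp_set$set_id,
                   direction = dir, ranked_snps = ranked, k = sel$k,
                   selected_snps = ranked[seq_len(sel$k)], assoc = sel$assoc),
              class = "sv_candidate")
  })
  names(out) <- c("+", "-")
  out
}

#' @export
print.sv_candidate <- function(x, ...) {
  cat(sprintf("<sv_candidate> %s: k = %d of %d SNPs, beta = %.4g, p = %.3g\n",
              x$name, x$k, length(x$ranked_snps), x$assoc$beta, x$assoc$p))
  invisible(x)
}

#' Conditional association test
#'
#' Tests the burden score with the usual covariates plus extra SNP dosage
#' columns (e.g. previously reported GWAS hits) added to the design, so the
#' score coefficient measures signal beyond the conditioned-on variants. A
#' score that is collinear with the extended design is flagged and reported
#' with `p = 1`.
#'
#' @param score per-sample burden score.
#' @param phenotype phenotype vector.
#' @param design an [sv_design].
#' @param extra_dosages numeric matrix of extra SNP dosage columns aligned
#'   with the design samples (rownames used for alignment if present), or
#'   `NULL`/zero-column for the unconditional test.
#' @return As [test_score()], plus `collinear` (logical flag).
#' @export
conditional_test <- function(score, phenotype, design, extra_dosages = NULL) {
  if (is.null(extra_dosages) || NCOL(extra_dosages) == 0) {
    a <- test_score(score, phenotype, design)
    a$collinear <- FALSE
    return(a)
  }
  extra_dosages <- as.matrix(extra_dosages)
  if (!is.null(rownames(extra_dosages)))
    extra_dosages <- extra_dosages[design$samples, , drop = FALSE]
  if (nrow(extra_dosages) != length(design$samples))
    stopf("extra dosage rows do not match design samples")
  Xe <- cbind(design$X, extra_dosages)
  qe <- qr(Xe)
  # project onto the column space of the extended design (pivoted basis
  # handles redundant extra columns)
  Q <- qr.Q(qe)[, seq_len(qe$rank), drop = FALSE]
  y <- align_vector(phenotype, design)
  x <- align_vector(score, design)
  ry <- y - Q %*% crossprod(Q, y)
  rx <- x - Q %*% crossprod(Q, x)
  df <- length(y) - qe$rank - 1
  a <- resid_assoc(ry, rx, df)
  a$n <- length(y)
  a$sign <- if (a$beta < 0) -1 else 1
  a$collinear <- a$degenerate
  if (a$collinear) a$p <- 1
  a
}

#' Write a candidate table to TSV
#'
#' Columns `name phenotype set_id direction k p_construction
#' beta_construction snps` (comma-joined selection).
#'
#' @param candidates list of `sv_candidate` objects.
#' @param path output file.
#' @export
write_candidates <- function(candidates, path) {
  tab <- do.call(rbind, lapply(candidates, function(cd)
    data.frame(name = cd$name, phenotype = cd$phenotype, set_id = cd$set_id,
               direction = cd$direction, k = cd$k,
               p_construction = cd$assoc$p, beta_construction = cd$assoc$beta,
               snps = paste(cd$selected_snps, collapse = ","))))
  utils::write.table(tab, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
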