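# Repeated split-sample discovery / internal-validation study. Each
# replication randomly halves the discovery cohort, constructs supervariant
# candidates on the first half, and re-tests candidates passing the
# discovery Bonferroni threshold -- with their SNP membership frozen -- on
# the second half. Candidates validated in enough replications are retained,
# together with their recurrently selected SNPs.

#' Bonferroni discovery threshold
#'
#' `fwer / (n_sets * n_directions * n_phenotypes)`: e.g. 2723 windows, two
#' directions and 22 phenotypes give 0.05 / 119,812 = 4.17e-7.
#'
#' @param n_sets number of SNP sets.
#' @param n_directions candidates per set (2: one per effect direction).
#' @param n_phenotypes number of phenotypes scanned.
#' @param fwer family-wise error rate budget.
#' @return Significance threshold.
#' @export
discovery_threshold <- function(n_sets, n_directions = 2, n_phenotypes = 1,
                                fwer = 0.05) {
  if (any(c(n_sets, n_directions, n_phenotypes) < 1)) stopf("counts must be positive")
  fwer / (n_sets * n_directions * n_phenotypes)
}

#' Study thresholds and retention rules
#'
#' @inheritParams discovery_threshold
#' @param n_replications number of random split replications.
#' @param retention_min minimum validations for a supervariant to be retained.
#' @param snp_retention_min minimum selections for a SNP to contribute to
#'   external validation.
#' @param split_fraction fraction of samples in the construction half.
#' @return List of class `sv_thresholds` with `alpha_discovery`
#'   (`fwer / (n_sets * n_directions * n_phenotypes)`) and
#'   `alpha_validation` (`fwer / n_phenotypes`).
#' @export
sv_thresholds <- function(n_sets, n_phenotypes, n_directions = 2, fwer = 0.05,
                          n_replications = 10, retention_min = 6,
                          snp_retention_min = 3, split_fraction = 0.5) {
  stopifnot(retention_min <= n_replications, split_fraction > 0,
            split_fraction < 1)
  structure(list(
    alpha_discovery = discovery_threshold(n_sets, n_directions, n_phenotypes, fwer),
    alpha_validation = fwer / n_phenotypes,
    n_replications = as.integer(n_replications),
    retention_min = as.integer(retention_min),
    snp_retention_min = as.integer(snp_retention_min),
    split_fraction = split_fraction,
    n_sets = n_sets, n_phenotypes = n_phenotypes, n_directions = n_directions,
    fwer = fwer), class = "sv_thresholds")
}

#' Random half-split of a cohort
#'
#' Disjoint and exhaustive: part 1 holds `floor(fraction * n)` samples,
#' part 2 the rest. The minor-allele orientation is fixed on part 1 and
#' propagated to part 2, so both halves count the same allele per SNP.
#'
#' @param cohort an [sv_cohort].
#' @param fraction part-1 fraction in (0, 1).
#' @param seed RNG seed (splits are deterministic per seed).
#' @return List with `part1`, `part2` (both [sv_cohort]) and `orientation`
#'   (part-1 minor-allele table).
#' @export
split_cohort <- function(cohort, fraction = 0.5, seed = 1L) {
  n <- length(cohort$genotypes$samples)
  if (n < 2) stopf("need at least 2 samples to split")
  stopifnot(fraction > 0, fraction < 1)
  idx1 <- with_seed(seed, sort(sample.int(n, floor(fraction * n))))
  part1 <- subset_cohort(cohort, idx1)
  part2 <- subset_cohort(cohort, setdiff(seq_len(n), idx1))
  o <- orient_to_minor(part1$genotypes)
  part1$genotypes <- o$genotypes
  h <- harmonize_to_reference(part2$genotypes, o$orientation)
  part2$genotypes <- h$genotypes
  list(part1 = part1, part2 = part2, orientation = o$orientation)
}

#' One discovery / internal-validation replication
#'
#' Splits the cohort, builds both direction candidates for every
#' (phenotype, set) on part 1, marks as discovered those with construction
#' `p < alpha_discovery`, freezes their selected SNPs, re-aggregates on
#' part 2 and regresses against the part-2 design (refit); a discovered
#' candidate is validated when its part-2 `p < alpha_validation`.
#'
#' @param cohort QC'd [sv_cohort] (minor-allele oriented).
#' @param sets list of `sv_snp_set`.
#' @param phenotypes phenotype column names in `cohort$phenotypes`.
#' @param thresholds an [sv_thresholds()].
#' @param seed split seed for this replication.
#' @return `data.frame`, one row per candidate: identity, `k`, construction
#'   and validation statistics, `discovered`, `validated`, `sign_concordant`,
#'   and the frozen selection (`snps`, comma-joined, discovered rows only).
#' @export
run_replication <- function(cohort, sets, phenotypes, thresholds, seed) {
  sp <- split_cohort(cohort, thresholds$split_fraction, seed)
  d1 <- build_design(sp$part1$covariates)
  d2 <- build_design(sp$part2$covariates)
  gm1 <- sp$part1$genotypes
  gm2 <- sp$part2$genotypes

  rows <- list()
  for (ph in phenotypes) {
    y1 <- stats::setNames(as.numeric(sp$part1$phenotypes[[ph]]),
                          sp$part1$phenotypes$IID)
    y2 <- stats::setNames(as.numeric(sp$part2$phenotypes[[ph]]),
                          sp$part2$phenotypes$IID)
    stats1 <- marginal_stats(gm1, y1, d1)
    for (s in sets) {
      cands <- build_supervariants(gm1, s, y1, d1, phenotype_name = ph,
                                   stats = stats1)
      for (cd in cands) {
        discovered <- cd$assoc$p < thresholds$alpha_discovery
        p_val <- NA_real_
        beta_val <- NA_real_
        validated <- FALSE
        concord <- NA
        if (discovered) {
          score2 <- aggregate_score(gm2, cd$selected_snps)
          a2 <- test_score(score2, y2, d2)
          p_val <- a2$p
          beta_val <- a2$beta
          validated <- a2$p < thresholds$alpha_validation
          concord <- a2$sign == cd$assoc$sign
        }
        rows[[length(rows) + 1L]] <- data.frame(
          name = cd$name, phenotype = ph, set_id = cd$set_id,
          direction = cd$direction, k = cd$k,
          p_construction = cd$assoc$p, beta_construction = cd$assoc$beta,
          p_validation = p_val, beta_validation = beta_val,
          discovered = discovered, validated = validated,
          sign_concordant = concord,
          snps = if (discovered) paste(cd$selected_snps, collapse = ",") else "",
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Run the full repeated split-sample study
#'
#' The central fitting function: repeats [run_replication()]
#' `n_replications` times with per-replication seeds `master_seed + r`,
#' counts how often each (phenotype, set, direction) candidate is discovered
#' and validated, and applies the retention rules — a supervariant is
#' retained when validated in at least `retention_min` replications, and a
#' SNP contributes to its frozen external-validation list when selected in
#' at least `snp_retention_min` of the replications in which the
#' supervariant was validated.
#'
#' @inheritParams run_replication
#' @param master_seed integer; replication r uses seed `master_seed + r`.
#' @param strict_sign if `TRUE`, validation additionally requires the part-2
#'   effect sign to match the construction sign (off by default; concordance
#'   is always recorded).
#' @return An object of class `sv_study`: list with `summary` (per-candidate
#'   counts), `retained` (subset meeting the retention rule, with frozen SNP
#'   lists), `snp_counts`, `replications` (per-replication log),
#'   `thresholds`, `orientation` (minor-allele table of the full cohort, for
#'   external harmonization) and `n_samples`.
#' @export
sv_study <- function(cohort, sets, phenotypes, thresholds, master_seed = 1L,
                     strict_sign = FALSE) {
  stopifnot(inherits(thresholds, "sv_thresholds"))
  logs <- vector("list", thresholds$n_replications)
  for (r in seq_len(thresholds$n_replications)) {
    rep_log <- run_replication(cohort, sets, phenotypes, thresholds,
                               seed = master_seed + r)
    rep_log$replication <- r
    logs[[r]] <- rep_log
  }
  log <- do.call(rbind, logs)
  if (strict_sign)
    log$validated <- log$validated & !is.na(log$sign_concordant) &
      log$sign_concordant

  agg <- stats::aggregate(cbind(discovered, validated) ~
                            name + phenotype + set_id + direction,
                          data = log, FUN = sum)
  names(agg)[names(agg) == "discovered"] <- "times_discovered"
  names(agg)[names(agg) == "validated"] <- "times_validated"
  ks <- stats::aggregate(k ~ name, data = log, FUN = stats::median)
  names(ks)[2] <- "median_k"
  agg <- merge(agg, ks, by = "name", sort = FALSE)
  agg <- agg[order(-agg$times_validated, agg$name), ]
  rownames(agg) <- NULL

  # SNP selection counts over validated replications of each candidate
  vrows <- log[log$validated & nzchar(log$snps), , drop = FALSE]
  snp_counts <- if (nrow(vrows)) {
    long <- do.call(rbind, lapply(seq_len(nrow(vrows)), function(i)
      data.frame(supervariant = vrows$name[i],
                 snp_id = strsplit(vrows$snps[i], ",", fixed = TRUE)[[1]],
                 stringsAsFactors = FALSE)))
    cnt <- stats::aggregate(times_selected ~ supervariant + snp_id,
                            data = cbind(long, times_selected = 1L), FUN = sum)
    cnt[order(cnt$supervariant, -cnt$times_selected, cnt$snp_id), ]
  } else {
    data.frame(supervariant = character(0), snp_id = character(0),
               times_selected = integer(0))
  }
  rownames(snp_counts) <- NULL

  retained <- agg[agg$times_validated >= thresholds$retention_min, ,
                  drop = FALSE]
  retained$snps <- vapply(retained$name, function(nm) {
    sel <- snp_counts[snp_counts$supervariant == nm &
                        snp_counts$times_selected >= thresholds$snp_retention_min,
                      "snp_id"]
    paste(sel, collapse = ",")
  }, character(1))
  rownames(retained) <- NULL

  structure(list(summary = agg, retained = retained, snp_counts = snp_counts,
                 replications = log, thresholds = thresholds,
                 orientation = orient_to_minor(cohort$genotypes)$orientation,
                 n_samples = length(cohort$genotypes$samples),
                 master_seed = master_seed),
            class = "sv_study")
}

#' @export
print.sv_study <- function(x, ...) {
  th <- x$thresholds
  cat(sprintf("<sv_study> %d samples, %d replications (split %.0f/%.0f)\n",
              x$n_samples, th$n_replications, 100 * th$split_fraction,
              100 * (1 - th$split_fraction)))
  cat(sprintf("  alpha_discovery = %.3g, alpha_validation = %.3g\n",
              th$alpha_discovery, th$alpha_validation))
  cat(sprintf("  retained (validated >= %d/%d): %d supervariant(s)\n",
              th$retention_min, th$n_replications, nrow(x$retained)))
  invisible(x)
}

#' @export
summary.sv_study <- function(object, ...) {
  th <- object$thresholds
  chance <- binomial_validation_probability(th$alpha_validation,
                                            th$n_replications, th$retention_min)
  structure(list(study = object, chance_retention = chance), class = "summary.sv_study")
}

#' @export
print.summary.sv_study <- function(x, ...) {
  print(x$study)
  cat(sprintf("  by-chance P(validated >= %d/%d | uniform p) = %.3g\n",
              x$study$thresholds$retention_min,
              x$study$thresholds$n_replications, x$chance_retention))
  if (nrow(x$study$retained)) {
    cat("  retained supervariants:\n")
    print(x$study$retained[, c("name", "times_discovered", "times_validated",
                               "median_k")], row.names = FALSE)
  }
  invisible(x)
}

#' Chance probability of repeated validation
#'
#' Upper-tail binomial probability of at least `k_min` successes in `n`
#' independent trials with per-trial success probability `p_trial` — the
#' probability that a null supervariant (uniform validation p-values) would
#' pass the retention rule by chance.
#'
#' @param p_trial per-replication success probability (e.g. the validation
#'   threshold 0.05/22).
#' @param n number of replications.
#' @param k_min minimum number of successes.
#' @return Tail probability.
#' @export
binomial_validation_probability <- function(p_trial, n, k_min) {
  stopifnot(p_trial >= 0, p_trial <= 1, k_min >= 0, k_min <= n)
  if (k_min == 0) return(1)
  stats::pbinom(k_min - 1, n, p_trial, lower.tail = FALSE)
}

#' Write study report tables
#'
#' Emits `retained.tsv` (`name times_discovered times_validated median_k`),
#' `snp_counts.tsv` (`snp_id supervariant times_selected`) and
#' `replications.tsv` (the per-replication log) under `dir`.
#'
#' @param study an [sv_study] object.
#' @param dir output directory.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(study$retained[, c("name", "times_discovered",
                                        "times_validated", "median_k")],
                     file.path(dir, "retained.tsv"), quote = FALSE,
                     sep = "\t", row.names = FALSE)
  utils::write.table(study$snp_counts[, c("snp_id", "supervariant",
                                          "times_selected")],
                     file.path(dir, "snp_counts.tsv"), quote = FALSE,
                     sep = "\t", row.names = FALSE)
  utils::write.table(study$replications, file.path(dir, "replications.tsv"),
                     quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(dir)
}
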