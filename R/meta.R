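# External validation of retained supervariants on independent cohorts and
# sample-size-weighted Z-score meta-analysis (the METAL weighting scheme:
# signed Z from the two-sided p, weights sqrt(n)).

#' Validate a frozen supervariant on an external cohort
#'
#' Harmonizes the cohort's allele coding to the discovery orientation, drops
#' frozen SNPs the cohort does not share (reported, not fatal), aggregates
#' the remainder additively and regresses the phenotype on the score with
#' the cohort's own covariate design.
#'
#' @param cohort an [sv_cohort].
#' @param snp_ids frozen contributing-SNP list from the discovery study.
#' @param phenotype phenotype column name in `cohort$phenotypes`.
#' @param orientation discovery minor-allele orientation table
#'   (`sv_study$orientation`); `NULL` if the cohort is already harmonized.
#' @param terms covariate term groups for [build_design()] (site terms are
#'   dropped automatically for cohorts without a site column).
#' @return List of class `sv_cohort_assoc`: `cohort`, `n`, `beta`, `se`,
#'   `t`, `p`, `sign`, `n_snps_used`, `n_snps_dropped`.
#' @export
external_validate <- function(cohort, snp_ids, phenotype, orientation = NULL,
                              terms = c("age", "sex", "site", "interactions", "pcs")) {
  gm <- cohort$genotypes
  if (!is.null(orientation)) {
    keep <- orientation[orientation$snp_id %in% snp_ids, , drop = FALSE]
    h <- harmonize_to_reference(gm, keep)
    gm <- h$genotypes
  }
  shared <- intersect(snp_ids, gm$snps$id)
  if (length(shared) == 0)
    stopf("cohort '%s': none of the %d frozen SNPs are available",
          cohort$label, length(snp_ids))
  design <- build_design(cohort$covariates, terms = terms)
  score <- aggregate_score(gm, shared)
  y <- stats::setNames(as.numeric(cohort$phenotypes[[phenotype]]),
                       cohort$phenotypes$IID)
  a <- test_score(score, y, design)
  structure(list(cohort = cohort$label, n = a$n, beta = a$beta, se = a$se,
                 t = a$t, p = a$p, sign = a$sign,
                 n_snps_used = length(shared),
                 n_snps_dropped = length(snp_ids) - length(shared)),
            class = "sv_cohort_assoc")
}

#' @export
print.sv_cohort_assoc <- function(x, ...) {
  cat(sprintf("<sv_cohort_assoc> %s (n = %d): beta = %.4g, p = %.3g, %d/%d SNPs used\n",
              x$cohort, x$n, x$beta, x$p, x$n_snps_used,
              x$n_snps_used + x$n_snps_dropped))
  invisible(x)
}

#' Sample-size-weighted Z-score meta-analysis
#'
#' Each cohort's two-sided p and effect sign give a signed Z,
#' `Z_i = sign_i * qnorm(1 - p_i / 2)`; the combined statistic is
#' `Z = sum(sqrt(n_i) Z_i) / sqrt(sum(n_i))` with two-sided
#' `p = 2 * pnorm(-|Z|)`. Underflowing per-cohort p-values are clamped at
#' the smallest positive double and flagged.
#'
#' @param results list of `sv_cohort_assoc` (or lists with `n`, `p`, `sign`).
#' @return List of class `sv_meta`: `z`, `p`, `n_total`, `weights`,
#'   `cohorts` (per-cohort table) and `clamped`.
#' @export
meta_analyze <- function(results) {
  stopifnot(length(results) >= 1)
  n <- vapply(results, function(r) as.numeric(r$n), numeric(1))
  p <- vapply(results, function(r) as.numeric(r$p), numeric(1))
  sg <- vapply(results, function(r) as.numeric(r$sign), numeric(1))
  stopifnot(all(n >= 1), all(sg %in% c(-1, 1)))
  clamped <- p <= 0
  p[clamped] <- .Machine$double.xmin
  z <- sg * stats::qnorm(p / 2, lower.tail = FALSE)
  w <- sqrt(n)
  z_meta <- sum(w * z) / sqrt(sum(n))
  p_meta <- 2 * stats::pnorm(-abs(z_meta))
  structure(list(z = z_meta, p = max(p_meta, .Machine$double.xmin),
                 n_total = sum(n), weights = w,
                 cohorts = data.frame(
                   cohort = vapply(results, function(r)
                     as.character(r$cohort %||% ""), character(1)),
                   n = n, p = p, sign = sg, z = z,
                   snps_dropped = vapply(results, function(r)
                     as.integer(r$n_snps_dropped %||% NA_integer_), integer(1))),
                 clamped = any(clamped)),
            class = "sv_meta")
}

#' @export
print.sv_meta <- function(x, ...) {
  cat(sprintf("<sv_meta> %d cohort(s), total n = %d: Z = %.4g, p = %.3g\n",
              nrow(x$cohorts), as.integer(x$n_total), x$z, x$p))
  invisible(x)
}

#' Summarize external validation across supervariants
#'
#' Builds the external replication report: per supervariant the combined Z
#' and p, pass/fail at the family Bonferroni level `fwer / N` and at the
#' nominal level, and a concordance flag (every cohort sign equal to the
#' discovery direction).
#'
#' @param meta_results named list of `sv_meta`, one per supervariant (names
#'   are supervariant names ending in their direction `+`/`-`).
#' @param directions optional named character vector of discovery directions
#'   (`"+"`/`"-"`); defaults to the trailing character of each name.
#' @param fwer family-wise budget (default 0.05).
#' @return Object of class `sv_external_report`: `data.frame` with columns
#'   `supervariant n_total z_meta p_meta pass_bonferroni pass_nominal
#'   concordant n_cohorts snps_dropped`, plus attributes `alpha_family` and
#'   `n_supervariants`.
#' @export
summarize_external <- function(meta_results, directions = NULL, fwer = 0.05) {
  N <- length(meta_results)
  alpha_family <- if (N > 0) fwer / N else NA_real_
  if (N == 0) {
    tab <- data.frame(supervariant = character(0), n_total = numeric(0),
                      z_meta = numeric(0), p_meta = numeric(0),
                      pass_bonferroni = logical(0), pass_nominal = logical(0),
                      concordant = logical(0), n_cohorts = integer(0),
                      snps_dropped = character(0))
  } else {
    nms <- names(meta_results)
    if (is.null(directions))
      directions <- stats::setNames(substring(nms, nchar(nms)), nms)
    tab <- do.call(rbind, lapply(nms, function(nm) {
      m <- meta_results[[nm]]
      dsign <- if (directions[[nm]] == "-") -1 else 1
      data.frame(supervariant = nm, n_total = m$n_total, z_meta = m$z,
                 p_meta = m$p,
                 pass_bonferroni = m$p < alpha_family,
                 pass_nominal = m$p < fwer,
                 concordant = all(m$cohorts$sign == dsign),
                 n_cohorts = nrow(m$cohorts),
                 snps_dropped = paste(m$cohorts$cohort, m$cohorts$snps_dropped,
                                      sep = ":", collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    rownames(tab) <- NULL
  }
  structure(tab, class = c("sv_external_report", "data.frame"),
            alpha_family = alpha_family, n_supervariants = N, fwer = fwer)
}

#' @export
print.sv_external_report <- function(x, ...) {
  N <- attr(x, "n_supervariants")
  cat(sprintf("<sv_external_report> %d supervariant(s); family threshold %s/%d = %.3g\n",
              N, format(attr(x, "fwer")), max(N, 1), attr(x, "alpha_family")))
  if (N > 0) {
    cat(sprintf("  pass Bonferroni: %d (%.1f%%); pass nominal 0.05: %d (%.1f%%)\n",
                sum(x$pass_bonferroni), 100 * mean(x$pass_bonferroni),
                sum(x$pass_nominal), 100 * mean(x$pass_nominal)))
    print(as.data.frame(x)[, c("supervariant", "n_total", "z_meta", "p_meta",
                               "pass_bonferroni", "pass_nominal", "concordant")],
          row.names = FALSE)
  }
  invisible(x)
}
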