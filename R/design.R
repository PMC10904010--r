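# Covariate design builder: intercept, age, sex, site indicators, age^2,
# age x sex, age^2 x sex, and principal-component columns, with terms
# present only when the underlying covariates exist in the cohort.

#' Build the covariate design matrix
#'
#' Derived columns (`age^2`, `age:sex`, `age^2:sex`) are formed here from the
#' raw `age`/`sex` columns; they are never stored in covariate tables. Site
#' enters as indicator columns with the first level dropped as reference and
#' is omitted entirely when fewer than two levels are present. Any `PC`
#' column (`PC1`, `PC2`, ...) is included as-is. Samples with a missing
#' value in any used covariate are dropped and counted.
#'
#' @param covariates `data.frame` with an `IID` column plus any of `age`
#'   (numeric), `sex` (0/1), `site` (categorical), `PC1`..`PCk`.
#' @param terms optional character vector restricting which term groups to
#'   use, a subset of `c("age", "sex", "site", "interactions", "pcs")`;
#'   default uses every group whose columns exist.
#' @return An object of class `sv_design`: list with `X` (model matrix
#'   including intercept), `samples` (ids kept), `terms` (column names) and
#'   `n_dropped` (samples removed for missing covariates).
#' @export
build_design <- function(covariates,
                         terms = c("age", "sex", "site", "interactions", "pcs")) {
  if (length(terms) > 0) terms <- match.arg(terms, several.ok = TRUE)
  ids <- as.character(covariates$IID)
  cols <- list(`(Intercept)` = rep(1, nrow(covariates)))

  has_age <- "age" %in% names(covariates) && "age" %in% terms
  has_sex <- "sex" %in% names(covariates) && "sex" %in% terms
  if (has_age) {
    age <- as.numeric(covariates$age)
    cols$age <- age
    cols$age2 <- age^2
  }
  if (has_sex) cols$sex <- as.numeric(covariates$sex)
  if (has_age && has_sex && "interactions" %in% terms) {
    cols$age_sex <- cols$age * cols$sex
    cols$age2_sex <- cols$age2 * cols$sex
  }
  if ("site" %in% names(covariates) && "site" %in% terms) {
    site <- factor(covariates$site)
    if (nlevels(site) >= 2) {
      for (lv in levels(site)[-1])  # first level is the reference
        cols[[paste0("site", lv)]] <- as.numeric(site == lv)
    }
  }
  if ("pcs" %in% terms) {
    pc_cols <- grep("^PC[0-9]+$", names(covariates), value = TRUE)
    pc_cols <- pc_cols[order(as.integer(sub("^PC", "", pc_cols)))]
    for (pc in pc_cols) cols[[pc]] <- as.numeric(covariates[[pc]])
  }

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  complete <- stats::complete.cases(X)
  n_dropped <- sum(!complete)
  X <- X[complete, , drop = FALSE]
  ids <- ids[complete]

  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1, ncol(X))]]
    stopf("design is rank deficient; collinear term(s): %s",
          paste(bad, collapse = ", "))
  }
  structure(list(X = X, samples = ids, terms = colnames(X),
                 n_dropped = n_dropped),
            class = "sv_design")
}

#' @export
print.sv_design <- function(x, ...) {
  cat(sprintf("<sv_design> %d samples x %d terms: %s\n", nrow(x$X), ncol(x$X),
              paste(x$terms, collapse = ", ")))
  if (x$n_dropped > 0)
    cat(sprintf("  %d sample(s) dropped for missing covariates\n", x$n_dropped))
  invisible(x)
}

# Orthonormal basis of the design column space, cached on the object.
design_Q <- function(design) {
  q <- attr(design, "Q")
  if (is.null(q)) q <- qr.Q(qr(design$X))
  q
}

# Residualize a vector or matrix against the design (projection complement).
design_resid <- function(design, y) {
  Q <- design_Q(design)
  y - Q %*% crossprod(Q, y)
}
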