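#' Maximum-likelihood logistic fit by iteratively reweighted least squares
#'
#' Minimal Newton/IRLS solver used by the per-SNP association scan, where
#' per-fit overhead matters. Convergence is declared when the largest
#' coefficient change drops below `tol`; fits that hit `maxit`, diverge, or
#' show (quasi-)complete separation (fitted probabilities collapsing to
#' 0/1 with escaping coefficients) are flagged unconverged and their
#' estimates should not be used.
#'
#' @param X design matrix including the intercept column.
#' @param y 0/1 response.
#' @param tol convergence tolerance on the coefficient change
#'   (default 1e-8).
#' @param maxit maximum IRLS iterations (default 25).
#' @param start optional starting coefficient vector (warm start for
#'   repeated fits sharing a covariate design).
#' @return list with `beta`, `se` (Wald, from the observed information),
#'   `loglik`, `converged`, `iter`.
#' @export
logistic_irls <- function(X, y, tol = 1e-8, maxit = 25, start = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  beta <- if (is.null(start)) numeric(p) else start
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    w[w < 1e-12] <- 1e-12
    H <- crossprod(X, X * w)
    g <- crossprod(X, y - mu)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) return(list(beta = rep(NA_real_, p), se = rep(NA_real_, p),
                                   loglik = NA_real_, converged = FALSE, iter = it))
    beta <- beta + drop(step)
    delta <- max(abs(step))
    if (!is.finite(delta) || max(abs(beta)) > 30) break  # divergence/separation
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  se <- rep(NA_real_, p)
  if (converged) {
    w <- mu * (1 - mu)
    w[w < 1e-12] <- 1e-12
    info <- crossprod(X, X * w)
    cv <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
    if (is.null(cv)) converged <- FALSE else se <- sqrt(diag(cv))
  }
  names(beta) <- names(se) <- colnames(X)
  list(beta = beta, se = se, loglik = ll, converged = converged, iter = it)
}

#' Single-SNP covariate-adjusted logistic association fit
#'
#' Fits the additive model
#' `logit(PC status) ~ dosage + covariates` by maximum likelihood and
#' returns the Wald test for the dosage term. Individuals with a missing
#' dosage are dropped for this variant only.
#'
#' @param dosage \{0,1,2,NA\} dosage vector.
#' @param pc_status 0/1 outcome.
#' @param covariates numeric covariate matrix (no intercept; one is added),
#'   or `NULL` for an unadjusted fit.
#' @return one-row data.frame: `log_or`, `se`, `p`, `or`, `n`, `converged`,
#'   `skip_reason` (`""`, `"constant_dosage"`).
#' @export
fit_snp_logistic <- function(dosage, pc_status, covariates = NULL) {
  v <- snp_fit_core(dosage, pc_status, covariates)
  data.frame(log_or = v[1], se = v[2], p = v[3], or = exp(v[1]), n = v[4],
             converged = v[5] == 1,
             skip_reason = if (v[6] == 1) "constant_dosage" else "",
             stringsAsFactors = FALSE, row.names = NULL)
}

# numeric core: c(log_or, se, p, n, converged, constant_dosage)
snp_fit_core <- function(dosage, pc_status, covariates = NULL, start = NULL) {
  if (length(unique(pc_status)) < 2) stop("outcome is constant")
  ok <- !is.na(dosage)
  d <- dosage[ok]
  n_used <- sum(ok)
  if (length(unique(d)) < 2)
    return(c(NA_real_, NA_real_, NA_real_, n_used, 0, 1))
  y <- pc_status[ok]
  X <- cbind(`(Intercept)` = 1, dosage = d)
  if (!is.null(covariates)) {
    cv <- if (all(ok)) covariates else covariates[ok, , drop = FALSE]
    X <- cbind(X, cv)
  }
  fit <- logistic_irls(X, y, start = start)
  if (!fit$converged) return(c(NA_real_, NA_real_, NA_real_, n_used, 0, 0))
  b <- fit$beta[2L]; s <- fit$se[2L]
  c(b, s, 2 * stats::pnorm(-abs(b / s)), n_used, 1, 0)
}

#' Risk-allele assignment from the association direction
#'
#' The risk allele is the minor allele when the odds ratio per counted
#' minor allele exceeds 1 and the major allele when it is below 1. At
#' exactly 1 the minor allele is reported with `tie = TRUE`.
#'
#' @param odds_ratio odds ratio per copy of the minor allele.
#' @param minor_allele,major_allele allele labels.
#' @return list with `allele` and `tie`.
#' @export
assign_risk_allele <- function(odds_ratio, minor_allele, major_allele) {
  tie <- odds_ratio == 1
  list(allele = ifelse(odds_ratio >= 1, minor_allele, major_allele), tie = tie)
}

#' Genome-wide association scan
#'
#' Per-variant additive logistic regression of comorbidity status on
#' dosage, adjusted for the first `n_mds` MDS ancestry components, sex, age
#' (two dummies), marital status and disease subtype. Dosages are
#' re-oriented to count the minor allele before fitting, so the reported
#' odds ratio is per minor-allele copy and the risk-allele rule applies
#' directly.
#'
#' @param geno a QC-filtered [genotype_matrix()].
#' @param cohort a `cohort_table` aligned to `geno` sample ids (with MDS
#'   columns attached when `n_mds > 0`).
#' @param n_mds number of MDS components to adjust for (default 5).
#' @return data.frame of class `gwas_result`: snp, chr, pos, a1, a2, maf,
#'   minor_allele, major_allele, n, log_or, se, p, or, risk_allele,
#'   risk_tie, converged, skip_reason.
#' @export
gwas_scan <- function(geno, cohort, n_mds = 5) {
  idx <- match(rownames(geno$dosages), cohort$sample_id)
  if (anyNA(idx)) stop("cohort rows missing for genotyped sample(s)")
  cohort <- cohort[idx, ]
  y <- cohort$pc_status
  covars <- covariate_design(cohort, n_mds = n_mds)
  # drop constant covariate columns (e.g. a level absent from a small cohort)
  keep_cov <- apply(covars, 2, function(v) stats::var(v) > 0)
  covars <- covars[, keep_cov, drop = FALSE]
  d <- geno$dosages
  maf <- maf_by_variant(geno)
  f1 <- colSums(d, na.rm = TRUE) / (2 * colSums(!is.na(d)))  # a1 frequency
  a1_minor <- f1 <= 0.5
  # warm start each per-SNP fit from the covariate-only model
  X0 <- cbind(`(Intercept)` = 1, covars)
  fit0 <- logistic_irls(X0, y)
  start <- if (fit0$converged)
    c(fit0$beta[1L], 0, fit0$beta[-1L]) else NULL
  out_mat <- matrix(NA_real_, nrow = ncol(d), ncol = 6)
  for (j in seq_len(ncol(d))) {
    dos <- d[, j]
    if (!a1_minor[j]) dos <- 2L - dos     # count the minor allele
    out_mat[j, ] <- snp_fit_core(dos, y, covars, start = start)
  }
  res <- data.frame(log_or = out_mat[, 1], se = out_mat[, 2],
                    p = out_mat[, 3], or = exp(out_mat[, 1]),
                    n = as.integer(out_mat[, 4]),
                    converged = out_mat[, 5] == 1,
                    skip_reason = ifelse(out_mat[, 6] == 1,
                                         "constant_dosage", ""),
                    stringsAsFactors = FALSE)
  minor <- ifelse(a1_minor, geno$variants$allele_a1, geno$variants$allele_a2)
  major <- ifelse(a1_minor, geno$variants$allele_a2, geno$variants$allele_a1)
  risk <- assign_risk_allele(res$or, minor, major)
  out <- data.frame(snp = geno$variants$variant_id,
                    chr = geno$variants$chromosome,
                    pos = geno$variants$position_bp,
                    a1 = geno$variants$allele_a1,
                    a2 = geno$variants$allele_a2,
                    maf = maf, minor_allele = minor, major_allele = major,
                    res,
                    risk_allele = ifelse(res$converged, risk$allele, NA_character_),
                    risk_tie = ifelse(res$converged, risk$tie, NA),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' Rank and export a GWAS scan
#'
#' Sorts by P-value, counts hits below the suggestive and genome-wide
#' thresholds, and produces Manhattan and QQ plot data (QQ expected
#' quantile for rank i of m is `-log10((i - 0.5)/m)`).
#'
#' @param results a `gwas_result`.
#' @param suggestive,genomewide significance thresholds (defaults 5e-5,
#'   5e-8).
#' @param prefix optional output path prefix; when given, writes
#'   `<prefix>.assoc.tsv`, `<prefix>.manhattan.tsv`, `<prefix>.qq.tsv`.
#' @return list: `table` (ranked results), `n_suggestive`, `n_genomewide`,
#'   `qq` (data.frame expected/observed -log10 P).
#' @export
export_scan <- function(results, suggestive = 5e-5, genomewide = 5e-8,
                        prefix = NULL) {
  fitted <- results[results$converged & !is.na(results$p), , drop = FALSE]
  ranked <- fitted[order(fitted$p), , drop = FALSE]
  m <- nrow(ranked)
  qq <- data.frame(expected = -log10((seq_len(m) - 0.5) / m),
                   observed = -log10(ranked$p))
  out <- list(table = ranked,
              n_suggestive = sum(ranked$p < suggestive),
              n_genomewide = sum(ranked$p < genomewide),
              qq = qq)
  if (!is.null(prefix)) {
    utils::write.table(ranked, paste0(prefix, ".assoc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(ranked[c("snp", "chr", "pos", "p")],
                       paste0(prefix, ".manhattan.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(qq, paste0(prefix, ".qq.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}
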