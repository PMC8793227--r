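# Fixture builders and independent oracles shared across the suite.

# Small genotype matrix straight from a dosage matrix.
make_geno <- function(d, chr = NULL, pos = NULL, a1 = NULL, a2 = NULL) {
  m <- ncol(d)
  genotype_matrix(d,
                  sample_ids = sprintf("s%02d", seq_len(nrow(d))),
                  variant_ids = sprintf("v%02d", seq_len(m)),
                  chromosome = chr %||% rep("1", m),
                  position_bp = pos %||% (seq_len(m) * 1000L),
                  allele_a1 = a1 %||% rep("A", m),
                  allele_a2 = a2 %||% rep("G", m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cohort with balanced covariates for n individuals and given outcome.
make_cohort <- function(y, mediator = rnorm(length(y)), seed = 42) {
  set.seed(seed)
  n <- length(y)
  cohort_table(data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    pc_status = y,
    sex = sample(c("male", "female"), n, replace = TRUE),
    age_category = sample(c("16 and under", "17 to 40", "over 40"), n,
                          replace = TRUE, prob = c(.1, .6, .3)),
    marital_status = sample(c("married/common-law", "single/divorced/widowed"),
                            n, replace = TRUE),
    disease_subtype = sample(c("Crohn's disease", "ulcerative colitis"), n,
                             replace = TRUE),
    mediator = mediator,
    stringsAsFactors = FALSE))
}

# ---- independent oracles ---------------------------------------------------

# HWE exact P-value by brute-force enumeration of every genotype
# configuration consistent with the observed allele counts.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  hets <- Filter(function(h) (nA - h) %% 2 == 0 && h <= min(nA, na) &&
                   (nA - h) / 2 + h + (na - h) / 2 == n,
                 0:min(nA, na))
  probs <- vapply(hets, function(h) {
    aa <- (nA - h) / 2; bb <- (na - h) / 2
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
          h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n))
  }, numeric(1))
  probs <- probs / sum(probs)
  obs <- probs[hets == n_Aa]
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# AUC by enumerating every case-control pair (ties count one half).
auc_oracle <- function(scores, labels) {
  cases <- scores[labels == 1]; controls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

# Greedy P-ordered clumping applied literally, pair by pair.
clump_oracle <- function(selected, geno, r2_max, window_bp) {
  ord <- order(selected$p, selected$pos, selected$snp)
  sel <- selected[ord, , drop = FALSE]
  keep <- character(0)
  alive <- rep(TRUE, nrow(sel))
  for (i in seq_len(nrow(sel))) {
    if (!alive[i]) next
    keep <- c(keep, sel$snp[i])
    alive[i] <- FALSE
    for (k in which(alive)) {
      if (sel$chr[k] != sel$chr[i]) next
      if (abs(sel$pos[k] - sel$pos[i]) > window_bp) next
      xi <- geno$dosages[, match(sel$snp[i], geno$variants$variant_id)]
      xk <- geno$dosages[, match(sel$snp[k], geno$variants$variant_id)]
      if (as.numeric(ld_r2(xi, xk)) >= r2_max) alive[k] <- FALSE
    }
  }
  keep
}

# Logistic MLE by direct Newton-Raphson on the log-likelihood, written
# independently of the package fitter (explicit gradient/Hessian loop).
newton_logistic_oracle <- function(X, y, iters = 60) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(iters)) {
    p <- 1 / (1 + exp(-X %*% beta))
    grad <- t(X) %*% (y - p)
    H <- -t(X) %*% (X * as.numeric(p * (1 - p)))
    beta <- beta - solve(H, grad)
  }
  drop(beta)
}
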