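#' Minor allele frequency of one dosage column
#'
#' Allele count of the counted allele over twice the number of non-missing
#' genotypes, folded to `min(f, 1 - f)`. Missing entries are excluded from
#' numerator and denominator.
#'
#' @param dosage integer vector of \{0,1,2,NA\} dosages.
#' @return the minor allele frequency in [0, 0.5].
#' @export
compute_maf <- function(dosage) {
  ok <- !is.na(dosage)
  if (!any(ok)) stop("all genotypes missing; MAF undefined")
  f <- sum(dosage[ok]) / (2 * sum(ok))
  min(f, 1 - f)
}

# Vectorized per-variant MAF / missing rate over a genotype matrix.
maf_by_variant <- function(geno) {
  d <- geno$dosages
  nm <- colSums(!is.na(d))
  if (any(nm == 0))
    stop("all genotypes missing for variant(s): ",
         paste(geno$variants$variant_id[nm == 0], collapse = ", "))
  f <- colSums(d, na.rm = TRUE) / (2 * nm)
  pmin(f, 1 - f)
}

miss_by_variant <- function(geno) colMeans(is.na(geno$dosages))

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the observed allele counts, the P-value is
#' the sum of probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count. Monomorphic
#' variants return 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total >= 1).
#' @return two-sided exact P-value in (0, 1].
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0, n_AA + n_Aa + n_aa >= 1)
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  rare <- min(nA, na)
  # admissible heterozygote counts share the parity of the rare-allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(n_Aa = h | nA, na, n) up to a shared constant:
  #   log n! - log nAA! - log nAa! - log naa! + h log 2
  logp <- lgamma(n + 1) - lgamma((nA - hets) / 2 + 1) -
    lgamma(hets + 1) - lgamma((na - hets) / 2 + 1) + hets * log(2)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[hets == n_Aa]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' SNP-level quality-control filter
#'
#' Applies the standard microarray QC removal rules with their boundary
#' conventions: a variant is removed when its missing rate is >= `miss_max`,
#' its minor allele frequency is < `maf_min`, or its exact Hardy-Weinberg
#' P-value is < `hwe_min`. A variant failing several rules is reported with
#' all applicable reason codes.
#'
#' @param geno a [genotype_matrix()].
#' @param maf_min MAF threshold (default 0.05; equality keeps).
#' @param miss_max missing-rate threshold (default 0.05; equality removes).
#' @param hwe_min HWE P-value threshold (default 5e-5; equality keeps).
#' @return a list: `genotypes` (the filtered matrix), `report` (data.frame
#'   with per-variant maf, miss_rate, hwe_p, kept flag and comma-joined
#'   reason codes among low_maf / high_missing / hwe_fail), and `counts`
#'   (removals per reason).
#' @export
filter_snps <- function(geno, maf_min = 0.05, miss_max = 0.05, hwe_min = 5e-5) {
  stopifnot(maf_min >= 0, maf_min <= 1, miss_max >= 0, miss_max <= 1,
            hwe_min >= 0, hwe_min <= 1)
  d <- geno$dosages
  maf <- maf_by_variant(geno)
  miss <- miss_by_variant(geno)
  hwe <- vapply(seq_len(ncol(d)), function(j) {
    v <- d[, j]
    hwe_test(sum(v == 2, na.rm = TRUE), sum(v == 1, na.rm = TRUE),
             sum(v == 0, na.rm = TRUE))
  }, numeric(1))
  low_maf <- maf < maf_min
  high_missing <- miss >= miss_max
  hwe_fail <- hwe < hwe_min
  kept <- !(low_maf | high_missing | hwe_fail)
  reasons <- vapply(seq_along(kept), function(j) {
    if (kept[j]) return("")
    paste(c("low_maf", "high_missing", "hwe_fail")[
      c(low_maf[j], high_missing[j], hwe_fail[j])], collapse = ",")
  }, character(1))
  report <- data.frame(variant_id = geno$variants$variant_id,
                       maf = maf, miss_rate = miss, hwe_p = hwe,
                       kept = kept, reasons = reasons,
                       stringsAsFactors = FALSE, row.names = NULL)
  if (!any(kept))
    stop("no variants survive QC; review thresholds (maf_min=", maf_min,
         ", miss_max=", miss_max, ", hwe_min=", hwe_min, ")")
  list(genotypes = subset_variants(geno, which(kept)),
       report = report,
       counts = c(low_maf = sum(low_maf), high_missing = sum(high_missing),
                  hwe_fail = sum(hwe_fail), kept = sum(kept)))
}

#' Squared Pearson correlation between two dosage columns (LD r-squared)
#'
#' Computed over pairwise-complete observations. If either column is
#' constant over the complete pairs the value is defined as 0 and the
#' result carries attribute `constant = TRUE`.
#'
#' @param dosage_a,dosage_b dosage vectors of equal length.
#' @return squared correlation in [0, 1].
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  if (sum(ok) < 2) stop("fewer than 2 complete pairs")
  a <- dosage_a[ok]; b <- dosage_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0)
    return(structure(0, constant = TRUE))
  stats::cor(a, b)^2
}

# r^2 of every column of d against index column j, pairwise complete,
# mean-imputing nothing: missing pairs excluded via complete-pair moments.
r2_against <- function(d, j) {
  x <- d[, j]
  vapply(seq_len(ncol(d)), function(k) {
    if (k == j) return(1)
    as.numeric(ld_r2(x, d[, k]))
  }, numeric(1))
}

#' Sliding-window LD pruning
#'
#' Greedy removal used before population-structure estimation: within each
#' window of `window_snps` position-sorted variants (advanced by `step`),
#' while any remaining pair has dosage r-squared exceeding `r2_max`, the
#' member of the worst-offending pair with the lower MAF is dropped (ties
#' broken by dropping the later position, then the lexicographically later
#' id). Deterministic; operates per chromosome.
#'
#' @param geno a [genotype_matrix()], variants position-sorted within
#'   chromosome.
#' @param r2_max r-squared above which one of a pair is removed
#'   (default 0.2).
#' @param window_snps,step window size and slide in variant counts.
#' @return character vector of retained variant ids (input order).
#' @export
ld_prune_window <- function(geno, r2_max = 0.2, window_snps = 50, step = 5) {
  v <- geno$variants
  maf <- maf_by_variant(geno)
  keep <- rep(TRUE, nrow(v))
  for (chr in unique(v$chromosome)) {
    idx <- which(v$chromosome == chr)
    idx <- idx[order(v$position_bp[idx])]
    starts <- seq(1, max(1, length(idx) - 1), by = step)
    for (s in starts) {
      win <- idx[s:min(s + window_snps - 1, length(idx))]
      win <- win[keep[win]]
      repeat {
        if (length(win) < 2) break
        d <- geno$dosages[, win, drop = FALSE]
        r2 <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))^2
        r2[is.na(r2)] <- 0
        diag(r2) <- 0
        if (max(r2) <= r2_max) break
        worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
        pair <- win[worst]
        drop <- pick_prune_victim(pair, maf, v)
        keep[drop] <- FALSE
        win <- setdiff(win, drop)
      }
    }
  }
  v$variant_id[keep]
}

# lower MAF loses; MAF tie -> later position; position tie -> later id
pick_prune_victim <- function(pair, maf, variants) {
  m <- maf[pair]
  if (m[1] != m[2]) return(pair[which.min(m)])
  pos <- variants$position_bp[pair]
  if (pos[1] != pos[2]) return(pair[which.max(pos)])
  pair[which.max(variants$variant_id[pair])]
}

#' Pairwise identity-by-state distance
#'
#' Similarity of two individuals at one variant is `(2 - |d_i - d_j|) / 2`;
#' the IBS similarity is its mean over variants where both calls are
#' present, and the distance is one minus that.
#'
#' @param geno a [genotype_matrix()] (typically LD-pruned).
#' @return symmetric n x n distance matrix with sample ids as dimnames.
#' @export
ibs_distance <- function(geno) {
  d <- geno$dosages
  present <- !is.na(d)
  I0 <- present & d == 0; I1 <- present & d == 1; I2 <- present & d == 2
  I0[is.na(I0)] <- FALSE; I1[is.na(I1)] <- FALSE; I2[is.na(I2)] <- FALSE
  storage.mode(I0) <- storage.mode(I1) <- storage.mode(I2) <- "double"
  P <- matrix(as.double(present), nrow(d))
  shared <- tcrossprod(P)                      # variants with both present
  same <- tcrossprod(I0) + tcrossprod(I1) + tcrossprod(I2)
  opp <- tcrossprod(I0, I2); opp <- opp + t(opp)   # |0 - 2| pairs
  if (any(shared == 0)) stop("individual pair with no shared non-missing variants")
  sum_abs <- shared - same + opp               # sum |d_i - d_j|
  dist <- sum_abs / (2 * shared)               # 1 - mean (2-|.|)/2
  dimnames(dist) <- list(rownames(d), rownames(d))
  dist
}

#' Population-structure components
#'
#' Classical (metric) multidimensional scaling of the pairwise IBS distance:
#' double-centering of the squared-distance matrix and projection on the
#' top-k eigenvectors scaled by the root eigenvalue (via
#' [stats::cmdscale()]). Components are ordered by decreasing eigenvalue;
#' their sign is arbitrary. `method = "pca"` instead runs a principal
#' component analysis of mean-imputed standardized dosages.
#'
#' @param geno a [genotype_matrix()], ideally LD-pruned.
#' @param k number of components (default 5).
#' @param method `"mds"` (classical MDS on IBS distance, default) or
#'   `"pca"`.
#' @return an object of class `mds_components`: list with `points`
#'   (n x k matrix, sample ids as rownames), `eig` (eigenvalues) and `k`.
#' @export
compute_mds <- function(geno, k = 5, method = c("mds", "pca")) {
  method <- match.arg(method)
  n <- n_individuals(geno)
  if (k >= n) stop("k must be smaller than the number of individuals")
  if (method == "mds") {
    dist <- ibs_distance(geno)
    fit <- stats::cmdscale(dist, k = k, eig = TRUE)
    pts <- fit$points
    if (ncol(pts) < k)
      warning(sprintf("only %d positive-eigenvalue components available (k = %d)",
                      ncol(pts), k))
    eig <- fit$eig
  } else {
    d <- geno$dosages
    mu <- colMeans(d, na.rm = TRUE)
    z <- sweep(d, 2, mu)
    z[is.na(z)] <- 0
    sdv <- apply(d, 2, stats::sd, na.rm = TRUE)
    sdv[sdv == 0 | is.na(sdv)] <- 1
    z <- sweep(z, 2, sdv, "/")
    pc <- stats::prcomp(z, center = FALSE)
    pts <- pc$x[, seq_len(min(k, ncol(pc$x))), drop = FALSE]
    rownames(pts) <- rownames(d)
    eig <- pc$sdev^2
  }
  colnames(pts) <- paste0("mds", seq_len(ncol(pts)))
  structure(list(points = pts, eig = eig, k = ncol(pts), method = method),
            class = "mds_components")
}
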