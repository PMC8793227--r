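#' Select risk variants by GWAS P-value threshold
#'
#' @param gwas a `gwas_result` from [gwas_scan()].
#' @param threshold P-value threshold; converged variants with `p <
#'   threshold` are retained, sorted by ascending P.
#' @return the selected subset of the scan, sorted by P.
#' @export
select_by_threshold <- function(gwas, threshold) {
  sel <- gwas[gwas$converged & !is.na(gwas$p) & gwas$p < threshold, ,
              drop = FALSE]
  if (!nrow(sel)) warning("no variants pass P < ", threshold)
  sel[order(sel$p), , drop = FALSE]
}

#' P-value-ordered LD clumping
#'
#' Greedy clumping of a selected variant set: repeatedly take the
#' lowest-P unassigned variant as index and remove all unassigned variants
#' on the same chromosome within `window_bp` of it whose dosage r-squared
#' with the index is at least `r2_max`. The retained set is the indices.
#' P ties are broken by position, then by variant id, so the procedure is
#' deterministic.
#'
#' @param selected a subset of a `gwas_result` (columns snp, chr, pos, p).
#' @param geno the [genotype_matrix()] providing dosage columns (the LD
#'   source).
#' @param r2_max clumping r-squared (default 0.3).
#' @param window_bp clumping radius in base pairs (default 250000, i.e.
#'   250 kB).
#' @return the retained subset, sorted by ascending P.
#' @export
ld_clump <- function(selected, geno, r2_max = 0.3, window_bp = 250000) {
  if (!nrow(selected)) return(selected)
  ord <- order(selected$p, selected$pos, selected$snp)
  sel <- selected[ord, , drop = FALSE]
  col <- match(sel$snp, geno$variants$variant_id)
  if (anyNA(col)) stop("selected variant(s) absent from genotype matrix")
  alive <- rep(TRUE, nrow(sel))
  retained <- logical(nrow(sel))
  for (i in seq_len(nrow(sel))) {
    if (!alive[i]) next
    retained[i] <- TRUE
    alive[i] <- FALSE
    near <- which(alive & sel$chr == sel$chr[i] &
                    abs(sel$pos - sel$pos[i]) <= window_bp)
    if (!length(near)) next
    x <- geno$dosages[, col[i]]
    r2 <- vapply(near, function(k)
      as.numeric(ld_r2(x, geno$dosages[, col[k]])), numeric(1))
    alive[near[r2 >= r2_max]] <- FALSE
  }
  sel[retained, , drop = FALSE]
}

#' Harmonize cohort risk variants against an external summary-statistics
#' panel
#'
#' For each retained cohort variant with its risk allele: variants absent
#' from the external panel are excluded (`unmatched`); variants whose
#' allele pair differs as a set from the external pair are excluded
#' (`mismatched`). When the allele sets agree, the weight is the external
#' log odds ratio if the external effect allele equals the cohort risk
#' allele, and its negation (flagged `swapped`) otherwise. `strict = TRUE`
#' instead excludes swapped-label variants; `drop_ambiguous = TRUE`
#' additionally excludes strand-ambiguous (A/T, C/G) variants.
#'
#' @param retained subset of a `gwas_result` with columns snp, a1, a2,
#'   risk_allele.
#' @param external a `summary_stats` panel.
#' @param strict exclude rather than sign-flip swapped effect alleles.
#' @param drop_ambiguous exclude strand-ambiguous allele pairs.
#' @return list: `weights` (data.frame snp, chr, pos, risk_allele, weight,
#'   swapped), `excluded` (data.frame snp, reason), `counts` (per reason).
#' @export
harmonize <- function(retained, external, strict = FALSE,
                      drop_ambiguous = FALSE) {
  if (anyDuplicated(external$variant_id))
    stop("duplicate external records for variant id(s): ",
         paste(unique(external$variant_id[duplicated(external$variant_id)]),
               collapse = ", "))
  hit <- match(retained$snp, external$variant_id)
  res <- data.frame(snp = retained$snp, chr = retained$chr,
                    pos = retained$pos, risk_allele = retained$risk_allele,
                    weight = rep(NA_real_, nrow(retained)),
                    swapped = rep(FALSE, nrow(retained)),
                    stringsAsFactors = FALSE)
  reason <- rep("", nrow(retained))
  reason[is.na(hit)] <- "unmatched"
  ok <- which(!is.na(hit))
  for (i in ok) {
    e <- external[hit[i], ]
    cohort_set <- sort(c(retained$a1[i], retained$a2[i]))
    ext_set <- sort(c(e$effect_allele, e$other_allele))
    if (!identical(cohort_set, ext_set)) { reason[i] <- "mismatched"; next }
    if (drop_ambiguous &&
        paste(cohort_set, collapse = "") %in% c("AT", "CG")) {
      reason[i] <- "ambiguous"; next
    }
    if (e$effect_allele == retained$risk_allele[i]) {
      res$weight[i] <- e$log_or
    } else if (strict) {
      reason[i] <- "swapped"
    } else {
      res$weight[i] <- -e$log_or
      res$swapped[i] <- TRUE
    }
  }
  matched <- reason == ""
  list(weights = res[matched, , drop = FALSE],
       excluded = data.frame(snp = retained$snp[!matched],
                             reason = reason[!matched],
                             stringsAsFactors = FALSE),
       counts = c(matched = sum(matched),
                  unmatched = sum(reason == "unmatched"),
                  mismatched = sum(reason == "mismatched"),
                  ambiguous = sum(reason == "ambiguous"),
                  swapped_excluded = sum(reason == "swapped")))
}

# Risk-allele count matrix for a harmonized weight table: per individual
# and variant, copies of the risk allele; the counted file allele is
# flipped (d -> 2 - d) where it is not the risk allele. Missing counts are
# mean-imputed as 2 x cohort risk-allele frequency.
risk_allele_count_matrix <- function(weights, geno, impute_missing = TRUE) {
  col <- match(weights$snp, geno$variants$variant_id)
  if (anyNA(col)) stop("weighted variant(s) absent from genotype matrix")
  x <- geno$dosages[, col, drop = FALSE]
  flip <- weights$risk_allele != geno$variants$allele_a1[col]
  x[, flip] <- 2L - x[, flip, drop = FALSE]
  storage.mode(x) <- "double"
  if (impute_missing && anyNA(x)) {
    freq <- colMeans(x, na.rm = TRUE) / 2
    for (j in which(colSums(is.na(x)) > 0))
      x[is.na(x[, j]), j] <- 2 * freq[j]
  }
  colnames(x) <- weights$snp
  x
}

#' Polygenic risk score (weighted sum of risk-allele counts)
#'
#' `PRS = sum_i w_i x_i` over the harmonized variant list, where `x_i` is
#' the individual's risk-allele count and `w_i` the external log odds
#' ratio aligned to the risk allele. A missing count is imputed as twice
#' the cohort risk-allele frequency of that variant.
#'
#' @param weights the `weights` data.frame from [harmonize()].
#' @param geno a [genotype_matrix()].
#' @return named numeric vector of raw scores, one per individual.
#' @export
compute_prs <- function(weights, geno) {
  if (!nrow(weights))
    return(stats::setNames(rep(0, n_individuals(geno)), rownames(geno$dosages)))
  x <- risk_allele_count_matrix(weights, geno)
  drop(x %*% weights$weight)[]
}

#' Standardize scores to cohort mean 0, SD 1
#'
#' @param raw numeric score vector (>= 2 values, non-constant); SD uses the
#'   n - 1 denominator.
#' @return standardized scores.
#' @export
standardize_scores <- function(raw) {
  if (length(raw) < 2) stop("need at least 2 individuals")
  s <- stats::sd(raw)
  if (s == 0) stop("scores are constant; cannot standardize")
  (raw - mean(raw)) / s
}

#' Per-individual count of risk alleles carried
#'
#' Unweighted row sum of risk-allele counts over the harmonized variant
#' list (companion summary to the score itself: e.g. whether every
#' individual carries at least one risk allele).
#'
#' @inheritParams compute_prs
#' @return named numeric vector of counts (missing genotypes mean-imputed
#'   as in [compute_prs()]).
#' @export
risk_allele_count_distribution <- function(weights, geno) {
  if (!nrow(weights))
    return(stats::setNames(rep(0, n_individuals(geno)), rownames(geno$dosages)))
  rowSums(risk_allele_count_matrix(weights, geno))
}

#' Clumping-and-thresholding PRS profiles at several P-value thresholds
#'
#' Full score construction per threshold: threshold selection from the
#' cohort scan, P-ordered LD clumping, allele harmonization against the
#' external panel, weighted risk-allele scoring and cohort standardization.
#'
#' @param gwas a `gwas_result`.
#' @param geno the cohort [genotype_matrix()] (LD source and score
#'   genotypes).
#' @param external a `summary_stats` panel supplying the weights.
#' @param thresholds P-value thresholds (default `c(5e-2, 5e-3, 5e-4)`).
#' @param clump_r2,clump_window_bp clumping parameters (defaults 0.3 and
#'   250000).
#' @param strict,drop_ambiguous passed to [harmonize()].
#' @return object of class `prs_profile`: per threshold a list with
#'   `scores` (data.frame sample_id, raw, standardized), `variants` (the
#'   harmonized weight table), `counts` (selected, clumped, matched);
#'   plus `stage_counts`, a thresholds x stages summary table.
#' @export
build_prs_profile <- function(gwas, geno, external,
                              thresholds = c(5e-2, 5e-3, 5e-4),
                              clump_r2 = 0.3, clump_window_bp = 250000,
                              strict = FALSE, drop_ambiguous = FALSE) {
  per <- lapply(thresholds, function(thr) {
    sel <- suppressWarnings(select_by_threshold(gwas, thr))
    clumped <- ld_clump(sel, geno, r2_max = clump_r2,
                        window_bp = clump_window_bp)
    harm <- harmonize(clumped, external, strict = strict,
                      drop_ambiguous = drop_ambiguous)
    raw <- compute_prs(harm$weights, geno)
    std <- if (nrow(harm$weights) && stats::sd(raw) > 0)
      standardize_scores(raw) else rep(NA_real_, length(raw))
    list(threshold = thr,
         scores = data.frame(sample_id = rownames(geno$dosages), raw = raw,
                             standardized = std, row.names = NULL,
                             stringsAsFactors = FALSE),
         variants = harm$weights, excluded = harm$excluded,
         counts = c(selected = nrow(sel), clumped = nrow(clumped),
                    matched = nrow(harm$weights)))
  })
  names(per) <- format(thresholds, scientific = TRUE)
  stage_counts <- do.call(rbind, lapply(per, function(p) p$counts))
  structure(list(thresholds = thresholds, profiles = per,
                 stage_counts = data.frame(threshold = names(per),
                                           stage_counts, row.names = NULL)),
            class = "prs_profile")
}

#' @export
print.prs_profile <- function(x, ...) {
  cat("clumping-and-thresholding PRS profile\n")
  print(x$stage_counts)
  invisible(x)
}
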