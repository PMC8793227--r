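#' @keywords internal
cohort_levels <- list(
  sex = c("male", "female"),
  age_category = c("16 and under", "17 to 40", "over 40"),
  marital_status = c("married/common-law", "single/divorced/widowed"),
  disease_subtype = c("Crohn's disease", "ulcerative colitis")
)

#' Assemble and validate a cohort table
#'
#' One row per genotyped individual, carrying the binary psychiatric
#' comorbidity status, the demographic covariates used throughout the
#' analysis, and the per-individual mediator expression value. MDS ancestry
#' components (`mds1` ... `mdsK`) are appended by [compute_mds()] /
#' [attach_mds()].
#'
#' @param df data.frame with columns `sample_id`, `pc_status` (0/1, 1 = with
#'   psychiatric comorbidity), `sex`, `age_category`, `marital_status`,
#'   `disease_subtype`, `mediator` (numeric).
#' @return the validated data.frame with class `cohort_table`, factor levels
#'   fixed to the canonical orderings.
#' @export
cohort_table <- function(df) {
  required <- c("sample_id", "pc_status", "sex", "age_category",
                "marital_status", "disease_subtype", "mediator")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("cohort table missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicated sample ids in cohort table")
  if (!all(df$pc_status %in% c(0L, 1L)))
    stop("pc_status must be 0/1")
  for (nm in names(cohort_levels)) {
    vals <- as.character(df[[nm]])
    bad <- setdiff(unique(vals), cohort_levels[[nm]])
    if (length(bad))
      stop(sprintf("unknown %s level(s): %s", nm, paste(bad, collapse = ", ")))
    df[[nm]] <- factor(vals, levels = cohort_levels[[nm]])
  }
  df$pc_status <- as.integer(df$pc_status)
  df$mediator <- as.numeric(df$mediator)
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Read / write the phenotype-covariate table
#'
#' Tab-separated with header `sample_id`, `pc_status`, `sex`,
#' `age_category`, `marital_status`, `disease_subtype`, `mediator`, plus any
#' `mds*` columns previously attached.
#'
#' @param path file path.
#' @return [read_cohort()]: a `cohort_table`; [write_cohort()]: `path`,
#'   invisibly.
#' @export
read_cohort <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "",
                          stringsAsFactors = FALSE,
                          colClasses = c(sample_id = "character"))
  cohort_table(df)
}

#' @rdname read_cohort
#' @param cohort a `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach MDS ancestry components to a cohort table
#'
#' @param cohort a `cohort_table`.
#' @param mds an `mds_components` object from [compute_mds()]; rows are
#'   matched to the cohort by sample id.
#' @return the cohort with columns `mds1` ... `mdsK` added.
#' @export
attach_mds <- function(cohort, mds) {
  pts <- mds$points
  idx <- match(cohort$sample_id, rownames(pts))
  if (anyNA(idx)) stop("MDS components missing for sample(s): ",
                       paste(cohort$sample_id[is.na(idx)], collapse = ", "))
  for (j in seq_len(ncol(pts))) cohort[[paste0("mds", j)]] <- pts[idx, j]
  cohort
}

#' Pearson chi-square P-value for an r x 2 contingency table
#'
#' Yates continuity correction is applied when the table is 2 x 2 and no
#' correction otherwise; this is the convention that reproduces the
#' published demographics of the motivating cohort.
#' @keywords internal
chisq_p <- function(tab) {
  suppressWarnings(
    stats::chisq.test(tab, correct = all(dim(tab) == c(2L, 2L)))$p.value
  )
}

#' Demographics report by comorbidity status
#'
#' For each demographic covariate, cross-tabulates its levels against
#' psychiatric-comorbidity status, computes column percentages (percent of
#' each PC group in each level, to one decimal) and a Pearson chi-square
#' P-value: Yates-corrected for 2 x 2 tables, uncorrected otherwise.
#' Covariate levels with a zero marginal total are dropped with a warning.
#'
#' @param cohort a `cohort_table` with at least 2 individuals per PC group.
#' @param covariates character vector of cohort columns to tabulate.
#' @return a list of class `demographics_report`: per covariate, a list with
#'   `counts` (levels x 2 matrix: columns without-PC, with-PC), `percent`
#'   (column percentages) and `p_value`.
#' @export
demographics_table <- function(cohort,
                               covariates = c("sex", "age_category",
                                              "disease_subtype",
                                              "marital_status")) {
  if (min(table(factor(cohort$pc_status, levels = 0:1))) < 2)
    stop("need at least 2 individuals per PC group")
  out <- lapply(covariates, function(nm) {
    tab <- table(cohort[[nm]], factor(cohort$pc_status, levels = 0:1))
    empty <- rowSums(tab) == 0
    if (any(empty)) {
      warning(sprintf("dropping empty %s level(s): %s", nm,
                      paste(rownames(tab)[empty], collapse = ", ")))
      tab <- tab[!empty, , drop = FALSE]
    }
    counts <- unclass(tab)
    colnames(counts) <- c("without_pc", "with_pc")
    pct <- round(100 * sweep(counts, 2, colSums(counts), "/"), 1)
    list(counts = counts, percent = pct, p_value = chisq_p(counts))
  })
  names(out) <- covariates
  structure(out, class = "demographics_report")
}

#' @export
print.demographics_report <- function(x, ...) {
  for (nm in names(x)) {
    cat(sprintf("%s (chi-square P = %.4g)\n", nm, x[[nm]]$p_value))
    disp <- x[[nm]]$counts
    pc <- x[[nm]]$percent
    for (i in seq_len(nrow(disp)))
      cat(sprintf("  %-26s %4d (%.1f%%)  %4d (%.1f%%)\n", rownames(disp)[i],
                  disp[i, 1], pc[i, 1], disp[i, 2], pc[i, 2]))
  }
  invisible(x)
}

#' Covariate design matrix for the association models
#'
#' Encodes the adjustment covariates the way the association models use
#' them: sex as a male indicator, age as two dummies against the reference
#' "17 to 40" (the largest group), marital status as a single/divorced/
#' widowed indicator, disease subtype as an ulcerative-colitis indicator,
#' plus the first `n_mds` MDS components when requested. No intercept
#' column; model-fitting code adds its own.
#'
#' @param cohort a `cohort_table`.
#' @param n_mds number of MDS components to include (0 to skip; requires
#'   `attach_mds()` to have been run when > 0).
#' @return numeric matrix with one row per individual.
#' @export
covariate_design <- function(cohort, n_mds = 0) {
  X <- cbind(
    sex_male = as.numeric(cohort$sex == "male"),
    age_16_under = as.numeric(cohort$age_category == "16 and under"),
    age_over_40 = as.numeric(cohort$age_category == "over 40"),
    marital_single = as.numeric(cohort$marital_status == "single/divorced/widowed"),
    subtype_uc = as.numeric(cohort$disease_subtype == "ulcerative colitis"))
  if (n_mds > 0) {
    cols <- paste0("mds", seq_len(n_mds))
    if (!all(cols %in% names(cohort)))
      stop("cohort lacks MDS columns; run compute_mds()/attach_mds() first")
    X <- cbind(X, as.matrix(cohort[cols]))
  }
  rownames(X) <- cohort$sample_id
  X
}
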