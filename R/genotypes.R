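#' Genotype matrix container
#'
#' Holds additive allele counts (dosages) for a cohort: an individuals x
#' variants integer matrix counting copies of `allele_a1` per variant, with
#' `NA` marking missing calls, plus per-variant chromosome, base-pair
#' position (1-based, as in bim files) and the two allele labels.
#'
#' @param dosages integer matrix, individuals x variants, values in
#'   \{0, 1, 2, NA\}.
#' @param sample_ids character vector of unique individual identifiers.
#' @param variant_ids character vector of unique variant identifiers.
#' @param chromosome per-variant chromosome label.
#' @param position_bp per-variant base-pair coordinate (non-negative integer).
#' @param allele_a1 per-variant counted allele (the allele `dosages` counts).
#' @param allele_a2 per-variant other allele.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages` (dimnames set to sample/variant ids) and `variants`
#'   (data.frame with columns variant_id, chromosome, position_bp,
#'   allele_a1, allele_a2).
#' @export
genotype_matrix <- function(dosages, sample_ids, variant_ids, chromosome,
                            position_bp, allele_a1, allele_a2) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  n <- length(sample_ids); m <- length(variant_ids)
  stopifnot(nrow(dosages) == n, ncol(dosages) == m,
            length(chromosome) == m, length(position_bp) == m,
            length(allele_a1) == m, length(allele_a2) == m)
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(variant_ids))
    stop("duplicated variant ids: ",
         paste(unique(variant_ids[duplicated(variant_ids)]), collapse = ", "))
  bad <- which(!(dosages %in% c(0L, 1L, 2L, NA)), arr.ind = FALSE)
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(dosages))
    stop(sprintf("dosage %s outside {0,1,2,NA} for sample '%s', variant '%s'",
                 dosages[bad[1]], sample_ids[ij[1]], variant_ids[ij[2]]))
  }
  if (any(position_bp < 0)) stop("negative base-pair positions")
  same <- allele_a1 == allele_a2
  if (any(same))
    stop("allele_a1 == allele_a2 for variant(s): ",
         paste(variant_ids[same], collapse = ", "))
  dimnames(dosages) <- list(as.character(sample_ids), as.character(variant_ids))
  structure(list(
    dosages = dosages,
    variants = data.frame(
      variant_id = as.character(variant_ids),
      chromosome = as.character(chromosome),
      position_bp = as.integer(position_bp),
      allele_a1 = as.character(allele_a1),
      allele_a2 = as.character(allele_a2),
      stringsAsFactors = FALSE)
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Number of individuals / variants in a genotype matrix
#' @param x a `genotype_matrix`.
#' @return integer count.
#' @export
n_individuals <- function(x) nrow(x$dosages)

#' @rdname n_individuals
#' @export
n_variants <- function(x) ncol(x$dosages)

#' Subset a genotype matrix by variant
#'
#' @param x a `genotype_matrix`.
#' @param keep variant ids (character) or a logical/integer index over
#'   variants.
#' @return a `genotype_matrix` restricted to the selected variants, order
#'   preserved as given by `keep`.
#' @export
subset_variants <- function(x, keep) {
  if (is.character(keep)) keep <- match(keep, x$variants$variant_id)
  v <- x$variants[keep, , drop = FALSE]
  genotype_matrix(x$dosages[, keep, drop = FALSE],
                  rownames(x$dosages), v$variant_id, v$chromosome,
                  v$position_bp, v$allele_a1, v$allele_a2)
}

# ---- text dialect ----------------------------------------------------------
# Two tab-separated files per prefix:
#   <prefix>.dose.tsv  header: sample_id <tab> variant ids...; one row per
#                      sample with dosages, "NA" for missing
#   <prefix>.vars.tsv  variant_id chromosome position_bp allele_a1 allele_a2

#' Read genotypes from disk
#'
#' Reads either the plain-text dialect (`<prefix>.dose.tsv` +
#' `<prefix>.vars.tsv`) or a PLINK bed/bim/fam triplet (`<prefix>.bed` etc.,
#' SNP-major; A1 is the counted allele).
#'
#' @param prefix path prefix of the file set (no extension).
#' @param dialect `"text"`, `"plink"`, or `"auto"` (detect from files
#'   present).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(prefix, dialect = c("auto", "text", "plink")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (file.exists(paste0(prefix, ".bed"))) "plink" else "text"
  }
  if (dialect == "text") read_genotypes_text(prefix) else read_genotypes_plink(prefix)
}

read_genotypes_text <- function(prefix) {
  dose_path <- paste0(prefix, ".dose.tsv")
  vars_path <- paste0(prefix, ".vars.tsv")
  for (p in c(dose_path, vars_path))
    if (!file.exists(p)) stop("missing companion file: ", p)
  vars <- utils::read.table(vars_path, header = TRUE, sep = "\t",
                            quote = "", comment.char = "",
                            colClasses = c("character", "character", "integer",
                                           "character", "character"))
  dose <- utils::read.table(dose_path, header = TRUE, sep = "\t",
                            quote = "", comment.char = "",
                            check.names = FALSE, colClasses = "character")
  sample_ids <- dose[[1]]
  d <- as.matrix(dose[, -1, drop = FALSE])
  if (!identical(colnames(d), vars$variant_id))
    stop("variant ids disagree between ", dose_path, " and ", vars_path)
  suppressWarnings(dn <- matrix(as.integer(d), nrow = nrow(d)))
  bad <- which(is.na(dn) & d != "NA")
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(d))
    stop(sprintf("non-numeric dosage '%s' for sample '%s', variant '%s'",
                 d[bad[1]], sample_ids[ij[1]], colnames(d)[ij[2]]))
  }
  out_of_range <- which(!is.na(dn) & (dn < 0L | dn > 2L))
  if (length(out_of_range)) {
    ij <- arrayInd(out_of_range[1], dim(d))
    stop(sprintf("dosage %s outside {0,1,2,NA} for sample '%s', variant '%s'",
                 d[out_of_range[1]], sample_ids[ij[1]], colnames(d)[ij[2]]))
  }
  genotype_matrix(dn, sample_ids, vars$variant_id, vars$chromosome,
                  vars$position_bp, vars$allele_a1, vars$allele_a2)
}

#' Write genotypes to disk
#'
#' @param x a [genotype_matrix()].
#' @param prefix output path prefix.
#' @param dialect `"text"` or `"plink"`.
#' @return `prefix`, invisibly.
#' @export
write_genotypes <- function(x, prefix, dialect = c("text", "plink")) {
  dialect <- match.arg(dialect)
  if (dialect == "text") write_genotypes_text(x, prefix) else write_genotypes_plink(x, prefix)
  invisible(prefix)
}

write_genotypes_text <- function(x, prefix) {
  d <- x$dosages
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, paste0(prefix, ".dose.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(x$variants, paste0(prefix, ".vars.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

# ---- PLINK bed/bim/fam -----------------------------------------------------
# SNP-major bed: magic 0x6c 0x1b, mode 0x01, then ceiling(n/4) bytes per
# variant; 2-bit codes per sample, least-significant pair first:
#   00 = homozygous A1 (dosage 2), 01 = missing, 10 = het, 11 = homozygous A2.

read_genotypes_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) if (!file.exists(p)) stop("missing companion file: ", p)
  fam <- utils::read.table(paths[3], header = FALSE, colClasses = "character")
  bim <- utils::read.table(paths[2], header = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a bed file (bad magic): ", paths[1])
  if (raw[3] != as.raw(0x01)) stop("only SNP-major bed files are supported")
  bpv <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bpv * m)
    stop(sprintf("bed payload size %d does not match %d variants x %d bytes",
                 length(body), m, bpv))
  bytes <- matrix(as.integer(body), nrow = bpv, ncol = m)
  # decode 2-bit fields for the 4 sample slots within each byte
  code_to_dose <- c(2L, NA, 1L, 0L)  # codes 0,1,2,3
  d <- matrix(NA_integer_, nrow = n, ncol = m)
  for (slot in 0:3) {
    idx <- seq.int(slot + 1L, by = 4L, length.out = bpv)
    idx <- idx[idx <= n]
    if (!length(idx)) next
    codes <- (bytes[seq_along(idx), , drop = FALSE] %/% 4L^slot) %% 4L
    d[idx, ] <- code_to_dose[codes + 1L]
  }
  genotype_matrix(d, fam[[2]], bim[[2]], bim[[1]], bim[[4]], bim[[5]], bim[[6]])
}

write_genotypes_plink <- function(x, prefix) {
  d <- x$dosages
  n <- nrow(d); m <- ncol(d)
  fam <- data.frame(rownames(d), rownames(d), 0, 0, 0, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  bim <- data.frame(x$variants$chromosome, x$variants$variant_id, 0,
                    x$variants$position_bp, x$variants$allele_a1,
                    x$variants$allele_a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  dose_to_code <- function(v) ifelse(is.na(v), 1L, c(3L, 2L, 0L)[v + 1L])
  bpv <- ceiling(n / 4)
  codes <- matrix(0L, nrow = 4L * bpv, ncol = m)
  codes[seq_len(n), ] <- dose_to_code(d)
  # pad slots beyond n stay 0 (homozygous A1 code is irrelevant; PLINK pads 0)
  w <- 4L^(0:3)
  bytes <- matrix(0L, nrow = bpv, ncol = m)
  for (slot in 0:3)
    bytes <- bytes + w[slot + 1L] * codes[seq.int(slot + 1L, by = 4L,
                                                  length.out = bpv), , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
}
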