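#' Read external GWAS summary statistics
#'
#' Parses a tab-separated panel with header columns `snp`, `chr`, `pos`,
#' `effect_allele`, `other_allele`, `effect`, `p`. The effect column may be
#' a natural-log odds ratio (`effect_column_type = "log_or"`) or an odds
#' ratio (`"or"`), in which case the natural log is taken on read; the
#' stored effect is always a log odds ratio, the PRS weight scale.
#'
#' Rows whose P-value falls outside (0, 1] are dropped; the count of dropped
#' rows is reported via `message()`.
#'
#' @param path path to the tab-separated file.
#' @param effect_column_type `"log_or"` (default) or `"or"`.
#' @return a data.frame of class `summary_stats` with columns `variant_id`,
#'   `chromosome`, `position_bp`, `effect_allele`, `other_allele`, `log_or`,
#'   `p_value`.
#' @export
read_summary_stats <- function(path, effect_column_type = c("log_or", "or")) {
  effect_column_type <- match.arg(effect_column_type)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "",
                          stringsAsFactors = FALSE)
  required <- c("snp", "chr", "pos", "effect_allele", "other_allele",
                "effect", "p")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("summary-statistics file missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  eff <- suppressWarnings(as.numeric(df$effect))
  if (anyNA(eff) && any(is.na(eff) & !is.na(df$effect)))
    stop("non-numeric effect value(s), e.g. '",
         df$effect[which(is.na(eff) & !is.na(df$effect))[1]], "'")
  log_or <- if (effect_column_type == "or") log(eff) else eff
  p <- suppressWarnings(as.numeric(df$p))
  keep <- !is.na(p) & p > 0 & p <= 1
  if (any(!keep))
    message(sum(!keep), " summary-statistics row(s) dropped: P-value outside (0,1]")
  out <- data.frame(variant_id = as.character(df$snp)[keep],
                    chromosome = as.character(df$chr)[keep],
                    position_bp = as.integer(df$pos)[keep],
                    effect_allele = as.character(df$effect_allele)[keep],
                    other_allele = as.character(df$other_allele)[keep],
                    log_or = log_or[keep],
                    p_value = p[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Write summary statistics in the canonical tab-separated layout
#'
#' The `effect` column written is the natural-log odds ratio.
#'
#' @param stats a `summary_stats` data.frame (see [read_summary_stats()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  out <- data.frame(snp = stats$variant_id, chr = stats$chromosome,
                    pos = stats$position_bp,
                    effect_allele = stats$effect_allele,
                    other_allele = stats$other_allele,
                    log_or = stats$log_or, p = stats$p_value)
  names(out)[names(out) == "log_or"] <- "effect"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
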