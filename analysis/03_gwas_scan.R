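#!/usr/bin/env Rscript
# Per-SNP additive logistic scan of comorbidity status adjusted for the
# five MDS components, sex, age, marital status and disease subtype.
# Exports the ranked association table with Manhattan/QQ plot data and the
# counts below the suggestive (5e-5) and genome-wide (5e-8) thresholds.

suppressPackageStartupMessages(library(prsmed))

geno <- read_genotypes("results/data/cohort_qc", dialect = "text")
cohort <- read_cohort("results/data/cohort_mds.pheno.tsv")

scan <- gwas_scan(geno, cohort, n_mds = 5)
res <- export_scan(scan, prefix = "results/gwas")
cat(sprintf("scan: %d SNPs fitted (%d skipped/unconverged)\n",
            sum(scan$converged), sum(!scan$converged)))
cat(sprintf("suggestive (P < 5e-5): %d; genome-wide (P < 5e-8): %d\n",
            res$n_suggestive, res$n_genomewide))
top <- head(res$table[c("snp", "chr", "pos", "or", "p", "risk_allele")], 5)
cat("top signals:\n")
print(top, row.names = FALSE)
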