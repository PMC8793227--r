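#!/usr/bin/env Rscript
# SNP-level QC (missingness >= 0.05, MAF < 0.05, exact HWE P < 5e-5) and
# population-structure estimation: LD pruning at r2 < 0.2 followed by
# classical MDS of the identity-by-state distance; the top five components
# become ancestry covariates for the scan.

suppressPackageStartupMessages(library(prsmed))
dir.create("results", showWarnings = FALSE)

geno <- read_genotypes("results/data/cohort", dialect = "text")
cohort <- read_cohort("results/data/cohort.pheno.tsv")

qc <- filter_snps(geno, maf_min = 0.05, miss_max = 0.05, hwe_min = 5e-5)
cat(sprintf("QC: %d of %d SNPs kept (low MAF %d, high missing %d, HWE fail %d)\n",
            qc$counts["kept"], n_variants(geno), qc$counts["low_maf"],
            qc$counts["high_missing"], qc$counts["hwe_fail"]))
write.table(qc$report, "results/qc_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_genotypes(qc$genotypes, "results/data/cohort_qc", dialect = "text")

pruned_ids <- ld_prune_window(qc$genotypes, r2_max = 0.2)
cat(sprintf("LD pruning for MDS: %d SNPs retained at r2 < 0.2\n",
            length(pruned_ids)))
mds <- compute_mds(subset_variants(qc$genotypes, pruned_ids), k = 5)
cohort_mds <- attach_mds(cohort, mds)
write_cohort(cohort_mds, "results/data/cohort_mds.pheno.tsv")
write.table(data.frame(sample_id = rownames(mds$points), mds$points),
            "results/mds_components.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("top-5 MDS eigenvalues:", signif(mds$eig[1:5], 3), "\n")
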