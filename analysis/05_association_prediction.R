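#!/usr/bin/env Rscript
# PRS-phenotype association (logit(status) ~ PRS, with and without the
# demographic covariates) reporting log OR, SE, Wald P and McFadden
# pseudo-R2 per threshold, followed by tenfold cross-validated prediction
# (logistic regression and linear-kernel SVM) with pooled out-of-fold
# ROC/AUC.

suppressPackageStartupMessages(library(prsmed))

geno <- read_genotypes("results/data/cohort_qc", dialect = "text")
cohort <- read_cohort("results/data/cohort_mds.pheno.tsv")
external <- read_summary_stats("results/data/cohort.sumstats.tsv")

scan <- gwas_scan(geno, cohort, n_mds = 5)
prof <- build_prs_profile(scan, geno, external)

assoc <- do.call(rbind, lapply(names(prof$profiles), function(nm) {
  p <- prof$profiles[[nm]]
  if (!p$counts["matched"] || anyNA(p$scores$standardized)) return(NULL)
  rbind(cbind(threshold = nm,
              fit_prs_association(p$scores$standardized, cohort, FALSE)),
        cbind(threshold = nm,
              fit_prs_association(p$scores$standardized, cohort, TRUE)))
}))
cat("PRS association (per SD of the standardized score):\n")
print(assoc[c("threshold", "model", "log_or", "se", "p", "r2")],
      row.names = FALSE, digits = 3)
write.table(assoc, "results/prs_association.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

covars <- covariate_design(cohort, n_mds = 0)
pred <- do.call(rbind, lapply(names(prof$profiles), function(nm) {
  p <- prof$profiles[[nm]]
  if (!p$counts["matched"] || anyNA(p$scores$standardized)) return(NULL)
  prs <- p$scores$standardized
  do.call(rbind, lapply(c("logistic", "svm"), function(mdl) {
    rbind(
      data.frame(threshold = nm, model = mdl, adjusted = FALSE,
                 auc = crossval_predict(cbind(prs = prs), cohort$pc_status,
                                        mdl, k = 10, seed = 2026)$auc),
      data.frame(threshold = nm, model = mdl, adjusted = TRUE,
                 auc = crossval_predict(cbind(prs = prs, covars),
                                        cohort$pc_status, mdl, k = 10,
                                        seed = 2026)$auc))
  }))
}))
cat("\ntenfold cross-validated AUC (pooled out-of-fold):\n")
print(pred, row.names = FALSE, digits = 3)
write.table(pred, "results/prediction_auc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
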