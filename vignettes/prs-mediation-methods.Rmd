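---
title: "Methods: polygenic scores and causal mediation for psychiatric comorbidity in IBD"
author: "prsmed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic scores and causal mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

About 40% of persons with inflammatory bowel disease (IBD) develop a
psychiatric comorbidity (PC) such as depression or anxiety. `prsmed`
implements, end to end, a genetic-liability analysis of that binary
phenotype in an IBD cohort: SNP quality control, population-structure
estimation, a covariate-adjusted association scan, a
clumping-and-thresholding (C+T) polygenic risk score weighted by an
external GWAS, PRS–phenotype association and prediction, and a
regression-based causal mediation decomposition through a gene-expression
mediator (the *RBPMS* expression role). Every stage is exercised against a
synthetic-cohort generator with known ground truth, which is what the test
suite and the acceptance script measure.

The core quantities are:

* **Per-SNP scan.** For each variant, the additive logistic model
  `logit(PC) ~ dosage + MDS1..5 + sex + age + marital + subtype`, fitted by
  maximum likelihood. Dosages are oriented to count the minor allele, so
  the reported odds ratio is per minor-allele copy and the risk allele is
  the minor allele when OR > 1 and the major allele when OR < 1 (minor,
  with a tie flag, at exactly 1).
* **PRS.** `PRS_i = sum_j w_j x_ij` over risk SNPs selected at P-value
  thresholds 5e-2 / 5e-3 / 5e-4, LD-clumped at r² = 0.3 within 250 kB,
  and harmonized against the external panel; `x_ij` is the individual's
  risk-allele count and `w_j` the external log odds ratio aligned to the
  risk allele. Scores are standardized over the whole analysis cohort.
* **Association.** `logit(PC) ~ PRS` and
  `logit(PC) ~ PRS + sex + age + marital + subtype`, reporting the PRS log
  OR per SD, Wald SE and P, and McFadden pseudo-R²
  (`1 - llik_model / llik_null`).
* **Prediction.** Stratified tenfold cross-validation of logistic
  regression and a linear-kernel SVM (cost 1); the AUC is the Mann–Whitney
  concordance of the pooled out-of-fold scores.
* **Mediation.** Outcome model
  `logit(PC) = θ0 + θ1·PRS + θ2·mediator + covariates` and mediator model
  `mediator = φ0 + φ1·PRS + covariates`. Direct effect = θ1, indirect
  effect = φ1·θ2, total = θ1 + φ1·θ2, proportion mediated =
  φ1·θ2 / (φ1·θ2 + θ1), with percentile bootstrap confidence intervals
  over resampled individuals.

## Key parameters and defaults

| parameter | default | role |
|---|---|---|
| QC: missing rate | remove if ≥ 0.05 | genotyping quality |
| QC: MAF | remove if < 0.05 (equality keeps) | rare-variant exclusion |
| QC: HWE exact P | remove if < 5e-5 | genotyping artifact filter |
| MDS | top 5 components, IBS distance, LD-pruned at r² < 0.2 | ancestry covariates |
| C+T thresholds | 5e-2, 5e-3, 5e-4 | selection stringency |
| Clumping | r² = 0.3, window 250 kB, P-ordered greedy | independent signals |
| CV | 10 folds, stratified, seeded | prediction assessment |
| Bootstrap | B = 1000, percentile (type-1 quantiles) | mediation CIs |

Boundary conventions follow the QC wording exactly: missingness removes at
equality, MAF keeps at equality. The exact Hardy–Weinberg test is the
conditional enumeration test (heterozygote counts no more probable than
the observed one, given the allele counts); a chi-square approximation is
only used as a large-sample cross-check in the tests.

## Design choices where the design was open

* **Chi-square convention for the demographics table.** Yates continuity
  correction on 2×2 tables and plain Pearson on larger tables. This is the
  unique convention under which all four published demographic P-values
  (0.054, 0.4564, 0.444, 0.799) are reproduced from the printed counts,
  and it is flagged here because the source analysis does not state its
  correction behavior.
* **"Pruning" of selected risk SNPs** is implemented as P-value-ordered
  greedy clumping (the most significant variant of each correlated cluster
  is the one retained). Plain MAF-based pairwise pruning would discard top
  signals arbitrarily; position- then id-ordered tie-breaks make the result
  deterministic. The MDS pruning step, by contrast, is windowed pairwise
  pruning (50 SNPs, step 5 — window parameters are conventional, exposed
  as arguments).
* **Allele harmonization.** Variants absent from the external panel or
  with a different allele *set* are excluded. When the external effect
  allele is the other member of the same pair, the default is the
  statistically correct sign flip (flagged `swapped`); `strict = TRUE`
  excludes such variants instead, mirroring a blanket
  "mismatched alleles were excluded" policy. Strand-ambiguous A/T and C/G
  pairs are not excluded by default (`drop_ambiguous` exists) because the
  synthetic panel shares strand by construction.
* **Missing genotypes in scoring** are mean-imputed as 2 × the cohort
  risk-allele frequency, the standard scoring convention.
* **Wald tests** for the scan and the PRS term (estimate/SE from observed
  information); separation and non-convergence are flagged, never rescued
  by penalization, so a flagged variant is transparently absent from
  downstream stages.
* **Age coding**: two dummies against the largest category ("17 to 40").
* **MDS vs PCA.** Population structure is estimated by classical metric
  MDS of the 1 − IBS distance (double-centered squared distances, top-k
  eigenvectors scaled by the root eigenvalue). PCA of standardized dosages
  is available behind `method = "pca"`; component signs are arbitrary and
  all tests are sign-invariant.
* **Mediation on the log-odds scale.** The decomposition uses the product
  of coefficients exactly as defined above. With a common outcome
  (prevalence near 39%), odds-ratio non-collapsibility means θ1 is a
  conditional effect and the decomposition is exact only under a
  rare-outcome approximation; the package implements the formulas verbatim
  and reports an opposite-sign warning whenever direct and indirect
  effects disagree in sign (the proportion is then reported unclipped).
  Bootstrap resampling is unstratified by default (`stratified` exists);
  significance stars record whether the percentile CI at the matching
  level (95/99/99.9%) excludes zero.

## The synthetic cohort: what it emulates, and what it does not

`sim_config()` defaults are the study conditions: 240 individuals with a
target case fraction 94/240; covariates drawn from the published
demographic marginals (43% male, 5/60/35% age bands, 72% married, 50%
Crohn's); an external panel with effective size 39,597 (so nominal
standard errors near 0.015); and mediator/outcome coefficients
φ1 = 0.055, θ2 = 0.4, θ1 = 0.15, giving an implied proportion mediated of
0.022/0.172 ≈ 0.128 — the magnitude of mediation reported for the real
cohort. The outcome intercept is solved numerically so the expected case
fraction hits the target.

Genotypes come from a Gaussian copula: within blocks of 10 consecutive
SNPs a latent Gaussian with exchangeable correlation 0.8 is thresholded at
each SNP's Hardy–Weinberg genotype frequencies (MAF drawn uniformly on
0.05–0.5). This gives controllable block LD but only approximate r²
targets, so LD-dependent tests assert orderings, not exact values. The
generator does **not** emulate realistic human LD maps, allele-frequency
spectra, ancestry admixture, or sex chromosomes; the external panel
reports each variant's *own* causal effect plus noise, not the LD-tagged
marginal effect a real GWAS would see. Outcomes are generated on the true
genetic score, so attenuation from noisy external weights is part of what
the pipeline must tolerate. Passing tests therefore demonstrate the
correctness and calibration of the machinery, not performance on real
genotype data.

## Numerical choices

* The per-SNP logistic fitter is an IRLS/Newton solver converging on a
  maximum coefficient change below 1e-8 within 25 iterations; divergence
  (|β| escaping) or hitting the iteration cap flags the fit unconverged,
  which downstream stages treat as missing. Its estimates agree with
  `stats::glm` and an independent Newton oracle to well below 1e-6.
* Bootstrap refits reuse the design matrix and the package IRLS with a
  warm start from the full-data fit; non-converged resamples are dropped
  and counted (warning above 10%, error above 50%).
* Percentile CIs use empirical (type-1) quantiles, so B = 2 degenerates
  to the min/max of the two replicates.
* Constant dosage columns, all-missing variants, empty threshold
  selections, degenerate (single-class) outcomes and constant scores all
  raise explicit errors or flagged skips rather than producing numbers.

## Problem sizes used by the tests

Unit tests run on fixtures of tens of individuals. The recovery checks use
20 seeds at n = 4000 with 1000 SNPs (20 causal, no LD, strong external
weights, selection gate open at threshold 1.0): the in-sample C+T
selection that the study-scale analysis necessarily performs is
winner's-curse biased when per-SNP effects are weak, so the recovery
configuration opens the selection gate to isolate scoring, harmonization
and mediation from selection noise; a separate property test runs the full
thresholded pipeline under block LD at a wider tolerance. Bootstrap
coverage uses 60 replications of B = 200 at n = 1000; null calibration
uses 500 null SNPs at n = 2000. These sizes were chosen so the whole suite
runs in a few minutes on one CPU while keeping Monte-Carlo slack small
relative to the asserted tolerances.

## Known limitations

* Weights from a phenotype-mismatched external GWAS attenuate the PRS;
  at n = 240 the per-threshold scores are unstable and can flip sign, as
  the study-scale driver scripts show. This mirrors the small-sample
  reality of the motivating analysis rather than a defect of the code.
* The mediation decomposition ignores exposure–mediator interaction and
  assumes no unmeasured mediator–outcome confounding; no sensitivity
  analysis for the latter is provided.
* Sample-level QC (call rate, relatedness, sex concordance, ancestry
  against a reference panel) is out of scope; genotypes are assumed to
  have passed it upstream.
* Only biallelic SNPs with integer dosages are supported; VCF input and
  imputation dosages are not.
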