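#' Simulation configuration for a synthetic IBD comorbidity cohort
#'
#' Defaults emulate the motivating study cohort at desk scale: 240
#' individuals with a target case fraction of 94/240, covariates drawn
#' from the published demographic marginals, an external summary panel of
#' effective size 39,597 (12,882 cases + 26,715 controls), and a mediator
#' on the causal path from the polygenic score to the binary outcome with
#' a study-scale implied proportion mediated of about 0.13
#' (`phi1 * theta2 / (phi1 * theta2 + theta1)` = 0.022 / 0.172).
#'
#' @param n_individuals cohort size (default 240).
#' @param n_snps number of biallelic SNPs (default 2000).
#' @param n_causal number of causal variants (default 50).
#' @param maf_range uniform range minor allele frequencies are drawn from.
#' @param ld_block_size SNPs per LD block (default 10).
#' @param ld_rho latent exchangeable correlation within a block
#'   (default 0.8).
#' @param beta_sd SD of causal true effects (log-odds per allele in the
#'   external phenotype; default 0.2).
#' @param external_noise_sd noise scale of external weights; the
#'   per-variant standard error is `external_noise_sd / sqrt(n_external)`
#'   (default 3, giving GWAS-realistic SEs near 0.015).
#' @param n_external effective external panel size (default 39597).
#' @param swap_fraction fraction of external records emitted with the
#'   allele labels swapped (effect reported for the other allele;
#'   default 0).
#' @param discordant_fraction fraction of external records emitted with a
#'   discordant (third) allele, which harmonization must exclude
#'   (default 0).
#' @param covariate_freqs named list of marginal frequencies: `male`,
#'   `age` (length-3, ordered 16-and-under / 17-to-40 / over-40),
#'   `married`, `crohns`. Defaults are the study marginals.
#' @param phi1_true exposure-to-mediator path coefficient (default 0.055).
#' @param mediator_sd residual SD of the mediator (default 1).
#' @param theta1_true direct effect per standardized-score unit
#'   (default 0.15).
#' @param theta2_true mediator coefficient on the outcome logit
#'   (default 0.4).
#' @param case_fraction target case fraction; the intercept `theta0` is
#'   solved to hit it in expectation (default 94/240).
#' @param missing_rate completely-at-random missing-genotype rate
#'   (default 0.01).
#' @param outcome_cov_effects,mediator_cov_effects named length-5 numeric
#'   vectors of covariate effects (order: male, age 16-and-under, age
#'   over-40, single, ulcerative colitis) on the outcome logit and the
#'   mediator mean.
#' @param seed RNG seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 240, n_snps = 2000, n_causal = 50,
                       maf_range = c(0.05, 0.5), ld_block_size = 10,
                       ld_rho = 0.8, beta_sd = 0.2,
                       external_noise_sd = 3, n_external = 39597,
                       swap_fraction = 0, discordant_fraction = 0,
                       covariate_freqs = list(
                         male = 104 / 240,
                         age = c(12, 144, 84) / 240,
                         married = 172 / 240,
                         crohns = 119 / 240),
                       phi1_true = 0.055, mediator_sd = 1,
                       theta1_true = 0.15, theta2_true = 0.4,
                       case_fraction = 94 / 240, missing_rate = 0.01,
                       outcome_cov_effects = c(male = -0.4,
                                               age_16_under = -0.3,
                                               age_over_40 = -0.1,
                                               single = 0.1, uc = -0.2),
                       mediator_cov_effects = c(male = 0.1,
                                                age_16_under = 0,
                                                age_over_40 = -0.05,
                                                single = 0, uc = 0.05),
                       seed = 1) {
  stopifnot(maf_range[1] > 0, maf_range[1] < maf_range[2],
            maf_range[2] <= 0.5, abs(ld_rho) < 1, n_causal <= n_snps,
            case_fraction > 0, case_fraction < 1,
            missing_rate >= 0, missing_rate < 1,
            swap_fraction >= 0, swap_fraction <= 1,
            discordant_fraction >= 0, discordant_fraction <= 1,
            abs(sum(covariate_freqs$age) - 1) < 1e-8)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate cohort genotypes with block LD
#'
#' Gaussian-copula generator: within each block of `ld_block_size`
#' consecutive SNPs a latent Gaussian with exchangeable correlation
#' `ld_rho` is thresholded at each SNP's Hardy-Weinberg genotype
#' frequencies for its drawn MAF, producing \{0,1,2\} dosages with
#' within-block LD. Missing entries are set completely at random at
#' `missing_rate`. Blocks are laid out across chromosomes 1-22 with 10 kb
#' SNP spacing within a block and 1 Mb gaps between blocks.
#'
#' @param config a [sim_config()].
#' @return list: `genotypes` (a [genotype_matrix()]), `maf` (the drawn
#'   per-SNP MAFs), `block` (per-SNP block index).
#' @export
simulate_genotypes <- function(config) {
  set.seed(config$seed)
  n <- config$n_individuals; m <- config$n_snps
  bsz <- config$ld_block_size
  block <- rep(seq_len(ceiling(m / bsz)), each = bsz)[seq_len(m)]
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  d <- matrix(0L, n, m)
  rho <- config$ld_rho
  for (b in unique(block)) {
    cols <- which(block == b)
    shared <- stats::rnorm(n)
    z <- sqrt(rho) * shared +
      sqrt(1 - rho) * matrix(stats::rnorm(n * length(cols)), n)
    u <- stats::pnorm(z)
    p <- maf[cols]
    p0 <- rep((1 - p)^2, each = n)        # homozygous major
    p01 <- rep((1 - p)^2 + 2 * p * (1 - p), each = n)
    d[, cols] <- (u > p0) + (u > p01)
  }
  if (config$missing_rate > 0)
    d[stats::runif(n * m) < config$missing_rate] <- NA_integer_
  # layout: blocks dealt across chromosomes, 10 kb within-block spacing,
  # 1 Mb between consecutive blocks on the same chromosome
  chr <- ((block - 1L) %% 22L) + 1L
  within <- stats::ave(seq_len(m), block, FUN = seq_along)
  block_on_chr <- stats::ave(block, chr, FUN = function(v)
    match(v, unique(v)))
  pos <- (block_on_chr - 1L) * 1000000L + within * 10000L
  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, m, replace = TRUE)
  a2 <- vapply(a1, function(a) sample(setdiff(bases, a), 1), character(1))
  geno <- genotype_matrix(d, sprintf("ind%04d", seq_len(n)),
                          sprintf("rs%05d", seq_len(m)), chr, pos, a1,
                          unname(a2))
  list(genotypes = geno, maf = maf, block = block)
}

#' Simulate an external GWAS summary-statistics panel
#'
#' Shares variant ids and alleles with the simulated cohort genotypes.
#' `n_causal` variants (the first of each of as many blocks) carry true
#' effects drawn `N(0, beta_sd^2)`; all others are null. Each reported
#' effect is the true effect plus Gaussian noise with the nominal standard
#' error `external_noise_sd / sqrt(n_external)`, and the P-value is the
#' Wald test of the noisy effect against that SE. Optionally a fraction of
#' records is emitted with swapped allele labels (effect reported for the
#' other allele, sign negated) and a fraction with a discordant third
#' allele, to exercise harmonization.
#'
#' @param config a [sim_config()].
#' @param sim result of [simulate_genotypes()].
#' @return list: `stats` (a `summary_stats` data.frame), `truth`
#'   (data.frame variant_id, beta_true, causal, swapped, discordant).
#' @export
simulate_summary_stats <- function(config, sim) {
  set.seed(config$seed + 1L)
  geno <- sim$genotypes
  m <- n_variants(geno)
  v <- geno$variants
  # causal variants: first SNP of successive blocks, spreading signal
  first_of_block <- which(!duplicated(sim$block))
  causal_idx <- first_of_block[seq_len(min(config$n_causal,
                                           length(first_of_block)))]
  if (length(causal_idx) < config$n_causal)
    causal_idx <- c(causal_idx,
                    setdiff(seq_len(m), causal_idx)[
                      seq_len(config$n_causal - length(causal_idx))])
  beta_true <- numeric(m)
  beta_true[causal_idx] <- stats::rnorm(config$n_causal, 0, config$beta_sd)
  se <- config$external_noise_sd / sqrt(config$n_external)
  effect <- beta_true + stats::rnorm(m, 0, se)
  p <- 2 * stats::pnorm(-abs(effect / se))
  p <- pmax(p, .Machine$double.xmin)
  effect_allele <- v$allele_a1
  other_allele <- v$allele_a2
  swapped <- stats::runif(m) < config$swap_fraction
  effect_allele[swapped] <- v$allele_a2[swapped]
  other_allele[swapped] <- v$allele_a1[swapped]
  effect[swapped] <- -effect[swapped]
  discordant <- stats::runif(m) < config$discordant_fraction
  bases <- c("A", "C", "G", "T")
  if (any(discordant))
    other_allele[discordant] <- vapply(which(discordant), function(i)
      sample(setdiff(bases, c(effect_allele[i], other_allele[i])), 1),
      character(1))
  stats <- data.frame(variant_id = v$variant_id, chromosome = v$chromosome,
                      position_bp = v$position_bp,
                      effect_allele = effect_allele,
                      other_allele = other_allele,
                      log_or = effect, p_value = p,
                      stringsAsFactors = FALSE)
  class(stats) <- c("summary_stats", "data.frame")
  list(stats = stats,
       truth = data.frame(variant_id = v$variant_id, beta_true = beta_true,
                          causal = seq_len(m) %in% causal_idx,
                          swapped = swapped, discordant = discordant,
                          stringsAsFactors = FALSE))
}

#' Simulate phenotypes, covariates and the mediator
#'
#' The true genetic score is `s = sum_j beta_j * dosage_j`, standardized
#' over the cohort (missing dosages mean-imputed for scoring). The
#' mediator is `phi1 * s + covariate effects + N(0, mediator_sd^2)`; the
#' outcome is Bernoulli with
#' `logit(p) = theta0 + theta1 * s + theta2 * mediator + covariate terms`,
#' where `theta0` is solved so the expected case fraction equals the
#' configured target. Covariates are drawn independently from the
#' configured marginal frequencies.
#'
#' @param config a [sim_config()].
#' @param sim result of [simulate_genotypes()].
#' @param truth the `truth` data.frame from [simulate_summary_stats()].
#' @return list: `cohort` (a `cohort_table`), `true_score` (standardized),
#'   `theta0`.
#' @export
simulate_phenotypes <- function(config, sim, truth) {
  set.seed(config$seed + 2L)
  geno <- sim$genotypes
  n <- n_individuals(geno)
  d <- geno$dosages
  storage.mode(d) <- "double"
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- mu[j]
  }
  s_raw <- drop(d %*% truth$beta_true)
  if (stats::sd(s_raw) == 0) stop("degenerate true score (no causal variation)")
  s <- standardize_scores(s_raw)
  fq <- config$covariate_freqs
  sex <- ifelse(stats::runif(n) < fq$male, "male", "female")
  age <- sample(cohort_levels$age_category, n, replace = TRUE, prob = fq$age)
  marital <- ifelse(stats::runif(n) < fq$married, "married/common-law",
                    "single/divorced/widowed")
  subtype <- ifelse(stats::runif(n) < fq$crohns, "Crohn's disease",
                    "ulcerative colitis")
  Xc <- cbind(as.numeric(sex == "male"),
              as.numeric(age == "16 and under"),
              as.numeric(age == "over 40"),
              as.numeric(marital == "single/divorced/widowed"),
              as.numeric(subtype == "ulcerative colitis"))
  mediator <- config$phi1_true * s +
    drop(Xc %*% config$mediator_cov_effects) +
    stats::rnorm(n, 0, config$mediator_sd)
  eta <- config$theta1_true * s + config$theta2_true * mediator +
    drop(Xc %*% config$outcome_cov_effects)
  theta0 <- stats::uniroot(function(t0)
    mean(stats::plogis(t0 + eta)) - config$case_fraction,
    c(-20, 20))$root
  y <- as.integer(stats::runif(n) < stats::plogis(theta0 + eta))
  if (length(unique(y)) < 2)
    stop("degenerate outcome (all cases or all controls); adjust theta0/case_fraction")
  cohort <- cohort_table(data.frame(
    sample_id = rownames(geno$dosages), pc_status = y, sex = sex,
    age_category = as.character(age), marital_status = marital,
    disease_subtype = subtype, mediator = mediator,
    stringsAsFactors = FALSE))
  list(cohort = cohort, true_score = s, theta0 = theta0)
}

#' Simulate a complete synthetic cohort with ground truth
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_summary_stats()] and [simulate_phenotypes()] and assembling
#' the ground-truth record, including the implied true proportion mediated
#' `phi1 * theta2 / (phi1 * theta2 + theta1)`.
#'
#' @param config a [sim_config()].
#' @return list: `genotypes`, `sumstats`, `cohort`, `true_score`, `truth`
#'   (list with per-variant causal table, `phi1_true`, `theta1_true`,
#'   `theta2_true`, `theta0`, `implied_proportion_mediated`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  sim <- simulate_genotypes(config)
  ss <- simulate_summary_stats(config, sim)
  ph <- simulate_phenotypes(config, sim, ss$truth)
  ind <- config$phi1_true * config$theta2_true
  list(genotypes = sim$genotypes, sumstats = ss$stats, cohort = ph$cohort,
       true_score = ph$true_score, maf = sim$maf, block = sim$block,
       truth = list(variants = ss$truth,
                    phi1_true = config$phi1_true,
                    theta1_true = config$theta1_true,
                    theta2_true = config$theta2_true,
                    theta0 = ph$theta0,
                    implied_proportion_mediated =
                      ind / (ind + config$theta1_true)))
}

#' Write a simulated cohort to disk
#'
#' Emits the genotype file set (text dialect or PLINK), the
#' summary-statistics TSV, the phenotype TSV and a ground-truth JSON
#' manifest.
#'
#' @param simdata result of [simulate_cohort()].
#' @param prefix output path prefix.
#' @param dialect genotype dialect (`"text"` or `"plink"`).
#' @return `prefix`, invisibly.
#' @export
write_simulated_cohort <- function(simdata, prefix, dialect = "text") {
  write_genotypes(simdata$genotypes, prefix, dialect = dialect)
  write_summary_stats(simdata$sumstats, paste0(prefix, ".sumstats.tsv"))
  write_cohort(simdata$cohort, paste0(prefix, ".pheno.tsv"))
  truth <- simdata$truth
  truth$variants <- truth$variants[truth$variants$causal |
                                     truth$variants$swapped |
                                     truth$variants$discordant, ]
  jsonlite::write_json(truth, paste0(prefix, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
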