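# small helper: a gwas_result-shaped data.frame for threshold/clump tests
fake_gwas <- function(snp, p, chr = "1", pos = seq_along(snp) * 1000,
                      a1 = "A", a2 = "G", risk = "A") {
  data.frame(snp = snp, chr = chr, pos = pos, a1 = a1, a2 = a2,
             p = p, or = 1.5, log_or = 0.4, converged = TRUE,
             risk_allele = risk, stringsAsFactors = FALSE)
}

test_that("threshold selection keeps converged variants below P, sorted", {
  gw <- fake_gwas(c("a", "b", "c"), c(0.04, 0.004, 0.0004))
  expect_equal(select_by_threshold(gw, 5e-3)$snp, c("c", "b"))
  expect_equal(nrow(select_by_threshold(gw, 1.0)), 3)
  expect_warning(sel <- select_by_threshold(gw, 1e-6), "no variants")
  expect_equal(nrow(sel), 0)
  gw$converged[2] <- FALSE
  expect_equal(select_by_threshold(gw, 1.0)$snp, c("c", "a"))
})

test_that("clumping retains the most significant variant of a correlated pair", {
  set.seed(31)
  x <- sample(0:2, 80, TRUE)
  d <- cbind(x, x, sample(0:2, 80, TRUE))
  g <- make_geno(d, pos = c(100000L, 200000L, 500000L))
  # v1/v2 identical (r2 = 1), 100 kb apart
  gw <- fake_gwas(c("v01", "v02", "v03"), c(1e-6, 1e-3, 0.02),
                  pos = c(100000, 200000, 500000))
  kept <- ld_clump(gw, g, r2_max = 0.3, window_bp = 250000)
  expect_true("v01" %in% kept$snp)
  expect_false("v02" %in% kept$snp)
  # single variant: itself
  expect_equal(ld_clump(gw[1, ], g)$snp, "v01")
  # 300 kb apart: outside the window, both retained whatever the r2
  gw2 <- fake_gwas(c("v01", "v02"), c(1e-6, 1e-3), pos = c(100000, 400000))
  g2 <- make_geno(cbind(x, x), pos = c(100000L, 400000L))
  expect_equal(nrow(ld_clump(gw2, g2, window_bp = 250000)), 2)
})

test_that("clumping equals the brute-force greedy oracle on small fixtures", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 50; m <- 12
    base <- sample(0:2, n, TRUE)
    d <- sapply(1:m, function(j) {
      flip <- runif(n) < 0.4
      out <- base; out[flip] <- sample(0:2, sum(flip), TRUE); as.integer(out)
    })
    pos <- sort(sample(1:1000000, m))
    g <- make_geno(d, pos = pos)
    gw <- fake_gwas(g$variants$variant_id, runif(m), pos = pos)
    mine <- ld_clump(gw, g, r2_max = 0.25, window_bp = 300000)
    oracle <- clump_oracle(gw, g, r2_max = 0.25, window_bp = 300000)
    expect_equal(sort(mine$snp), sort(oracle))
  }
})

test_that("harmonization matches, flips, and excludes per the allele rules", {
  retained <- data.frame(
    snp = c("m", "sw", "mis", "un", "amb"),
    chr = "1", pos = 1:5 * 1000,
    a1 = c("A", "A", "A", "A", "A"),
    a2 = c("G", "G", "G", "G", "T"),
    risk_allele = c("A", "A", "A", "A", "A"), stringsAsFactors = FALSE)
  external <- data.frame(
    variant_id = c("m", "sw", "mis", "amb"),
    chromosome = "1", position_bp = c(1000, 2000, 3000, 5000),
    effect_allele = c("A", "G", "A", "A"),
    other_allele = c("G", "A", "C", "T"),
    log_or = c(0.2, 0.2, 0.3, 0.1), p_value = 0.01,
    stringsAsFactors = FALSE)
  h <- harmonize(retained, external)
  expect_equal(h$weights$weight[h$weights$snp == "m"], 0.2)
  expect_equal(h$weights$weight[h$weights$snp == "sw"], -0.2)  # sign flip
  expect_true(h$weights$swapped[h$weights$snp == "sw"])
  expect_equal(sort(h$excluded$snp), c("mis", "un"))
  expect_equal(h$excluded$reason[h$excluded$snp == "mis"], "mismatched")
  expect_equal(h$excluded$reason[h$excluded$snp == "un"], "unmatched")
  # strict mode excludes the swapped record instead
  hs <- harmonize(retained, external, strict = TRUE)
  expect_false("sw" %in% hs$weights$snp)
  expect_equal(hs$counts[["swapped_excluded"]], 1)
  # ambiguous A/T dropped only under drop_ambiguous
  expect_true("amb" %in% h$weights$snp)
  ha <- harmonize(retained, external, drop_ambiguous = TRUE)
  expect_false("amb" %in% ha$weights$snp)
  # duplicate external ids are an error
  expect_error(harmonize(retained, external[c(1, 1, 2), ]), "duplicate external")
})

test_that("PRS is the weighted risk-allele count sum with mean imputation", {
  d <- rbind(c(2L, 1L, 0L), c(0L, NA, 2L))
  g <- make_geno(d, a1 = c("A", "A", "A"), a2 = c("G", "G", "G"))
  w <- data.frame(snp = c("v01", "v02", "v03"), chr = "1",
                  pos = c(1000, 2000, 3000),
                  risk_allele = c("A", "A", "A"),
                  weight = c(0.1, 0.2, -0.3), stringsAsFactors = FALSE)
  scores <- compute_prs(w, g)
  expect_equal(unname(scores[1]), 0.1 * 2 + 0.2 * 1 - 0.3 * 0)
  # missing count imputed as 2 x cohort risk-allele frequency (= 1 here,
  # from the single observed dosage 1 at v02)
  expect_equal(unname(scores[2]), 0.1 * 0 + 0.2 * 1 - 0.3 * 2)
  # documented arithmetic: weight 0.5, risk-allele frequency 0.3 -> 0.3
  g2 <- make_geno(rbind(2L, 1L, 0L, 0L, 0L, NA))
  w2 <- data.frame(snp = "v01", chr = "1", pos = 1000, risk_allele = "A",
                   weight = 0.5, stringsAsFactors = FALSE)
  s2 <- compute_prs(w2, g2)
  expect_equal(unname(s2[6]), 0.5 * 2 * 0.3)
  # all weights zero -> all scores zero
  w$weight <- 0
  expect_true(all(compute_prs(w, g) == 0))
})

test_that("PRS is invariant to recoding the counted file allele", {
  set.seed(33)
  n <- 40
  d <- matrix(sample(0:2, n * 5, TRUE), n, 5)
  g <- make_geno(d, a1 = rep("A", 5), a2 = rep("G", 5))
  w <- data.frame(snp = g$variants$variant_id, chr = "1",
                  pos = g$variants$position_bp,
                  risk_allele = c("A", "G", "A", "G", "A"),
                  weight = c(0.3, -0.2, 0.5, 0.1, -0.4),
                  stringsAsFactors = FALSE)
  base <- compute_prs(w, g)
  # recode variant 3: count G instead of A, dosage flips to 2 - d
  d2 <- d; d2[, 3] <- 2L - d2[, 3]
  g2 <- make_geno(d2, a1 = c("A", "A", "G", "A", "A"),
                  a2 = c("G", "G", "A", "G", "G"))
  expect_equal(compute_prs(w, g2), base)
})

test_that("standardization gives mean 0 SD 1 and catches degenerate input", {
  expect_equal(standardize_scores(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(34)
  x <- rnorm(100, 5, 3)
  z <- standardize_scores(x)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  expect_error(standardize_scores(rep(2, 5)), "constant")
  expect_error(standardize_scores(1), "at least 2")
})

test_that("risk-allele carriage counts equal the column-sum oracle", {
  d <- rbind(c(0L, 1L, 2L), c(1L, 1L, 1L), c(2L, 2L, 2L))
  g <- make_geno(d)
  w <- data.frame(snp = g$variants$variant_id, chr = "1",
                  pos = g$variants$position_bp, risk_allele = "A",
                  weight = c(0.1, 0.1, 0.1), stringsAsFactors = FALSE)
  cnt <- risk_allele_count_distribution(w, g)
  expect_equal(unname(cnt), rowSums(d))
  # single variant: counts are the dosages themselves
  expect_equal(unname(risk_allele_count_distribution(w[1, ], g)), d[, 1])
  # all-homozygous-risk fixture: everyone carries 2 x n_variants
  g5 <- make_geno(matrix(2L, 3, 5))
  w5 <- data.frame(snp = g5$variants$variant_id, chr = "1",
                   pos = g5$variants$position_bp, risk_allele = "A",
                   weight = 1, stringsAsFactors = FALSE)
  expect_equal(unname(risk_allele_count_distribution(w5, g5)), rep(10, 3))
})

test_that("profile stage counts are monotone: selected >= clumped >= matched", {
  set.seed(35)
  sim <- simulate_cohort(sim_config(n_individuals = 120, n_snps = 300,
                                    n_causal = 15, seed = 35,
                                    discordant_fraction = 0.1))
  scan <- gwas_scan(sim$genotypes, sim$cohort, n_mds = 0)
  prof <- build_prs_profile(scan, sim$genotypes, sim$sumstats)
  sc <- prof$stage_counts
  expect_true(all(sc$selected >= sc$clumped))
  expect_true(all(sc$clumped >= sc$matched))
  # standardized scores have cohort mean 0 / SD 1 where defined
  for (p in prof$profiles) {
    if (p$counts["matched"] > 0 && !anyNA(p$scores$standardized)) {
      expect_equal(mean(p$scores$standardized), 0, tolerance = 1e-10)
      expect_equal(sd(p$scores$standardized), 1, tolerance = 1e-10)
    }
  }
})
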