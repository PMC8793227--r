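test_that("compute_maf folds to the minor allele and skips missing", {
  expect_equal(compute_maf(rep(c(2L, 1L, 0L), c(25, 50, 25))), 0.5)
  expect_equal(compute_maf(rep(0L, 10)), 0)
  # AA=90, Aa=9, aa=1 -> (2*1 + 9)/200 counting the rare allele
  expect_equal(compute_maf(rep(c(2L, 1L, 0L), c(90, 9, 1))), 0.055)
  expect_equal(compute_maf(c(2L, NA, 0L, NA)), 0.5)
  expect_error(compute_maf(c(NA_integer_, NA_integer_)), "all genotypes missing")
})

test_that("exact HWE test matches brute-force enumeration for all small tables", {
  expect_equal(hwe_test(100, 0, 0), 1)
  expect_equal(hwe_test(3, 5, 2), hwe_oracle(3, 5, 2), tolerance = 1e-12)
  # exhaustive sweep over genotype configurations with total <= 20
  for (n in c(3, 7, 12, 20)) {
    for (n_AA in 0:n) for (n_Aa in 0:(n - n_AA)) {
      n_aa <- n - n_AA - n_Aa
      expect_equal(hwe_test(n_AA, n_Aa, n_aa), hwe_oracle(n_AA, n_Aa, n_aa),
                   tolerance = 1e-10,
                   label = sprintf("hwe(%d,%d,%d)", n_AA, n_Aa, n_aa))
    }
  }
})

test_that("HWE exact test agrees with chi-square for large balanced samples", {
  # observed counts at exact Hardy-Weinberg proportions are modal
  expect_gte(hwe_test(250, 500, 250), 0.5)
  for (p in c(0.2, 0.35, 0.5)) {
    n <- 800
    nAA <- round(n * (1 - p)^2); naa <- round(n * p^2)
    nAa <- n - nAA - naa
    chi <- suppressWarnings(stats::chisq.test(
      c(nAA, nAa, naa),
      p = c((1 - p)^2, 2 * p * (1 - p), p^2))$p.value)
    expect_lt(abs(hwe_test(nAA, nAa, naa) - chi), 0.02)
  }
})

test_that("filter_snps applies the published boundary conventions", {
  set.seed(11)
  n <- 100
  hw <- function(p) sample(0:2, n, replace = TRUE,
                           prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
  # v1 fails MAF (rare), v2 fails MAF (monomorphic), v3 exactly 5% missing,
  # v4 gross HWE violation (all hets), v5-v6 clean
  d <- cbind(rep(c(0L, 1L), c(98, 2)), rep(0L, n), hw(0.4), rep(1L, n),
             hw(0.3), hw(0.45))
  d[1:5, 3] <- NA  # missing rate exactly 0.05 -> removed (>= rule)
  g <- make_geno(d)
  res <- filter_snps(g)
  expect_equal(res$genotypes$variants$variant_id, c("v05", "v06"))
  expect_equal(unname(res$counts["low_maf"]), 2)
  expect_true(grepl("high_missing", res$report$reasons[3]))
  expect_true(grepl("hwe_fail", res$report$reasons[4]))
  expect_equal(nrow(res$report), 6)  # every input variant appears once
  expect_true(all(res$report$reasons[res$report$kept] == ""))

  # MAF exactly at the threshold is kept (strict < rule)
  d2 <- cbind(rep(c(0L, 1L), c(90, 10)), hw(0.4))  # MAF exactly 0.05
  res2 <- filter_snps(make_geno(d2))
  expect_true(res2$report$kept[1])

  # idempotence: filtering a filtered panel removes nothing
  res3 <- filter_snps(res$genotypes)
  expect_equal(n_variants(res3$genotypes), n_variants(res$genotypes))

  expect_error(filter_snps(make_geno(cbind(rep(0L, 50)))), "no variants survive")
})

test_that("a variant failing several rules reports all reasons", {
  d <- cbind(rep(c(0L, 1L), c(58, 2)), rep(c(0L, 1L, 2L), 20))
  d[1:6, 1] <- NA  # 10% missing AND rare
  res <- filter_snps(make_geno(d))
  expect_true(grepl("low_maf", res$report$reasons[1]))
  expect_true(grepl("high_missing", res$report$reasons[1]))
})

test_that("ld_r2 computes pairwise-complete squared correlation", {
  a <- c(0L, 1L, 2L, 1L, 0L)
  expect_equal(as.numeric(ld_r2(a, a)), 1)
  b <- c(1L, 0L, 1L, 2L, 1L)  # engineered zero covariance with a
  expect_equal(as.numeric(stats::cov(a, b)), 0)
  expect_equal(as.numeric(ld_r2(a, b)), 0)
  const <- rep(1L, 5)
  r <- ld_r2(a, const)
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "constant"))
  expect_error(ld_r2(c(1L, NA, NA), c(NA, 1L, 2L)), "fewer than 2")
  # missing entries drop the pair, not the column
  expect_equal(as.numeric(ld_r2(c(a, NA), c(b, 0L))), 0)
})

test_that("windowed LD pruning keeps independent panels and collapses duplicates", {
  set.seed(5)
  n <- 60
  d_indep <- sapply(runif(8, .2, .5), function(p)
    sample(0:2, n, TRUE, c((1 - p)^2, 2 * p * (1 - p), p^2)))
  g <- make_geno(d_indep)
  r2max <- max(suppressWarnings(stats::cor(d_indep))[upper.tri(diag(8))]^2)
  kept <- ld_prune_window(g, r2_max = r2max + 1e-6)
  expect_equal(kept, g$variants$variant_id)  # all below threshold -> identity

  d_dup <- cbind(d_indep[, 1], d_indep[, 1], d_indep[, 2])
  kept2 <- ld_prune_window(make_geno(d_dup), r2_max = 0.2)
  expect_equal(length(kept2), 2)  # exactly one of the duplicate pair survives
})

test_that("windowed pruning equals the literal rule applied per window", {
  # oracle: same greedy rule evaluated with scalar loops over each window
  prune_oracle <- function(geno, r2_max, window_snps, step) {
    v <- geno$variants
    maf <- sapply(seq_len(ncol(geno$dosages)),
                  function(j) compute_maf(geno$dosages[, j]))
    keep <- rep(TRUE, nrow(v))
    idx <- order(v$position_bp)
    starts <- seq(1, max(1, length(idx) - 1), by = step)
    for (s in starts) {
      win <- idx[s:min(s + window_snps - 1, length(idx))]
      repeat {
        live <- win[keep[win]]
        if (length(live) < 2) break
        worst <- c(0, 0); wr2 <- -1
        for (i in seq_along(live)) for (k in seq_along(live)) {
          if (i >= k) next
          r2 <- as.numeric(ld_r2(geno$dosages[, live[i]],
                                 geno$dosages[, live[k]]))
          if (r2 > wr2) { wr2 <- r2; worst <- c(live[i], live[k]) }
        }
        if (wr2 <= r2_max) break
        m <- maf[worst]
        drop <- if (m[1] != m[2]) worst[which.min(m)] else
          worst[which.max(v$position_bp[worst])]
        keep[drop] <- FALSE
      }
    }
    v$variant_id[keep]
  }
  set.seed(9)
  n <- 50
  base <- sample(0:2, n, TRUE)
  d <- sapply(1:10, function(j) {
    flip <- runif(n) < 0.3
    out <- base; out[flip] <- sample(0:2, sum(flip), TRUE); as.integer(out)
  })
  g <- make_geno(d)
  expect_equal(ld_prune_window(g, r2_max = 0.3, window_snps = 5, step = 2),
               prune_oracle(g, 0.3, 5, 2))
})

test_that("IBS distance and classical MDS behave on hand-checkable cases", {
  set.seed(3)
  d <- matrix(sample(0:2, 6 * 20, TRUE), 6, 20)
  d[2, ] <- d[1, ]  # duplicated individual
  g <- make_geno(d)
  dist <- ibs_distance(g)
  expect_equal(dist[1, 2], 0)
  expect_equal(dist, t(dist))
  expect_equal(unname(diag(dist)), rep(0, 6))
  # hand value for one pair
  expect_equal(dist[1, 3], sum(abs(d[1, ] - d[3, ])) / (2 * 20))
  mds <- compute_mds(g, k = 2)
  expect_equal(unname(mds$points[1, ]), unname(mds$points[2, ]),
               tolerance = 1e-10)
})

test_that("classical MDS matches a direct eigen-decomposition oracle", {
  D <- matrix(c(0, 3, 4, 5,
                3, 0, 5, 4,
                4, 5, 0, 3,
                5, 4, 3, 0), 4, 4)
  # oracle: double-center -D^2/2, eigendecompose, scale by root eigenvalue
  J <- diag(4) - matrix(1 / 4, 4, 4)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen(B, symmetric = TRUE)
  oracle <- e$vectors[, 1:2] %*% diag(sqrt(e$values[1:2]))
  fit <- stats::cmdscale(D, k = 2, eig = TRUE)
  for (j in 1:2)  # sign per component is arbitrary
    expect_true(max(abs(fit$points[, j] - oracle[, j])) < 1e-8 ||
                  max(abs(fit$points[, j] + oracle[, j])) < 1e-8)
  # Euclidean-embeddable input: reconstructed distances match to 1e-8
  rec <- as.matrix(dist(fit$points))
  expect_lt(max(abs(rec - D)), 1e-8)
})

test_that("compute_mds returns the requested component count on a cohort", {
  set.seed(21)
  p <- runif(40, .1, .5)
  d <- sapply(p, function(q) sample(0:2, 30, TRUE,
                                    c((1 - q)^2, 2 * q * (1 - q), q^2)))
  g <- make_geno(d)
  mds <- compute_mds(g, k = 5)
  expect_equal(ncol(mds$points), 5)
  expect_equal(colnames(mds$points), paste0("mds", 1:5))
  # components ordered by decreasing eigenvalue
  expect_true(all(diff(mds$eig[1:5]) <= 1e-12))
  expect_error(compute_mds(g, k = 30), "smaller than")
  pca <- compute_mds(g, k = 3, method = "pca")
  expect_equal(ncol(pca$points), 3)
})
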