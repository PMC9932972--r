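test_that("allele frequency matches direct gene-copy counting", {
  g <- make_geno(matrix(c(3, 3), 2, 1))
  af <- allele_frequency(g)
  expect_equal(af$p, 0.5)
  expect_equal(af$maf, 0.5)
  expect_equal(allele_frequency(make_geno(matrix(0, 3, 1)))$maf, 0)
  # counting oracle on a random column with missing values
  g2 <- random_geno(50, 1, seed = 8, miss = 0.2)
  x <- g2$dosage[, 1]
  expect_equal(allele_frequency(g2)$p,
               sum(x, na.rm = TRUE) / (6 * sum(!is.na(x))))
  g3 <- make_geno(matrix(NA_integer_, 2, 1))
  expect_true(is.na(allele_frequency(g3)$p))
})

test_that("filter_markers applies depth, missingness, and MAF in order", {
  withr::with_seed(11, {
    n <- 20; L <- 100
    d <- matrix(rbinom(n * L, 6, rep(runif(L, 0.05, 0.5), each = n)), n, L)
    d[runif(n * L) < 0.1] <- NA
    dp <- matrix(rpois(n * L, 60), n, L)
    g <- make_geno(d, chrom = rep("chr01", L), pos = seq_len(L) * 10L, dp = dp)
  })
  cfg <- filter_config(min_depth = 45, locus_missing_max = 0.3,
                       sample_missing_max = 0.3, maf_final = 0.05)
  res <- filter_markers(g, cfg)
  # independent sequential re-implementation of the four rules
  d <- g$dosage
  d[!is.na(g$dp) & g$dp < 45 & !is.na(d)] <- NA
  keep_l <- colMeans(is.na(d)) <= 0.3
  d2 <- d[, keep_l, drop = FALSE]
  keep_s <- rowMeans(is.na(d2)) <= 0.3
  d3 <- d2[keep_s, , drop = FALSE]
  p <- colSums(d3, na.rm = TRUE) / (6 * colSums(!is.na(d3)))
  keep_m <- pmin(p, 1 - p) >= 0.05 & !is.na(p)
  expect_equal(loci(res$genotypes) %in% colnames(d3)[keep_m],
               rep(TRUE, ncol(res$genotypes$dosage)))
  expect_equal(ncol(res$genotypes$dosage), sum(keep_m))
  expect_equal(res$genotypes$dosage,
               d3[, keep_m, drop = FALSE])
  # report counts reconcile input and output locus totals
  rep_l <- res$report$removed
  expect_equal(ncol(g$dosage) - ncol(res$genotypes$dosage), rep_l[2] + rep_l[4])
})

test_that("permissive thresholds are the identity filter", {
  g <- random_geno(10, 20, seed = 12, miss = 0.1)
  cfg <- filter_config(min_depth = 0, locus_missing_max = 1,
                       sample_missing_max = 1, maf_final = 0)
  res <- filter_markers(g, cfg)
  expect_equal(res$genotypes$dosage, g$dosage)
  expect_equal(sum(res$report$removed), 0)
  g40 <- make_geno(cbind(c(rep(NA, 4), rep(2L, 6)), rep(3L, 10)))
  res2 <- filter_markers(g40, filter_config(min_depth = 0,
                                            locus_missing_max = 0.3))
  expect_equal(res2$report$removed[2], 1)
  expect_error(filter_markers(g, filter_config(min_depth = 0, maf_final = 0.6)),
               "all loci")
})

test_that("composite r2 is symmetric, self-unit, and flip-invariant", {
  g <- random_geno(60, 4, seed = 13, n_chrom = 1)
  expect_equal(composite_ld_r2(g, 1, 1), 1.0)
  expect_equal(composite_ld_r2(g, 1, 2), composite_ld_r2(g, 2, 1))
  flipped <- g
  flipped$dosage[, 2] <- 6L - flipped$dosage[, 2]
  expect_equal(composite_ld_r2(flipped, 1, 2), composite_ld_r2(g, 1, 2))
  dup <- make_geno(cbind(g$dosage[, 1], 6L - g$dosage[, 1]))
  expect_equal(composite_ld_r2(dup, 1, 2), 1.0)
  # zero variance -> undefined
  zv <- make_geno(cbind(rep(3L, 60), g$dosage[, 1]))
  expect_true(is.na(composite_ld_r2(zv, 1, 2)))
  expect_true(is.na(composite_ld_r2(g, 1, 2, min_pairs = 100)))
})

test_that("allele-copying weight w yields dosage r2 near w^2", {
  w <- 0.8
  r2s <- sapply(1:20, function(s) withr::with_seed(400 + s, {
    n <- 200; p <- 0.4
    u1 <- matrix(rbinom(n * 6, 1, p), n, 6)
    keep <- matrix(runif(n * 6) < w, n, 6)
    u2 <- ifelse(keep, u1, matrix(rbinom(n * 6, 1, p), n, 6))
    cor(rowSums(u1), rowSums(u2))^2
  }))
  expect_lt(abs(mean(r2s) - w^2), 0.03)
})

test_that("LD pruning drops the lower-MAF member and matches brute force", {
  base <- random_geno(80, 1, seed = 14)$dosage[, 1]
  # two strongly correlated loci with different MAFs
  d <- cbind(l1 = base, l2 = pmin(base, 3L))
  g <- make_geno(d)
  maf <- allele_frequency(g)$maf
  res <- ld_prune(g, filter_config(ld_r2_threshold = 0.1, min_pairs = 2))
  expect_equal(res$pruned_locus_ids,
               loci(g)[which.min(maf)])
  # all pairs below threshold: identity
  g2 <- random_geno(100, 10, seed = 15, n_chrom = 1)
  res2 <- ld_prune(g2, filter_config(ld_r2_threshold = 0.99, min_pairs = 2))
  expect_equal(loci(res2$genotypes), loci(g2))
  # oracle: greedy over the full pair list in the same scan order
  g3 <- random_geno(60, 30, seed = 16, n_chrom = 1)
  # inject correlated blocks so that pruning actually fires
  g3$dosage[, 5] <- g3$dosage[, 4]
  g3$dosage[, 12] <- pmin(6L, g3$dosage[, 11] + 1L)
  g3$dosage[, 20] <- 6L - g3$dosage[, 19]
  maf3 <- allele_frequency(g3)$maf
  keep_oracle <- brute_ld_prune_keep(g3$dosage, maf3, thr = 0.1)
  res3 <- ld_prune(g3, filter_config(ld_r2_threshold = 0.1, min_pairs = 2))
  expect_equal(loci(res3$genotypes), loci(g3)[keep_oracle])
  # invariant: no surviving same-chromosome pair above the threshold
  kept <- res3$genotypes$dosage
  r2 <- suppressWarnings(cor(kept))^2
  diag(r2) <- 0
  expect_true(all(r2 <= 0.1 + 1e-12, na.rm = TRUE))
})

test_that("LD decay crossing distances behave on linked and unlinked data", {
  rho <- log(2) / 1000  # r2 halves every 500 bp
  cfg <- sim_config(n_accessions = 200, n_loci = 500, n_populations = 1,
                    pop_sizes = 200, fst_target = 0, n_chromosomes = 2,
                    chrom_length_bp = 50000, ld_rho = rho,
                    missing_rate = 0, seed = 42)
  so <- simulate_collection(cfg)
  ld <- ld_decay(so$genotypes, thresholds = c(0.2, 0.1), max_dist_bp = 2e4,
                 n_bins = 20)
  expect_true(all(ld$decay$reached))
  expect_lt(ld$decay$distance_bp[ld$decay$threshold == 0.1], 5000)
  expect_lte(ld$decay$distance_bp[ld$decay$threshold == 0.2],
             ld$decay$distance_bp[ld$decay$threshold == 0.1])
  # unlinked: smoothed curve essentially flat near zero
  cfg2 <- sim_config(n_accessions = 150, n_loci = 300, n_populations = 1,
                     pop_sizes = 150, fst_target = 0, n_chromosomes = 2,
                     ld_rho = Inf, missing_rate = 0, seed = 43)
  so2 <- simulate_collection(cfg2)
  ld2 <- ld_decay(so2$genotypes, max_dist_bp = 3e6, n_bins = 15)
  expect_lt(max(ld2$curve$r2_smoothed), 0.05)
  expect_error(ld_decay(so2$genotypes, max_dist_bp = 100), "100")
})

test_that("filtering is invariant to accession order", {
  g <- random_geno(30, 40, seed = 17, miss = 0.1)
  perm <- withr::with_seed(1, sample(30))
  gp <- subset_dosage_for_test(g, perm)
  cfg <- filter_config(min_depth = 0, maf_final = 0.05)
  expect_equal(sort(loci(filter_markers(g, cfg)$genotypes)),
               sort(loci(filter_markers(gp, cfg)$genotypes)))
})
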