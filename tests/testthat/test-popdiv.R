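test_that("population frequencies match a per-allele tally", {
  g <- make_geno(matrix(c(6L, 0L), 2, 1))
  pa <- population_assignment(accessions(g), c("p1", "p1"))
  pf <- population_frequencies(g, pa)
  expect_equal(unname(pf$freq[1, 1]), 0.5)
  expect_equal(unname(pf$copies[1, 1]), 12)
  # missing accession reduces the copy count by ploidy
  g2 <- make_geno(matrix(c(6L, NA, 0L), 3, 1))
  pa2 <- population_assignment(accessions(g2), rep("p1", 3))
  expect_equal(unname(population_frequencies(g2, pa2)$copies[1, 1]), 12)
  # random fixture vs tally oracle
  g3 <- random_geno(30, 20, seed = 21, miss = 0.1)
  pa3 <- population_assignment(accessions(g3), rep(c("a", "b"), 15))
  pf3 <- population_frequencies(g3, pa3)
  for (pop in c("a", "b")) {
    rows <- pa3$accession[pa3$population == pop]
    d <- g3$dosage[rows, , drop = FALSE]
    expect_equal(unname(pf3$freq[pop, ]),
                 unname(colSums(d, na.rm = TRUE) / (6 * colSums(!is.na(d)))))
  }
  expect_error(population_frequencies(
    g, population_assignment(accessions(g), c("p1", NA))[1:1, ]), "label")
})

test_that("PIC, Ae, and Shannon index hit their analytic values", {
  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_equal(pic(c(1, 0)), 0)
  expect_equal(pic(c(0.1, 0.9)), 1 - 0.01 - 0.81 - 2 * 0.01 * 0.81)
  expect_equal(effective_alleles(c(0.5, 0.5)), 2)
  expect_equal(effective_alleles(c(1, 0)), 1)
  expect_equal(effective_alleles(c(0.2, 0.8)), 1 / 0.68)
  expect_equal(shannon_index(c(0.5, 0.5)), log(2))
  expect_equal(shannon_index(c(1, 0)), 0)
  expect_equal(shannon_index(c(0.2, 0.8)), -(0.2 * log(0.2) + 0.8 * log(0.8)))
})

test_that("rarefied allelic richness follows the hypergeometric form", {
  expect_equal(allelic_richness(c(12, 0), 6), 1)
  expect_equal(allelic_richness(c(6, 6), 12), 2)
  expect_equal(allelic_richness(c(9, 3), 4),
               (1 - choose(3, 4) / choose(12, 4)) +
                 (1 - choose(9, 4) / choose(12, 4)))
  expect_error(allelic_richness(c(9, 3), 0), "positive")
  # monotone non-decreasing in g
  ar <- sapply(1:12, function(g) allelic_richness(c(9, 3), g))
  expect_true(all(diff(ar) >= -1e-12))
  expect_true(all(ar >= 1 - 1e-9 & ar <= 2 + 1e-9))
})

test_that("private alleles match an exhaustive membership oracle", {
  # three populations, four loci, constructed frequencies
  freq <- rbind(p1 = c(0.5, 0.0, 1.0, 0.3),
                p2 = c(0.4, 0.0, 1.0, 0.0),
                p3 = c(0.6, 0.2, 1.0, 0.0))
  pf <- structure(list(freq = freq, copies = freq * 0 + 60,
                       populations = rownames(freq), loci = colnames(freq),
                       ploidy = 6), class = "population_frequencies")
  np <- private_alleles(pf)
  # oracle: enumerate both alleles at every locus
  oracle <- sapply(1:3, function(k) {
    cnt <- 0
    for (l in 1:4) for (al in 1:2) {
      f <- if (al == 1) freq[, l] else 1 - freq[, l]
      if (f[k] > 0 && all(f[-k] == 0)) cnt <- cnt + 1
    }
    cnt / 4
  })
  expect_equal(unname(np), oracle)
  # all shared -> zero everywhere
  shared <- pf; shared$freq <- matrix(0.4, 3, 4, dimnames = dimnames(freq))
  expect_true(all(private_alleles(shared) == 0))
})

test_that("Hudson Fst behaves at its analytic extremes", {
  mk_pf <- function(freq, copies) structure(
    list(freq = freq, copies = copies, populations = rownames(freq)),
    class = "population_frequencies")
  # maximal divergence: fixed opposite alleles
  f <- rbind(a = rep(1, 5), b = rep(0, 5))
  r <- fst_pairwise(mk_pf(f, f * 0 + 12), "a", "b")
  expect_equal(r$fst, 1)
  # no differentiation: same draws in both populations
  g <- random_geno(100, 2000, seed = 23)
  pa <- population_assignment(accessions(g), rep(c("x", "y"), each = 50))
  pf <- population_frequencies(g, pa)
  expect_lt(abs(fst_pairwise(pf, "x", "y")$fst), 0.01)
})

test_that("Fst estimates increase with simulated differentiation", {
  est <- sapply(c(0.02, 0.05, 0.1, 0.2), function(F) {
    mean(sapply(1:3, function(s) {
      cfg <- sim_config(n_accessions = 200, n_loci = 2000, n_populations = 2,
                        pop_sizes = c(100, 100), fst_target = F, ld_rho = Inf,
                        missing_rate = 0, seed = 600 + s)
      so <- simulate_collection(cfg)
      pf <- population_frequencies(so$genotypes, so$passport)
      fst_pairwise(pf, "region_01", "region_02")$fst
    }))
  })
  expect_true(all(diff(est) > 0))
})

test_that("Nei's distance matches the hand-evaluated example and is a metric-like measure", {
  freq <- rbind(x = c(0.5, 0.5), y = c(1.0, 0.0))
  pf <- structure(list(freq = freq, copies = freq * 0 + 60,
                       populations = rownames(freq)),
                  class = "population_frequencies")
  expect_equal(nei_distance(pf, "x", "y"), -log(0.5 / sqrt(0.5)),
               tolerance = 1e-12)
  expect_equal(nei_distance(pf, "x", "x"), 0)
  expect_equal(nei_distance(pf, "x", "y"), nei_distance(pf, "y", "x"))
  # increases with simulated divergence
  d_by_f <- sapply(c(0.02, 0.2), function(F) {
    cfg <- sim_config(n_accessions = 100, n_loci = 1000, n_populations = 2,
                      pop_sizes = c(50, 50), fst_target = F, ld_rho = Inf,
                      missing_rate = 0, seed = 71)
    so <- simulate_collection(cfg)
    pf2 <- population_frequencies(so$genotypes, so$passport)
    nei_distance(pf2, "region_01", "region_02")
  })
  expect_gt(d_by_f[2], d_by_f[1])
})

test_that("diversity_table composes the per-locus indices it reports", {
  cfg <- small_sim(seed = 25)
  so <- simulate_collection(cfg)
  ds <- diversity_table(so$genotypes, so$passport)
  expect_true(isSymmetric(ds$fst))
  expect_true(all(diag(ds$fst) == 0))
  expect_true(isSymmetric(ds$nei_d))
  # composition oracle: recompute one population's PIC mean manually
  pf <- population_frequencies(so$genotypes, so$passport)
  p <- pf$freq["region_02", ]
  p <- p[!is.na(p)]
  manual_pic <- mean(sapply(p, function(pp) pic(c(pp, 1 - pp))))
  expect_equal(ds$table$PIC[ds$table$population == "region_02"], manual_pic)
  manual_ae <- mean(1 / (p^2 + (1 - p)^2))
  expect_equal(ds$table$Ae[ds$table$population == "region_02"], manual_ae)
  # invariance to accession order and label renaming
  perm <- withr::with_seed(2, sample(nrow(so$genotypes$dosage)))
  gp <- subset_dosage_for_test(so$genotypes, perm)
  pa_renamed <- population_assignment(
    so$passport$accession, paste0("pop_", so$passport$population))
  ds2 <- diversity_table(gp, pa_renamed)
  expect_equal(unname(as.matrix(ds2$table[, -1])),
               unname(as.matrix(ds$table[, -1])), tolerance = 1e-12)
  expect_equal(ds2$global_fst, ds$global_fst)
})

test_that("degenerate population layouts give zero differentiation", {
  g <- random_geno(20, 50, seed = 26)
  pa1 <- population_assignment(accessions(g), rep("only", 20))
  ds1 <- diversity_table(g, pa1)
  expect_equal(dim(ds1$fst), c(1L, 1L))
  expect_equal(ds1$global_fst, 0)
  # two identical populations (duplicated accession blocks)
  d <- rbind(g$dosage, g$dosage)
  rownames(d) <- c(paste0("a", 1:20), paste0("b", 1:20))
  g2 <- dosage_matrix(d, g$chrom, g$pos, 6)
  pa2 <- population_assignment(accessions(g2), rep(c("A", "B"), each = 20))
  ds2 <- diversity_table(g2, pa2)
  expect_lt(abs(ds2$fst["A", "B"]), 0.02)
  expect_lt(ds2$nei_d["A", "B"], 1e-10)
})
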