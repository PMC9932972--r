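mk_pheno <- function(n = 40, seed = 91) {
  withr::with_seed(seed, {
    df <- data.frame(
      q1 = rnorm(n, 50, 10), q2 = exp(rnorm(n)),
      s1 = sample(1:9, n, TRUE),
      c1 = sample(c("A", "B", "C"), n, TRUE, prob = c(0.6, 0.3, 0.1)),
      c2 = sample(c("u", "v"), n, TRUE),
      stringsAsFactors = FALSE)
    df$q1[1:3] <- NA
    rownames(df) <- sprintf("a%03d", seq_len(n))
    phenotype_table(df)
  })
}

test_that("criteria are zero for the full collection and match first principles", {
  pt <- mk_pheno()
  kinds <- classify_traits(pt, min_n = 5)
  full <- criteria_scores(pt$accession_ids, pt, kinds)
  expect_equal(unname(full), rep(0, 6))
  sub <- withr::with_seed(92, sample(pt$accession_ids, 12))
  cs <- criteria_scores(sub, pt, kinds)
  # independent recomputation
  cat_traits <- c("c1", "c2"); quant_traits <- c("q1", "q2", "s1")
  losses <- sapply(cat_traits, function(tr) {
    fullv <- pt$table[[tr]]; subv <- pt$table[sub, tr]
    length(setdiff(unique(fullv[!is.na(fullv)]), unique(subv[!is.na(subv)])))
  })
  rho <- sapply(quant_traits, function(tr) {
    fullv <- pt$table[[tr]]; subv <- as.numeric(pt$table[sub, tr])
    1 - diff(range(subv, na.rm = TRUE)) / diff(range(fullv, na.rm = TRUE))
  })
  dev <- sapply(quant_traits, function(tr) {
    fullv <- as.numeric(pt$table[[tr]]); subv <- as.numeric(pt$table[sub, tr])
    abs(mean(subv, na.rm = TRUE) - mean(fullv, na.rm = TRUE)) /
      sd(fullv, na.rm = TRUE)
  })
  expect_equal(unname(cs), unname(c(sum(losses), mean(losses), max(losses),
                                    mean(rho), max(rho), mean(dev))),
               tolerance = 1e-12)
  expect_gte(cs[["c1_total_cat_loss"]], cs[["c3_max_cat_loss"]])
  expect_error(criteria_scores(character(0), pt, kinds), "empty")
})

test_that("a categorical trait loses exactly its absent categories", {
  df <- data.frame(t = rep(c("A", "B"), c(90, 10)), stringsAsFactors = FALSE)
  rownames(df) <- paste0("a", 1:100)
  pt <- phenotype_table(df)
  kinds <- classify_traits(pt, min_n = 5)
  cs <- criteria_scores(paste0("a", 1:50), pt, kinds)  # all A
  expect_equal(unname(cs[["c1_total_cat_loss"]]), 1)
  expect_equal(unname(cs[["c3_max_cat_loss"]]), 1)
})

test_that("criteria are monotone under subset nesting", {
  pt <- mk_pheno(60, seed = 93)
  kinds <- classify_traits(pt, min_n = 5)
  A <- pt$accession_ids[1:10]
  B <- pt$accession_ids[1:30]
  ca <- criteria_scores(A, pt, kinds)
  cb <- criteria_scores(B, pt, kinds)
  expect_gte(ca[["c1_total_cat_loss"]], cb[["c1_total_cat_loss"]])
  expect_gte(ca[["c4_mean_spread_reduction"]], cb[["c4_mean_spread_reduction"]])
})

test_that("candidate sampling respects clusters, fixing, and uniformity", {
  cl <- setNames(rep(1:4, each = 3), paste0("a", 1:12))
  # all-singleton clusters return the whole collection
  singl <- setNames(1:5, paste0("s", 1:5))
  expect_setequal(withr::with_seed(1, sample_candidate(singl, names(singl))),
                  names(singl))
  # a fixed member suppresses further draws from its cluster
  cand <- withr::with_seed(2, sample_candidate(cl, names(cl), fixed = "a1"))
  expect_equal(sum(cand %in% paste0("a", 1:3)), 1)
  expect_true("a1" %in% cand)
  expect_equal(length(cand), 4)
  expect_error(sample_candidate(cl, names(cl), fixed = "zz"), "absent")
  # uniform draws within a cluster
  draws <- withr::with_seed(3, replicate(2000, {
    sample_candidate(cl[1:3], names(cl)[1:3])
  }))
  tab <- table(draws) / 2000
  expect_true(all(abs(tab - 1 / 3) < 0.04))
})

test_that("the decision rule matches brute-force enumeration on scripted scores", {
  brute_decide <- function(S, q, step = 0.01) {
    n <- nrow(S)
    rk <- sapply(1:6, function(j) sapply(1:n, function(i)
      sum(S[, j] < S[i, j]) / n))
    repeat {
      feas <- which(sapply(1:n, function(i) all(rk[i, ] <= q)))
      if (length(feas)) break
      q <- q + step
    }
    best_counts <- sapply(feas, function(i)
      sum(sapply(1:6, function(j) S[i, j] == min(S[feas, j]))))
    sums <- sapply(feas, function(i) sum(rk[i, ]))
    feas[order(-best_counts, sums, feas)][1]
  }
  for (seed in 101:103) {
    S <- withr::with_seed(seed, {
      m <- cbind(rpois(100, 3), runif(100), rpois(100, 1),
                 runif(100), runif(100), rexp(100))
      m[, 2] <- m[, 1] / 5  # correlated pair with heavy ties
      m
    })
    dec <- polycore:::decide_winner(S, 0.21)
    expect_equal(dec$winner, brute_decide(S, 0.21))
  }
  # dominance: a candidate minimal on all six criteria wins
  S <- matrix(runif(60, 1, 2), 10, 6)
  S[7, ] <- 0
  expect_equal(polycore:::decide_winner(S, 0.21)$winner, 7)
  # degenerate ties: identical scores -> lowest index, ranks all zero
  S2 <- matrix(1, 20, 6)
  dec2 <- polycore:::decide_winner(S2, 0.21)
  expect_equal(dec2$winner, 1)
  expect_true(all(dec2$ranks == 0))
  expect_false(dec2$relaxed)
})

test_that("select_subset is reproducible and reports its decision", {
  pt <- mk_pheno(40, seed = 94)
  cl <- setNames(rep(1:8, each = 5), pt$accession_ids)
  cfg <- selection_config(subset_sizes = c(8), n_iter = 60, seed = 12,
                          anchors = "a001")
  r1 <- select_subset(cl, pt$accession_ids, pt, cfg)
  r2 <- select_subset(cl, pt$accession_ids, pt, cfg)
  expect_identical(r1$chosen, r2$chosen)
  expect_true(all(r1$chosen_ranks <= r1$effective_quantile + 1e-12))
  expect_equal(length(r1$chosen), 8)
  expect_error(select_subset(cl, pt$accession_ids, pt,
                             selection_config(n_iter = 2))$chosen, NA)
})

test_that("nested selection nests, anchors, and represents every cluster", {
  pt <- mk_pheno(16, seed = 95)
  D <- withr::with_seed(96, {
    B <- matrix(runif(256, 0.1, 2), 16, 16)
    B <- (B + t(B)) / 2; diag(B) <- 0
    dimnames(B) <- list(pt$accession_ids, pt$accession_ids)
    B
  })
  model <- upgma(D)
  cfg <- selection_config(subset_sizes = c(4, 8), n_iter = 50,
                          anchors = c("a001", "a002"), seed = 33)
  res <- nested_selection(model, pt$accession_ids, pt, cfg)
  s4 <- res$by_size[["4"]]$chosen
  s8 <- res$by_size[["8"]]$chosen
  expect_true(all(s4 %in% s8))
  expect_true(all(c("a001", "a002") %in% s4))
  expect_true(all(c("a001", "a002") %in% s8))
  # one representative per cluster (anchors in distinct clusters or reported)
  for (K in c(4, 8)) {
    cl <- cut_clusters(model, K)
    chosen <- res$by_size[[as.character(K)]]$chosen
    expect_setequal(unique(cl[chosen]), unique(cl))
    if (res$by_size[[as.character(K)]]$oversize == 0)
      expect_equal(length(chosen), K)
  }
  # byte-identical rerun under the same seed
  res2 <- nested_selection(model, pt$accession_ids, pt, cfg)
  expect_identical(res, res2)
})
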