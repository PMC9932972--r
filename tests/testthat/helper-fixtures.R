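# Small in-code fixtures and independent brute-force oracles used across
# the suite. Oracles are deliberately naive re-derivations, not calls back
# into the code paths they check.

make_geno <- function(d, chrom = NULL, pos = NULL, ploidy = 6, dp = NULL) {
  d <- as.matrix(d)
  chrom <- chrom %||% rep("chr01", ncol(d))
  pos <- pos %||% seq_len(ncol(d)) * 100L
  dosage_matrix(d, chrom, pos, ploidy, dp = dp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_geno <- function(n, L, seed, ploidy = 6, miss = 0, n_chrom = 2) {
  withr::with_seed(seed, {
    p <- runif(L, 0.1, 0.9)
    d <- matrix(rbinom(n * L, ploidy, rep(p, each = n)), n, L)
    if (miss > 0) d[runif(n * L) < miss] <- NA
    chrom <- sprintf("chr%02d", sort(rep_len(seq_len(n_chrom), L)))
    pos <- unlist(lapply(unique(chrom), function(ch)
      sort(sample.int(1e6, sum(chrom == ch)))))
    rownames(d) <- sprintf("s%03d", seq_len(n))
    dosage_matrix(d, chrom, pos, ploidy)
  })
}

# naive average-linkage agglomeration; returns the cophenetic matrix
brute_upgma_cophenetic <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  act <- D
  diag(act) <- Inf
  while (length(clusters) > 1) {
    ij <- which(act == min(act), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    h <- act[i, j]
    for (a in clusters[[i]]) for (b in clusters[[j]])
      coph[a, b] <- coph[b, a] <- h
    ni <- length(clusters[[i]]); nj <- length(clusters[[j]])
    for (k in seq_along(clusters)) {
      if (k == i || k == j) next
      act[i, k] <- act[k, i] <- (ni * act[i, k] + nj * act[j, k]) / (ni + nj)
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
    act <- act[-j, -j, drop = FALSE]
  }
  coph
}

# greedy LD pruning over the full within-chromosome pair list in scan order
brute_ld_prune_keep <- function(d, maf, thr, min_pairs = 2) {
  L <- ncol(d)
  alive <- rep(TRUE, L)
  for (a in seq_len(L)) {
    for (b in seq_len(L)) {
      if (b <= a || !alive[a] || !alive[b]) next
      x <- d[, a]; y <- d[, b]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < min_pairs) next
      if (sd(x[ok]) == 0 || sd(y[ok]) == 0) next
      r2 <- cor(x[ok], y[ok])^2
      if (r2 <= thr) next
      if (maf[a] < maf[b]) alive[a] <- FALSE else alive[b] <- FALSE
    }
  }
  alive
}

# naive double-loop autopolyploid GRM
brute_grm <- function(d, ploidy) {
  n_obs <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (ploidy * n_obs)
  use <- p > 0 & p < 1
  d <- d[, use, drop = FALSE]; p <- p[use]
  n <- nrow(d)
  Z <- matrix(0, n, ncol(d))
  for (i in seq_len(n)) for (j in seq_len(ncol(d)))
    Z[i, j] <- (if (is.na(d[i, j])) ploidy * p[j] else d[i, j]) - ploidy * p[j]
  den <- ploidy * sum(p * (1 - p))
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in seq_len(n))
    G[i, k] <- sum(Z[i, ] * Z[k, ]) / den
  G
}

subset_dosage_for_test <- function(g, acc_order) {
  dosage_matrix(g$dosage[acc_order, , drop = FALSE], g$chrom, g$pos, g$ploidy)
}

# small simulated collection reused by several files
small_sim <- function(seed = 5, n = 90, L = 300, pops = 3) {
  sim_config(n_accessions = n, n_loci = L, n_populations = pops,
             pop_sizes = rep(n / pops, pops), fst_target = 0.1,
             n_chromosomes = 3, ld_rho = Inf, missing_rate = 0.02,
             seed = seed,
             trait_spec = default_trait_spec(n_quant = 3, n_skewed = 1,
                                             n_semi = 1, n_categorical = 3,
                                             n_rare_cat = 1))
}
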