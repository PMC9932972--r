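#' Marker filtering configuration
#'
#' Thresholds follow common practice for dosage-based polyploid SNP data:
#' an initial MAF of 0.02 at variant calling, per-genotype minimum read
#' depth (45 for hexaploid dosage calls; 6 and 25 are typical for diploid
#' and tetraploid data), locus and sample missing-rate caps of 0.3, a final
#' MAF of 0.05, and composite-LD pruning at r-squared 0.1.
#'
#' @param maf_initial,maf_final minor-allele-frequency thresholds.
#' @param locus_missing_max,sample_missing_max missing-rate caps in `[0,1]`.
#' @param min_depth per-genotype read-depth floor (applied only when a
#'   depth matrix is available).
#' @param ld_r2_threshold r-squared above which one member of a locus pair
#'   is pruned.
#' @param ld_window_bp pair-comparison window; `Inf` (default) compares all
#'   same-chromosome pairs.
#' @param min_pairs minimum pairwise-complete accessions for an r-squared
#'   to be considered defined.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(maf_initial = 0.02, maf_final = 0.05,
                          locus_missing_max = 0.3, sample_missing_max = 0.3,
                          min_depth = 45, ld_r2_threshold = 0.1,
                          ld_window_bp = Inf, min_pairs = 30) {
  for (f in c(maf_initial, maf_final, locus_missing_max, sample_missing_max,
              ld_r2_threshold))
    stop_if(!is_fraction(f, closed_top = TRUE), "fractions must be in [0,1]")
  structure(list(maf_initial = maf_initial, maf_final = maf_final,
                 locus_missing_max = locus_missing_max,
                 sample_missing_max = sample_missing_max,
                 min_depth = min_depth, ld_r2_threshold = ld_r2_threshold,
                 ld_window_bp = ld_window_bp, min_pairs = min_pairs),
            class = "filter_config")
}

#' Per-locus allele frequency and MAF from dosages
#'
#' The alternate-allele frequency is the dosage-count estimate
#' `p_j = sum_i d_ij / (ploidy * n_nonmissing_j)`, i.e. each accession
#' contributes `ploidy` gene copies. Loci with no non-missing call get
#' `NA` (they auto-fail downstream MAF filters).
#'
#' @param g a [dosage_matrix].
#' @param subset optional accession IDs or indices to restrict to.
#' @return data.frame with per-locus `p` (alt frequency) and `maf`.
#' @export
allele_frequency <- function(g, subset = NULL) {
  d <- g$dosage
  if (!is.null(subset)) d <- d[subset, , drop = FALSE]
  n_obs <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (g$ploidy * n_obs)
  p[n_obs == 0] <- NA_real_
  data.frame(locus = colnames(d), p = p, maf = pmin(p, 1 - p),
             n_nonmissing = n_obs, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Filter markers and samples on depth, missingness, and MAF
#'
#' Steps are applied in a fixed, reported order: (1) genotypes with read
#' depth below `min_depth` are set missing (when a depth matrix is
#' present); (2) loci with missing rate above `locus_missing_max` are
#' dropped; (3) samples with missing rate above `sample_missing_max` are
#' dropped; (4) loci with MAF below `maf_final` are dropped.
#'
#' @param g a [dosage_matrix] (its `dp` element, if any, supplies depths).
#' @param config a [filter_config].
#' @return list with `genotypes` (filtered [dosage_matrix]) and `report`
#'   (data.frame of per-step removal counts; genotype masking is counted in
#'   cells, locus/sample steps in loci/samples).
#' @export
filter_markers <- function(g, config = filter_config()) {
  d <- g$dosage
  masked <- 0L
  if (!is.null(g$dp) && config$min_depth > 0) {
    low <- !is.na(g$dp) & g$dp < config$min_depth & !is.na(d)
    masked <- sum(low)
    d[low] <- NA_integer_
  }
  loc_miss <- colMeans(is.na(d))
  keep_loc <- loc_miss <= config$locus_missing_max
  d2 <- d[, keep_loc, drop = FALSE]
  samp_miss <- rowMeans(is.na(d2))
  keep_samp <- samp_miss <= config$sample_missing_max
  d3 <- d2[keep_samp, , drop = FALSE]
  n_obs <- colSums(!is.na(d3))
  p <- colSums(d3, na.rm = TRUE) / (g$ploidy * n_obs)
  maf <- pmin(p, 1 - p)
  keep_maf <- !is.na(maf) & maf >= config$maf_final
  loc_idx <- which(keep_loc)[keep_maf]
  stop_if(length(loc_idx) == 0, "all loci removed by filtering")
  out <- dosage_matrix(d[keep_samp, loc_idx, drop = FALSE],
                       g$chrom[loc_idx], g$pos[loc_idx], g$ploidy,
                       dp = if (!is.null(g$dp))
                         g$dp[keep_samp, loc_idx, drop = FALSE])
  report <- data.frame(
    step = c("depth_mask_cells", "locus_missing", "sample_missing", "maf"),
    removed = c(masked, sum(!keep_loc), sum(!keep_samp), sum(!keep_maf)),
    stringsAsFactors = FALSE)
  list(genotypes = out, report = report)
}

#' Composite LD between two loci
#'
#' Composite (genotype-level) linkage disequilibrium measured as the
#' squared Pearson correlation of the two dosage vectors over
#' pairwise-complete accessions; no phase information is needed.
#'
#' @param g a [dosage_matrix].
#' @param locus_i,locus_j locus IDs or column indices (same chromosome).
#' @param min_pairs minimum pairwise-complete accessions.
#' @return r-squared in `[0,1]`, or `NA` if undefined (zero variance or too
#'   few complete pairs).
#' @export
composite_ld_r2 <- function(g, locus_i, locus_j, min_pairs = 30) {
  i <- if (is.character(locus_i)) match(locus_i, loci(g)) else locus_i
  j <- if (is.character(locus_j)) match(locus_j, loci(g)) else locus_j
  stop_if(g$chrom[i] != g$chrom[j], "loci must be on the same chromosome")
  x <- g$dosage[, i]; y <- g$dosage[, j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_pairs) return(NA_real_)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])^2
}

# full pairwise r2 matrix for a block of loci (pairwise-complete), with the
# pair-count matrix; entries failing min_pairs or zero variance are NA
ld_r2_matrix <- function(d, min_pairs) {
  suppressWarnings(r <- cor(d, use = "pairwise.complete.obs"))
  npair <- crossprod(!is.na(d))
  r2 <- r^2
  r2[npair < min_pairs] <- NA_real_
  r2
}

#' Prune loci by composite LD
#'
#' Within each chromosome, loci are scanned in position order; for each
#' surviving pair with r-squared above the threshold, the lower-MAF member
#' is removed immediately and takes no part in later comparisons (greedy).
#' MAF ties keep the earlier-position locus. The traversal is deterministic.
#'
#' @param g a [dosage_matrix] (loci already sorted by chromosome, position).
#' @param config a [filter_config] (threshold, window, min_pairs).
#' @return list with `genotypes` (retained loci), `pruned_locus_ids`, and
#'   `n_pairs_tested`.
#' @export
ld_prune <- function(g, config = filter_config()) {
  thr <- config$ld_r2_threshold
  maf <- allele_frequency(g)$maf
  keep <- rep(TRUE, ncol(g$dosage))
  n_tested <- 0L
  for (ch in unique(g$chrom)) {
    idx <- which(g$chrom == ch)
    if (length(idx) < 2) next
    r2 <- ld_r2_matrix(g$dosage[, idx, drop = FALSE], config$min_pairs)
    pos <- g$pos[idx]
    alive <- rep(TRUE, length(idx))
    for (a in seq_along(idx)) {
      if (!alive[a]) next
      for (b in seq_along(idx)) {
        if (b <= a || !alive[a] || !alive[b]) next
        if (is.finite(config$ld_window_bp) &&
            abs(pos[b] - pos[a]) > config$ld_window_bp) next
        v <- r2[a, b]
        n_tested <- n_tested + 1L
        if (is.na(v) || v <= thr) next
        mi <- maf[idx[a]]; mj <- maf[idx[b]]
        drop_local <- if (mi < mj) a else if (mj < mi) b else b  # tie: keep earlier
        alive[drop_local] <- FALSE
      }
    }
    keep[idx] <- alive
  }
  list(genotypes = subset_dosage(g, loc = which(keep)),
       pruned_locus_ids = loci(g)[!keep],
       n_pairs_tested = n_tested)
}

#' LD decay distance estimation
#'
#' Computes all within-chromosome pairwise r-squared at distances up to
#' `max_dist_bp` (subsampled reproducibly if more than `max_pairs`), bins
#' the pairs by distance, and fits a cubic smoothing spline to the binned
#' mean r-squared. The decay distance at a threshold is the smallest
#' distance at which the smoothed curve first falls below it; `NA` with
#' `reached = FALSE` is reported if the curve never crosses.
#'
#' @param g a [dosage_matrix].
#' @param thresholds r-squared thresholds (default `c(0.2, 0.1)`).
#' @param max_dist_bp distance cap for pairs (default 100 kb).
#' @param n_bins number of distance bins for smoothing.
#' @param max_pairs subsampling cap on the number of pairs.
#' @param min_pairs per-pair completeness requirement.
#' @param seed seed for pair subsampling.
#' @return list with `pairs` (data.frame distance/r2), `curve` (smoothed
#'   grid), and `decay` (data.frame threshold/distance/reached).
#' @export
ld_decay <- function(g, thresholds = c(0.2, 0.1), max_dist_bp = 1e5,
                     n_bins = 25, max_pairs = 1e6, min_pairs = 30,
                     seed = 1) {
  dists <- numeric(0); r2s <- numeric(0)
  for (ch in unique(g$chrom)) {
    idx <- which(g$chrom == ch)
    if (length(idx) < 2) next
    r2 <- ld_r2_matrix(g$dosage[, idx, drop = FALSE], min_pairs)
    pos <- g$pos[idx]
    ut <- which(upper.tri(r2), arr.ind = TRUE)
    dd <- abs(pos[ut[, 2]] - pos[ut[, 1]])
    vv <- r2[ut]
    ok <- !is.na(vv) & dd <= max_dist_bp
    dists <- c(dists, dd[ok]); r2s <- c(r2s, vv[ok])
  }
  stop_if(length(dists) < 100, "need at least 100 within-chromosome pairs")
  if (length(dists) > max_pairs) {
    pick <- local_seed(seed, sample.int(length(dists), max_pairs))
    dists <- dists[pick]; r2s <- r2s[pick]
  }
  stop_if(length(dists) < n_bins,
          "fewer pairs than bins; reduce n_bins")
  brk <- seq(0, max(dists), length.out = n_bins + 1)
  bin <- cut(dists, breaks = brk, include.lowest = TRUE)
  mids <- (head(brk, -1) + brk[-1]) / 2
  bm <- tapply(r2s, bin, mean)
  okb <- !is.na(bm)
  stop_if(sum(okb) < 4, "too few populated bins; reduce n_bins")
  fit <- smooth.spline(mids[okb], bm[okb], df = min(6, sum(okb) - 1))
  grid <- seq(min(mids[okb]), max(mids[okb]), length.out = 512)
  sm <- predict(fit, grid)$y
  decay <- data.frame(threshold = thresholds, distance_bp = NA_real_,
                      reached = FALSE)
  for (i in seq_along(thresholds)) {
    below <- which(sm < thresholds[i])
    if (length(below)) {
      decay$distance_bp[i] <- grid[min(below)]
      decay$reached[i] <- TRUE
    }
  }
  list(pairs = data.frame(distance_bp = dists, r2 = r2s),
       curve = data.frame(distance_bp = grid, r2_smoothed = sm),
       decay = decay,
       smoother = "cubic smoothing spline on binned means")
}
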