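#' Per-population allele frequencies and gene-copy counts
#'
#' Treats each accession as `ploidy` independent gene copies (polysomic
#' assumption): per population and locus, the alternate-allele frequency is
#' the dosage sum over the population divided by `ploidy * n_nonmissing`,
#' and the gene-copy count is `ploidy * n_nonmissing`.
#'
#' @param g a [dosage_matrix].
#' @param assignment a [population_assignment] covering every accession.
#' @return object of class `population_frequencies`: list with `freq`
#'   (populations x loci alt-allele frequencies), `copies` (gene-copy
#'   counts), `alt_copies` (integer alt-allele copy counts), `populations`,
#'   `loci`, `ploidy`.
#' @export
population_frequencies <- function(g, assignment) {
  lab <- setNames(assignment$population, assignment$accession)[accessions(g)]
  stop_if(anyNA(lab), "every genotyped accession needs a population label")
  pops <- sort(unique(lab))
  L <- ncol(g$dosage)
  freq <- copies <- altc <- matrix(NA_real_, length(pops), L,
                                   dimnames = list(pops, loci(g)))
  for (k in seq_along(pops)) {
    d <- g$dosage[lab == pops[k], , drop = FALSE]
    stop_if(nrow(d) == 0, "population with zero genotyped accessions: ", pops[k])
    n_obs <- colSums(!is.na(d))
    copies[k, ] <- g$ploidy * n_obs
    altc[k, ] <- colSums(d, na.rm = TRUE)
    freq[k, ] <- ifelse(n_obs > 0, altc[k, ] / (g$ploidy * n_obs), NA_real_)
  }
  structure(list(freq = freq, copies = copies, alt_copies = altc,
                 populations = pops, loci = loci(g), ploidy = g$ploidy),
            class = "population_frequencies")
}

#' Polymorphic information content (Botstein 1980)
#'
#' `PIC = 1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2`. For a biallelic locus
#' with alt frequency p this reduces to `1 - p^2 - q^2 - 2 p^2 q^2`.
#'
#' @param freqs numeric vector of allele frequencies summing to 1.
#' @return PIC in `[0, 1)`.
#' @export
pic <- function(freqs) {
  s2 <- sum(freqs^2)
  cross <- (s2^2 - sum(freqs^4)) / 2
  1 - s2 - 2 * cross
}

#' Effective number of alleles
#' @param freqs allele frequencies summing to 1.
#' @return `Ae = 1 / sum p_i^2`, in `[1, k]`.
#' @export
effective_alleles <- function(freqs) 1 / sum(freqs^2)

#' Shannon information index of allele frequencies
#' @param freqs allele frequencies summing to 1.
#' @return `I = -sum_{p>0} p ln p`.
#' @export
shannon_index <- function(freqs) {
  p <- freqs[freqs > 0]
  -sum(p * log(p))
}

#' Rarefied allelic richness at one locus
#'
#' Expected number of distinct alleles in a random draw of `g` gene copies
#' from the observed copies: `Ar(g) = sum_i [1 - C(N - N_i, g) / C(N, g)]`
#' where `N` is the total copy count and `N_i` the copies of allele i.
#'
#' @param counts integer vector of per-allele copy counts.
#' @param g rarefaction sample size (> 0, <= N).
#' @return expected allele count in `[1, min(k, g)]`.
#' @export
allelic_richness <- function(counts, g) {
  stop_if(g <= 0, "rarefaction size g must be positive")
  N <- sum(counts)
  stop_if(g > N, "g exceeds the total gene-copy count")
  sum(vapply(counts, function(Ni) {
    1 - exp(lchoose(N - Ni, g) - lchoose(N, g))
  }, numeric(1)))
}

#' Private alleles per population
#'
#' An allele is private to a population when its frequency is positive
#' there and zero in every other population. Returns the per-population
#' mean (over loci) count of private alleles.
#'
#' @param pf a [population_frequencies].
#' @return named numeric vector, one value per population.
#' @export
private_alleles <- function(pf) {
  alt_pos <- pf$freq > 0 & !is.na(pf$freq)
  ref_pos <- pf$freq < 1 & !is.na(pf$freq)
  np <- numeric(length(pf$populations))
  for (k in seq_along(pf$populations)) {
    other <- -k
    priv_alt <- alt_pos[k, ] & colSums(alt_pos[other, , drop = FALSE]) == 0
    priv_ref <- ref_pos[k, ] & colSums(ref_pos[other, , drop = FALSE]) == 0
    np[k] <- mean(priv_alt + priv_ref)
  }
  setNames(np, pf$populations)
}

#' Pairwise Fst (Hudson estimator, ratio of sums)
#'
#' Hudson's two-population Fst in the Bhatia et al. (2013) form: per locus,
#' `N_l = (p_a - p_b)^2 - p_a(1-p_a)/(n_a - 1) - p_b(1-p_b)/(n_b - 1)` and
#' `D_l = p_a(1-p_b) + p_b(1-p_a)` with `n` in gene copies; the estimate is
#' `sum N_l / sum D_l`. Loci monomorphic for the same allele in both
#' populations, or with fewer than 2 copies in either, are excluded.
#'
#' @param pf a [population_frequencies].
#' @param pop_a,pop_b population labels.
#' @return list with `fst`, `n_loci_used`, and per-locus sums.
#' @export
fst_pairwise <- function(pf, pop_a, pop_b) {
  a <- match(pop_a, pf$populations); b <- match(pop_b, pf$populations)
  stop_if(is.na(a) || is.na(b), "unknown population label")
  pa <- pf$freq[a, ]; pb <- pf$freq[b, ]
  na <- pf$copies[a, ]; nb <- pf$copies[b, ]
  use <- !is.na(pa) & !is.na(pb) & na > 1 & nb > 1 &
    !((pa == 0 & pb == 0) | (pa == 1 & pb == 1))
  num <- (pa - pb)^2 - pa * (1 - pa) / (na - 1) - pb * (1 - pb) / (nb - 1)
  den <- pa * (1 - pb) + pb * (1 - pa)
  list(fst = sum(num[use]) / sum(den[use]),
       n_loci_used = sum(use),
       sum_num = sum(num[use]), sum_den = sum(den[use]))
}

#' Nei's (1972) standard genetic distance
#'
#' `D_s = -ln( J_xy / sqrt(J_x J_y) )` with gene identities averaged over
#' loci (ratio of means): `J_x = mean_l sum_i p_xli^2`,
#' `J_xy = mean_l sum_i p_xli p_yli`. For biallelic loci both alleles enter
#' the sums. `J_xy = 0` yields `Inf`, flagged by the caller.
#'
#' @param pf a [population_frequencies].
#' @param pop_x,pop_y population labels.
#' @return non-negative distance (possibly `Inf`).
#' @export
nei_distance <- function(pf, pop_x, pop_y) {
  x <- match(pop_x, pf$populations); y <- match(pop_y, pf$populations)
  stop_if(is.na(x) || is.na(y), "unknown population label")
  px <- pf$freq[x, ]; py <- pf$freq[y, ]
  use <- !is.na(px) & !is.na(py)
  px <- px[use]; py <- py[use]
  jx <- mean(px^2 + (1 - px)^2)
  jy <- mean(py^2 + (1 - py)^2)
  jxy <- mean(px * py + (1 - px) * (1 - py))
  if (jxy == 0) return(Inf)
  max(0, -log(jxy / sqrt(jx * jy)))
}

#' Per-population diversity summary and differentiation matrices
#'
#' Assembles, per population and for the pooled collection: mean number of
#' distinct alleles per locus (k), mean PIC, mean effective alleles (Ae),
#' mean rarefied allelic richness (Ar, rarefaction size = the smallest
#' population's gene-copy count at each locus), mean Shannon index (I),
#' and mean private-allele count (NP); plus pairwise Hudson Fst and Nei
#' (1972) distance matrices and a global ratio-of-sums Fst pooled over all
#' population pairs. Values reflect the biallelic-SNP allele definition
#' (k per locus is 1 or 2).
#'
#' @param g a [dosage_matrix].
#' @param assignment a [population_assignment].
#' @return object of class `diversity_summary`: list with `table`
#'   (data.frame of indices), `fst` and `nei_d` matrices, `global_fst`.
#' @export
diversity_table <- function(g, assignment) {
  pf <- population_frequencies(g, assignment)
  pops <- pf$populations
  # rarefaction size per locus: min copies across populations (>= ploidy)
  g_rar <- apply(pf$copies, 2, min)
  per_pop <- function(k) {
    p <- pf$freq[k, ]; cp <- pf$copies[k, ]; ac <- pf$alt_copies[k, ]
    use <- !is.na(p) & cp > 0
    p <- p[use]; cp <- cp[use]; ac <- ac[use]; gr <- pmax(1, g_rar[use])
    kvals <- (p > 0) + (p < 1)
    picv <- vapply(p, function(pp) pic(c(pp, 1 - pp)), numeric(1))
    aev <- vapply(p, function(pp) effective_alleles(c(pp, 1 - pp)), numeric(1))
    iv <- vapply(p, function(pp) shannon_index(c(pp, 1 - pp)), numeric(1))
    arv <- mapply(function(a, n, gg) allelic_richness(c(a, n - a), min(gg, n)),
                  ac, cp, gr)
    c(k = mean(kvals), PIC = mean(picv), Ae = mean(aev),
      Ar = mean(arv), I = mean(iv))
  }
  rows <- t(vapply(seq_along(pops), per_pop, numeric(5)))
  np <- private_alleles(pf)
  # pooled (all accessions as one population)
  all_assign <- population_assignment(assignment$accession,
                                      rep("all", nrow(assignment)))
  pf_all <- population_frequencies(g, all_assign)
  g_all <- pf_all$copies[1, ]
  p_all <- pf_all$freq[1, ]; use <- !is.na(p_all)
  total <- c(
    k = mean((p_all[use] > 0) + (p_all[use] < 1)),
    PIC = mean(vapply(p_all[use], function(pp) pic(c(pp, 1 - pp)), numeric(1))),
    Ae = mean(vapply(p_all[use], function(pp) effective_alleles(c(pp, 1 - pp)), numeric(1))),
    Ar = mean(mapply(function(a, n, gg) allelic_richness(c(a, n - a), min(gg, n)),
                     pf_all$alt_copies[1, use], pf_all$copies[1, use],
                     pmax(1, g_rar[use]))),
    I = mean(vapply(p_all[use], function(pp) shannon_index(c(pp, 1 - pp)), numeric(1))))
  tab <- data.frame(
    population = c("all", pops),
    n = c(nrow(g$dosage), as.vector(table(factor(
      setNames(assignment$population, assignment$accession)[accessions(g)],
      levels = pops)))),
    rbind(total, rows),
    NP = c(mean(np), np),
    row.names = NULL, stringsAsFactors = FALSE)
  K <- length(pops)
  fst <- neid <- matrix(0, K, K, dimnames = list(pops, pops))
  snum <- sden <- 0
  if (K > 1) {
    for (i in seq_len(K - 1)) for (j in (i + 1):K) {
      fr <- fst_pairwise(pf, pops[i], pops[j])
      fst[i, j] <- fst[j, i] <- fr$fst
      snum <- snum + fr$sum_num; sden <- sden + fr$sum_den
      neid[i, j] <- neid[j, i] <- nei_distance(pf, pops[i], pops[j])
    }
  }
  structure(list(table = tab, fst = fst, nei_d = neid,
                 global_fst = if (K > 1) snum / sden else 0,
                 fst_estimator = "Hudson (Bhatia et al. 2013), ratio of sums"),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat("Diversity summary (", x$fst_estimator, ")\n", sep = "")
  print(x$table, digits = 4)
  cat(sprintf("global Fst (pooled over pairs): %.4f\n", x$global_fst))
  invisible(x)
}

#' Write diversity summary tables as TSV
#' @param ds a `diversity_summary`.
#' @param prefix output path prefix; writes `<prefix>_diversity.tsv`,
#'   `<prefix>_fst.tsv`, `<prefix>_neiD.tsv`.
#' @return the paths, invisibly.
#' @export
write_diversity <- function(ds, prefix) {
  p1 <- paste0(prefix, "_diversity.tsv")
  p2 <- paste0(prefix, "_fst.tsv")
  p3 <- paste0(prefix, "_neiD.tsv")
  utils::write.table(ds$table, p1, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(ds$fst, p2, sep = "\t", quote = FALSE)
  utils::write.table(ds$nei_d, p3, sep = "\t", quote = FALSE)
  invisible(c(p1, p2, p3))
}
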