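#' Full-autopolyploid genomic relationship matrix
#'
#' VanRaden-style GRM generalized to a ploidy-m autopolyploid: with
#' per-locus allele frequencies `p_j` estimated from all accessions,
#' missing dosages mean-imputed to `m * p_j`, and `Z = M - m * P` the
#' centered dosage matrix, `G = Z Z' / (m * sum_j p_j (1 - p_j))`.
#' Monomorphic loci (`p_j` 0 or 1) are excluded from numerator and
#' denominator. Mean imputation (rather than pairwise-complete
#' normalization) keeps G positive semidefinite.
#'
#' @param g a [dosage_matrix] with no all-missing accession.
#' @return symmetric accession x accession matrix of class `matrix` with
#'   attribute `denominator`.
#' @export
grm_autopolyploid <- function(g) {
  stop_if(any(rowSums(!is.na(g$dosage)) == 0), "all-missing accession present")
  m <- g$ploidy
  p <- allele_frequency(g)$p
  use <- !is.na(p) & p > 0 & p < 1
  stop_if(!any(use), "all loci monomorphic; GRM denominator is zero")
  d <- g$dosage[, use, drop = FALSE]
  p <- p[use]
  M <- sweep(d, 2, m * p, `-`)
  M[is.na(M)] <- 0  # imputed to m*p then centered => 0
  denom <- m * sum(p * (1 - p))
  G <- tcrossprod(M) / denom
  attr(G, "denominator") <- denom
  G
}

#' Convert a relationship matrix to a distance matrix
#'
#' Cosine-style normalization: `d_ij = 1 - G_ij / sqrt(G_ii G_jj)`, clipped
#' at zero, with an exactly zero diagonal. Clones (identical genotype rows)
#' get distance 0.
#'
#' @param K symmetric relationship matrix with positive diagonal.
#' @return symmetric non-negative distance matrix, zero diagonal.
#' @export
kinship_to_distance <- function(K) {
  s <- sqrt(diag(K))
  D <- 1 - K / tcrossprod(s)
  D[D < 0] <- 0
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D
}

#' UPGMA clustering of a distance matrix
#'
#' Average-linkage agglomeration via [stats::hclust]; node heights are
#' reported on the ultrametric scale (half the average inter-cluster
#' distance at each merge), so two leaves at distance d join at height
#' d / 2. Cophenetic distances are on the original distance scale.
#'
#' @param D square symmetric zero-diagonal distance matrix (no NA).
#' @param method linkage; `"average"` (UPGMA, default) or `"complete"`.
#' @return object of class `cluster_model`: list with `hclust`, `height`
#'   (ultrametric node heights), `labels`, `method`.
#' @export
upgma <- function(D, method = c("average", "complete")) {
  method <- match.arg(method)
  D <- as.matrix(D)
  stop_if(anyNA(D), "NA in distance matrix")
  stop_if(nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-12 ||
            any(diag(D) != 0), "need a square symmetric zero-diagonal matrix")
  hc <- hclust(stats::as.dist(D), method = method)
  structure(list(hclust = hc, height = hc$height / 2,
                 labels = hc$labels %||% as.character(seq_len(nrow(D))),
                 method = method),
            class = "cluster_model")
}

#' Cut a cluster model into exactly K clusters
#'
#' Undoes the last K - 1 merges of the tree, so assignments at a larger K
#' refine those at a smaller K by construction.
#'
#' @param model a `cluster_model` from [upgma].
#' @param K number of clusters (1..n leaves).
#' @return named integer vector of cluster memberships.
#' @export
cut_clusters <- function(model, K) {
  n <- length(model$labels)
  stop_if(!is_count(K) || K > n, "K must be an integer in 1..n")
  cutree(model$hclust, k = K)
}

#' Cophenetic distances of a cluster model
#' @param model a `cluster_model`.
#' @return symmetric matrix of cophenetic distances (original scale).
#' @export
cophenetic_distances <- function(model) {
  as.matrix(cophenetic(model$hclust))
}

#' Export a cluster model as a Newick tree
#' @param model a `cluster_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(model, path) {
  ape::write.tree(ape::as.phylo(model$hclust), file = path)
  invisible(path)
}
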