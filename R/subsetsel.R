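#' Selection configuration for nested breeder subsets
#'
#' @param subset_sizes strictly increasing target sizes (default
#'   24, 48, 96, 384, the nested subset ladder of the motivating study).
#' @param n_iter candidate draws per size (default 1000).
#' @param quantile feasibility quantile for the multi-criteria decision
#'   (default 0.21: candidates must sit in the lowest 21 percent on every
#'   criterion).
#' @param anchors accession IDs fixed into every subset (e.g. reference
#'   cultivars).
#' @param seed integer seed driving all candidate sampling.
#' @param relax_step quantile relaxation increment used only when no
#'   candidate satisfies all six criteria at the requested quantile.
#' @return object of class `selection_config`.
#' @export
selection_config <- function(subset_sizes = c(24, 48, 96, 384), n_iter = 1000,
                             quantile = 0.21, anchors = character(0),
                             seed = 1, relax_step = 0.01) {
  stop_if(any(diff(subset_sizes) <= 0), "subset_sizes must be strictly increasing")
  stop_if(!(quantile > 0 && quantile <= 1), "quantile must be in (0,1]")
  stop_if(n_iter < 2, "n_iter must be >= 2")
  structure(list(subset_sizes = as.integer(subset_sizes),
                 n_iter = as.integer(n_iter), quantile = quantile,
                 anchors = as.character(anchors), seed = as.integer(seed),
                 relax_step = relax_step),
            class = "selection_config")
}

# Precompute per-trait structures once so that thousands of candidate
# subsets can be scored cheaply. Returns a function(accession_ids) -> the
# six criteria, plus the trait bookkeeping.
make_criteria_scorer <- function(pt, kinds = NULL, min_n = 30) {
  kinds <- kinds %||% classify_traits(pt, min_n = min_n)
  ids <- pt$accession_ids
  cat_traits <- kinds$trait[kinds$kind == "categorical"]
  quant_traits <- kinds$trait[kinds$kind %in% c("quantitative", "semi_quantitative")]
  cats <- lapply(cat_traits, function(tr) {
    f <- factor(pt$table[[tr]])
    list(codes = setNames(as.integer(f), ids), n_cat = nlevels(f))
  })
  names(cats) <- cat_traits
  quants <- lapply(quant_traits, function(tr) {
    v <- setNames(suppressWarnings(as.numeric(pt$table[[tr]])), ids)
    vv <- v[!is.na(v)]
    list(values = v, full_min = min(vv), full_max = max(vv),
         full_mean = mean(vv), full_sd = sd(vv),
         full_spread = max(vv) - min(vv))
  })
  names(quants) <- quant_traits
  scorer <- function(subset_ids) {
    stop_if(length(subset_ids) == 0, "empty subset")
    losses <- vapply(cats, function(ct) {
      sub <- ct$codes[subset_ids]
      ct$n_cat - length(unique(sub[!is.na(sub)]))
    }, numeric(1))
    rho <- dev <- rep(NA_real_, length(quants))
    for (i in seq_along(quants)) {
      qt <- quants[[i]]
      sub <- qt$values[subset_ids]
      sub <- sub[!is.na(sub)]
      if (length(sub) == 0) {
        rho[i] <- 1   # total spread loss; excluded from mean deviation
        next
      }
      rho[i] <- if (qt$full_spread == 0) 0 else
        1 - (max(sub) - min(sub)) / qt$full_spread
      if (qt$full_sd > 0)
        dev[i] <- abs(mean(sub) - qt$full_mean) / qt$full_sd
    }
    c(c1_total_cat_loss = sum(losses),
      c2_mean_cat_loss = if (length(losses)) mean(losses) else 0,
      c3_max_cat_loss = if (length(losses)) max(losses) else 0,
      c4_mean_spread_reduction = if (length(rho)) mean(rho) else 0,
      c5_max_spread_reduction = if (length(rho)) max(rho) else 0,
      c6_mean_abs_std_mean_dev = if (any(!is.na(dev))) mean(dev, na.rm = TRUE) else 0)
  }
  list(score = scorer, kinds = kinds,
       n_categorical = length(cat_traits), n_quantitative = length(quant_traits))
}

#' Six phenotypic-loss criteria for a candidate subset
#'
#' Measures what a subset loses relative to the full collection. Per
#' categorical trait, the loss L is the number of categories present among
#' the full collection's non-missing values but absent from the subset:
#' c1 = total L, c2 = mean L, c3 = max L. Per quantitative or
#' semi-quantitative trait, the spread reduction is
#' `1 - spread_subset / spread_full` (spread = max - min over non-missing;
#' 0 if the full spread is 0): c4 = mean, c5 = max. c6 is the mean over
#' traits of `|mean_subset - mean_full| / sd_full` (traits with zero full
#' sd skipped). A trait with no non-missing subset value contributes its
#' full category count (categorical) or a spread reduction of 1, and is
#' excluded from c6. All six criteria are 0 when the subset is the full
#' collection.
#'
#' @param subset_ids accession IDs of the candidate subset.
#' @param pt a [phenotype_table] for the full collection.
#' @param kinds optional trait classification from [classify_traits]
#'   (discarded traits are ignored).
#' @return named numeric vector of the six criteria.
#' @export
criteria_scores <- function(subset_ids, pt, kinds = NULL) {
  make_criteria_scorer(pt, kinds)$score(subset_ids)
}

#' Draw one candidate subset: one accession per cluster
#'
#' The candidate contains every fixed accession, plus one uniform draw from
#' `cluster intersect directed_set` for each cluster holding no fixed
#' member (clusters with a fixed member contribute no extra draw). If a
#' cluster does not intersect the directed set (possible only when the
#' clustering is cut at a K other than the directed set's reference K),
#' the draw falls back to the whole cluster with a warning.
#'
#' @param assignment named cluster membership vector (names = accessions).
#' @param directed character vector: the directed sampling pool D.
#' @param fixed character vector of accessions forced into the candidate.
#' @return character vector of accession IDs.
#' @export
sample_candidate <- function(assignment, directed, fixed = character(0)) {
  stop_if(!all(fixed %in% names(assignment)),
          "fixed accession absent from the collection")
  fixed_cl <- unique(assignment[fixed])
  open <- setdiff(unique(assignment), fixed_cl)
  picks <- vapply(open, function(cl) {
    members <- names(assignment)[assignment == cl]
    pool <- intersect(members, directed)
    if (length(pool) == 0) {
      warning("cluster without directed-set member; sampling whole cluster")
      pool <- members
    }
    if (length(pool) == 1) pool else sample(pool, 1)
  }, character(1))
  c(fixed, unname(picks))
}

# empirical quantile rank: fraction of candidates with a strictly smaller
# score; tied candidates (including ties at the minimum) share the rank of
# the group, so identical score tables rank 0 everywhere
quantile_ranks <- function(scores) {
  apply(scores, 2, function(s) (rank(s, ties.method = "min") - 1) / length(s))
}

# the multi-criteria decision rule, applied to an n_candidates x 6 score
# matrix: feasible = all six quantile ranks <= quantile (relaxed upward by
# relax_step only when empty); winner = feasible candidate attaining the
# feasible-set minimum on the most criteria, ties broken by lowest rank
# sum, then lowest index
decide_winner <- function(scores, quantile, relax_step = 0.01) {
  ranks <- quantile_ranks(scores)
  q_eff <- quantile
  feasible <- which(apply(ranks <= q_eff, 1, all))
  relaxed <- FALSE
  while (length(feasible) == 0) {
    q_eff <- q_eff + relax_step
    relaxed <- TRUE
    feasible <- which(apply(ranks <= q_eff, 1, all))
    stop_if(q_eff > 1 + 1e-9, "relaxation failed")  # unreachable: ranks < 1
  }
  fmin <- apply(scores[feasible, , drop = FALSE], 2, min)
  n_best <- rowSums(sweep(scores[feasible, , drop = FALSE], 2, fmin, `==`))
  rank_sum <- rowSums(ranks[feasible, , drop = FALSE])
  o <- order(-n_best, rank_sum, feasible)
  list(winner = feasible[o[1]], ranks = ranks, effective_quantile = q_eff,
       relaxed = relaxed)
}

#' Select the best subset of a given size by iterative sampling
#'
#' Draws `n_iter` candidates via [sample_candidate] (seeded), scores all of
#' them on the six phenotypic-loss criteria, and applies the multi-criteria
#' decision rule: each candidate's empirical quantile rank per criterion is
#' the fraction of candidates scoring strictly lower; the feasible set
#' holds candidates whose six ranks are all at or below the quantile
#' (relaxed upward in `relax_step` increments, with a record, only if
#' empty); the winner is the feasible candidate attaining the feasible-set
#' minimum on the largest number of criteria, with ties broken by the
#' lowest sum of the six ranks, then by the lowest candidate index.
#'
#' @param assignment named cluster membership at the target K.
#' @param directed the directed sampling pool (character IDs).
#' @param scorer a scorer from `make_criteria_scorer` (or a
#'   [phenotype_table], from which one is built).
#' @param config a [selection_config] (its first size is ignored here;
#'   `n_iter`, `quantile`, `anchors`, `relax_step` are used).
#' @param fixed accessions forced into every candidate.
#' @param seed seed for this size's candidate stream.
#' @return list with `chosen` (accession IDs), `chosen_scores`,
#'   `chosen_ranks`, `effective_quantile`, `relaxed`, `candidates`
#'   (score data.frame), `winner_index`.
#' @export
select_subset <- function(assignment, directed, scorer, config, fixed = NULL,
                          seed = NULL) {
  if (inherits(scorer, "phenotype_table")) scorer <- make_criteria_scorer(scorer)
  fixed <- fixed %||% config$anchors
  seed <- seed %||% config$seed
  n_iter <- config$n_iter
  stop_if(n_iter < 2, "n_iter must be >= 2")
  stop_if(!all(fixed %in% names(assignment)),
          "fixed accession absent from the collection")
  # precompute per-cluster sampling pools (same draw law as sample_candidate)
  fixed_cl <- unique(assignment[fixed])
  open <- setdiff(unique(assignment), fixed_cl)
  pools <- lapply(open, function(cl) {
    members <- names(assignment)[assignment == cl]
    pool <- intersect(members, directed)
    if (length(pool) == 0) {
      warning("cluster without directed-set member; sampling whole cluster")
      pool <- members
    }
    pool
  })
  cand <- vector("list", n_iter)
  local_seed(seed, {
    for (i in seq_len(n_iter)) {
      picks <- vapply(pools, function(p)
        if (length(p) == 1) p else p[sample.int(length(p), 1)], character(1))
      cand[[i]] <- c(fixed, picks)
    }
  })
  scores <- t(vapply(cand, scorer$score, numeric(6)))
  dec <- decide_winner(scores, config$quantile, config$relax_step)
  win <- dec$winner
  list(chosen = cand[[win]], chosen_scores = scores[win, ],
       chosen_ranks = dec$ranks[win, ], effective_quantile = dec$effective_quantile,
       relaxed = dec$relaxed,
       candidates = as.data.frame(scores), winner_index = win)
}

#' Nested breeder-subset selection
#'
#' Iterates over the requested sizes in ascending order, cutting the same
#' UPGMA tree at each size so the clusterings nest. At each size the fixed
#' set is the anchors united with the previous winner; because finer cuts
#' refine coarser ones, distinct fixed accessions land in distinct
#' clusters and the chosen subsets nest. If several anchors share one
#' cluster at the smallest size, all anchors are kept, that cluster
#' contributes no extra draw, and the oversize is reported in the result
#' (never silently truncated).
#'
#' @param model a `cluster_model` from [upgma] covering all accessions.
#' @param directed a `directed_set` (or a character vector pool).
#' @param pt a [phenotype_table] for the full collection.
#' @param config a [selection_config]; sizes above the number of
#'   accessions are capped at it (with a note in the result).
#' @return object of class `breeder_subset_result`: per size, `chosen`,
#'   `scores`, `ranks`, `effective_quantile`, `relaxed`, `oversize`; plus
#'   `sizes`, `anchors`, `seed`, and the candidate score tables.
#' @export
nested_selection <- function(model, directed, pt, config = selection_config()) {
  pool <- if (inherits(directed, "directed_set")) directed$accessions else directed
  scorer <- make_criteria_scorer(pt)
  n <- length(model$labels)
  sizes <- unique(pmin(config$subset_sizes, n))
  fixed <- config$anchors
  stop_if(!all(fixed %in% model$labels), "anchor absent from the collection")
  out <- list()
  for (si in seq_along(sizes)) {
    K <- sizes[si]
    assignment <- cut_clusters(model, K)
    sel <- select_subset(assignment, pool, scorer, config, fixed = fixed,
                         seed = child_seed(config$seed, si))
    out[[as.character(K)]] <- list(
      K = K, chosen = sel$chosen, scores = sel$chosen_scores,
      ranks = sel$chosen_ranks, effective_quantile = sel$effective_quantile,
      relaxed = sel$relaxed, oversize = length(sel$chosen) - K,
      candidates = sel$candidates)
    fixed <- unique(c(config$anchors, sel$chosen))
  }
  structure(list(by_size = out, sizes = sizes, anchors = config$anchors,
                 seed = config$seed, quantile = config$quantile),
            class = "breeder_subset_result")
}

#' @export
print.breeder_subset_result <- function(x, ...) {
  cat("Nested breeder subsets (quantile ", x$quantile, ", seed ", x$seed, ")\n",
      sep = "")
  for (s in x$by_size) {
    cat(sprintf("  K=%d: %d accessions, max rank %.3f%s%s\n", s$K,
                length(s$chosen), max(s$ranks),
                if (s$relaxed) sprintf(" (quantile relaxed to %.2f)",
                                       s$effective_quantile) else "",
                if (s$oversize > 0) sprintf(" [oversize by %d: anchors share clusters]",
                                            s$oversize) else ""))
  }
  invisible(x)
}

#' Write nested-subset results as TSV + JSON manifest
#' @param res a `breeder_subset_result`.
#' @param prefix output prefix.
#' @return the paths, invisibly.
#' @export
write_subsets <- function(res, prefix) {
  paths <- character(0)
  for (s in res$by_size) {
    p <- sprintf("%s_subset_K%d.tsv", prefix, s$K)
    utils::write.table(data.frame(accession = sort(s$chosen)), p,
                       sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  manifest <- list(
    seed = res$seed, quantile = res$quantile, anchors = res$anchors,
    sizes = res$sizes,
    per_size = lapply(res$by_size, function(s)
      list(K = s$K, n = length(s$chosen), scores = as.list(s$scores),
           ranks = as.list(s$ranks), effective_quantile = s$effective_quantile,
           relaxed = s$relaxed, oversize = s$oversize)))
  mp <- paste0(prefix, "_selection.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}
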