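#' Classify descriptor traits and discard uninformative ones
#'
#' Traits with fewer than `min_n` non-missing observations are discarded.
#' Among the rest, numeric-valued traits with at most 9 distinct
#' small-integer levels are labelled semi-quantitative (ordinal scales,
#' treated with the quantitative rules downstream), other numeric traits
#' quantitative, and everything else categorical.
#'
#' @param pt a [phenotype_table].
#' @param min_n informativeness threshold on the non-missing count.
#' @return data.frame with `trait`, `kind`
#'   (`quantitative | semi_quantitative | categorical | discarded`), and
#'   `n_nonmissing`.
#' @export
classify_traits <- function(pt, min_n = 30) {
  stop_if(ncol(pt$table) == 0, "empty phenotype table")
  res <- lapply(names(pt$table), function(tr) {
    v <- pt$table[[tr]]
    nn <- sum(!is.na(v))
    kind <- if (nn < min_n) "discarded"
    else {
      num <- suppressWarnings(as.numeric(v[!is.na(v)]))
      if (anyNA(num)) "categorical"
      else if (length(unique(num)) <= 9 && all(num == floor(num)))
        "semi_quantitative"
      else "quantitative"
    }
    data.frame(trait = tr, kind = kind, n_nonmissing = nn,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Flag accessions with rare quantitative phenotypes
#'
#' `tail95` flags values outside the empirical 2.5/97.5 percent quantiles
#' (a 95 percent interval); `extreme10` flags outside the 5/95 percent
#' quantiles (the most extreme ~10 percent); `auto` picks `tail95` for
#' bell-shaped distributions (|sample skewness| <= 0.5) and `extreme10`
#' otherwise. Quantiles use linear interpolation; values tied with a
#' cutoff are all flagged.
#'
#' @param values named numeric vector (names = accession IDs; NA = missing).
#' @param mode `"auto"`, `"tail95"`, or `"extreme10"`.
#' @return list with `flagged` (accession names), `mode_used`, `cutoffs`.
#' @export
flag_rare_quantitative <- function(values, mode = c("auto", "tail95", "extreme10")) {
  mode <- match.arg(mode)
  ok <- !is.na(values)
  v <- values[ok]
  if (length(unique(v)) == 1) {
    warning("constant trait: nobody flagged")
    return(list(flagged = character(0), mode_used = mode,
                cutoffs = c(NA_real_, NA_real_)))
  }
  if (mode == "auto")
    mode <- if (abs(sample_skewness(v)) <= 0.5) "tail95" else "extreme10"
  probs <- if (mode == "tail95") c(0.025, 0.975) else c(0.05, 0.95)
  cut <- quantile(v, probs, type = 7, names = FALSE)
  flg <- names(v)[v <= cut[1] | v >= cut[2]]
  list(flagged = flg, mode_used = mode, cutoffs = cut)
}

#' Flag accessions carrying rare categories
#'
#' A category observed in strictly less than 10 percent of the non-missing
#' observations of a trait flags all of its carriers.
#'
#' @param values named character vector (names = accession IDs).
#' @param max_freq rarity threshold (strict inequality; default 0.10).
#' @return list with `flagged` and `rare_categories`.
#' @export
flag_rare_categorical <- function(values, max_freq = 0.10) {
  ok <- !is.na(values)
  v <- as.character(values[ok])
  tab <- table(v) / length(v)
  rare <- names(tab)[tab < max_freq]
  list(flagged = names(values)[ok][v %in% rare], rare_categories = rare)
}

#' Flag rare phenotypes across a whole descriptor table
#'
#' Applies [classify_traits], then [flag_rare_quantitative] (quantitative
#' and semi-quantitative traits) or [flag_rare_categorical] (categorical
#' traits) per trait, and unions the flagged accessions. Discarded traits
#' flag nobody.
#'
#' @param pt a [phenotype_table].
#' @param min_n informativeness threshold.
#' @param mode quantitative flagging mode (see [flag_rare_quantitative]);
#'   may also be a named character vector of per-trait overrides with an
#'   unnamed or `"default"` fallback.
#' @return object of class `rare_flag_report`: list with `per_trait`
#'   (data.frame trait/kind/rule/n_flagged), `flagged_by_trait` (list),
#'   `rare_set` (union of flagged accession IDs), `discarded`.
#' @export
rare_flag_report <- function(pt, min_n = 30, mode = "auto") {
  kinds <- classify_traits(pt, min_n = min_n)
  default_mode <- if (is.null(names(mode))) mode[1] else
    (mode[["default"]] %||% "auto")
  per <- list(); flags <- list()
  for (i in seq_len(nrow(kinds))) {
    tr <- kinds$trait[i]; kind <- kinds$kind[i]
    v <- pt$table[[tr]]
    names(v) <- pt$accession_ids
    if (kind == "discarded") {
      rule <- "discarded"; fl <- character(0)
    } else if (kind == "categorical") {
      rule <- "rare_category"
      fl <- flag_rare_categorical(v)$flagged
    } else {
      tr_mode <- if (!is.null(names(mode)) && tr %in% names(mode))
        mode[[tr]] else default_mode
      r <- suppressWarnings(
        flag_rare_quantitative(setNames(suppressWarnings(as.numeric(v)),
                                        names(v)), mode = tr_mode))
      rule <- r$mode_used; fl <- r$flagged
    }
    per[[i]] <- data.frame(trait = tr, kind = kind, rule = rule,
                           n_flagged = length(fl), stringsAsFactors = FALSE)
    flags[[tr]] <- fl
  }
  structure(list(per_trait = do.call(rbind, per),
                 flagged_by_trait = flags,
                 rare_set = sort(unique(unlist(flags))),
                 discarded = kinds$trait[kinds$kind == "discarded"],
                 kinds = kinds),
            class = "rare_flag_report")
}

#' Build the directed sampling set
#'
#' Unites the rare-phenotype accession set R with every accession from
#' genetic clusters (at the reference K) containing no member of R, so
#' that the resulting pool intersects every cluster while favouring
#' phenotypic extremes.
#'
#' @param rare_set character vector of rare-phenotype accession IDs.
#' @param assignment named cluster membership vector covering all
#'   accessions (names = accession IDs).
#' @return object of class `directed_set`: list with `accessions` (the
#'   pool D), `provenance` (`rare` or `cluster_representative`),
#'   `covered_clusters` (count of clusters containing a rare member),
#'   `n_clusters`.
#' @export
build_directed_set <- function(rare_set, assignment) {
  stop_if(is.null(names(assignment)), "assignment must be named by accession")
  rare_set <- intersect(rare_set, names(assignment))
  covered <- unique(assignment[rare_set])
  uncovered_acc <- names(assignment)[!(assignment %in% covered)]
  d <- c(rare_set, uncovered_acc)
  prov <- setNames(c(rep("rare", length(rare_set)),
                     rep("cluster_representative", length(uncovered_acc))), d)
  structure(list(accessions = d, provenance = prov,
                 covered_clusters = length(covered),
                 n_clusters = length(unique(assignment))),
            class = "directed_set")
}

#' @export
print.directed_set <- function(x, ...) {
  cat(sprintf(
    "directed_set: %d accessions (%d rare + %d from the %d clusters without a rare member; %d/%d clusters covered by rare set)\n",
    length(x$accessions), sum(x$provenance == "rare"),
    sum(x$provenance == "cluster_representative"),
    x$n_clusters - x$covered_clusters, x$covered_clusters, x$n_clusters))
  invisible(x)
}
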