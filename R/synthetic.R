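#' Configuration for the synthetic collection generator
#'
#' Defaults emulate the motivating germplasm collection: 604 hexaploid
#' accessions from 7 geographic regions (region sizes 47, 31, 33, 104, 168,
#' 102, 119), moderate differentiation (target Fst 0.05, close to the
#' observed mean of about 0.051 among regions), and within-chromosome LD
#' calibrated so that r-squared decays to about 0.1 within roughly 0.7 kb.
#' The locus count defaults to a desk-scale 5,000 (the real collection has
#' two orders of magnitude more markers; all per-locus statistics are
#' averages, so the scale does not change their meaning).
#'
#' @param n_accessions number of accessions.
#' @param n_loci number of biallelic loci.
#' @param ploidy ploidy (>= 2; default 6).
#' @param n_populations number of differentiated populations.
#' @param fst_target Balding-Nichols differentiation parameter F in `[0,1)`;
#'   0 degenerates to a single panmictic pool.
#' @param pop_sizes integer vector summing to `n_accessions`.
#' @param n_chromosomes,chrom_length_bp genome layout; positions are drawn
#'   uniformly (1-based) per chromosome.
#' @param ld_rho per-bp decay rate of the allele-copying weight
#'   `w = exp(-ld_rho * distance)`; adjacent-locus dosage r-squared is
#'   approximately `w^2`. `Inf` disables LD entirely.
#' @param missing_rate completely-at-random genotype missingness in `[0,1)`.
#' @param maf_floor lower bound of the ancestral allele frequency.
#' @param trait_spec data.frame describing traits (see [default_trait_spec]).
#' @param seed integer RNG seed; all outputs are deterministic given it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_accessions = 604, n_loci = 5000, ploidy = 6,
                       n_populations = 7, fst_target = 0.05,
                       pop_sizes = NULL, n_chromosomes = 15,
                       chrom_length_bp = 3e6, ld_rho = 0.00164,
                       missing_rate = 0.05, maf_floor = 0.05,
                       trait_spec = default_trait_spec(), seed = 1) {
  if (is.null(pop_sizes)) {
    if (n_accessions == 604 && n_populations == 7) {
      pop_sizes <- c(47, 31, 33, 104, 168, 102, 119)
    } else {
      base <- n_accessions %/% n_populations
      pop_sizes <- rep(base, n_populations)
      pop_sizes[seq_len(n_accessions - base * n_populations)] <-
        pop_sizes[seq_len(n_accessions - base * n_populations)] + 1L
    }
  }
  stop_if(!is_count(ploidy) || ploidy < 2, "ploidy must be an integer >= 2")
  stop_if(sum(pop_sizes) != n_accessions, "pop_sizes must sum to n_accessions")
  stop_if(length(pop_sizes) != n_populations, "need one size per population")
  stop_if(!is_fraction(fst_target), "fst_target must be in [0,1)")
  stop_if(!is_fraction(missing_rate), "missing_rate must be in [0,1)")
  stop_if(!is_fraction(maf_floor) || maf_floor >= 0.5,
          "maf_floor must be in [0, 0.5)")
  stop_if(!(is.numeric(ld_rho) && length(ld_rho) == 1 && ld_rho >= 0),
          "ld_rho must be a non-negative scalar (Inf allowed)")
  structure(list(
    n_accessions = as.integer(n_accessions), n_loci = as.integer(n_loci),
    ploidy = as.integer(ploidy), n_populations = as.integer(n_populations),
    fst_target = fst_target, pop_sizes = as.integer(pop_sizes),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.integer(chrom_length_bp), ld_rho = ld_rho,
    missing_rate = missing_rate, maf_floor = maf_floor,
    trait_spec = trait_spec, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default trait specification for the synthetic phenotype table
#'
#' A desk-scale stand-in for a GRIN-Global descriptor export: bell-shaped
#' and right-skewed quantitative traits, small-integer ordinal
#' (semi-quantitative) scales, categorical traits with and without rare
#' categories, and one sparsely observed trait so that downstream trait
#' discarding is exercised.
#'
#' @param n_quant,n_skewed,n_semi,n_categorical,n_rare_cat counts of each
#'   trait flavour; `n_rare_cat` of the categorical traits carry a rare
#'   category holding `rare_fraction` of the probability mass.
#' @param rare_fraction probability mass of the designated rare category
#'   (must be < 0.5: rare categories are minorities by definition).
#' @param missing_rate per-trait missingness applied to every trait except
#'   the sparse one.
#' @param sparse_nonmissing target non-missing count of the sparse trait
#'   (below the default informativeness threshold of 30).
#' @return data.frame with columns `name`, `kind`, `shape`, `rare_fraction`,
#'   `missing_rate`, `n_levels`.
#' @export
default_trait_spec <- function(n_quant = 7, n_skewed = 3, n_semi = 2,
                               n_categorical = 6, n_rare_cat = 2,
                               rare_fraction = 0.06, missing_rate = 0.1,
                               sparse_nonmissing = 10) {
  stop_if(rare_fraction >= 0.5, "rare_fraction must be < 0.5")
  stop_if(n_rare_cat > n_categorical, "n_rare_cat exceeds n_categorical")
  rows <- list()
  add <- function(name, kind, shape, rare, miss, lev)
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, kind = kind, shape = shape, rare_fraction = rare,
      missing_rate = miss, n_levels = lev, stringsAsFactors = FALSE)
  for (i in seq_len(n_quant))
    add(sprintf("quant_bell_%02d", i), "quantitative", "normal", 0, missing_rate, NA)
  for (i in seq_len(n_skewed))
    add(sprintf("quant_skew_%02d", i), "quantitative", "lognormal", 0, missing_rate, NA)
  for (i in seq_len(n_semi))
    add(sprintf("scale_1to9_%02d", i), "semi_quantitative", "ordinal", 0, missing_rate, 9)
  for (i in seq_len(n_categorical))
    add(sprintf("cat_%02d", i), "categorical", "categorical",
        if (i <= n_rare_cat) rare_fraction else 0, missing_rate, 4)
  add("sparse_trait", "quantitative", "normal", 0, NA, NA)
  out <- do.call(rbind, rows)
  attr(out, "sparse_nonmissing") <- sparse_nonmissing
  out
}

#' Simulate a polyploid germplasm collection
#'
#' Generates allele-dosage genotypes under the Balding-Nichols model:
#' ancestral frequencies `q_j ~ Uniform(maf_floor, 1 - maf_floor)`;
#' population frequencies `p_kj ~ Beta(q_j (1-F)/F, (1-q_j)(1-F)/F)` with
#' `F = fst_target` (for `F = 0`, `p_kj = q_j` exactly); dosages
#' `d_ij ~ Binomial(ploidy, p_kj)`. Within-chromosome LD is induced at the
#' homologue-copy level: scanning loci in position order, each of the
#' `ploidy` allele copies of an accession is copied from the previous locus
#' with probability `w = exp(-ld_rho * distance)` and drawn fresh otherwise,
#' which gives dosage-level r-squared of approximately `w^2` with monotone
#' decay in distance. Missing calls are introduced completely at random.
#'
#' @param config a [sim_config].
#' @return a list of class `sim_output`: `genotypes` ([dosage_matrix]),
#'   `phenotypes` ([phenotype_table]), `passport`
#'   ([population_assignment]), and `truth` (ancestral frequencies `q`,
#'   per-population frequency matrix `p`, population labels, locus layout).
#' @export
simulate_collection <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  local_seed(cfg$seed, {
    n <- cfg$n_accessions; L <- cfg$n_loci; m <- cfg$ploidy
    Fst <- cfg$fst_target
    # locus layout: loci spread round-robin over chromosomes, uniform positions
    chrom_of <- sort(rep_len(seq_len(cfg$n_chromosomes), L))
    chrom <- sprintf("chr%02d", chrom_of)
    pos <- integer(L)
    for (c in seq_len(cfg$n_chromosomes)) {
      idx <- which(chrom_of == c)
      pos[idx] <- sort(sample.int(cfg$chrom_length_bp, length(idx)))
    }
    o <- order(chrom, pos)
    chrom <- chrom[o]; pos <- pos[o]

    q <- runif(L, cfg$maf_floor, 1 - cfg$maf_floor)
    P <- matrix(0, cfg$n_populations, L)
    for (k in seq_len(cfg$n_populations)) {
      P[k, ] <- if (Fst == 0) q else
        rbeta(L, q * (1 - Fst) / Fst, (1 - q) * (1 - Fst) / Fst)
    }
    labels <- rep(seq_len(cfg$n_populations), cfg$pop_sizes)
    pop_names <- sprintf("region_%02d", seq_len(cfg$n_populations))
    acc_ids <- sprintf("acc%04d", seq_len(n))

    pmat <- P[labels, , drop = FALSE]   # n x L per-accession frequencies
    w <- exp(-cfg$ld_rho * c(NA, diff(pos)))
    w[c(TRUE, diff(match(chrom, unique(chrom))) != 0)] <- 0  # chromosome starts
    w[is.na(w)] <- 0
    if (all(w < 1e-12)) {
      dosage <- matrix(rbinom(n * L, m, as.vector(pmat)), n, L)
    } else {
      dosage <- matrix(0L, n, L)
      u_prev <- matrix(0L, n, m)
      for (l in seq_len(L)) {
        fresh <- matrix(rbinom(n * m, 1L, rep(pmat[, l], m)), n, m)
        if (w[l] > 1e-12) {
          keep <- matrix(runif(n * m) < w[l], n, m)
          u <- ifelse(keep, u_prev, fresh)
        } else u <- fresh
        dosage[, l] <- as.integer(rowSums(u))
        u_prev <- u
      }
    }
    if (cfg$missing_rate > 0)
      dosage[runif(n * L) < cfg$missing_rate] <- NA_integer_
    rownames(dosage) <- acc_ids
    geno <- dosage_matrix(dosage, chrom, pos, m)

    passport <- population_assignment(acc_ids, pop_names[labels])
    pheno <- simulate_traits(cfg, cluster_labels = labels,
                             accession_ids = acc_ids,
                             seed = child_seed(cfg$seed, 101))
    structure(list(
      genotypes = geno, phenotypes = pheno, passport = passport,
      truth = list(q = q, p = P, labels = labels, pop_names = pop_names,
                   chrom = chrom, pos = pos)
    ), class = "sim_output")
  })
}

#' Simulate a mixed-type phenotype table
#'
#' Quantitative traits are Normal (bell-shaped) or log-Normal (skewed);
#' semi-quantitative traits are 1..n_levels ordinal scales; categorical
#' traits place `rare_fraction` of their probability mass on a designated
#' rare category and split the remainder evenly. A mild per-cluster mean
#' shift links quantitative traits to genetic structure when cluster labels
#' are supplied. One sparse trait is emitted with fewer non-missing values
#' than the default informativeness threshold, so that trait discarding is
#' exercised downstream.
#'
#' @param config a [sim_config] (its `trait_spec` is used).
#' @param cluster_labels optional integer labels used for mean shifts.
#' @param accession_ids optional IDs (default `acc0001..`).
#' @param seed RNG seed (default derived from `config$seed`).
#' @return a [phenotype_table].
#' @export
simulate_traits <- function(config, cluster_labels = NULL,
                            accession_ids = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$trait_spec
  stop_if(is.null(spec) || nrow(spec) == 0, "trait_spec must be nonempty")
  stop_if(any(spec$rare_fraction >= 0.5), "rare_fraction must be < 0.5")
  n <- config$n_accessions
  accession_ids <- accession_ids %||% sprintf("acc%04d", seq_len(n))
  seed <- seed %||% child_seed(config$seed, 101)
  shift <- if (is.null(cluster_labels)) rep(0, n) else
    (cluster_labels - mean(cluster_labels)) * 0.4
  sparse_n <- attr(spec, "sparse_nonmissing") %||% 10
  local_seed(seed, {
    cols <- vector("list", nrow(spec))
    for (t in seq_len(nrow(spec))) {
      s <- spec[t, ]
      v <- switch(s$shape,
        normal = rnorm(n, 50, 10) + shift * 10,
        lognormal = exp(rnorm(n, 3, 0.6) + shift * 0.2),
        ordinal = pmin(s$n_levels, pmax(1, rbinom(n, s$n_levels - 1L, 0.5) + 1L)),
        categorical = {
          k <- s$n_levels
          pr <- if (s$rare_fraction > 0)
            c(rep((1 - s$rare_fraction) / (k - 1), k - 1), s$rare_fraction)
          else rep(1 / k, k)
          sample(paste0("cat", seq_len(k)), n, replace = TRUE, prob = pr)
        },
        stop("unknown trait shape: ", s$shape))
      if (is.na(s$missing_rate)) {
        # sparse trait: keep only sparse_n observations
        drop <- sample.int(n, max(0L, n - sparse_n))
        v[drop] <- NA
      } else if (s$missing_rate > 0) {
        v[runif(n) < s$missing_rate] <- NA
      }
      cols[[t]] <- v
    }
    names(cols) <- spec$name
    df <- as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
    rownames(df) <- accession_ids
    phenotype_table(df)
  })
}
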