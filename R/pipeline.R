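#' Run the full analysis pipeline on a synthetic or supplied collection
#'
#' Orchestrates simulate -> marker QC -> diversity -> kinship/UPGMA ->
#' structure (PCA, K-means/BIC, DAPC) -> rare-phenotype flagging ->
#' nested subset selection, with fail-fast semantics. Any stage input can
#' be supplied externally through `genotypes` / `phenotypes` / `passport`,
#' in which case simulation is skipped. When `out_dir` is given, stage
#' outputs are written as TSV/CSV/JSON and a manifest with per-stage
#' timings and file digests is saved; reruns with the same config and seed
#' reproduce the digests bit for bit.
#'
#' @param sim a [sim_config] used when no genotypes are supplied.
#' @param genotypes,phenotypes,passport optional externally supplied
#'   inputs ([dosage_matrix], [phenotype_table], [population_assignment]).
#' @param qc a [filter_config]; set `NULL` to skip filtering/pruning.
#' @param selection a [selection_config]; its anchors default to the first
#'   accession of each simulated population when unset.
#' @param n_pca PCs retained for structure analysis (capped at the data).
#' @param k_max largest K for the K-means/BIC scan.
#' @param out_dir optional output directory.
#' @return object of class `pipeline_result`: list with all stage outputs
#'   and a `manifest` (config echo, seeds, timings, digests).
#' @export
run_pipeline <- function(sim = sim_config(), genotypes = NULL,
                         phenotypes = NULL, passport = NULL,
                         qc = filter_config(min_depth = 0),
                         selection = selection_config(),
                         n_pca = 50, k_max = 8, out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timings[[name]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  simulated <- is.null(genotypes)
  if (simulated) {
    so <- simulate_collection(sim)
    genotypes <- so$genotypes
    phenotypes <- phenotypes %||% so$phenotypes
    passport <- passport %||% so$passport
    truth <- so$truth
  } else truth <- NULL
  stop_if(is.null(phenotypes), "phenotypes required")
  stop_if(is.null(passport), "passport required")
  tick("simulate")

  if (!is.null(qc)) {
    filt <- filter_markers(genotypes, qc)
    pruned <- ld_prune(filt$genotypes, qc)
    geno <- pruned$genotypes
    qc_report <- list(filter = filt$report,
                      n_pruned = length(pruned$pruned_locus_ids))
  } else {
    geno <- genotypes
    qc_report <- NULL
  }
  tick("qc")

  diversity <- diversity_table(geno, passport)
  tick("diversity")

  G <- grm_autopolyploid(geno)
  model <- upgma(kinship_to_distance(G))
  tick("cluster")

  n_pca <- min(n_pca, nrow(geno$dosage) - 1, ncol(geno$dosage))
  basis <- pca_dosage(geno, n_pca)
  km <- kmeans_bic(basis$scores, k_max = k_max, seed = child_seed(sim$seed, 7))
  kl <- km$assignments[[as.character(km$best_k)]]
  dapc <- if (km$best_k >= 2 && all(table(kl) >= 2))
    dapc_fit(basis, kl, n_pc = min(n_pca, 20)) else NULL
  assign_q <- if (!is.null(dapc)) assign_by_q(dapc$Q) else NULL
  tick("structure")

  rare <- rare_flag_report(phenotypes)
  ref_k <- min(max(selection$subset_sizes), length(model$labels))
  directed <- build_directed_set(rare$rare_set, cut_clusters(model, ref_k))
  tick("rare")

  if (length(selection$anchors) == 0) {
    first_per_pop <- tapply(passport$accession, passport$population, `[`, 1)
    selection$anchors <- as.character(
      first_per_pop[seq_len(min(4, length(first_per_pop)))])
  }
  subsets <- nested_selection(model, directed, phenotypes, selection)
  tick("select")

  result <- structure(list(
    genotypes = geno, phenotypes = phenotypes, passport = passport,
    truth = truth, qc_report = qc_report, diversity = diversity,
    grm = G, cluster_model = model, pca = basis, kmeans = km, dapc = dapc,
    assignment_q = assign_q, rare = rare, directed = directed,
    subsets = subsets,
    manifest = list(seed = sim$seed, simulated = simulated,
                    n_accessions = nrow(geno$dosage),
                    n_loci = ncol(geno$dosage),
                    anchors = selection$anchors, timings = timings)
  ), class = "pipeline_result")
  if (!is.null(out_dir)) result$manifest$files <- write_pipeline(result, out_dir)
  result
}

# write stage outputs and return named md5 digests
write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, paste0(...))
  write_dosage_csv(result$genotypes, p("genotypes.csv"))
  write_phenotypes(result$phenotypes, p("phenotypes.csv"))
  write_passport(result$passport, p("passport.csv"))
  write_diversity(result$diversity, file.path(out_dir, "tables"))
  write_newick(result$cluster_model, p("upgma.nwk"))
  utils::write.table(result$rare$per_trait, p("rare_traits.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(accession = result$directed$accessions,
                                provenance = unname(result$directed$provenance)),
                     p("directed_set.tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  write_subsets(result$subsets, file.path(out_dir, "breeder"))
  files <- list.files(out_dir, full.names = TRUE, recursive = TRUE)
  dig <- tools::md5sum(files)
  names(dig) <- basename(files)
  as.list(dig)
}
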