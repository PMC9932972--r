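# polycore

Dosage-based genetic diversity analysis and breeder-subset selection for
autopolyploid germplasm collections.

## The problem

Genebanks for clonally propagated polyploids — the motivating case is the
hexaploid sweetpotato (*Ipomoea batatas*, 2n = 6x = 90) germplasm
collection — need two things from a genotyping campaign: an honest picture
of the collection's diversity and structure, and small, nested "breeder
subsets" of accessions that preserve as much of the collection's genotypic
and phenotypic diversity as possible while being cheap to maintain and
phenotype. Both must work on *allele dosages*: at a biallelic SNP a
hexaploid carries an integer 0..6 alternate-allele count, not a diploid
genotype, so diploid toolchains do not apply directly.

`polycore` implements the full post-variant-calling pipeline on dosage
matrices:

* **Marker QC** — depth / missingness / MAF filtering with an auditable
  per-step report; composite LD (squared Pearson correlation of dosage
  vectors, `r²`) with greedy pruning that drops the lower-MAF member of
  any same-chromosome pair with `r² > 0.1`; LD-decay distance estimation
  from a smoothed `r²`-vs-distance curve.
* **Diversity** — per-population PIC, effective alleles `Ae = 1/Σp²`,
  rarefied allelic richness `Ar(g) = Σᵢ[1 − C(N−Nᵢ,g)/C(N,g)]`, Shannon
  index, private alleles; pairwise Hudson F<sub>ST</sub> (Bhatia
  ratio-of-sums form) and Nei's (1972) standard distance
  `D_s = −ln(J_xy/√(J_x J_y))`.
* **Kinship & clustering** — full-autopolyploid genomic relationship
  matrix `G = ZZ′/(m Σ p(1−p))` on frequency-centered dosages, cosine
  distance, UPGMA trees, nested cluster cuts at any K.
* **Structure** — PCA of dosages, K-means with
  `BIC(K) = n·ln(WSS/n) + K·ln(n)`, DAPC (LDA on retained PCs with
  Gaussian posterior memberships), cross-validated choice of the PC
  count, and q-threshold (default 0.65) assigned/admixed calls.
* **Breeder subsets** — rare-phenotype flagging of GRIN-Global-style
  descriptor tables (quantitative tails, rare categories < 10%), the
  *directed set* (rare accessions plus all members of genetic clusters
  they miss), and iterative nested subset selection: 1,000 candidates per
  size (one accession per cluster, anchors fixed), six phenotypic-loss
  criteria, and a lowest-21%-quantile multi-criteria decision rule.
* **Synthetic collections** — a seedable generator (Balding–Nichols
  differentiation, copy-level LD with `r² ≈ exp(−2ρ·distance)`,
  mixed-type trait tables) so the whole pipeline is testable offline.

See `vignettes/polycore-methods.Rmd` for the models, assumptions, and
design choices.

## Worked example

```r
library(polycore)

cfg <- sim_config(n_accessions = 150, n_loci = 1000, n_populations = 3,
                  pop_sizes = c(50, 50, 50), fst_target = 0.08,
                  n_chromosomes = 5, seed = 42)
so <- simulate_collection(cfg)
so$genotypes
#> dosage_matrix: 150 accessions x 1000 loci (ploidy 6, 5 chromosome(s), 5.0% missing)

qc <- filter_markers(so$genotypes, filter_config(min_depth = 0))
qc$report
#>               step removed
#> 1 depth_mask_cells       0
#> 2    locus_missing       0
#> 3   sample_missing       0
#> 4              maf      39

pruned <- ld_prune(qc$genotypes, filter_config(ld_r2_threshold = 0.1))
ncol(pruned$genotypes$dosage)
#> [1] 389

diversity_table(pruned$genotypes, so$passport)
#> Diversity summary (Hudson (Bhatia et al. 2013), ratio of sums)
#>   population   n k    PIC    Ae Ar      I NP
#> 1        all 150 2 0.2968 1.653  2 0.5533  0
#> 2  region_01  50 2 0.2918 1.640  2 0.5447  0
#> 3  region_02  50 2 0.2905 1.631  2 0.5419  0
#> 4  region_03  50 2 0.2908 1.632  2 0.5423  0
#> global Fst (pooled over pairs): 0.0294
```

Each row averages per-locus indices over loci; `k` and `Ar` are at most 2
under the biallelic allele definition, and `NP = 0` because at this
sample size every allele segregates in every region. Note the global
F<sub>ST</sub> (0.029) sits below the simulated 0.08: pooling
differentiated populations induces admixture LD, so pruning at
`r² > 0.1` preferentially removes differentiated loci — an expected
effect of LD filtering under structure, visible here because the
generator's truth is known.

```r
G    <- grm_autopolyploid(pruned$genotypes)
tree <- upgma(kinship_to_distance(G))
rare <- rare_flag_report(so$phenotypes)
directed <- build_directed_set(rare$rare_set, cut_clusters(tree, 150))
directed
#> directed_set: 150 accessions (92 rare + 58 from the 58 clusters without
#> a rare member; 92/150 clusters covered by rare set)

nested_selection(tree, directed, so$phenotypes,
                 selection_config(subset_sizes = c(12, 24, 48), n_iter = 500,
                                  anchors = c("acc0001", "acc0051", "acc0101"),
                                  seed = 42))
#> Nested breeder subsets (quantile 0.21, seed 42)
#>   K=12: 12 accessions, max rank 0.104
#>   K=24: 24 accessions, max rank 0.086
#>   K=48: 48 accessions, max rank 0.114
```

Each chosen subset contains the three anchors, one accession per UPGMA
cluster at its K, nests inside the next larger subset, and sits within
the lowest 21% of its 500 candidates on all six phenotypic-loss criteria
(the "max rank" line is the worst of the six quantile ranks).

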