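---
title: "Methods: dosage-based diversity analysis and breeder subset selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosage-based diversity analysis and breeder subset selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polycore)
```

## Scope and data model

`polycore` analyses allele-dosage genotypes of autopolyploid germplasm
collections. The motivating system is hexaploid sweetpotato (*Ipomoea
batatas*, 2n = 6x = 90): at a biallelic SNP each accession carries an
integer dosage 0..6, the count of the alternate allele among its six
homologue copies. The central container, `dosage_matrix`, holds the
accessions x loci integer matrix (`NA` = missing call), per-locus
chromosome and 1-based position, and the ploidy. All statistics treat an
accession as `ploidy` independent gene copies (a polysomic model). This is
the standard first-order treatment for hexasomic inheritance; it ignores
double reduction and preferential pairing, which would require genotype
(not allele) frequency models.

## Marker QC

Filtering applies four steps in a fixed, reported order: (1) genotype
calls below the read-depth floor are set missing (default 45, the
conventional floor for confident hexaploid dosage calls; 6 and 25 are the
diploid/tetraploid analogues), (2) loci with missing rate > 0.3 are
dropped, (3) samples with missing rate > 0.3 are dropped, (4) loci with
MAF < 0.05 are dropped. The thresholds are the defaults of
`filter_config()`; the order is a package choice (the thresholds, not the
order, are what practice fixes) and the per-step removal counts are
returned so the composition is auditable.

Allele frequencies are dosage-count estimates,
`p = sum(d) / (ploidy * n_nonmissing)`. Inheritance-model-based
estimators (e.g. likelihood under disomic/polysomic mixtures) exist in
specialised software whose internals are not reproducible here; the
count-based estimator is transparent, unbiased under polysomy, and is
used consistently for MAF filtering and LD tie-breaking.

Composite LD is the squared Pearson correlation of two dosage vectors
over pairwise-complete accessions — the genotype-level (phase-free) LD
measure appropriate for unphased polyploid calls. Pruning scans each
chromosome in position order and greedily removes the lower-MAF member of
any surviving pair with r² above the threshold (default 0.1); MAF ties
keep the earlier locus, removed loci take no further part, and the
traversal is deterministic. The traversal order is a package convention:
only the drop rule (lower MAF goes) is externally fixed. MAF for
tie-breaking is computed after missingness filtering.

LD decay is estimated from all within-chromosome pairs up to a distance
cap (default 100 kb; pairs are subsampled reproducibly above 10^6), by a
cubic smoothing spline fitted to distance-binned mean r². A generalized
additive model would serve equally; the binned-spline smoother keeps the
dependency surface small, is monotone-stable on the bin means, and its
identity is recorded in the output metadata. The decay distance at a
threshold is the first grid point where the smoothed curve falls below
it; if the curve never crosses, the result is flagged "not reached"
rather than extrapolated.

## Diversity and differentiation

Per population (and pooled), the per-locus indices are averaged over
loci: number of distinct alleles k, Botstein's polymorphic information
content `PIC = 1 - Σp² - Σ_{i<j} 2 p_i² p_j²`, effective alleles
`Ae = 1/Σp²`, Shannon index `I = -Σ p ln p`, rarefied allelic richness
`Ar(g) = Σ_i [1 - C(N - N_i, g)/C(N, g)]` with g defaulting per locus to
the smallest population's gene-copy count, and the mean count of private
alleles (frequency positive in one population, zero in all others). Under
the biallelic SNP definition k is at most 2 per locus, so k and Ar sit in
[1, 2]; software that recodes loci multi-allelically will report larger
magnitudes that are not comparable to these.

Pairwise differentiation uses the Hudson FST estimator in the Bhatia et
al. (2013) ratio-of-sums form, with sample sizes in gene copies. It is
unbiased to first order, requires no inbreeding model, and has a clean
parameter-recovery check: on Balding-Nichols simulations it returns the
simulated F (the test suite verifies ±0.015 across F in 0.02..0.2). A
global value pools numerators and denominators over all population pairs;
the aggregation rule is reported alongside the value because "global FST"
is not uniquely defined for more than two populations. Nei's (1972)
standard distance is computed ratio-of-means over loci,
`D_s = -ln(J_xy / sqrt(J_x J_y))`, with both alleles of each biallelic
locus entering the gene-identity sums.

## Kinship and clustering

The genomic relationship matrix generalizes VanRaden's method to ploidy
m: `G = ZZ' / (m Σ p(1-p))` with `Z = M - mP` the frequency-centered
dosages. Missing dosages are mean-imputed (to `m p_j`) before centering —
the alternative, pairwise-complete normalization, loses positive
semidefiniteness, which downstream eigen-based checks and distance
conversion rely on. Monomorphic loci are excluded from numerator and
denominator. The relationship-to-distance transform is cosine-style,
`d_ij = 1 - G_ij / sqrt(G_ii G_jj)`, clipped at zero: it maps clones to
distance 0 regardless of their inbreeding level, which a naive `1 - G`
does not.

Trees are built by average-linkage agglomeration (UPGMA) via
`stats::hclust`; an hclust "complete" option is exposed because the two
names are sometimes conflated in applied reports, but UPGMA is the
default and the linkage used is recorded in the model object. Node
heights are reported on the ultrametric scale (half the merge distance),
so two leaves at distance d join at height d/2; cophenetic distances stay
on the input scale. Tie handling among exactly equal merge candidates
follows hclust's deterministic order. Cluster assignments at any K come
from cutting the single tree, which guarantees that finer cuts refine
coarser ones — the property the nested subset selection depends on.

## Population structure

PCA mean-imputes missing dosages per locus, centers columns, and uses the
SVD, with a deterministic sign convention (largest-magnitude loading
positive). K selection runs best-of-restarts K-means for K = 1..k_max and
evaluates `BIC(K) = n ln(WSS/n) + K ln(n)`. Two caveats are worth
stating. First, the full curve is returned and the argmin reported, but a
local valley can be more informative than the global minimum when the
curve flattens. Second, this WSS-based BIC is meaningful on genotype PC
scores — where group separation is concentrated on a few axes on top of
high-dimensional sampling noise — and will overfit low-dimensional,
tightly clustered toy data, where any split of Gaussian noise reduces WSS
faster than the `K ln n` penalty grows. The tests therefore exercise it
on simulated collections, its actual domain.

DAPC fits a linear discriminant analysis on the leading PC scores:
discriminant axes from the generalized eigenproblem of between- and
pooled within-class scatter (a ridge of `1e-8 * trace` is added, with a
message, if the within-class scatter is numerically singular), accession
coordinates on at most K-1 axes, and posterior memberships Q from the
Gaussian class model with shared covariance and proportional priors. The
implementation is self-contained so the ridge and posterior definitions
are exactly as stated; the test suite cross-checks it against an
independent LDA implementation. The number of retained PCs is chosen by
stratified repeated holdout (default 10% held out, 30 repetitions):
maximize mean assignment success, break ties by lower mean squared error
`mean((1 - Q_true)²)`, then by fewer PCs. This replaces alpha-score
optimisation with spline interpolation, whose exact procedure is
package-internal elsewhere and not reproducible; the cross-validated
selector optimises the same two published criteria directly. Ancestry
thresholding assigns an accession to its argmax cluster when max Q >= the
q-threshold (default 0.65) and calls it admixed otherwise.

## Rare phenotypes and the directed set

Descriptor tables are typed automatically: traits with fewer than 30
non-missing values are discarded as uninformative (30 is a package
choice standing in for a judgement call), numeric traits with <= 9
distinct integer levels are semi-quantitative (ordinal scales, handled by
the quantitative rules), remaining numeric traits quantitative, all else
categorical. Quantitative flagging has two tail definitions: `tail95`
flags outside the empirical 2.5/97.5 percent quantiles (a 95 percent
interval), `extreme10` outside 5/95 (the most extreme ~10 percent). The
`auto` mode routes bell-shaped traits (|sample skewness| <= 0.5) to
`tail95` and skewed traits to `extreme10`, replacing by-eye histogram
judgement with an explicit, overridable rule; both readings of "the
extreme tails" are exposed because applied descriptions of the cutoff are
ambiguous between 2.5+2.5 and 5+5. Values tied with a cutoff are all
flagged. Categorical flagging marks carriers of categories at strictly
less than 10 percent frequency among non-missing observations.

The directed sampling set D unites the rare-phenotype accessions R with
every accession of clusters (at the reference K, default 384 or n if
smaller) containing no member of R. By construction D intersects every
cluster, and since coarser cuts are unions of finer ones, D intersects
every cluster at all smaller K too.

## Nested breeder-subset selection

At each target size K (default ladder 24, 48, 96, 384), 1,000 candidate
subsets are drawn: every fixed accession (the anchors plus, after the
first size, the previous winner) enters, and each cluster without a fixed
member contributes one uniform draw from its intersection with D. All
candidates are scored on six phenotypic-loss criteria against the full
collection:

* c1/c2/c3 — total / mean / maximum number of categories lost per
  categorical trait (a category counts as lost when present among the
  collection's non-missing values but absent from the subset's);
* c4/c5 — mean / maximum reduction in spread, `1 - spread_sub/spread_full`
  with spread = max - min, over quantitative and semi-quantitative traits;
* c6 — mean standardized deviation of the subset trait mean,
  `|mean_sub - mean_full| / sd_full` (zero-variance traits skipped).

A trait with no non-missing subset value contributes its full category
count, or a spread reduction of 1, and is excluded from c6. c2 is the
unnormalized mean of per-trait losses; c6 standardizes by the full
collection's standard deviation so traits on different scales are
commensurable.

The decision rule: each candidate's quantile rank per criterion is the
fraction of candidates with a strictly smaller score. Tied candidates
share the rank of their group, so the tied-at-minimum group ranks 0 —
with the practical consequences that an all-tied criterion disqualifies
nobody and that degenerate pools (e.g. a size cap equal to the collection
size, where every candidate is the whole collection) are feasible rather
than paradoxically infeasible, which a midrank convention would make
them. The feasible set contains candidates at or below the quantile
(default 0.21) on all six criteria; only if it is empty is the quantile
relaxed upward in 0.01 steps, with the relaxation recorded in the result.
The winner is the feasible candidate attaining the feasible-set minimum
on the most criteria, ties broken by the lowest sum of the six ranks,
then by the lowest candidate index — a fully deterministic chain, since
"best on a majority of criteria" alone does not always single out one
candidate. Candidate draws are not deduplicated. Sizes above the
collection size are capped at it. If several anchors share one cluster at
the smallest size the subset exceeds K by the overlap; this is reported
prominently in the result, never silently truncated.

Because each size fixes the previous winner and cluster cuts nest, the
chosen subsets nest (24 ⊂ 48 ⊂ 96 ⊂ 384), contain the anchors, and hold
exactly one member per cluster except where multiple fixed members share
one.

## The synthetic collection generator

The generator exists so every stage is testable without external data.
Differentiation follows the Balding-Nichols model: ancestral frequencies
`q ~ Uniform(maf_floor, 1 - maf_floor)`, population frequencies
`p ~ Beta(q(1-F)/F, (1-q)(1-F)/F)`, dosages `Binomial(ploidy, p)`. The
model was chosen because its differentiation parameter F is exactly the
quantity the Hudson estimator recovers, giving closed-loop
parameter-recovery tests; `F = 0` degenerates cleanly to panmixia. LD is
induced at the homologue-copy level: scanning loci in position order,
each of an accession's `ploidy` allele copies is carried over from the
previous locus with probability `w = exp(-ld_rho * distance)` and redrawn
otherwise. Copy-level correlation w makes dosage-level r² ≈ w² with
exact Markov decay across loci, and the construction is fast and
ploidy-consistent. Missingness is completely at random; positions are
uniform per chromosome (1-based).

Defaults mirror the motivating collection where it states conditions:
604 accessions in 7 regions of sizes 47/31/33/104/168/102/119, ploidy 6,
15 chromosomes, target F = 0.05 (the observed mean regional
differentiation is about 0.051), and `ld_rho = 0.00164` per bp so that r²
decays to 0.1 within roughly 0.7 kb, matching the reported decay scale.
The locus count defaults to a desk-scale 5,000 rather than the >10^5 of
the real data; every reported statistic is a per-locus average or a
ratio of per-locus sums, so scale affects Monte-Carlo error, not meaning.
The default trait table has 20 traits (bell-shaped, log-normal skewed,
1-9 ordinal, categorical with and without rare categories, plus one
sparse trait that exercises discarding) rather than the 117 descriptors
of a full GRIN-Global export; trait counts only average into the six
criteria. Cluster labels can shift quantitative trait means so phenotype
correlates mildly with structure.

What the generator does *not* emulate: genotyping error and dosage
miscalling, depth-dependent missingness, pedigree/clonal substructure
within regions, admixed individuals, and non-random descriptor
missingness. Passing tests therefore demonstrate correctness of the
algorithms under the stated models, not robustness to those real-data
pathologies.

## Problem sizes and reproducibility

The test suite and the acceptance script run simulations at 90-420
accessions and 300-5,000 loci with 60-1,000 selection iterations — sizes
chosen so the whole battery completes in minutes on one core while
keeping Monte-Carlo error well inside the asserted tolerances (e.g. FST
recovery to ±0.015 uses 2 x 200 accessions x 5,000 loci x 10 seeds).
Every stochastic routine takes an explicit integer seed, restores the
caller's RNG state, and derives per-stage child seeds, so identical
configurations reproduce results bit for bit; the pipeline writes md5
digests of its outputs to make this checkable.

## Known limitations

* Allele-frequency-based indices assume polysomic gene-copy counting;
  no correction for double reduction or mixed inheritance.
* Biallelic loci only; multiallelic VCF records are skipped, not split.
* The Hudson estimator is a two-population measure; the pooled "global"
  value is one of several defensible aggregations.
* LD pruning is O(L²) per chromosome on the r² matrix; for very dense
  maps a window (`ld_window_bp`) should be set.
* Bayesian admixture (MCMC) inference is out of scope; externally
  computed Q matrices can be fed to `assign_by_q()`.
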