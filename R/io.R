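#' Construct a dosage matrix
#'
#' The central genotype container: an accessions x loci matrix of integer
#' allele-dosage calls (count of the alternate allele among the `ploidy`
#' homologue copies, 0..ploidy), with `NA` marking missing calls, plus
#' per-locus chromosome and 1-based physical position. Loci are stored
#' sorted by (chromosome, position).
#'
#' @param dosage integer matrix, accessions in rows (rownames = accession
#'   IDs), loci in columns (colnames = locus IDs; defaults to
#'   `"chrom:pos"`). `NA` = missing call.
#' @param chrom character vector of per-locus chromosome labels.
#' @param pos integer vector of per-locus 1-based positions (bp).
#' @param ploidy integer ploidy level (>= 2); 6 for hexaploid sweetpotato.
#' @param dp optional integer matrix of per-call read depths, same shape
#'   as `dosage`.
#' @return an object of class `dosage_matrix` with elements `dosage`,
#'   `chrom`, `pos`, `ploidy` and optionally `dp`.
#' @export
dosage_matrix <- function(dosage, chrom, pos, ploidy, dp = NULL) {
  dosage <- as.matrix(dosage)
  stop_if(!is_count(ploidy) || ploidy < 2, "ploidy must be an integer >= 2")
  stop_if(length(chrom) != ncol(dosage) || length(pos) != ncol(dosage),
          "chrom/pos length must equal the number of loci")
  stop_if(any(pos < 1) || any(pos != floor(pos)), "positions must be integers >= 1")
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("acc%04d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0(chrom, ":", pos)
  stop_if(anyDuplicated(rownames(dosage)) > 0, "duplicate accession IDs")
  stop_if(anyDuplicated(colnames(dosage)) > 0, "duplicate locus IDs")
  bad <- !is.na(dosage) & (dosage < 0 | dosage > ploidy | dosage != floor(dosage))
  stop_if(any(bad), "dosage values must be integers in [0, ploidy] or NA")
  o <- order(chrom, pos)
  x <- structure(list(
    dosage = dosage[, o, drop = FALSE],
    chrom = as.character(chrom)[o],
    pos = as.integer(pos)[o],
    ploidy = as.integer(ploidy)
  ), class = "dosage_matrix")
  if (!is.null(dp)) {
    dp <- as.matrix(dp)
    stop_if(!all(dim(dp) == dim(dosage)), "dp must have the shape of dosage")
    x$dp <- dp[, o, drop = FALSE]
  }
  x
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("dosage_matrix: %d accessions x %d loci (ploidy %d, %d chromosome(s), %.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage), x$ploidy,
              length(unique(x$chrom)),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.dosage_matrix <- function(x) dim(x$dosage)

accessions <- function(g) rownames(g$dosage)
loci <- function(g) colnames(g$dosage)

# subset a dosage_matrix by accession and/or locus index
subset_dosage <- function(g, acc = NULL, loc = NULL) {
  acc <- acc %||% seq_len(nrow(g$dosage))
  loc <- loc %||% seq_len(ncol(g$dosage))
  dosage_matrix(g$dosage[acc, loc, drop = FALSE], g$chrom[loc], g$pos[loc],
                g$ploidy, dp = if (!is.null(g$dp)) g$dp[acc, loc, drop = FALSE])
}

#' Construct a phenotype table
#'
#' Accession x trait table in GRIN-Global descriptor export style: one
#' column per descriptor, mixed categorical/quantitative values, `NA` for
#' missing observations.
#'
#' @param table data.frame of trait values with accession IDs as row names
#'   (or in a column named `accession`).
#' @return object of class `phenotype_table` with elements `table`
#'   (data.frame) and `accession_ids`.
#' @export
phenotype_table <- function(table) {
  if ("accession" %in% names(table)) {
    ids <- as.character(table$accession)
    table <- table[, setdiff(names(table), "accession"), drop = FALSE]
    rownames(table) <- ids
  }
  stop_if(is.null(rownames(table)), "accession IDs required as row names")
  stop_if(anyDuplicated(rownames(table)) > 0, "duplicate accession IDs")
  structure(list(table = table, accession_ids = rownames(table)),
            class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("phenotype_table: %d accessions x %d traits (%.1f%% missing)\n",
              nrow(x$table), ncol(x$table),
              100 * mean(is.na(as.matrix(x$table)))))
  invisible(x)
}

#' Construct a population (passport) assignment
#'
#' @param accession character vector of accession IDs.
#' @param population character vector of population / region labels;
#'   missing labels are replaced by `"unknown"`.
#' @param country optional character vector of countries.
#' @return object of class `population_assignment` (a data.frame).
#' @export
population_assignment <- function(accession, population, country = NULL) {
  stop_if(anyDuplicated(accession) > 0, "duplicate accession IDs")
  population <- as.character(population)
  population[is.na(population) | population == ""] <- "unknown"
  df <- data.frame(accession = as.character(accession),
                   population = population,
                   stringsAsFactors = FALSE)
  if (!is.null(country)) df$country <- as.character(country)
  structure(df, class = c("population_assignment", "data.frame"))
}

# -------------------------------------------------------------------------
# VCF

#' Read hexaploid (or other polyploid) dosages from a VCF file
#'
#' Parses a VCF 4.2 file with per-sample GT (and optionally DP) fields and
#' converts each biallelic genotype into an integer alternate-allele dosage.
#' `"/"` and `"|"` separators are both accepted (dosage is phase-invariant);
#' a GT containing any `"."` allele is treated as missing. Multiallelic
#' records are skipped with a message.
#'
#' @param path path to an uncompressed or bgzipped VCF.
#' @param ploidy expected GT arity; a non-missing call with a different
#'   arity is an error naming the record and sample.
#' @return a [dosage_matrix] (with `dp` if the VCF carries DP).
#' @export
read_vcf_dosage <- function(path, ploidy = 6) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix  # always a matrix, even for a single record
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  # sortedness check: positions must be non-decreasing within each CHROM block
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    stop_if(is.unsorted(p), sprintf("VCF not sorted by position on %s", ch))
  }
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    message(sum(multi), " multiallelic record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  has_dp <- "DP" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID
  dp <- if (has_dp) vcfR::extract.gt(v, element = "DP", as.numeric = TRUE) else NULL
  keep <- which(!multi)
  n_samp <- ncol(gt)
  dos <- matrix(NA_integer_, nrow = n_samp, ncol = length(keep),
                dimnames = list(colnames(gt), NULL))
  dpm <- if (!is.null(dp)) matrix(NA_integer_, n_samp, length(keep),
                                  dimnames = list(colnames(gt), NULL)) else NULL
  ids <- character(length(keep))
  for (jj in seq_along(keep)) {
    j <- keep[jj]
    ids[jj] <- paste0(chrom[j], ":", pos[j])
    for (s in seq_len(n_samp)) {
      g <- gt[j, s]
      if (is.na(g)) next
      alleles <- strsplit(g, "[/|]")[[1]]
      if (any(alleles == ".")) next
      stop_if(length(alleles) != ploidy,
              sprintf("GT arity %d != ploidy %d at %s:%d sample %s",
                      length(alleles), ploidy, chrom[j], pos[j], colnames(gt)[s]))
      dos[s, jj] <- sum(alleles == "1")
    }
    if (!is.null(dpm)) dpm[, jj] <- dp[j, ]
  }
  colnames(dos) <- ids
  if (!is.null(dpm)) colnames(dpm) <- ids
  dosage_matrix(dos, chrom[keep], pos[keep], ploidy, dp = dpm)
}

#' Write a dosage matrix as a VCF 4.2 file
#'
#' Emits one biallelic record per locus with GT (and DP when available)
#' FORMAT fields; dosage d becomes the unphased genotype with d alternate
#' alleles, e.g. d = 2 at ploidy 6 is `0/0/0/0/1/1`.
#'
#' @param g a [dosage_matrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf_dosage <- function(g, path) {
  m <- g$ploidy
  gt_strings <- vapply(0:m, function(d)
    paste(c(rep("0", m - d), rep("1", d)), collapse = "/"), character(1))
  miss <- paste(rep(".", m), collapse = "/")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=polycore",
    sprintf("##contig=<ID=%s>", unique(g$chrom)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", accessions(g)), collapse = "\t")
  ), con)
  has_dp <- !is.null(g$dp)
  for (j in seq_along(g$pos)) {
    d <- g$dosage[, j]
    gts <- ifelse(is.na(d), miss, gt_strings[d + 1L])
    if (has_dp) {
      dpj <- g$dp[, j]
      gts <- paste0(gts, ":", ifelse(is.na(dpj), ".", as.character(dpj)))
    }
    writeLines(paste(c(g$chrom[j], g$pos[j], colnames(g$dosage)[j], "A", "T",
                       ".", "PASS", ".", if (has_dp) "GT:DP" else "GT", gts),
                     collapse = "\t"), con)
  }
  invisible(path)
}

# -------------------------------------------------------------------------
# CSV

#' Read a dosage matrix from CSV
#'
#' Expected layout: header `accession,<chrom:pos>,<chrom:pos>,...`; one row
#' per accession; integer cells in `[0, ploidy]`; empty cell = missing.
#'
#' @inheritParams read_vcf_dosage
#' @return a [dosage_matrix].
#' @export
read_dosage_csv <- function(path, ploidy = 6) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stop_if(names(df)[1] != "accession", "first column must be 'accession'")
  ids <- as.character(df[[1]])
  stop_if(anyDuplicated(ids) > 0, "duplicate accession IDs")
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "integer"
  rownames(m) <- ids
  bad <- which(!is.na(m) & (m < 0 | m > ploidy), arr.ind = TRUE)
  stop_if(nrow(bad) > 0,
          sprintf("dosage out of [0,%d] at accession %s, locus %s",
                  ploidy, ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
  parts <- strsplit(colnames(m), ":", fixed = TRUE)
  chrom <- vapply(parts, `[`, character(1), 1L)
  pos <- as.integer(vapply(parts, `[`, character(1), 2L))
  stop_if(anyNA(pos), "locus IDs must be 'chrom:pos'")
  dosage_matrix(m, chrom, pos, ploidy)
}

#' Write a dosage matrix as CSV
#' @param g a [dosage_matrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dosage_csv <- function(g, path) {
  df <- data.frame(accession = accessions(g), g$dosage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write phenotype tables and passport files
#'
#' CSV with header, UTF-8, missing encoded as the empty string. Writers are
#' loss-free inverses of the readers for the supported value types.
#'
#' @param path CSV file path.
#' @return `read_phenotypes()` a [phenotype_table]; `read_passport()` a
#'   [population_assignment].
#' @export
read_phenotypes <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 na.strings = "")
  phenotype_table(df)
}

#' @rdname read_phenotypes
#' @param pt a [phenotype_table].
#' @export
write_phenotypes <- function(pt, path) {
  df <- data.frame(accession = pt$accession_ids, pt$table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname read_phenotypes
#' @param genotyped optional character vector of genotyped accession IDs;
#'   passport entries absent from it are kept but reported via a message.
#' @export
read_passport <- function(path, genotyped = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 na.strings = "")
  pa <- population_assignment(df$accession, df$population, df$country)
  if (!is.null(genotyped)) {
    extra <- setdiff(pa$accession, genotyped)
    if (length(extra))
      message(length(extra), " passport accession(s) absent from genotypes")
  }
  pa
}

#' @rdname read_phenotypes
#' @param pa a [population_assignment].
#' @export
write_passport <- function(pa, path) {
  write.csv(as.data.frame(pa), path, row.names = FALSE, na = "")
  invisible(path)
}
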