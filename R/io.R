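# Plain-text interchange: fixture files for a simulated cohort, GWAS-SSF
# style summary statistics, PLINK-dialect square LD matrices, BED6 gene
# models. All readers/writers round-trip exactly at full double precision.

SSF_COLUMNS <- c("snp_id", "chromosome", "base_pair_location", "effect_allele",
                 "other_allele", "effect_allele_frequency", "beta",
                 "standard_error", "p_value", "mlog10_p", "n", "trait",
                 "stratum", "method", "flag")

#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

#' @noRd
read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

#' Write summary statistics in GWAS-SSF-like TSV dialect
#'
#' Columns: chromosome, base_pair_location, effect_allele, other_allele,
#' effect_allele_frequency, beta, standard_error, p_value, n, trait,
#' stratum (plus snp_id, mlog10_p, method, flag carried by this package).
#' Missing numerics are written as `NA`.
#'
#' @param sumstats a summary-statistic data.frame from [assoc_scan()].
#' @param path output file.
#' @export
write_sumstats <- function(sumstats, path) {
  miss <- setdiff(SSF_COLUMNS, names(sumstats))
  assert_that(!length(miss), paste("sumstats missing columns:", paste(miss, collapse = ", ")))
  write_tsv(sumstats[, SSF_COLUMNS], path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) read_tsv(path)

#' Write / read a square LD matrix with SNP-id header (values are r)
#'
#' @param R square correlation matrix with dimnames.
#' @param path file path.
#' @export
write_ld_matrix <- function(R, path) {
  assert_that(!is.null(colnames(R)), "LD matrix needs SNP-id dimnames")
  df <- data.frame(snp_id = colnames(R), R, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_ld_matrix
#' @export
read_ld_matrix <- function(path) {
  df <- read_tsv(path)
  ids <- df$snp_id
  R <- as.matrix(df[, -1, drop = FALSE])
  dimnames(R) <- list(ids, ids)
  R
}

#' Write the synthetic cohort and its ground truth as fixture files
#'
#' Emits genotype and phenotype tables, the SNP map (1-based positions),
#' rare-variant tables, gene models as BED6 (0-based half-open), the
#' annotation and expression-weight tables, and the planted truth tables.
#'
#' @param cohort,truth output of [simulate_cohort()].
#' @param outdir output directory (created if needed).
#' @param force overwrite existing files? Default `FALSE`: refuses if any
#'   target file already exists.
#' @return invisible character vector of written paths.
#' @export
write_fixtures <- function(cohort, truth, outdir, force = FALSE) {
  stopifnot(inherits(cohort, "cohort_data"), inherits(truth, "truth_set"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  files <- c("genotypes.tsv", "phenotypes.tsv", "snp_map.tsv",
             "rare_genotypes.tsv", "rare_variants.tsv", "gene_models.bed",
             "annotations.tsv", "expression_weights.tsv",
             "truth_loci.tsv", "truth_genes.tsv")
  paths <- file.path(outdir, files)
  names(paths) <- files
  if (!force) {
    hit <- paths[file.exists(paths)]
    assert_that(!length(hit),
                paste("refusing to overwrite existing fixtures (use force = TRUE):",
                      paste(basename(hit), collapse = ", ")))
  }
  gdf <- data.frame(iid = cohort$phenotypes$iid, cohort$genotypes,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(gdf, paths["genotypes.tsv"])
  write_tsv(cohort$phenotypes, paths["phenotypes.tsv"])
  write_tsv(cohort$snp_map, paths["snp_map.tsv"])
  rdf <- data.frame(iid = cohort$phenotypes$iid, cohort$rare_genotypes,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(rdf, paths["rare_genotypes.tsv"])
  write_tsv(cohort$rare_variants, paths["rare_variants.tsv"])
  gm <- truth$gene_models
  bed <- data.frame(chr = gm$chr, start = gm$start - 1L, end = gm$end,
                    name = gm$gene, score = 0L, strand = gm$strand)
  utils::write.table(bed, paths["gene_models.bed"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_tsv(truth$annotations, paths["annotations.tsv"])
  write_tsv(truth$expression_weights, paths["expression_weights.tsv"])
  write_tsv(truth$loci, paths["truth_loci.tsv"])
  write_tsv(truth$genes, paths["truth_genes.tsv"])
  invisible(paths)
}

#' Read gene models from a BED6 file into 1-based closed coordinates
#'
#' BED is 0-based half-open; the returned `start` is `bed_start + 1` so a
#' SNP at 1-based position `p` falls inside the gene iff
#' `start <= p <= end`.
#'
#' @param path BED6 file.
#' @return data.frame with gene, chr, start, end, strand.
#' @export
read_gene_models <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(bed)[1:6] <- c("chr", "start", "end", "name", "score", "strand")
  data.frame(gene = bed$name, chr = bed$chr, start = bed$start + 1L,
             end = bed$end, strand = bed$strand, stringsAsFactors = FALSE)
}

#' Read back a fixture directory written by [write_fixtures()]
#'
#' @param outdir fixture directory.
#' @return list with the same tables (`genotypes` as a numeric matrix).
#' @export
read_fixtures <- function(outdir) {
  gdf <- read_tsv(file.path(outdir, "genotypes.tsv"))
  geno <- as.matrix(gdf[, -1, drop = FALSE])
  rownames(geno) <- NULL
  rdf <- read_tsv(file.path(outdir, "rare_genotypes.tsv"))
  rare <- as.matrix(rdf[, -1, drop = FALSE])
  rownames(rare) <- NULL
  list(
    genotypes = geno,
    phenotypes = read_tsv(file.path(outdir, "phenotypes.tsv")),
    snp_map = read_tsv(file.path(outdir, "snp_map.tsv")),
    rare_genotypes = rare,
    rare_variants = read_tsv(file.path(outdir, "rare_variants.tsv")),
    gene_models = read_gene_models(file.path(outdir, "gene_models.bed")),
    annotations = read_tsv(file.path(outdir, "annotations.tsv")),
    expression_weights = read_tsv(file.path(outdir, "expression_weights.tsv")),
    truth_loci = read_tsv(file.path(outdir, "truth_loci.tsv")),
    truth_genes = read_tsv(file.path(outdir, "truth_genes.tsv"))
  )
}
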