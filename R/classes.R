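#' Construct a genotype matrix object
#'
#' Bundles an additive-dosage matrix (samples in rows, SNPs in columns,
#' entries 0/1/2 counting minor alleles) with per-SNP metadata.
#'
#' @param dosage numeric matrix, samples x SNPs, with row and column names.
#' @param info data.frame with one row per SNP: `snp_id`, `chrom`, `pos`
#'   (1-based), and optionally `gene_id` (the cis gene the SNP was placed
#'   near, for simulated data).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, info) {
  if (!is.matrix(dosage)) stopf("dosage must be a matrix")
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stopf("dosage must have sample rownames and SNP colnames")
  if (!all(c("snp_id", "chrom", "pos") %in% names(info)))
    stopf("info must have columns snp_id, chrom, pos")
  if (nrow(info) != ncol(dosage))
    stopf("info has %d rows but dosage has %d SNPs", nrow(info), ncol(dosage))
  if (anyDuplicated(info$snp_id)) stopf("duplicate SNP ids")
  if (!identical(colnames(dosage), as.character(info$snp_id)))
    stopf("dosage colnames must equal info$snp_id in order")
  structure(list(dosage = dosage, info = info), class = "genotype_matrix")
}

#' Empirical minor allele frequencies
#'
#' MAF is computed as `min(p, 1 - p)` with `p = mean(dosage) / 2`,
#' missing entries excluded.
#'
#' @param geno a `genotype_matrix`.
#' @return Named numeric vector of per-SNP MAFs.
#' @export
maf <- function(geno) {
  p <- colMeans(geno$dosage, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs\n",
              nrow(x$dosage), ncol(x$dosage)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$info$chrom), collapse = ", ")))
  m <- maf(x)
  cat(sprintf("  MAF range: %.3f - %.3f\n", min(m), max(m)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

# Subset SNPs (by id or index), keeping dosage and metadata aligned.
subset_snps <- function(geno, snps) {
  idx <- if (is.character(snps)) match(snps, geno$info$snp_id) else snps
  if (anyNA(idx)) stopf("unknown SNP id(s): %s",
                        paste(snps[is.na(idx)], collapse = ", "))
  genotype_matrix(geno$dosage[, idx, drop = FALSE],
                  geno$info[idx, , drop = FALSE])
}
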