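#' Define cis windows around transcription start sites
#'
#' A gene's cis window spans +/- `width` bp around its TSS, clamped at
#' position 1; SNP membership tests are inclusive at both ends.
#'
#' @param annotation data.frame with `gene_id`, `chrom`, `tss`.
#' @param width half-width in bp (default 500 kb).
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @export
define_cis_windows <- function(annotation, width = 5e5) {
  ok <- !is.na(annotation$tss)
  if (any(!ok))
    warnf("skipping %d gene(s) without a TSS", sum(!ok))
  ann <- annotation[ok, , drop = FALSE]
  data.frame(gene_id = ann$gene_id, chrom = ann$chrom,
             start = pmax(1, ann$tss - width), end = ann$tss + width)
}

#' Filter SNPs on completeness and minor allele frequency
#'
#' Removes SNPs with any missing dosage, then SNPs with empirical
#' MAF below `maf_min` (MAF = min(p, 1-p), p = mean(dosage)/2).
#'
#' @param genotypes a [genotype_matrix()].
#' @param maf_min MAF threshold (default 0.05; SNPs below it are excluded).
#' @return Filtered [genotype_matrix()].
#' @export
filter_snps <- function(genotypes, maf_min = 0.05) {
  complete <- colSums(is.na(genotypes$dosage)) == 0L
  keep <- complete & maf(genotypes) >= maf_min
  if (!any(keep)) message("filter_snps: no SNPs retained")
  subset_snps(genotypes, which(keep))
}

#' Map cis-QTLs by per-SNP linear regression
#'
#' For every (SNP, feature) pair with the SNP inside the feature's cis
#' window, fits OLS of the phenotype on the dosage with an intercept and
#' reports the per-allele effect, its standard error, the t statistic on
#' n - 2 degrees of freedom and the two-sided p-value. This is the
#' standard matrix-eQTL operating model; dosages are not standardized, so
#' effects are per minor allele and comparable between eQTL and pQTL scans.
#'
#' @param genotypes a [genotype_matrix()] (already filtered; pairs whose
#'   dosage is constant within the analysis samples are skipped and
#'   counted).
#' @param phenotypes samples x features matrix (expression or protein
#'   levels), samples matching `genotypes`.
#' @param windows output of [define_cis_windows()].
#' @param tissue label stored on every record (a tissue name or "plasma").
#' @param feature_map optional data.frame mapping phenotype columns to
#'   window genes (`feature_id`, `gene_id`); by default feature ids are
#'   assumed to be gene ids.
#' @return data.frame of QTL records (`snp_id`, `feature_id`, `tissue`,
#'   `beta`, `se`, `tstat`, `p`) with attribute `n_skipped`; pass it to
#'   [apply_fdr()] for significance calls.
#' @export
map_cis_qtl <- function(genotypes, phenotypes, windows, tissue = "plasma",
                        feature_map = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"), is.matrix(phenotypes))
  if (!identical(rownames(genotypes$dosage), rownames(phenotypes)))
    stopf("samples of genotypes and phenotypes are not harmonized")
  n <- nrow(phenotypes)
  if (is.null(feature_map))
    feature_map <- data.frame(feature_id = colnames(phenotypes),
                              gene_id = colnames(phenotypes))
  info <- genotypes$info
  out <- vector("list", ncol(phenotypes))
  skipped <- 0L
  for (i in seq_len(ncol(phenotypes))) {
    fid <- colnames(phenotypes)[i]
    gid <- feature_map$gene_id[match(fid, feature_map$feature_id)]
    w <- windows[match(gid, windows$gene_id), ]
    if (is.na(w$gene_id[1L])) next
    snp_idx <- which(info$chrom == w$chrom & info$pos >= w$start &
                       info$pos <= w$end)
    if (!length(snp_idx)) next
    X <- genotypes$dosage[, snp_idx, drop = FALSE]
    y <- phenotypes[, i]
    xc <- sweep(X, 2L, colMeans(X))
    yc <- y - mean(y)
    sxx <- colSums(xc^2)
    ok <- sxx > 0
    skipped <- skipped + sum(!ok)
    if (!any(ok)) next
    sxy <- colSums(xc[, ok, drop = FALSE] * yc)
    sxx <- sxx[ok]
    beta <- sxy / sxx
    sse <- sum(yc^2) - beta * sxy
    sse <- pmax(sse, 0)
    se <- sqrt(sse / (n - 2) / sxx)
    tstat <- beta / se
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    out[[i]] <- data.frame(snp_id = info$snp_id[snp_idx][ok],
                           feature_id = fid, tissue = tissue,
                           beta = beta, se = se, tstat = tstat, p = p)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(snp_id = character(), feature_id = character(),
                      tissue = character(), beta = numeric(), se = numeric(),
                      tstat = numeric(), p = numeric())
  rownames(res) <- NULL
  attr(res, "n_skipped") <- skipped
  res
}

#' Benjamini-Hochberg FDR over QTL records
#'
#' Adds `fdr` (BH step-up adjusted p) and `significant` (`fdr <= alpha`)
#' columns, either over all records jointly (the matrix-eQTL default) or
#' within each feature.
#'
#' @param records output of [map_cis_qtl()].
#' @param alpha FDR threshold (default 0.05).
#' @param scope "global" (one family, default) or "per_feature".
#' @return `records` with `fdr` and `significant` columns.
#' @export
apply_fdr <- function(records, alpha = 0.05,
                      scope = c("global", "per_feature")) {
  scope <- match.arg(scope)
  if (nrow(records) == 0L) {
    records$fdr <- numeric(0)
    records$significant <- logical(0)
    return(records)
  }
  records$fdr <- if (scope == "global") {
    stats::p.adjust(records$p, method = "BH")
  } else {
    stats::ave(records$p, records$feature_id,
               FUN = function(p) stats::p.adjust(p, method = "BH"))
  }
  records$significant <- records$fdr <= alpha
  records
}
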