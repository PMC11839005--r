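#' Write and read additive dosage matrices ("-012" convention)
#'
#' Files store SNPs in rows and samples in columns, preceded by `snp_id`,
#' `chrom` and `pos` columns; entries are 0/1/2 minor-allele counts.
#'
#' @param geno a [genotype_matrix()].
#' @param path TSV file path.
#' @return `write_dosage` returns `path` invisibly; `read_dosage` returns a
#'   [genotype_matrix()].
#' @export
write_dosage <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  out <- cbind(geno$info[c("snp_id", "chrom", "pos")],
               as.data.frame(t(geno$dosage)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage
#' @export
read_dosage <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(df)))
    stopf("dosage file must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(df$snp_id))
    stopf("duplicate SNP ids in %s", path)
  dos <- as.matrix(df[setdiff(names(df), need)])
  bad <- which(!(is.na(dos) | dos == 0 | dos == 1 | dos == 2), arr.ind = TRUE)
  if (nrow(bad))
    stopf("dosage value %s outside {0,1,2} at SNP %s, sample %s",
          format(dos[bad[1L, , drop = FALSE]]), df$snp_id[bad[1L, 1L]],
          colnames(dos)[bad[1L, 2L]])
  rownames(dos) <- df$snp_id
  genotype_matrix(t(dos), data.frame(snp_id = df$snp_id, chrom = df$chrom,
                                     pos = df$pos))
}

#' Write and read feature matrices
#'
#' Files store features (genes, proteins, eigengenes) in rows and samples
#' in columns with a leading `feature_id` column; internally matrices are
#' oriented samples x features.
#'
#' @param mat numeric samples x features matrix with dimnames.
#' @param path TSV file path.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` returns a
#'   samples x features matrix.
#' @export
write_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(dimnames(mat)))
  out <- data.frame(feature_id = colnames(mat), t(mat), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "feature_id")
    stopf("feature matrix file must start with a feature_id column")
  if (anyDuplicated(df$feature_id)) stopf("duplicate feature ids in %s", path)
  m <- t(as.matrix(df[-1L]))
  colnames(m) <- df$feature_id
  m
}

#' Read gene annotation from BED
#'
#' Expects 4-column BED (`chrom`, `tss - 1`, `tss`, `gene_id`) in 0-based
#' half-open coordinates; the transcription start site is converted to the
#' package's 1-based internal convention (tss = BED end column).
#'
#' @param path BED file path.
#' @return data.frame with `gene_id`, `chrom`, `tss`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stopf("annotation BED needs 4 columns")
  ann <- data.frame(gene_id = df[[4L]], chrom = df[[1L]], tss = df[[3L]])
  if (anyDuplicated(ann$gene_id)) stopf("duplicate gene ids in %s", path)
  if (any(ann$tss < 1)) stopf("TSS positions must be >= 1")
  ann
}

#' Write gene annotation as BED
#'
#' @param annotation data.frame with `gene_id`, `chrom`, `tss` (1-based).
#' @param path BED file path.
#' @export
write_annotation <- function(annotation, path) {
  out <- data.frame(annotation$chrom, annotation$tss - 1L, annotation$tss,
                    annotation$gene_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read dosages from a VCF
#'
#' Uses the DS FORMAT field when present, otherwise counts ALT alleles in
#' GT. A file with neither field is rejected.
#'
#' @param path VCF file path (plain or gzipped).
#' @return A [genotype_matrix()] (dosages are ALT-allele counts).
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stopf("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- t(as.matrix(fx))  # single-record VCF
  has <- function(f) f %in% unlist(strsplit(unique(v@gt[, "FORMAT"]), ":"))
  if (has("DS")) {
    dos <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else if (has("GT")) {
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- matrix(vapply(gsub("[|]", "/", gt), function(x) {
      if (is.na(x)) return(NA_real_)
      sum(as.integer(strsplit(x, "/")[[1L]]) > 0)
    }, numeric(1L)), nrow(gt), ncol(gt), dimnames = dimnames(gt))
  } else {
    stopf("VCF has neither GT nor DS FORMAT fields")
  }
  ids <- unname(fx[, "ID"])
  miss <- is.na(ids) | ids == "."
  ids[miss] <- paste0(fx[miss, "CHROM"], ":", fx[miss, "POS"])
  if (anyDuplicated(ids)) stopf("duplicate variant ids in %s", path)
  rownames(dos) <- ids
  genotype_matrix(t(dos),
                  data.frame(snp_id = ids, chrom = fx[, "CHROM"],
                             pos = as.integer(fx[, "POS"])))
}

#' Write a minimal VCF for a genotype matrix
#'
#' Emits a plain-text VCFv4.2 file with GT calls reconstructed from 0/1/2
#' dosages (0 -> 0/0, 1 -> 0/1, 2 -> 1/1) and placeholder REF/ALT alleles.
#' Intended for interoperability checks on simulated data, not as a general
#' VCF exporter.
#'
#' @param geno a [genotype_matrix()].
#' @param path output file path.
#' @export
write_minimal_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(geno$dosage)),
                     collapse = "\t")),
             con)
  gtmap <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(geno$dosage))) {
    gt <- gtmap[geno$dosage[, j] + 1L]
    gt[is.na(gt)] <- "./."
    writeLines(paste(c(geno$info$chrom[j], geno$info$pos[j],
                       geno$info$snp_id[j], "A", "G", ".", "PASS", ".",
                       "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a covariate table
#'
#' @param path TSV with a `sample_id` column followed by numeric covariates.
#' @return data.frame with rownames set to sample ids.
#' @export
read_covariates <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "sample_id")
    stopf("covariate file must start with a sample_id column")
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample ids in %s", path)
  rownames(df) <- df$sample_id
  df[-1L]
}

#' Restrict matrices to their common samples
#'
#' Takes any number of samples x features matrices, genotype matrices or
#' covariate data.frames (samples in rows, identified by rownames) and
#' returns them restricted to the intersection of sample ids, all in the
#' same order.
#'
#' @param ... matrices / genotype matrices / data.frames, optionally named.
#' @return Named list of the restricted inputs with attribute `n_common`.
#' @export
harmonize_samples <- function(...) {
  objs <- list(...)
  if (length(objs) == 1L && is.list(objs[[1L]]) &&
      !is.data.frame(objs[[1L]]) && !inherits(objs[[1L]], "genotype_matrix"))
    objs <- objs[[1L]]
  ids <- lapply(objs, function(o) {
    if (inherits(o, "genotype_matrix")) rownames(o$dosage) else rownames(o)
  })
  common <- Reduce(intersect, ids)
  if (length(common) == 0L) stopf("no samples shared by all inputs")
  message(sprintf("harmonize_samples: %d common samples", length(common)))
  out <- lapply(objs, function(o) {
    if (inherits(o, "genotype_matrix")) {
      genotype_matrix(o$dosage[common, , drop = FALSE], o$info)
    } else o[common, , drop = FALSE]
  })
  attr(out, "n_common") <- length(common)
  out
}

#' Residualize features on covariates
#'
#' Replaces every feature (column) by the residual of its OLS fit on an
#' intercept plus the covariates, the standard adjustment applied to
#' normalized protein expression (NPX) values before analysis (batch
#' principal components, age, sex). Residualization is idempotent and the
#' output is orthogonal to every covariate.
#'
#' @param mat numeric samples x features matrix.
#' @param covariates data.frame or matrix of numeric covariates with sample
#'   rownames matching `mat` (order is aligned by name).
#' @param drop_constant drop zero-variance features with a warning rather
#'   than failing (default TRUE).
#' @return samples x features matrix of residuals.
#' @export
adjust_covariates <- function(mat, covariates, drop_constant = TRUE) {
  stopifnot(is.matrix(mat))
  if (!is.null(rownames(mat)) && !is.null(rownames(covariates))) {
    if (!all(rownames(mat) %in% rownames(covariates)))
      stopf("covariates missing for some samples")
    covariates <- covariates[rownames(mat), , drop = FALSE]
  }
  if (anyNA(covariates)) stopf("covariates contain missing values")
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    bad <- colnames(X)[qr_$pivot[(qr_$rank + 1L):ncol(X)]]
    stopf("covariate design is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  const <- apply(mat, 2L, function(y) stats::var(y) == 0)
  if (any(const)) {
    if (!drop_constant) stopf("zero-variance feature(s): %s",
                              paste(colnames(mat)[const], collapse = ", "))
    warnf("dropping %d zero-variance feature(s)", sum(const))
    mat <- mat[, !const, drop = FALSE]
  }
  res <- qr.resid(qr_, mat)
  dimnames(res) <- dimnames(mat)
  res
}
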