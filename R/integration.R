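#' Overlap significant eQTLs and pQTLs across tissues
#'
#' For each protein, finds the tissues in which at least one SNP is
#' significant both for the protein's seed gene (tissue eQTL) and for the
#' plasma protein (pQTL), with "shared" meaning the same SNP id in both
#' sets. Also tallies how many proteins fall in each tissue-combination
#' intersection (the counts behind an UpSet-style plot).
#'
#' @param eqtl_by_tissue named list of [apply_fdr()]-annotated eQTL record
#'   sets, one per tissue; `feature_id` holds gene ids.
#' @param pqtl_records [apply_fdr()]-annotated pQTL records; `feature_id`
#'   holds protein ids.
#' @param protein_map data.frame (`protein_id`, `gene_id`).
#' @return list with `sharing` (data.frame `protein_id`, `tissue`,
#'   `n_shared_snps`) and `intersection_counts` (named integer vector,
#'   names are "+"-joined tissue sets).
#' @export
overlap_qtls <- function(eqtl_by_tissue, pqtl_records, protein_map) {
  psig <- pqtl_records[pqtl_records$significant, c("feature_id", "snp_id")]
  esig <- lapply(eqtl_by_tissue, function(r)
    r[r$significant, c("feature_id", "snp_id")])
  rows <- list()
  sets <- character(0)
  for (i in seq_len(nrow(protein_map))) {
    p <- protein_map$protein_id[i]; g <- protein_map$gene_id[i]
    psnps <- psig$snp_id[psig$feature_id == p]
    tis_in <- character(0)
    if (length(psnps)) {
      for (tis in names(esig)) {
        shared <- intersect(psnps,
                            esig[[tis]]$snp_id[esig[[tis]]$feature_id == g])
        if (length(shared)) {
          tis_in <- c(tis_in, tis)
          rows[[length(rows) + 1L]] <-
            data.frame(protein_id = p, tissue = tis,
                       n_shared_snps = length(shared))
        }
      }
    }
    sets <- c(sets, paste(sort(tis_in), collapse = "+"))
  }
  sharing <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(), tissue = character(),
               n_shared_snps = integer())
  counts <- table(sets[sets != ""])
  list(sharing = sharing,
       intersection_counts = stats::setNames(as.integer(counts),
                                             names(counts)))
}

#' Classify allelic coherence of an eQTL/pQTL effect pair
#'
#' With m = max(beta_e, beta_p) and d = |beta_e - beta_p|: a negative m
#' means both effects are negative (negatively coherent); a positive m
#' exceeding d means both are positive (positively coherent); a positive m
#' below d means the effects have opposite signs (divergent). The
#' measure-zero ties m = 0 or m = d (one beta exactly zero) are classified
#' divergent and flagged.
#'
#' @param beta_e,beta_p numeric vectors of per-allele eQTL and pQTL
#'   effects (recycled to common length; NaN/NA is an error).
#' @return data.frame with `beta_e`, `beta_p`, `call` (factor:
#'   positively_coherent / negatively_coherent / divergent) and `tie`.
#' @export
classify_coherence <- function(beta_e, beta_p) {
  k <- max(length(beta_e), length(beta_p))
  beta_e <- rep_len(beta_e, k); beta_p <- rep_len(beta_p, k)
  if (any(!is.finite(beta_e)) || any(!is.finite(beta_p)))
    stopf("coherence classification requires finite effect sizes")
  m <- pmax(beta_e, beta_p)
  d <- abs(beta_e - beta_p)
  call <- ifelse(m < 0, "negatively_coherent",
                 ifelse(m > d, "positively_coherent", "divergent"))
  tie <- (m == 0) | (m > 0 & m == d)
  call[tie] <- "divergent"
  data.frame(beta_e = beta_e, beta_p = beta_p,
             call = factor(call, levels = c("positively_coherent",
                                            "negatively_coherent",
                                            "divergent")),
             tie = tie)
}

#' Coherence calls for all shared e/pQTLs
#'
#' For every (protein, tissue) pair with shared significant e/pSNPs, picks
#' the shared SNP with the smallest max(p_e, p_p) and classifies the
#' coherence of its effect pair.
#'
#' @inheritParams overlap_qtls
#' @return data.frame with `protein_id`, `gene_id`, `tissue`, `snp_id`,
#'   `beta_e`, `beta_p`, `call`, `tie`.
#' @export
coherence_calls <- function(eqtl_by_tissue, pqtl_records, protein_map) {
  ov <- overlap_qtls(eqtl_by_tissue, pqtl_records, protein_map)$sharing
  if (nrow(ov) == 0L)
    return(data.frame(protein_id = character(), gene_id = character(),
                      tissue = character(), snp_id = character(),
                      beta_e = numeric(), beta_p = numeric(),
                      call = character(), tie = logical()))
  rows <- lapply(seq_len(nrow(ov)), function(i) {
    p <- ov$protein_id[i]; tis <- ov$tissue[i]
    g <- protein_map$gene_id[protein_map$protein_id == p]
    pq <- pqtl_records[pqtl_records$significant &
                         pqtl_records$feature_id == p, ]
    eq <- eqtl_by_tissue[[tis]]
    eq <- eq[eq$significant & eq$feature_id == g, ]
    shared <- intersect(pq$snp_id, eq$snp_id)
    pe <- eq$p[match(shared, eq$snp_id)]
    pp <- pq$p[match(shared, pq$snp_id)]
    best <- shared[order(pmax(pe, pp), shared)][1L]
    data.frame(protein_id = p, gene_id = g, tissue = tis, snp_id = best,
               beta_e = eq$beta[match(best, eq$snp_id)],
               beta_p = pq$beta[match(best, pq$snp_id)])
  })
  res <- do.call(rbind, rows)
  cbind(res[c("protein_id", "gene_id", "tissue", "snp_id")],
        classify_coherence(res$beta_e, res$beta_p))
}

#' Greedy LD pruning to independent SNPs
#'
#' Sorts candidate SNPs by ascending p-value (ties broken by SNP id),
#' repeatedly keeps the best remaining SNP and discards every remaining SNP
#' whose dosage correlates with it at |Pearson r| above `r_threshold`.
#'
#' @param snp_ids character vector of candidate SNPs.
#' @param genotypes a [genotype_matrix()] containing them.
#' @param p_values p-values aligned with `snp_ids`.
#' @param r_threshold LD threshold on |Pearson r| (default 0.8).
#' @return Character vector of retained (independent) SNP ids.
#' @export
ld_prune <- function(snp_ids, genotypes, p_values, r_threshold = 0.8) {
  if (length(snp_ids) == 0L) return(character(0))
  stopifnot(length(snp_ids) == length(p_values))
  ord <- order(p_values, snp_ids)
  ids <- snp_ids[ord]
  X <- genotypes$dosage[, match(ids, genotypes$info$snp_id), drop = FALSE]
  kept <- character(0)
  remaining <- seq_along(ids)
  while (length(remaining)) {
    best <- remaining[1L]
    kept <- c(kept, ids[best])
    remaining <- remaining[-1L]
    if (length(remaining)) {
      r <- suppressWarnings(
        as.vector(stats::cor(X[, best], X[, remaining, drop = FALSE])))
      r[is.na(r)] <- 0  # constant dosage: uncorrelated by convention
      remaining <- remaining[abs(r) <= r_threshold]
    }
  }
  kept
}

#' Variance in protein levels explained by independent cis-SNPs
#'
#' LD-prunes the protein's significant pSNPs (keeping the strongest SNP per
#' LD group), fits one multiple OLS of the protein on all retained dosages
#' plus an intercept, and reports the adjusted coefficient of determination
#' r2_adj = 1 - (1 - R^2)(n - 1)/(n - k - 1).
#'
#' @param protein numeric vector of protein levels, named by sample in the
#'   order of `genotypes`.
#' @param records [apply_fdr()]-annotated pQTL records for this protein.
#' @param genotypes a [genotype_matrix()].
#' @param r_threshold LD-pruning threshold (default 0.8).
#' @return list of class `variance_explained`: `n_independent_snps`,
#'   `r2_adjusted` (NA when no SNP is significant: undefined, never 0),
#'   `snp_ids`, `undefined`.
#' @export
variance_explained <- function(protein, records, genotypes,
                               r_threshold = 0.8) {
  sig <- records[records$significant, , drop = FALSE]
  if (nrow(sig) == 0L)
    return(structure(list(n_independent_snps = 0L, r2_adjusted = NA_real_,
                          snp_ids = character(0), undefined = TRUE),
                     class = "variance_explained"))
  keep <- ld_prune(sig$snp_id, genotypes, sig$p, r_threshold)
  X <- genotypes$dosage[, match(keep, genotypes$info$snp_id), drop = FALSE]
  n <- length(protein)
  if (n <= ncol(X) + 1L)
    stopf("need n_samples > n_independent_snps + 1 (n = %d, k = %d)",
          n, ncol(X))
  qr_ <- qr(cbind(1, X))
  if (qr_$rank < ncol(X) + 1L) {
    drop <- qr_$pivot[(qr_$rank + 1L):(ncol(X) + 1L)] - 1L
    message(sprintf("variance_explained: dropping %d near-collinear SNP(s)",
                    length(drop)))
    keep <- keep[-drop]
    X <- X[, -drop, drop = FALSE]
    qr_ <- qr(cbind(1, X))
  }
  res <- qr.resid(qr_, protein)
  sst <- sum((protein - mean(protein))^2)
  r2 <- 1 - sum(res^2) / sst
  k <- ncol(X)
  structure(list(n_independent_snps = k,
                 r2_adjusted = 1 - (1 - r2) * (n - 1) / (n - k - 1),
                 snp_ids = keep, undefined = FALSE),
            class = "variance_explained")
}

#' @export
print.variance_explained <- function(x, ...) {
  if (x$undefined) {
    cat("variance_explained: undefined (no significant pSNPs)\n")
  } else {
    cat(sprintf("variance_explained: adjusted R^2 = %.4f from %d independent SNP(s)\n",
                x$r2_adjusted, x$n_independent_snps))
  }
  invisible(x)
}
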