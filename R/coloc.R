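#' Colocalization priors
#'
#' Per-SNP prior probabilities that a SNP is associated with trait 1 only
#' (`p1`), trait 2 only (`p2`), or both (`p12`), plus the standard
#' deviation of the effect-size prior used in the approximate Bayes
#' factor. Defaults are the canonical single-variant colocalization priors
#' for quantitative traits.
#'
#' @param p1,p2 per-SNP association priors (default 1e-4).
#' @param p12 per-SNP shared-association prior (default 1e-5; must not
#'   exceed min(p1, p2)).
#' @param prior_sd effect prior SD (default 0.15; W = prior_sd^2).
#' @return list of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5, prior_sd = 0.15) {
  if (p12 <= 0 || p12 > min(p1, p2)) stopf("need 0 < p12 <= min(p1, p2)")
  if (p1 + p2 + p12 >= 1) stopf("need p1 + p2 + p12 < 1")
  if (prior_sd <= 0) stopf("prior_sd must be > 0")
  structure(list(p1 = p1, p2 = p2, p12 = p12, prior_sd = prior_sd),
            class = "coloc_priors")
}

#' Restrict summary statistics to a window around a TSS
#'
#' Keeps SNPs with |position - tss| <= half_width (both ends inclusive).
#'
#' @param stats summary-statistic data.frame with a `position` column.
#' @param tss 1-based anchor position.
#' @param half_width window half-width in bp (default 100 kb).
#' @return The subset of `stats` inside the window.
#' @export
region_select <- function(stats, tss, half_width = 1e5) {
  stats[abs(stats$position - tss) <= half_width, , drop = FALSE]
}

#' Eligible gene-protein pairs for colocalization
#'
#' A (gene, protein, tissue) pair is taken forward only when at least one
#' SNP is significant in both the gene's eQTL records and the protein's
#' pQTL records (matching on SNP id).
#'
#' @param eqtl_by_tissue named list of [apply_fdr()]-annotated eQTL records.
#' @param pqtl_records [apply_fdr()]-annotated pQTL records.
#' @param protein_map data.frame (`protein_id`, `gene_id`).
#' @return data.frame (`protein_id`, `gene_id`, `tissue`) of eligible pairs.
#' @export
prefilter_pairs <- function(eqtl_by_tissue, pqtl_records, protein_map) {
  ov <- overlap_qtls(eqtl_by_tissue, pqtl_records, protein_map)$sharing
  gid <- protein_map$gene_id[match(ov$protein_id, protein_map$protein_id)]
  data.frame(protein_id = ov$protein_id, gene_id = gid, tissue = ov$tissue)
}

#' Wakefield log approximate Bayes factor
#'
#' For one SNP with estimated effect `beta` and squared standard error
#' `varbeta`, under a N(0, W) effect prior with W = prior_sd^2:
#' log ABF = 0.5 log(1 - r) + 0.5 z^2 r, where r = W / (W + varbeta) and
#' z^2 = beta^2 / varbeta. Vectorized over SNPs.
#'
#' @param beta effect estimate(s).
#' @param varbeta squared standard error(s) (> 0).
#' @param prior_sd effect prior SD (default 0.15).
#' @return Numeric vector of log ABFs.
#' @export
log_abf <- function(beta, varbeta, prior_sd = 0.15) {
  if (any(varbeta <= 0)) stopf("varbeta must be > 0")
  W <- prior_sd^2
  r <- W / (W + varbeta)
  z2 <- beta^2 / varbeta
  0.5 * log1p(-r) + 0.5 * z2 * r
}

#' Approximate-Bayes-factor colocalization of two traits
#'
#' Computes the posterior probabilities of the five single-causal-variant
#' hypotheses for a region: H0 no association, H1/H2 association with one
#' trait only, H3 two distinct causal variants, H4 one shared causal
#' variant. Summary statistics are aligned on the intersection of SNP ids;
#' per-SNP log ABFs are combined with log-sum-exp stability, so extreme
#' z-scores do not overflow. The region is called colocalized when
#' PP(H4) > 0.5.
#'
#' @param stats1,stats2 summary-statistic data.frames with columns
#'   `snp_id`, `beta`, `varbeta` (and `maf` if `strict`).
#' @param priors a [coloc_priors()] object.
#' @param strict if TRUE, error when the two traits disagree on MAF by
#'   more than 0.05 for any shared SNP (a sign of allele misalignment).
#' @return list of class `coloc_posterior`: `pp` (named numeric, H0-H4),
#'   `nsnps`, `colocalized`, `priors`.
#' @export
coloc_abf <- function(stats1, stats2, priors = coloc_priors(),
                      strict = FALSE) {
  stopifnot(inherits(priors, "coloc_priors"))
  if (anyDuplicated(stats1$snp_id) || anyDuplicated(stats2$snp_id))
    stopf("duplicated SNP ids in summary statistics")
  shared <- intersect(stats1$snp_id, stats2$snp_id)
  if (length(shared) < 1L) stopf("no shared SNPs between the two traits")
  s1 <- stats1[match(shared, stats1$snp_id), ]
  s2 <- stats2[match(shared, stats2$snp_id), ]
  if (strict && !is.null(s1$maf) && !is.null(s2$maf) &&
      any(abs(s1$maf - s2$maf) > 0.05))
    stopf("MAF discrepancy > 0.05 between traits; check allele orientation")
  l1 <- log_abf(s1$beta, s1$varbeta, priors$prior_sd)
  l2 <- log_abf(s2$beta, s2$varbeta, priors$prior_sd)
  L1 <- logsumexp(l1)
  L2 <- logsumexp(l2)
  L12 <- logsumexp(l1 + l2)
  lw <- c(H0 = 0,
          H1 = log(priors$p1) + L1,
          H2 = log(priors$p2) + L2,
          H3 = log(priors$p1) + log(priors$p2) + logdiffexp(L1 + L2, L12),
          H4 = log(priors$p12) + L12)
  pp <- exp(lw - logsumexp(lw))
  names(pp) <- paste0("PP.", names(lw))
  structure(list(pp = pp, nsnps = length(shared),
                 colocalized = unname(pp["PP.H4"] > 0.5), priors = priors),
            class = "coloc_posterior")
}

#' Colocalization of a pQTL region with GWAS summary statistics
#'
#' The same machinery as [coloc_abf()], with the second trait drawn from a
#' GWAS summary file in the shared schema (`snp_id`, `position`, `beta`,
#' `varbeta`, `maf`, `n`).
#'
#' @inheritParams coloc_abf
#' @param pqtl_stats pQTL summary statistics.
#' @param gwas_stats GWAS summary statistics.
#' @return A `coloc_posterior`.
#' @export
coloc_gwas <- function(pqtl_stats, gwas_stats, priors = coloc_priors(),
                       strict = FALSE) {
  coloc_abf(pqtl_stats, gwas_stats, priors = priors, strict = strict)
}

#' @export
print.coloc_posterior <- function(x, digits = 4, ...) {
  cat(sprintf("coloc_posterior over %d shared SNPs\n", x$nsnps))
  print(round(x$pp, digits))
  cat(if (x$colocalized) "colocalized (PP.H4 > 0.5)\n"
      else "not colocalized (PP.H4 <= 0.5)\n")
  invisible(x)
}

#' Summary statistics from a QTL scan
#'
#' Converts [map_cis_qtl()] records for one feature into the summary
#' schema consumed by [coloc_abf()].
#'
#' @param records QTL records for a single feature.
#' @param genotypes the [genotype_matrix()] the scan used (for positions
#'   and MAF).
#' @param n sample size behind the scan.
#' @return data.frame with `snp_id`, `position`, `beta`, `varbeta`,
#'   `maf`, `n`.
#' @export
qtl_summary_stats <- function(records, genotypes, n) {
  idx <- match(records$snp_id, genotypes$info$snp_id)
  if (anyNA(idx)) stopf("records reference SNPs absent from genotypes")
  data.frame(snp_id = records$snp_id, position = genotypes$info$pos[idx],
             beta = records$beta, varbeta = records$se^2,
             maf = maf(genotypes)[idx], n = n)
}
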