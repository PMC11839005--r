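# Independent oracles used across the suite. These deliberately take the
# naive route (normal equations, direct summation, textbook formulas) so
# they share no code path with the implementation they check.

# OLS via explicit normal equations, with t-based two-sided p-values.
ols_oracle <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  XtX <- crossprod(X1)
  b <- solve(XtX, crossprod(X1, y))
  res <- y - X1 %*% b
  df <- length(y) - ncol(X1)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * s2)
  tt <- drop(b) / se
  list(beta = drop(b), se = se, tstat = tt,
       p = 2 * pt(-abs(tt), df), df = df,
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

# Colocalization posteriors by direct summation of Bayes factors,
# no log-sum-exp (valid only for well-scaled inputs).
coloc_oracle <- function(l1, l2, pr) {
  bf1 <- exp(l1); bf2 <- exp(l2)
  S1 <- sum(bf1); S2 <- sum(bf2); S12 <- sum(bf1 * bf2)
  w <- c(1, pr$p1 * S1, pr$p2 * S2,
         pr$p1 * pr$p2 * (S1 * S2 - S12), pr$p12 * S12)
  w / sum(w)
}

# Wakefield log ABF as a log-density ratio of the two marginal models.
log_abf_oracle <- function(beta, varbeta, prior_sd) {
  dnorm(beta, 0, sqrt(varbeta + prior_sd^2), log = TRUE) -
    dnorm(beta, 0, sqrt(varbeta), log = TRUE)
}

# Spearman rho by the classical sum-of-squared-rank-differences formula
# (tie-free inputs only).
spearman_d2_oracle <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# A minimal genotype_matrix around a bare dosage matrix.
toy_geno <- function(dos, chrom = "chr1", pos = NULL) {
  if (is.null(rownames(dos))) rownames(dos) <- sprintf("S%03d", seq_len(nrow(dos)))
  if (is.null(colnames(dos))) colnames(dos) <- sprintf("snp%03d", seq_len(ncol(dos)))
  if (is.null(pos)) pos <- seq_len(ncol(dos)) * 1000L
  genotype_matrix(dos, data.frame(snp_id = colnames(dos), chrom = chrom,
                                  pos = pos))
}

# Small simulation configs used by several files.
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_samples = 200L, n_genes = 10L, n_tissues = 2L,
                   snps_per_gene = 5L, n_modules = 2L, module_size = 4L,
                   ld_rho = 0, rng_seed = 42L)
  do.call(simulation_config, utils::modifyList(defaults, args))
}
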