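test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_samples = 5), "n_samples")
  expect_error(simulation_config(maf_low = 0.01), "maf_low")
  expect_error(simulation_config(ld_rho = 1), "ld_rho")
  expect_error(simulation_config(noise_sd = 0), "noise_sd")
  expect_error(simulation_config(n_modules = 0), "n_modules")
})

test_that("genotypes are complete 0/1/2 dosages with honest allele frequencies", {
  cfg <- tiny_config(n_samples = 2000L, maf_low = 0.1, maf_high = 0.4)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$dosage %in% c(0, 1, 2)))
  expect_false(anyNA(g$dosage))
  expect_true(all(maf(g) >= cfg$maf_low - 0.02))
  # HWE at p = 0.5: mean dosage 2p = 1
  cfg2 <- tiny_config(n_samples = 10000L, n_genes = 2L,
                      maf_low = 0.5, maf_high = 0.5)
  g2 <- simulate_genotypes(cfg2)
  expect_true(all(abs(colMeans(g2$dosage) - 1) < 0.05))
})

test_that("simulation is bit-for-bit reproducible under a fixed seed", {
  cfg <- tiny_config()
  s1 <- simulate_category_study(tiny_config(n_genes = 20L, n_modules = 2L),
                                n_per_category = 2L)
  s2 <- simulate_category_study(tiny_config(n_genes = 20L, n_modules = 2L),
                                n_per_category = 2L)
  expect_identical(s1$genotypes$dosage, s2$genotypes$dosage)
  expect_identical(s1$expression, s2$expression)
  expect_identical(unclass(s1$proteins), unclass(s2$proteins))
  g1 <- simulate_genotypes(cfg)
  g3 <- simulate_genotypes(tiny_config(rng_seed = 43L))
  expect_false(identical(g1$dosage, g3$dosage))
})

test_that("ld_rho = 0 gives independent SNPs; ld_rho > 0 gives block LD", {
  g0 <- simulate_genotypes(tiny_config(n_samples = 10000L, n_genes = 3L,
                                       snps_per_gene = 10L, ld_rho = 0))
  cm <- cor(g0$dosage)
  expect_lt(mean(abs(cm[upper.tri(cm)])), 0.05)

  adj_cor <- function(geno, cfg) {
    # mean adjacent-pair dosage correlation inside LD blocks
    rs <- c()
    for (gene in unique(geno$info$gene_id)) {
      idx <- which(geno$info$gene_id == gene)
      for (b in split(idx, (seq_along(idx) - 1L) %/% cfg$ld_block_size)) {
        if (length(b) > 1L)
          for (j in seq_len(length(b) - 1L))
            rs <- c(rs, cor(geno$dosage[, b[j]], geno$dosage[, b[j + 1L]]))
      }
    }
    mean(rs)
  }
  cfg_lo <- tiny_config(n_samples = 4000L, n_genes = 4L, snps_per_gene = 10L,
                        ld_block_size = 5L, ld_rho = 0.3)
  cfg_hi <- tiny_config(n_samples = 4000L, n_genes = 4L, snps_per_gene = 10L,
                        ld_block_size = 5L, ld_rho = 0.9)
  g_lo <- simulate_genotypes(cfg_lo)
  g_hi <- simulate_genotypes(cfg_hi)
  expect_gt(adj_cor(g_hi, cfg_hi), adj_cor(g_lo, cfg_lo))
})

test_that("adjacent-SNP dosage correlation matches the thresholded-copula oracle", {
  # Monte-Carlo integration of the copula at one fixed MAF, 1e6 draws
  rho <- 0.9; p <- 0.3
  set.seed(99)
  z1 <- rnorm(1e6)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(1e6)
  thr <- function(z) (z > qnorm((1 - p)^2)) + (z > qnorm(1 - p^2))
  r_oracle <- cor(thr(z1), thr(z2))

  cfg <- tiny_config(n_samples = 10000L, n_genes = 5L, snps_per_gene = 10L,
                     ld_block_size = 5L, ld_rho = 0.9,
                     maf_low = 0.3, maf_high = 0.3)
  g <- simulate_genotypes(cfg)
  rs <- c()
  for (gene in unique(g$info$gene_id)) {
    idx <- which(g$info$gene_id == gene)
    for (b in split(idx, (seq_along(idx) - 1L) %/% cfg$ld_block_size))
      for (j in seq_len(length(b) - 1L))
        rs <- c(rs, cor(g$dosage[, b[j]], g$dosage[, b[j + 1L]]))
  }
  expect_lt(abs(mean(rs) - r_oracle), 0.03)
})

test_that("expression carries the planted cis effects and module structure", {
  cfg <- tiny_config(n_samples = 10000L, n_genes = 6L, n_tissues = 1L,
                     maf_low = 0.5, maf_high = 0.5, noise_sd = 1)
  g <- simulate_genotypes(cfg)

  # no planted effect: gene-dosage correlations look null
  beta0 <- matrix(0, cfg$n_genes, 1,
                  dimnames = list(sprintf("G%04d", 1:6), "LIV"))
  t0 <- make_truth_table(cfg, g, eqtl_beta = beta0,
                         module_membership = data.frame(module_id = character(),
                                                        gene_id = character(),
                                                        tissue = character()))
  e0 <- simulate_expression(g, t0, cfg)
  r0 <- sapply(seq_len(cfg$n_genes), function(i)
    cor(e0$LIV[, i], g$dosage[, t0$causal_snp_per_gene[i]]))
  expect_lt(quantile(abs(r0), 0.95), 2.58 / sqrt(cfg$n_samples))

  # beta = 1, noise 1, MAF 0.5, no module factor: R^2 = Var(2p(1-p))/(.5+1) = 1/3
  beta1 <- beta0 + 1
  t1 <- make_truth_table(cfg, g, eqtl_beta = beta1,
                         module_membership = t0$module_membership)
  e1 <- simulate_expression(g, t1, cfg)
  r2 <- sapply(seq_len(cfg$n_genes), function(i)
    summary(lm(e1$LIV[, i] ~ g$dosage[, t1$causal_snp_per_gene[i]]))$r.squared)
  expect_true(all(abs(r2 - 1 / 3) < 0.03))

  # shared dominant module factor: member genes strongly correlated
  cfg_m <- tiny_config(n_samples = 500L, n_genes = 4L, n_tissues = 1L,
                       n_modules = 1L, module_size = 2L,
                       module_gene_loading = 20, noise_sd = 1)
  g_m <- simulate_genotypes(cfg_m)
  mem <- data.frame(module_id = "M001", gene_id = c("G0001", "G0002"),
                    tissue = "LIV")
  t_m <- make_truth_table(cfg_m, g_m, module_membership = mem,
                          eqtl_beta = matrix(0, 4, 1,
                                             dimnames = list(sprintf("G%04d", 1:4), "LIV")))
  e_m <- simulate_expression(g_m, t_m, cfg_m)
  expect_gt(cor(e_m$LIV[, "G0001"], e_m$LIV[, "G0002"]), 0.9)
})

test_that("planted eQTL effects are recovered by OLS within 3 SE", {
  hits <- 0L; total <- 0L
  for (rep in 1:200) {
    cfg <- tiny_config(n_samples = 150L, n_genes = 1L, n_tissues = 1L,
                       snps_per_gene = 3L, rng_seed = rep)
    g <- simulate_genotypes(cfg)
    tt <- make_truth_table(cfg, g)
    e <- simulate_expression(g, tt, cfg)
    fit <- summary(lm(e[[1]][, 1] ~ g$dosage[, tt$causal_snp_per_gene[1]]))
    est <- fit$coefficients[2, 1]; se <- fit$coefficients[2, 2]
    hits <- hits + (abs(est - tt$eqtl_beta[1, 1]) <= 3 * se)
    total <- total + 1L
  }
  expect_gte(hits / total, 0.95)
})

test_that("proteins express transmission, module effects and target genetic variance", {
  # noise-free single-tissue transmission: protein tracks the seed gene
  cfg <- tiny_config(n_samples = 300L, n_genes = 3L, n_tissues = 2L,
                     noise_sd = 1)
  g <- simulate_genotypes(cfg)
  sw <- matrix(0, 3, 2, dimnames = list(sprintf("P%04d", 1:3),
                                        c("LIV", "BLOOD")))
  sw["P0001", "LIV"] <- 1
  tt <- make_truth_table(cfg, g, seed_weights = sw)
  e <- simulate_expression(g, tt, cfg)
  # make transmission dominate: inflate the seed gene's scale
  e$LIV[, "G0001"] <- e$LIV[, "G0001"] * 1000
  pr <- simulate_proteins(e, g, tt, cfg)
  expect_gt(cor(pr[, "P0001"], e$LIV[, "G0001"], method = "spearman"), 0.99)

  # all weights zero: protein-expression correlations are null
  tt0 <- make_truth_table(cfg, g)
  e0 <- simulate_expression(g, tt0, cfg)
  pr0 <- simulate_proteins(e0, g, tt0, cfg)
  r <- abs(cor(pr0, e0$LIV))
  expect_lt(max(r), 4 / sqrt(cfg$n_samples))

  # planted genetic variance fraction is realized
  cfg2 <- tiny_config(n_samples = 10000L, n_genes = 2L, n_tissues = 1L)
  g2 <- simulate_genotypes(cfg2)
  f <- c(P0001 = 0.2, P0002 = 0.35)
  tt2 <- make_truth_table(cfg2, g2, protein_genetic_variance_fraction = f)
  e2 <- simulate_expression(g2, tt2, cfg2)
  pr2 <- simulate_proteins(e2, g2, tt2, cfg2)
  for (p in names(f)) {
    dos <- g2$dosage[, tt2$causal_snp_per_gene[sub("^P", "G", p)]]
    expect_lt(abs(summary(lm(pr2[, p] ~ dos))$r.squared - f[[p]]), 0.03)
  }
  expect_equal(unname(attr(pr2, "realized_genetic_variance")[names(f)]),
               unname(f), tolerance = 1e-10)
})

test_that("summary-statistic pairs realize the requested causal scenarios", {
  expect_error(simulate_summary_pair("distinct", region_size = 1), "distinct")

  nul <- simulate_summary_pair("null", 50, rng_seed = 1)
  z <- abs(nul$trait1$beta) / sqrt(nul$trait1$varbeta)
  expect_lt(max(z), 5)

  sh <- simulate_summary_pair("shared", 50, effect_z = 8, rng_seed = 2)
  z1 <- abs(sh$trait1$beta) / sqrt(sh$trait1$varbeta)
  z2 <- abs(sh$trait2$beta) / sqrt(sh$trait2$varbeta)
  expect_equal(which.max(z1), which.max(z2))
  expect_equal(which.max(z1), sh$causal[1])

  di <- simulate_summary_pair("distinct", 50, effect_z = 8, rng_seed = 3)
  z1 <- abs(di$trait1$beta) / sqrt(di$trait1$varbeta)
  z2 <- abs(di$trait2$beta) / sqrt(di$trait2$varbeta)
  expect_false(which.max(z1) == which.max(z2))
})
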