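test_that("spearman correlation is rank-based with a t-approximation p", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_cor(x, x^3)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  # hand-enumeration via the sum-of-squared-differences formula
  y <- c(2, 1, 4, 3, 5)
  expect_equal(spearman_cor(x, y)$rho, spearman_d2_oracle(x, y))
  # agreement with the reference implementation (rho and asymptotic p)
  set.seed(40)
  for (i in 1:10) {
    a <- rnorm(30); b <- rnorm(30)
    ref <- suppressWarnings(cor.test(a, b, method = "spearman",
                                     exact = FALSE))
    got <- spearman_cor(a, b)
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  }
  # exact permutation p for tiny n matches the reference exact routine
  a <- rnorm(7); b <- rnorm(7)
  expect_equal(spearman_cor(a, b, exact = TRUE)$p,
               cor.test(a, b, method = "spearman", exact = TRUE)$p.value)
  expect_error(spearman_cor(rnorm(20), rnorm(20), exact = TRUE), "n <= 10")
  # degenerate input flagged
  expect_warning(res <- spearman_cor(rep(1, 10), rnorm(10)), "constant")
  expect_true(is.na(res$rho))
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(41)
  x <- rnorm(50); y <- rnorm(50)
  base <- spearman_cor(x, y)
  transforms <- list(function(u) u^3, exp, function(u) atan(u),
                     function(u) 5 * u - 2, function(u) u + abs(min(u)) + 1)
  for (i in 1:20) {
    f <- transforms[[1 + (i - 1) %% length(transforms)]]
    g <- transforms[[1 + i %% length(transforms)]]
    got <- spearman_cor(f(x), g(y))
    expect_identical(got$rho, base$rho)
    expect_identical(got$p, base$p)
  }
})

test_that("spearman_grid equals the scalar routine entry by entry", {
  set.seed(42)
  X <- matrix(rnorm(200), 20, 10)
  Y <- matrix(rnorm(100), 20, 5)
  g <- spearman_grid(X, Y)
  for (i in 1:10) for (j in 1:5) {
    s <- spearman_cor(X[, i], Y[, j])
    expect_equal(unname(g$rho[i, j]), s$rho, tolerance = 1e-12)
    expect_equal(unname(g$p[i, j]), s$p, tolerance = 1e-12)
  }
})

test_that("q-values behave under the null, a spiked mixture, and edge cases", {
  # all p = 1 stays 1
  suppressMessages(q1 <- qvalues(rep(1, 50)))
  expect_equal(as.numeric(q1), rep(1, 50))
  # small families fall back to pi0 = 1 (BH-equivalent) with a message
  set.seed(43)
  p50 <- runif(50)
  expect_message(qvalues(p50), "fewer than 100")
  suppressMessages(q50 <- qvalues(p50))
  expect_equal(as.numeric(q50), p.adjust(p50, method = "BH"))
  # uniform null: pi0 estimate near 1
  set.seed(44)
  pi0s <- replicate(20, attr(qvalues(runif(10000)), "pi0"))
  expect_gte(mean(pi0s >= 0.9), 0.9)
  # spiked mixture with true pi0 = 0.7
  set.seed(45)
  pi0_spiked <- mean(replicate(10, {
    p <- c(rbeta(3000, 0.05, 10), runif(7000))
    attr(qvalues(p), "pi0")
  }))
  expect_lt(abs(pi0_spiked - 0.7), 0.07)
  # q monotone in p and never below pi0 * BH
  p <- runif(10000)
  q <- qvalues(p)
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-15))
  expect_true(all(q <= p.adjust(p, method = "BH") + 1e-15))
})

test_that("seed-gene correlation flags planted transmission and stays calibrated", {
  cfg <- tiny_config(n_samples = 500L, n_genes = 120L, n_tissues = 2L,
                     snps_per_gene = 2L, noise_sd = 0.05)
  g <- simulate_genotypes(cfg)
  genes <- sprintf("G%04d", 1:120)
  tissues <- c("LIV", "BLOOD")
  sw <- matrix(0, 120, 2, dimnames = list(sub("G", "P", genes), tissues))
  sw[1, "LIV"] <- 1  # strong single-tissue transmission
  eb <- matrix(0, 120, 2, dimnames = list(genes, tissues))
  eb[1, "LIV"] <- 1  # give the seed gene expression variance well above noise
  tt <- make_truth_table(cfg, g, seed_weights = sw, eqtl_beta = eb)
  e <- simulate_expression(g, tt, cfg)
  pr <- simulate_proteins(e, g, tt, cfg)
  rec <- correlate_seed_genes(e, pr, tt$protein_map)
  hit <- rec[rec$protein_id == "P0001" & rec$tissue == "LIV", ]
  expect_true(hit$significant)
  expect_gt(hit$rho, 0.9)
  # null pairs: seed flags at about the q-level false-positive rate
  null_rec <- rec[rec$protein_id != "P0001", ]
  expect_lte(mean(null_rec$significant), 0.05)
  # proteins without any measurable transcript are counted
  small_map <- rbind(tt$protein_map,
                     data.frame(protein_id = "PX", gene_id = "GX"))
  rec2 <- correlate_seed_genes(e, pr, small_map)
  expect_equal(attr(rec2, "n_excluded"), 1L)
})

test_that("QQ tables compare observed with uniform-expected quantiles", {
  set.seed(46)
  p_null <- runif(10000)
  expect_lt(abs(qq_slope(p_null) - 1), 0.1)
  p_enr <- c(rbeta(2000, 0.2, 5), runif(8000))
  tab <- qq_compare(p_enr, p_null, labels = c("enriched", "null"))
  top <- tab[tab$expected > 3, ]
  expect_gt(mean(top$observed[top$set == "enriched"]),
            mean(top$observed[top$set == "null"]))
  # identical vectors give identical curves
  t2 <- qq_compare(p_null, p_null)
  expect_identical(t2$observed[t2$set == "a"], t2$observed[t2$set == "b"])
})

test_that("the multivariate model matches OLS oracles and reduces cleanly", {
  set.seed(47)
  n <- 145
  samples <- sprintf("S%03d", 1:n)
  x_liv <- rnorm(n); x_blood <- 0.8 * x_liv + 0.6 * rnorm(n)
  y <- 1 * x_liv + rnorm(n, sd = 0.5)
  e <- list(LIV = matrix(x_liv, n, 1, dimnames = list(samples, "G1")),
            BLOOD = matrix(x_blood, n, 1, dimnames = list(samples, "G1")))
  pr <- matrix(y, n, 1, dimnames = list(samples, "P1"))
  pmap <- data.frame(protein_id = "P1", gene_id = "G1")
  suppressMessages(fit <- multivariate_seed_model(pr, e, pmap))
  co <- fit$coefficients
  o <- ols_oracle(cbind(x_liv, x_blood), y)
  expect_equal(co$beta[co$tissue == "LIV"], unname(o$beta[2]),
               tolerance = 1e-10)
  expect_equal(co$beta[co$tissue == "BLOOD"], unname(o$beta[3]),
               tolerance = 1e-10)
  expect_equal(co$se, unname(o$se[2:3]), tolerance = 1e-10)
  # driving tissue significant, correlated bystander shrunk toward zero
  expect_lt(co$p[co$tissue == "LIV"], 1e-6)
  expect_lt(abs(co$beta[co$tissue == "BLOOD"]), 3 * co$se[co$tissue == "BLOOD"])

  # single tissue reduces to simple regression
  suppressMessages(f1 <- multivariate_seed_model(pr, e["LIV"], pmap))
  o1 <- ols_oracle(x_liv, y)
  expect_equal(f1$coefficients$beta, unname(o1$beta[2]), tolerance = 1e-12)

  # orthogonal signals recover their weights within 3 SE
  set.seed(48)
  x1 <- rnorm(n); x2 <- rnorm(n)
  y2 <- 1 * x1 + 0.5 * x2 + rnorm(n)
  e2 <- list(LIV = matrix(x1, n, 1, dimnames = list(samples, "G1")),
             SF = matrix(x2, n, 1, dimnames = list(samples, "G1")))
  pr2 <- matrix(y2, n, 1, dimnames = list(samples, "P1"))
  suppressMessages(f2 <- multivariate_seed_model(pr2, e2, pmap))
  co2 <- f2$coefficients
  expect_lt(abs(co2$beta[co2$tissue == "LIV"] - 1),
            3 * co2$se[co2$tissue == "LIV"])
  expect_lt(abs(co2$beta[co2$tissue == "SF"] - 0.5),
            3 * co2$se[co2$tissue == "SF"])

  # collinear transcript columns are dropped with a warning
  e3 <- list(LIV = e2$LIV, SF = e2$SF, VAF = e2$LIV)
  expect_warning(suppressMessages(multivariate_seed_model(pr2, e3, pmap)),
                 "collinear")
})

test_that("cross-tissue adjustment strips marginal-only associations", {
  # proteins driven by the liver transcript; another tissue's transcript is
  # merely correlated with liver and should lose significance after
  # adjustment while staying marginally associated
  set.seed(49)
  n <- 300; n_cases <- 20
  samples <- sprintf("S%03d", 1:n)
  genes <- sprintf("G%02d", 1:n_cases)
  liv <- matrix(rnorm(n * n_cases), n, n_cases,
                dimnames = list(samples, genes))
  blood <- 0.9 * liv + sqrt(1 - 0.81) *
    matrix(rnorm(n * n_cases), n, n_cases, dimnames = list(samples, genes))
  pr <- liv + 0.7 * matrix(rnorm(n * n_cases), n, n_cases)
  colnames(pr) <- sub("G", "P", genes)
  pmap <- data.frame(protein_id = colnames(pr), gene_id = genes)
  e <- list(LIV = liv, BLOOD = blood)

  marg <- correlate_seed_genes(e, pr, pmap)
  marg_blood <- marg[marg$tissue == "BLOOD", ]
  suppressMessages(fit <- multivariate_seed_model(pr, e, pmap))
  co <- fit$coefficients
  stripped <- sapply(seq_len(n_cases), function(i) {
    m <- marg_blood[marg_blood$protein_id == colnames(pr)[i], ]
    cc <- co[co$protein_id == colnames(pr)[i], ]
    m$significant && cc$q[cc$tissue == "BLOOD"] > 0.05 &&
      cc$q[cc$tissue == "LIV"] <= 0.05
  })
  expect_gte(mean(stripped), 0.8)
})
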