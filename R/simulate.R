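#' Simulation configuration
#'
#' Parameters of the synthetic multi-tissue study generator. The defaults
#' describe the reference design used throughout the package's validation:
#' 500 samples, 200 genes each flanked by 50 cis-SNPs, seven tissues, and
#' 20 co-expression modules.
#'
#' @param n_samples number of individuals (>= 10).
#' @param n_genes number of genes; each gene yields one candidate plasma
#'   protein.
#' @param n_tissues number of tissues with expression data.
#' @param snps_per_gene number of SNPs placed in each gene's cis region.
#' @param maf_low,maf_high bounds for per-SNP minor allele frequencies;
#'   `maf_low` must be at least 0.05 (rarer variants are excluded from the
#'   analysis, so none are generated).
#' @param ld_block_size number of consecutive SNPs forming one LD block.
#' @param ld_rho latent AR(1) correlation within an LD block, in [0, 1).
#' @param eqtl_effect_sd standard deviation of planted per-allele cis-eQTL
#'   effects.
#' @param seed_weight_range range from which nonzero seed-gene transmission
#'   weights are drawn.
#' @param n_modules number of co-expression modules.
#' @param module_size number of (gene, tissue) members per module.
#' @param eigengene_effect_sd scale of planted module-to-protein effects.
#' @param module_gene_loading loading of a member gene's expression on its
#'   module's latent factor.
#' @param noise_sd residual standard deviation for expression and protein
#'   values (> 0).
#' @param rng_seed integer seed; the same configuration and seed reproduce
#'   all simulated objects bit for bit.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 500L, n_genes = 200L,
                              n_tissues = 7L, snps_per_gene = 50L,
                              maf_low = 0.05, maf_high = 0.5,
                              ld_block_size = 10L, ld_rho = 0.6,
                              eqtl_effect_sd = 0.7,
                              seed_weight_range = c(0.5, 1),
                              n_modules = 20L, module_size = 25L,
                              eigengene_effect_sd = 1,
                              module_gene_loading = 0.8,
                              noise_sd = 1, rng_seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              n_tissues = as.integer(n_tissues),
              snps_per_gene = as.integer(snps_per_gene),
              maf_low = maf_low, maf_high = maf_high,
              ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
              eqtl_effect_sd = eqtl_effect_sd,
              seed_weight_range = seed_weight_range,
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              eigengene_effect_sd = eigengene_effect_sd,
              module_gene_loading = module_gene_loading,
              noise_sd = noise_sd, rng_seed = as.integer(rng_seed))
  counts <- c("n_genes", "n_tissues", "snps_per_gene", "ld_block_size",
              "n_modules", "module_size")
  for (f in counts) if (cfg[[f]] < 1L) stopf("%s must be >= 1", f)
  if (cfg$n_samples < 10L)
    stopf("n_samples must be >= 10 for downstream regression to be defined")
  if (cfg$maf_low < 0.05) stopf("maf_low must be >= 0.05")
  if (cfg$maf_high > 0.5 || cfg$maf_high < cfg$maf_low)
    stopf("need maf_low <= maf_high <= 0.5")
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1) stopf("ld_rho must lie in [0, 1)")
  if (cfg$noise_sd <= 0) stopf("noise_sd must be > 0")
  structure(cfg, class = "simulation_config")
}

tissue_names <- function(n) {
  base <- c("LIV", "BLOOD", "SKLM", "SF", "VAF", "AOR", "MAM")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("T%02d", seq_len(n - length(base)) + length(base)))
}

gene_ids <- function(n) sprintf("G%04d", seq_len(n))
sample_ids <- function(n) sprintf("S%04d", seq_len(n))

#' Gene annotation for a simulated study
#'
#' Genes are laid out on one chromosome with transcription start sites
#' spaced 1 Mb apart, so that +/- 500 kb cis windows of neighbouring genes
#' do not capture each other's SNPs.
#'
#' @param config a [simulation_config()].
#' @return data.frame with `gene_id`, `chrom`, `tss` (1-based) and
#'   `protein_id` (the plasma protein encoded by the gene).
#' @export
simulate_annotation <- function(config) {
  g <- gene_ids(config$n_genes)
  data.frame(gene_id = g, chrom = "chr1",
             tss = seq_len(config$n_genes) * 1e6L,
             protein_id = sub("^G", "P", g))
}

#' Simulate Hardy-Weinberg genotypes with block LD
#'
#' Dosages are drawn through a latent Gaussian copula: within each LD block
#' the latent variables follow an AR(1) process with correlation `ld_rho`,
#' and each latent value is thresholded at the Hardy-Weinberg genotype
#' frequencies of its SNP's minor allele frequency, giving 0/1/2 minor
#' allele counts. Blocks never span genes.
#'
#' @param config a [simulation_config()].
#' @return A [genotype_matrix()]; `info$gene_id` records the cis gene each
#'   SNP belongs to.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_samples
  m <- config$n_genes * config$snps_per_gene
  ann <- simulate_annotation(config)
  with_seed(config$rng_seed, {
    p <- runif(m, config$maf_low, config$maf_high)
    # SNP positions: sorted draws within +/- 400 kb of the gene's TSS
    pos <- unlist(lapply(seq_len(config$n_genes), function(g) {
      sort(sample.int(8e5, config$snps_per_gene) - 4e5L + ann$tss[g])
    }))
    Z <- matrix(rnorm(n * m), n, m)
    rho <- config$ld_rho
    if (rho > 0) {
      w <- sqrt(1 - rho^2)
      for (g in seq_len(config$n_genes)) {
        off <- (g - 1L) * config$snps_per_gene
        blocks <- split(seq_len(config$snps_per_gene),
                        (seq_len(config$snps_per_gene) - 1L) %/%
                          config$ld_block_size)
        for (b in blocks) {
          for (j in b[-1L]) Z[, off + j] <- rho * Z[, off + j - 1L] +
              w * Z[, off + j]
        }
      }
    }
    c0 <- qnorm((1 - p)^2)           # below: homozygous major (dosage 0)
    c1 <- qnorm(1 - p^2)             # above: homozygous minor (dosage 2)
    dos <- (sweep(Z, 2L, c0, ">") + sweep(Z, 2L, c1, ">")) * 1
    dimnames(dos) <- list(sample_ids(n), sprintf("rs%06d", seq_len(m)))
    info <- data.frame(snp_id = colnames(dos), chrom = "chr1", pos = pos,
                       gene_id = rep(ann$gene_id, each = config$snps_per_gene),
                       maf_target = p)
    genotype_matrix(dos, info)
  })
}

#' Construct a planted truth table
#'
#' The truth table holds every quantity the simulator plants and the
#' downstream analyses try to recover: the causal cis-SNP of each gene,
#' per-tissue eQTL effects, seed-gene transmission weights into plasma
#' proteins, module memberships, module-to-protein effects, and target
#' genetic variance fractions for direct cis effects on proteins.
#'
#' @param config a [simulation_config()].
#' @param genotypes the [simulate_genotypes()] output the truth refers to.
#' @param eqtl_beta optional genes x tissues effect matrix; default draws
#'   every effect from N(0, `eqtl_effect_sd`^2).
#' @param seed_weights optional proteins x tissues transmission weight
#'   matrix; default all zero.
#' @param module_membership optional data.frame (`module_id`, `gene_id`,
#'   `tissue`); by default half the modules are tissue-specific and half
#'   cross-tissue, each (gene, tissue) pair belonging to at most one module.
#' @param protein_module_effects optional proteins x modules effect matrix;
#'   default all zero.
#' @param protein_genetic_variance_fraction optional per-protein target for
#'   the fraction of protein variance explained by the causal cis-SNP
#'   (values in [0, 1], NA = no direct cis effect is forced).
#' @return A list of class `truth_table`.
#' @export
make_truth_table <- function(config, genotypes,
                             eqtl_beta = NULL, seed_weights = NULL,
                             module_membership = NULL,
                             protein_module_effects = NULL,
                             protein_genetic_variance_fraction = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(genotypes, "genotype_matrix"))
  genes <- gene_ids(config$n_genes)
  tissues <- tissue_names(config$n_tissues)
  proteins <- sub("^G", "P", genes)
  modules <- sprintf("M%03d", seq_len(config$n_modules))
  with_seed(config$rng_seed + 1L, {
    causal <- vapply(genes, function(g) {
      sample(genotypes$info$snp_id[genotypes$info$gene_id == g], 1L)
    }, character(1L))
    if (is.null(eqtl_beta)) {
      eqtl_beta <- matrix(rnorm(length(genes) * length(tissues),
                                sd = config$eqtl_effect_sd),
                          length(genes), length(tissues),
                          dimnames = list(genes, tissues))
    }
    if (is.null(seed_weights)) {
      seed_weights <- matrix(0, length(proteins), length(tissues),
                             dimnames = list(proteins, tissues))
    }
    if (is.null(module_membership)) {
      module_membership <- default_module_membership(config, genes, tissues,
                                                     modules)
    }
    if (is.null(protein_module_effects)) {
      protein_module_effects <- matrix(0, length(proteins), length(modules),
                                       dimnames = list(proteins, modules))
    }
    if (is.null(protein_genetic_variance_fraction)) {
      protein_genetic_variance_fraction <-
        stats::setNames(rep(NA_real_, length(proteins)), proteins)
    }
  })
  tt <- structure(list(
    causal_snp_per_gene = causal,
    eqtl_beta = eqtl_beta,
    seed_weights = seed_weights,
    module_membership = module_membership,
    protein_module_effects = protein_module_effects,
    protein_genetic_variance_fraction = protein_genetic_variance_fraction,
    protein_map = data.frame(protein_id = proteins, gene_id = genes)),
    class = "truth_table")
  validate_truth_table(tt, genotypes, genes, tissues)
  tt
}

default_module_membership <- function(config, genes, tissues, modules) {
  n_ts <- ceiling(config$n_modules / 2)
  rows <- vector("list", config$n_modules)
  used <- character(0)  # "gene|tissue" pairs already assigned
  for (i in seq_len(config$n_modules)) {
    if (i <= n_ts) {
      tis <- tissues[1L + (i - 1L) %% length(tissues)]
      pool <- setdiff(paste(genes, tis, sep = "|"), used)
    } else {
      pool <- setdiff(as.vector(outer(genes, tissues, paste, sep = "|")), used)
    }
    take <- sample(pool, min(config$module_size, length(pool)))
    if (length(take) == 0L) next
    used <- c(used, take)
    parts <- strsplit(take, "|", fixed = TRUE)
    rows[[i]] <- data.frame(module_id = modules[i],
                            gene_id = vapply(parts, `[`, "", 1L),
                            tissue = vapply(parts, `[`, "", 2L))
  }
  do.call(rbind, rows)
}

validate_truth_table <- function(tt, genotypes, genes, tissues) {
  if (!all(tt$causal_snp_per_gene %in% genotypes$info$snp_id))
    stopf("truth table references SNPs absent from the genotype matrix")
  if (!all(tt$module_membership$gene_id %in% genes))
    stopf("truth table module members reference unknown genes")
  if (!all(tt$module_membership$tissue %in% tissues))
    stopf("truth table module members reference unknown tissues")
  f <- tt$protein_genetic_variance_fraction
  if (any(!is.na(f) & (f < 0 | f >= 1)))
    stopf("protein_genetic_variance_fraction must lie in [0, 1)")
  invisible(tt)
}

#' Simulate per-tissue gene expression
#'
#' Expression of gene g in tissue t is the planted cis-eQTL effect times the
#' dosage of the gene's causal SNP, plus (for module members) the member
#' loading times the module's latent factor, plus Gaussian noise. Module
#' latent factors are standard normal per sample and shared by all members
#' of a module; they are returned in the `module_factors` attribute because
#' module-to-protein effects act through them.
#'
#' @param genotypes a [genotype_matrix()].
#' @param truth a [make_truth_table()] truth table.
#' @param config the [simulation_config()] used for `genotypes`.
#' @return Named list (one samples x genes matrix per tissue) with
#'   attribute `module_factors` (samples x modules matrix).
#' @export
simulate_expression <- function(genotypes, truth, config) {
  stopifnot(inherits(truth, "truth_table"))
  n <- config$n_samples
  genes <- rownames(truth$eqtl_beta)
  tissues <- colnames(truth$eqtl_beta)
  modules <- colnames(truth$protein_module_effects)
  with_seed(config$rng_seed + 2L, {
    factors <- matrix(rnorm(n * length(modules)), n, length(modules),
                      dimnames = list(rownames(genotypes$dosage), modules))
    expr <- lapply(tissues, function(tis) {
      E <- matrix(rnorm(n * length(genes), sd = config$noise_sd), n,
                  length(genes),
                  dimnames = list(rownames(genotypes$dosage), genes))
      beta <- truth$eqtl_beta[, tis]
      hit <- which(beta != 0)
      if (length(hit)) {
        dos <- genotypes$dosage[, truth$causal_snp_per_gene[genes[hit]],
                                drop = FALSE]
        E[, hit] <- E[, hit] + sweep(dos, 2L, beta[hit], "*")
      }
      mem <- truth$module_membership[truth$module_membership$tissue == tis, ,
                                     drop = FALSE]
      if (nrow(mem)) {
        E[, mem$gene_id] <- E[, mem$gene_id] +
          config$module_gene_loading * factors[, mem$module_id, drop = FALSE]
      }
      E
    })
    names(expr) <- tissues
    attr(expr, "module_factors") <- factors
    expr
  })
}

#' Simulate plasma protein levels
#'
#' Each protein is the weighted sum of its seed gene's expression across
#' tissues, plus module effects acting through the module latent factors,
#' plus an optional direct cis-genetic effect, plus Gaussian noise. When a
#' target genetic variance fraction is set for a protein, the direct effect
#' of the causal SNP is scaled so the in-sample fraction of protein variance
#' explained by that SNP equals the target exactly.
#'
#' @param expression output of [simulate_expression()] (its
#'   `module_factors` attribute is required).
#' @param genotypes a [genotype_matrix()].
#' @param truth a [make_truth_table()] truth table.
#' @param config the matching [simulation_config()].
#' @return samples x proteins matrix with attributes
#'   `realized_genetic_variance` (per-protein in-sample R^2 on the causal
#'   SNP) and `pure_noise` (ids of proteins generated as noise because their
#'   seed gene is expressed nowhere and no direct effect was requested).
#' @export
simulate_proteins <- function(expression, genotypes, truth, config) {
  stopifnot(inherits(truth, "truth_table"))
  factors <- attr(expression, "module_factors")
  if (is.null(factors))
    stopf("expression must carry the module_factors attribute")
  n <- config$n_samples
  map <- truth$protein_map
  prot <- matrix(NA_real_, n, nrow(map),
                 dimnames = list(rownames(genotypes$dosage), map$protein_id))
  realized <- stats::setNames(rep(NA_real_, nrow(map)), map$protein_id)
  pure_noise <- character(0)
  with_seed(config$rng_seed + 3L, {
    noise <- matrix(rnorm(n * nrow(map), sd = config$noise_sd), n, nrow(map))
    for (i in seq_len(nrow(map))) {
      p <- map$protein_id[i]; g <- map$gene_id[i]
      trans <- numeric(n)
      expressed <- FALSE
      for (tis in names(expression)) {
        w <- truth$seed_weights[p, tis]
        if (g %in% colnames(expression[[tis]])) {
          expressed <- TRUE
          if (w != 0) trans <- trans + w * expression[[tis]][, g]
        }
      }
      modpart <- as.vector(factors %*% truth$protein_module_effects[p, ])
      rest <- trans + modpart + noise[, i]
      f <- truth$protein_genetic_variance_fraction[p]
      dos <- genotypes$dosage[, truth$causal_snp_per_gene[g]]
      if (!is.na(f)) {
        vg <- stats::var(dos)
        if (vg == 0) stopf("causal SNP of %s has zero dosage variance", p)
        b_rest <- stats::cov(rest, dos) / vg
        e <- rest - b_rest * dos
        a <- sqrt(f / (1 - f) * stats::var(e) / vg)
        prot[, i] <- e + a * dos
      } else {
        if (!expressed) pure_noise <- c(pure_noise, p)
        prot[, i] <- rest
      }
      fit <- stats::lm.fit(cbind(1, dos), prot[, i])
      realized[p] <- 1 - sum(fit$residuals^2) /
        sum((prot[, i] - mean(prot[, i]))^2)
    }
  })
  attr(prot, "realized_genetic_variance") <- realized
  attr(prot, "pure_noise") <- pure_noise
  prot
}

#' Simulate a pair of summary-statistic sets for colocalization
#'
#' Generates per-SNP effect estimates and their variances for two
#' quantitative traits over a common region of independent SNPs, under a
#' named causal configuration: `shared` places the causal association at
#' the same SNP in both traits, `distinct` at two different SNPs,
#' `single_trait` in trait 1 only, and `null` nowhere. Per-SNP variances
#' follow 1 / (2 n maf (1 - maf)); the z-score at a causal SNP is
#' `effect_z` plus standard normal sampling noise.
#'
#' @param scenario one of "shared", "distinct", "single_trait", "null".
#' @param region_size number of SNPs in the region (>= 2 for "distinct").
#' @param n1,n2 sample sizes behind the two traits.
#' @param effect_z expected |z| at a causal SNP.
#' @param rng_seed integer seed.
#' @return list with `trait1` and `trait2` summary data.frames (columns
#'   `snp_id`, `position`, `beta`, `varbeta`, `maf`, `n`) and `causal`,
#'   the planted causal SNP index per trait (NA if none).
#' @export
simulate_summary_pair <- function(scenario = c("shared", "distinct",
                                               "single_trait", "null"),
                                  region_size = 50L, n1 = 5000L, n2 = 5000L,
                                  effect_z = 8, rng_seed = 1L) {
  scenario <- match.arg(scenario)
  if (region_size < 1L) stopf("region_size must be >= 1")
  if (scenario == "distinct" && region_size < 2L)
    stopf("the distinct scenario needs at least 2 SNPs in the region")
  with_seed(rng_seed, {
    k <- as.integer(region_size)
    maf_ <- runif(k, 0.1, 0.5)
    ids <- sprintf("rs%05d", seq_len(k))
    pos <- seq_len(k) * 1000L
    causal <- switch(scenario,
      shared = rep(sample.int(k, 1L), 2L),
      distinct = sample.int(k, 2L),
      single_trait = c(sample.int(k, 1L), NA),
      null = c(NA, NA))
    mk <- function(nn, cs) {
      z <- rnorm(k)
      if (!is.na(cs)) z[cs] <- z[cs] + effect_z
      vb <- 1 / (2 * nn * maf_ * (1 - maf_))
      data.frame(snp_id = ids, position = pos, beta = z * sqrt(vb),
                 varbeta = vb, maf = maf_, n = nn)
    }
    list(trait1 = mk(n1, causal[1L]), trait2 = mk(n2, causal[2L]),
         causal = causal)
  })
}
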