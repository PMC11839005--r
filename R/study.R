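#' Simulate a three-way protein-regulation study
#'
#' Builds the package's reference validation design: a multi-tissue cohort
#' in which measured plasma proteins split into three equal groups driven
#' by (i) seed-gene transmission from a single tissue, (ii) a
#' tissue-specific co-expression module and (iii) a cross-tissue module.
#' Module members are drawn from genes that do not encode measured
#' proteins, so each protein's true category is unambiguous. Half the
#' modules are tissue-specific (all members from one tissue) and half
#' cross-tissue.
#'
#' @param config a [simulation_config()]; `n_genes` must exceed
#'   `3 * n_per_category` so module members can avoid protein-coding
#'   genes, and `n_modules` must be even.
#' @param n_per_category proteins per driving mechanism (default 30).
#' @return list with `config`, `genotypes`, `annotation`, `truth`,
#'   `expression`, `proteins` (the measured proteins only), `protein_map`,
#'   `modules` (membership table) and `true_category`.
#' @export
simulate_category_study <- function(config = simulation_config(),
                                    n_per_category = 30L) {
  n_prot <- 3L * n_per_category
  if (config$n_genes <= n_prot)
    stopf("need n_genes > %d so module members avoid measured proteins",
          n_prot)
  if (config$n_modules %% 2L != 0L) stopf("n_modules must be even")
  genotypes <- simulate_genotypes(config)
  annotation <- simulate_annotation(config)
  genes <- gene_ids(config$n_genes)
  tissues <- tissue_names(config$n_tissues)
  proteins <- sub("^G", "P", genes)
  modules <- sprintf("M%03d", seq_len(config$n_modules))
  n_ts <- config$n_modules %/% 2L
  bg_genes <- genes[(n_prot + 1L):config$n_genes]

  with_seed(config$rng_seed + 10L, {
    mem <- list()
    used <- character(0)
    for (i in seq_len(config$n_modules)) {
      if (i <= n_ts) {
        tis <- tissues[1L + (i - 1L) %% length(tissues)]
        pool <- setdiff(paste(bg_genes, tis, sep = "|"), used)
      } else {
        pool <- setdiff(as.vector(outer(bg_genes, tissues, paste,
                                        sep = "|")), used)
      }
      take <- sample(pool, config$module_size)
      used <- c(used, take)
      parts <- strsplit(take, "|", fixed = TRUE)
      mem[[i]] <- data.frame(module_id = modules[i],
                             gene_id = vapply(parts, `[`, "", 1L),
                             tissue = vapply(parts, `[`, "", 2L))
    }
    mem <- do.call(rbind, mem)

    sw <- matrix(0, length(proteins), length(tissues),
                 dimnames = list(proteins, tissues))
    pme <- matrix(0, length(proteins), length(modules),
                  dimnames = list(proteins, modules))
    truecat <- rep(NA_character_, n_prot)
    for (i in seq_len(n_prot)) {
      if (i <= n_per_category) {
        tis <- tissues[1L + (i - 1L) %% length(tissues)]
        sw[i, tis] <- runif(1L, config$seed_weight_range[1L],
                            config$seed_weight_range[2L])
        truecat[i] <- "seed_gene"
      } else if (i <= 2L * n_per_category) {
        m <- 1L + (i - n_per_category - 1L) %% n_ts
        pme[i, m] <- config$eigengene_effect_sd * sample(c(-1, 1), 1L)
        truecat[i] <- "tissue_specific_grn"
      } else {
        m <- n_ts + 1L + (i - 2L * n_per_category - 1L) %% n_ts
        pme[i, m] <- config$eigengene_effect_sd * sample(c(-1, 1), 1L)
        truecat[i] <- "cross_tissue_grn"
      }
    }
  })
  truth <- make_truth_table(config, genotypes,
                            seed_weights = sw, module_membership = mem,
                            protein_module_effects = pme)
  expression <- simulate_expression(genotypes, truth, config)
  all_prot <- simulate_proteins(expression, genotypes, truth, config)
  measured <- proteins[seq_len(n_prot)]
  list(config = config, genotypes = genotypes, annotation = annotation,
       truth = truth, expression = expression,
       proteins = all_prot[, measured, drop = FALSE],
       protein_map = truth$protein_map[seq_len(n_prot), , drop = FALSE],
       modules = mem,
       true_category = data.frame(protein_id = measured,
                                  category = truecat))
}

#' Run the association pipeline on a simulated study
#'
#' Computes seed-gene associations, recomputes module eigengenes from
#' expression, runs the eigengene association grid and assigns each
#' protein its strongest-association category; when the study carries a
#' planted truth, the category recovery rate is reported.
#'
#' @param study output of [simulate_category_study()] (or a list with the
#'   same components).
#' @param alpha significance threshold on q (default 0.05).
#' @return list with `seed_records`, `module_info`, `eigengenes`,
#'   `eigengene_records`, `categories` and `recovery` (fraction of
#'   proteins assigned their true category; NA without a truth table).
#' @export
run_association_pipeline <- function(study, alpha = 0.05) {
  seed_rec <- correlate_seed_genes(study$expression, study$proteins,
                                   study$protein_map, alpha = alpha)
  me <- module_eigengenes(study$expression, study$modules)
  eg_rec <- correlate_eigengenes(study$proteins, me$eigengenes, me$info,
                                 alpha = alpha)
  cats <- categorize_proteins(seed_rec, eg_rec, study$modules,
                              study$protein_map, alpha = alpha)
  recovery <- if (!is.null(study$true_category)) {
    truth <- study$true_category
    mean(cats$category[match(truth$protein_id, cats$protein_id)] ==
           truth$category)
  } else NA_real_
  list(seed_records = seed_rec, module_info = me$info,
       eigengenes = me$eigengenes, eigengene_records = eg_rec,
       categories = cats, recovery = recovery)
}

#' Run the cis-QTL arm of the pipeline on a simulated study
#'
#' Filters SNPs, maps cis-pQTLs for the measured proteins and cis-eQTLs
#' for their seed genes in every tissue, applies global FDR control, and
#' derives tissue-sharing sets and allelic-coherence calls for the shared
#' e/pQTLs.
#'
#' @param study output of [simulate_category_study()].
#' @param fdr_alpha FDR threshold (default 0.05).
#' @return list with `windows`, `pqtl`, `eqtl` (per tissue), `overlap`
#'   and `coherence`.
#' @export
run_qtl_pipeline <- function(study, fdr_alpha = 0.05) {
  geno <- filter_snps(study$genotypes)
  windows <- define_cis_windows(study$annotation)
  fm <- data.frame(feature_id = study$protein_map$protein_id,
                   gene_id = study$protein_map$gene_id)
  pqtl <- apply_fdr(map_cis_qtl(geno, study$proteins, windows,
                                tissue = "plasma", feature_map = fm),
                    alpha = fdr_alpha)
  eqtl <- lapply(names(study$expression), function(tis) {
    apply_fdr(map_cis_qtl(geno, study$expression[[tis]], windows,
                          tissue = tis), alpha = fdr_alpha)
  })
  names(eqtl) <- names(study$expression)
  ov <- overlap_qtls(eqtl, pqtl, study$protein_map)
  coh <- coherence_calls(eqtl, pqtl, study$protein_map)
  list(windows = windows, pqtl = pqtl, eqtl = eqtl, overlap = ov,
       coherence = coh, genotypes = geno)
}
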