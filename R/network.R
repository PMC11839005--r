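#' Module eigengene
#'
#' The eigengene is the first principal-component score of the module's
#' standardized member expression: genes are centered and scaled to unit
#' variance, the first right singular vector gives per-sample scores,
#' which are rescaled to unit variance. The sign is fixed so that the mean
#' correlation with member genes is non-negative, making the result
#' deterministic across linear-algebra backends.
#'
#' @param expr samples x members numeric matrix (the module's member
#'   expression, samples harmonized).
#' @return list of class `eigengene`: `values` (named per-sample vector,
#'   unit variance), `pc1_variance_fraction`, `n_members`.
#' @export
compute_eigengene <- function(expr) {
  if (is.null(dim(expr))) expr <- matrix(expr, ncol = 1L)
  if (ncol(expr) == 0L) stopf("empty module")
  sds <- apply(expr, 2L, stats::sd)
  if (any(sds == 0)) {
    warnf("dropping %d constant member(s)", sum(sds == 0))
    expr <- expr[, sds > 0, drop = FALSE]
    if (ncol(expr) == 0L) stopf("all module members are constant")
  }
  Z <- scale(expr)
  sv <- svd(Z, nu = 1L, nv = 0L)
  score <- sv$u[, 1L] * sv$d[1L]
  score <- score / stats::sd(score)
  if (mean(stats::cor(score, Z)) < 0) score <- -score
  names(score) <- rownames(expr)
  structure(list(values = score,
                 pc1_variance_fraction = sv$d[1L]^2 / sum(sv$d^2),
                 n_members = ncol(expr)),
            class = "eigengene")
}

#' Classify a module as tissue-specific or cross-tissue
#'
#' Purity is the largest fraction of members contributed by a single
#' tissue; modules with purity >= `purity_threshold` are tissue-specific,
#' the rest cross-tissue.
#'
#' @param members data.frame with `gene_id` and `tissue` (one module's
#'   membership).
#' @param module_id module identifier stored on the result.
#' @param purity_threshold default 0.95.
#' @return list of class `module_definition`: `module_id`, `n_members`,
#'   `purity`, `class`, `major_tissue`.
#' @export
classify_module <- function(members, module_id = "module",
                            purity_threshold = 0.95) {
  if (nrow(members) == 0L) stopf("empty module")
  tab <- table(members$tissue)
  purity <- max(tab) / nrow(members)
  structure(list(module_id = module_id, n_members = nrow(members),
                 purity = unname(purity),
                 class = if (purity >= purity_threshold) "tissue_specific"
                         else "cross_tissue",
                 major_tissue = names(tab)[which.max(tab)]),
            class = "module_definition")
}

#' Eigengenes and classes for all modules
#'
#' Recomputes every module's eigengene from expression restricted to the
#' samples shared by all tissues, and classifies each module by tissue
#' purity.
#'
#' @param expression named list of samples x genes matrices per tissue.
#' @param modules membership data.frame (`module_id`, `gene_id`, `tissue`).
#' @param purity_threshold passed to [classify_module()].
#' @return list with `eigengenes` (samples x modules matrix, unit-variance
#'   columns) and `info` (data.frame `module_id`, `n_members`, `purity`,
#'   `class`, `pc1_variance_fraction`).
#' @export
module_eigengenes <- function(expression, modules, purity_threshold = 0.95) {
  common <- Reduce(intersect, lapply(expression, rownames))
  if (length(common) < 3L) stopf("fewer than 3 samples shared across tissues")
  ids <- unique(modules$module_id)
  eg <- matrix(NA_real_, length(common), length(ids),
               dimnames = list(common, ids))
  info <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    mem <- modules[modules$module_id == ids[i], , drop = FALSE]
    cols <- lapply(seq_len(nrow(mem)), function(j) {
      E <- expression[[mem$tissue[j]]]
      if (is.null(E) || !(mem$gene_id[j] %in% colnames(E)))
        return(NULL)
      E[common, mem$gene_id[j]]
    })
    keep <- !vapply(cols, is.null, logical(1L))
    if (!any(keep))
      stopf("module %s has no member with expression data", ids[i])
    sub <- do.call(cbind, cols[keep])
    e <- compute_eigengene(sub)
    cl <- classify_module(mem, ids[i], purity_threshold)
    eg[, i] <- e$values
    info[[i]] <- data.frame(module_id = ids[i], n_members = cl$n_members,
                            purity = cl$purity, class = cl$class,
                            pc1_variance_fraction = e$pc1_variance_fraction)
  }
  list(eigengenes = eg, info = do.call(rbind, info))
}

#' Correlate module eigengenes with plasma proteins
#'
#' Full protein x module Spearman grid with Storey-Tibshirani q-values
#' over the grid family. Each record's predictor class reflects the
#' module's tissue purity.
#'
#' @param proteins samples x proteins matrix.
#' @param eigengenes samples x modules matrix (e.g. from
#'   [module_eigengenes()]).
#' @param module_info optional data.frame with `module_id` and `class`;
#'   when absent all modules are labeled "eigengene".
#' @param alpha significance threshold on q (default 0.05).
#' @return data.frame of association records (`predictor_id`,
#'   `predictor_class`, `protein_id`, `rho`, `p`, `q`, `n`,
#'   `significant`).
#' @export
correlate_eigengenes <- function(proteins, eigengenes, module_info = NULL,
                                 alpha = 0.05) {
  common <- intersect(rownames(proteins), rownames(eigengenes))
  if (length(common) < 3L) stopf("fewer than 3 shared samples")
  g <- spearman_grid(eigengenes[common, , drop = FALSE],
                     proteins[common, , drop = FALSE])
  rec <- data.frame(predictor_id = rep(colnames(eigengenes),
                                       times = ncol(proteins)),
                    protein_id = rep(colnames(proteins),
                                     each = ncol(eigengenes)),
                    rho = as.vector(g$rho), p = as.vector(g$p), n = g$n)
  rec$predictor_class <- if (is.null(module_info)) "eigengene" else {
    cls <- module_info$class[match(rec$predictor_id, module_info$module_id)]
    ifelse(cls == "tissue_specific", "tissue_specific_grn",
           "cross_tissue_grn")
  }
  rec <- rec[!is.na(rec$rho), , drop = FALSE]
  rec$q <- as.numeric(qvalues(rec$p))
  rec$significant <- rec$q <= alpha
  rec
}

#' Permutation null for eigengene-protein associations
#'
#' In every permutation round the sample labels of each eigengene are
#' shuffled independently (protein-protein correlation structure is
#' preserved) and the full Spearman association grid is recomputed; the
#' pooled p-values form the empirical null of the association scan.
#'
#' @param proteins samples x proteins matrix.
#' @param eigengenes samples x modules matrix.
#' @param n_perm number of permutation rounds (>= 100, default 1000).
#' @param rng_seed integer seed.
#' @return Numeric vector of pooled permuted p-values
#'   (`n_perm * n_proteins * n_modules` values).
#' @export
permutation_null <- function(proteins, eigengenes, n_perm = 1000L,
                             rng_seed = 1L) {
  if (n_perm < 100L) stopf("n_perm must be >= 100")
  common <- intersect(rownames(proteins), rownames(eigengenes))
  P <- proteins[common, , drop = FALSE]
  E <- eigengenes[common, , drop = FALSE]
  n <- length(common)
  with_seed(rng_seed, {
    out <- vector("list", n_perm)
    for (b in seq_len(n_perm)) {
      Ep <- apply(E, 2L, function(col) col[sample.int(n)])
      rownames(Ep) <- common
      out[[b]] <- as.vector(spearman_grid(Ep, P)$p)
    }
    unlist(out)
  })
}

#' Is a protein's seed gene a member of a module?
#'
#' TRUE when the protein's coding gene appears among the module's members
#' in any tissue.
#'
#' @param protein_id protein identifier.
#' @param module_id module identifier.
#' @param modules membership data.frame (`module_id`, `gene_id`, `tissue`).
#' @param protein_map data.frame (`protein_id`, `gene_id`).
#' @return logical flag; FALSE with a warning for an unmapped protein.
#' @export
seedgene_in_module <- function(protein_id, module_id, modules, protein_map) {
  gid <- protein_map$gene_id[match(protein_id, protein_map$protein_id)]
  if (is.na(gid)) {
    warnf("protein %s has no mapped coding gene", protein_id)
    return(FALSE)
  }
  any(modules$module_id == module_id & modules$gene_id == gid)
}

#' Assign each protein its strongest-association category
#'
#' Among a protein's significant associations (q <= alpha) across the
#' seed-gene and eigengene families, picks the record with the largest
#' |rho| (ties broken by smaller q, then lexicographic predictor id); the
#' protein's category is the winning predictor's class (seed_gene,
#' tissue_specific_grn or cross_tissue_grn), or "none" without any
#' significant association. Also emits per-protein overlap flags: any
#' significant seed-gene association, and significant associations with
#' modules containing versus not containing the protein's seed gene.
#'
#' @param seed_records output of [correlate_seed_genes()].
#' @param eigengene_records output of [correlate_eigengenes()].
#' @param modules membership data.frame (for the overlap flags).
#' @param protein_map data.frame (`protein_id`, `gene_id`).
#' @param alpha significance threshold on q (default 0.05).
#' @return data.frame with one row per protein: `protein_id`, `category`,
#'   `best_predictor`, `best_rho`, `assoc_seed`, `assoc_grn_with_seed`,
#'   `assoc_grn_without_seed`.
#' @export
categorize_proteins <- function(seed_records, eigengene_records,
                                modules = NULL, protein_map = NULL,
                                alpha = 0.05) {
  cols <- c("predictor_id", "predictor_class", "protein_id", "rho", "q")
  all_rec <- rbind(cbind(seed_records[cols]), cbind(eigengene_records[cols]))
  prots <- sort(unique(c(seed_records$protein_id,
                         eigengene_records$protein_id)))
  out <- lapply(prots, function(p) {
    r <- all_rec[all_rec$protein_id == p & all_rec$q <= alpha, ,
                 drop = FALSE]
    if (nrow(r) == 0L) {
      best <- data.frame(category = "none", best_predictor = NA_character_,
                         best_rho = NA_real_)
    } else {
      r <- r[order(-abs(r$rho), r$q, r$predictor_id), , drop = FALSE]
      best <- data.frame(category = r$predictor_class[1L],
                         best_predictor = r$predictor_id[1L],
                         best_rho = r$rho[1L])
    }
    grn <- r[r$predictor_class != "seed_gene", , drop = FALSE]
    in_mod <- if (nrow(grn) && !is.null(modules) && !is.null(protein_map)) {
      vapply(grn$predictor_id, function(m)
        seedgene_in_module(p, m, modules, protein_map), logical(1L))
    } else logical(0)
    cbind(data.frame(protein_id = p), best,
          data.frame(assoc_seed = any(r$predictor_class == "seed_gene"),
                     assoc_grn_with_seed = any(in_mod),
                     assoc_grn_without_seed = nrow(grn) > 0 && !all(in_mod)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
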