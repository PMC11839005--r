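#' Spearman rank correlation with a t-approximation p-value
#'
#' rho is the Pearson correlation of average-ranked values; the two-sided
#' p-value uses the large-sample t approximation
#' t = rho sqrt((n - 2)/(1 - rho^2)) on n - 2 degrees of freedom. For tiny
#' samples an exact p-value over the permutation distribution is available.
#'
#' @param x,y numeric vectors of equal length >= 3, no missing values.
#' @param exact use the exact permutation distribution (requires n <= 10
#'   and no ties).
#' @return list with `rho`, `p` and `n`; `rho` is NA (flagged with a
#'   warning) when either vector has zero rank variance.
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  n <- length(x)
  if (length(y) != n || n < 3L) stopf("need equal-length vectors, n >= 3")
  if (anyNA(x) || anyNA(y)) stopf("missing values are not allowed")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    warnf("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 10L) stopf("exact p-values are supported for n <= 10 only")
    p <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- if (!is.finite(tt)) 0 else 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = min(p, 1), n = n)
}

# Spearman rho/p for matched column pairs of X and Y (both n x k).
spearman_pairs <- function(X, Y) {
  n <- nrow(X)
  Xr <- rank_standardize(X)
  Yr <- rank_standardize(Y)
  rho <- colSums(Xr * Yr) / (n - 1)
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- pmin(2 * stats::pt(-abs(tt), df = n - 2), 1)
  p[abs(rho) >= 1] <- 0
  list(rho = rho, p = p, n = n)
}

#' Spearman correlation grid
#'
#' All-pairs Spearman correlations between the columns of two matrices
#' sharing rows (samples), with t-approximation p-values.
#'
#' @param X,Y numeric matrices with identical row counts (samples).
#' @return list of matrices `rho` and `p` (columns of X by columns of Y)
#'   and the sample count `n`.
#' @export
spearman_grid <- function(X, Y) {
  stopifnot(nrow(X) == nrow(Y))
  n <- nrow(X)
  Xr <- rank_standardize(X)
  Yr <- rank_standardize(Y)
  rho <- crossprod(Xr, Yr) / (n - 1)
  rho <- pmin(pmax(rho, -1), 1)
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(rho) >= 1] <- 0
  list(rho = rho, p = p, n = n)
}

#' Storey-Tibshirani q-values
#'
#' Estimates the null proportion pi0 on the lambda grid 0.05, 0.10, ...,
#' 0.95 with the smoother method (a 3-df smoothing spline of pi0(lambda)
#' evaluated at the largest lambda, clipped to (0, 1]), then computes
#' q_i = pi0 * min over p-rank >= i of m p_(j) / j — i.e. pi0 times the
#' Benjamini-Hochberg step-up adjustment, so q is monotone in p. With
#' fewer than 100 p-values pi0 estimation is unreliable and pi0 = 1 is
#' used (the BH-equivalent), with a message.
#'
#' @param p vector of p-values in [0, 1].
#' @param lambda grid for pi0 estimation.
#' @return q-values, same order as `p`, with attribute `pi0`.
#' @export
qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(structure(numeric(0), pi0 = 1))
  if (m < 100L) {
    message("qvalues: fewer than 100 tests; using pi0 = 1 (BH-equivalent)")
    pi0 <- 1
  } else {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1L))
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
    pi0 <- min(pi0, 1)
    if (pi0 <= 0) {
      warnf("qvalues: smoothed pi0 estimate <= 0; clipping")
      pi0 <- max(min(pi0_l[pi0_l > 0]), .Machine$double.eps)
    }
  }
  q <- pi0 * stats::p.adjust(p, method = "BH")
  structure(pmin(q, 1), pi0 = pi0)
}

#' Correlate seed-gene expression with plasma protein levels
#'
#' For every tissue and every protein whose coding gene is expressed in
#' that tissue, computes the Spearman correlation between the gene's
#' tissue expression and the plasma protein level over the samples shared
#' by the two datasets (sample sets may differ across tissues). q-values
#' are computed over the pooled family by default, or per tissue. A record
#' is flagged a seed gene where q <= alpha.
#'
#' @param expression named list of samples x genes matrices, one per
#'   tissue.
#' @param proteins samples x proteins matrix.
#' @param protein_map data.frame (`protein_id`, `gene_id`).
#' @param alpha significance threshold on q (default 0.05).
#' @param scope q-value family: "global" pools all tissues (default),
#'   "per_tissue" adjusts within tissue.
#' @return data.frame of association records (`predictor_id`,
#'   `predictor_class` = "seed_gene", `tissue`, `protein_id`, `rho`, `p`,
#'   `q`, `n`, `significant`), with attribute `n_excluded` counting
#'   proteins whose transcript is expressed in no tissue.
#' @export
correlate_seed_genes <- function(expression, proteins, protein_map,
                                 alpha = 0.05,
                                 scope = c("global", "per_tissue")) {
  scope <- match.arg(scope)
  rows <- list()
  covered <- character(0)
  for (tis in names(expression)) {
    E <- expression[[tis]]
    common <- intersect(rownames(E), rownames(proteins))
    map <- protein_map[protein_map$gene_id %in% colnames(E) &
                         protein_map$protein_id %in% colnames(proteins), ,
                       drop = FALSE]
    if (!nrow(map) || length(common) < 3L) next
    covered <- union(covered, map$protein_id)
    sp <- spearman_pairs(E[common, map$gene_id, drop = FALSE],
                         proteins[common, map$protein_id, drop = FALSE])
    rows[[tis]] <- data.frame(predictor_id = map$gene_id,
                              predictor_class = "seed_gene", tissue = tis,
                              protein_id = map$protein_id,
                              rho = sp$rho, p = sp$p, n = sp$n)
  }
  rec <- do.call(rbind, rows)
  if (is.null(rec)) stopf("no gene-protein pair is measurable in any tissue")
  rownames(rec) <- NULL
  rec <- rec[!is.na(rec$rho), , drop = FALSE]
  rec$q <- if (scope == "global") qvalues(rec$p) else
    stats::ave(rec$p, rec$tissue, FUN = function(p) as.numeric(qvalues(p)))
  rec$significant <- rec$q <= alpha
  attr(rec, "n_excluded") <-
    sum(!unique(protein_map$protein_id) %in% covered)
  rec
}

#' Observed-versus-expected quantiles of two p-value sets
#'
#' For each set, pairs the sorted observed -log10 p-values with the
#' -log10 of the uniform order-statistic expectations (i - 0.5)/m — the
#' table behind a QQ plot comparing, e.g., seed-gene against non-seed-gene
#' associations.
#'
#' @param p_a,p_b p-value vectors.
#' @param labels length-2 labels for the two sets.
#' @return data.frame with `set`, `expected`, `observed` (-log10 scale).
#' @export
qq_compare <- function(p_a, p_b, labels = c("a", "b")) {
  one <- function(p, lab) {
    m <- length(p)
    data.frame(set = lab, expected = -log10((seq_len(m) - 0.5) / m),
               observed = -log10(sort(p)))
  }
  rbind(one(p_a, labels[1L]), one(p_b, labels[2L]))
}

#' Slope of a p-value QQ line
#'
#' Through-origin regression slope of observed on expected -log10
#' p-values; approximately 1 for uniform p-values, above 1 under
#' enrichment.
#'
#' @param p p-value vector.
#' @return Fitted slope.
#' @export
qq_slope <- function(p) {
  m <- length(p)
  e <- -log10((seq_len(m) - 0.5) / m)
  o <- -log10(sort(p))
  sum(e * o) / sum(e^2)
}

#' Multivariate cross-tissue seed-gene model
#'
#' For each protein Y, fits Y = b0 + sum_t b_t X_t + e by OLS, where X_t
#' is the coding gene's expression in tissue t, over the samples present
#' in every dataset (all tissues and the protein matrix). Coefficient
#' p-values come from per-coefficient t-tests; q-values are computed over
#' the pooled protein x tissue coefficient family. Proteins whose
#' transcript is expressed in no tissue are excluded and counted;
#' collinear transcript columns are dropped with a warning.
#'
#' @inheritParams correlate_seed_genes
#' @return list of class `multitissue_fit`: `coefficients` (data.frame
#'   `protein_id`, `tissue`, `beta`, `se`, `tstat`, `p`, `q`),
#'   `intercepts`, `n` (common sample count), `n_excluded`.
#' @export
multivariate_seed_model <- function(proteins, expression, protein_map) {
  common <- Reduce(intersect, c(lapply(expression, rownames),
                                list(rownames(proteins))))
  if (length(common) < 3L) stopf("fewer than 3 samples shared by all datasets")
  rows <- list(); icpt <- list()
  excluded <- 0L
  for (pid in intersect(protein_map$protein_id, colnames(proteins))) {
    gid <- protein_map$gene_id[match(pid, protein_map$protein_id)]
    tiss <- names(expression)[vapply(expression, function(E)
      gid %in% colnames(E), logical(1L))]
    if (!length(tiss)) { excluded <- excluded + 1L; next }
    X <- vapply(tiss, function(tis) expression[[tis]][common, gid],
                numeric(length(common)))
    y <- proteins[common, pid]
    fit <- stats::lm(y ~ X)
    cf <- stats::coef(fit)
    aliased <- is.na(cf)
    if (any(aliased)) {
      warnf("%s: dropping collinear transcript column(s) %s", pid,
            paste(tiss[aliased[-1L]], collapse = ", "))
    }
    sm <- summary(fit)$coefficients
    keep <- rownames(sm) != "(Intercept)"
    kept_tis <- tiss[!aliased[-1L]]
    rows[[pid]] <- data.frame(protein_id = pid, tissue = kept_tis,
                              beta = sm[keep, 1L], se = sm[keep, 2L],
                              tstat = sm[keep, 3L], p = sm[keep, 4L])
    icpt[[pid]] <- unname(cf[1L])
  }
  if (!length(rows)) stopf("no protein has an expressed transcript")
  co <- do.call(rbind, rows)
  rownames(co) <- NULL
  co$q <- as.numeric(qvalues(co$p))
  structure(list(coefficients = co, intercepts = unlist(icpt),
                 n = length(common), n_excluded = excluded),
            class = "multitissue_fit")
}

#' @export
print.multitissue_fit <- function(x, ...) {
  cat(sprintf("multitissue_fit: %d proteins, %d samples, %d excluded\n",
              length(unique(x$coefficients$protein_id)), x$n, x$n_excluded))
  cat(sprintf("  %d coefficients, %d with q <= 0.05\n",
              nrow(x$coefficients), sum(x$coefficients$q <= 0.05)))
  invisible(x)
}
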