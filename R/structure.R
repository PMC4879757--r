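# Preprocessing used by the structure scan. TPM spans 4-5 orders of
# magnitude, so raw-scale PCA is dominated by the loudest genes; the default
# log-transforms and standardises per gene.
preprocess_expression <- function(m, preprocessing = c("log10p_zscore", "log10p", "raw"),
                                  drop_constant = TRUE) {
  preprocessing <- match.arg(preprocessing)
  x <- unclass(m)
  if (preprocessing %in% c("log10p", "log10p_zscore")) x <- log10(x + 1)
  v <- apply(x, 2, stats::var)
  if (drop_constant && any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance gene(s)")
    x <- x[, v > 0, drop = FALSE]
  }
  if (!ncol(x)) stop("all selected genes have zero variance")
  if (preprocessing == "log10p_zscore") x <- scale(x)
  x
}

#' Most variable genes
#'
#' Ranks genes by the variance of log10(TPM + 1) across cells and returns the
#' top `ceiling(fraction * n_genes)`. Ties at the cut boundary are broken by
#' lexicographic gene symbol order (smaller symbol kept), so the selection is
#' deterministic.
#'
#' @param m an [expr_matrix()].
#' @param fraction proportion of genes to keep, in (0, 1]; the conventional
#'   scan uses the top 10%.
#' @return character vector of gene symbols.
#' @export
top_variable_genes <- function(m, fraction = 0.1) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  v <- apply(log10(unclass(m) + 1), 2, stats::var)
  ord <- order(-v, colnames(m))
  colnames(m)[ord][seq_len(ceiling(fraction * ncol(m)))]
}

#' PCA variance profile
#'
#' Principal component analysis of the cells-by-selected-genes submatrix
#' after the chosen preprocessing (default: log10(TPM + 1) then per-gene
#' z-score). Reports the proportion of variance explained by each of the
#' `min(n_cells - 1, n_genes)` components.
#'
#' @param m an [expr_matrix()].
#' @param genes gene symbols to use (>= 2; zero-variance genes are dropped
#'   with a warning).
#' @param preprocessing `"log10p_zscore"` (default), `"log10p"`, or `"raw"`.
#' @return list of class `pca_profile` with `variance_explained`,
#'   `n_components`, `preprocessing`.
#' @export
pca_profile <- function(m, genes = gene_ids(m),
                        preprocessing = c("log10p_zscore", "log10p", "raw")) {
  preprocessing <- match.arg(preprocessing)
  if (length(genes) < 2) stop("PCA requires at least 2 genes")
  if (nrow(m) < 3) stop("PCA requires at least 3 cells")
  missing <- setdiff(genes, colnames(m))
  if (length(missing)) stop("genes absent from matrix: ", paste(missing, collapse = ", "))
  x <- preprocess_expression(m[, genes, drop = FALSE], preprocessing)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  k <- min(nrow(m) - 1, ncol(x))
  ve <- ve[seq_len(min(k, length(ve)))]
  structure(list(variance_explained = ve, n_components = length(ve),
                 preprocessing = preprocessing),
            class = "pca_profile")
}

# Independently permute each gene's values across cells: preserves each
# gene's marginal multiset exactly, destroys cross-gene correlation.
shuffle_within_genes <- function(m) {
  x <- unclass(m)
  for (g in seq_len(ncol(x))) x[, g] <- x[sample.int(nrow(x)), g]
  x
}

#' Randomized-order PCA null
#'
#' Compares the real PCA variance profile against profiles of null datasets
#' in which each gene's values are independently permuted across cells
#' ("the same expression data in randomized order"). If the cells carry
#' genuine cross-gene population structure, the real PC1 should concentrate
#' more variance than the shuffled data can. `pc1_excess_p` is the empirical
#' probability `(1 + #{null PC1 >= real PC1}) / (n_shuffles + 1)`.
#'
#' @param m an [expr_matrix()].
#' @param genes gene symbols to analyse.
#' @param n_shuffles number of null datasets (>= 19).
#' @param seed integer seed.
#' @param preprocessing passed to [pca_profile()].
#' @param global_shuffle if `TRUE`, permute the whole matrix as one pool
#'   instead of within genes (breaks per-gene marginals; off by default).
#' @return list with `real_profile`, `null_pc1` (vector of null PC1
#'   proportions), `null_profiles` (list), `pc1_excess_p`, `n_shuffles`.
#' @export
randomized_pca_null <- function(m, genes = gene_ids(m), n_shuffles = 99,
                                seed = 1L,
                                preprocessing = c("log10p_zscore", "log10p", "raw"),
                                global_shuffle = FALSE) {
  preprocessing <- match.arg(preprocessing)
  if (n_shuffles < 19) stop("n_shuffles must be at least 19")
  real <- pca_profile(m, genes, preprocessing)
  sub <- m[, genes, drop = FALSE]
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(seed)
  null_profiles <- vector("list", n_shuffles)
  for (r in seq_len(n_shuffles)) {
    xs <- if (global_shuffle) {
      x <- unclass(sub)
      matrix(sample(x), nrow(x), ncol(x), dimnames = dimnames(x))
    } else {
      shuffle_within_genes(sub)
    }
    ms <- expr_matrix(xs, rownames(sub), colnames(sub))
    null_profiles[[r]] <- suppressWarnings(pca_profile(ms, preprocessing = preprocessing))
  }
  null_pc1 <- vapply(null_profiles, function(p) p$variance_explained[1], numeric(1))
  pc1 <- real$variance_explained[1]
  list(real_profile = real, null_pc1 = null_pc1, null_profiles = null_profiles,
       pc1_excess_p = (1 + sum(null_pc1 >= pc1 - 1e-12)) / (n_shuffles + 1),
       n_shuffles = n_shuffles)
}

#' Hierarchical-clustering subset scan
#'
#' Average-linkage hierarchical clustering on Euclidean distances of the
#' preprocessed data, evaluating cuts at k = 2..`max_k` by mean silhouette
#' width. A population of genuinely distinct subsets produces a cut with a
#' high silhouette; `subset_detected` flags a best silhouette above the
#' (configurable, conventional) 0.25 threshold.
#'
#' @param m an [expr_matrix()] with >= 4 cells.
#' @param genes gene symbols to use.
#' @param max_k largest number of clusters to evaluate (>= 2).
#' @param preprocessing passed to [preprocess_expression()].
#' @param detect_threshold silhouette level above which subsets are called.
#' @return list with `subset_score` (best mean silhouette), `best_k`,
#'   `silhouette_by_k`, `subset_detected`.
#' @export
subset_scan <- function(m, genes = gene_ids(m), max_k = 6,
                        preprocessing = c("log10p_zscore", "log10p", "raw"),
                        detect_threshold = 0.25) {
  preprocessing <- match.arg(preprocessing)
  if (max_k < 2) stop("max_k must be at least 2")
  if (nrow(m) < 4) stop("subset scan requires at least 4 cells")
  x <- preprocess_expression(m[, genes, drop = FALSE], preprocessing)
  d <- stats::dist(x)
  hc <- stats::hclust(d, method = "average")
  ks <- 2:min(max_k, nrow(m) - 1)
  sil <- vapply(ks, function(k) {
    cl <- stats::cutree(hc, k)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, numeric(1))
  best <- which.max(sil)
  list(subset_score = sil[best], best_k = ks[best],
       silhouette_by_k = stats::setNames(sil, ks),
       subset_detected = sil[best] > detect_threshold)
}
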