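#' Per-cell polarization state calls
#'
#' For each cell, records which panel genes exceed the chosen TPM tier
#' (strict `>`) and which distinct polarization classes those genes
#' represent. At the very-high tier (100) this is the basis for counting
#' cells that strongly co-express programs from multiple classes.
#'
#' @param m an [expr_matrix()].
#' @param panel a [marker_panel()]; at least one panel gene must be present
#'   in `m`.
#' @param tier TPM cut-off (strict `>`).
#' @return list of class `state_profiles`: per cell, a list with `cell_id`,
#'   `calls` (data.frame gene/class) and `classes_hit` (character).
#' @export
call_states <- function(m, panel, tier) {
  present <- panel[panel$gene %in% colnames(m), , drop = FALSE]
  if (!nrow(present)) stop("no panel genes present in the expression matrix")
  sub <- unclass(m)[, present$gene, drop = FALSE]
  hit <- sub > tier
  profiles <- lapply(seq_len(nrow(m)), function(i) {
    j <- which(hit[i, ])
    list(cell_id = rownames(m)[i],
         calls = data.frame(gene = present$gene[j], class = present$class[j],
                            stringsAsFactors = FALSE),
         classes_hit = unique(present$class[j]))
  })
  structure(profiles, class = "state_profiles", tier = tier)
}

#' Count cells hitting markers of multiple polarization classes
#'
#' Counts the profiled cells whose calls span at least `min_classes` distinct
#' polarization classes; e.g. at tier 100 with `min_classes = 2` this is the
#' fraction of cells very highly co-expressing at least two genes from
#' distinct programs.
#'
#' @param profiles result of [call_states()].
#' @param min_classes minimum number of distinct classes (>= 2).
#' @return list with `count`, `fraction`, `n_cells`, `min_classes`.
#' @export
count_multiclass_cells <- function(profiles, min_classes = 2) {
  if (min_classes < 2) stop("min_classes must be at least 2")
  n_hit <- vapply(profiles, function(p) length(p$classes_hit), integer(1))
  count <- sum(n_hit >= min_classes)
  list(count = count, fraction = count / length(profiles),
       n_cells = length(profiles), min_classes = min_classes)
}

# log odds ratio of a 2x2 table given n11 and fixed margins; Haldane-Anscombe
# +0.5 applied only when some cell is empty.
log_or_from_n11 <- function(n11, ka, kb, n) {
  n10 <- ka - n11
  n01 <- kb - n11
  n00 <- n - ka - kb + n11
  zero <- n11 == 0 | n10 == 0 | n01 == 0 | n00 == 0
  h <- ifelse(zero, 0.5, 0)
  log(((n11 + h) * (n00 + h)) / ((n10 + h) * (n01 + h)))
}

#' Cross-class co-occurrence with a within-gene permutation null
#'
#' For every unordered pair of panel genes from different polarization
#' classes, builds the 2x2 positivity contingency at the chosen tier
#' (strict `>`), computes the odds ratio (Haldane-Anscombe +0.5 correction
#' applied only when a cell of the table is zero), and compares the observed
#' |log OR| against a null in which each gene's values are independently
#' permuted across cells. This null preserves every gene's marginal
#' distribution exactly while destroying all cross-gene structure — the
#' operational meaning of "no more likely than at random". Two-sided testing
#' on |log OR| detects both mutual exclusivity (OR < 1, the admixture
#' signature) and excess co-occurrence.
#'
#' The permutation p-value is `(1 + b) / (n_perm + 1)` where `b` counts null
#' draws at least as extreme as observed, so it is never zero.
#'
#' @param m an [expr_matrix()].
#' @param panel a [marker_panel()] with genes from >= 2 classes present.
#' @param tier TPM cut-off; default is the high tier (10), the level at
#'   which positivity best separates active from inactive programs.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed for the permutation stream.
#' @param th a [pc_thresholds()] object (supplies the default tier).
#' @return data.frame with one row per across-class pair: contingency counts,
#'   `odds_ratio`, `log_or`, `perm_p`, `n_permutations`.
#' @export
cooccurrence_permutation <- function(m, panel, tier = NULL, n_perm = 999,
                                     seed = 1L, th = pc_thresholds()) {
  if (is.null(tier)) tier <- th$high_tpm
  if (n_perm < 99) stop("n_perm must be at least 99")
  present <- panel[panel$gene %in% colnames(m), , drop = FALSE]
  if (length(unique(present$class)) < 2) {
    stop("fewer than 2 polarization classes present in the matrix")
  }
  pairs <- panel_pairs(m, panel, "across_class")
  n <- nrow(m)
  B <- unclass(m)[, present$gene, drop = FALSE] > tier
  storage.mode(B) <- "double"
  k <- colSums(B)
  ia <- match(pairs$gene_a, present$gene)
  ib <- match(pairs$gene_b, present$gene)
  pair_idx <- cbind(ia, ib)

  n11_obs <- crossprod(B)[pair_idx]
  lor_obs <- log_or_from_n11(n11_obs, k[ia], k[ib], n)

  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(seed)
  exceed <- numeric(nrow(pairs))
  G <- ncol(B)
  for (r in seq_len(n_perm)) {
    Bp <- B
    for (g in seq_len(G)) Bp[, g] <- B[sample.int(n), g]
    n11_p <- crossprod(Bp)[pair_idx]
    lor_p <- log_or_from_n11(n11_p, k[ia], k[ib], n)
    exceed <- exceed + (abs(lor_p) >= abs(lor_obs) - 1e-12)
  }
  perm_p <- (1 + exceed) / (n_perm + 1)

  data.frame(gene_a = pairs$gene_a, class_a = pairs$class_a,
             gene_b = pairs$gene_b, class_b = pairs$class_b,
             n11 = n11_obs,
             n10 = k[ia] - n11_obs, n01 = k[ib] - n11_obs,
             n00 = n - k[ia] - k[ib] + n11_obs,
             odds_ratio = exp(lor_obs), log_or = lor_obs,
             perm_p = perm_p, n_permutations = n_perm, tier = tier,
             stringsAsFactors = FALSE)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Admixture vs mixed-state verdict
#'
#' Summarises a co-occurrence table into the study's central dichotomy. An
#' admixture of class-pure cells makes cross-class marker positivity mutually
#' exclusive (significant pairs with OR < 1 dominate); mixed-state cells make
#' cross-class positivity independent (almost no pair beats the null).
#'
#' Declaring "mixed-state-like" means asserting the significant fraction is
#' below `mixed_fraction`, which a handful of pairs cannot resolve: with fewer
#' than `1 / mixed_fraction` pairs the verdict falls back to
#' `"indeterminate"` rather than over-reading absence of evidence.
#'
#' @param results data.frame from [cooccurrence_permutation()].
#' @param sig_level per-pair significance level on the permutation p-value.
#' @param admixture_fraction verdict is `"admixture-like"` when the fraction
#'   of pairs significant with OR < 1 exceeds this.
#' @param mixed_fraction verdict is `"mixed-state-like"` when that fraction is
#'   below this; `"indeterminate"` in between.
#' @return list with `median_log_or`, `fraction_exclusive_significant`,
#'   `n_pairs`, `verdict`.
#' @export
admixture_vs_mixed_verdict <- function(results, sig_level = 0.05,
                                       admixture_fraction = 0.5,
                                       mixed_fraction = 0.1) {
  if (!nrow(results)) stop("no across-class pair results supplied")
  frac <- mean(results$perm_p < sig_level & results$odds_ratio < 1)
  verdict <- if (frac > admixture_fraction) "admixture-like"
             else if (frac < mixed_fraction && nrow(results) >= 1 / mixed_fraction)
               "mixed-state-like"
             else "indeterminate"
  list(median_log_or = stats::median(results$log_or),
       fraction_exclusive_significant = frac,
       n_pairs = nrow(results), verdict = verdict)
}
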