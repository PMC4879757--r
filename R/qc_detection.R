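#' Cell-level QC filter
#'
#' Keeps cells meeting both sequencing-quality criteria: at least
#' `min_aligned_reads` aligned reads and at least `min_mapped_fraction` of
#' reads mapped. The exclusion rule drops cells with *fewer than* the
#' cut-off, so boundary values (exactly 1e6 reads, exactly 0.5 mapped) pass.
#' Input order is preserved; filtering an already-filtered set is a no-op.
#'
#' @param qc a [cell_qc()] table.
#' @param th a [pc_thresholds()] object.
#' @return character vector of kept cell ids, in input order.
#' @export
filter_cells <- function(qc, th = pc_thresholds()) {
  if (!nrow(qc)) stop("QC table is empty")
  keep <- qc$aligned_reads >= th$min_aligned_reads &
    qc$mapped_fraction >= th$min_mapped_fraction
  qc$cell_id[keep]
}

#' Population-level gene detectability
#'
#' A gene is detectably expressed when its TPM exceeds the detectable tier
#' (strict `>`) in strictly more than `detectable_cell_fraction` of cells
#' (the conventional call is TPM > 0.1 in > 50% of cells).
#'
#' @param m an [expr_matrix()].
#' @param th a [pc_thresholds()] object.
#' @return character vector of detectable gene symbols.
#' @export
detectable_genes <- function(m, th = pc_thresholds()) {
  if (nrow(m) < 1) stop("matrix must contain at least one cell")
  frac <- colMeans(unclass(m) > th$detectable_tpm)
  colnames(m)[frac > th$detectable_cell_fraction]
}

#' Fraction of cells positive for a gene at a TPM tier
#'
#' Counts cells whose TPM for `gene` exceeds `threshold`. The comparison is
#' strict (`>`) for every tier except the high tier (TPM >= 10), which is
#' conventionally inclusive; `comparison` makes the choice explicit and
#' overrides the per-tier default.
#'
#' @param m an [expr_matrix()].
#' @param gene gene symbol (must be present).
#' @param threshold TPM cut-off.
#' @param comparison `">"` or `">="`; default picks `">="` exactly when
#'   `threshold == th$high_tpm`.
#' @param th a [pc_thresholds()] object (supplies the tier convention).
#' @return data.frame row with `gene`, `threshold`, `comparison`,
#'   `n_positive`, `fraction_positive`.
#' @export
positive_fraction <- function(m, gene, threshold,
                              comparison = NULL, th = pc_thresholds()) {
  v <- gene_values(m, gene)
  if (is.null(comparison)) {
    comparison <- if (isTRUE(threshold == th$high_tpm)) ">=" else ">"
  }
  comparison <- match.arg(comparison, c(">", ">="))
  n_pos <- if (comparison == ">") sum(v > threshold) else sum(v >= threshold)
  data.frame(gene = gene, threshold = threshold, comparison = comparison,
             n_positive = n_pos, fraction_positive = n_pos / length(v),
             stringsAsFactors = FALSE)
}

#' Positivity summary across all four TPM tiers
#'
#' Convenience wrapper applying [positive_fraction()] at the detectable,
#' positive, high and very-high tiers for each requested gene.
#'
#' @param m an [expr_matrix()].
#' @param genes gene symbols (default: all genes in `m`).
#' @param th a [pc_thresholds()] object.
#' @return data.frame with one row per gene x tier.
#' @export
detection_summary <- function(m, genes = gene_ids(m), th = pc_thresholds()) {
  tiers <- c(detectable = th$detectable_tpm, positive = th$positive_tpm,
             high = th$high_tpm, very_high = th$very_high_tpm)
  out <- lapply(genes, function(g) {
    rows <- lapply(seq_along(tiers), function(i) {
      r <- positive_fraction(m, g, tiers[[i]], th = th)
      r$tier <- names(tiers)[i]
      r
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  out[, c("gene", "tier", "threshold", "comparison", "n_positive", "fraction_positive")]
}

#' Association between marker dropout and read coverage
#'
#' Sanity check that zero expression of a gene is a biological/technical
#' dropout rather than a symptom of shallow sequencing: splits cells into
#' zero-TPM vs nonzero-TPM for the gene and compares their aligned read
#' counts with a two-sided Mann-Whitney U test ([mw_test()]). When either
#' group is empty no test is possible and `applicable` is `FALSE`.
#'
#' @param m an [expr_matrix()].
#' @param qc a [cell_qc()] table covering every cell in `m`.
#' @param gene gene symbol.
#' @return list with `gene`, `n_zero_cells`, `n_nonzero_cells`,
#'   `u_statistic`, `p_value`, `applicable`.
#' @export
coverage_association <- function(m, qc, gene) {
  v <- gene_values(m, gene)
  idx <- match(rownames(m), qc$cell_id)
  if (anyNA(idx)) {
    stop("cells missing from QC table: ",
         paste(rownames(m)[is.na(idx)], collapse = ", "))
  }
  reads <- qc$aligned_reads[idx]
  zero <- v == 0
  n0 <- sum(zero); n1 <- sum(!zero)
  if (n0 == 0 || n1 == 0) {
    return(list(gene = gene, n_zero_cells = n0, n_nonzero_cells = n1,
                u_statistic = NA_real_, p_value = NA_real_, applicable = FALSE))
  }
  t <- mw_test(reads[zero], reads[!zero])
  list(gene = gene, n_zero_cells = n0, n_nonzero_cells = n1,
       u_statistic = t$u_statistic, p_value = t$p_value, applicable = TRUE)
}
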