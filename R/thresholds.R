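#' Graded TPM and QC thresholds
#'
#' The analysis uses a fixed ladder of TPM cut-offs to grade expression —
#' detectable (0.1), positive (1), high (10), very high (100) — together with
#' the cell-level QC cut-offs on sequencing depth and mapping rate. All values
#' can be overridden, but the defaults are the ones used throughout the
#' pipeline.
#'
#' @param detectable_tpm TPM above which a gene counts as detectably expressed
#'   in a cell (strict `>`).
#' @param positive_tpm TPM above which a cell counts as positive for a gene.
#' @param high_tpm TPM at/above which expression counts as high (this tier is
#'   conventionally compared with `>=`, the others with `>`).
#' @param very_high_tpm TPM above which expression counts as very high; the
#'   tier used for strong cross-class co-expression calls.
#' @param detectable_cell_fraction fraction of cells that must exceed
#'   `detectable_tpm` (strict `>`) for a gene to be called detectable in the
#'   population.
#' @param min_aligned_reads minimum aligned read count for a cell to pass QC
#'   (cells with fewer are excluded, so the boundary passes).
#' @param min_mapped_fraction minimum mapped-read fraction for a cell to pass
#'   QC (boundary passes).
#'
#' @return A list of class `pc_thresholds`.
#' @export
#' @examples
#' th <- pc_thresholds()
#' th$very_high_tpm
pc_thresholds <- function(detectable_tpm = 0.1,
                          positive_tpm = 1,
                          high_tpm = 10,
                          very_high_tpm = 100,
                          detectable_cell_fraction = 0.5,
                          min_aligned_reads = 1e6,
                          min_mapped_fraction = 0.5) {
  th <- list(
    detectable_tpm = detectable_tpm,
    positive_tpm = positive_tpm,
    high_tpm = high_tpm,
    very_high_tpm = very_high_tpm,
    detectable_cell_fraction = detectable_cell_fraction,
    min_aligned_reads = min_aligned_reads,
    min_mapped_fraction = min_mapped_fraction
  )
  if (!all(vapply(th, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), logical(1)))) {
    stop("all thresholds must be finite numeric scalars")
  }
  if (!(detectable_tpm > 0 && detectable_tpm < positive_tpm &&
        positive_tpm < high_tpm && high_tpm < very_high_tpm)) {
    stop("TPM tiers must satisfy 0 < detectable < positive < high < very_high")
  }
  if (detectable_cell_fraction <= 0 || detectable_cell_fraction >= 1) {
    stop("detectable_cell_fraction must lie strictly between 0 and 1")
  }
  if (min_aligned_reads < 0 || min_mapped_fraction < 0 || min_mapped_fraction > 1) {
    stop("invalid QC cut-offs")
  }
  structure(th, class = "pc_thresholds")
}

#' @export
print.pc_thresholds <- function(x, ...) {
  cat("TPM tiers: detectable >", x$detectable_tpm,
      "| positive >", x$positive_tpm,
      "| high >=", x$high_tpm,
      "| very high >", x$very_high_tpm, "\n")
  cat("detectable in population: > ", x$detectable_cell_fraction * 100,
      "% of cells\n", sep = "")
  cat("cell QC: aligned reads >=", format(x$min_aligned_reads, big.mark = ","),
      "and mapped fraction >=", x$min_mapped_fraction, "\n")
  invisible(x)
}
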