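#' Pairwise marker coherence by linear regression
#'
#' Ordinary least squares of `gene_b` on `gene_a` across cells, reporting the
#' squared Pearson correlation (coefficient of determination). The default
#' operates on raw TPM; `scale = "log10p"` applies log10(TPM + 1) to both
#' genes first, which compresses the 4-5 orders of magnitude a marker can
#' span.
#'
#' @param m an [expr_matrix()].
#' @param gene_a,gene_b gene symbols (both present, >= 3 cells, nonzero
#'   variance in each).
#' @param scale `"linear"` (raw TPM, default) or `"log10p"`.
#' @return data.frame row with `gene_a`, `gene_b`, `r_squared`, `slope`,
#'   `intercept`, `n_cells`, `scale`.
#' @export
#' @examples
#' m <- expr_matrix(cbind(a = c(1, 2, 3), b = c(2, 4, 6)),
#'                  cell_ids = paste0("c", 1:3))
#' pair_regression(m, "a", "b")$r_squared  # 1
pair_regression <- function(m, gene_a, gene_b, scale = c("linear", "log10p")) {
  scale <- match.arg(scale)
  a <- gene_values(m, gene_a)
  b <- gene_values(m, gene_b)
  if (length(a) < 3) stop("pair regression requires at least 3 cells")
  if (scale == "log10p") {
    a <- log10(a + 1); b <- log10(b + 1)
  }
  for (g in list(c(gene_a, stats::var(a)), c(gene_b, stats::var(b)))) {
    if (as.numeric(g[2]) == 0) {
      stop("gene '", g[1], "' has zero variance; regression is degenerate")
    }
  }
  fit <- stats::lm.fit(cbind(1, a), b)
  r <- stats::cor(a, b)
  data.frame(gene_a = gene_a, gene_b = gene_b,
             r_squared = r^2,
             slope = unname(fit$coefficients[2]),
             intercept = unname(fit$coefficients[1]),
             n_cells = length(a), scale = scale,
             stringsAsFactors = FALSE)
}

#' Split cells by marker positivity
#'
#' Dichotomises cells on one gene the way the predictability analysis
#' requires: positive cells have TPM above the positive tier (> 1), negative
#' cells are at or below the detectable tier (<= 0.1), and cells falling in
#' the ambiguous band (0.1, 1] are excluded from both groups (the dichotomy
#' "expressing (TPM > 1)" vs "not expressing" leaves that band undefined, so
#' the split reports rather than mislabels it). The three sets partition the
#' cells.
#'
#' @param m an [expr_matrix()].
#' @param gene gene symbol.
#' @param th a [pc_thresholds()] object.
#' @return list of character vectors `positive`, `negative`, `excluded`.
#' @export
split_by_positivity <- function(m, gene, th = pc_thresholds()) {
  v <- gene_values(m, gene)
  list(positive = rownames(m)[v > th$positive_tpm],
       negative = rownames(m)[v <= th$detectable_tpm],
       excluded = rownames(m)[v > th$detectable_tpm & v <= th$positive_tpm])
}

#' Does positivity for one marker predict the level of another?
#'
#' Splits cells on the predictor with [split_by_positivity()] and compares
#' the response TPM between predictor-positive and predictor-negative cells
#' with a two-sided Mann-Whitney U test ([mw_test()]). Under coherent
#' polarization, positivity for a marker of one program should shift markers
#' of other programs; under incoherent (mixed-state) expression it does not.
#' When either group is empty the result is flagged not applicable instead of
#' erroring.
#'
#' @param m an [expr_matrix()].
#' @param predictor,response gene symbols.
#' @param th a [pc_thresholds()] object.
#' @return list with group sizes, group means of the response, `u_statistic`,
#'   `p_value`, `excluded_intermediate`, `applicable`.
#' @export
predictability_test <- function(m, predictor, response, th = pc_thresholds()) {
  sp <- split_by_positivity(m, predictor, th)
  resp <- gene_values(m, response)
  names(resp) <- rownames(m)
  pos <- resp[sp$positive]; neg <- resp[sp$negative]
  base <- list(predictor = predictor, response = response,
               n_positive = length(pos), n_negative = length(neg),
               excluded_intermediate = length(sp$excluded))
  if (!length(pos) || !length(neg)) {
    return(c(base, list(mean_response_positive = if (length(pos)) mean(pos) else NA_real_,
                        mean_response_negative = if (length(neg)) mean(neg) else NA_real_,
                        u_statistic = NA_real_, p_value = NA_real_,
                        applicable = FALSE)))
  }
  t <- mw_test(pos, neg)
  c(base, list(mean_response_positive = mean(pos),
               mean_response_negative = mean(neg),
               u_statistic = t$u_statistic, p_value = t$p_value,
               applicable = TRUE))
}

# Unordered pairs of panel genes present in the matrix, optionally restricted
# to within- or across-class pairs.
panel_pairs <- function(m, panel, pairs = c("all", "within_class", "across_class")) {
  pairs <- match.arg(pairs)
  present <- panel[panel$gene %in% colnames(m), , drop = FALSE]
  if (nrow(present) < 2) stop("need at least 2 panel genes present in the matrix")
  idx <- utils::combn(nrow(present), 2)
  out <- data.frame(gene_a = present$gene[idx[1, ]],
                    class_a = present$class[idx[1, ]],
                    gene_b = present$gene[idx[2, ]],
                    class_b = present$class[idx[2, ]],
                    stringsAsFactors = FALSE)
  if (pairs == "within_class") out <- out[out$class_a == out$class_b, , drop = FALSE]
  if (pairs == "across_class") out <- out[out$class_a != out$class_b, , drop = FALSE]
  out
}

#' Regression screen over panel gene pairs
#'
#' Runs [pair_regression()] over every requested unordered pair of panel
#' genes present in the matrix, annotated with class labels. Degenerate pairs
#' (a zero-variance gene) are skipped with a message rather than aborting the
#' screen. Optional Benjamini-Hochberg adjustment is available for the
#' regression slope p-values when `adjust = TRUE` (the primary readout is
#' r-squared, reported raw).
#'
#' @param m an [expr_matrix()].
#' @param panel a [marker_panel()].
#' @param pairs `"within_class"`, `"across_class"`, or `"all"`.
#' @param scale passed to [pair_regression()].
#' @return data.frame with one row per non-degenerate pair.
#' @export
coherence_screen <- function(m, panel, pairs = c("all", "within_class", "across_class"),
                             scale = c("linear", "log10p")) {
  pairs <- match.arg(pairs)
  scale <- match.arg(scale)
  tab <- panel_pairs(m, panel, pairs)
  if (pairs != "across_class" && !nrow(tab)) stop("no valid gene pairs to screen")
  rows <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    r <- tryCatch(pair_regression(m, tab$gene_a[i], tab$gene_b[i], scale),
                  error = function(e) {
                    message("skipping ", tab$gene_a[i], ":", tab$gene_b[i], " - ",
                            conditionMessage(e))
                    NULL
                  })
    if (!is.null(r)) {
      r$class_a <- tab$class_a[i]
      r$class_b <- tab$class_b[i]
      rows[[i]] <- r
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    if (pairs == "across_class" && !nrow(tab)) {
      return(data.frame(gene_a = character(), class_a = character(),
                        gene_b = character(), class_b = character(),
                        r_squared = numeric(), slope = numeric(),
                        intercept = numeric(), n_cells = integer(),
                        scale = character(), stringsAsFactors = FALSE))
    }
    stop("no valid gene pairs to screen")
  }
  out <- do.call(rbind, rows)
  out[, c("gene_a", "class_a", "gene_b", "class_b", "r_squared",
          "slope", "intercept", "n_cells", "scale")]
}
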