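#' Cells-by-genes TPM expression matrix
#'
#' Thin validated wrapper around a base numeric matrix with cells in rows and
#' genes in columns. Values are TPM (transcripts per million): non-negative,
#' no missing entries, unique cell and gene identifiers.
#'
#' @param values numeric matrix, one row per cell, one column per gene.
#' @param cell_ids character vector of unique cell identifiers (defaults to
#'   existing rownames).
#' @param gene_ids character vector of unique gene symbols (defaults to
#'   existing colnames).
#'
#' @return A matrix of class `expr_matrix` with `cell_ids` as rownames and
#'   `gene_ids` as colnames.
#' @export
#' @examples
#' m <- expr_matrix(matrix(c(0, 5, 1, 120), 2, 2),
#'                  cell_ids = c("c1", "c2"), gene_ids = c("Arg1", "Tnf"))
#' n_cells(m)
expr_matrix <- function(values, cell_ids = rownames(values), gene_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (is.null(cell_ids) || is.null(gene_ids)) {
    stop("cell_ids and gene_ids are required (or set as dimnames)")
  }
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values)) {
    stop("length of cell_ids (", length(cell_ids), ") does not match row count (",
         nrow(values), ")")
  }
  if (length(gene_ids) != ncol(values)) {
    stop("length of gene_ids (", length(gene_ids), ") does not match column count (",
         ncol(values), ")")
  }
  if (anyDuplicated(cell_ids)) stop("duplicate cell identifiers")
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  if (anyNA(values)) stop("missing values are not allowed")
  if (any(values < 0)) stop("negative TPM values are not allowed")
  dimnames(values) <- list(cell_ids, gene_ids)
  class(values) <- c("expr_matrix", class(values))
  values
}

#' @rdname expr_matrix
#' @param m an `expr_matrix`.
#' @export
n_cells <- function(m) nrow(m)

#' @rdname expr_matrix
#' @export
n_genes <- function(m) ncol(m)

#' @rdname expr_matrix
#' @export
cell_ids <- function(m) rownames(m)

#' @rdname expr_matrix
#' @export
gene_ids <- function(m) colnames(m)

# Extract one gene's TPM vector; absence of a requested gene is a data
# defect, never an implicit zero.
gene_values <- function(m, gene) {
  stopifnot(length(gene) == 1)
  if (!gene %in% colnames(m)) {
    stop("gene '", gene, "' is not present in the expression matrix")
  }
  m[, gene]
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix: ", nrow(x), " cells x ", ncol(x), " genes (TPM)\n", sep = "")
  cat("TPM range: [", format(min(x)), ", ", format(max(x)), "], ",
      round(100 * mean(x == 0), 1), "% exact zeros\n", sep = "")
  invisible(x)
}
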