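#' Read and write expression matrices, marker panels and QC tables
#'
#' Two on-disk matrix layouts are supported. The dense TSV has cells in rows:
#' first column `cell_id`, remaining columns gene symbols. The sparse
#' MatrixMarket layout follows the single-cell community convention of genes
#' in rows and cells in columns, with `genes.tsv` / `barcodes.tsv` name
#' sidecars next to the `.mtx` file; it is transposed to cells-by-genes on
#' load. Both writers format numbers with 17 significant digits so that a
#' write/read round trip reproduces the doubles bit for bit.
#'
#' @param path for TSV, the file; for MTX, the `.mtx` file (sidecars are
#'   looked up in its directory).
#' @param format `"tsv"` or `"mtx"`.
#' @return [read_expression_matrix()] returns an [expr_matrix()].
#' @seealso [read_marker_panel()], [read_qc_table()]
#' @export
read_expression_matrix <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2 || names(tab)[1] != "cell_id") {
      stop("expression TSV must have a leading 'cell_id' column and >= 1 gene column")
    }
    vals <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(vals)) stop("non-numeric expression values in ", path)
    expr_matrix(vals, cell_ids = tab$cell_id, gene_ids = names(tab)[-1])
  } else {
    dir <- dirname(path)
    genes_file <- file.path(dir, "genes.tsv")
    cells_file <- file.path(dir, "barcodes.tsv")
    for (f in c(genes_file, cells_file)) {
      if (!file.exists(f)) stop("missing MTX sidecar file: ", f)
    }
    mm <- Matrix::readMM(path)  # genes x cells on disk
    genes <- readLines(genes_file)
    cells <- readLines(cells_file)
    if (nrow(mm) != length(genes)) {
      stop("MTX declares ", nrow(mm), " genes but genes.tsv lists ", length(genes))
    }
    if (ncol(mm) != length(cells)) {
      stop("MTX declares ", ncol(mm), " cells but barcodes.tsv lists ", length(cells))
    }
    expr_matrix(t(as.matrix(mm)), cell_ids = cells, gene_ids = genes)
  }
}

#' @rdname read_expression_matrix
#' @param m an [expr_matrix()].
#' @export
write_expression_matrix <- function(m, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("cell_id", colnames(m)), collapse = "\t"), con)
    for (i in seq_len(nrow(m))) {
      writeLines(paste(c(rownames(m)[i], fmt_full(m[i, ])), collapse = "\t"), con)
    }
  } else {
    # genes x cells coordinate MatrixMarket, full-precision values
    dir <- dirname(path)
    tm <- t(unclass(m))
    nz <- which(tm != 0)
    con <- file(path, "w")
    writeLines("%%MatrixMarket matrix coordinate real general", con)
    writeLines(paste(nrow(tm), ncol(tm), length(nz)), con)
    if (length(nz)) {
      ij <- arrayInd(nz, dim(tm))
      writeLines(paste(ij[, 1], ij[, 2], fmt_full(tm[nz])), con)
    }
    close(con)
    writeLines(rownames(tm), file.path(dir, "genes.tsv"))
    writeLines(colnames(tm), file.path(dir, "barcodes.tsv"))
  }
  invisible(path)
}

fmt_full <- function(x) sprintf("%.17g", x)

#' Polarization classes recognised by the pipeline
#'
#' Macrophage activation programs named by their prototypical in vitro
#' stimulus: alternative/wound-healing M(IL4), classical/inflammatory
#' M(LPS,IFNg), regulatory M(IL10), and immune-complex M(IC).
#' @export
POLARIZATION_CLASSES <- c("M(IL4)", "M(LPS,IFNg)", "M(IL10)", "M(IC)")

#' Read a marker panel
#'
#' A panel maps gene symbols to polarization classes. The file is a TSV with
#' header `gene<TAB>class<TAB>consensus` (`consensus` in \{0,1\} flags
#' membership in the smaller consensus marker set; it is carried as metadata).
#' Gene symbols are matched case-sensitively downstream.
#'
#' @param path TSV file.
#' @return data.frame of class `marker_panel` with columns `gene`, `class`,
#'   `consensus`.
#' @export
read_marker_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "class")
  if (!all(need %in% names(tab))) {
    stop("marker panel must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(tab$consensus)) tab$consensus <- 0L
  marker_panel(tab$gene, tab$class, tab$consensus)
}

#' @rdname read_marker_panel
#' @param gene,class,consensus vectors defining the panel directly.
#' @export
marker_panel <- function(gene, class, consensus = 0L) {
  gene <- as.character(gene)
  class <- as.character(class)
  if (anyDuplicated(gene)) {
    stop("duplicated gene in marker panel: ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "))
  }
  bad <- setdiff(unique(class), POLARIZATION_CLASSES)
  if (length(bad)) {
    stop("unknown polarization class label: ", paste(bad, collapse = ", "),
         " (expected one of ", paste(POLARIZATION_CLASSES, collapse = ", "), ")")
  }
  out <- data.frame(gene = gene, class = class,
                    consensus = as.integer(consensus),
                    stringsAsFactors = FALSE)
  if (!all(out$consensus %in% c(0L, 1L))) stop("consensus flag must be 0 or 1")
  structure(out, class = c("marker_panel", "data.frame"))
}

#' @rdname read_marker_panel
#' @export
default_marker_panel <- function() {
  read_marker_panel(system.file("extdata", "marker_panel.tsv",
                                package = "polcoherence", mustWork = TRUE))
}

#' @rdname read_marker_panel
#' @param panel a `marker_panel`.
#' @export
write_marker_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-cell QC metrics table
#'
#' TSV with columns `cell_id`, `aligned_reads`, `mapped_fraction`; one row
#' per sequenced cell library. These metrics come from the alignment step and
#' are inputs to the pipeline, never computed by it.
#'
#' @param path TSV file.
#' @return data.frame of class `cell_qc` with one validated record per cell.
#' @export
read_qc_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "aligned_reads", "mapped_fraction")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("QC table missing column(s): ", paste(miss, collapse = ", "))
  cell_qc(tab$cell_id, tab$aligned_reads, tab$mapped_fraction)
}

#' @rdname read_qc_table
#' @param cell_id,aligned_reads,mapped_fraction vectors defining records directly.
#' @export
cell_qc <- function(cell_id, aligned_reads, mapped_fraction) {
  cell_id <- as.character(cell_id)
  if (anyDuplicated(cell_id)) stop("duplicated cell_id in QC table")
  if (anyNA(aligned_reads) || any(aligned_reads < 0)) {
    stop("aligned_reads must be non-negative")
  }
  if (anyNA(mapped_fraction) || any(mapped_fraction < 0) || any(mapped_fraction > 1)) {
    stop("mapped_fraction must lie in [0, 1]")
  }
  structure(data.frame(cell_id = cell_id,
                       aligned_reads = as.numeric(aligned_reads),
                       mapped_fraction = as.numeric(mapped_fraction),
                       stringsAsFactors = FALSE),
            class = c("cell_qc", "data.frame"))
}

#' @rdname read_qc_table
#' @param qc a `cell_qc` table.
#' @export
write_qc_table <- function(qc, path) {
  utils::write.table(as.data.frame(qc), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
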