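# Small in-code fixtures shared across the suite.

toy_matrix <- function(values, cells = NULL, genes = NULL) {
  values <- as.matrix(values)
  if (is.null(cells)) cells <- rownames(values)
  if (is.null(genes)) genes <- colnames(values)
  if (is.null(cells)) cells <- sprintf("c%d", seq_len(nrow(values)))
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(ncol(values)))
  expr_matrix(values, cell_ids = cells, gene_ids = genes)
}

# two-class toy panel
toy_panel <- function() {
  marker_panel(gene = c("Arg1", "Mrc1", "Tnf", "Il1b"),
               class = c("M(IL4)", "M(IL4)", "M(LPS,IFNg)", "M(LPS,IFNg)"))
}

random_matrix <- function(n_cells, n_genes, seed) {
  set.seed(seed)
  vals <- matrix(stats::rlnorm(n_cells * n_genes, 1, 2), n_cells, n_genes)
  vals[stats::runif(length(vals)) < 0.2] <- 0
  toy_matrix(vals)
}
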