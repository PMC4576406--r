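# small deterministic fixtures used across test files

make_counts <- function(counts, genes = NULL, cells = NULL, ...) {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(counts)))
  if (is.null(cells)) cells <- paste0("c", seq_len(ncol(counts)))
  dimnames(counts) <- list(genes, cells)
  storage.mode(counts) <- "integer"
  count_matrix(counts, ...)
}

# matrix with planted spike-ins and mito rows, Poisson counts
make_sim_matrix <- function(n_genes = 50, n_cells = 20, n_spike = 10,
                            n_mito = 3, mean_count = 50, seed = 1) {
  withr::with_seed(seed, {
    counts <- matrix(rpois(n_genes * n_cells, mean_count), n_genes, n_cells)
    genes <- c(sprintf("gene%d", seq_len(n_genes - n_spike - n_mito)),
               sprintf("mt-%d", seq_len(n_mito)),
               sprintf("ERCC-%05d", seq_len(n_spike)))
    dimnames(counts) <- list(genes, paste0("cell", seq_len(n_cells)))
    storage.mode(counts) <- "integer"
    count_matrix(counts,
                 is_mito = startsWith(genes, "mt-"))
  })
}

# small normalized-scale expression matrix for embedding tests
make_expr <- function(mat, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(mat)))
  if (is.null(cells)) cells <- paste0("c", seq_len(ncol(mat)))
  dimnames(mat) <- list(genes, cells)
  mat
}
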