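#' Construct a validated gene-by-cell count matrix
#'
#' The canonical container for a single-cell experiment: an integer matrix
#' with genes as rows and cells as columns, plus per-gene flags marking ERCC
#' spike-in rows and mitochondrially encoded genes. All downstream steps
#' (QC, normalization, variable-gene testing, embeddings) consume this
#' object. Orientation is always genes x cells.
#'
#' @param counts Integer matrix (genes x cells) with unique rownames (gene
#'   ids) and colnames (cell ids). All entries must be finite, whole and
#'   non-negative.
#' @param is_spikein Logical vector, one entry per gene, marking spike-in
#'   rows. Defaults to ids starting with `spikein_prefix`.
#' @param is_mito Logical vector, one entry per gene, marking mitochondrial
#'   genes. Defaults to all `FALSE`.
#' @param spikein_prefix Gene-id prefix used to auto-flag spike-in rows when
#'   `is_spikein` is not given (default `"ERCC-"`).
#'
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `is_spikein`, `is_mito`.
#' @export
#'
#' @examples
#' m <- count_matrix(matrix(c(0:3, 10L, 20L), nrow = 3, byrow = TRUE,
#'   dimnames = list(c("Kit", "Ly6a", "ERCC-00001"), c("c1", "c2"))))
#' m$is_spikein
count_matrix <- function(counts, is_spikein = NULL, is_mito = NULL,
                         spikein_prefix = "ERCC-") {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (nrow(counts) == 0L) stop("no genes: count matrix has zero rows")
  if (ncol(counts) == 0L) stop("no cells: count matrix has zero columns")
  gene_ids <- rownames(counts)
  cell_ids <- colnames(counts)
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("counts must carry gene ids as rownames and cell ids as colnames")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(cell_ids)) {
    stop("duplicate cell ids: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(counts))
    stop(sprintf(
      "counts must be finite non-negative integers; offending value %s at gene '%s', cell '%s'",
      format(counts[bad[1]]), gene_ids[i[1]], cell_ids[i[2]]))
  }
  storage.mode(counts) <- "integer"
  if (is.null(is_spikein)) is_spikein <- startsWith(gene_ids, spikein_prefix)
  if (is.null(is_mito)) is_mito <- rep(FALSE, length(gene_ids))
  stopifnot(length(is_spikein) == nrow(counts),
            length(is_mito) == nrow(counts))
  is_spikein <- as.logical(is_spikein)
  is_mito <- as.logical(is_mito)
  if (all(is_spikein)) stop("at least one non-spike-in gene is required")
  if (any(is_spikein & is_mito)) {
    stop("spike-in and mitochondrial flags must be disjoint")
  }
  structure(
    list(counts = counts, is_spikein = is_spikein, is_mito = is_mito),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "<count_matrix> %d genes x %d cells (%d spike-ins, %d mitochondrial)\n",
    nrow(x$counts), ncol(x$counts), sum(x$is_spikein), sum(x$is_mito)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Gene and cell identifiers of a count matrix
#' @param m A [count_matrix()].
#' @return Character vector of ids.
#' @export
gene_ids <- function(m) rownames(m$counts)

#' @rdname gene_ids
#' @export
cell_ids <- function(m) colnames(m$counts)

#' Subset a count matrix by cells and/or genes
#'
#' @param m A [count_matrix()].
#' @param cells,genes Character vectors of ids to keep (default: all).
#' @return A `count_matrix` restricted to the requested ids, in the
#'   requested order.
#' @export
subset_cells <- function(m, cells = cell_ids(m), genes = gene_ids(m)) {
  missing_c <- setdiff(cells, cell_ids(m))
  missing_g <- setdiff(genes, gene_ids(m))
  if (length(missing_c)) stop("unknown cell ids: ",
                              paste(utils::head(missing_c, 5), collapse = ", "))
  if (length(missing_g)) stop("unknown gene ids: ",
                              paste(utils::head(missing_g, 5), collapse = ", "))
  gi <- match(genes, gene_ids(m))
  count_matrix(m$counts[gi, cells, drop = FALSE],
               is_spikein = m$is_spikein[gi], is_mito = m$is_mito[gi])
}

#' Split a count matrix into biological and spike-in parts
#'
#' @param m A [count_matrix()].
#' @return Integer matrix of the biological (non-spike-in) or spike-in rows.
#' @export
biological_counts <- function(m) {
  m$counts[!m$is_spikein, , drop = FALSE]
}

#' @rdname biological_counts
#' @export
spikein_counts <- function(m) {
  m$counts[m$is_spikein, , drop = FALSE]
}

#' Tidy a count matrix into long format
#'
#' @param x A [count_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per (gene, cell) pair and columns
#'   `gene_id`, `cell_id`, `count`, `is_spikein`, `is_mito`.
#' @export
tidy.count_matrix <- function(x, ...) {
  tibble::tibble(
    gene_id = rep(gene_ids(x), times = ncol(x$counts)),
    cell_id = rep(cell_ids(x), each = nrow(x$counts)),
    count = as.vector(x$counts),
    is_spikein = rep(x$is_spikein, times = ncol(x$counts)),
    is_mito = rep(x$is_mito, times = ncol(x$counts)))
}

#' Per-cell metadata table
#'
#' Validates a tibble of per-cell annotations: experimental group (e.g.
#' genotype), read count over a screened deletion region (used to detect
#' incomplete knockout cells), and the microscopy capture flag for the
#' microfluidic capture site.
#'
#' @param cell_id Character vector of unique cell ids.
#' @param group Per-cell group label (genotype / dataset); recycled.
#' @param deletion_region_count Non-negative integer count of reads in the
#'   screened deletion region, or `NA` when not assayed.
#' @param capture_flag One of `"single"`, `"empty"`, `"multiplet"`,
#'   `"anomalous"`, `"unknown"`; recycled.
#' @return A tibble of class `cell_metadata`.
#' @export
cell_metadata <- function(cell_id, group = "all",
                          deletion_region_count = NA_integer_,
                          capture_flag = "single") {
  if (anyDuplicated(cell_id)) stop("duplicate cell ids in metadata")
  flags <- c("single", "empty", "multiplet", "anomalous", "unknown")
  out <- tibble::tibble(
    cell_id = as.character(cell_id),
    group = as.character(group),
    deletion_region_count = as.integer(deletion_region_count),
    capture_flag = as.character(capture_flag))
  if (!all(out$capture_flag %in% flags)) {
    stop("capture_flag must be one of: ", paste(flags, collapse = ", "))
  }
  bad <- !is.na(out$deletion_region_count) & out$deletion_region_count < 0
  if (any(bad)) stop("deletion_region_count must be >= 0 when present")
  class(out) <- c("cell_metadata", class(out))
  out
}
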