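#' Read a gene-by-cell count matrix from disk
#'
#' Two plain-text layouts are supported: a dense TSV whose header row holds
#' cell ids and whose first column holds gene ids, and MatrixMarket
#' coordinate (triplet) format accompanied by `<stem>.genes.txt` and
#' `<stem>.cells.txt` sidecar files listing the row and column ids.
#'
#' Spike-in rows are auto-flagged by id prefix; mitochondrial genes are
#' flagged through an optional gene annotation mapping gene id to
#' chromosome, since the matrix itself carries no positional information.
#'
#' @param path Path to the TSV or `.mtx` file.
#' @param format `"tsv"` or `"mtx"`; guessed from the file extension by
#'   default.
#' @param spikein_prefix Id prefix marking spike-in rows (default
#'   `"ERCC-"`).
#' @param gene_annotation Optional data frame (or path to a TSV) with
#'   columns `gene_id` and `chromosome`; genes on a mitochondrial
#'   chromosome (`MT`, `chrM`, `mt`, `M`) are flagged.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, format = c("auto", "tsv", "mtx"),
                              spikein_prefix = "ERCC-",
                              gene_annotation = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (format == "tsv") {
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (nrow(tab) == 0L) stop("no genes: ", path, " has no data rows")
    genes <- as.character(tab[[1]])
    mat <- as.matrix(tab[, -1, drop = FALSE])
    rownames(mat) <- genes
  } else {
    stem <- sub("\\.mtx$", "", path)
    genes_path <- paste0(stem, ".genes.txt")
    cells_path <- paste0(stem, ".cells.txt")
    if (!file.exists(genes_path) || !file.exists(cells_path)) {
      stop("MatrixMarket input needs sidecar files ", genes_path,
           " and ", cells_path)
    }
    sp <- Matrix::readMM(path)
    genes <- readLines(genes_path)
    cells <- readLines(cells_path)
    if (nrow(sp) != length(genes) || ncol(sp) != length(cells)) {
      stop("sidecar id counts do not match matrix dimensions")
    }
    mat <- as.matrix(sp)
    dimnames(mat) <- list(genes, cells)
  }
  mito <- NULL
  if (!is.null(gene_annotation)) {
    if (is.character(gene_annotation)) {
      gene_annotation <- utils::read.delim(gene_annotation,
                                           stringsAsFactors = FALSE)
    }
    stopifnot(all(c("gene_id", "chromosome") %in% names(gene_annotation)))
    mito_genes <- gene_annotation$gene_id[
      gene_annotation$chromosome %in% c("MT", "chrM", "mt", "M")]
    mito <- rownames(mat) %in% mito_genes
  }
  count_matrix(mat, is_mito = mito, spikein_prefix = spikein_prefix)
}

#' Write a count matrix to disk
#'
#' @param m A [count_matrix()].
#' @param path Output path; a `.mtx` extension selects MatrixMarket triplet
#'   format with id sidecars, anything else a dense TSV.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path) {
  if (grepl("\\.mtx$", path)) {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(m$counts, sparse = TRUE), path)
    writeLines(gene_ids(m), paste0(stem, ".genes.txt"))
    writeLines(cell_ids(m), paste0(stem, ".cells.txt"))
  } else {
    tab <- data.frame(gene_id = gene_ids(m), m$counts, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each GMT line holds a set name, a description and then the member gene
#' ids, all tab-separated. Member order is preserved; duplicated members
#' within one set are dropped with a warning.
#'
#' @param path Path to a GMT file.
#' @return A [gene_sets()] collection.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short)) {
    stop("GMT line ", short[1], " has fewer than 3 tab-separated fields")
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name: ", nm[duplicated(nm)][1])
  }
  members <- lapply(seq_along(fields), function(i) {
    g <- fields[[i]][-(1:2)]
    g <- g[nzchar(g)]
    if (anyDuplicated(g)) {
      warning("set '", nm[i], "': duplicated members de-duplicated")
      g <- unique(g)
    }
    g
  })
  names(members) <- nm
  gene_sets(members, vapply(fields, `[[`, "", 2L))
}

#' Construct a named collection of gene sets
#'
#' @param sets Named list of character vectors (gene ids).
#' @param descriptions Optional character vector of per-set descriptions.
#' @return A named list of class `gene_set_collection` with a
#'   `descriptions` attribute.
#' @export
gene_sets <- function(sets, descriptions = rep("", length(sets))) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("every gene set must be named")
  }
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names")
  if (any(lengths(sets) == 0L)) {
    stop("empty gene set: ", names(sets)[lengths(sets) == 0L][1])
  }
  sets <- lapply(sets, as.character)
  structure(sets, descriptions = stats::setNames(descriptions, names(sets)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets (sizes %d-%d)\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' Write a gene-set collection as GMT
#'
#' @param sets A [gene_sets()] collection.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Floating-point columns are serialized at a fixed number of significant
#' digits (default 6) so that a write/read cycle is lossless at that
#' precision; `NaN`/`NA` become the literal `NA`. A provenance note, when
#' attached to the table as attribute `"provenance"` (or passed directly),
#' is written as a leading `#` comment line.
#'
#' @param table A data frame.
#' @param path Output path.
#' @param digits Significant digits for numeric columns (default 6).
#' @param provenance Optional one-line provenance note.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, digits = 6,
                          provenance = attr(table, "provenance")) {
  stopifnot(is.data.frame(table))
  out <- as.data.frame(table)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], digits)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path Path to the TSV.
#' @return A tibble; a leading `#` comment line is restored as the
#'   `"provenance"` attribute.
#' @export
read_results <- function(path) {
  first <- readLines(path, n = 1)
  prov <- NULL
  if (startsWith(first, "# ")) prov <- sub("^# ", "", first)
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  tab <- tibble::as_tibble(tab)
  attr(tab, "provenance") <- prov
  tab
}
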