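#' Median-of-ratios size factors
#'
#' Computes per-cell size factors with the DESeq median-of-ratios
#' estimator, separately for biological genes and for spike-in rows: for
#' cell j, `s_j = median_i k_ij / g_i`, where `g_i` is the geometric mean
#' of gene i across cells and the median runs over genes whose counts are
#' positive in every cell (so the geometric mean is positive). No post-hoc
#' rescaling is applied. Spike-in factors track pipetting/capture
#' efficiency rather than cellular RNA content, which is why the two kinds
#' are kept apart.
#'
#' @param m A [count_matrix()].
#' @param rows Which rows to estimate from: `"biological"` (default) or
#'   `"spikein"`.
#' @return A named positive numeric vector of per-cell factors, classed
#'   `size_factor_vec`.
#' @export
#'
#' @examples
#' counts <- matrix(c(2L, 4L, 2L, 4L, 8L, 16L), nrow = 3, byrow = TRUE,
#'   dimnames = list(c("a", "b", "c"), c("c1", "c2")))
#' median_ratio_size_factors(count_matrix(counts))
median_ratio_size_factors <- function(m, rows = c("biological", "spikein")) {
  rows <- match.arg(rows)
  k <- if (rows == "biological") biological_counts(m) else spikein_counts(m)
  if (nrow(k) == 0L) stop("no ", rows, " rows in matrix")
  usable <- rowSums(k > 0) == ncol(k)
  if (!any(usable)) {
    stop("no ", rows, " gene has positive counts in every cell; ",
         "median-of-ratios reference is empty (a pseudo-reference ",
         "fallback must be requested explicitly, it is not applied silently)")
  }
  k <- k[usable, , drop = FALSE]
  log_gm <- rowMeans(log(k))
  sf <- apply(k, 2, function(col) exp(stats::median(log(col) - log_gm)))
  structure(sf, class = "size_factor_vec")
}

#' Size factors for biological genes and spike-ins
#'
#' Convenience wrapper computing both [median_ratio_size_factors()]
#' components of a count matrix.
#'
#' @param m A [count_matrix()].
#' @return A list of class `size_factors` with elements `cell` (biological
#'   rows) and `spikein` (spike-in rows; `NULL` when the matrix has none),
#'   both named by cell id.
#' @export
size_factors <- function(m) {
  sf <- list(cell = unclass(median_ratio_size_factors(m, "biological")),
             spikein = NULL)
  if (any(m$is_spikein)) {
    sf$spikein <- unclass(median_ratio_size_factors(m, "spikein"))
  }
  structure(sf, class = "size_factors")
}

#' @export
print.size_factors <- function(x, ...) {
  cat(sprintf("<size_factors> %d cells; spike-in factors: %s\n",
              length(x$cell), if (is.null(x$spikein)) "absent" else "present"))
  invisible(x)
}

#' @export
tidy.size_factors <- function(x, ...) {
  out <- tibble::tibble(cell_id = names(x$cell), size_factor = unname(x$cell))
  if (!is.null(x$spikein)) {
    out$size_factor_spikein <- unname(x$spikein[out$cell_id])
  }
  out
}

#' Normalize a count matrix by size factors
#'
#' Divides every cell's counts by its size factor: biological rows by the
#' cell factor, spike-in rows by the spike-in factor (falling back to the
#' cell factor when no spike-in factors exist).
#'
#' @param m A [count_matrix()].
#' @param sf A [size_factors()] object (or a named per-cell numeric vector
#'   applied to all rows).
#' @return A real-valued matrix with the same dimensions and dimnames as
#'   the counts.
#' @export
normalize_counts <- function(m, sf = size_factors(m)) {
  if (is.numeric(sf)) sf <- structure(list(cell = sf, spikein = NULL),
                                      class = "size_factors")
  cells <- cell_ids(m)
  if (!all(cells %in% names(sf$cell))) {
    stop("size factors missing for some cells: ",
         paste(utils::head(setdiff(cells, names(sf$cell)), 5), collapse = ", "))
  }
  div <- matrix(rep(sf$cell[cells], each = nrow(m$counts)),
                nrow = nrow(m$counts))
  if (any(m$is_spikein) && !is.null(sf$spikein)) {
    if (!all(cells %in% names(sf$spikein))) {
      stop("spike-in size factors missing for some cells")
    }
    div[m$is_spikein, ] <- rep(sf$spikein[cells],
                               each = sum(m$is_spikein))
  }
  out <- m$counts / div
  dimnames(out) <- dimnames(m$counts)
  out
}

#' Genes detected per cell at a normalized-count threshold
#'
#' The per-cell number of biological genes whose normalized count exceeds
#' a threshold (default 1) -- the depth-robust detection statistic used to
#' compare datasets sequenced to different depths.
#'
#' @param norm Normalized matrix from [normalize_counts()].
#' @param m The [count_matrix()] the normalization came from (for spike-in
#'   flags); omit to count all rows.
#' @param threshold Detection threshold on the normalized scale.
#' @return A tibble with columns `cell_id`, `genes_detected_norm`.
#' @export
genes_detected_normalized <- function(norm, m = NULL, threshold = 1) {
  if (!is.null(m)) norm <- norm[!m$is_spikein, , drop = FALSE]
  tibble::tibble(cell_id = colnames(norm),
                 genes_detected_norm = unname(colSums(norm > threshold)))
}
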