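#' Quality-control thresholds
#'
#' Cell-level filters applied to single-cell libraries: minimum total
#' counts in annotated (non-spike-in) genes, minimum number of genes with
#' any count, maximum fraction of counts on mitochondrially encoded genes,
#' and -- for groups subject to the deletion screen -- the maximum
#' tolerated read count over the screened deletion region. Count and gene
#' thresholds are strict (`< min` removes), the mitochondrial threshold is
#' strict the other way (`> max` removes), matching the conventions
#' "less than 500,000 counts", "less than 3000 genes", ">10 %".
#'
#' @param min_total_counts Minimum total counts (default 500000).
#' @param min_genes_detected Minimum genes with count > 0 (default 3000).
#' @param max_mito_fraction Maximum mitochondrial fraction (default 0.10).
#' @param deletion_region_max Maximum deletion-region reads for screened
#'   groups (default 0).
#' @param outlier_mad_k MAD multiplier for the PCA outlier screen
#'   (default 6).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_total_counts = 500000,
                          min_genes_detected = 3000,
                          max_mito_fraction = 0.10,
                          deletion_region_max = 0,
                          outlier_mad_k = 6) {
  stopifnot(min_total_counts >= 0, min_genes_detected >= 0,
            max_mito_fraction >= 0, max_mito_fraction <= 1,
            deletion_region_max >= 0, outlier_mad_k >= 0)
  structure(list(min_total_counts = min_total_counts,
                 min_genes_detected = min_genes_detected,
                 max_mito_fraction = max_mito_fraction,
                 deletion_region_max = deletion_region_max,
                 outlier_mad_k = outlier_mad_k),
            class = "qc_thresholds")
}

#' Per-cell quality-control metrics
#'
#' Computes, over non-spike-in genes only: total counts, number of genes
#' detected (raw count > 0) and the mitochondrial fraction (mitochondrial
#' counts / total non-spike-in counts; `NA` when the matrix carries no
#' mitochondrial flags). Metadata columns (group, deletion-region count,
#' capture flag) are joined when provided.
#'
#' @param m A [count_matrix()].
#' @param meta Optional [cell_metadata()].
#' @return A tibble with one row per cell: `cell_id`, `group`,
#'   `total_counts`, `genes_detected`, `mito_fraction`,
#'   `deletion_region_count`, `capture_flag`.
#' @export
compute_qc_metrics <- function(m, meta = NULL) {
  bio <- biological_counts(m)
  total <- colSums(bio)
  detected <- colSums(bio > 0)
  mito_flag <- m$is_mito[!m$is_spikein]
  if (any(mito_flag)) {
    mito_counts <- colSums(bio[mito_flag, , drop = FALSE])
    mito_fraction <- ifelse(total > 0, mito_counts / total, 0)
  } else {
    mito_fraction <- rep(NA_real_, ncol(bio))
  }
  out <- tibble::tibble(
    cell_id = colnames(bio),
    group = "all",
    total_counts = unname(total),
    genes_detected = unname(detected),
    mito_fraction = unname(mito_fraction),
    deletion_region_count = NA_integer_,
    capture_flag = "unknown")
  if (!is.null(meta)) {
    idx <- match(out$cell_id, meta$cell_id)
    if (anyNA(idx)) {
      stop("metadata missing for cells: ",
           paste(utils::head(out$cell_id[is.na(idx)], 5), collapse = ", "))
    }
    out$group <- meta$group[idx]
    out$deletion_region_count <- meta$deletion_region_count[idx]
    out$capture_flag <- meta$capture_flag[idx]
  }
  out
}

#' Apply cell-level quality-control filters
#'
#' A cell is removed iff its total counts fall below `min_total_counts`,
#' its detected genes below `min_genes_detected`, its mitochondrial
#' fraction above `max_mito_fraction`, its capture flag is `empty`,
#' `multiplet` or `anomalous`, or -- when its group is listed in
#' `deletion_screen_groups` -- its deletion-region read count exceeds
#' `deletion_region_max`. The filters are a pure conjunction: the order of
#' application is irrelevant and tightening any threshold can only shrink
#' the kept set.
#'
#' @param metrics Output of [compute_qc_metrics()].
#' @param thresholds A [qc_thresholds()].
#' @param deletion_screen_groups Character vector of group labels subject
#'   to the deletion-region screen (default none).
#' @return The metrics tibble (class `qc_report`) augmented with logical
#'   columns `pass_counts`, `pass_genes`, `pass_mito`, `pass_deletion`,
#'   `pass_capture`, the conjunction `keep`, and a comma-separated
#'   `fail_reasons` string.
#' @export
apply_qc_filters <- function(metrics, thresholds = qc_thresholds(),
                             deletion_screen_groups = character()) {
  thr <- thresholds
  if (any(is.na(metrics$mito_fraction)) && thr$max_mito_fraction < 1) {
    stop("mitochondrial fraction is NA for some cells (no mito flags in ",
         "the matrix) but the mito filter is enabled")
  }
  screened <- metrics$group %in% deletion_screen_groups
  del <- metrics$deletion_region_count
  del_fail <- screened & !is.na(del) & del > thr$deletion_region_max
  out <- dplyr::mutate(
    metrics,
    pass_counts = .data$total_counts >= thr$min_total_counts,
    pass_genes = .data$genes_detected >= thr$min_genes_detected,
    pass_mito = dplyr::coalesce(!(.data$mito_fraction > thr$max_mito_fraction),
                                TRUE),
    pass_deletion = !del_fail,
    pass_capture = !(.data$capture_flag %in%
                       c("empty", "multiplet", "anomalous")))
  out$keep <- out$pass_counts & out$pass_genes & out$pass_mito &
    out$pass_deletion & out$pass_capture
  reasons <- cbind(
    ifelse(out$pass_counts, NA, "low_counts"),
    ifelse(out$pass_genes, NA, "few_genes"),
    ifelse(out$pass_mito, NA, "high_mito"),
    ifelse(out$pass_deletion, NA, "deletion_region"),
    ifelse(out$pass_capture, NA, "capture_flag"))
  out$fail_reasons <- apply(reasons, 1, function(r) {
    paste(r[!is.na(r)], collapse = ",")
  })
  attr(out, "provenance") <- sprintf(
    "apply_qc_filters: min_total=%g min_genes=%g max_mito=%g del_max=%g screen=[%s]",
    thr$min_total_counts, thr$min_genes_detected, thr$max_mito_fraction,
    thr$deletion_region_max, paste(deletion_screen_groups, collapse = ","))
  class(out) <- c("qc_report", class(out))
  out
}

#' Cell ids retained by a QC report
#' @param report Output of [apply_qc_filters()].
#' @return Character vector of kept cell ids.
#' @export
qc_kept_cells <- function(report) report$cell_id[report$keep]

#' Whole-transcriptome PCA outlier screen
#'
#' A deterministic surrogate for visual outlier removal: PCA of
#' `log2(count + 1)` over non-spike-in genes, flagging cells whose PC1 or
#' PC2 score deviates from the per-component median by more than
#' `k_mad` times the median absolute deviation.
#'
#' @param m A [count_matrix()].
#' @param cells Cells to screen (default all).
#' @param k_mad MAD multiplier (default 6).
#' @return A tibble `cell_id`, `pc1`, `pc2`, `outlier`.
#' @export
pca_outlier_screen <- function(m, cells = cell_ids(m), k_mad = 6) {
  if (length(cells) < 5L) stop("need at least 5 cells for the PCA screen")
  x <- log2(biological_counts(m)[, cells, drop = FALSE] + 1)
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE, rank. = 2)
  scores <- pc$x
  flag <- rep(FALSE, length(cells))
  for (k in seq_len(min(2L, ncol(scores)))) {
    s <- scores[, k]
    dev <- abs(s - stats::median(s))
    flag <- flag | dev > k_mad * stats::mad(s)
  }
  tibble::tibble(cell_id = cells, pc1 = unname(scores[, 1]),
                 pc2 = if (ncol(scores) >= 2) unname(scores[, 2]) else NA_real_,
                 outlier = unname(flag))
}

#' QC overview plot
#'
#' @param object A `qc_report` from [apply_qc_filters()].
#' @param ... Unused.
#' @return A ggplot: total counts vs genes detected, coloured by keep
#'   status, sized by mitochondrial fraction.
#' @export
autoplot.qc_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$total_counts, y = .data$genes_detected,
    colour = .data$keep, size = .data$mito_fraction)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$group)) +
    ggplot2::labs(x = "total counts (non-spike-in)", y = "genes detected",
                  colour = "kept", size = "mito fraction")
}
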