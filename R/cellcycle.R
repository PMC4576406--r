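#' PCA embedding of cells on a curated gene list
#'
#' Transforms the normalized matrix as `log2(x + 1)`, restricts to the
#' requested gene list (absent genes are dropped with a warning), centres
#' each gene (no unit-variance scaling) and eigendecomposes the cell
#' covariance. Component signs are fixed deterministically: PC1 is
#' oriented so the summed loading of the S/G2-M anchor panel is
#' non-negative (so proliferative cells sit at positive PC1); components
#' without anchor information are oriented by their largest-magnitude
#' loading.
#'
#' @param norm Normalized matrix (genes x cells) from
#'   [normalize_counts()].
#' @param genes Character vector of gene ids to embed on.
#' @param n_components Number of components to retain (default 2).
#' @param anchor_genes Genes whose summed PC1 loading is forced
#'   non-negative; default the S and G2/M panels of
#'   [default_stage_panels()]. `NULL` disables anchoring.
#' @return An object of class `pca_embedding`: gene list used, per-gene
#'   centring means, orthonormal loadings (genes x components), per-cell
#'   scores, variance explained, and the centred training matrix (for the
#'   hierarchical cross-check).
#' @export
pca_embed <- function(norm, genes, n_components = 2, anchor_genes = NULL) {
  stopifnot(is.matrix(norm))
  if (ncol(norm) < 2L) stop("need at least 2 cells")
  present <- intersect(genes, rownames(norm))
  if (length(present) < length(genes)) {
    warning(length(genes) - length(present),
            " listed genes absent from the matrix; dropped")
  }
  if (length(present) < 2L) stop("fewer than 2 usable genes for PCA")
  if (is.null(anchor_genes)) {
    panels <- default_stage_panels()
    anchor_genes <- unique(c(panels[["S"]]$high, panels[["G2/M"]]$high))
  }
  x <- t(log2(norm[present, , drop = FALSE] + 1))
  centers <- colMeans(x)
  xc <- sweep(x, 2, centers)
  n_components <- min(n_components, ncol(xc), nrow(xc) - 1L)
  pc <- stats::prcomp(xc, center = FALSE, scale. = FALSE)
  load <- pc$rotation[, seq_len(n_components), drop = FALSE]
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  anchors <- intersect(anchor_genes, present)
  for (k in seq_len(n_components)) {
    flip <- if (k == 1L && length(anchors)) {
      sum(load[anchors, 1]) < 0
    } else {
      load[which.max(abs(load[, k])), k] < 0
    }
    if (flip) {
      load[, k] <- -load[, k]
      scores[, k] <- -scores[, k]
    }
  }
  var_expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    genes = present, centers = centers, loadings = load, scores = scores,
    var_explained = var_expl[seq_len(n_components)],
    anchor_genes = anchors, centred = xc),
    class = "pca_embedding")
}

#' @export
print.pca_embedding <- function(x, ...) {
  cat(sprintf(
    "<pca_embedding> %d cells x %d genes; %d components (%.1f%%, %.1f%% ...)\n",
    nrow(x$scores), length(x$genes), ncol(x$scores),
    100 * x$var_explained[1],
    if (length(x$var_explained) > 1) 100 * x$var_explained[2] else NA))
  invisible(x)
}

#' @export
tidy.pca_embedding <- function(x, ...) {
  out <- tibble::as_tibble(x$scores, .name_repair = "minimal")
  names(out) <- paste0("pc", seq_len(ncol(out)))
  dplyr::bind_cols(tibble::tibble(cell_id = rownames(x$scores)), out)
}

#' @export
autoplot.pca_embedding <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$pc1, .data$pc2)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2]))
}

#' Project new cells into an existing embedding
#'
#' Centres the new cells with the reference per-gene means and projects
#' them onto the reference loadings. At least 80% of the embedding's gene
#' list must be present in the new matrix.
#'
#' @param emb A [pca_embed()] result.
#' @param norm_new Normalized matrix of the new cells (genes x cells).
#' @param min_overlap Minimum fraction of embedding genes that must be
#'   present (default 0.8).
#' @return Matrix of scores (cells x components).
#' @export
project_embedding <- function(emb, norm_new, min_overlap = 0.8) {
  present <- intersect(emb$genes, rownames(norm_new))
  if (length(present) < min_overlap * length(emb$genes)) {
    stop(sprintf(
      "gene overlap %d/%d below the %.0f%% threshold",
      length(present), length(emb$genes), 100 * min_overlap))
  }
  x <- t(log2(norm_new[present, , drop = FALSE] + 1))
  xc <- sweep(x, 2, emb$centers[present])
  xc %*% emb$loadings[present, , drop = FALSE]
}

#' Cluster cells in embedding space
#'
#' Seeded k-means (25 restarts, best inertia kept) on the retained
#' components; clusters are renamed `C1..Ck` in order of ascending mean
#' PC1 so labels are stable across runs. As a cross-check the partition is
#' compared (adjusted Rand index) with complete-linkage hierarchical
#' clustering of the cells on 1 - Pearson correlation distance over the
#' embedding's centred expression; the agreement is reported, not
#' enforced.
#'
#' @param emb A [pca_embed()] result.
#' @param k Number of clusters (default 5).
#' @param seed Integer seed for the k-means restarts.
#' @param nstart Number of k-means restarts (default 25).
#' @return A list of class `cluster_result`: `clusters` (tibble `cell_id`,
#'   `cluster`), `centroids` (k x components), `hclust_agreement`
#'   (adjusted Rand index vs the hierarchical partition).
#' @export
cluster_embedding <- function(emb, k = 5, seed = 1L, nstart = 25) {
  n <- nrow(emb$scores)
  if (k > n) stop("k = ", k, " exceeds the number of cells (", n, ")")
  km <- withr::with_seed(seed,
    stats::kmeans(emb$scores, centers = k, nstart = nstart, iter.max = 100))
  ord <- order(km$centers[, 1])
  relabel <- match(seq_len(k), ord)
  cl <- relabel[km$cluster]
  centroids <- km$centers[ord, , drop = FALSE]
  rownames(centroids) <- paste0("C", seq_len(k))
  agreement <- NA_real_
  if (!is.null(emb$centred) && n >= 3L) {
    d <- stats::as.dist(1 - stats::cor(t(emb$centred)))
    hcl <- stats::cutree(stats::hclust(d, method = "complete"), k = k)
    agreement <- mclust::adjustedRandIndex(cl, hcl)
  }
  structure(list(
    clusters = tibble::tibble(cell_id = rownames(emb$scores),
                              cluster = paste0("C", cl)),
    centroids = centroids,
    hclust_agreement = agreement),
    class = "cluster_result")
}

#' Label clusters with cell-cycle stages from marker panels
#'
#' Gene expression (`log2(normalized + 1)`) is z-scored across all cells;
#' for every cluster and stage the score is the mean, over the stage's
#' panel genes, of the cluster-mean z-score, with "low" panel genes
#' contributing negated. Each cluster receives its argmax stage; ties
#' break toward the earlier stage in cycle order with a warning, and
#' clusters smaller than `min_cells_for_label` are labelled
#' `"undetermined"`.
#'
#' @param emb The [pca_embed()] result the clusters live in.
#' @param clustering A [cluster_embedding()] result.
#' @param norm Normalized matrix (genes x cells) covering the clustered
#'   cells.
#' @param panels Stage marker panels as in [default_stage_panels()].
#' @param groups Optional named vector (cell id -> group label) used for
#'   per-group occupancy.
#' @param min_cells_for_label Minimum cluster size for a stage label
#'   (default 5).
#' @return A list of class `stage_model` (centroids, cluster-stage map,
#'   panels, the embedding's gene list) together with an attached
#'   `stage_assignment` for the training cells; access it with
#'   `$assignment`.
#' @export
assign_cluster_stages <- function(emb, clustering, norm,
                                  panels = default_stage_panels(),
                                  groups = NULL,
                                  min_cells_for_label = 5) {
  cl <- clustering$clusters
  cells <- cl$cell_id
  if (!all(cells %in% colnames(norm))) stop("normalized matrix missing cells")
  if (any(table(cl$cluster) == 0)) stop("empty cluster")
  x <- log2(norm[, cells, drop = FALSE] + 1)
  z_of <- function(genes) {
    present <- intersect(genes, rownames(x))
    if (length(present) < length(genes)) {
      warning("panel genes absent from matrix: ",
              paste(setdiff(genes, present), collapse = ", "))
    }
    present
  }
  scores <- matrix(NA_real_, nrow = nrow(clustering$centroids),
                   ncol = length(panels),
                   dimnames = list(rownames(clustering$centroids),
                                   names(panels)))
  zmat <- t(scale(t(x)))
  zmat[!is.finite(zmat)] <- 0  # constant genes carry no panel information
  for (st in names(panels)) {
    hi <- z_of(panels[[st]]$high)
    lo <- z_of(panels[[st]]$low)
    if (length(hi) + length(lo) == 0L) {
      stop("stage panel '", st, "' has no genes present in the matrix")
    }
    for (cname in rownames(scores)) {
      in_cl <- cells[cl$cluster == cname]
      zz <- c(rowMeans(zmat[hi, in_cl, drop = FALSE]),
              -rowMeans(zmat[lo, in_cl, drop = FALSE]))
      scores[cname, st] <- mean(zz)
    }
  }
  sizes <- table(cl$cluster)[rownames(scores)]
  stage_order <- names(panels)
  labels <- apply(scores, 1, function(s) {
    best <- which(s == max(s))
    if (length(best) > 1) {
      warning("stage-score tie broken toward the earlier stage")
      best <- best[order(match(stage_order[best], stage_order))][1]
    }
    stage_order[best]
  })
  labels[sizes < min_cells_for_label] <- "undetermined"
  model <- structure(list(
    centroids = clustering$centroids,
    cluster_stage = labels,
    panels = panels,
    stage_scores = scores,
    genes = emb$genes,
    min_cells_for_label = min_cells_for_label),
    class = "stage_model")
  model$assignment <- .make_stage_assignment(
    cells, cl$cluster, labels[cl$cluster], emb$scores[cells, , drop = FALSE],
    groups)
  model
}

.make_stage_assignment <- function(cells, cluster, stage, scores, groups) {
  grp <- if (is.null(groups)) rep("all", length(cells)) else
    unname(groups[cells])
  cells_tb <- tibble::tibble(
    cell_id = cells, cluster = cluster, stage = stage, group = grp)
  sc <- tibble::as_tibble(scores, .name_repair = "minimal")
  names(sc) <- paste0("pc", seq_len(ncol(sc)))
  cells_tb <- dplyr::bind_cols(cells_tb, sc)
  occupancy <- cells_tb |>
    dplyr::count(.data$group, .data$stage, name = "n") |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  structure(list(cells = cells_tb, occupancy = occupancy),
            class = "stage_assignment")
}

#' @export
print.stage_model <- function(x, ...) {
  cat("<stage_model>\n")
  for (cname in names(x$cluster_stage)) {
    cat(sprintf("  %s -> %s\n", cname, x$cluster_stage[[cname]]))
  }
  invisible(x)
}

#' @export
print.stage_assignment <- function(x, ...) {
  cat(sprintf("<stage_assignment> %d cells\n", nrow(x$cells)))
  print(x$occupancy)
  invisible(x)
}

#' @export
tidy.stage_assignment <- function(x, ...) x$cells

#' @export
glance.stage_assignment <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$cells),
    n_clusters = dplyr::n_distinct(x$cells$cluster),
    n_undetermined = sum(x$cells$stage == "undetermined"))
}

#' @export
autoplot.stage_assignment <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(.data$pc1, .data$pc2,
                               colour = .data$stage,
                               shape = .data$group)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = "PC1", y = "PC2", colour = "stage", shape = "group")
}

#' Project new cells and classify them by nearest stage cluster
#'
#' New cells (e.g. a knockout population) are projected into the
#' reference embedding with [project_embedding()], assigned to the
#' nearest cluster centroid (Euclidean distance in the retained
#' components) and inherit that cluster's stage label.
#'
#' @param emb The reference [pca_embed()] result.
#' @param model A `stage_model` from [assign_cluster_stages()].
#' @param norm_new Normalized matrix of the new cells.
#' @param groups Optional named vector (cell id -> group label).
#' @return A `stage_assignment` for the new cells.
#' @export
project_and_classify <- function(emb, model, norm_new, groups = NULL) {
  scores <- project_embedding(emb, norm_new)
  cent <- model$centroids
  d2 <- outer(rowSums(scores^2), rowSums(cent^2), `+`) -
    2 * scores %*% t(cent)
  nearest <- rownames(cent)[max.col(-d2, ties.method = "first")]
  .make_stage_assignment(rownames(scores), nearest,
                         unname(model$cluster_stage[nearest]),
                         scores, groups)
}

#' Compare stage occupancy between two populations
#'
#' Two-sided Fisher exact test on the 2x2 table of cells inside versus
#' outside a set of stages, between two assignments.
#'
#' @param a,b `stage_assignment` objects (e.g. knockout and control).
#' @param stages Stage labels forming the "in" bin, e.g. `c("S", "G2/M")`.
#' @return A one-row tibble: per-group in-fractions, their difference
#'   (a minus b), the 2x2 counts and the Fisher p-value.
#' @export
compare_occupancy <- function(a, b, stages = c("S", "G2/M")) {
  n_a <- nrow(a$cells); n_b <- nrow(b$cells)
  if (n_a == 0L || n_b == 0L) stop("empty group")
  in_a <- sum(a$cells$stage %in% stages)
  in_b <- sum(b$cells$stage %in% stages)
  tab <- matrix(c(in_a, n_a - in_a, in_b, n_b - in_b), nrow = 2)
  ft <- stats::fisher.test(tab)
  tibble::tibble(
    stages = paste(stages, collapse = "+"),
    frac_a = in_a / n_a, frac_b = in_b / n_b,
    difference = in_a / n_a - in_b / n_b,
    in_a = in_a, n_a = n_a, in_b = in_b, n_b = n_b,
    p_value = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Per-cell transcriptional activity and rank-sum comparisons
#'
#' Activity is the total non-spike-in count of a cell divided by its
#' spike-in size factor -- an absolute measure of transcriptional output
#' calibrated by the fixed spike-in pool. Cells are binned into
#' quiescent (`G0/early-G1`, `late-G1`) versus proliferative
#' (`S`, `G2/M`) stages and compared by two-sided Wilcoxon rank-sum
#' tests within each genotype (bin vs bin) and within each bin
#' (genotype vs genotype). Comparisons with fewer than 3 cells on a side
#' are skipped with a warning.
#'
#' @param m A [count_matrix()].
#' @param sf A [size_factors()] object with spike-in factors.
#' @param assignment A `stage_assignment` covering the cells (may be the
#'   concatenation of several; see [bind_assignments()]).
#' @return A list of class `activity_result`: `activity` (per-cell
#'   tibble) and `comparisons` (tibble of Wilcoxon tests).
#' @export
transcriptional_activity <- function(m, sf, assignment) {
  if (is.null(sf$spikein)) stop("spike-in size factors are required")
  cells <- assignment$cells$cell_id
  cells <- intersect(cells, cell_ids(m))
  total <- colSums(biological_counts(m)[, cells, drop = FALSE])
  act <- tibble::tibble(
    cell_id = cells,
    activity = unname(total / sf$spikein[cells])) |>
    dplyr::left_join(assignment$cells[, c("cell_id", "group", "stage")],
                     by = "cell_id") |>
    dplyr::mutate(stage_bin = dplyr::case_when(
      .data$stage %in% c("G0/early-G1", "late-G1") ~ "G0/G1",
      .data$stage %in% c("S", "G2/M") ~ "S/G2/M",
      TRUE ~ NA_character_)) |>
    dplyr::filter(!is.na(.data$stage_bin))
  cmp <- list()
  test_pair <- function(x, y, label) {
    if (length(x) < 3L || length(y) < 3L) {
      warning("comparison '", label, "' skipped: fewer than 3 cells per side")
      return(NULL)
    }
    wt <- stats::wilcox.test(x, y, exact = FALSE)
    tibble::tibble(comparison = label, n_x = length(x), n_y = length(y),
                   median_x = stats::median(x), median_y = stats::median(y),
                   p_value = wt$p.value)
  }
  for (g in unique(act$group)) {
    sub <- act[act$group == g, ]
    cmp[[length(cmp) + 1]] <- test_pair(
      sub$activity[sub$stage_bin == "S/G2/M"],
      sub$activity[sub$stage_bin == "G0/G1"],
      paste0(g, ": S/G2/M vs G0/G1"))
  }
  grps <- unique(act$group)
  if (length(grps) >= 2) {
    pairs <- utils::combn(grps, 2, simplify = FALSE)
    for (pr in pairs) {
      for (b in c("G0/G1", "S/G2/M")) {
        sub <- act[act$stage_bin == b, ]
        cmp[[length(cmp) + 1]] <- test_pair(
          sub$activity[sub$group == pr[1]],
          sub$activity[sub$group == pr[2]],
          paste0(b, ": ", pr[1], " vs ", pr[2]))
      }
    }
  }
  structure(list(activity = act, comparisons = dplyr::bind_rows(cmp)),
            class = "activity_result")
}

#' Concatenate stage assignments
#'
#' @param ... `stage_assignment` objects with disjoint cells.
#' @return A single `stage_assignment` with recomputed per-group
#'   occupancy.
#' @export
bind_assignments <- function(...) {
  parts <- list(...)
  cells <- dplyr::bind_rows(lapply(parts, function(p) p$cells))
  if (anyDuplicated(cells$cell_id)) stop("assignments share cells")
  occupancy <- cells |>
    dplyr::count(.data$group, .data$stage, name = "n") |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  structure(list(cells = cells, occupancy = occupancy),
            class = "stage_assignment")
}
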