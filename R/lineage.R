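#' Default quiescence / lymphoid-competence anchor panel
#'
#' Regulators whose mean expression orders lineage subgroups so that H1
#' is the most quiescent, lymphoid-competent-like subgroup.
#' @return Character vector of gene symbols.
#' @export
default_quiescence_anchors <- function() {
  c("Bcl11a", "Egr1", "Jun", "Mecom", "Hlf")
}

#' PCA embedding on hematopoietic genes with cycle genes removed
#'
#' Hematopoietic genes that are also annotated to the cell cycle are
#' removed before embedding, so that lineage structure is not confounded
#' by proliferation; the rest is delegated to [pca_embed()] (without a
#' cyclin anchor -- component signs follow the largest-loading rule).
#'
#' @param norm Normalized matrix (genes x cells).
#' @param hematopoietic_genes Curated hematopoietic gene list.
#' @param cycle_genes Cell-cycle gene list to subtract.
#' @param n_components Components to retain (default 2).
#' @return A [pca_embed()] result.
#' @export
lineage_embed <- function(norm, hematopoietic_genes, cycle_genes = character(),
                          n_components = 2) {
  keep <- setdiff(hematopoietic_genes, cycle_genes)
  if (length(intersect(keep, rownames(norm))) < 2L) {
    stop("fewer than 2 hematopoietic genes remain after removing ",
         "cell-cycle genes")
  }
  pca_embed(norm, keep, n_components = n_components,
            anchor_genes = character())
}

#' Subgroup cells on the lineage embedding
#'
#' Seeded k-means into `k` subgroups, relabelled deterministically by
#' descending mean expression of a quiescence anchor panel so that H1 is
#' the most quiescent (lymphoid-competent-like) subgroup. Cell-cycle
#' stage labels are joined when an assignment is supplied, giving the
#' per-subgroup genotype and stage composition.
#'
#' @param emb A [lineage_embed()] result.
#' @param norm Normalized matrix (for the anchor score).
#' @param k Number of subgroups (default 4).
#' @param seed Integer seed.
#' @param anchor_panel Genes scoring quiescence (default
#'   [default_quiescence_anchors()]).
#' @param groups Optional named vector cell id -> group.
#' @param stage_assignment Optional `stage_assignment` providing stages.
#' @return A list of class `subgroup_assignment`: `cells` (tibble
#'   `cell_id`, `subgroup`, `group`, `stage`, scores) and `composition`
#'   (counts by subgroup x group x stage).
#' @export
subgroup_cells <- function(emb, norm, k = 4, seed = 1L,
                           anchor_panel = default_quiescence_anchors(),
                           groups = NULL, stage_assignment = NULL) {
  n <- nrow(emb$scores)
  if (k > n) stop("k = ", k, " exceeds the number of cells (", n, ")")
  n_distinct_pts <- nrow(unique(emb$scores))
  if (n_distinct_pts < k) {
    warning("only ", n_distinct_pts, " distinct embedding points; ",
            "k reduced (degenerate clustering)")
    k <- max(1L, n_distinct_pts)
  }
  km <- withr::with_seed(seed,
    stats::kmeans(emb$scores, centers = k, nstart = 25, iter.max = 100))
  x <- log2(norm[, rownames(emb$scores), drop = FALSE] + 1)
  anchors <- intersect(anchor_panel, rownames(x))
  if (length(anchors) == 0L) {
    warning("no anchor-panel genes in matrix; subgroups ordered by PC1")
    anchor_score <- -tapply(emb$scores[, 1], km$cluster, mean)
  } else {
    cell_anchor <- colMeans(x[anchors, , drop = FALSE])
    anchor_score <- tapply(cell_anchor, km$cluster, mean)
  }
  ord <- order(anchor_score, decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  sub <- paste0("H", relabel[km$cluster])
  cells_tb <- tibble::tibble(
    cell_id = rownames(emb$scores), subgroup = sub,
    group = if (is.null(groups)) "all" else
      unname(groups[rownames(emb$scores)]))
  sc <- tibble::as_tibble(emb$scores, .name_repair = "minimal")
  names(sc) <- paste0("pc", seq_len(ncol(sc)))
  cells_tb <- dplyr::bind_cols(cells_tb, sc)
  cells_tb$stage <- NA_character_
  if (!is.null(stage_assignment)) {
    idx <- match(cells_tb$cell_id, stage_assignment$cells$cell_id)
    cells_tb$stage <- stage_assignment$cells$stage[idx]
  }
  composition <- cells_tb |>
    dplyr::count(.data$subgroup, .data$group, .data$stage, name = "n")
  structure(list(cells = cells_tb, composition = composition),
            class = "subgroup_assignment")
}

#' @export
print.subgroup_assignment <- function(x, ...) {
  cat(sprintf("<subgroup_assignment> %d cells in %d subgroups\n",
              nrow(x$cells), dplyr::n_distinct(x$cells$subgroup)))
  invisible(x)
}

#' @export
tidy.subgroup_assignment <- function(x, ...) x$cells

#' @export
glance.subgroup_assignment <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$cells),
                 n_subgroups = dplyr::n_distinct(x$cells$subgroup))
}

#' @export
autoplot.subgroup_assignment <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(.data$pc1, .data$pc2,
                               colour = .data$subgroup,
                               shape = .data$group)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = "PC1", y = "PC2")
}

#' Co-expression clustering of transcriptional regulators
#'
#' Pairwise Spearman correlation of the chosen regulators over cells,
#' complete-linkage hierarchical clustering on the distance
#' `1 - rho`, and a cut into `n_clusters` groups (default 2, separating
#' e.g. a cell-cycle-associated cluster from a quiescence-associated
#' one). Constant genes are dropped with a warning. Mean within- and
#' between-cluster correlations are reported.
#'
#' @param norm Normalized matrix (genes x cells).
#' @param regulators Gene list (default [default_regulators()]).
#' @param n_clusters Number of clusters at the cut (default 2).
#' @return A list of class `correlation_clusters`: `correlation` (gene x
#'   gene Spearman matrix), `hclust`, `clusters` (tibble `gene_id`,
#'   `cluster`), `summary` (mean within/between rho).
#' @export
regulator_correlation_clusters <- function(norm,
                                           regulators = default_regulators(),
                                           n_clusters = 2) {
  present <- intersect(regulators, rownames(norm))
  x <- log2(norm[present, , drop = FALSE] + 1)
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warning("constant regulators excluded: ",
            paste(present[sds == 0], collapse = ", "))
    x <- x[sds > 0, , drop = FALSE]
  }
  if (nrow(x) < 3L) stop("fewer than 3 usable (non-constant) regulators")
  rho <- stats::cor(t(x), method = "spearman")
  hc <- stats::hclust(stats::as.dist(1 - rho), method = "complete")
  cl <- stats::cutree(hc, k = n_clusters)
  within <- c(); between <- c()
  for (i in seq_len(nrow(rho) - 1)) {
    for (j in seq((i + 1), nrow(rho))) {
      if (cl[i] == cl[j]) within <- c(within, rho[i, j])
      else between <- c(between, rho[i, j])
    }
  }
  structure(list(
    correlation = rho, hclust = hc,
    clusters = tibble::tibble(gene_id = rownames(rho),
                              cluster = paste0("cluster_", unname(cl))),
    summary = tibble::tibble(
      mean_within = if (length(within)) mean(within) else NA_real_,
      mean_between = if (length(between)) mean(between) else NA_real_)),
    class = "correlation_clusters")
}

#' @export
print.correlation_clusters <- function(x, ...) {
  cat(sprintf(
    "<correlation_clusters> %d genes, %d clusters; mean rho within %.3f / between %.3f\n",
    nrow(x$correlation), dplyr::n_distinct(x$clusters$cluster),
    x$summary$mean_within, x$summary$mean_between))
  invisible(x)
}

#' @export
tidy.correlation_clusters <- function(x, ...) x$clusters

#' Write a regulator dendrogram as Newick
#'
#' @param x A [regulator_correlation_clusters()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(x, path) {
  ape::write.tree(ape::as.phylo(x$hclust), file = path)
  invisible(path)
}
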