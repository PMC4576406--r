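#' Rank genes by signal-to-noise between two classes
#'
#' For each gene, `s2n = (mean_A - mean_B) / (sd_A + sd_B)`, where each
#' class standard deviation is floored at 0.2 times the magnitude of its
#' class mean (0.2 absolute when the mean is 0) -- the classic GSEA
#' variance floor. The list is ordered by descending metric with a
#' deterministic lexicographic tie-break on gene id; positive metric
#' means higher expression in the first-listed class.
#'
#' @param norm Normalized (or otherwise comparable) matrix, genes x
#'   cells.
#' @param labels Per-cell class labels (2 classes, each with >= 3 cells);
#'   a factor's level order, or the order of first appearance, defines
#'   which class is "first".
#' @return A tibble of class `ranked_list` (`gene_id`, `metric`), ordered.
#' @export
rank_genes_s2n <- function(norm, labels) {
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(norm))
  classes <- unique(labels)
  if (length(classes) != 2L) stop("exactly two classes required")
  n_a <- sum(labels == classes[1]); n_b <- sum(labels == classes[2])
  if (min(n_a, n_b) < 3L) {
    stop("each class needs at least 3 cells (got ", n_a, " and ", n_b, ")")
  }
  metric <- .s2n_metric(norm, labels == classes[1])
  ord <- order(-metric, rownames(norm), method = "radix")
  out <- tibble::tibble(gene_id = rownames(norm)[ord],
                        metric = unname(metric[ord]))
  attr(out, "metric_name") <- "signal-to-noise"
  attr(out, "classes") <- classes
  class(out) <- c("ranked_list", class(out))
  out
}

# vectorized signal-to-noise with the GSEA sd floor
.s2n_metric <- function(norm, in_a) {
  xa <- norm[, in_a, drop = FALSE]
  xb <- norm[, !in_a, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  sda <- sqrt(rowSums((xa - ma)^2) / (ncol(xa) - 1))
  sdb <- sqrt(rowSums((xb - mb)^2) / (ncol(xb) - 1))
  floor_a <- ifelse(ma == 0, 0.2, 0.2 * abs(ma))
  floor_b <- ifelse(mb == 0, 0.2, 0.2 * abs(mb))
  (ma - mb) / (pmax(sda, floor_a) + pmax(sdb, floor_b))
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list accumulating `|metric|^p / sum_hits |metric|^p`
#' at every set member ("hit") and `-1 / (N - N_hits)` at every miss; the
#' enrichment score is the signed maximum deviation of this running sum
#' from zero. The leading edge is the set members at or before the
#' positive extremum (at or after the negative one).
#'
#' @param ranked A [rank_genes_s2n()] result (or any tibble with
#'   `gene_id`, `metric`, ordered by descending metric).
#' @param set Character vector of member gene ids.
#' @param weight_p Weighting exponent (default 1; 0 gives the classic
#'   unweighted KS statistic).
#' @return A list: `es`, `running_sum` (length-N profile), `leading_edge`
#'   (character vector).
#' @export
enrichment_score <- function(ranked, set, weight_p = 1) {
  genes <- ranked$gene_id
  n <- length(genes)
  hit <- genes %in% set
  nh <- sum(hit)
  if (nh == 0L) stop("gene set has no members in the ranked list")
  if (nh == n) stop("gene set covers the whole ranked list; the miss ",
                    "decrement is undefined")
  w <- abs(ranked$metric)^weight_p
  w[!hit] <- 0
  tot <- sum(w)
  inc <- if (tot > 0) w / tot else as.numeric(hit) / nh
  steps <- inc - (!hit) / (n - nh)
  rs <- cumsum(steps)
  i_ext <- which.max(abs(rs))
  es <- rs[i_ext]
  if (abs(max(rs)) == abs(min(rs)) && max(rs) > 0) es <- max(rs)
  leading <- if (es >= 0) genes[hit & seq_len(n) <= i_ext]
             else genes[hit & seq_len(n) >= i_ext]
  list(es = es, running_sum = rs, leading_edge = leading)
}

# fast ES from hit positions in a ranked metric vector (no profile)
.es_fast <- function(metric, pos, n, weight_p = 1) {
  pos <- sort(pos)
  nh <- length(pos)
  w <- abs(metric[pos])^weight_p
  tot <- sum(w)
  cw <- if (tot > 0) cumsum(w) / tot else seq_len(nh) / nh
  miss_before <- pos - seq_len(nh)            # misses strictly before hit
  after <- cw - miss_before / (n - nh)        # running sum just after hit
  before <- c(0, cw[-nh]) - miss_before / (n - nh)  # just before hit
  hi <- max(after); lo <- min(c(before, 0))
  if (hi >= -lo) hi else lo
}

#' Gene set enrichment analysis with phenotype permutation
#'
#' For every gene set: observed [enrichment_score()] on the
#' signal-to-noise ranking; null distribution from `n_perm` permutations
#' of the class labels (the ranking is recomputed for each permutation);
#' nominal p as the add-one-smoothed fraction of same-sign permuted
#' scores at least as extreme; NES as the observed score divided by the
#' mean magnitude of same-sign permuted scores; and FDR q from the
#' standard pooled-NES procedure (the permuted NES of all sets form the
#' null pool, separately per sign). A positive NES means enrichment in
#' the first-listed class.
#'
#' @param norm Normalized matrix, genes x cells.
#' @param labels Two-class per-cell labels (first class = positive
#'   direction).
#' @param sets A [gene_sets()] collection.
#' @param n_perm Number of label permutations (>= 100; default 1000).
#' @param weight_p ES weight (default 1).
#' @param seed Integer seed.
#' @param min_size Sets with fewer in-matrix members are dropped
#'   (default 2).
#' @return A tibble of class `gsea_result`: `set`, `size`, `es`, `nes`,
#'   `p_value`, `fdr_q`, `leading_edge` (list column), `n_perm`.
#' @export
gsea <- function(norm, labels, sets, n_perm = 1000, weight_p = 1,
                 seed = 1L, min_size = 2) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2L) stop("exactly two classes required")
  if (min(table(labels)) < 3L) stop("each class needs at least 3 cells")
  genes <- rownames(norm)
  sets_in <- lapply(sets, function(s) intersect(s, genes))
  keep <- lengths(sets_in) >= min_size & lengths(sets_in) < length(genes)
  if (!any(keep)) stop("no gene set with enough members in the matrix")
  sets_in <- sets_in[keep]
  n <- length(genes)
  in_a <- labels == classes[1]

  obs_rank <- rank_genes_s2n(norm, labels)
  obs <- lapply(sets_in, function(s) enrichment_score(obs_rank, s, weight_p))
  es_obs <- vapply(obs, `[[`, 0, "es")
  set_idx <- lapply(sets_in, function(s) match(s, genes))

  perm_es <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      pl <- sample(in_a)
      metric <- .s2n_metric(norm, pl)
      ord <- order(-metric, genes, method = "radix")
      metric_o <- metric[ord]
      rank_pos <- match(seq_len(n), ord)  # gene index -> rank position
      vapply(set_idx, function(idx) {
        .es_fast(metric_o, rank_pos[idx], n, weight_p)
      }, 0)
    }, numeric(length(sets_in)))
  })
  if (is.null(dim(perm_es))) perm_es <- matrix(perm_es, nrow = 1)

  p_val <- nes <- numeric(length(es_obs))
  nes_perm <- matrix(NA_real_, nrow(perm_es), ncol(perm_es))
  for (i in seq_along(es_obs)) {
    pe <- perm_es[i, ]
    pos_mean <- mean(pe[pe >= 0]); neg_mean <- mean(abs(pe[pe < 0]))
    same <- if (es_obs[i] >= 0) pe[pe >= 0] else pe[pe < 0]
    p_val[i] <- (1 + sum(abs(same) >= abs(es_obs[i]))) / (1 + length(same))
    denom <- if (es_obs[i] >= 0) pos_mean else neg_mean
    nes[i] <- if (is.finite(denom) && denom > 0) es_obs[i] / denom else NA_real_
    nes_perm[i, pe >= 0] <- pe[pe >= 0] / pos_mean
    nes_perm[i, pe < 0] <- -abs(pe[pe < 0]) / neg_mean
  }
  fdr <- .gsea_fdr(nes, nes_perm)

  out <- tibble::tibble(
    set = names(sets_in), size = lengths(sets_in),
    es = unname(es_obs), nes = nes, p_value = p_val, fdr_q = fdr,
    leading_edge = unname(lapply(obs, `[[`, "leading_edge")),
    n_perm = n_perm)
  attr(out, "classes") <- classes
  class(out) <- c("gsea_result", class(out))
  out
}

# pooled-NES FDR: compare each observed NES against the pooled permuted
# NES of matching sign, normalized by the observed tail fraction
.gsea_fdr <- function(nes, nes_perm) {
  pool <- as.vector(nes_perm)
  pool <- pool[is.finite(pool)]
  q <- rep(NA_real_, length(nes))
  for (i in seq_along(nes)) {
    if (!is.finite(nes[i])) next
    if (nes[i] >= 0) {
      num_pool <- sum(pool >= nes[i]) / max(1, sum(pool >= 0))
      num_obs <- sum(nes >= nes[i], na.rm = TRUE) /
        max(1, sum(nes >= 0, na.rm = TRUE))
    } else {
      num_pool <- sum(pool <= nes[i]) / max(1, sum(pool < 0))
      num_obs <- sum(nes <= nes[i], na.rm = TRUE) /
        max(1, sum(nes < 0, na.rm = TRUE))
    }
    q[i] <- min(1, num_pool / max(num_obs, .Machine$double.eps))
  }
  q
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("<gsea_result> %d sets, %d permutations (positive = %s)\n",
              nrow(x), x$n_perm[1], attr(x, "classes")[1]))
  print(tibble::as_tibble(x[, c("set", "size", "es", "nes", "p_value",
                                "fdr_q")]))
  invisible(x)
}

#' @export
tidy.gsea_result <- function(x, ...) {
  tibble::as_tibble(x[, c("set", "size", "es", "nes", "p_value", "fdr_q")])
}

#' Significant sets under the joint FDR / nominal-p rule
#'
#' @param x A [gsea()] result.
#' @param fdr_max Maximum FDR q (default 0.1).
#' @param p_max Maximum nominal p (default 0.05).
#' @return The rows passing both cutoffs.
#' @export
gsea_significant <- function(x, fdr_max = 0.1, p_max = 0.05) {
  dplyr::filter(x, .data$fdr_q < fdr_max, .data$p_value < p_max)
}

#' @export
autoplot.gsea_result <- function(object, ...) {
  dat <- dplyr::mutate(tidy(object),
                       significant = .data$fdr_q < 0.1 & .data$p_value < 0.05)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$nes, y = stats::reorder(.data$set, .data$nes),
    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "NES", y = NULL, fill = "FDR<0.1 & p<0.05")
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of each set's overlap with a selected
#' gene list against a universe, Benjamini-Hochberg adjusted across
#' sets. Sets are intersected with the universe first.
#'
#' @param selected Character vector of selected genes (must lie within
#'   the universe).
#' @param universe Character vector of background genes.
#' @param sets A [gene_sets()] collection.
#' @return A tibble of class `ora_result`: `set`, `set_size`, `overlap`,
#'   `selected_size`, `universe_size`, `p_value`, `p_adjust`.
#' @export
ora_hypergeometric <- function(selected, universe, sets) {
  selected <- unique(selected); universe <- unique(universe)
  extra <- setdiff(selected, universe)
  if (length(extra)) {
    stop("selected genes outside the universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  n_u <- length(universe); n_s <- length(selected)
  rows <- purrr::imap(unclass(sets), function(members, nm) {
    inset <- intersect(members, universe)
    k <- length(intersect(inset, selected))
    p <- if (length(inset) == 0L) 1 else
      stats::phyper(k - 1, length(inset), n_u - length(inset), n_s,
                    lower.tail = FALSE)
    tibble::tibble(set = nm, set_size = length(inset), overlap = k,
                   selected_size = n_s, universe_size = n_u, p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  class(out) <- c("ora_result", class(out))
  out
}
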