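test_that("PCA on rank-1 data puts essentially all variance on PC1", {
  base <- c(1, 2, 5, 9)
  mat <- make_expr(outer(c(1, 2, 4), base))  # genes proportional
  emb <- pca_embed(mat, rownames(mat), n_components = 2)
  expect_gte(emb$var_explained[1], 0.999)
})

test_that("2-gene loadings match the closed-form eigendecomposition", {
  mat <- make_expr(matrix(c(3, 1, 4, 2, 8, 5), nrow = 2))
  emb <- pca_embed(mat, rownames(mat), n_components = 2)
  x <- t(log2(mat + 1))
  xc <- sweep(x, 2, colMeans(x))
  cv <- stats::cov(xc)
  # closed-form leading eigenvector of a symmetric 2x2 matrix
  a <- cv[1, 1]; b <- cv[1, 2]; d <- cv[2, 2]
  lam <- ((a + d) + sqrt((a - d)^2 + 4 * b^2)) / 2
  v <- c(b, lam - a); v <- v / sqrt(sum(v^2))
  got <- emb$loadings[, 1]
  expect_equal(abs(sum(got * v)), 1, tolerance = 1e-10)
  # re-projection of training cells reproduces stored scores
  reproj <- project_embedding(emb, mat)
  expect_equal(reproj, emb$scores, tolerance = 1e-10)
})

test_that("absent list genes are dropped with a warning; too few is an error", {
  mat <- make_expr(matrix(rexp(30, 1 / 10), nrow = 3))
  expect_warning(emb <- pca_embed(mat, c(rownames(mat), "ghost")),
                 "absent")
  expect_equal(length(emb$genes), 3)
  expect_error(suppressWarnings(pca_embed(mat, c("g1", "ghost"))),
               "2 usable")
})

test_that("k-means separates well-separated blobs and is seed-stable", {
  withr::with_seed(10, {
    blob <- rbind(matrix(rnorm(40, 0), ncol = 2),
                  matrix(rnorm(40, 10), ncol = 2))
  })
  emb <- structure(list(scores = `dimnames<-`(
    blob, list(paste0("c", 1:40), NULL)), centred = NULL),
    class = "pca_embedding")
  cl <- cluster_embedding(emb, k = 2, seed = 1)
  expect_equal(length(unique(cl$clusters$cluster[1:20])), 1)
  expect_equal(length(unique(cl$clusters$cluster[21:40])), 1)
  cl2 <- cluster_embedding(emb, k = 2, seed = 1)
  expect_identical(cl$clusters, cl2$clusters)
  expect_error(cluster_embedding(emb, k = 50), "exceeds")
})

test_that("marker panels label clusters with the expected stages", {
  sim <- simulate_experiment(sim_config(n_cells = c(WT = 150),
                                        n_genes = 800, seed = 23,
                                        cycle_list_size = 250,
                                        hema_list_size = 150))
  sf <- size_factors(sim$counts)
  norm <- normalize_counts(sim$counts, sf)
  emb <- pca_embed(norm, sim$sets$cell_cycle)
  cl <- cluster_embedding(emb, k = 5, seed = 2)
  model <- assign_cluster_stages(emb, cl, norm)
  truth <- sim$truth$cells
  asg <- model$assignment$cells
  # the cluster dominated by true G0 cells must carry high Cdkn1c/Txnip
  # and the G0 label; the true-S-dominated cluster the S label
  for (st in c("G0/early-G1", "S")) {
    true_cells <- truth$cell_id[truth$stage == st]
    dominant <- names(which.max(table(
      asg$cluster[asg$cell_id %in% true_cells])))
    expect_equal(unname(model$cluster_stage[dominant]), st)
  }
  # occupancy fractions sum to 1 per group
  s <- dplyr::summarise(dplyr::group_by(model$assignment$occupancy, group),
                        total = sum(fraction))
  expect_equal(s$total, rep(1, nrow(s)))
})

test_that("small clusters are undetermined and stage scores drive labels", {
  # 3 crafted clusters: one big high-Cdkn1c/Txnip, one big high-Rrm2/Mcm,
  # one 3-cell cluster -> undetermined at min_cells_for_label = 5
  genes <- c("Cdkn1c", "Txnip", "Uhrf1", "Rrm2", "Mcm2", "Mcm5", "Mcm7",
             "Ccna2", "Ccnd2", "Ccne2", "Cdk2", "Ccnb2", "Cdk1", "Ccnf",
             "Prc1", "Plk1", "Mki67")
  n <- c(8, 8, 3)
  expr <- matrix(10, nrow = length(genes), ncol = sum(n),
                 dimnames = list(genes, paste0("c", seq_len(sum(n)))))
  g0 <- 1:8; sc <- 9:16; tiny <- 17:19
  expr[c("Cdkn1c", "Txnip"), g0] <- 100
  expr["Uhrf1", g0] <- 1
  expr[c("Rrm2", "Mcm2", "Mcm5", "Mcm7", "Ccna2", "Uhrf1"), sc] <- 100
  clusters <- structure(list(
    clusters = tibble::tibble(cell_id = colnames(expr),
                              cluster = rep(c("C1", "C2", "C3"), n)),
    centroids = matrix(0, 3, 2, dimnames = list(c("C1", "C2", "C3"), NULL)),
    hclust_agreement = NA_real_), class = "cluster_result")
  emb <- structure(list(scores = matrix(0, sum(n), 2,
                                        dimnames = list(colnames(expr), NULL)),
                        genes = genes), class = "pca_embedding")
  model <- suppressWarnings(assign_cluster_stages(emb, clusters, expr))
  expect_equal(unname(model$cluster_stage[c("C1", "C2", "C3")]),
               c("G0/early-G1", "S", "undetermined"))
})

test_that("projection returns reference cells to their own clusters", {
  sim <- simulate_experiment(sim_config(n_cells = c(WT = 80), n_genes = 800,
                                                              cycle_list_size = 250, hema_list_size = 150,
                                        seed = 29))
  sf <- size_factors(sim$counts)
  norm <- normalize_counts(sim$counts, sf)
  emb <- pca_embed(norm, sim$sets$cell_cycle)
  cl <- cluster_embedding(emb, k = 4, seed = 3)
  model <- assign_cluster_stages(emb, cl, norm)
  back <- project_and_classify(emb, model, norm)
  # nearest-centroid self-classification agrees with k-means for nearly
  # all cells (k-means boundaries are centroid-Voronoi up to convergence)
  agree <- mean(back$cells$cluster ==
                  cl$clusters$cluster[match(back$cells$cell_id,
                                            cl$clusters$cell_id)])
  expect_gte(agree, 0.95)
  expect_error(project_and_classify(emb, model,
                                    norm[seq_len(50), , drop = FALSE]),
               "overlap")
})

test_that("occupancy comparison matches exact hypergeometric enumeration", {
  a <- structure(list(cells = tibble::tibble(
    cell_id = paste0("a", 1:61), group = "KO",
    stage = rep(c("S", "G0/early-G1"), c(36, 25)))),
    class = "stage_assignment")
  b <- structure(list(cells = tibble::tibble(
    cell_id = paste0("b", 1:119), group = "WT",
    stage = rep(c("G2/M", "late-G1"), c(31, 88)))),
    class = "stage_assignment")
  cmp <- compare_occupancy(a, b, stages = c("S", "G2/M"))
  expect_equal(cmp$difference, 36 / 61 - 31 / 119, tolerance = 1e-12)
  expect_lt(abs(cmp$difference - 0.329), 0.001)
  expect_lt(cmp$p_value, 0.001)
  # oracle: two-sided Fisher p by direct enumeration of the 2x2 margin
  probs <- stats::dhyper(0:61, 67, 113, 61)
  p_exact <- sum(probs[probs <= stats::dhyper(36, 67, 113, 61) *
                         (1 + 1e-7)])
  expect_equal(cmp$p_value, p_exact, tolerance = 1e-9)

  same <- compare_occupancy(a, a)
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)

  # extreme split: all-in vs all-out equals the closed-form tail
  x <- structure(list(cells = tibble::tibble(
    cell_id = paste0("x", 1:5), group = "g1", stage = "S")),
    class = "stage_assignment")
  y <- structure(list(cells = tibble::tibble(
    cell_id = paste0("y", 1:5), group = "g2", stage = "G0/early-G1")),
    class = "stage_assignment")
  ext <- compare_occupancy(x, y, stages = "S")
  expect_equal(ext$p_value, 2 / choose(10, 5), tolerance = 1e-12)
})

test_that("transcriptional activity detects the planted KO scale-up", {
  cfg <- sim_config(n_cells = c(WT = 120, KO = 80), n_genes = 700,
                                                    cycle_list_size = 250, hema_list_size = 150,
                    activity_scale = 1.5, seed = 41)
  sim <- simulate_experiment(cfg)
  sf <- size_factors(sim$counts)
  truth <- sim$truth$cells
  asg <- structure(list(cells = tibble::tibble(
    cell_id = truth$cell_id, cluster = "C1", stage = truth$stage,
    group = truth$group)), class = "stage_assignment")
  act <- transcriptional_activity(sim$counts, sf, asg)
  cmp <- act$comparisons
  ko_vs_wt <- cmp[cmp$comparison == "S/G2/M: WT vs KO", ]
  expect_lt(ko_vs_wt$p_value, 0.01)
  expect_lt(ko_vs_wt$median_x, ko_vs_wt$median_y)  # KO higher
  # within KO, proliferative cells are the more active bin
  ko_bins <- cmp[cmp$comparison == "KO: S/G2/M vs G0/G1", ]
  expect_gt(ko_bins$median_x, ko_bins$median_y)
})

test_that("activity comparisons are calibrated under the null", {
  cfg <- sim_config(n_cells = c(A = 40, B = 40), n_genes = 700,
                                                 cycle_list_size = 250, hema_list_size = 150,
                    activity_scale = 1, ko_groups = "B",
                    lineage_prevalence = list(
                      A = c(lymphoid = 0.5, mega_erythroid = 0.2,
                            gran_mac = 0.1, none = 0.2),
                      B = c(lymphoid = 0.5, mega_erythroid = 0.2,
                            gran_mac = 0.1, none = 0.2)),
                    stage_occupancy = list(A = c(0.4, 0.1, 0.3, 0.2),
                                           B = c(0.4, 0.1, 0.3, 0.2)),
                    seed = 51)
  ps <- vapply(1:20, function(i) {
    cfg$seed <- 51 + i
    sim <- simulate_experiment(cfg)
    sf <- size_factors(sim$counts)
    truth <- sim$truth$cells
    asg <- structure(list(cells = tibble::tibble(
      cell_id = truth$cell_id, cluster = "C1", stage = truth$stage,
      group = truth$group)), class = "stage_assignment")
    act <- transcriptional_activity(sim$counts, sf, asg)
    act$comparisons$p_value[
      act$comparisons$comparison == "S/G2/M: A vs B"]
  }, 0)
  # no genotype effect planted: p should not pile up near 0
  expect_gt(mean(ps > 0.05), 0.6)
  expect_gt(min(ps), 1e-4)
})
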