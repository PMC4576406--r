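test_that("cycle-gene removal works and empty difference errors", {
  mat <- make_expr(matrix(rexp(40, 1 / 10), nrow = 4))
  expect_error(lineage_embed(mat, c("g1", "g2"), c("g1", "g2", "g3")),
               "fewer than 2")
  emb_a <- lineage_embed(mat, c("g1", "g2", "g3"), c("g4"))
  emb_b <- pca_embed(mat, c("g1", "g2", "g3"), anchor_genes = character())
  expect_equal(emb_a$loadings, emb_b$loadings)
  expect_equal(emb_a$scores, emb_b$scores)
})

test_that("subgroups recover planted lineages and order H1 by quiescence", {
  sim <- simulate_experiment(sim_config(seed = 9))
  sf <- size_factors(sim$counts)
  norm <- normalize_counts(sim$counts, sf)
  grp <- stats::setNames(sim$metadata$group, sim$metadata$cell_id)
  emb <- lineage_embed(norm, sim$sets$hematopoiesis, sim$sets$cell_cycle)
  sub <- subgroup_cells(emb, norm, k = 4, seed = 3, groups = grp)
  truth <- sim$truth$cells
  lin <- truth$lineage[match(sub$cells$cell_id, truth$cell_id)]
  expect_gte(mclust::adjustedRandIndex(sub$cells$subgroup, lin), 0.7)
  # H1 = most quiescent/lymphoid-competent-like subgroup
  h1_lin <- table(lin[sub$cells$subgroup == "H1"])
  expect_equal(names(which.max(h1_lin)), "lymphoid")
  # lineage embedding separates lineages while stages mix within subgroups
  sil <- cluster::silhouette(as.integer(factor(lin)),
                             stats::dist(emb$scores))
  expect_gte(mean(sil[, 3]), 0.3)
  stage <- truth$stage[match(sub$cells$cell_id, truth$cell_id)]
  expect_lt(mclust::adjustedRandIndex(sub$cells$subgroup, stage), 0.2)
})

test_that("reciprocal Gfi1/Gfi1b exclusion shows up across subgroups", {
  sim <- simulate_experiment(sim_config(seed = 9))
  sf <- size_factors(sim$counts)
  norm <- normalize_counts(sim$counts, sf)
  emb <- lineage_embed(norm, sim$sets$hematopoiesis, sim$sets$cell_cycle)
  sub <- subgroup_cells(emb, norm, k = 4, seed = 3)
  x <- log2(norm + 1)
  by_sub <- function(g) tapply(x[g, sub$cells$cell_id],
                               sub$cells$subgroup, mean)
  gfi1b <- by_sub("Gfi1b"); gfi1 <- by_sub("Gfi1")
  me_sub <- names(which.max(gfi1b))
  gm_sub <- names(which.max(gfi1))
  expect_false(me_sub == gm_sub)
  expect_lt(gfi1[me_sub], max(gfi1))   # Gfi1 low where Gfi1b peaks
  expect_lt(gfi1b[gm_sub], max(gfi1b))
})

test_that("identical cells yield a degenerate but non-crashing subgrouping", {
  mat <- make_expr(matrix(5, nrow = 6, ncol = 10))
  emb <- pca_embed(mat, rownames(mat), anchor_genes = character())
  w <- testthat::capture_warnings(
    sub <- subgroup_cells(emb, mat, k = 4, seed = 1))
  expect_true(any(grepl("distinct|degenerate", w)))
  expect_equal(nrow(sub$cells), 10)
})

test_that("subgrouping is invariant to gene and cell order", {
  sim <- simulate_experiment(sim_config(n_cells = c(WT = 60), n_genes = 700,
                                                              cycle_list_size = 250, hema_list_size = 150,
                                        seed = 13))
  sf <- size_factors(sim$counts)
  norm <- normalize_counts(sim$counts, sf)
  emb <- lineage_embed(norm, sim$sets$hematopoiesis, sim$sets$cell_cycle)
  sub <- subgroup_cells(emb, norm, k = 3, seed = 5)
  normp <- norm[sample(nrow(norm)), sample(ncol(norm))]
  embp <- lineage_embed(normp, sim$sets$hematopoiesis, sim$sets$cell_cycle)
  subp <- subgroup_cells(embp, normp, k = 3, seed = 5)
  idx <- match(sub$cells$cell_id, subp$cells$cell_id)
  expect_gte(mclust::adjustedRandIndex(sub$cells$subgroup,
                                       subp$cells$subgroup[idx]), 0.99)
})

test_that("planted anti-correlated regulator blocks split into two clusters", {
  withr::with_seed(7, {
    n <- 80
    driver <- rnorm(n)
    up <- t(vapply(1:4, function(i) 10 + 3 * driver + rnorm(n, 0, 1), numeric(n)))
    dn <- t(vapply(1:4, function(i) 10 - 3 * driver + rnorm(n, 0, 1), numeric(n)))
  })
  mat <- make_expr(rbind(up, dn), genes = paste0("r", 1:8))
  mat <- pmax(mat, 0)
  cc <- regulator_correlation_clusters(mat, paste0("r", 1:8))
  cl <- cc$clusters$cluster
  expect_equal(length(unique(cl[1:4])), 1)
  expect_equal(length(unique(cl[5:8])), 1)
  expect_false(cl[1] == cl[5])
  expect_lt(cc$summary$mean_between, 0)
  expect_gt(cc$summary$mean_within, 0.5)
})

test_that("constant regulators are dropped; one block stays non-negative", {
  withr::with_seed(8, {
    driver <- rnorm(50)
    block <- t(vapply(1:4, function(i) 10 + 2 * driver + rnorm(50, 0, 0.5),
                      numeric(50)))
  })
  mat <- make_expr(rbind(block, 3), genes = c(paste0("r", 1:4), "flat"))
  mat <- pmax(mat, 0)
  expect_warning(cc <- regulator_correlation_clusters(mat, rownames(mat)),
                 "constant")
  expect_false("flat" %in% cc$clusters$gene_id)
  expect_gte(cc$summary$mean_between, 0)
  expect_error(
    suppressWarnings(regulator_correlation_clusters(mat[1:2, ], rownames(mat)[1:2])),
    "3 usable")
})

test_that("Spearman matrix is invariant to monotone per-gene transforms", {
  withr::with_seed(9, {
    mat <- make_expr(matrix(rexp(5 * 40, 1 / 20), nrow = 5))
  })
  cc <- regulator_correlation_clusters(mat, rownames(mat))
  mat2 <- mat
  mat2[1, ] <- mat[1, ]^3          # monotone on expression scale
  mat2[2, ] <- 8 * mat[2, ] + 2
  cc2 <- regulator_correlation_clusters(mat2, rownames(mat2))
  expect_equal(cc$correlation, cc2$correlation, tolerance = 1e-12)
  # dendrogram serializes as newick
  path <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(cc, path)
  expect_match(readLines(path), "^\\(")
})
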