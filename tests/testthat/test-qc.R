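test_that("metrics use non-spike-in genes only and mito fraction is exact", {
  counts <- matrix(c(600000L, 50000L, 0L, 0L, 0L, 1000000L), nrow = 3,
                   dimnames = list(c("gA", "mt-1", "ERCC-00001"),
                                   c("good", "spikeonly")))
  m <- count_matrix(counts, is_mito = c(FALSE, TRUE, FALSE))
  qc <- compute_qc_metrics(m)
  expect_equal(qc$total_counts, c(650000, 0))
  expect_equal(qc$mito_fraction[1], 50000 / 650000)
  expect_equal(qc$genes_detected, c(2, 0))
  # a cell with only spike-in reads has zero annotated counts
  expect_equal(qc$total_counts[qc$cell_id == "spikeonly"], 0)
})

test_that("filters use strict inequalities exactly as stated", {
  qc <- tibble::tibble(
    cell_id = c("under", "boundary", "high_mito"),
    group = "WT",
    total_counts = c(499999, 600000, 700000),
    genes_detected = c(5000, 3000, 5000),
    mito_fraction = c(0.05, 0.10, 0.101),
    deletion_region_count = NA_integer_,
    capture_flag = "single")
  rep <- apply_qc_filters(qc, qc_thresholds())
  expect_equal(rep$keep, c(FALSE, TRUE, FALSE))
  expect_equal(rep$fail_reasons[1], "low_counts")
  expect_equal(rep$fail_reasons[3], "high_mito")
})

test_that("deletion screen applies only to listed groups; capture flags kill", {
  qc <- tibble::tibble(
    cell_id = c("ko_leak", "wt_expr", "multiplet"),
    group = c("KO", "WT", "WT"),
    total_counts = 1e6, genes_detected = 5000, mito_fraction = 0.01,
    deletion_region_count = c(5L, 5L, 0L),
    capture_flag = c("single", "single", "multiplet"))
  rep <- apply_qc_filters(qc, qc_thresholds(), "KO")
  expect_equal(rep$keep, c(FALSE, TRUE, FALSE))
  expect_equal(rep$fail_reasons[1], "deletion_region")
})

test_that("missing mito flags with the filter enabled is an error", {
  qc <- tibble::tibble(cell_id = "c", group = "WT", total_counts = 1e6,
                       genes_detected = 5000, mito_fraction = NA_real_,
                       deletion_region_count = NA_integer_,
                       capture_flag = "single")
  expect_error(apply_qc_filters(qc, qc_thresholds()), "mito")
  rep <- apply_qc_filters(qc, qc_thresholds(max_mito_fraction = 1))
  expect_true(rep$keep)
})

test_that("tightening any threshold never enlarges the kept set", {
  sim <- simulate_experiment(sim_config(n_cells = c(WT = 40), n_genes = 700,
                                                              cycle_list_size = 250, hema_list_size = 150,
                                        low_quality_fraction = 0.2,
                                        seed = 21))
  qc <- compute_qc_metrics(sim$counts, sim$metadata)
  base <- qc_thresholds(min_total_counts = 2000, min_genes_detected = 200,
                        max_mito_fraction = 0.1)
  kept0 <- qc_kept_cells(apply_qc_filters(qc, base))
  for (thr in list(
    qc_thresholds(min_total_counts = 4000, min_genes_detected = 200,
                  max_mito_fraction = 0.1),
    qc_thresholds(min_total_counts = 2000, min_genes_detected = 400,
                  max_mito_fraction = 0.1),
    qc_thresholds(min_total_counts = 2000, min_genes_detected = 200,
                  max_mito_fraction = 0.05))) {
    expect_true(all(qc_kept_cells(apply_qc_filters(qc, thr)) %in% kept0))
  }
})

test_that("planted QC failures are recovered with matching reasons", {
  sim <- simulate_experiment(sim_config(n_cells = c(WT = 60), n_genes = 700,
                                                              cycle_list_size = 250, hema_list_size = 150,
                                        low_quality_fraction = 0.25,
                                        seed = 8))
  qc <- compute_qc_metrics(sim$counts, sim$metadata)
  rep <- apply_qc_filters(qc, qc_thresholds(min_total_counts = 2000,
                                            min_genes_detected = 150,
                                            max_mito_fraction = 0.1))
  truth <- sim$truth$cells
  expect_identical(!rep$keep,
                   truth$low_quality[match(rep$cell_id, truth$cell_id)])
  expect_true(all(grepl("low_counts|few_genes|high_mito",
                        rep$fail_reasons[!rep$keep])))
})

test_that("PCA screen flags a planted outlier and spares homogeneous cells", {
  m <- make_sim_matrix(n_genes = 80, n_cells = 60, n_spike = 5, n_mito = 0,
                       mean_count = 100, seed = 5)
  screen <- pca_outlier_screen(m, k_mad = 6)
  expect_false(any(screen$outlier))

  counts <- m$counts
  counts[1:40, 1] <- counts[1:40, 1] + 3000L  # one wildly divergent cell
  m2 <- make_counts(counts, genes = gene_ids(m), cells = cell_ids(m))
  screen2 <- pca_outlier_screen(m2, k_mad = 6)
  expect_true(screen2$outlier[1])
  expect_equal(sum(screen2$outlier), 1)

  degenerate <- pca_outlier_screen(m, k_mad = 0)
  expect_gt(mean(degenerate$outlier), 0.5)
  expect_error(pca_outlier_screen(m, cells = cell_ids(m)[1:4]),
               "at least 5")
})
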