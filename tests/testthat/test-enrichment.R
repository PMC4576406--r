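# independent brute-force running-sum oracle: explicit loop over the list
brute_force_es <- function(metric, is_hit, weight_p = 1) {
  n <- length(metric)
  nh <- sum(is_hit)
  wsum <- sum(abs(metric[is_hit])^weight_p)
  rs <- 0; best <- 0
  for (i in seq_len(n)) {
    if (is_hit[i]) {
      rs <- rs + (if (wsum > 0) abs(metric[i])^weight_p / wsum else 1 / nh)
    } else {
      rs <- rs - 1 / (n - nh)
    }
    if (abs(rs) > abs(best) ||
        (abs(rs) == abs(best) && rs > best)) best <- rs
  }
  best
}

test_that("signal-to-noise ranking applies the variance floor", {
  mk <- function(a_vals, b_vals) {
    mat <- rbind(g = c(a_vals, b_vals))
    colnames(mat) <- paste0("c", seq_len(ncol(mat)))
    rank_genes_s2n(mat, rep(c("A", "B"), c(length(a_vals), length(b_vals))))
  }
  # equal class means -> 0
  expect_equal(mk(c(3, 4, 5), c(5, 4, 3))$metric, 0)
  # means (4, 2), sds (1, 1) -> 1.0
  r <- mk(c(3, 4, 5), c(1, 2, 3))
  expect_equal(r$metric, 1)
  # zero-variance classes: floors 0.2*|mean| and 0.2 for a zero mean
  r2 <- mk(c(1, 1, 1), c(0, 0, 0))
  expect_equal(r2$metric, (1 - 0) / (0.2 * 1 + 0.2))
  expect_error(mk(c(1, 2), c(1, 2, 3)), "3 cells")
})

test_that("ranking is descending with lexicographic tie-break", {
  mat <- rbind(zeb = c(0, 0, 0, 5, 5, 5), abc = c(0, 0, 0, 5, 5, 5),
               top = c(9, 9, 9, 0, 0, 0))
  colnames(mat) <- paste0("c", 1:6)
  r <- rank_genes_s2n(mat, rep(c("A", "B"), each = 3))
  expect_equal(r$gene_id, c("top", "abc", "zeb"))
})

test_that("enrichment score handles the textbook edge cases", {
  ranked <- tibble::tibble(gene_id = paste0("g", 1:10),
                           metric = seq(5, -4, length.out = 10))
  # unweighted, single top-ranked hit: running sum reaches exactly 1
  es <- enrichment_score(ranked, "g1", weight_p = 0)
  expect_equal(es$es, 1)
  expect_equal(es$leading_edge, "g1")
  # hits concentrated at the bottom give a negative score
  expect_lt(enrichment_score(ranked, c("g9", "g10"))$es, 0)
  expect_error(enrichment_score(ranked, "absent"), "no members")
  expect_error(enrichment_score(ranked, ranked$gene_id), "whole")
})

test_that("ES equals the brute-force oracle on 100 random instances", {
  withr::with_seed(123, {
    for (i in 1:100) {
      n <- 20
      metric <- sort(rnorm(n), decreasing = TRUE)
      ranked <- tibble::tibble(gene_id = sprintf("g%02d", 1:n),
                               metric = metric)
      hit_idx <- sample(n, 5)
      set <- ranked$gene_id[hit_idx]
      es <- enrichment_score(ranked, set, weight_p = 1)$es
      oracle <- brute_force_es(metric, seq_len(n) %in% hit_idx, 1)
      expect_equal(es, oracle, tolerance = 1e-12)
      # the fast hit-position path used for permutations must agree too
      fast <- hsccycle:::.es_fast(metric, sort(hit_idx), n, 1)
      expect_equal(fast, oracle, tolerance = 1e-12)
    }
  })
})

test_that("unweighted ES is invariant under monotone metric transforms", {
  withr::with_seed(5, {
    metric <- sort(rexp(15), decreasing = TRUE)
  })
  ranked <- tibble::tibble(gene_id = sprintf("g%02d", 1:15), metric = metric)
  ranked2 <- dplyr::mutate(ranked, metric = log1p(.data$metric) * 3)
  set <- c("g02", "g03", "g09")
  expect_equal(enrichment_score(ranked, set, weight_p = 0)$es,
               enrichment_score(ranked2, set, weight_p = 0)$es)
})

test_that("gsea is deterministic, signed and significant when planted", {
  sim <- simulate_experiment(sim_config(n_cells = c(WT = 40, KO = 30),
                                        n_genes = 700, seed = 61,
                                        cycle_list_size = 250,
                                        hema_list_size = 150))
  sf <- size_factors(sim$counts)
  norm <- normalize_counts(sim$counts, sf)
  bio <- norm[!sim$counts$is_spikein, ]
  labs <- sim$metadata$group[match(colnames(bio), sim$metadata$cell_id)]
  sig <- gene_sets(unclass(sim$sets)[c("lymphoid_signature",
                                       "mega_erythroid_signature")])
  res <- gsea(bio, labs, sig, n_perm = 200, seed = 7)
  res2 <- gsea(bio, labs, sig, n_perm = 200, seed = 7)
  expect_equal(res$p_value, res2$p_value)
  expect_equal(res$nes, res2$nes)
  # lymphoid program silenced in KO -> enriched toward the first class
  first <- attr(res, "classes")[1]
  lym <- res[res$set == "lymphoid_signature", ]
  if (first == "WT") expect_gt(lym$es, 0) else expect_lt(lym$es, 0)
  expect_lt(lym$p_value, 0.05)
  expect_true(all(sign(res$nes) == sign(res$es)))
  expect_true(all(abs(res$es) <= 1))
  expect_error(gsea(bio, labs, sig, n_perm = 50), "100")
})

test_that("ORA matches choose()-based enumeration and handles edges", {
  # universe 20, set 5, selected 5, overlap 4:
  # p = (C(5,4) C(15,1) + C(5,5) C(15,0)) / C(20,5) = 76/15504
  universe <- paste0("u", 1:20)
  set5 <- universe[1:5]
  selected <- c(universe[1:4], universe[20])
  res <- ora_hypergeometric(selected, universe,
                            gene_sets(list(s = set5)))
  expect_equal(res$overlap, 4)
  expect_equal(res$p_value, 76 / 15504, tolerance = 1e-12)

  none <- ora_hypergeometric(universe[16:20], universe,
                             gene_sets(list(s = universe[1:5])))
  expect_equal(none$p_value, 1)

  all_sel <- ora_hypergeometric(universe, universe,
                                gene_sets(list(s = set5)))
  expect_equal(all_sel$overlap, 5)
  expect_equal(all_sel$p_value, 1)

  expect_error(ora_hypergeometric(c("u1", "ghost"), universe,
                                  gene_sets(list(s = set5))), "outside")
})

test_that("ORA p equals full enumeration on random small instances", {
  enum_p <- function(U, S, n_sel, k) {
    tot <- choose(U, n_sel)
    sum(vapply(k:min(S, n_sel), function(j) {
      choose(S, j) * choose(U - S, n_sel - j)
    }, 0)) / tot
  }
  withr::with_seed(11, {
    for (i in 1:50) {
      U <- sample(5:25, 1)
      S <- sample(1:U, 1)
      n_sel <- sample(1:U, 1)
      universe <- paste0("u", seq_len(U))
      set <- sample(universe, S)
      selected <- sample(universe, n_sel)
      k <- length(intersect(set, selected))
      res <- ora_hypergeometric(selected, universe,
                                gene_sets(list(s = set)))
      expect_equal(res$p_value, enum_p(U, S, n_sel, k), tolerance = 1e-12)
    }
  })
})
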