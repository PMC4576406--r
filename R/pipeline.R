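#' Configuration for an end-to-end pipeline run
#'
#' Bundles the per-stage parameter blocks and stage toggles. All
#' randomness derives from one root seed: each stage's seed is the root
#' seed plus a stable hash of the stage name, so toggling one stage never
#' changes another stage's draws. Unknown keys are rejected.
#'
#' @param sim A [sim_config()] (its own seed is re-derived from
#'   `root_seed`).
#' @param qc A [qc_thresholds()]. The defaults mirror a deeply sequenced
#'   study; desk-scale synthetic runs want far smaller cutoffs.
#' @param deletion_screen_groups Groups subject to the deletion-region
#'   screen (default the sim config's knockout groups).
#' @param hvg List: `min_biol_cv`, `padj_threshold`.
#' @param cycle List: `k`, `n_components`, `min_cells_for_label`,
#'   `reference_group` (the group whose cells train the embedding;
#'   default the first non-knockout group), `proliferative_stages`.
#' @param lineage List: `k`, `n_components`.
#' @param gsea_params List: `n_perm`, `weight_p`, `set_names` (which
#'   emitted signature sets to test; default the lineage signatures).
#' @param stages Character vector of enabled stages, a subset of
#'   `c("qc", "hvg", "cycle", "lineage", "gsea")` (simulation and
#'   normalization always run).
#' @param root_seed Integer root seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       qc = qc_thresholds(min_total_counts = 5000,
                                          min_genes_detected = 500,
                                          max_mito_fraction = 0.10),
                       deletion_screen_groups = NULL,
                       hvg = list(min_biol_cv = 0.5, padj_threshold = 0.1),
                       cycle = list(k = 5, n_components = 2,
                                    min_cells_for_label = 5,
                                    reference_group = NULL,
                                    proliferative_stages = c("S", "G2/M")),
                       lineage = list(k = 4, n_components = 2),
                       gsea_params = list(n_perm = 1000, weight_p = 1,
                                          set_names = NULL),
                       stages = c("qc", "hvg", "cycle", "lineage", "gsea"),
                       root_seed = 1L) {
  known <- c("qc", "hvg", "cycle", "lineage", "gsea")
  unknown <- setdiff(stages, known)
  if (length(unknown)) stop("unknown stages: ", paste(unknown, collapse = ", "))
  if (is.null(deletion_screen_groups)) {
    deletion_screen_groups <- intersect(sim$ko_groups, names(sim$n_cells))
  }
  structure(list(sim = sim, qc = qc,
                 deletion_screen_groups = deletion_screen_groups,
                 hvg = hvg, cycle = cycle, lineage = lineage,
                 gsea_params = gsea_params, stages = stages,
                 root_seed = as.integer(root_seed)),
            class = "run_config")
}

#' Derive a per-stage seed from the root seed
#'
#' Stable polynomial hash of the stage name folded into the root seed,
#' kept inside the 32-bit integer range.
#'
#' @param root_seed Integer root seed.
#' @param stage Stage name.
#' @return An integer seed.
#' @export
stage_seed <- function(root_seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1e6
  as.integer((as.numeric(root_seed) * 1013 + h) %% .Machine$integer.max)
}

#' Run the full pipeline on a synthetic experiment
#'
#' Simulates data, applies cell QC, computes size factors and the
#' normalized matrix, fits the technical-noise law and tests variable
#' genes, reconstructs cell-cycle stages on the reference group and
#' projects the remaining groups, subgroups cells on hematopoietic genes
#' and runs lineage-signature GSEA between the first two groups. Stage
#' outputs are written as TSV under `outdir` and checksummed into the
#' returned manifest; a stage failure halts the run with an error naming
#' the stage.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if missing); `NULL` keeps
#'   everything in memory.
#' @return A list of class `run_manifest`: `config_hash`,
#'   `package_version`, `stages` (tibble: stage, status, note, elapsed
#'   seconds), `files` (tibble: file, md5), and `results` (the in-memory
#'   stage outputs).
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  results <- list()
  stage_log <- list()
  files <- character()
  emit <- function(tab, name) {
    if (!is.null(outdir)) {
      path <- file.path(outdir, paste0(name, ".tsv"))
      write_results(tab, path)
      files <<- c(files, path)
    }
  }
  log_stage <- function(stage, note, t_start) {
    stage_log[[length(stage_log) + 1]] <<- tibble::tibble(
      stage = stage, status = "ok", note = note,
      elapsed = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  }
  run_stage <- function(stage, fn) {
    t_start <- Sys.time()
    tryCatch(fn(t_start), error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }

  # simulate ----
  run_stage("simulate", function(ts) {
    cfg <- config$sim
    cfg$seed <- stage_seed(config$root_seed, "simulate")
    results$sim <<- simulate_experiment(cfg)
    log_stage("simulate", sprintf("%d genes x %d cells",
                                  nrow(results$sim$counts$counts),
                                  ncol(results$sim$counts$counts)), ts)
  })
  sim <- results$sim
  groups_vec <- stats::setNames(sim$metadata$group, sim$metadata$cell_id)

  # qc ----
  m <- sim$counts
  if ("qc" %in% config$stages) {
    run_stage("qc", function(ts) {
      metrics <- compute_qc_metrics(sim$counts, sim$metadata)
      report <- apply_qc_filters(metrics, config$qc,
                                 config$deletion_screen_groups)
      kept <- qc_kept_cells(report)
      if (length(kept) == 0L) stop("0 cells pass the QC filters")
      if (length(kept) >= 5L && config$qc$outlier_mad_k > 0) {
        screen <- pca_outlier_screen(sim$counts, kept,
                                     config$qc$outlier_mad_k)
        kept <- setdiff(kept, screen$cell_id[screen$outlier])
        results$pca_screen <<- screen
      }
      results$qc <<- report
      results$kept_cells <<- kept
      emit(report, "qc_report")
      log_stage("qc", sprintf("%d/%d cells kept", length(kept),
                              nrow(report)), ts)
    })
    m <- subset_cells(sim$counts, results$kept_cells)
  }

  # normalize ----
  run_stage("normalize", function(ts) {
    sf <- size_factors(m)
    results$size_factors <<- sf
    results$norm <<- normalize_counts(m, sf)
    emit(tidy(sf), "size_factors")
    log_stage("normalize", sprintf("%d cells", length(sf$cell)), ts)
  })
  norm <- results$norm
  sf <- results$size_factors

  # hvg ----
  if ("hvg" %in% config$stages) {
    run_stage("hvg", function(ts) {
      fit <- fit_technical_noise(norm[m$is_spikein, , drop = FALSE], sf)
      tab <- test_highly_variable(norm[!m$is_spikein, , drop = FALSE], fit,
                                  min_biol_cv = config$hvg$min_biol_cv,
                                  padj_threshold = config$hvg$padj_threshold)
      results$noise_fit <<- fit
      results$hvg <<- tab
      emit(tab, "hvg_table")
      log_stage("hvg", sprintf("%d highly variable genes",
                               sum(tab$highly_variable)), ts)
    })
  }

  # cycle ----
  if ("cycle" %in% config$stages) {
    run_stage("cycle", function(ts) {
      ref_group <- config$cycle$reference_group
      if (is.null(ref_group)) {
        ref_group <- setdiff(unique(sim$metadata$group),
                             config$sim$ko_groups)[1]
        if (is.na(ref_group)) ref_group <- unique(sim$metadata$group)[1]
      }
      ref_cells <- intersect(colnames(norm),
                             names(groups_vec)[groups_vec == ref_group])
      other_cells <- setdiff(colnames(norm), ref_cells)
      cyc_genes <- sim$sets$cell_cycle
      emb <- pca_embed(norm[, ref_cells, drop = FALSE], cyc_genes,
                       config$cycle$n_components)
      cl <- cluster_embedding(emb, k = config$cycle$k,
                              seed = stage_seed(config$root_seed, "cycle"))
      model <- assign_cluster_stages(
        emb, cl, norm[, ref_cells, drop = FALSE],
        groups = groups_vec,
        min_cells_for_label = config$cycle$min_cells_for_label)
      assignment <- model$assignment
      if (length(other_cells)) {
        proj <- project_and_classify(emb, model,
                                     norm[, other_cells, drop = FALSE],
                                     groups = groups_vec)
        assignment <- bind_assignments(model$assignment, proj)
      }
      results$embedding <<- emb
      results$stage_model <<- model
      results$stage_assignment <<- assignment
      results$activity <<- transcriptional_activity(m, sf, assignment)
      emit(assignment$cells, "stage_assignment")
      emit(assignment$occupancy, "stage_occupancy")
      log_stage("cycle", sprintf("%d cells staged (ref group %s)",
                                 nrow(assignment$cells), ref_group), ts)
    })
  }

  # lineage ----
  if ("lineage" %in% config$stages) {
    run_stage("lineage", function(ts) {
      emb <- lineage_embed(norm, sim$sets$hematopoiesis,
                           sim$sets$cell_cycle,
                           config$lineage$n_components)
      sub <- subgroup_cells(
        emb, norm, k = config$lineage$k,
        seed = stage_seed(config$root_seed, "lineage"),
        groups = groups_vec,
        stage_assignment = results$stage_assignment)
      results$lineage_embedding <<- emb
      results$subgroups <<- sub
      results$regulator_clusters <<- tryCatch(
        regulator_correlation_clusters(norm),
        error = function(e) NULL)
      emit(sub$cells, "subgroups")
      log_stage("lineage", sprintf("%d subgroups",
                                   dplyr::n_distinct(sub$cells$subgroup)), ts)
    })
  }

  # gsea ----
  if ("gsea" %in% config$stages) {
    run_stage("gsea", function(ts) {
      grps <- unique(groups_vec[colnames(norm)])
      if (length(grps) < 2) {
        log_stage("gsea", "skipped: fewer than 2 groups", ts)
        return(invisible())
      }
      set_names <- config$gsea_params$set_names
      if (is.null(set_names)) {
        set_names <- grep("_signature$", names(sim$sets), value = TRUE)
      }
      lab <- groups_vec[colnames(norm)]
      two <- lab %in% grps[1:2]
      res <- gsea(norm[!m$is_spikein, two, drop = FALSE], lab[two],
                  gene_sets(unclass(sim$sets)[set_names]),
                  n_perm = config$gsea_params$n_perm,
                  weight_p = config$gsea_params$weight_p,
                  seed = stage_seed(config$root_seed, "gsea"))
      results$gsea <<- res
      emit(tidy(res), "gsea")
      log_stage("gsea", sprintf("%d sets tested (%s vs %s)", nrow(res),
                                grps[1], grps[2]), ts)
    })
  }

  file_tab <- tibble::tibble(file = basename(files),
                             md5 = unname(tools::md5sum(files)))
  structure(list(
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("hsccycle")),
    stages = dplyr::bind_rows(stage_log),
    files = file_tab,
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    results = results),
    class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> config %s, version %s, %.1fs\n",
              substr(x$config_hash, 1, 8), x$package_version, x$elapsed))
  print(x$stages)
  invisible(x)
}
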