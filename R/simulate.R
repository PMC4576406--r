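#' Default cell-cycle stage names, in cycle order
#' @return Character vector of the four transcriptomic stages.
#' @export
stage_levels <- function() c("G0/early-G1", "late-G1", "S", "G2/M")

#' Default stage marker panels
#'
#' Marker panels used to label clusters with cell-cycle stages: quiescent
#' cells express the CDK inhibitor Cdkn1c (p57) and the G1-arrest factor
#' Txnip while lacking the G1/S licensing regulator Uhrf1; late G1 is
#' marked by cyclin D/E with Cdk2; S phase by ribonucleotide reductase
#' (Rrm2), MCM replication-licensing factors and cyclin A; G2/M by cyclin
#' B, Cdk1 and mitotic genes (Prc1, Plk1, Mki67). Each panel has `high`
#' and optional `low` members; `low` genes contribute with negated sign.
#'
#' @return A named list (one element per stage) of lists with `high` and
#'   `low` character vectors.
#' @export
default_stage_panels <- function() {
  list(
    "G0/early-G1" = list(high = c("Cdkn1c", "Txnip"), low = "Uhrf1"),
    "late-G1" = list(high = c("Ccnd2", "Ccne2", "Cdk2"), low = character()),
    "S" = list(high = c("Rrm2", "Mcm2", "Mcm5", "Mcm7", "Ccna2", "Uhrf1"),
               low = character()),
    "G2/M" = list(high = c("Ccnb2", "Cdk1", "Ccnf", "Prc1", "Plk1", "Mki67"),
                  low = character()))
}

#' Default transcriptional-regulator list for co-expression clustering
#' @return Character vector of regulator gene symbols.
#' @export
default_regulators <- function() {
  c("Bcl11a", "Egr1", "Fos", "Jun", "Mecom", "Meis1", "Hlf", "Nr4a1",
    "Hes1", "Tcf7l2", "Id1", "Id3", "Gfi1", "Gfi1b", "Cebpa", "Klf1",
    "Mpo", "Csf1r", "Epor", "Itga2b")
}

.lineage_markers <- function() {
  list(
    lymphoid = c("Bcl11a", "Egr1", "Jun", "Mecom", "Hlf", "Flt3", "Dntt"),
    mega_erythroid = c("Epor", "Selp", "Gp9", "Gfi1b", "Itga2b", "Klf1"),
    gran_mac = c("Mpo", "Cebpa", "Gfi1", "Csf1r", "Elane"))
}

.mito_gene_names <- function() {
  paste0("mt-", c("Nd1", "Nd2", "Co1", "Co2", "Atp8", "Atp6", "Co3",
                  "Nd3", "Nd4l", "Nd4", "Nd5", "Nd6", "Cytb"))
}

#' Configuration for the synthetic single-cell experiment
#'
#' Declares the study conditions the generator plants: group sizes,
#' per-group cell-cycle stage occupancy, stage and lineage expression
#' programs, a set of highly variable genes with known biological CV,
#' library-size variation, and the spike-in technical-noise law
#' (`CV2 = a1 / mu + alpha0`). The default occupancy for the wild-type
#' group follows the observed staging of 117 assignable HSCs
#' (72/14/21/10 across G0/early-G1, late-G1, S, G2/M); the knockout
#' default shifts mass into S and G2/M so that the proliferative
#' fraction is 0.59, silences the lymphoid lineage program, and scales
#' up total transcription of proliferative cells.
#'
#' @param n_cells Named integer vector of cells per group, e.g.
#'   `c(WT = 119, KO = 61)`.
#' @param n_genes Number of biological genes (>= 400).
#' @param n_spikeins Number of spike-in species (default 92).
#' @param stage_occupancy Named list (one per group) of probability
#'   vectors over [stage_levels()]; each must sum to 1.
#' @param stage_lfc log2 fold-change of stage-program genes in their
#'   stage (default 2.5).
#' @param n_stage_extra Filler genes added to each stage program beyond
#'   the named markers (default 30).
#' @param lineage_prevalence Named list (one per group) of probability
#'   vectors over lymphoid / mega_erythroid / gran_mac / none.
#' @param lineage_lfc log2 fold-change of lineage-program genes (default
#'   2.5).
#' @param n_lineage_extra Filler genes per lineage program (default 25).
#' @param n_hv_genes Genes given extra biological dispersion (default 300).
#' @param hv_bio_cv Biological coefficient of variation of those genes
#'   (default 1).
#' @param libsize_meanlog,libsize_sdlog Log-normal library-size-factor
#'   parameters (default 0, 0.25).
#' @param base_meanlog,base_sdlog Log-normal baseline gene-mean
#'   parameters (default 3, 1).
#' @param spikein_pool Per-species true abundance; default a geometric
#'   ladder spanning `2^-2 .. 2^13`, mimicking a serial-dilution mix.
#' @param spikein_a1,spikein_alpha0 Planted technical-noise law on the
#'   spike-ins (defaults 1 = pure shot noise, and 0.05).
#' @param capture_efficiency_sd sdlog of the per-cell spike-in capture
#'   efficiency (default 0.25).
#' @param cycle_list_size,hema_list_size Sizes of the emitted cell-cycle
#'   and hematopoietic gene lists (defaults 600 and 300); program genes
#'   are always included, the remainder are unperturbed genes.
#' @param hema_cycle_overlap Cycle-program genes also placed on the
#'   hematopoietic list (default 20), exercising the cycle-gene removal
#'   step of the lineage embedding.
#' @param mito_fraction Expected mitochondrial fraction of a healthy cell
#'   (default 0.04).
#' @param activity_scale Transcriptional-activity multiplier applied to
#'   proliferative (S, G2/M) cells of `ko_groups` (default 1.5); set to 1
#'   to switch the effect off.
#' @param ko_groups Groups treated as knockout for the lymphoid-deletion /
#'   activity effects and the deletion-region screen (default `"KO"`,
#'   ignored if absent from `n_cells`).
#' @param deletion_region_mean Mean read count over the screened deletion
#'   region in cells that still carry it (default 20).
#' @param deletion_leak_fraction Fraction of knockout cells with residual
#'   (incomplete-deletion) reads (default 0).
#' @param low_quality_fraction Fraction of cells planted as QC failures
#'   (shrunken library, inflated mitochondrial load; default 0).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cells = c(WT = 119, KO = 61),
                       n_genes = 2000,
                       n_spikeins = 92,
                       stage_occupancy = NULL,
                       stage_lfc = 2.5,
                       n_stage_extra = 30,
                       lineage_prevalence = NULL,
                       lineage_lfc = 2.5,
                       n_lineage_extra = 25,
                       n_hv_genes = 300,
                       hv_bio_cv = 1,
                       libsize_meanlog = 0,
                       libsize_sdlog = 0.25,
                       base_meanlog = 3,
                       base_sdlog = 1,
                       spikein_pool = NULL,
                       spikein_a1 = 1,
                       spikein_alpha0 = 0.05,
                       capture_efficiency_sd = 0.25,
                       cycle_list_size = 600,
                       hema_list_size = 300,
                       hema_cycle_overlap = 20,
                       mito_fraction = 0.04,
                       activity_scale = 1.5,
                       ko_groups = "KO",
                       deletion_region_mean = 20,
                       deletion_leak_fraction = 0,
                       low_quality_fraction = 0,
                       seed = 1L) {
  if (is.null(names(n_cells)) || any(!nzchar(names(n_cells)))) {
    stop("n_cells must be a named vector of group sizes")
  }
  groups <- names(n_cells)
  wt_occ <- c(72, 14, 21, 10) / 117
  ko_occ <- c(0.26, 0.15, 0.34, 0.25)
  if (is.null(stage_occupancy)) {
    stage_occupancy <- lapply(groups, function(g) {
      if (g %in% ko_groups) ko_occ else wt_occ
    })
    names(stage_occupancy) <- groups
  }
  for (g in groups) {
    occ <- stage_occupancy[[g]]
    if (is.null(occ)) stop("no stage occupancy for group '", g, "'")
    if (length(occ) != 4L) stop("stage occupancy must have 4 entries")
    if (abs(sum(occ) - 1) > 1e-8) {
      stop("stage occupancy for group '", g, "' sums to ", sum(occ),
           ", not 1")
    }
  }
  if (is.null(lineage_prevalence)) {
    lineage_prevalence <- lapply(groups, function(g) {
      if (g %in% ko_groups) {
        c(lymphoid = 0, mega_erythroid = 0.45, gran_mac = 0.35, none = 0.20)
      } else {
        c(lymphoid = 0.45, mega_erythroid = 0.20, gran_mac = 0.15,
          none = 0.20)
      }
    })
    names(lineage_prevalence) <- groups
  }
  for (g in groups) {
    prev <- lineage_prevalence[[g]]
    if (abs(sum(prev) - 1) > 1e-8) {
      stop("lineage prevalence for group '", g, "' must sum to 1")
    }
  }
  if (is.null(spikein_pool)) {
    spikein_pool <- 2^seq(-2, 13, length.out = n_spikeins)
  }
  if (length(spikein_pool) != n_spikeins) {
    stop("spikein_pool must have n_spikeins entries")
  }
  if (spikein_a1 < 1) stop("spikein_a1 must be >= 1 (Poisson limit is 1)")
  n_stage_prog <- length(unlist(lapply(default_stage_panels(), `[[`, "high"))) +
    4L * n_stage_extra
  n_lin_prog <- length(unlist(.lineage_markers())) + 3L * n_lineage_extra
  n_program <- n_stage_prog + n_lin_prog + length(.mito_gene_names())
  # the emitted lists pad with disjoint unperturbed filler genes, which must
  # not collide with the variable-gene block
  n_cyc_null <- max(0L, cycle_list_size - n_stage_prog)
  n_hema_null <- max(0L, hema_list_size - n_lin_prog -
                       min(hema_cycle_overlap, n_stage_prog))
  n_needed <- n_program + n_hv_genes + n_cyc_null + n_hema_null
  if (n_genes < n_needed) {
    stop("n_genes too small: need at least ", n_needed,
         " for the configured programs, variable genes and list padding")
  }
  structure(mget(names(formals()), envir = environment()),
            class = "sim_config")
}

# deterministic gene layout for a config: names, program membership, flags
.sim_gene_layout <- function(cfg) {
  panels <- default_stage_panels()
  stage_genes <- lapply(stage_levels(), function(s) {
    safe <- gsub("[^A-Za-z0-9]+", ".", s)
    c(panels[[s]]$high,
      sprintf("cyc%s_%03d", safe, seq_len(cfg$n_stage_extra)))
  })
  names(stage_genes) <- stage_levels()
  lin_markers <- .lineage_markers()
  lineage_genes <- lapply(names(lin_markers), function(l) {
    c(lin_markers[[l]], sprintf("lin%s_%03d", l, seq_len(cfg$n_lineage_extra)))
  })
  names(lineage_genes) <- names(lin_markers)
  mito <- .mito_gene_names()
  named <- c(unlist(stage_genes), unlist(lineage_genes), mito)
  n_fill <- cfg$n_genes - length(named)
  filler <- sprintf("gene_%05d", seq_len(n_fill))
  genes <- c(unname(unlist(stage_genes)), unname(unlist(lineage_genes)),
             mito, filler)
  hv <- filler[seq_len(cfg$n_hv_genes)]
  list(genes = genes, stage_genes = stage_genes,
       lineage_genes = lineage_genes, mito = mito, filler = filler,
       hv = hv)
}

#' Simulate a spike-in-calibrated single-cell experiment
#'
#' Draws a gene-by-cell count matrix with planted structure: per-cell
#' cell-cycle stage (stage-program genes up-regulated in their stage),
#' per-cell lineage priming (lymphoid / mega-erythroid /
#' granulocyte-macrophage programs), a genotype effect (occupancy shift,
#' lymphoid deletion, activity scale-up in proliferative knockout cells),
#' log-normal library sizes, genes with known biological dispersion, and
#' ERCC-style spike-ins obeying `CV2 = a1 / mu + alpha0` across cells.
#' Biological counts are negative-binomial around
#' `mu_ij = base_i x stage/lineage folds x libsize_j` with per-gene
#' dispersion equal to the squared biological CV (Poisson when 0);
#' spike-ins are drawn from a fixed pool times a per-cell capture
#' efficiency, with over-dispersion planting `a1` and a multiplicative
#' noise floor planting `alpha0`.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_experiment` with elements
#'   \describe{
#'     \item{counts}{the [count_matrix()] (spike-in and mito rows flagged);}
#'     \item{metadata}{a [cell_metadata()] tibble (group, deletion-region
#'       count, capture flag);}
#'     \item{truth}{ground truth: `cells` (stage, lineage, group, library
#'       size factor, planted QC failure) and `genes` (baseline mean,
#'       biological CV, program memberships) tibbles plus the planted
#'       noise-law parameters;}
#'     \item{sets}{a [gene_sets()] collection naming the planted cycle
#'       list, hematopoietic list, per-stage programs and lineage
#'       signatures.}
#'   }
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  withr::with_seed(cfg$seed, .simulate_experiment_impl(cfg))
}

.simulate_experiment_impl <- function(cfg) {
  lay <- .sim_gene_layout(cfg)
  genes <- lay$genes
  n_genes <- length(genes)
  groups <- names(cfg$n_cells)
  n_total <- sum(cfg$n_cells)
  cell_group <- rep(groups, cfg$n_cells)
  cell_id <- sprintf("%s_c%03d", cell_group,
                     unlist(lapply(cfg$n_cells, seq_len)))

  # per-cell truth draws
  stages <- unlist(lapply(groups, function(g) {
    sample(stage_levels(), cfg$n_cells[[g]], replace = TRUE,
           prob = cfg$stage_occupancy[[g]])
  }))
  lineages <- unlist(lapply(groups, function(g) {
    prev <- cfg$lineage_prevalence[[g]]
    sample(names(prev), cfg$n_cells[[g]], replace = TRUE, prob = prev)
  }))
  libsize <- stats::rlnorm(n_total, cfg$libsize_meanlog, cfg$libsize_sdlog)
  low_q <- stats::runif(n_total) < cfg$low_quality_fraction

  # per-gene baselines; mitochondrial genes rescaled to the target fraction
  base <- stats::rlnorm(n_genes, cfg$base_meanlog, cfg$base_sdlog)
  names(base) <- genes
  program_genes <- c(unlist(lay$stage_genes), unlist(lay$lineage_genes))
  base[program_genes] <- stats::rlnorm(length(program_genes),
                                       cfg$base_meanlog, 0.5)
  is_mito <- genes %in% lay$mito
  mito_target <- cfg$mito_fraction / (1 - cfg$mito_fraction) *
    sum(base[!is_mito])
  base[is_mito] <- base[is_mito] * mito_target / sum(base[is_mito])

  bio_cv <- stats::setNames(rep(0, n_genes), genes)
  bio_cv[lay$hv] <- cfg$hv_bio_cv

  stage_of_gene <- stats::setNames(rep(NA_character_, n_genes), genes)
  for (s in stage_levels()) stage_of_gene[lay$stage_genes[[s]]] <- s
  lineage_of_gene <- stats::setNames(rep(NA_character_, n_genes), genes)
  for (l in names(lay$lineage_genes)) {
    lineage_of_gene[lay$lineage_genes[[l]]] <- l
  }

  # mean matrix: baseline x stage fold x lineage fold x libsize x effects
  mu <- matrix(base, nrow = n_genes, ncol = n_total)
  stage_fold <- 2^cfg$stage_lfc
  lineage_fold <- 2^cfg$lineage_lfc
  for (j in seq_len(n_total)) {
    sg <- lay$stage_genes[[stages[j]]]
    mu[match(sg, genes), j] <- mu[match(sg, genes), j] * stage_fold
    if (lineages[j] != "none") {
      lg <- lay$lineage_genes[[lineages[j]]]
      mu[match(lg, genes), j] <- mu[match(lg, genes), j] * lineage_fold
    }
  }
  act <- rep(1, n_total)
  prolif <- stages %in% c("S", "G2/M")
  act[prolif & cell_group %in% cfg$ko_groups] <- cfg$activity_scale
  lib_eff <- libsize * act
  lib_eff[low_q] <- lib_eff[low_q] * 0.03
  mu <- sweep(mu, 2, lib_eff, `*`)
  # planted QC failures also carry a high mitochondrial load
  if (any(low_q)) {
    mu[is_mito, low_q] <- mu[is_mito, low_q] * 12
  }

  disp <- bio_cv^2
  counts <- matrix(0L, nrow = n_genes, ncol = n_total)
  pois_rows <- disp == 0
  counts[pois_rows, ] <- stats::rpois(sum(pois_rows) * n_total,
                                      mu[pois_rows, ])
  if (any(!pois_rows)) {
    nb <- which(!pois_rows)
    counts[nb, ] <- stats::rnbinom(length(nb) * n_total,
                                   mu = mu[nb, ], size = 1 / disp[nb])
  }

  # spike-ins: fixed pool x per-cell capture efficiency, planted noise law
  eff <- stats::rlnorm(n_total, -cfg$capture_efficiency_sd^2 / 2,
                       cfg$capture_efficiency_sd)
  sp <- .draw_spikeins(cfg$spikein_pool, eff, cfg$spikein_a1,
                       cfg$spikein_alpha0)
  spike_ids <- sprintf("ERCC-%05d", seq_len(cfg$n_spikeins))

  all_counts <- rbind(counts, sp)
  dimnames(all_counts) <- list(c(genes, spike_ids), cell_id)
  m <- count_matrix(all_counts,
                    is_spikein = c(rep(FALSE, n_genes),
                                   rep(TRUE, cfg$n_spikeins)),
                    is_mito = c(is_mito, rep(FALSE, cfg$n_spikeins)))

  del <- integer(n_total)
  is_ko <- cell_group %in% cfg$ko_groups
  del[!is_ko] <- stats::rpois(sum(!is_ko), cfg$deletion_region_mean)
  leak <- is_ko & stats::runif(n_total) < cfg$deletion_leak_fraction
  del[leak] <- stats::rpois(sum(leak), cfg$deletion_region_mean)
  meta <- cell_metadata(cell_id, group = cell_group,
                        deletion_region_count = del)

  # emitted gene lists: programs plus unperturbed filler
  null_pool <- setdiff(lay$filler, lay$hv)
  cyc_prog <- unname(unlist(lay$stage_genes))
  n_cyc_null <- max(0L, cfg$cycle_list_size - length(cyc_prog))
  cycle_list <- c(cyc_prog, null_pool[seq_len(n_cyc_null)])
  lin_prog <- unname(unlist(lay$lineage_genes))
  n_hema_null <- max(0L, cfg$hema_list_size - length(lin_prog) -
                       cfg$hema_cycle_overlap)
  hema_list <- c(lin_prog,
                 cyc_prog[seq_len(min(cfg$hema_cycle_overlap,
                                      length(cyc_prog)))],
                 null_pool[n_cyc_null + seq_len(n_hema_null)])
  safe <- function(s) gsub("[^A-Za-z0-9_]+", "_", s)
  sets <- list(cell_cycle = cycle_list, hematopoiesis = hema_list)
  for (s in stage_levels()) {
    sets[[paste0("program_", safe(s))]] <- lay$stage_genes[[s]]
  }
  for (l in names(lay$lineage_genes)) {
    sets[[paste0(l, "_signature")]] <- lay$lineage_genes[[l]]
  }
  sets <- gene_sets(sets)

  truth <- structure(list(
    cells = tibble::tibble(
      cell_id = cell_id, group = cell_group, stage = stages,
      lineage = lineages, libsize_factor = libsize,
      low_quality = low_q),
    genes = tibble::tibble(
      gene_id = genes, base_mean = unname(base),
      bio_cv = unname(bio_cv), stage_program = unname(stage_of_gene),
      lineage_program = unname(lineage_of_gene),
      is_mito = is_mito),
    params = list(a1 = cfg$spikein_a1, alpha0 = cfg$spikein_alpha0,
                  activity_scale = cfg$activity_scale)),
    class = "sim_truth")

  structure(list(counts = m, metadata = meta, truth = truth, sets = sets),
            class = "sim_experiment")
}

# spike-in draw: quasi-Poisson dispersion a1 (variance a1 * mu at the
# shot-noise level) plus a multiplicative log-normal floor with CV2 alpha0
.draw_spikeins <- function(pool, eff, a1, alpha0) {
  .draw_technical(pool, eff, a1, alpha0, NULL)
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat("<sim_experiment>\n")
  print(x$counts)
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s=%d", names(table(x$metadata$group)),
                            table(x$metadata$group)), collapse = ", ")))
  invisible(x)
}

#' Simulate counts obeying a known technical-noise law
#'
#' A stripped-down generator for calibration and power studies of the
#' variable-gene test: biological genes and spike-ins are drawn from the
#' same technical process (`CV2_tech = a1 / mu + alpha0`, via a shared
#' per-cell capture efficiency, quasi-Poisson dispersion `a1` and a
#' multiplicative noise floor `alpha0`), with optional extra biological
#' dispersion on chosen genes. Under `gene_bio_cv = 0` every gene is a
#' true null of the variable-gene test.
#'
#' @param n_cells Number of cells.
#' @param n_genes Number of biological genes.
#' @param n_spikeins Number of spike-in species (default 92).
#' @param gene_means Baseline means; default a log-normal draw
#'   (meanlog 3, sdlog 1).
#' @param gene_bio_cv Per-gene biological CV (scalar or vector; default 0).
#' @param spikein_pool Spike-in abundances; default ladder `2^-2 .. 2^13`.
#' @param a1,alpha0 Planted technical-noise law (defaults 1, 0).
#' @param capture_sd sdlog of the per-cell capture efficiency (default
#'   0.1).
#' @param seed Integer seed.
#' @return A [count_matrix()].
#' @export
simulate_noise_experiment <- function(n_cells = 100, n_genes = 2000,
                                      n_spikeins = 92, gene_means = NULL,
                                      gene_bio_cv = 0, spikein_pool = NULL,
                                      a1 = 1, alpha0 = 0,
                                      capture_sd = 0.1, seed = 1L) {
  if (a1 < 1) stop("a1 must be >= 1")
  withr::with_seed(seed, {
    if (is.null(gene_means)) gene_means <- stats::rlnorm(n_genes, 3, 1)
    if (is.null(spikein_pool)) {
      spikein_pool <- 2^seq(-2, 13, length.out = n_spikeins)
    }
    gene_bio_cv <- rep_len(gene_bio_cv, n_genes)
    eff <- stats::rlnorm(n_cells, -capture_sd^2 / 2, capture_sd)
    bio <- matrix(1, n_genes, n_cells)
    has_bio <- gene_bio_cv > 0
    if (any(has_bio)) {
      shape <- 1 / gene_bio_cv[has_bio]^2
      bio[has_bio, ] <- matrix(
        stats::rgamma(sum(has_bio) * n_cells, shape = shape,
                      rate = shape), sum(has_bio), n_cells)
    }
    gk <- .draw_technical(gene_means, eff, a1, alpha0, bio)
    sk <- .draw_technical(spikein_pool, eff, a1, alpha0, NULL)
    counts <- rbind(gk, sk)
    dimnames(counts) <- list(
      c(sprintf("gene_%05d", seq_len(n_genes)),
        sprintf("ERCC-%05d", seq_len(n_spikeins))),
      sprintf("cell_%04d", seq_len(n_cells)))
    count_matrix(counts)
  })
}

.draw_technical <- function(means, eff, a1, alpha0, bio) {
  n_r <- length(means)
  n_c <- length(eff)
  lam <- outer(means, eff)
  if (!is.null(bio)) lam <- lam * bio
  if (alpha0 > 0) {
    sdl <- sqrt(log1p(alpha0))
    lam <- lam * matrix(stats::rlnorm(n_r * n_c, -sdl^2 / 2, sdl), n_r, n_c)
  }
  if (a1 > 1) {
    matrix(stats::rnbinom(n_r * n_c, mu = lam, size = lam / (a1 - 1)),
           n_r, n_c)
  } else {
    matrix(stats::rpois(n_r * n_c, lam), n_r, n_c)
  }
}
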