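#' Fit the spike-in technical-noise model
#'
#' Models the squared coefficient of variation of the ERCC spike-ins as a
#' function of their normalized mean, `CV2_tech(mu) = a1 / mu + alpha0`,
#' by a gamma-family generalized linear fit with identity link. `a1`
#' captures shot noise (sequencing/sampling), `alpha0` the asymptotic
#' technical CV2 floor at high expression. The fit is restricted to
#' spike-ins whose mean exceeds a data-driven cutoff (by default the 80th
#' percentile of spike-in means among species with CV2 > 0.3), so that
#' near-zero species do not dominate.
#'
#' The returned `psi` is the shot-noise scale entering the variable-gene
#' test denominator: with `xi = mean(1 / s_ercc)`,
#' `psi = xi + (a1 - xi) * mean(s_ercc / s_cell)` -- the fitted `1/mu`
#' coefficient translated from the spike-in to the biological size-factor
#' scale. When both factor sets coincide, `psi` reduces to `a1`.
#'
#' @param norm_spikeins Spike-in rows of the normalized matrix (spike-in
#'   size factors applied), species x cells.
#' @param sf A [size_factors()] object with both `cell` and `spikein`
#'   components.
#' @param min_mean_for_fit Mean cutoff for inclusion in the fit; `NULL`
#'   (default) applies the percentile rule above.
#' @param cv2_init Percentile rule parameters: spike-ins with CV2 above
#'   `cv2_init` define the mean distribution whose `quantile_for_fit`
#'   quantile is the cutoff.
#' @param quantile_for_fit See `cv2_init`.
#' @return An object of class `tech_noise_fit` with fields `a1`, `alpha0`,
#'   `psi`, `min_mean_for_fit`, `n_spikeins_used`, and the per-species
#'   `spikein_stats` tibble (mean, cv2, used flag).
#' @export
fit_technical_noise <- function(norm_spikeins, sf, min_mean_for_fit = NULL,
                                cv2_init = 0.3, quantile_for_fit = 0.8) {
  stopifnot(is.matrix(norm_spikeins))
  if (ncol(norm_spikeins) < 2L) stop("need at least 2 cells")
  mu <- rowMeans(norm_spikeins)
  v <- apply(norm_spikeins, 1, stats::var)
  cv2 <- v / mu^2
  if (is.null(min_mean_for_fit)) {
    pool <- mu[!is.na(cv2) & cv2 > cv2_init]
    if (length(pool) < 2L) {
      warning("too few spike-ins with CV2 > ", cv2_init,
              "; mean cutoff taken over all spike-ins")
      pool <- mu
    }
    min_mean_for_fit <- unname(stats::quantile(pool, quantile_for_fit))
  }
  use <- !is.na(cv2) & mu >= min_mean_for_fit
  if (sum(use) < 10L) {
    stop("fewer than 10 usable spike-ins above the mean cutoff (",
         sum(use), " available)")
  }
  dat <- data.frame(cv2 = cv2[use], inv_mu = 1 / mu[use])
  start <- stats::coef(stats::lm(cv2 ~ inv_mu, data = dat))
  start <- pmax(start, c(1e-8, 1e-8))
  fit <- tryCatch(
    stats::glm(cv2 ~ inv_mu, data = dat, family = stats::Gamma(link = "identity"),
               start = unname(start)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) {
    fit <- suppressWarnings(
      stats::glm(cv2 ~ inv_mu, data = dat,
                 family = stats::Gamma(link = "identity"),
                 start = unname(start), control = stats::glm.control(maxit = 200)))
  }
  if (!fit$converged) {
    stop("gamma GLM for the technical-noise law did not converge; ",
         "spike-in means span ", format(min(dat$inv_mu)), "-",
         format(max(dat$inv_mu)), " on the 1/mu scale")
  }
  a1 <- unname(stats::coef(fit)["inv_mu"])
  alpha0 <- unname(stats::coef(fit)["(Intercept)"])
  if (a1 <= 0) stop("fitted a1 is not positive; spike-ins carry no ",
                    "resolvable shot-noise component")
  if (alpha0 < 0) {
    warning("fitted alpha0 was negative (", signif(alpha0, 3),
            "); clamped to 0")
    alpha0 <- 0
  }
  if (is.null(sf$spikein)) stop("spike-in size factors are required")
  cells <- colnames(norm_spikeins)
  s_ercc <- sf$spikein[cells]
  s_cell <- sf$cell[cells]
  xi <- mean(1 / s_ercc)
  psi <- xi + (a1 - xi) * mean(s_ercc / s_cell)
  if (psi <= 0) psi <- a1
  structure(list(
    a1 = a1, alpha0 = alpha0, psi = psi,
    min_mean_for_fit = min_mean_for_fit,
    n_spikeins_used = sum(use),
    spikein_stats = tibble::tibble(
      gene_id = rownames(norm_spikeins), mean = unname(mu),
      cv2 = unname(cv2), used_in_fit = unname(use))),
    class = "tech_noise_fit")
}

#' @export
print.tech_noise_fit <- function(x, ...) {
  cat(sprintf(
    "<tech_noise_fit> CV2_tech(mu) = %.4g/mu + %.4g  (psi = %.4g, %d spike-ins used)\n",
    x$a1, x$alpha0, x$psi, x$n_spikeins_used))
  invisible(x)
}

#' @export
tidy.tech_noise_fit <- function(x, ...) {
  tibble::tibble(term = c("a1", "alpha0", "psi"),
                 estimate = c(x$a1, x$alpha0, x$psi))
}

#' @export
glance.tech_noise_fit <- function(x, ...) {
  tibble::tibble(a1 = x$a1, alpha0 = x$alpha0, psi = x$psi,
                 min_mean_for_fit = x$min_mean_for_fit,
                 n_spikeins_used = x$n_spikeins_used)
}

#' Predicted technical CV2 at given means
#'
#' @param object A [fit_technical_noise()] result.
#' @param mu Vector of normalized means.
#' @param ... Unused.
#' @return Numeric vector `a1 / mu + alpha0`.
#' @export
predict.tech_noise_fit <- function(object, mu, ...) {
  object$a1 / mu + object$alpha0
}

#' Test genes for excess (biological) variability
#'
#' Chi-squared test of each gene's observed variance against the spike-in
#' technical-noise expectation plus a minimal biological dispersion. With
#' `m` cells, normalized per-gene mean `mu_i` and variance `v_i`, minimal
#' biological squared CV `minBiolDisp = min_biol_cv^2` and
#' `c = alpha0 + minBiolDisp + alpha0 * minBiolDisp`, the denominator is
#' `d_i = (mu_i * psi + mu_i^2 * c) / (1 + c / minBiolDisp)` and the
#' statistic `T_i = (m - 1) * v_i / d_i` is referred to the upper tail of
#' a chi-squared distribution with `m - 1` degrees of freedom. Setting
#' `min_biol_cv = 0` tests against the pure technical law
#' `d_i = mu_i * psi + mu_i^2 * alpha0`. P-values are Benjamini-Hochberg
#' adjusted across all genes with positive mean; genes never detected get
#' `p = 1` and do not enter the multiplicity count.
#'
#' @param norm_genes Biological rows of the normalized matrix (cell size
#'   factors applied), genes x cells.
#' @param fit A [fit_technical_noise()] result.
#' @param min_biol_cv Minimal biological coefficient of variation a gene
#'   must exceed the technical law by (default 0.5, i.e. 50% biological
#'   CV; squared internally).
#' @param padj_threshold Adjusted-p cutoff for the `highly_variable` flag
#'   (default 0.1).
#' @return A tibble of class `hvg_table`: `gene_id`, `mean`, `variance`,
#'   `cv2`, `statistic`, `p_value`, `p_adjust`, `highly_variable`.
#' @export
test_highly_variable <- function(norm_genes, fit, min_biol_cv = 0.5,
                                 padj_threshold = 0.1) {
  stopifnot(inherits(fit, "tech_noise_fit"), is.matrix(norm_genes))
  m <- ncol(norm_genes)
  if (m < 2L) stop("need at least 2 cells")
  mu <- rowMeans(norm_genes)
  v <- apply(norm_genes, 1, stats::var)
  if (min_biol_cv > 0) {
    mbd <- min_biol_cv^2
    cc <- fit$alpha0 + mbd + fit$alpha0 * mbd
    d <- (mu * fit$psi + mu^2 * cc) / (1 + cc / mbd)
  } else {
    d <- mu * fit$psi + mu^2 * fit$alpha0
  }
  stat <- (m - 1) * v / d
  p <- stats::pchisq(stat, df = m - 1, lower.tail = FALSE)
  zero <- mu == 0
  stat[zero] <- 0
  p[zero] <- 1
  padj <- rep(NA_real_, length(p))
  padj[!zero] <- stats::p.adjust(p[!zero], method = "BH")
  padj[zero] <- 1
  out <- tibble::tibble(
    gene_id = rownames(norm_genes),
    mean = unname(mu), variance = unname(v),
    cv2 = unname(ifelse(mu > 0, v / mu^2, NA_real_)),
    statistic = unname(stat), p_value = unname(p),
    p_adjust = unname(padj),
    highly_variable = unname(padj < padj_threshold))
  attr(out, "provenance") <- sprintf(
    "test_highly_variable: min_biol_cv=%g padj_threshold=%g a1=%.5g alpha0=%.5g psi=%.5g",
    min_biol_cv, padj_threshold, fit$a1, fit$alpha0, fit$psi)
  class(out) <- c("hvg_table", class(out))
  out
}

#' CV2-versus-mean diagnostic plot
#'
#' Spike-ins and biological genes on the log-log CV2/mean plane, with the
#' fitted technical-noise law and the margin for genes exceeding it by the
#' minimal biological CV.
#'
#' @param object An `hvg_table` from [test_highly_variable()].
#' @param fit The [fit_technical_noise()] result used for the test.
#' @param min_biol_cv Margin drawn as the dashed line (default 0.5).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hvg_table <- function(object, fit, min_biol_cv = 0.5, ...) {
  pts <- dplyr::filter(object, .data$mean > 0)
  grid <- tibble::tibble(
    mean = exp(seq(log(min(pts$mean)), log(max(pts$mean)), length.out = 200)))
  grid$tech <- predict(fit, grid$mean)
  grid$margin <- grid$tech + min_biol_cv^2
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$mean, y = .data$cv2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$highly_variable),
                        size = 0.6, alpha = 0.6) +
    ggplot2::geom_point(data = dplyr::mutate(fit$spikein_stats,
                                             highly_variable = NA),
                        colour = "blue", shape = 17, size = 1.5) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$tech),
                       colour = "red", inherit.aes = FALSE,
                       mapping = ggplot2::aes(x = .data$mean, y = .data$tech)) +
    ggplot2::geom_line(data = grid,
                       mapping = ggplot2::aes(x = .data$mean, y = .data$margin),
                       colour = "red", linetype = "dashed",
                       inherit.aes = FALSE) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "normalized mean", y = expression(CV^2),
                  colour = "highly variable")
}
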