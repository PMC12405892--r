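# broom-style tidiers and ggplot2 visualisations for result objects

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a REML variance-component fit
#'
#' @param x A `reml_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per component (`sigma_u2`, `sigma_e2`,
#'   `rho2`) and columns `term`, `estimate`, `std.error`.
#' @export
tidy.reml_fit <- function(x, ...) {
  tibble::tibble(
    term = c("sigma_u2", "sigma_e2", "rho2"),
    estimate = c(x$sigma_u2, x$sigma_e2, x$rho2),
    std.error = c(NA_real_, NA_real_, x$se_rho2))
}

#' Glance at a REML variance-component fit
#'
#' @param x A `reml_fit` object.
#' @param ... Unused.
#' @return One-row tibble with `rho2`, `se_rho2`, `sigma_u2`, `sigma_e2`,
#'   `logLik`, `converged`, `nobs`.
#' @export
glance.reml_fit <- function(x, ...) {
  tibble::tibble(rho2 = x$rho2, se_rho2 = x$se_rho2,
                 sigma_u2 = x$sigma_u2, sigma_e2 = x$sigma_e2,
                 logLik = x$log_likelihood, converged = x$converged,
                 nobs = x$n)
}

#' Plot population structure from a relationship-matrix PCA
#'
#' @param object A `relmat_pca` from [pca_relationship()].
#' @param ... Unused.
#' @return A ggplot object (PC1 vs PC2, axes labelled with the
#'   variance-explained fractions).
#' @export
autoplot.relmat_pca <- function(object, ...) {
  df <- object$scores
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$fractions[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$fractions[2])) +
    ggplot2::theme_minimal()
  if ("group" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = factor(.data$group)), alpha = 0.8) +
      ggplot2::labs(colour = "group")
  } else {
    p + ggplot2::geom_point(alpha = 0.8)
  }
}

#' Plot paired cross-tissue eQTL effect sizes
#'
#' @param object A `cross_tissue_effects` object.
#' @param ... Unused.
#' @return A ggplot object: effect in tissue 1 vs tissue 2, discordant-sign
#'   pairs highlighted, faceted by tissue pair.
#' @export
autoplot.cross_tissue_effects <- function(object, ...) {
  df <- object$pairs
  df$discordant <- sign(df$beta1) != sign(df$beta2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta1, y = .data$beta2,
                                   colour = .data$discordant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "deeppink3")) +
    ggplot2::facet_grid(tissue2 ~ tissue1) +
    ggplot2::labs(x = "effect size (tissue 1, SD units)",
                  y = "effect size (tissue 2, SD units)",
                  colour = "opposite sign") +
    ggplot2::theme_minimal()
}

#' Manhattan plot of an association scan
#'
#' @param assoc Association tibble with `chrom`, `pos`, `p` columns (e.g.
#'   from [mlm_scan()]).
#' @param threshold Optional significance threshold drawn as a line.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(assoc, threshold = NULL) {
  df <- dplyr::filter(assoc, !is.na(.data$p))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6,
                                        y = -log10(.data$p))) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7, colour = "steelblue4") +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 linetype = 2, colour = "firebrick")
  }
  p
}

#' Bar plot of gene-set enrichment folds
#'
#' @param enrichment Tibble from [enrich()].
#' @param fdr_max Sets with FDR at or below this are drawn filled.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, fdr_max = 0.05) {
  df <- dplyr::arrange(enrichment, .data$fold)
  df$set_id <- factor(df$set_id, levels = df$set_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold, y = .data$set_id,
                                   fill = .data$fdr <= fdr_max)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "darkorange3", `FALSE` = "grey70")) +
    ggplot2::labs(x = "fold of enrichment", y = NULL,
                  fill = sprintf("FDR <= %.2g", fdr_max)) +
    ggplot2::theme_minimal()
}
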