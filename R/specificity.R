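# Tissue-specificity scoring: per-gene, per-tissue t-statistics from a
# tested-tissue-vs-rest regression on pooled standardized log2 counts, the
# top-5% + median-fold-change caller, and generic hypergeometric gene-set
# enrichment.

#' Per-gene tissue-contrast t-statistics
#'
#' For each gene, the log2 counts are scaled to mean 0, variance 1 across
#' all samples pooled over tissues; then, one tissue at a time, the scaled
#' vector is regressed on an intercept plus a +1/-1 dummy (tested tissue =
#' +1, all other tissues = -1) and the t-statistic of the tissue effect is
#' returned. This equals the pooled two-sample t statistic for
#' tissue-versus-rest. Genes with zero pooled variance get t = 0.
#'
#' @param expr An [expression_matrix()] spanning at least two tissues.
#' @return Tibble with columns `gene_id`, `tissue`, `t_stat`.
#' @export
specificity_tstats <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  tset <- tissues(expr)
  assert_that(length(tset) >= 2, "at least two tissues are required")
  counts_t <- table(expr$samples$tissue)
  small <- names(counts_t)[counts_t < 2]
  assert_that(length(small) == 0,
              paste0("tissue(s) with fewer than 2 samples: ", paste(small, collapse = ", ")))
  lg <- log2(expr$counts + 1)
  sds <- apply(lg, 2, stats::sd)
  Y <- lg
  Y[, sds > 0] <- scale(lg[, sds > 0, drop = FALSE])
  Y[, sds == 0] <- 0
  n <- nrow(Y)
  Syy <- colSums(Y^2)
  out <- lapply(tset, function(t_code) {
    x <- ifelse(expr$samples$tissue == t_code, 1, -1)
    xc <- x - mean(x)
    Sxx <- sum(xc^2)
    Sxy <- as.numeric(crossprod(Y, xc))
    b <- Sxy / Sxx
    rss <- pmax(unname(Syy) - Sxy^2 / Sxx, 0)
    s2 <- rss / (n - 2)
    t_stat <- ifelse(s2 > 0, b / sqrt(s2 / Sxx), 0)
    t_stat[sds == 0] <- 0
    t_stat <- unname(t_stat)
    tibble::tibble(gene_id = expr$gene_ids, tissue = t_code, t_stat = t_stat)
  })
  dplyr::bind_rows(out)
}

#' Call tissue-specific genes
#'
#' Per tissue, genes are ranked by their tissue-contrast t-statistic and the
#' top `top_pct` percent become candidates (ties at the cutoff are all
#' retained); a candidate is called specific when its median fold change on
#' the count scale versus the other tissues reaches `min_median_fc`. The
#' fold change against each other tissue is
#' `(median count in tissue + pseudocount) / (median count in other + pseudocount)`,
#' and by default the median of these per-other-tissue ratios is used
#' (`fc_method = "median_of_ratios"`); `"ratio_of_medians"` compares the
#' tissue median against the median of the other-tissue medians instead.
#'
#' @param t_stats Tibble from [specificity_tstats()].
#' @param expr The [expression_matrix()] the statistics were computed from.
#' @param top_pct Candidate percentile (default 5).
#' @param min_median_fc Minimum median fold change (default 2).
#' @param pseudocount Added to medians before forming ratios.
#' @param fc_method `"median_of_ratios"` (default) or `"ratio_of_medians"`.
#' @return Tibble with one row per gene x tissue: `gene_id`, `tissue`,
#'   `t_stat`, `rank_pct`, `median_fc`, `is_specific`.
#' @export
call_tissue_specific <- function(t_stats, expr, top_pct = 5, min_median_fc = 2,
                                 pseudocount = 1,
                                 fc_method = c("median_of_ratios", "ratio_of_medians")) {
  fc_method <- match.arg(fc_method)
  stopifnot(inherits(expr, "expression_matrix"))
  assert_that(top_pct > 0 && min_median_fc > 0, "thresholds must be positive")
  tset <- tissues(expr)
  n_genes <- length(expr$gene_ids)
  n_cand <- floor(top_pct / 100 * n_genes)
  if (n_cand < 1) {
    rlang::warn("call_tissue_specific: fewer than 1/top_pct genes; no candidates")
  }
  # per-tissue median counts, genes x tissues
  med <- vapply(tset, function(t_code) {
    apply(expr$counts[expr$samples$tissue == t_code, , drop = FALSE], 2, stats::median)
  }, numeric(n_genes))
  out <- lapply(tset, function(t_code) {
    tt <- t_stats[t_stats$tissue == t_code, ]
    tt <- tt[match(expr$gene_ids, tt$gene_id), ]
    rk <- rank(-tt$t_stat, ties.method = "min")
    rank_pct <- 100 * rk / n_genes
    if (n_cand >= 1) {
      cutoff <- sort(tt$t_stat, decreasing = TRUE)[n_cand]
      candidate <- tt$t_stat >= cutoff     # ties at the boundary all retained
    } else {
      candidate <- rep(FALSE, n_genes)
    }
    others <- setdiff(tset, t_code)
    ratios <- (med[, t_code] + pseudocount) /
      (med[, others, drop = FALSE] + pseudocount)
    median_fc <- if (fc_method == "median_of_ratios") {
      unname(apply(ratios, 1, stats::median))
    } else {
      unname((med[, t_code] + pseudocount) /
               (apply(med[, others, drop = FALSE], 1, stats::median) + pseudocount))
    }
    tibble::tibble(gene_id = expr$gene_ids, tissue = t_code,
                   t_stat = tt$t_stat, rank_pct = rank_pct,
                   median_fc = median_fc,
                   is_specific = candidate & median_fc >= min_median_fc)
  })
  dplyr::bind_rows(out)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a query gene list
#' and each gene set (both intersected with the universe), with
#' Benjamini-Hochberg FDR across sets and the fold of enrichment
#' `(k/n) / (K/N)`.
#'
#' @param query Character vector of query genes (must be a subset of
#'   `universe`).
#' @param gene_sets Tibble from [read_gene_sets()] (columns `set_id`,
#'   `description`, list-column `genes`).
#' @param universe Character vector of background genes.
#' @return Tibble with columns `set_id`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `fold`, `p_hyper`, `fdr`.
#' @export
enrich <- function(query, gene_sets, universe) {
  universe <- unique(universe)
  query <- unique(query)
  assert_that(length(universe) > 0, "`universe` must be non-empty")
  assert_that(all(query %in% universe), "`query` must be a subset of `universe`")
  N <- length(universe); n <- length(query)
  rows <- purrr::pmap(gene_sets[c("set_id", "genes")], function(set_id, genes) {
    members <- intersect(unique(genes), universe)
    K <- length(members)
    k <- length(intersect(members, query))
    p <- if (K == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fold <- if (K == 0 || n == 0) 0 else (k / n) / (K / N)
    tibble::tibble(set_id = set_id, overlap = k, set_size = K,
                   query_size = n, universe_size = N, fold = fold, p_hyper = p)
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- stats::p.adjust(out$p_hyper, method = "BH")
  out
}
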