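# Per-gene, per-tissue eQTL mapping with conditional analysis, cis/trans
# classification, LD-based clustering of eQTLs across tissues, and
# cross-tissue effect comparison.

#' Map eQTLs per gene and tissue
#'
#' For every gene in every tissue, runs a mixed-model association scan of
#' the standardized expression on all variants, with the tissue's latent
#' factors as fixed covariates and the kinship matrix as the random-effect
#' covariance (EMMAX-style: variance components fit once per gene under the
#' null). Genes whose smallest p passes `threshold_p` then undergo stepwise
#' conditional analysis, enumerating independent signals round by round.
#' Expression is standardized, so effect sizes are in SD units and
#' comparable across tissues. Records are classified cis/trans against the
#' annotation (cis: same chromosome and within `cis_window` of the TSS).
#'
#' @param pe A `processed_expression` from [log_standardize()].
#' @param G A [genotype_matrix()] of the panel lines.
#' @param kinship A [relationship_matrix()] over the same lines.
#' @param annotation Gene annotation tibble (`gene_id`, `chrom`, `tss`);
#'   must cover every mapped gene.
#' @param factors Optional `latent_factors` from [estimate_latent_factors()].
#' @param threshold_p Genome-wide significance threshold (e.g.
#'   `bonferroni_threshold(0.05, effective_marker_number(G))`).
#' @param genes Optional subset of gene ids to map (default: all kept genes).
#' @param max_rounds Cap on conditional rounds per gene.
#' @return Tibble of eQTL records: `gene_id`, `tissue`, `variant_id`,
#'   `chrom`, `pos`, `beta`, `se`, `p`, `kind`, `conditional_round`.
#' @export
map_eqtls <- function(pe, G, kinship, annotation, factors = NULL,
                      threshold_p, genes = NULL, max_rounds = 10) {
  stopifnot(inherits(pe, "processed_expression"), inherits(G, "genotype_matrix"))
  assert_that(threshold_p > 0 && threshold_p < 1, "`threshold_p` must lie in (0, 1)")
  K <- as_relationship_input(kinship)
  D_all <- impute_dosages(G$dosages)
  vr <- G$variants
  records <- list()
  for (t_code in names(pe)) {
    tt <- pe[[t_code]]
    gene_set <- colnames(tt$z)
    if (!is.null(genes)) gene_set <- intersect(gene_set, genes)
    if (length(gene_set) == 0) next
    miss_ann <- setdiff(gene_set, annotation$gene_id)
    if (length(miss_ann) > 0) {
      abort_regulatlas(paste0("gene(s) absent from annotation: ",
                              paste(utils::head(miss_ann, 3), collapse = ", ")))
    }
    li <- match(tt$samples$line_id, G$sample_ids)
    assert_that(!anyNA(li), paste0("expression samples in tissue ", t_code,
                                   " not present in the genotype panel"))
    D <- D_all[li, , drop = FALSE]
    rot <- rotate_setup(K[li, li])
    n <- length(li)
    Ct0 <- crossprod(rot$U, cbind(rep(1, n), if (!is.null(factors)) factors[[t_code]]))
    Gt <- crossprod(rot$U, D)
    Gt2 <- Gt^2
    for (g_id in gene_set) {
      yt <- crossprod(rot$U, tt$z[, g_id])
      res <- scan_gene_conditional(yt, Ct0, Gt, Gt2, rot$d, D, vr,
                                   threshold_p, max_rounds)
      if (nrow(res) > 0) {
        res$gene_id <- g_id
        res$tissue <- t_code
        records[[length(records) + 1]] <- res
      }
    }
  }
  if (length(records) == 0) {
    out <- tibble::tibble(gene_id = character(), tissue = character(),
                          variant_id = character(), chrom = character(),
                          pos = integer(), beta = numeric(), se = numeric(),
                          p = numeric(), conditional_round = integer())
    out$kind <- character()
    return(out)
  }
  out <- dplyr::bind_rows(records)
  out <- out[, c("gene_id", "tissue", "variant_id", "chrom", "pos",
                 "beta", "se", "p", "conditional_round")]
  classify_cis_trans(out, annotation)
}

# one gene's scan plus conditional rounds, all in rotated coordinates
scan_gene_conditional <- function(yt, Ct0, Gt, Gt2, d, D, vr, threshold_p,
                                  max_rounds) {
  Ct <- Ct0
  sel_rows <- list()
  sel_idx <- integer(0)
  for (round in seq_len(max_rounds)) {
    prof <- reml_profile(yt, Ct, d)
    v <- if (prof$flat) rep(1, length(yt)) else prof$h * d + (1 - prof$h)
    st <- gls_scan_stats(yt, Ct, Gt, v, Gt2)
    cand <- which(is.na(st$note) & st$p < threshold_p)
    cand <- setdiff(cand, sel_idx)
    if (length(cand) == 0) break
    ord <- cand[order(st$p[cand], vr$pos[cand], vr$variant_id[cand])]
    picked <- NA_integer_
    for (j in ord) {
      if (length(sel_idx) > 0) {
        r <- suppressWarnings(stats::cor(D[, j], D[, sel_idx, drop = FALSE]))
        if (any(abs(r) >= 1 - 1e-10, na.rm = TRUE)) next
      }
      picked <- j
      break
    }
    if (is.na(picked)) break
    sel_rows[[round]] <- tibble::tibble(
      variant_id = vr$variant_id[picked], chrom = vr$chrom[picked],
      pos = vr$pos[picked], beta = st$beta[picked], se = st$se[picked],
      p = st$p[picked], conditional_round = round)
    sel_idx <- c(sel_idx, picked)
    Ct <- cbind(Ct, Gt[, picked])
  }
  if (length(sel_rows) == 0) {
    return(tibble::tibble(variant_id = character(), chrom = character(),
                          pos = integer(), beta = numeric(), se = numeric(),
                          p = numeric(), conditional_round = integer()))
  }
  dplyr::bind_rows(sel_rows)
}

#' Classify association records as cis or trans
#'
#' A record is cis when its variant lies on the same chromosome as the
#' gene and within `window` bp of the transcription start site (inclusive);
#' otherwise trans.
#'
#' @param records Tibble with columns `gene_id`, `chrom`, `pos`.
#' @param annotation Gene annotation tibble covering every gene in `records`.
#' @param window Cis window in bp (default 1 Mb).
#' @return `records` with a `kind` column set to "cis"/"trans".
#' @export
classify_cis_trans <- function(records, annotation, window = 1e6) {
  miss <- setdiff(unique(records$gene_id), annotation$gene_id)
  if (length(miss) > 0) {
    abort_regulatlas(paste0("gene(s) absent from annotation: ",
                            paste(utils::head(miss, 3), collapse = ", ")))
  }
  ann <- annotation[match(records$gene_id, annotation$gene_id), ]
  records$kind <- ifelse(records$chrom == ann$chrom &
                           abs(records$pos - ann$tss) <= window, "cis", "trans")
  records
}

#' Linkage disequilibrium r-squared between two variants
#'
#' Squared Pearson correlation of dosages across samples where both variants
#' are called.
#'
#' @param G A [genotype_matrix()].
#' @param variant_a,variant_b Variant ids.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(G, variant_a, variant_b) {
  stopifnot(inherits(G, "genotype_matrix"))
  ia <- match(variant_a, G$variants$variant_id)
  ib <- match(variant_b, G$variants$variant_id)
  assert_that(!is.na(ia) && !is.na(ib), "both variants must be present")
  a <- G$dosages[, ia]; b <- G$dosages[, ib]
  ok <- !is.na(a) & !is.na(b)
  assert_that(sum(ok) >= 2, "too few samples with both variants called")
  assert_that(stats::sd(a[ok]) > 0 && stats::sd(b[ok]) > 0,
              "LD undefined for a monomorphic variant")
  stats::cor(a[ok], b[ok])^2
}

#' Group eQTLs across tissues into clusters by LD and distance
#'
#' Builds a graph over the distinct top variants of the records with an edge
#' whenever two variants are on the same chromosome, strictly closer than
#' `max_dist` bp, and have dosage LD strictly above `r2_min`; connected
#' components become clusters, so eQTLs from multiple tissues linked by a
#' chain of such pairs are counted as a single regulatory signal. Each
#' cluster's representative is the member record with the smallest p
#' (ties: smaller position, then lexicographic id).
#'
#' @param records eQTL record tibble (e.g. from [map_eqtls()]).
#' @param G The [genotype_matrix()] used for LD (full panel by default).
#' @param r2_min LD threshold (edges require r2 strictly greater).
#' @param max_dist Distance threshold in bp (edges require strictly smaller).
#' @return Object of class `eqtl_clusters`: list with `members` (records
#'   plus `cluster_id`, `is_representative`) and `clusters` (one row per
#'   cluster with its representative variant and summary counts).
#' @export
cluster_eqtls <- function(records, G, r2_min = 0.2, max_dist = 5e5) {
  assert_that(nrow(records) > 0, "`records` must be non-empty")
  vars <- dplyr::distinct(records[, c("variant_id", "chrom", "pos")])
  vars <- vars[order(vars$chrom, vars$pos, vars$variant_id), ]
  edges <- list()
  Dimp <- impute_dosages(G$dosages)
  for (ch in unique(vars$chrom)) {
    vv <- vars[vars$chrom == ch, ]
    if (nrow(vv) < 2) next
    for (i in seq_len(nrow(vv) - 1)) {
      for (j in (i + 1):nrow(vv)) {
        if (abs(vv$pos[j] - vv$pos[i]) >= max_dist) next
        ci <- match(vv$variant_id[i], G$variants$variant_id)
        cj <- match(vv$variant_id[j], G$variants$variant_id)
        r2 <- suppressWarnings(stats::cor(Dimp[, ci], Dimp[, cj]))^2
        if (!is.na(r2) && r2 > r2_min) {
          edges[[length(edges) + 1]] <- c(vv$variant_id[i], vv$variant_id[j])
        }
      }
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(vars$variant_id)
  if (length(edges) > 0) {
    g <- g + igraph::edges(unlist(edges))
  }
  comp <- igraph::components(g)$membership
  members <- records
  members$.comp <- comp[members$variant_id]
  # representative and deterministic cluster ids ordered by genome position
  reps <- members |>
    dplyr::group_by(.data$.comp) |>
    dplyr::arrange(.data$p, .data$pos, .data$variant_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chrom, .data$pos, .data$variant_id)
  reps$cluster_id <- sprintf("clu%04d", seq_len(nrow(reps)))
  id_of <- stats::setNames(reps$cluster_id, reps$.comp)
  members$cluster_id <- unname(id_of[as.character(members$.comp)])
  rep_key <- paste(reps$.comp, reps$gene_id, reps$tissue, reps$variant_id,
                   reps$conditional_round %||% 1)
  members$is_representative <- paste(members$.comp, members$gene_id,
                                     members$tissue, members$variant_id,
                                     members$conditional_round %||% 1) %in% rep_key
  members$.comp <- NULL
  summary_tab <- members |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(
      chrom = .data$chrom[1],
      n_members = dplyr::n(),
      n_tissues = dplyr::n_distinct(.data$tissue),
      n_genes = dplyr::n_distinct(.data$gene_id),
      min_p = min(.data$p), .groups = "drop")
  rep_cols <- reps[, c("cluster_id", "variant_id", "pos")]
  names(rep_cols) <- c("cluster_id", "rep_variant", "rep_pos")
  clusters <- dplyr::left_join(summary_tab, rep_cols, by = "cluster_id") |>
    dplyr::arrange(.data$cluster_id)
  structure(list(members = members, clusters = clusters), class = "eqtl_clusters")
}

#' @export
print.eqtl_clusters <- function(x, ...) {
  cat(sprintf("<eqtl_clusters> %d records in %d clusters\n",
              nrow(x$members), nrow(x$clusters)))
  invisible(x)
}

#' Compare eQTL effect sizes across tissues
#'
#' For eQTLs detected in two tissues for the same gene and cluster, pairs
#' the standardized effect sizes and summarizes each tissue pair with the
#' Pearson correlation and the fraction of pairs with opposite signs.
#'
#' @param clusters An `eqtl_clusters` object from [cluster_eqtls()].
#' @return Object of class `cross_tissue_effects`: list with `pairs`
#'   (gene, cluster, tissue pair, both betas) and `summary` (per tissue
#'   pair: `n`, `pearson_r`, `sign_discordance`).
#' @export
cross_tissue_effects <- function(clusters) {
  stopifnot(inherits(clusters, "eqtl_clusters"))
  m <- clusters$members |>
    dplyr::group_by(.data$gene_id, .data$cluster_id, .data$tissue) |>
    dplyr::arrange(.data$p, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "cluster_id", "tissue", "beta")
  pairs <- dplyr::inner_join(m, m, by = c("gene_id", "cluster_id"),
                             relationship = "many-to-many",
                             suffix = c("1", "2")) |>
    dplyr::filter(.data$tissue1 < .data$tissue2)
  if (nrow(pairs) == 0) {
    return(structure(list(pairs = pairs,
                          summary = tibble::tibble(tissue1 = character(),
                                                   tissue2 = character(),
                                                   n = integer(),
                                                   pearson_r = numeric(),
                                                   sign_discordance = numeric())),
                     class = "cross_tissue_effects"))
  }
  summary_tab <- pairs |>
    dplyr::group_by(.data$tissue1, .data$tissue2) |>
    dplyr::summarise(
      n = dplyr::n(),
      pearson_r = if (dplyr::n() >= 3) stats::cor(.data$beta1, .data$beta2) else NA_real_,
      sign_discordance = mean(sign(.data$beta1) != sign(.data$beta2)),
      .groups = "drop")
  structure(list(pairs = pairs, summary = summary_tab),
            class = "cross_tissue_effects")
}

#' @export
print.cross_tissue_effects <- function(x, ...) {
  cat(sprintf("<cross_tissue_effects> %d shared (gene, cluster) pairs across %d tissue pair(s)\n",
              nrow(x$pairs), nrow(x$summary)))
  invisible(x)
}
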