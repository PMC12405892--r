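# Linking regulatory variation to traits: transcriptome variance
# partitioning through the omics relationship matrix, mixed-model TWAS,
# distance colocalization with published QTL, summary-based Mendelian
# randomization with the HEIDI heterogeneity test, enrichment-style
# comparisons against random gene/SNP sets, and replication in a second
# dataset.

#' Omics (transcriptomic) relationship matrix
#'
#' `A = Z Z' / g` over the standardized gene columns of one tissue; the
#' covariance structure for transcriptome variance partitioning and TWAS.
#'
#' @param pe A `processed_expression` from [log_standardize()], or a
#'   standardized samples x genes matrix.
#' @param tissue Tissue to use when `pe` is a `processed_expression`.
#' @return A [relationship_matrix()] of kind "orm".
#' @export
compute_orm <- function(pe, tissue = NULL) {
  if (inherits(pe, "processed_expression")) {
    tissue <- tissue %||% names(pe)[1]
    Z <- pe[[tissue]]$z
    ids <- pe[[tissue]]$samples$line_id
  } else {
    Z <- as.matrix(pe)
    ids <- rownames(Z) %||% paste0("S", seq_len(nrow(Z)))
  }
  assert_that(ncol(Z) > 0, "no genes available to build the ORM")
  assert_that(nrow(Z) >= 2, "need at least 2 samples")
  A <- tcrossprod(Z) / ncol(Z)
  relationship_matrix((A + t(A)) / 2, "orm", ids)
}

#' Proportion of trait variance explained by transcriptome variation
#'
#' REML fit of the intraclass-correlation model `y = mu + W u + e` with
#' `W W' = A`, the omics relationship matrix: the PVE is
#' `rho2 = sigma_u2 / (sigma_u2 + sigma_e2)`. Thin delegation to
#' [reml_fit()] with `R = A`.
#'
#' @param y Trait values (e.g. line BLUPs) aligned with the ORM samples.
#' @param orm A [relationship_matrix()] of kind "orm" (any PSD matrix works).
#' @param covariates Optional fixed covariates.
#' @return A `reml_fit` object; `rho2` is the PVE.
#' @export
transcriptome_pve <- function(y, orm, covariates = NULL) {
  reml_fit(y, orm, covariates = covariates)
}

#' Mixed-model transcriptome-wide association scan
#'
#' Tests the fixed effect of each gene's standardized expression on the
#' trait, with a random effect of covariance `sigma_u2 A + sigma_e2 I`
#' absorbing the rest of the transcriptome (components fit once under the
#' null, as in the association scan). Attaches the Bonferroni threshold
#' `0.05 / n_genes` and the lenient threshold `0.05 / n_associated`
#' (computed from the realized count of genes passing the strict threshold)
#' as attributes.
#'
#' @param y Trait values aligned with the expression samples.
#' @param pe `processed_expression` (one tissue used) or a standardized
#'   samples x genes matrix.
#' @param orm ORM built from the same expression (see [compute_orm()]).
#' @param tissue Tissue to use when `pe` is a `processed_expression`.
#' @param covariates Optional fixed covariates.
#' @param alpha Family-wise rate used for the attached thresholds.
#' @return Tibble with columns `gene_id`, `beta`, `se`, `z`, `p`, `note`;
#'   attributes `threshold_strict`, `threshold_lenient`, `n_associated`.
#' @export
twas_scan <- function(y, pe, orm, tissue = NULL, covariates = NULL, alpha = 0.05) {
  if (inherits(pe, "processed_expression")) {
    tissue <- tissue %||% names(pe)[1]
    Z <- pe[[tissue]]$z
  } else {
    Z <- as.matrix(pe)
  }
  y <- as.numeric(y)
  n <- length(y)
  assert_that(n == nrow(Z), "`y` must align with the expression samples")
  fit0 <- reml_fit(y, orm, covariates = covariates)
  rot <- fit0$rotation
  v <- if (fit0$converged) fit0$sigma_u2 * rot$d + fit0$sigma_e2
       else rep(fit0$sigma_e2, n)
  C <- cbind(rep(1, n), covariates)
  yt <- crossprod(rot$U, y)
  Ct <- crossprod(rot$U, C)
  Xt <- crossprod(rot$U, Z)
  st <- gls_scan_stats(yt, Ct, Xt, v)
  st$note[!is.na(st$note)] <- "constant expression"
  out <- dplyr::bind_cols(tibble::tibble(gene_id = colnames(Z)), st)
  n_genes <- ncol(Z)
  thr <- bonferroni_threshold(alpha, n_genes)
  n_assoc <- sum(out$p < thr, na.rm = TRUE)
  attr(out, "threshold_strict") <- thr
  attr(out, "threshold_lenient") <- bonferroni_threshold(alpha, max(1, n_assoc))
  attr(out, "n_associated") <- n_assoc
  attr(out, "sigma_u2") <- fit0$sigma_u2
  attr(out, "sigma_e2") <- fit0$sigma_e2
  out
}

#' Colocalize trait QTLs with eQTL clusters by physical distance
#'
#' Pairs each published trait QTL with every eQTL cluster whose
#' representative variant (or, optionally, any member) lies on the same
#' chromosome strictly closer than `max_dist` bp.
#'
#' @param qtls Trait QTL tibble (columns `trait`, `chrom`, `pos`, ...).
#' @param clusters An `eqtl_clusters` object.
#' @param max_dist Distance threshold in bp (strict; default 100).
#' @param match One of "representative" (default) or "any" (any member
#'   variant may establish the colocalization; the distance reported is the
#'   smallest).
#' @return Tibble of colocalized pairs: `trait`, `chrom`, `qtl_pos`,
#'   `cluster_id`, `variant_id`, `eqtl_pos`, `distance`.
#' @export
colocalize <- function(qtls, clusters, max_dist = 100,
                       match = c("representative", "any")) {
  match <- match.arg(match)
  stopifnot(inherits(clusters, "eqtl_clusters"))
  cand <- if (match == "representative") {
    tibble::tibble(cluster_id = clusters$clusters$cluster_id,
                   chrom = clusters$clusters$chrom,
                   variant_id = clusters$clusters$rep_variant,
                   eqtl_pos = clusters$clusters$rep_pos)
  } else {
    dplyr::distinct(clusters$members[, c("cluster_id", "chrom", "variant_id", "pos")]) |>
      dplyr::rename(eqtl_pos = "pos")
  }
  out <- dplyr::inner_join(
    dplyr::rename(tibble::as_tibble(qtls)[c("trait", "chrom", "pos")], qtl_pos = "pos"),
    cand, by = "chrom", relationship = "many-to-many") |>
    dplyr::mutate(distance = abs(.data$qtl_pos - .data$eqtl_pos)) |>
    dplyr::filter(.data$distance < max_dist) |>
    dplyr::arrange(.data$trait, .data$chrom, .data$qtl_pos, .data$cluster_id,
                   .data$distance) |>
    dplyr::distinct(.data$trait, .data$chrom, .data$qtl_pos, .data$cluster_id,
                    .keep_all = TRUE)
  out[, c("trait", "chrom", "qtl_pos", "cluster_id", "variant_id",
          "eqtl_pos", "distance")]
}

#' Summary-based Mendelian randomization test
#'
#' Uses the top eQTL as an instrument: the effect of expression on the
#' trait is `b_xy = b_gwas / b_eqtl`, tested with
#' `T_smr = z_gwas^2 z_eqtl^2 / (z_gwas^2 + z_eqtl^2)` against the
#' chi-square(1) upper tail; `se_xy` follows from the delta method.
#' Vectorized over instruments.
#'
#' @param b_gwas,se_gwas Trait-scan effect and SE at the instrument.
#' @param b_eqtl,se_eqtl Expression-scan effect and SE at the instrument
#'   (`b_eqtl` must be non-zero).
#' @return Tibble with columns `b_xy`, `se_xy`, `t_smr`, `p_smr`.
#' @export
smr_test <- function(b_gwas, se_gwas, b_eqtl, se_eqtl) {
  assert_that(all(se_gwas > 0) && all(se_eqtl > 0), "SEs must be positive")
  z_g <- b_gwas / se_gwas
  z_e <- b_eqtl / se_eqtl
  assert_that(all(z_e != 0), "SMR undefined for a null instrument (z_eqtl = 0)")
  b_xy <- b_gwas / b_eqtl
  t_smr <- z_g^2 * z_e^2 / (z_g^2 + z_e^2)
  p_smr <- stats::pchisq(t_smr, df = 1, lower.tail = FALSE)
  se_xy <- abs(b_xy) * sqrt(1 / z_g^2 + 1 / z_e^2)
  se_xy[b_xy == 0] <- se_gwas[b_xy == 0] / abs(b_eqtl[b_xy == 0])
  tibble::tibble(b_xy = b_xy, se_xy = se_xy, t_smr = t_smr, p_smr = p_smr)
}

# delta-method covariance between b_xy estimates at two instruments given
# signed LD r (GWAS and eQTL summary statistics treated as independent)
bxy_cov <- function(r, b_g_i, se_g_i, b_e_i, se_e_i, b_g_j, se_g_j, b_e_j, se_e_j) {
  bxy_i <- b_g_i / b_e_i
  bxy_j <- b_g_j / b_e_j
  r * se_g_i * se_g_j / (b_e_i * b_e_j) +
    bxy_i * bxy_j * r * se_e_i * se_e_j / (b_e_i * b_e_j)
}

#' HEIDI heterogeneity-in-dependent-instruments test
#'
#' Distinguishes a single shared causal variant (mediation: every cis
#' instrument implies the same `b_xy`) from linkage of distinct causal
#' variants (heterogeneous `b_xy`). Instruments besides the top variant are
#' eligible when their eQTL p is below `p_eqtl_max` and their LD r-squared
#' with the top variant lies within `r2_range`, capped at `max_snps` by eQTL
#' significance. The statistic is the sum of squared standardized
#' differences `d_i = b_xy(i) - b_xy(top)`, whose null distribution (a
#' weighted sum of chi-squares from the LD-induced correlation of the
#' differences) is approximated by Satterthwaite moment matching.
#'
#' @param region Tibble with one row per variant: `variant_id`, `b_gwas`,
#'   `se_gwas`, `b_eqtl`, `se_eqtl`, `p_eqtl`.
#' @param top_variant Id of the instrument (the top eQTL variant).
#' @param ld Signed correlation matrix of dosages for the region's variants
#'   (dimnames must include the variant ids), e.g.
#'   `cor(impute_dosages(G$dosages[, ids]))`.
#' @param p_eqtl_max Eligibility threshold on the eQTL p-value.
#' @param r2_range Eligible LD window with the top variant.
#' @param max_snps Cap on the number of instruments used.
#' @return Tibble with `p_heidi`, `t_heidi`, `n_snps` (instruments used
#'   besides the top; `p_heidi` is `NA` when fewer than 3 are eligible).
#' @export
heidi_test <- function(region, top_variant, ld, p_eqtl_max = 1.6e-3,
                       r2_range = c(0.05, 0.9), max_snps = 20) {
  region <- tibble::as_tibble(region)
  assert_that(top_variant %in% region$variant_id, "`top_variant` must be in `region`")
  top <- region[region$variant_id == top_variant, ]
  others <- region[region$variant_id != top_variant, ]
  r_top <- ld[others$variant_id, top_variant]
  elig <- others$p_eqtl < p_eqtl_max &
    r_top^2 >= r2_range[1] & r_top^2 <= r2_range[2]
  others <- others[which(elig), ]
  if (nrow(others) > max_snps) {
    others <- others[order(others$p_eqtl), ][seq_len(max_snps), ]
  }
  n_snps <- nrow(others)
  if (n_snps < 3) {
    return(tibble::tibble(p_heidi = NA_real_, t_heidi = NA_real_, n_snps = n_snps))
  }
  ids <- others$variant_id
  bxy_top <- top$b_gwas / top$b_eqtl
  bxy_i <- others$b_gwas / others$b_eqtl
  d <- bxy_i - bxy_top

  var_bxy <- function(b_g, se_g, b_e, se_e) {
    (b_g / b_e)^2 * (se_g^2 / b_g^2 + se_e^2 / b_e^2)
  }
  v_top <- var_bxy(top$b_gwas, top$se_gwas, top$b_eqtl, top$se_eqtl)
  cov_d <- matrix(0, n_snps, n_snps)
  for (i in seq_len(n_snps)) {
    for (j in i:n_snps) {
      cij <- bxy_cov(ld[ids[i], ids[j]],
                     others$b_gwas[i], others$se_gwas[i], others$b_eqtl[i], others$se_eqtl[i],
                     others$b_gwas[j], others$se_gwas[j], others$b_eqtl[j], others$se_eqtl[j])
      ci_top <- bxy_cov(ld[ids[i], top_variant],
                        others$b_gwas[i], others$se_gwas[i], others$b_eqtl[i], others$se_eqtl[i],
                        top$b_gwas, top$se_gwas, top$b_eqtl, top$se_eqtl)
      cj_top <- bxy_cov(ld[ids[j], top_variant],
                        others$b_gwas[j], others$se_gwas[j], others$b_eqtl[j], others$se_eqtl[j],
                        top$b_gwas, top$se_gwas, top$b_eqtl, top$se_eqtl)
      cov_d[i, j] <- cov_d[j, i] <- cij - ci_top - cj_top + v_top
    }
  }
  sd_d <- sqrt(pmax(diag(cov_d), 0))
  degen <- sd_d <= 1e-150
  z_d <- ifelse(degen, 0, d / pmax(sd_d, 1e-300))
  t_heidi <- sum(z_d^2)
  if (t_heidi == 0) {
    return(tibble::tibble(p_heidi = 1, t_heidi = 0, n_snps = n_snps))
  }
  corr_d <- cov_d / tcrossprod(pmax(sd_d, 1e-300))
  corr_d[degen, ] <- 0
  corr_d[, degen] <- 0
  diag(corr_d) <- 1
  corr_d <- (corr_d + t(corr_d)) / 2
  lam <- pmax(eigen(corr_d, symmetric = TRUE, only.values = TRUE)$values, 0)
  s1 <- sum(lam); s2 <- sum(lam^2)
  if (s1 <= 0 || s2 <= 0) {
    return(tibble::tibble(p_heidi = 1, t_heidi = t_heidi, n_snps = n_snps))
  }
  scale <- s2 / s1
  df <- s1^2 / s2
  p_heidi <- stats::pchisq(t_heidi / scale, df = df, lower.tail = FALSE)
  tibble::tibble(p_heidi = p_heidi, t_heidi = t_heidi, n_snps = n_snps)
}

#' Compare TWAS p-values of colocalized eGenes against random gene sets
#'
#' Two-sided Wilcoxon rank-sum comparison of `-log10 p` between the
#' colocalized gene set and the remaining tested genes, plus an empirical p
#' from `n_draws` size-matched random gene sets (statistic: difference in
#' mean `-log10 p`).
#'
#' @param twas TWAS record tibble (from [twas_scan()]).
#' @param coloc_genes Character vector of colocalized eGene ids (subset of
#'   the tested genes).
#' @param n_draws Number of random draws (0 = asymptotic test only).
#' @param seed Seed for the draws.
#' @return Tibble with `statistic` (mean -log10 p difference),
#'   `p_asymptotic` (rank-sum) and `p_empirical` (`NA` when `n_draws = 0`).
#' @export
compare_coloc_vs_random <- function(twas, coloc_genes, n_draws = 1000, seed = 1) {
  assert_that(length(coloc_genes) > 0, "`coloc_genes` must be non-empty")
  assert_that(all(coloc_genes %in% twas$gene_id),
              "`coloc_genes` must be TWAS-tested genes")
  lp <- -log10(pmax(twas$p, 1e-300))
  names(lp) <- twas$gene_id
  in_set <- twas$gene_id %in% coloc_genes
  stat <- mean(lp[in_set]) - mean(lp[!in_set])
  p_asym <- stats::wilcox.test(lp[in_set], lp[!in_set], exact = FALSE)$p.value
  p_emp <- NA_real_
  if (n_draws > 0) {
    set.seed(derive_seeds(seed, 1))
    k <- sum(in_set)
    null_stats <- vapply(seq_len(n_draws), function(b) {
      draw <- sample.int(length(lp), k)
      mean(lp[draw]) - mean(lp[-draw])
    }, numeric(1))
    p_emp <- (1 + sum(null_stats >= stat)) / (n_draws + 1)
  }
  tibble::tibble(statistic = stat, p_asymptotic = p_asym, p_empirical = p_emp)
}

#' PVE of a SNP set versus size-matched random SNP sets
#'
#' Estimates the trait variance explained by a set of variants through a
#' GRM built from only those variants, and compares it against the PVE
#' distribution of `n_draws` random variant sets of the same size.
#'
#' @param y Trait values aligned with the genotype samples.
#' @param G A [genotype_matrix()].
#' @param snp_set Variant ids of the focal set (at least 2).
#' @param n_draws Number of random sets.
#' @param seed Seed for the draws.
#' @param covariates Optional fixed covariates passed to the REML fits.
#' @return List with `pve_set`, `random_pve` (numeric vector) and
#'   `p_empirical` (fraction of random PVEs at least as large).
#' @export
pve_snpset_vs_random <- function(y, G, snp_set, n_draws = 100, seed = 1,
                                 covariates = NULL) {
  assert_that(length(snp_set) >= 2, "`snp_set` needs at least 2 variants")
  assert_that(all(snp_set %in% G$variants$variant_id), "unknown variant in `snp_set`")
  pve_of <- function(ids) {
    K <- compute_kinship(subset_genotypes(G, variants = ids), "grm")
    fit <- reml_fit(y, K, covariates = covariates)
    if (fit$converged) fit$rho2 else NA_real_
  }
  pve_set <- pve_of(snp_set)
  set.seed(derive_seeds(seed, 1))
  pool <- setdiff(G$variants$variant_id, snp_set)
  k <- length(snp_set)
  random_pve <- vapply(seq_len(n_draws), function(b) pve_of(sample(pool, k)),
                       numeric(1))
  p_emp <- if (n_draws > 0) {
    (1 + sum(random_pve >= pve_set, na.rm = TRUE)) / (n_draws + 1)
  } else NA_real_
  list(pve_set = pve_set, random_pve = random_pve, p_empirical = p_emp)
}

#' Replication of gene-trait correlations in a second dataset
#'
#' For each candidate gene-trait pair, the Pearson correlation between the
#' gene's expression and the trait across the lines of an independent
#' dataset, with a two-sided p-value. The replicated fraction (p < 0.05)
#' and, when expected signs are supplied, the sign-consistent replicated
#' fraction are attached as attributes.
#'
#' @param expr2 An [expression_matrix()] (one tissue) for the replication
#'   panel.
#' @param traits2 Tibble with a `line_id` column and one column per trait.
#' @param pairs Tibble with columns `gene_id`, `trait` and optionally
#'   `expected_sign` (+1/-1 from the discovery dataset).
#' @param alpha Replication threshold (default 0.05).
#' @return Tibble per pair: `gene_id`, `trait`, `n`, `r`, `p`, `replicated`,
#'   `skipped`; attributes `replicated_fraction`, `sign_consistent_fraction`.
#' @export
replication_correlation <- function(expr2, traits2, pairs, alpha = 0.05) {
  stopifnot(inherits(expr2, "expression_matrix"))
  traits2 <- tibble::as_tibble(traits2)
  pairs <- tibble::as_tibble(pairs)
  assert_that(all(pairs$gene_id %in% expr2$gene_ids),
              "pair references a gene absent from the replication expression")
  assert_that(all(pairs$trait %in% names(traits2)),
              "pair references a trait absent from the replication traits")
  lg <- log2(expr2$counts + 1)
  li <- match(expr2$samples$line_id, traits2$line_id)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- lg[, pairs$gene_id[i]]
    yv <- traits2[[pairs$trait[i]]][li]
    ok <- !is.na(x) & !is.na(yv)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(yv[ok]) == 0) {
      return(tibble::tibble(gene_id = pairs$gene_id[i], trait = pairs$trait[i],
                            n = sum(ok), r = NA_real_, p = NA_real_,
                            replicated = NA, skipped = TRUE))
    }
    ct <- stats::cor.test(x[ok], yv[ok], method = "pearson")
    tibble::tibble(gene_id = pairs$gene_id[i], trait = pairs$trait[i],
                   n = sum(ok), r = unname(ct$estimate), p = ct$p.value,
                   replicated = ct$p.value < alpha, skipped = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  tested <- !out$skipped
  attr(out, "replicated_fraction") <-
    if (any(tested)) mean(out$replicated[tested]) else NA_real_
  if ("expected_sign" %in% names(pairs)) {
    sgn_ok <- tested & !is.na(out$r) & sign(out$r) == pairs$expected_sign
    attr(out, "sign_consistent_fraction") <-
      if (any(tested)) mean(out$replicated[tested] & sgn_ok[tested]) else NA_real_
  }
  out
}
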