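# Synthetic genotypes, multi-tissue expression and traits with recorded
# ground truth. The generator emulates the statistical structure of a
# structured inbred diversity panel assayed in several tissues: LD-blocked
# biallelic SNPs with subpopulation allele-frequency shifts, log-normal
# counts with planted cis/trans regulatory effects, tissue-specific genes,
# shared latent factors, and traits with genetic plus transcriptomic
# architecture.

#' Simulate LD-blocked genotypes with population structure
#'
#' Haplotypes are generated by a copying process: within an LD block each
#' variant copies the previous variant's allele with probability
#' `1 - switch_prob`, otherwise it draws a fresh allele at the variant's
#' (subpopulation-specific) frequency. `switch_prob = 0` gives perfect LD
#' within a block; `switch_prob = 0.5` gives near-independent variants.
#' Subpopulation structure comes from logit-normal shifts of the base allele
#' frequency.
#'
#' @param n_samples,n_variants Panel dimensions.
#' @param maf_range Base alternate-allele frequencies are drawn uniformly
#'   from this interval (within (0, 0.5]).
#' @param block_size Number of variants per LD block.
#' @param switch_prob Per-variant probability of a fresh draw inside a block.
#' @param n_subpops Number of subpopulations (1 = unstructured).
#' @param n_chrom Number of chromosomes over which variants are spread.
#' @param spacing Distance in bp between adjacent variants.
#' @param subpop_sd Standard deviation of the logit-scale subpopulation
#'   frequency shifts.
#' @param seed Scenario seed; fully determines the output.
#' @return A [genotype_matrix()] with a `subpop` attribute giving each
#'   sample's subpopulation.
#' @export
simulate_genotypes <- function(n_samples, n_variants, maf_range = c(0.05, 0.5),
                               block_size = 50, switch_prob = 0.1,
                               n_subpops = 1, n_chrom = 1, spacing = 2000,
                               subpop_sd = 0.3, seed = 1) {
  assert_that(length(maf_range) == 2 && maf_range[1] > 0 && maf_range[2] <= 0.5 &&
                maf_range[1] <= maf_range[2],
              "`maf_range` must lie within (0, 0.5]")
  assert_that(block_size >= 1, "`block_size` must be >= 1")
  assert_that(n_subpops <= n_samples, "`n_subpops` cannot exceed `n_samples`")
  seeds <- derive_seeds(seed, 2)

  set.seed(seeds[1])
  m <- n_variants; n <- n_samples
  base_p <- stats::runif(m, maf_range[1], maf_range[2])
  subpop <- rep(seq_len(n_subpops), length.out = n)
  # subpop x variant allele frequencies
  P <- matrix(rep(base_p, each = n_subpops), nrow = n_subpops)
  if (n_subpops > 1) {
    P <- stats::plogis(stats::qlogis(P) +
                         matrix(stats::rnorm(n_subpops * m, 0, subpop_sd), n_subpops, m))
  }
  chrom_of <- rep(seq_len(n_chrom), each = ceiling(m / n_chrom))[seq_len(m)]
  idx_in_chrom <- stats::ave(seq_len(m), chrom_of, FUN = seq_along)
  pos <- idx_in_chrom * spacing
  new_block <- idx_in_chrom == 1 | ((idx_in_chrom - 1) %% block_size == 0)

  set.seed(seeds[2])
  sample_p <- P[subpop, , drop = FALSE]            # n x m
  D <- matrix(0, n, m)
  for (hap in 1:2) {
    H <- matrix(0L, n, m)
    fresh <- matrix(stats::runif(n * m), n, m) < sample_p
    copy <- matrix(stats::runif(n * m), n, m) >= switch_prob
    H[, 1] <- fresh[, 1]
    for (j in seq_len(m)[-1]) {
      if (new_block[j]) H[, j] <- fresh[, j]
      else H[, j] <- ifelse(copy[, j], H[, j - 1], fresh[, j])
    }
    D <- D + H
  }

  af <- colMeans(D) / 2
  variants <- tibble::tibble(
    variant_id = sprintf("snp%05d", seq_len(m)),
    chrom = paste0("chr", chrom_of),
    pos = as.integer(pos),
    ref = "A", alt = "G",
    maf = pmin(af, 1 - af),
    missing_rate = 0
  )
  G <- genotype_matrix(D, variants, sprintf("L%03d", seq_len(n)))
  attr(G, "subpop") <- subpop
  G
}

#' Simulate multi-tissue expression with planted regulatory effects
#'
#' Log2-scale expression per tissue is baseline + planted eQTL effects
#' (cis variants drawn within 1 Mb of the gene's assigned TSS, trans
#' elsewhere) + tissue-specific boosts + shared latent factors + Gaussian
#' noise; counts are `2^log2expr` rounded and floored at zero. Planted truth
#' (eQTLs with per-tissue signed effects, tissue-specific genes, factor
#' loadings) is recorded for parameter-recovery tests.
#'
#' @param genotypes A [genotype_matrix()] of the panel lines.
#' @param tissues Character vector of at least two tissue codes.
#' @param n_genes Number of genes.
#' @param n_eqtl_genes Number of genes carrying one planted eQTL.
#' @param cis_fraction Fraction of planted eQTLs that are cis (within 1 Mb of
#'   the gene's TSS).
#' @param effect_sd Magnitude of planted eQTL effects, in log2 units per
#'   standardized dosage (approximately SD units of expression).
#' @param n_specific_per_tissue Planted tissue-specific genes per tissue.
#' @param specific_fold Multiplicative count boost of specific genes in their
#'   tissue.
#' @param n_factors Number of shared latent factors (loadings shared across
#'   tissues, scores drawn per tissue).
#' @param factor_sd SD of factor loadings.
#' @param noise_sd Residual SD on the log2 scale.
#' @param baseline_mean,baseline_sd Log2-scale baseline distribution.
#' @param low_expr_fraction Fraction of genes given a near-zero baseline so
#'   that zero counts occur, exercising detection filters.
#' @param shared_fraction Fraction of planted eQTLs active in every tissue
#'   (the rest act in a single random tissue).
#' @param flip_fraction Among tissue-shared eQTLs, fraction whose effect sign
#'   is flipped in one random tissue (cross-tissue discordance).
#' @param cis_window Window in bp defining cis (default 1 Mb).
#' @param seed Scenario seed.
#' @return List with elements `expression` (an [expression_matrix()]),
#'   `annotation` (gene_id/chrom/tss/strand tibble) and `truth`.
#' @export
simulate_expression <- function(genotypes, tissues = c("RT", "SH", "LD"),
                                n_genes = 1000,
                                n_eqtl_genes = round(0.1 * n_genes),
                                cis_fraction = 0.8, effect_sd = 1,
                                n_specific_per_tissue = 10, specific_fold = 8,
                                n_factors = 5, factor_sd = 0.5, noise_sd = 0.5,
                                baseline_mean = 6, baseline_sd = 1.5,
                                low_expr_fraction = 0.05,
                                shared_fraction = 0.5, flip_fraction = 0,
                                cis_window = 1e6, seed = 1) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  assert_that(length(tissues) >= 2, "at least two tissues are required")
  assert_that(nrow(genotypes$dosages) > 0, "`genotypes` is empty")
  n_spec_total <- n_specific_per_tissue * length(tissues)
  assert_that(n_eqtl_genes + n_spec_total <= n_genes,
              "too many planted genes for `n_genes`")
  seeds <- derive_seeds(seed, 4)
  lines <- genotypes$sample_ids
  n <- length(lines)
  vr <- genotypes$variants
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))

  # gene coordinates over the simulated chromosomes
  set.seed(seeds[1])
  chroms <- unique(vr$chrom)
  gene_chrom <- sample(chroms, n_genes, replace = TRUE,
                       prob = as.numeric(table(vr$chrom)[chroms]))
  span <- vapply(chroms, function(ch) range(vr$pos[vr$chrom == ch]), numeric(2))
  tss <- vapply(seq_len(n_genes), function(k) {
    s <- span[, gene_chrom[k]]
    as.integer(round(stats::runif(1, s[1], s[2])))
  }, integer(1))
  annotation <- tibble::tibble(gene_id = gene_ids, chrom = gene_chrom, tss = tss,
                               strand = sample(c("+", "-"), n_genes, replace = TRUE))

  # planted eQTLs
  set.seed(seeds[2])
  eqtl_gene_idx <- sample.int(n_genes, n_eqtl_genes)
  eqtl_rows <- list()
  for (k in eqtl_gene_idx) {
    is_cis <- stats::runif(1) < cis_fraction
    same_chr <- vr$chrom == gene_chrom[k]
    in_win <- same_chr & abs(vr$pos - tss[k]) <= cis_window
    cand <- if (is_cis) which(in_win) else which(!in_win)
    if (length(cand) == 0) {
      abort_regulatlas(sprintf("no %s variant available for gene %s",
                               if (is_cis) "cis" else "trans", gene_ids[k]))
    }
    v <- cand[sample.int(length(cand), 1)]
    eff <- effect_sd * sample(c(-1, 1), 1)
    if (stats::runif(1) < shared_fraction) {
      scope <- tissues
      effs <- rep(eff, length(tissues))
      if (flip_fraction > 0 && stats::runif(1) < flip_fraction) {
        effs[sample.int(length(tissues), 1)] <- -eff
      }
    } else {
      scope <- sample(tissues, 1)
      effs <- eff
    }
    eqtl_rows[[length(eqtl_rows) + 1]] <- tibble::tibble(
      gene_id = gene_ids[k], tissue = scope,
      variant_id = vr$variant_id[v], variant_idx = v,
      effect = effs, kind = if (is_cis) "cis" else "trans")
  }
  truth_eqtls <- if (length(eqtl_rows)) dplyr::bind_rows(eqtl_rows) else
    tibble::tibble(gene_id = character(), tissue = character(),
                   variant_id = character(), variant_idx = integer(),
                   effect = numeric(), kind = character())

  # planted tissue-specific genes, disjoint from eQTL genes and each other
  pool <- setdiff(seq_len(n_genes), eqtl_gene_idx)
  spec_idx <- if (n_spec_total > 0) sample(pool, n_spec_total) else integer(0)
  truth_specific <- tibble::tibble(
    gene_id = gene_ids[spec_idx],
    tissue = rep(tissues, each = n_specific_per_tissue),
    fold = specific_fold)

  # baselines, loadings, planted dosage effects
  set.seed(seeds[3])
  base <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  low <- sample.int(n_genes, round(low_expr_fraction * n_genes))
  base[low] <- stats::rnorm(length(low), 0.5, 0.5)
  loadings <- if (n_factors > 0)
    matrix(stats::rnorm(n_genes * n_factors, 0, factor_sd), n_genes, n_factors)
  else matrix(0, n_genes, 0)

  zdos <- matrix(0, n, nrow(truth_eqtls))
  if (nrow(truth_eqtls) > 0) {
    for (r in seq_len(nrow(truth_eqtls))) {
      d <- genotypes$dosages[, truth_eqtls$variant_idx[r]]
      s <- stats::sd(d)
      zdos[, r] <- if (s > 0) (d - mean(d)) / s else 0
    }
  }

  set.seed(seeds[4])
  count_blocks <- vector("list", length(tissues))
  names(count_blocks) <- tissues
  for (ti in seq_along(tissues)) {
    t_code <- tissues[ti]
    L <- matrix(rep(base, each = n), n, n_genes)
    sp <- truth_specific[truth_specific$tissue == t_code, ]
    if (nrow(sp) > 0) {
      ki <- match(sp$gene_id, gene_ids)
      L[, ki] <- L[, ki] + rep(log2(sp$fold), each = n)
    }
    er <- which(truth_eqtls$tissue == t_code)
    for (r in er) {
      ki <- match(truth_eqtls$gene_id[r], gene_ids)
      L[, ki] <- L[, ki] + truth_eqtls$effect[r] * zdos[, r]
    }
    if (n_factors > 0) {
      Fs <- matrix(stats::rnorm(n * n_factors), n, n_factors)
      L <- L + Fs %*% t(loadings)
    }
    if (noise_sd > 0) L <- L + matrix(stats::rnorm(n * n_genes, 0, noise_sd), n, n_genes)
    count_blocks[[ti]] <- pmax(round(2^L), 0)
  }

  counts <- do.call(rbind, count_blocks)
  samples <- tibble::tibble(
    sample_id = paste(rep(lines, times = length(tissues)),
                      rep(tissues, each = n), sep = "_"),
    tissue = rep(tissues, each = n),
    line_id = rep(lines, times = length(tissues)))
  expr <- expression_matrix(counts, samples, gene_ids)

  truth <- structure(list(
    eqtls = dplyr::select(truth_eqtls, -"variant_idx"),
    specific = truth_specific,
    loadings = loadings,
    tissues = tissues), class = "sim_truth")
  list(expression = expr, annotation = annotation, truth = truth)
}

#' Simulate a trait with genetic and transcriptomic architecture
#'
#' The trait is a sum of a genetic component (random causal variants), a
#' transcriptomic component (weighted causal-gene expression in one tissue)
#' and noise, with the component variances scaled empirically so that the
#' transcriptome-explained fraction is `target_rho2` and the direct genetic
#' fraction is `genetic_h2`.
#'
#' @param genotypes A [genotype_matrix()].
#' @param expression An [expression_matrix()] from [simulate_expression()].
#' @param n_causal_variants,n_causal_genes Numbers of causal variants/genes.
#' @param target_rho2 Transcriptome-explained variance fraction, in \[0, 1).
#' @param genetic_h2 Direct genetic variance fraction.
#' @param tissue Tissue whose expression drives the trait (default: first).
#' @param causal_genes Optional explicit gene ids to use as the causal set
#'   (overrides the random draw of `n_causal_genes`).
#' @param causal_gene_weights Optional weights for `causal_genes` (default:
#'   standard-normal draws).
#' @param seed Scenario seed.
#' @return List with `trait` (named numeric vector per line) and `truth`.
#' @export
simulate_trait <- function(genotypes, expression, n_causal_variants = 5,
                           n_causal_genes = 20, target_rho2 = 0.5,
                           genetic_h2 = 0.2, tissue = NULL,
                           causal_genes = NULL, causal_gene_weights = NULL,
                           seed = 1) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(expression, "expression_matrix"))
  assert_that(target_rho2 >= 0 && target_rho2 < 1, "`target_rho2` must lie in [0, 1)")
  assert_that(genetic_h2 >= 0 && target_rho2 + genetic_h2 <= 1,
              "`genetic_h2` + `target_rho2` must not exceed 1")
  assert_that(n_causal_variants <= ncol(genotypes$dosages),
              "more causal variants than available")
  assert_that(n_causal_genes <= length(expression$gene_ids),
              "more causal genes than available")
  tissue <- tissue %||% tissues(expression)[1]
  seeds <- derive_seeds(seed, 2)
  lines <- genotypes$sample_ids
  n <- length(lines)

  sel <- expression$samples$tissue == tissue
  assert_that(any(sel), paste0("no samples for tissue ", tissue))
  Z <- log2(expression$counts[sel, , drop = FALSE] + 1)
  Z <- Z[match(lines, expression$samples$line_id[sel]), , drop = FALSE]
  assert_that(!anyNA(Z[, 1]), "expression lines do not cover the genotype panel")

  set.seed(seeds[1])
  gvar <- if (n_causal_variants > 0) sample.int(ncol(genotypes$dosages), n_causal_variants) else integer(0)
  ggene <- if (!is.null(causal_genes)) {
    idx <- match(causal_genes, expression$gene_ids)
    assert_that(!anyNA(idx), "unknown gene id in `causal_genes`")
    idx
  } else if (n_causal_genes > 0) {
    sample.int(ncol(Z), n_causal_genes)
  } else integer(0)
  beta_v <- stats::rnorm(length(gvar))
  w_g <- if (!is.null(causal_gene_weights)) {
    assert_that(length(causal_gene_weights) == length(ggene),
                "`causal_gene_weights` must match the causal gene count")
    causal_gene_weights
  } else stats::rnorm(length(ggene))

  unit_scale <- function(x) {
    s <- stats::sd(x)
    if (s > 0) (x - mean(x)) / s else rep(0, length(x))
  }
  g_part <- if (length(gvar)) unit_scale(impute_dosages(
    genotypes$dosages[, gvar, drop = FALSE]) %*% beta_v) else rep(0, n)
  t_part <- if (length(ggene)) unit_scale(scale(Z[, ggene, drop = FALSE]) %*% w_g) else rep(0, n)

  set.seed(seeds[2])
  noise_var <- 1 - genetic_h2 - target_rho2
  y <- sqrt(genetic_h2) * g_part + sqrt(target_rho2) * t_part +
    sqrt(noise_var) * stats::rnorm(n)
  y <- as.numeric(y)
  names(y) <- lines
  truth <- structure(list(
    causal_variants = tibble::tibble(
      variant_id = genotypes$variants$variant_id[gvar], effect = beta_v),
    causal_genes = tibble::tibble(
      gene_id = expression$gene_ids[ggene], weight = w_g),
    target_rho2 = target_rho2, genetic_h2 = genetic_h2, tissue = tissue),
    class = "sim_truth")
  list(trait = y, truth = truth)
}

#' Simulate replicated multi-environment phenotypes
#'
#' One observation per line per environment:
#' `y = mu + line effect + environment effect + residual`, with the three
#' variance components as stated. Feeds the BLUP stage.
#'
#' @param n_lines,n_envs Numbers of lines and environments.
#' @param var_line,var_env,var_resid Variance components (all >= 0).
#' @param mu Grand mean.
#' @param seed Scenario seed.
#' @return Tibble with columns `line_id`, `env`, `value` and a
#'   `line_effects` attribute holding the simulated true line effects.
#' @export
simulate_multienv_phenotypes <- function(n_lines, n_envs, var_line = 1,
                                         var_env = 0.5, var_resid = 1,
                                         mu = 0, seed = 1) {
  assert_that(n_envs >= 1, "`n_envs` must be >= 1")
  assert_that(all(c(var_line, var_env, var_resid) >= 0), "variances must be >= 0")
  seeds <- derive_seeds(seed, 1)
  set.seed(seeds[1])
  u <- stats::rnorm(n_lines, 0, sqrt(var_line))
  v <- stats::rnorm(n_envs, 0, sqrt(var_env))
  out <- tidyr::expand_grid(line = seq_len(n_lines), env = seq_len(n_envs))
  out$value <- mu + u[out$line] + v[out$env] +
    stats::rnorm(nrow(out), 0, sqrt(var_resid))
  res <- tibble::tibble(line_id = sprintf("L%03d", out$line),
                        env = paste0("E", out$env),
                        value = out$value)
  attr(res, "line_effects") <- stats::setNames(u, sprintf("L%03d", seq_len(n_lines)))
  res
}
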