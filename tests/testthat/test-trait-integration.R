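# trait integration: ORM, PVE delegation, TWAS, colocalization, SMR/HEIDI,
# set-vs-random comparisons and replication

test_that("the ORM is the scaled cross-product of standardized expression", {
  Z <- rbind(c(1, -1), c(0.5, 2), c(-1.5, -1))
  rownames(Z) <- paste0("L", 1:3)
  A <- compute_orm(Z)
  expect_equal(unclass(A), tcrossprod(Z) / 2, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(attr(A, "kind"), "orm")

  # identical expression -> off-diagonal equals diagonal
  Zi <- rbind(c(1, 2, -1), c(1, 2, -1))
  Ai <- compute_orm(Zi)
  expect_equal(Ai[1, 2], Ai[1, 1])

  # orthonormal rows scale to the identity
  Q <- qr.Q(qr(matrix(stats::rnorm(16), 4)))
  Ao <- compute_orm(Q)
  expect_equal(unclass(Ao), diag(4) / 4, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("transcriptome PVE delegates exactly to the REML core", {
  set.seed(1)
  n <- 80
  Z <- scale(matrix(stats::rnorm(n * 50), n, 50))
  rownames(Z) <- paste0("L", 1:n)
  A <- compute_orm(Z)
  y <- stats::rnorm(n)
  f1 <- transcriptome_pve(y, A)
  f2 <- reml_fit(y, A)
  expect_identical(glance(f1), glance(f2))
})

test_that("TWAS reduces to per-gene OLS when the random effect vanishes", {
  set.seed(2)
  n <- 100
  Z <- scale(matrix(stats::rnorm(n * 20), n, 20))
  colnames(Z) <- paste0("g", 1:20)
  y <- stats::rnorm(n) + 0.6 * Z[, 3]
  tw <- twas_scan(y, Z, diag(n))          # identity covariance: OLS limit
  for (j in c(3, 11)) {
    fit <- stats::lm(y ~ Z[, j])
    expect_equal(tw$beta[j], unname(stats::coef(fit)[2]), tolerance = 1e-8)
  }
  expect_equal(which.min(tw$p), 3L)
  expect_true(attr(tw, "threshold_strict") == 0.05 / 20)
})

test_that("TWAS detects a planted causal gene and attaches thresholds", {
  set.seed(3)
  n <- 200
  Z <- scale(matrix(stats::rnorm(n * 100), n, 100))
  colnames(Z) <- paste0("g", 1:100)
  A <- compute_orm(Z)
  y <- sqrt(0.10) * Z[, 7] + sqrt(0.90) * stats::rnorm(n)
  tw <- twas_scan(y, Z, A)
  expect_lt(tw$p[7], attr(tw, "threshold_strict"))
  expect_equal(attr(tw, "threshold_lenient"),
               0.05 / max(1, attr(tw, "n_associated")))

  # null genes give roughly uniform p-values
  y0 <- stats::rnorm(n)
  tw0 <- twas_scan(y0, Z, A)
  expect_gt(stats::ks.test(tw0$p, "punif")$p.value, 0.01)
})

test_that("colocalization applies the strict 100 bp rule per chromosome", {
  clusters <- structure(list(
    members = tibble::tibble(),
    clusters = tibble::tibble(cluster_id = c("clu1", "clu2", "clu3"),
                              chrom = c("1", "1", "2"),
                              n_members = 1L, n_tissues = 1L, n_genes = 1L,
                              min_p = 1e-9,
                              rep_variant = c("vA", "vB", "vC"),
                              rep_pos = c(87808526L, 90000000L, 87808526L))),
    class = "eqtl_clusters")
  qtls <- tibble::tibble(trait = c("zeinoxanthin", "PH", "EH"),
                         chrom = c("1", "1", "2"),
                         pos = c(87808526L, 90000100L, 87808576L),
                         p = 1e-9, source = "cat")
  cc <- colocalize(qtls, clusters, max_dist = 100)
  expect_equal(nrow(cc), 2)
  expect_equal(cc$distance[cc$trait == "zeinoxanthin"], 0)   # same bp
  expect_equal(cc$cluster_id[cc$trait == "EH"], "clu3")      # same chrom only
  expect_false("PH" %in% cc$trait)                           # 100 bp exactly: out
  # deterministic under input reordering
  cc2 <- colocalize(qtls[c(3, 1, 2), ], clusters, max_dist = 100)
  expect_equal(cc, cc2)
})

test_that("the SMR statistic follows its closed form", {
  # symmetric case: T = z^2 / 2
  r <- smr_test(b_gwas = 0.4, se_gwas = 0.1, b_eqtl = 0.4, se_eqtl = 0.1)
  expect_equal(r$t_smr, (0.4 / 0.1)^2 / 2)
  expect_equal(r$b_xy, 1)

  # infinitely strong instrument: T -> z_gwas^2
  r2 <- smr_test(0.4, 0.1, 1, 1e-9)
  expect_equal(r2$t_smr, 16, tolerance = 1e-6)

  # z_gwas = 4, z_eqtl = 6: T = 576 / 52, p from the chi-square(1) tail
  r3 <- smr_test(0.4, 0.1, 0.6, 0.1)
  expect_equal(r3$t_smr, 576 / 52, tolerance = 1e-12)
  expect_equal(r3$p_smr, stats::pchisq(576 / 52, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  # invariant to simultaneous sign flips of both summary effects
  r4 <- smr_test(-0.4, 0.1, -0.6, 0.1)
  expect_equal(r4$p_smr, r3$p_smr)
  expect_equal(r4$b_xy, r3$b_xy)
  expect_error(smr_test(0.4, 0.1, 0, 0.1), "null instrument")
})

test_that("HEIDI returns homogeneity for identical b_xy and NA when starved", {
  ids <- paste0("v", 1:6)
  ld <- outer(1:6, 1:6, function(i, j) 0.8^abs(i - j))
  dimnames(ld) <- list(ids, ids)
  b_e <- c(0.50, 0.40, 0.35, 0.30, 0.28, 0.45)
  region <- tibble::tibble(variant_id = ids,
                           b_eqtl = b_e, se_eqtl = 0.02,
                           b_gwas = 0.3 * b_e, se_gwas = 0.02,
                           p_eqtl = 1e-8)
  ht <- heidi_test(region, "v1", ld)
  expect_equal(ht$t_heidi, 0, tolerance = 1e-20)
  expect_equal(ht$p_heidi, 1)

  starved <- heidi_test(region[1:3, ], "v1", ld[1:3, 1:3])
  expect_true(is.na(starved$p_heidi))
  expect_equal(starved$n_snps, 2)
})

test_that("HEIDI keeps size under mediation and rejects under linkage", {
  p_null <- vapply(1:40, function(s) {
    st <- heidi_mediation_stats(s, n = 2500, eff = 0.2)
    heidi_test(st$region, st$top, st$ld)$p_heidi
  }, numeric(1))
  expect_lt(mean(p_null < 0.05, na.rm = TRUE), 0.2)
  expect_gt(stats::ks.test(p_null, "punif")$p.value, 0.001)

  p_link <- vapply(1:10, function(s) {
    st <- heidi_mediation_stats(s + 900, n = 4000, eff = 0.5,
                                two_causals = TRUE)
    heidi_test(st$region, st$top, st$ld)$p_heidi
  }, numeric(1))
  expect_gt(mean(p_link < 0.05, na.rm = TRUE), 0.6)
})

test_that("colocalized-gene TWAS comparison separates signal from null", {
  set.seed(4)
  n <- 150
  Z <- scale(matrix(stats::rnorm(n * 120), n, 120))
  colnames(Z) <- paste0("g", 1:120)
  A <- compute_orm(Z)
  causal <- paste0("g", 1:10)
  y <- Z[, causal] %*% rep(0.25, 10) + stats::rnorm(n)
  tw <- twas_scan(y, Z, A)
  res <- compare_coloc_vs_random(tw, causal, n_draws = 300, seed = 5)
  expect_lt(res$p_asymptotic, 0.01)
  expect_lt(res$p_empirical, 0.02)

  rand_set <- paste0("g", c(30, 55, 77, 90, 101))
  res0 <- compare_coloc_vs_random(tw, rand_set, n_draws = 300, seed = 6)
  expect_gt(res0$p_empirical, 0.05)

  res_no <- compare_coloc_vs_random(tw, causal, n_draws = 0)
  expect_true(is.na(res_no$p_empirical))
  expect_error(compare_coloc_vs_random(tw, character(0)), "non-empty")
})

test_that("SNP-set PVE stands out against size-matched random draws", {
  set.seed(7)
  n <- 200
  G <- simulate_genotypes(n, 150, seed = 8, n_chrom = 2, switch_prob = 0.4)
  causal_idx <- c(10, 50, 90, 130)
  Zc <- scale(G$dosages[, causal_idx])
  y <- Zc %*% rep(0.45, 4) + stats::rnorm(n)
  snp_set <- G$variants$variant_id[causal_idx]
  res <- suppressWarnings(
    pve_snpset_vs_random(y, G, snp_set, n_draws = 40, seed = 9))
  expect_lt(res$p_empirical, 0.1)
  expect_gt(res$pve_set, stats::median(res$random_pve, na.rm = TRUE))
  res_b <- suppressWarnings(
    pve_snpset_vs_random(y, G, snp_set, n_draws = 40, seed = 9))
  expect_identical(res$random_pve, res_b$random_pve)
  expect_error(pve_snpset_vs_random(y, G, snp_set[1], n_draws = 2),
               "at least 2")
})

test_that("replication correlations flag pairs and summarize the fraction", {
  set.seed(10)
  n <- 120
  cnt <- matrix(stats::rpois(n * 4, 40), n, 4)
  em <- toy_expression(cnt, "LEAF")
  traits2 <- tibble::tibble(line_id = em$samples$line_id,
                            t_perfect = log2(cnt[, 1] + 1),
                            t_null = stats::rnorm(n))
  pairs <- tibble::tibble(gene_id = c("g1", "g2"),
                          trait = c("t_perfect", "t_null"))
  out <- replication_correlation(em, traits2, pairs)
  expect_equal(out$r[1], 1, tolerance = 1e-12)
  expect_true(out$replicated[1])
  expect_equal(attr(out, "replicated_fraction"),
               mean(out$replicated[!out$skipped]))

  # too few complete observations: skipped with flag
  traits3 <- traits2
  traits3$t_null[-(1:2)] <- NA
  out3 <- replication_correlation(em, traits3,
                                  tibble::tibble(gene_id = "g2",
                                                 trait = "t_null"))
  expect_true(out3$skipped)
})
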