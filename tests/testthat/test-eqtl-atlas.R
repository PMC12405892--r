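# eQTL mapping, cis/trans classification, LD r2, cross-tissue clustering
# and effect comparison

test_that("cis/trans classification respects the 1 Mb TSS window", {
  ann <- tibble::tibble(gene_id = "g1", chrom = "chr1", tss = 5e6L, strand = "+")
  recs <- tibble::tibble(gene_id = "g1",
                         chrom = c("chr1", "chr1", "chr1", "chr2"),
                         pos = c(5e6 + 999999, 5e6 + 1000000, 5e6 + 1000001, 5e6))
  out <- classify_cis_trans(recs, ann)
  expect_equal(out$kind, c("cis", "cis", "trans", "trans"))
  expect_error(classify_cis_trans(dplyr::mutate(recs, gene_id = "gX"), ann),
               "absent from annotation")
})

test_that("LD r2 is the squared dosage correlation on complete pairs", {
  D <- cbind(c(0, 1, 2, 0), c(0, 1, 2, 2), c(0, 1, 2, 0), c(2, 2, 2, 2))
  G <- toy_genotypes(D)
  expect_equal(ld_r2(G, "v1", "v3"), 1)
  expect_equal(ld_r2(G, "v1", "v2"), 25 / 121, tolerance = 1e-12)
  expect_error(ld_r2(G, "v1", "v4"), "monomorphic")

  Dorth <- cbind(c(0, 0, 2, 2), c(0, 2, 2, 0))
  expect_equal(ld_r2(toy_genotypes(Dorth), "v1", "v2"), 0)
})

test_that("clustering joins variants by the LD-and-distance chain rule", {
  set.seed(1)
  base <- stats::rbinom(40, 2, 0.4)
  # v1-v2 correlated (r2 ~ 0.2066 pattern scaled up), v3 independent
  v1 <- rep(c(0, 1, 2, 0), 10)
  v2 <- rep(c(0, 1, 2, 2), 10)
  v3 <- sample(0:2, 40, replace = TRUE)
  G <- toy_genotypes(cbind(v1, v2, v3),
                     pos = c(100000L, 550000L, 2000000L))
  recs <- tibble::tibble(gene_id = c("gA", "gB", "gC"),
                         tissue = c("RT", "SH", "RT"),
                         variant_id = c("v1", "v2", "v3"),
                         chrom = "chr1",
                         pos = c(100000L, 550000L, 2000000L),
                         beta = c(0.9, 0.8, 0.5), se = 0.1,
                         p = c(1e-10, 1e-8, 1e-6),
                         kind = "cis", conditional_round = 1L)
  cl <- cluster_eqtls(recs, G, r2_min = 0.2, max_dist = 5e5)
  # 450 kb apart with r2 > 0.2: one cluster; the distant third variant is its own
  expect_equal(nrow(cl$clusters), 2)
  m <- cl$members
  expect_equal(m$cluster_id[m$variant_id == "v1"],
               m$cluster_id[m$variant_id == "v2"])
  expect_false(m$cluster_id[m$variant_id == "v3"] ==
                 m$cluster_id[m$variant_id == "v1"])
  # representative carries the smallest p
  rep1 <- cl$clusters$rep_variant[cl$clusters$cluster_id ==
                                    m$cluster_id[m$variant_id == "v1"]]
  expect_equal(rep1, "v1")

  # distance exactly at the threshold is NOT merged (strict <)
  Gfar <- toy_genotypes(cbind(v1, v1), pos = c(100000L, 600000L))
  recs2 <- recs[1:2, ]
  recs2$variant_id <- c("v1", "v2")
  recs2$pos <- c(100000L, 600000L)
  cl2 <- cluster_eqtls(recs2, Gfar, max_dist = 5e5)
  expect_equal(nrow(cl2$clusters), 2)

  # r2 exactly at the threshold is NOT merged (strict >)
  cl3 <- cluster_eqtls(recs[1:2, ], G, r2_min = 25 / 121, max_dist = 5e5)
  expect_equal(nrow(cl3$clusters), 2)
})

test_that("clustering is invariant to record order and partitions records", {
  set.seed(2)
  G <- simulate_genotypes(80, 60, seed = 3, switch_prob = 0.05, block_size = 10)
  idx <- c(4, 6, 25, 26, 45, 58)
  recs <- tibble::tibble(gene_id = paste0("g", 1:6),
                         tissue = rep(c("RT", "SH"), 3),
                         variant_id = G$variants$variant_id[idx],
                         chrom = G$variants$chrom[idx],
                         pos = G$variants$pos[idx],
                         beta = stats::rnorm(6), se = 0.1,
                         p = stats::runif(6, 1e-12, 1e-6),
                         kind = "cis", conditional_round = 1L)
  cl_a <- cluster_eqtls(recs, G)
  cl_b <- cluster_eqtls(recs[sample(6), ], G)
  key <- function(cl) dplyr::arrange(cl$members, .data$gene_id)[
    , c("gene_id", "cluster_id")]
  expect_equal(key(cl_a), key(cl_b))
  # every record lands in exactly one cluster
  expect_equal(nrow(cl_a$members), nrow(recs))
  expect_true(all(cl_a$members$cluster_id %in% cl_a$clusters$cluster_id))
  # chain rule: members of one cluster are connected via qualifying edges
  for (cid in cl_a$clusters$cluster_id) {
    vv <- unique(cl_a$members$variant_id[cl_a$members$cluster_id == cid])
    if (length(vv) < 2) next
    sub <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(vv)
    for (i in seq_along(vv)) for (j in seq_len(i - 1)) {
      pi <- G$variants$pos[match(vv[i], G$variants$variant_id)]
      pj <- G$variants$pos[match(vv[j], G$variants$variant_id)]
      if (abs(pi - pj) < 5e5 && ld_r2(G, vv[i], vv[j]) > 0.2) {
        sub <- sub + igraph::edges(c(vv[i], vv[j]))
      }
    }
    expect_equal(igraph::components(sub)$no, 1)
  }
})

test_that("eQTL mapping recovers planted signals and counts rounds", {
  set.seed(4)
  n <- 250
  G <- simulate_genotypes(n, 400, seed = 5, n_chrom = 2, switch_prob = 0.2)
  K <- compute_kinship(G, "grm")
  # gene with two independent planted eQTLs, second gene null
  z1 <- scale(G$dosages[, 30]); z2 <- scale(G$dosages[, 350])
  lg <- cbind(g1 = 6 + 0.9 * z1 + 0.9 * z2 + stats::rnorm(n, 0, 0.5),
              g2 = 6 + stats::rnorm(n, 0, 0.5))
  em <- toy_expression(round(2^lg), "RT", line_id = G$sample_ids,
                       gene_ids = c("g1", "g2"))
  pe <- log_standardize(em)
  ann <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                        tss = c(G$variants$pos[30], 100L), strand = "+")
  eq <- map_eqtls(pe, G, K, ann, threshold_p = 1e-6)
  g1_hits <- eq[eq$gene_id == "g1", ]
  expect_equal(sort(g1_hits$conditional_round), 1:2)
  # the two selected variants tag the two planted loci
  tagged <- vapply(g1_hits$variant_id, function(v) {
    which.max(c(ld_r2(G, v, "snp00030"), ld_r2(G, v, "snp00350")))
  }, integer(1))
  expect_setequal(unname(tagged), 1:2)
  for (v in g1_hits$variant_id) {
    expect_gt(max(ld_r2(G, v, "snp00030"), ld_r2(G, v, "snp00350")), 0.5)
  }
  expect_equal(nrow(eq[eq$gene_id == "g2", ]), 0)
  # kind column is always set
  expect_true(all(g1_hits$kind %in% c("cis", "trans")))
  expect_error(map_eqtls(pe, G, K, ann[1, ], threshold_p = 1e-6),
               "absent from annotation")
})

test_that("cross-tissue effect comparison measures correlation and discordance", {
  recs <- tibble::tibble(
    gene_id = rep(paste0("g", 1:10), 2),
    tissue = rep(c("RT", "LT"), each = 10),
    cluster_id = rep(paste0("clu", 1:10), 2),
    variant_id = rep(paste0("v", 1:10), 2),
    chrom = "chr1", pos = 1:20, se = 0.1, p = 1e-9,
    beta = c(1:10 / 10, 1:10 / 10 * c(-1, -1, 1, 1, 1, 1, 1, 1, 1, 1)),
    kind = "cis", conditional_round = 1L)
  cl <- structure(list(members = recs,
                       clusters = tibble::tibble(cluster_id = paste0("clu", 1:10))),
                  class = "eqtl_clusters")
  ct <- cross_tissue_effects(cl)
  expect_equal(nrow(ct$pairs), 10)
  expect_equal(ct$summary$sign_discordance, 0.2)

  same <- recs
  same$beta <- rep(1:10 / 10, 2)
  cl2 <- structure(list(members = same, clusters = cl$clusters),
                   class = "eqtl_clusters")
  ct2 <- cross_tissue_effects(cl2)
  expect_equal(ct2$summary$sign_discordance, 0)
  expect_equal(ct2$summary$pearson_r, 1)

  solo <- recs[recs$tissue == "RT", ]
  cl3 <- structure(list(members = solo, clusters = cl$clusters),
                   class = "eqtl_clusters")
  expect_equal(nrow(cross_tissue_effects(cl3)$pairs), 0)
})
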