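# QC filters, standardization, latent factors, relatedness matrices, PCA
# and multi-environment BLUPs

test_that("gene detection filter uses a strict majority per tissue", {
  cnt <- cbind(g1 = rep(1, 10),                       # 10/10
               g2 = c(rep(2, 6), rep(0, 4)),          # 6/10
               g3 = c(rep(2, 5), rep(0, 5)),          # 5/10 (boundary)
               g4 = rep(0, 10))                       # 0/10
  em <- toy_expression(cnt, "RT")
  fs <- filter_genes(em, 0.5)
  expect_equal(colnames(fs$RT$counts), c("g1", "g2"))
})

test_that("log standardization gives exact log2 values and unit moments", {
  em <- toy_expression(cbind(g1 = c(0, 1, 3), g2 = c(5, 5, 5)), "RT")
  pe <- log_standardize(em)
  # raw log2(count + 1) of [0, 1, 3] is [0, 1, 2]
  expect_equal(log2(c(0, 1, 3) + 1), c(0, 1, 2))
  expect_equal(pe$RT$dropped, "g2")        # constant gene flagged out
  expect_equal(mean(pe$RT$z[, "g1"]), 0, tolerance = 1e-12)
  expect_equal(stats::var(pe$RT$z[, "g1"]), 1, tolerance = 1e-10)
})

test_that("filter + standardize leaves every kept column with mean 0 / var 1", {
  G <- simulate_genotypes(40, 20, seed = 1, n_chrom = 2)
  sim <- simulate_expression(G, tissues = c("RT", "SH"), n_genes = 80,
                             n_eqtl_genes = 5, seed = 2)
  pe <- log_standardize(filter_genes(sim$expression))
  for (t_code in names(pe)) {
    expect_true(all(abs(colMeans(pe[[t_code]]$z)) < 1e-8))
    expect_true(all(abs(apply(pe[[t_code]]$z, 2, stats::var) - 1) < 1e-6))
  }
})

test_that("latent factors reproduce planted structure and stay orthogonal", {
  set.seed(3)
  n <- 60
  v <- stats::rnorm(n)
  Z <- tcrossprod(v, stats::rnorm(40))            # rank-1 matrix
  pe <- structure(list(RT = list(
    z = Z, samples = tibble::tibble(sample_id = paste0("s", 1:n),
                                    tissue = "RT",
                                    line_id = paste0("L", 1:n)),
    dropped = character(0))), class = "processed_expression")
  f1 <- estimate_latent_factors(pe, k = 1)$RT
  expect_gt(abs(stats::cor(f1[, 1], v)), 0.999999)

  f0 <- estimate_latent_factors(pe, k = 0)$RT
  expect_equal(ncol(f0), 0)
  expect_error(estimate_latent_factors(pe, k = n), "smaller than")

  # planted 3-factor recovery by canonical correlation
  set.seed(4)
  Fs <- matrix(stats::rnorm(100 * 3), 100, 3)
  L <- matrix(stats::rnorm(3 * 200), 3, 200)
  Z3 <- scale(Fs %*% L + matrix(stats::rnorm(100 * 200, 0, 0.3), 100, 200))
  pe3 <- structure(list(RT = list(
    z = Z3, samples = tibble::tibble(sample_id = paste0("s", 1:100),
                                     tissue = "RT",
                                     line_id = paste0("L", 1:100)),
    dropped = character(0))), class = "processed_expression")
  f3 <- estimate_latent_factors(pe3, k = 3)$RT
  cc <- stats::cancor(f3, Fs)$cor
  expect_true(all(cc > 0.95))
  expect_equal(crossprod(scale(f3, scale = FALSE))[1, 2], 0, tolerance = 1e-6)
})

test_that("IBS matches its allele-sharing definition", {
  D <- rbind(c(0, 2, 1), c(0, 2, 1), c(2, 0, 1))
  G <- toy_genotypes(D)
  K <- compute_kinship(G, "ibs")
  expect_equal(K[1, 2], 1)                      # identical individuals
  expect_equal(K[1, 3], (0 + 0 + 1) / 3)        # two opposite + one shared het
  Dop <- rbind(c(0, 0, 2), c(2, 2, 0))
  expect_equal(compute_kinship(toy_genotypes(Dop), "ibs")[1, 2], 0)

  # missing pairs are excluded per variant
  Dm <- rbind(c(0, NA, 2), c(0, 2, 2), c(2, 2, NA))
  Km <- suppressWarnings(compute_kinship(toy_genotypes(Dm), "ibs"))
  expect_equal(Km[1, 2], (2 + 2) / 4)           # variants 1 and 3 only
})

test_that("GRM equals the hand-computed scaled cross-product", {
  D <- rbind(c(0, 2), c(1, 1), c(2, 0))
  G <- toy_genotypes(D)
  K <- compute_kinship(G, "grm")
  p <- colMeans(D) / 2
  Z <- sweep(sweep(D, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  expect_equal(unclass(K), tcrossprod(Z) / 2, ignore_attr = TRUE,
               tolerance = 1e-12)

  # exchangeable under sample permutation
  perm <- c(3, 1, 2)
  Kp <- compute_kinship(toy_genotypes(D[perm, ]), "grm")
  expect_equal(unclass(Kp), unclass(K)[perm, perm], ignore_attr = TRUE,
               tolerance = 1e-12)

  Dmono <- cbind(c(0, 0, 0), c(0, 1, 2))
  expect_warning(compute_kinship(toy_genotypes(Dmono), "grm"), "MAF 0")
})

test_that("relationship-matrix PCA separates clusters and orders fractions", {
  n <- 20
  M <- matrix(0.05, n, n)
  M[1:10, 1:10] <- 0.9
  M[11:20, 11:20] <- 0.9
  diag(M) <- 1
  pc <- pca_relationship(relationship_matrix(M, "grm"), n_pc = 3,
                         groups = rep(c("a", "b"), each = 10))
  s1 <- pc$scores$PC1
  expect_true(all(s1[1:10] * s1[11:20][1] < 0))  # PC1 splits the two blocks
  expect_true(all(diff(pc$all_fractions) <= 1e-12))
  expect_lte(sum(pc$all_fractions), 1 + 1e-8)
  expect_gt(pc$fractions[1], 0.8)
})

test_that("BLUPs shrink line means by the balanced closed form", {
  ph <- simulate_multienv_phenotypes(80, 4, var_line = 1, var_env = 0.5,
                                     var_resid = 1, seed = 21)
  bl <- compute_blups(ph)
  # closed form: blup = shrink * (line mean - env-adjusted grand mean)
  s_l <- attr(bl, "sigma_line2"); s_e <- attr(bl, "sigma_e2")
  shrink <- s_l / (s_l + s_e / 4)
  adj <- stats::lm(value ~ env, data = ph)
  dev <- tapply(stats::resid(adj), ph$line_id, mean)
  expect_equal(bl$blup, as.numeric(shrink * dev[bl$line_id]), tolerance = 1e-6)
})

test_that("BLUPs agree with the lme4 oracle on an unbalanced design", {
  skip_if_not_installed("lme4")
  ph <- simulate_multienv_phenotypes(50, 3, var_line = 1.5, var_env = 0.3,
                                     var_resid = 0.8, seed = 22)
  ph <- ph[-c(3, 17, 40, 90), ]    # unbalance it
  bl <- compute_blups(ph)
  fit <- lme4::lmer(value ~ env + (1 | line_id), data = ph, REML = TRUE)
  u <- lme4::ranef(fit)$line_id
  expect_equal(bl$blup, u[bl$line_id, 1], tolerance = 1e-4)
})

test_that("BLUPs collapse to zero when the line variance vanishes", {
  ph <- simulate_multienv_phenotypes(60, 4, var_line = 0, var_env = 0.5,
                                     var_resid = 1, seed = 23)
  bl <- compute_blups(ph)
  expect_lt(max(abs(bl$blup)), 0.05)
  one_obs <- tibble::tibble(line_id = paste0("L", 1:5), env = "E1",
                            value = stats::rnorm(5))
  expect_error(compute_blups(one_obs), "not estimable")
})
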