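# QC and preprocessing: per-tissue gene detection filter, log2
# standardization, latent-factor covariates, relatedness matrices, PCA of a
# relationship matrix, and multi-environment BLUPs.

#' Filter genes by per-tissue detection rate
#'
#' Within each tissue, keeps genes expressed (count > 0) in strictly more
#' than `min_expressed_fraction` of that tissue's samples. Because every
#' downstream analysis is per tissue, the result is a named list of
#' per-tissue expression matrices, each with its own kept-gene set.
#'
#' @param expr An [expression_matrix()].
#' @param min_expressed_fraction Detection-rate threshold (strict
#'   inequality), in (0, 1].
#' @return Named list (one [expression_matrix()] per tissue) of class
#'   `expression_set`.
#' @export
filter_genes <- function(expr, min_expressed_fraction = 0.5) {
  stopifnot(inherits(expr, "expression_matrix"))
  assert_that(min_expressed_fraction > 0 && min_expressed_fraction <= 1,
              "`min_expressed_fraction` must lie in (0, 1]")
  tset <- tissues(expr)
  out <- lapply(tset, function(t_code) {
    sel <- expr$samples$tissue == t_code
    assert_that(sum(sel) > 0, paste0("tissue ", t_code, " has no samples"))
    cnt <- expr$counts[sel, , drop = FALSE]
    frac <- colMeans(cnt > 0)
    keep <- frac > min_expressed_fraction
    assert_that(any(keep), paste0("no genes pass the detection filter in tissue ", t_code))
    expression_matrix(cnt[, keep, drop = FALSE], expr$samples[sel, ],
                      expr$gene_ids[keep])
  })
  names(out) <- tset
  structure(out, class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat("<expression_set>\n")
  for (t_code in names(x)) {
    cat(sprintf("  %s: %d samples x %d genes\n", t_code,
                nrow(x[[t_code]]$counts), ncol(x[[t_code]]$counts)))
  }
  invisible(x)
}

#' Log2-transform and standardize expression per tissue
#'
#' Computes `log2(count + 1)` and z-scores each gene within tissue so that
#' every kept column has mean 0 and variance 1; zero-variance genes are
#' flagged and excluded from the standardized output. Standardization makes
#' eQTL effect sizes comparable across tissues.
#'
#' @param expr An [expression_matrix()] or an `expression_set` from
#'   [filter_genes()].
#' @return Object of class `processed_expression`: a named per-tissue list
#'   with elements `z` (samples x kept genes, standardized), `samples`
#'   (metadata tibble) and `dropped` (zero-variance gene ids).
#' @export
log_standardize <- function(expr) {
  if (inherits(expr, "expression_matrix")) {
    tset <- tissues(expr)
    expr <- structure(lapply(tset, function(t_code) {
      sel <- expr$samples$tissue == t_code
      expression_matrix(expr$counts[sel, , drop = FALSE], expr$samples[sel, ],
                        expr$gene_ids)
    }), names = tset, class = "expression_set")
  }
  stopifnot(inherits(expr, "expression_set") || is.list(expr))
  out <- lapply(expr, function(em) {
    lg <- log2(em$counts + 1)
    sds <- apply(lg, 2, stats::sd)
    dropped <- em$gene_ids[sds == 0]
    z <- scale(lg[, sds > 0, drop = FALSE])
    attr(z, "scaled:center") <- NULL
    attr(z, "scaled:scale") <- NULL
    list(z = z, samples = em$samples, dropped = dropped)
  })
  structure(out, class = "processed_expression")
}

#' @export
print.processed_expression <- function(x, ...) {
  cat("<processed_expression>\n")
  for (t_code in names(x)) {
    cat(sprintf("  %s: %d samples x %d genes (%d zero-variance dropped)\n",
                t_code, nrow(x[[t_code]]$z), ncol(x[[t_code]]$z),
                length(x[[t_code]]$dropped)))
  }
  invisible(x)
}

#' Estimate latent expression covariates per tissue
#'
#' Deterministic surrogate for hidden-factor estimation: the first `k` left
#' singular vectors of each tissue's standardized expression matrix, scaled
#' to unit variance. Factors are mutually orthogonal and are intended as
#' nuisance covariates in eQTL scans, absorbing batch effects and broad
#' transcriptome-wide variation.
#'
#' @param pe A `processed_expression` from [log_standardize()].
#' @param k Number of factors per tissue (default 25).
#' @return Named list of samples x k factor-score matrices, class
#'   `latent_factors`.
#' @export
estimate_latent_factors <- function(pe, k = 25) {
  stopifnot(inherits(pe, "processed_expression"))
  out <- lapply(pe, function(tt) {
    n <- nrow(tt$z)
    assert_that(k < n, "`k` must be smaller than the tissue's sample count")
    if (k == 0) {
      f <- matrix(numeric(0), n, 0)
    } else {
      sv <- svd(tt$z, nu = k, nv = 0)
      f <- sv$u * sqrt(n - 1)   # unit-variance, orthogonal columns
      colnames(f) <- paste0("factor", seq_len(k))
    }
    rownames(f) <- tt$samples$sample_id
    f
  })
  structure(out, class = "latent_factors")
}

#' Compute a genomic relatedness matrix
#'
#' `kind = "ibs"` gives the identity-by-state matrix
#' `IBS[i, j] = mean((2 - |d_i - d_j|) / 2)` over variants where both
#' samples are called. `kind = "grm"` gives the standard centered-scaled
#' cross-product `Z Z' / m` with mean-imputed missing dosages; variants with
#' MAF 0 cannot be scaled and are skipped with a warning.
#'
#' @param G A [genotype_matrix()] with at least 2 samples and 1 variant.
#' @param kind `"ibs"` or `"grm"`.
#' @return A [relationship_matrix()].
#' @export
compute_kinship <- function(G, kind = c("grm", "ibs")) {
  kind <- match.arg(kind)
  stopifnot(inherits(G, "genotype_matrix"))
  D <- G$dosages
  n <- nrow(D); m <- ncol(D)
  assert_that(n >= 2 && m >= 1, "need at least 2 samples and 1 variant")
  if (kind == "ibs") {
    has <- !is.na(D)
    X0 <- (D == 0) & has; X1 <- (D == 1) & has; X2 <- (D == 2) & has
    X0[is.na(X0)] <- FALSE; X1[is.na(X1)] <- FALSE; X2[is.na(X2)] <- FALSE
    X0 <- X0 * 1; X1 <- X1 * 1; X2 <- X2 * 1
    S <- tcrossprod(X0, X1) + tcrossprod(X1, X0) +
      tcrossprod(X1, X2) + tcrossprod(X2, X1) +
      2 * (tcrossprod(X0, X2) + tcrossprod(X2, X0))
    NN <- tcrossprod(has * 1)
    assert_that(all(NN > 0), "some sample pairs share no called variants")
    M <- 1 - S / (2 * NN)
    M <- (M + t(M)) / 2
    return(relationship_matrix(M, "ibs", G$sample_ids))
  }
  D <- impute_dosages(D)
  p <- colMeans(D) / 2
  ok <- p > 0 & p < 1
  if (any(!ok)) {
    rlang::warn(sprintf("compute_kinship: skipping %d variant(s) with MAF 0", sum(!ok)))
  }
  assert_that(any(ok), "no polymorphic variants for GRM")
  Dp <- D[, ok, drop = FALSE]; pp <- p[ok]
  Z <- sweep(Dp, 2, 2 * pp, "-")
  Z <- sweep(Z, 2, sqrt(2 * pp * (1 - pp)), "/")
  A <- tcrossprod(Z) / ncol(Z)
  relationship_matrix((A + t(A)) / 2, "grm", G$sample_ids)
}

#' Principal component analysis of a relationship matrix
#'
#' Eigendecomposition of the double-centered relationship matrix; the
#' variance-explained fraction of each component is its eigenvalue divided
#' by the trace of the centered matrix.
#'
#' @param R A [relationship_matrix()] (or symmetric matrix).
#' @param n_pc Number of components to return.
#' @param groups Optional per-sample grouping (carried into the scores table
#'   for plotting).
#' @return Object of class `relmat_pca`: list with `scores` (tibble:
#'   sample_id, PC1..PCk, group) and `fractions` (variance-explained,
#'   descending).
#' @export
pca_relationship <- function(R, n_pc = 2, groups = NULL) {
  M <- as_relationship_input(R)
  n <- nrow(M)
  assert_that(n_pc <= n, "`n_pc` cannot exceed the sample count")
  H <- diag(n) - matrix(1 / n, n, n)
  B <- H %*% M %*% H
  B <- (B + t(B)) / 2
  ev <- eigen(B, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  tr <- sum(lam)
  scores <- ev$vectors[, seq_len(n_pc), drop = FALSE] %*%
    diag(sqrt(lam[seq_len(n_pc)]), n_pc)
  colnames(scores) <- paste0("PC", seq_len(n_pc))
  ids <- rownames(M) %||% paste0("S", seq_len(n))
  tab <- dplyr::bind_cols(tibble::tibble(sample_id = ids),
                          tibble::as_tibble(scores))
  if (!is.null(groups)) tab$group <- groups
  structure(list(scores = tab,
                 fractions = lam[seq_len(n_pc)] / tr,
                 all_fractions = lam / tr),
            class = "relmat_pca")
}

#' Best linear unbiased predictors of line values across environments
#'
#' Fits `value = mu + environment (fixed) + line (random) + e` by REML on
#' the package's mixed-model core (the line random effect enters through the
#' relationship matrix `Z Z'` of the line incidence) and returns each line's
#' BLUP, i.e. its shrunken deviation from the environment-adjusted mean.
#'
#' @param pheno Data frame with columns `line_id`, `env`, `value`
#'   (one observation per line per environment, unbalanced designs allowed).
#' @return Tibble with columns `line_id`, `blup`; the variance components of
#'   the fit are attached as attributes (`sigma_line2`, `sigma_e2`).
#' @export
compute_blups <- function(pheno) {
  pheno <- tibble::as_tibble(pheno)
  assert_that(all(c("line_id", "env", "value") %in% names(pheno)),
              "`pheno` needs line_id, env, value columns")
  lines <- sort(unique(pheno$line_id))
  envs <- sort(unique(pheno$env))
  assert_that(length(lines) >= 2, "need at least 2 lines")
  assert_that(nrow(pheno) > length(lines),
              "variance components are not estimable with a single observation per line")
  y <- pheno$value
  n <- length(y)
  Z <- matrix(0, n, length(lines))
  Z[cbind(seq_len(n), match(pheno$line_id, lines))] <- 1
  C_env <- if (length(envs) > 1) {
    stats::model.matrix(~ factor(env, levels = envs), data = pheno)[, -1, drop = FALSE]
  } else NULL
  R <- tcrossprod(Z)
  fit <- reml_fit(y, R, covariates = C_env)
  if (!fit$converged || is.na(fit$sigma_u2)) {
    return(tibble::tibble(line_id = lines, blup = 0))
  }
  rot <- fit$rotation
  v <- fit$sigma_u2 * rot$d + fit$sigma_e2
  C <- cbind(1, C_env)
  Ct <- crossprod(rot$U, C); yt <- crossprod(rot$U, y)
  Wi <- 1 / v
  beta <- solve(crossprod(Ct, Ct * Wi), crossprod(Ct * Wi, yt))
  resid_rot <- as.numeric(yt - Ct %*% beta)
  vinv_r <- rot$U %*% (resid_rot * Wi)
  u <- fit$sigma_u2 * crossprod(Z, vinv_r)
  out <- tibble::tibble(line_id = lines, blup = as.numeric(u))
  attr(out, "sigma_line2") <- fit$sigma_u2
  attr(out, "sigma_e2") <- fit$sigma_e2
  out
}
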