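# Mixed-linear-model core: REML variance components with an arbitrary
# relationship matrix, GLS association scans (EMMAX-style one-time fit or
# exact per-variant refits), stepwise conditional analysis, and the
# effective-marker-number multiple-testing threshold.
#
# Everything works in the rotated coordinate system of the relationship
# matrix: with R = U D U', V = sigma_u2 R + sigma_e2 I becomes diagonal
# after rotation by U', so REML reduces to 1-d profile optimization and each
# association test to a weighted regression.

rotate_setup <- function(R, n = NULL) {
  M <- as_relationship_input(R, n)
  ev <- eigen(M, symmetric = TRUE)
  dmax <- max(abs(ev$values), 1)
  assert_that(min(ev$values) >= -0.05 * dmax,
              "relationship matrix is not positive semi-definite")
  list(U = ev$vectors, d = pmax(ev$values, 0))
}

# restricted negative log-likelihood profiled over h at unit total variance;
# returns the objective up to an additive constant
reml_negll <- function(h, yt, Ct, d) {
  w <- h * d + (1 - h)
  Wi <- 1 / w
  Cw <- Ct * Wi
  M <- crossprod(Ct, Cw)
  cM <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(cM)) return(Inf)
  beta <- backsolve(cM, forwardsolve(t(cM), crossprod(Cw, yt)))
  r <- yt - Ct %*% beta
  rss <- sum(Wi * r^2)
  n <- length(yt); p <- ncol(Ct)
  sigma2 <- rss / (n - p)
  if (sigma2 <= 0) return(Inf)
  0.5 * ((n - p) * log(sigma2) + sum(log(w)) + 2 * sum(log(diag(cM))))
}

reml_profile <- function(yt, Ct, d, h_bounds = c(1e-6, 1 - 1e-6), tol = 1e-9) {
  flat <- (max(d) - min(d)) < 1e-7 * max(d, 1)
  if (flat) return(list(h = NA_real_, negll = NA_real_, flat = TRUE))
  f <- function(h) reml_negll(h, yt, Ct, d)
  opt <- stats::optimize(f, interval = h_bounds, tol = tol)
  cand_h <- c(opt$minimum, h_bounds)
  cand_v <- c(opt$objective, f(h_bounds[1]), f(h_bounds[2]))
  best <- which.min(cand_v)
  list(h = cand_h[best], negll = cand_v[best], flat = FALSE)
}

#' Fit variance components by REML with a relationship matrix
#'
#' Fits `y = C beta + u + e` with `u ~ N(0, sigma_u2 R)` and
#' `e ~ N(0, sigma_e2 I)`. The relationship matrix is eigendecomposed once
#' and the restricted likelihood is profiled over the intraclass correlation
#' `rho2 = sigma_u2 / (sigma_u2 + sigma_e2)` by bracketed scalar
#' optimization in the rotated coordinates. The standard error of `rho2`
#' comes from the observed information (numerical curvature of the profile
#' restricted log-likelihood).
#'
#' When `R` is proportional to the identity the two components are aliased
#' and the fit is flagged `converged = FALSE` with `rho2 = NA`.
#'
#' @param y Numeric response vector.
#' @param R Relationship matrix ([relationship_matrix()] or plain symmetric
#'   matrix) matching `y` in dimension.
#' @param covariates Optional numeric matrix of fixed covariates (an
#'   intercept is always added).
#' @return An object of class `reml_fit` with elements `sigma_u2`,
#'   `sigma_e2`, `rho2`, `se_rho2`, `log_likelihood`, `converged`.
#' @export
reml_fit <- function(y, R, covariates = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  C <- cbind(`(Intercept)` = rep(1, n), covariates)
  assert_that(nrow(C) == n, "covariate rows must match `y`")
  assert_that(n > ncol(C) + 1, "too few observations for REML")
  rot <- rotate_setup(R, n)
  yt <- crossprod(rot$U, y)
  Ct <- crossprod(rot$U, C)
  prof <- reml_profile(yt, Ct, rot$d)
  p <- ncol(C)
  if (prof$flat) {
    r <- stats::lm.fit(C, y)$residuals
    out <- list(sigma_u2 = NA_real_, sigma_e2 = sum(r^2) / (n - p),
                rho2 = NA_real_, se_rho2 = NA_real_,
                log_likelihood = NA_real_, converged = FALSE,
                n = n, p = p, rotation = rot, h = NA_real_)
    return(structure(out, class = "reml_fit"))
  }
  h <- prof$h
  w <- h * rot$d + (1 - h)
  Wi <- 1 / w
  Cw <- Ct * Wi
  M <- crossprod(Ct, Cw)
  beta <- solve(M, crossprod(Cw, yt))
  rss <- sum(Wi * (yt - Ct %*% beta)^2)
  sigma2 <- rss / (n - p)
  # observed information for rho2 = h from the profile likelihood
  delta <- min(1e-4, h / 2, (1 - h) / 2)
  d2 <- (reml_negll(h + delta, yt, Ct, rot$d) - 2 * prof$negll +
           reml_negll(h - delta, yt, Ct, rot$d)) / delta^2
  se_rho2 <- if (is.finite(d2) && d2 > 0) sqrt(1 / d2) else NA_real_
  ll <- -prof$negll - 0.5 * (n - p) * (1 + log(2 * pi))
  structure(list(sigma_u2 = h * sigma2, sigma_e2 = (1 - h) * sigma2,
                 rho2 = h, se_rho2 = se_rho2, log_likelihood = ll,
                 converged = TRUE, n = n, p = p, beta = as.numeric(beta),
                 rotation = rot, h = h),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<reml_fit> unidentifiable (relationship matrix ~ identity); rho2 = NA\n")
  } else {
    cat(sprintf("<reml_fit> rho2 = %.4f (SE %.4f), sigma_u2 = %.4g, sigma_e2 = %.4g, n = %d\n",
                x$rho2, x$se_rho2, x$sigma_u2, x$sigma_e2, x$n))
  }
  invisible(x)
}

# vectorized GLS Wald statistics for each column of Xt given diagonal
# rotated covariance weights v (V = U diag(v) U'); all inputs pre-rotated
gls_scan_stats <- function(yt, Ct, Xt, v, Xt_sq = NULL) {
  Wi <- 1 / v
  Cw <- Ct * Wi
  M <- crossprod(Ct, Cw)
  Mi <- solve(M)
  a <- Wi * yt - Cw %*% (Mi %*% crossprod(Cw, yt))
  num <- as.numeric(crossprod(Xt, a))
  B <- crossprod(Cw, Xt)
  qf <- colSums(B * (Mi %*% B))
  if (is.null(Xt_sq)) Xt_sq <- Xt^2
  den <- as.numeric(crossprod(Xt_sq, Wi)) - unname(qf)
  mono <- den <= 1e-10 * max(den, 1e-300)
  beta <- z <- numeric(length(den))
  se <- rep(NA_real_, length(den))
  p <- rep(1, length(den))
  ok <- !mono
  beta[ok] <- num[ok] / den[ok]
  se[ok] <- sqrt(1 / den[ok])
  z[ok] <- beta[ok] / se[ok]
  p[ok] <- 2 * stats::pnorm(-abs(z[ok]))
  tibble::tibble(beta = beta, se = se, z = z, p = p,
                 note = ifelse(mono, "monomorphic", NA_character_))
}

#' Mixed-linear-model association scan
#'
#' Tests each variant for association with `y` under a mixed model with the
#' relationship-matrix random effect. In `"emmax"` mode the variance
#' components are fit once under the null model and every variant is tested
#' by GLS with the fixed covariance `V = sigma_u2 R + sigma_e2 I`; in
#' `"exact"` mode the components are refit for every variant. Two-sided
#' Wald p-values use the normal reference. Missing dosages are mean-imputed
#' per variant; variants monomorphic after imputation are reported with
#' `beta = 0`, `p = 1` and a note.
#'
#' @param y Numeric trait vector, one value per sample of `G`.
#' @param G A [genotype_matrix()].
#' @param R Relationship matrix (e.g. from [compute_kinship()]).
#' @param covariates Optional fixed-covariate matrix (intercept added).
#' @param mode `"emmax"` (default) or `"exact"`.
#' @return Tibble with columns `variant_id`, `chrom`, `pos`, `beta`, `se`,
#'   `z`, `p`, `note`; variance-component estimates of the null model are
#'   attached as attributes `sigma_u2`/`sigma_e2`.
#' @export
mlm_scan <- function(y, G, R, covariates = NULL, mode = c("emmax", "exact")) {
  mode <- match.arg(mode)
  stopifnot(inherits(G, "genotype_matrix"))
  y <- as.numeric(y)
  n <- length(y)
  assert_that(n == nrow(G$dosages), "`y` must have one value per genotype sample")
  D <- impute_dosages(G$dosages)
  C <- cbind(`(Intercept)` = rep(1, n), covariates)
  fit0 <- reml_fit(y, R, covariates = covariates)
  rot <- fit0$rotation
  if (!fit0$converged) {
    v <- rep(fit0$sigma_e2, n)   # aliased components: OLS covariance
    sigma_u2 <- 0; sigma_e2 <- fit0$sigma_e2
  } else {
    v <- fit0$sigma_u2 * rot$d + fit0$sigma_e2
    sigma_u2 <- fit0$sigma_u2; sigma_e2 <- fit0$sigma_e2
  }
  yt <- crossprod(rot$U, y)
  Ct <- crossprod(rot$U, C)
  Xt <- crossprod(rot$U, D)
  if (mode == "emmax") {
    stats_tab <- gls_scan_stats(yt, Ct, Xt, v)
  } else {
    m <- ncol(D)
    rows <- vector("list", m)
    for (j in seq_len(m)) {
      g <- D[, j]
      if (stats::sd(g) == 0) {
        rows[[j]] <- tibble::tibble(beta = 0, se = NA_real_, z = 0, p = 1,
                                    note = "monomorphic")
        next
      }
      fit_j <- reml_fit(y, R, covariates = cbind(covariates, g))
      v_j <- if (fit_j$converged) fit_j$sigma_u2 * rot$d + fit_j$sigma_e2
             else rep(fit_j$sigma_e2, n)
      rows[[j]] <- gls_scan_stats(yt, Ct, Xt[, j, drop = FALSE], v_j)
    }
    stats_tab <- dplyr::bind_rows(rows)
  }
  out <- dplyr::bind_cols(G$variants[c("variant_id", "chrom", "pos")], stats_tab)
  attr(out, "sigma_u2") <- sigma_u2
  attr(out, "sigma_e2") <- sigma_e2
  out
}

#' Stepwise conditional association analysis
#'
#' Repeats the mixed-model scan, each round adding the smallest-p variant
#' below `threshold_p` to the fixed covariates, until no variant passes.
#' Ties are broken by smallest p, then smallest position, then lexicographic
#' variant id. A candidate perfectly collinear with the already-selected
#' dosages is skipped with a warning.
#'
#' @inheritParams mlm_scan
#' @param threshold_p Significance threshold for entering the model.
#' @param max_rounds Safety cap on the number of rounds.
#' @return Tibble of selected variants in selection order with their
#'   conditional effects (`round`, `beta`, `se`, `z`, `p`).
#' @export
conditional_scan <- function(y, G, R, threshold_p, covariates = NULL,
                             mode = c("emmax", "exact"), max_rounds = 50) {
  mode <- match.arg(mode)
  assert_that(threshold_p > 0 && threshold_p < 1, "`threshold_p` must lie in (0, 1)")
  selected <- character(0)
  sel_dos <- NULL
  rows <- list()
  for (round in seq_len(max_rounds)) {
    scan <- mlm_scan(y, G, R, covariates = cbind(covariates, sel_dos), mode = mode)
    cand <- scan[is.na(scan$note) & scan$p < threshold_p &
                   !(scan$variant_id %in% selected), ]
    if (nrow(cand) == 0) break
    cand <- cand[order(cand$p, cand$pos, cand$variant_id), ]
    picked <- FALSE
    for (i in seq_len(nrow(cand))) {
      g <- impute_dosages(G$dosages[, cand$variant_id[i], drop = FALSE])
      if (!is.null(sel_dos) &&
          any(abs(suppressWarnings(stats::cor(g, sel_dos))) >= 1 - 1e-10, na.rm = TRUE)) {
        rlang::warn(sprintf("conditional_scan: skipping %s (collinear with selected set)",
                            cand$variant_id[i]))
        next
      }
      sel_dos <- cbind(sel_dos, g)
      selected <- c(selected, cand$variant_id[i])
      rows[[length(rows) + 1]] <- dplyr::mutate(cand[i, ], round = round,
                                                .before = "beta")
      picked <- TRUE
      break
    }
    if (!picked) break
  }
  if (length(rows) == 0) {
    return(tibble::tibble(variant_id = character(), chrom = character(),
                          pos = integer(), note = character(), round = integer(),
                          beta = numeric(), se = numeric(), z = numeric(),
                          p = numeric())[, c("variant_id", "chrom", "pos", "round",
                                             "beta", "se", "z", "p", "note")])
  }
  dplyr::bind_rows(rows)
}

#' Ordinary least-squares marginal association scan
#'
#' Per-variant marginal regression of `y` on dosage (optionally after
#' projecting out covariates), returning summary statistics in the same
#' record shape as [mlm_scan()]. This is the summary-statistics generator
#' for SMR/HEIDI region analyses and for unstructured panels where no
#' kinship correction is needed; two-sided p-values use the normal
#' reference.
#'
#' @inheritParams mlm_scan
#' @return Tibble with columns `variant_id`, `chrom`, `pos`, `beta`, `se`,
#'   `z`, `p`, `note`.
#' @export
ols_scan <- function(y, G, covariates = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  y <- as.numeric(y)
  n <- length(y)
  assert_that(n == nrow(G$dosages), "`y` must have one value per genotype sample")
  D <- impute_dosages(G$dosages)
  C <- cbind(rep(1, n), covariates)
  qC <- qr(C)
  yr <- qr.resid(qC, y)
  Dr <- qr.resid(qC, D)
  sxx <- unname(colSums(Dr^2))
  mono <- sxx <= 1e-10 * max(sxx, 1e-300)
  sxy <- as.numeric(crossprod(Dr, yr))
  beta <- ifelse(mono, 0, sxy / sxx)
  rss <- pmax(sum(yr^2) - ifelse(mono, 0, sxy^2 / sxx), 0)
  df <- n - ncol(C) - 1
  se <- ifelse(mono, NA_real_, sqrt(rss / df / sxx))
  z <- ifelse(mono, 0, beta / se)
  p <- ifelse(mono, 1, 2 * stats::pnorm(-abs(z)))
  dplyr::bind_cols(G$variants[c("variant_id", "chrom", "pos")],
                   tibble::tibble(beta = beta, se = se, z = z, p = p,
                                  note = ifelse(mono, "monomorphic", NA_character_)))
}

li_ji_me <- function(lambda) {
  snapped <- ifelse(abs(lambda - round(lambda)) < 1e-9, round(lambda), lambda)
  sum((snapped >= 1) + (snapped - floor(snapped)))
}

#' Effective number of independent markers
#'
#' Estimates the effective number of independent tests from the eigenvalue
#' spectrum of the variant correlation matrix in sliding windows
#' (Li-Ji rule): each window contributes
#' `sum(1(lambda >= 1) + (lambda - floor(lambda)))`. A window's contribution
#' is spread uniformly over its variants, and variants covered by two
#' overlapping windows average their shares, so mutually independent markers
#' give exactly M and perfectly duplicated pairs give M/2.
#'
#' @param G A [genotype_matrix()].
#' @param window_size Variants per window (a window larger than the variant
#'   count degenerates to a single whole-set window).
#' @param overlap Variants shared by consecutive windows.
#' @return The estimated effective marker number (scalar).
#' @export
effective_marker_number <- function(G, window_size = 200, overlap = 50) {
  stopifnot(inherits(G, "genotype_matrix"))
  assert_that(window_size > overlap && overlap >= 0,
              "`window_size` must exceed `overlap` (>= 0)")
  D <- impute_dosages(G$dosages)
  sds <- apply(D, 2, stats::sd)
  if (any(sds == 0)) {
    rlang::warn(sprintf("effective_marker_number: dropping %d monomorphic variant(s)",
                        sum(sds == 0)))
    D <- D[, sds > 0, drop = FALSE]
  }
  m <- ncol(D)
  assert_that(m >= 1, "no polymorphic variants")
  if (window_size >= m) {
    windows <- list(seq_len(m))
  } else {
    step <- window_size - overlap
    starts <- seq(1, m, by = step)
    windows <- lapply(starts, function(s) s:min(s + window_size - 1, m))
    # drop tail windows fully contained in their predecessor
    keep <- rep(TRUE, length(windows))
    for (i in seq_along(windows)[-1]) {
      if (all(windows[[i]] %in% windows[[i - 1]])) keep[i] <- FALSE
    }
    windows <- windows[keep]
  }
  shares <- numeric(m); cover <- numeric(m)
  for (w in windows) {
    lam <- eigen(stats::cor(D[, w, drop = FALSE]), symmetric = TRUE,
                 only.values = TRUE)$values
    me_w <- li_ji_me(lam)
    shares[w] <- shares[w] + me_w / length(w)
    cover[w] <- cover[w] + 1
  }
  sum(shares / cover)
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param n_tests Number of (effective) tests; e.g. the effective marker
#'   number from [effective_marker_number()] for a genome-wide scan, or the
#'   number of genes for a transcriptome-wide scan.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  assert_that(n_tests >= 1, "`n_tests` must be >= 1")
  alpha / n_tests
}
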