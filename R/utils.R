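# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_regulatlas <- function(msg, class = "regulatlas_error") {
  rlang::abort(msg, class = class)
}

assert_that <- function(ok, msg, class = "regulatlas_error") {
  if (!isTRUE(ok)) abort_regulatlas(msg, class)
}

#' Derive reproducible sub-stream seeds from a scenario seed
#'
#' One scenario seed governs every stochastic component; each component draws
#' its own seed from this deterministic stream so that adding a component never
#' perturbs the draws of another.
#'
#' @param seed Integer scenario seed.
#' @param n Number of sub-seeds to derive.
#' @return Integer vector of length `n`, each below 2^31.
#' @keywords internal
derive_seeds <- function(seed, n) {
  assert_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(abs(seed) %% (.Machine$integer.max - 1L)))
  sample.int(.Machine$integer.max - 1L, n)
}

# mean-impute missing dosages column-wise; columns that are all-missing
# become all-zero (and are monomorphic downstream)
impute_dosages <- function(D) {
  if (!anyNA(D)) return(D)
  mu <- colMeans(D, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  idx <- which(is.na(D), arr.ind = TRUE)
  D[idx] <- mu[idx[, 2]]
  D
}

check_symmetric <- function(M, tol = 1e-8, name = "matrix") {
  assert_that(is.matrix(M) && nrow(M) == ncol(M), paste0("`", name, "` must be square"))
  assert_that(max(abs(M - t(M))) <= tol * max(1, max(abs(M))),
              paste0("`", name, "` must be symmetric"))
  invisible(M)
}
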