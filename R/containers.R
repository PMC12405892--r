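# Light S3 containers. Records flowing between modules are plain tibbles;
# the matrix-valued objects below wrap base matrices with their metadata.

#' Construct a genotype matrix
#'
#' Holds biallelic SNP dosages (counts of the alternate allele, 0/1/2, `NA`
#' for missing calls) for a panel of samples, together with per-variant
#' metadata: position, alleles, minor allele frequency and missing rate.
#'
#' @param dosages Numeric matrix, samples x variants, values in
#'   \{0, 1, 2, NA\}.
#' @param variants Data frame with columns `variant_id`, `chrom`, `pos`
#'   (1-based bp), `ref`, `alt`, `maf`, `missing_rate`.
#' @param sample_ids Character vector of sample identifiers.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants, sample_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  variants <- tibble::as_tibble(variants)
  assert_that(!is.null(sample_ids) && length(sample_ids) == nrow(dosages),
              "`sample_ids` must name every row of `dosages`")
  assert_that(ncol(dosages) == nrow(variants),
              "`variants` must have one row per dosage column")
  assert_that(all(c("variant_id", "chrom", "pos") %in% names(variants)),
              "`variants` needs at least variant_id, chrom, pos columns")
  assert_that(!anyDuplicated(variants$variant_id), "variant ids must be unique")
  assert_that(all(variants$pos >= 1), "positions are 1-based and must be >= 1")
  vals <- dosages[!is.na(dosages)]
  assert_that(all(vals %in% c(0, 1, 2)), "dosages must be 0, 1, 2 or NA")
  if ("maf" %in% names(variants)) {
    assert_that(all(is.na(variants$maf) | (variants$maf >= 0 & variants$maf <= 0.5)),
                "maf must lie in [0, 0.5]")
  }
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$variant_id
  structure(list(dosages = dosages, variants = variants, sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants (%d chromosome%s)\n",
              length(x$sample_ids), nrow(x$variants),
              length(unique(x$variants$chrom)),
              if (length(unique(x$variants$chrom)) == 1) "" else "s"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by sample and/or variant
#'
#' @param G A [genotype_matrix()].
#' @param samples Sample ids (or logical/integer index) to keep.
#' @param variants Variant ids (or logical/integer index) to keep.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(G, samples = NULL, variants = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  si <- if (is.null(samples)) seq_along(G$sample_ids) else {
    if (is.character(samples)) match(samples, G$sample_ids) else samples
  }
  vi <- if (is.null(variants)) seq_len(nrow(G$variants)) else {
    if (is.character(variants)) match(variants, G$variants$variant_id) else variants
  }
  assert_that(!anyNA(si), "unknown sample id in `samples`")
  assert_that(!anyNA(vi), "unknown variant id in `variants`")
  genotype_matrix(G$dosages[si, vi, drop = FALSE], G$variants[vi, , drop = FALSE],
                  G$sample_ids[si])
}

#' Construct a multi-tissue expression matrix
#'
#' Normalized (non-negative) expression counts for samples drawn from one or
#' more tissues. Each sample carries a tissue code and, when samples are
#' repeated measurements of inbred lines, a line id.
#'
#' @param counts Numeric matrix, samples x genes, non-negative.
#' @param samples Data frame with columns `sample_id`, `tissue` and optionally
#'   `line_id`.
#' @param gene_ids Character vector naming the columns of `counts`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, samples, gene_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  samples <- tibble::as_tibble(samples)
  assert_that(all(c("sample_id", "tissue") %in% names(samples)),
              "`samples` needs sample_id and tissue columns")
  assert_that(nrow(samples) == nrow(counts), "one metadata row per sample required")
  assert_that(!is.null(gene_ids) && length(gene_ids) == ncol(counts),
              "`gene_ids` must name every column of `counts`")
  assert_that(all(counts >= 0, na.rm = TRUE), "expression counts must be non-negative")
  if (!"line_id" %in% names(samples)) samples$line_id <- samples$sample_id
  rownames(counts) <- samples$sample_id
  colnames(counts) <- gene_ids
  structure(list(counts = counts, samples = samples, gene_ids = gene_ids),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d samples x %d genes, tissues: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(sort(unique(x$samples$tissue)), collapse = ", ")))
  invisible(x)
}

#' Tissue codes present in an expression matrix
#' @param expr An [expression_matrix()].
#' @return Character vector of tissue codes.
#' @export
tissues <- function(expr) sort(unique(expr$samples$tissue))

#' Construct a relationship matrix
#'
#' A symmetric positive semi-definite similarity matrix among samples:
#' identity-by-state (IBS), genomic relationship matrix (GRM) or omics
#' (transcriptomic) relationship matrix (ORM). Used as the covariance
#' structure of the random effect in all mixed models.
#'
#' @param mat Symmetric numeric matrix.
#' @param kind One of "ibs", "grm", "orm".
#' @param sample_ids Sample identifiers (defaults to rownames).
#' @return An object of class `relationship_matrix` (a matrix with metadata).
#' @export
relationship_matrix <- function(mat, kind = c("grm", "ibs", "orm"),
                                sample_ids = rownames(mat)) {
  kind <- match.arg(kind)
  mat <- as.matrix(mat)
  check_symmetric(mat, 1e-10, "relationship matrix")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(mat)))
  dimnames(mat) <- list(sample_ids, sample_ids)
  ev <- eigen(mat, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    # per-variant missing-pair exclusion (IBS) can leave an indefinite
    # estimate; negative eigenvalues are clipped where the matrix enters a
    # model, and badly indefinite matrices are rejected there
    rlang::warn(sprintf("relationship matrix is indefinite (min eigenvalue %.3g); negative modes are clipped when the matrix enters a model",
                        min(ev)))
  }
  structure(mat, kind = kind, class = c("relationship_matrix", "matrix", "array"))
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("<relationship_matrix> kind=%s, %d x %d, mean diagonal %.3f\n",
              attr(x, "kind"), nrow(x), ncol(x), mean(diag(x))))
  invisible(x)
}

rel_mat <- function(R) {
  m <- unclass(R)
  attr(m, "kind") <- NULL
  m
}

as_relationship_input <- function(R, n = NULL, name = "R") {
  if (inherits(R, "relationship_matrix")) {
    M <- rel_mat(R)
  } else {
    M <- as.matrix(R)
    check_symmetric(M, 1e-8, name)
  }
  if (!is.null(n)) assert_that(nrow(M) == n, paste0("`", name, "` dimension must match sample count"))
  M
}
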