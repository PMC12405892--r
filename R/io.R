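# Readers and writers for the external formats the pipeline touches:
# VCF genotypes, TSV expression / annotation / QTL catalogs, GMT gene sets,
# and the registered tabular output schemas. Readers validate and refuse
# out-of-domain values rather than coercing.

#' Read genotypes from a VCF file
#'
#' Parses diploid GT fields of biallelic SNP records into alternate-allele
#' dosages and applies the panel QC filter: variants are retained when their
#' minor allele frequency exceeds `maf_floor` and their missing rate is below
#' `missing_ceiling`. Multi-allelic and non-SNP records are dropped with a
#' message. Heterozygote phase is ignored ("0/1" and "1|0" both give dosage 1)
#' and MAF is computed over non-missing calls only.
#'
#' @param path Path to a VCF file (uncompressed or gzipped).
#' @param maf_floor Retain variants with MAF strictly greater than this.
#' @param missing_ceiling Retain variants with missing rate strictly below this.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, maf_floor = 0.05, missing_ceiling = 0.99) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  assert_that(n_rec > 0, "VCF contains no variant records")
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  is_snp <- !is.na(ref) & !is.na(alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_drop_shape <- sum(!is_snp)
  if (n_drop_shape > 0) {
    rlang::inform(sprintf("read_vcf: dropped %d multi-allelic or non-SNP record(s)", n_drop_shape))
  }
  assert_that(any(is_snp), "no biallelic SNP records in VCF")

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = n_rec)
  gt <- gt[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]

  gt_chr <- as.vector(gt)
  dos <- rep(NA_real_, length(gt_chr))
  core <- sub("^([^:]*).*$", "\\1", gt_chr)
  core[is.na(gt_chr)] <- NA
  known <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1, "1|0" = 1,
             "1/1" = 2, "1|1" = 2)
  hit <- core %in% names(known)
  miss <- is.na(core) | core %in% c("./.", ".|.", ".")
  bad <- which(!hit & !miss)
  if (length(bad) > 0) {
    abort_regulatlas(sprintf("read_vcf: unparseable GT '%s' at record %d",
                             core[bad[1]], ((bad[1] - 1) %% nrow(gt)) + 1),
                     class = "regulatlas_parse_error")
  }
  dos[hit] <- known[core[hit]]
  D <- t(matrix(dos, nrow = nrow(gt)))        # samples x variants
  sample_ids <- colnames(gt)
  n <- nrow(D)

  n_called <- colSums(!is.na(D))
  missing_rate <- 1 - n_called / n
  af <- ifelse(n_called > 0, colSums(D, na.rm = TRUE) / (2 * n_called), NA_real_)
  maf <- pmin(af, 1 - af)

  keep <- !is.na(maf) & maf > maf_floor & missing_rate < missing_ceiling
  n_drop_qc <- sum(!keep)
  if (n_drop_qc > 0) {
    rlang::inform(sprintf("read_vcf: dropped %d variant(s) failing MAF/missing-rate QC", n_drop_qc))
  }
  assert_that(any(keep), "read_vcf: zero variants retained after QC",
              class = "regulatlas_empty_result")

  ids <- unname(fix[, "ID"])
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
  variants <- tibble::tibble(
    variant_id = ids, chrom = unname(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = unname(ref[is_snp]), alt = unname(alt[is_snp]),
    maf = unname(maf), missing_rate = unname(missing_rate)
  )[keep, ]
  genotype_matrix(D[, keep, drop = FALSE], variants, sample_ids)
}

#' Read a multi-tissue expression table
#'
#' Expects a TSV whose first two columns are `sample_id` and `tissue`,
#' followed by one numeric column of normalized counts per gene. An optional
#' `line_id` column (third position) maps repeated tissue samples back to
#' inbred lines.
#'
#' @param path Path to the TSV file.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  pr <- readr::problems(tab)
  if (nrow(pr) > 0) {
    abort_regulatlas(sprintf("read_expression: malformed table at row %d (%s)",
                             pr$row[1], pr$expected[1]),
                     class = "regulatlas_parse_error")
  }
  assert_that(all(c("sample_id", "tissue") %in% names(tab)),
              "expression table needs sample_id and tissue columns")
  meta_cols <- intersect(c("sample_id", "tissue", "line_id"), names(tab))
  gene_cols <- setdiff(names(tab), meta_cols)
  assert_that(length(gene_cols) > 0, "expression table has no gene columns")
  counts <- as.matrix(tab[, gene_cols])
  if (!is.numeric(counts)) {
    bad <- which(!vapply(tab[gene_cols], is.numeric, logical(1)))[1]
    abort_regulatlas(sprintf("read_expression: non-numeric values in gene column '%s'",
                             gene_cols[bad]),
                     class = "regulatlas_parse_error")
  }
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    abort_regulatlas(sprintf("read_expression: negative count for sample '%s', gene '%s'",
                             tab$sample_id[neg[1, 1]], gene_cols[neg[1, 2]]))
  }
  expression_matrix(counts, tab[meta_cols], gene_cols)
}

#' Read a gene annotation table
#'
#' BED-like TSV with columns `gene_id`, `chrom`, `tss` (1-based bp) and
#' `strand`; used to classify eQTLs as cis or trans relative to the
#' transcription start site.
#'
#' @param path Path to the TSV file.
#' @return Tibble with one row per gene.
#' @export
read_gene_annotation <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           gene_id = readr::col_character(),
                           chrom = readr::col_character(),
                           tss = readr::col_integer(),
                           strand = readr::col_character()))
  assert_that(!anyDuplicated(tab$gene_id), "gene ids must be unique")
  assert_that(all(tab$tss >= 1), "tss is 1-based and must be >= 1")
  assert_that(all(tab$strand %in% c("+", "-")), "strand must be '+' or '-'")
  tab
}

#' Read a catalog of published trait QTLs
#'
#' TSV with columns `trait`, `chrom`, `pos`, `p`, `source`. Duplicate
#' (trait, chrom, pos) rows are collapsed with a warning.
#'
#' @param path Path to the TSV file.
#' @return Tibble of QTL records.
#' @export
read_qtl_catalog <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           trait = readr::col_character(),
                           chrom = readr::col_character(),
                           pos = readr::col_integer(),
                           p = readr::col_double(),
                           source = readr::col_character()))
  if (nrow(tab) == 0) return(tab)
  assert_that(all(tab$p > 0 & tab$p <= 1), "QTL p-values must lie in (0, 1]")
  assert_that(all(tab$pos >= 1), "positions are 1-based and must be >= 1")
  dup <- duplicated(tab[c("trait", "chrom", "pos")])
  if (any(dup)) {
    rlang::warn(sprintf("read_qtl_catalog: removed %d duplicate (trait, chrom, pos) row(s)",
                        sum(dup)))
    tab <- tab[!dup, ]
  }
  tab
}

#' Read gene sets in GMT format
#'
#' Standard tab-separated GMT: set id, description, then member gene ids.
#' Members are deduplicated; a line with fewer than three fields is an error.
#'
#' @param path Path to the GMT file.
#' @return Tibble with columns `set_id`, `description` and list-column `genes`.
#' @export
read_gene_sets <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, integer(1)) < 3)
  if (length(short) > 0) {
    abort_regulatlas(sprintf("read_gene_sets: line %d has fewer than 3 fields", short[1]),
                     class = "regulatlas_parse_error")
  }
  tibble::tibble(
    set_id = vapply(parts, `[[`, character(1), 1),
    description = vapply(parts, `[[`, character(1), 2),
    genes = lapply(parts, function(x) unique(x[-(1:2)]))
  )
}

# --- registered output schemas -------------------------------------------

.schemas <- list(
  assoc = c(predictor_id = "c", chrom = "c", pos = "i", beta = "d", se = "d",
            z = "d", p = "p"),
  eqtl = c(gene_id = "c", tissue = "c", variant_id = "c", chrom = "c", pos = "i",
           beta = "d", se = "d", p = "p", kind = "c", conditional_round = "i"),
  cluster = c(cluster_id = "c", gene_id = "c", tissue = "c", variant_id = "c",
              chrom = "c", pos = "i", p = "p", is_representative = "l"),
  twas = c(gene_id = "c", tissue = "c", trait = "c", beta = "d", se = "d",
           z = "d", p = "p"),
  smr = c(gene_id = "c", tissue = "c", trait = "c", instrument = "c",
          b_xy = "d", se_xy = "d", p_smr = "p", p_heidi = "p", n_heidi_snps = "i"),
  coloc = c(trait = "c", chrom = "c", qtl_pos = "i", cluster_id = "c",
            variant_id = "c", eqtl_pos = "i", distance = "i"),
  specificity = c(gene_id = "c", tissue = "c", t_stat = "d", rank_pct = "d",
                  median_fc = "d", is_specific = "l"),
  enrichment = c(set_id = "c", overlap = "i", set_size = "i", query_size = "i",
                 universe_size = "i", fold = "d", p_hyper = "p", fdr = "p")
)

format_cell <- function(x, type) {
  out <- switch(type,
    c = as.character(x),
    i = as.character(as.integer(x)),
    l = ifelse(x, "TRUE", "FALSE"),
    d = vapply(x, function(v) if (is.na(v)) NA_character_ else sprintf("%.12g", v), character(1)),
    p = vapply(x, function(v) if (is.na(v)) NA_character_ else formatC(v, format = "e", digits = 5), character(1))
  )
  out[is.na(x)] <- "NA"
  out
}

#' Write analysis records under a registered output schema
#'
#' All pipeline outputs share one writer: deterministic column order,
#' tab-separated, p-values serialized in scientific notation with six
#' significant digits. Writing the same records twice produces byte-identical
#' files, and [read_table()] recovers the records.
#'
#' @param records Data frame conforming to the schema.
#' @param path Output path.
#' @param schema_id One of `r paste0('"', names(.schemas), '"', collapse = ", ")`.
#' @return Invisibly, the path.
#' @export
write_table <- function(records, path, schema_id) {
  assert_that(schema_id %in% names(.schemas),
              paste0("unknown schema_id: ", schema_id))
  schema <- .schemas[[schema_id]]
  missing_cols <- setdiff(names(schema), names(records))
  assert_that(length(missing_cols) == 0,
              paste0("records lack schema column(s): ", paste(missing_cols, collapse = ", ")))
  records <- as.data.frame(records)[names(schema)]
  body <- vapply(seq_along(schema),
                 function(j) format_cell(records[[j]], schema[[j]]),
                 character(nrow(records)))
  if (nrow(records) == 1) body <- matrix(body, nrow = 1)
  if (nrow(records) == 0) body <- matrix(character(0), ncol = length(schema))
  lines <- c(paste(names(schema), collapse = "\t"),
             apply(body, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read records written by [write_table()]
#'
#' @param path Path to the TSV file.
#' @param schema_id Registered schema id.
#' @return Tibble with schema-typed columns.
#' @export
read_table <- function(path, schema_id) {
  assert_that(schema_id %in% names(.schemas),
              paste0("unknown schema_id: ", schema_id))
  schema <- .schemas[[schema_id]]
  spec <- lapply(unname(schema), function(t) switch(t,
    c = readr::col_character(), i = readr::col_integer(),
    l = readr::col_logical(), d = readr::col_double(), p = readr::col_double()))
  names(spec) <- names(schema)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = do.call(readr::cols, spec), na = "NA")
}
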