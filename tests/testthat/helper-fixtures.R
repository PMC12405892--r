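# fixtures built in code: tiny VCFs, hand-made genotype/expression objects,
# and the two-cohort summary-statistics generator used by the SMR/HEIDI
# simulations

write_toy_vcf <- function(gt_rows, path = tempfile(fileext = ".vcf"),
                          chrom = NULL, pos = NULL, ref = NULL, alt = NULL,
                          samples = NULL) {
  n_var <- length(gt_rows)
  n_samp <- length(strsplit(gt_rows[[1]], "\t")[[1]])
  chrom <- chrom %||% rep("1", n_var)
  pos <- pos %||% seq(100, by = 100, length.out = n_var)
  ref <- ref %||% rep("A", n_var)
  alt <- alt %||% rep("G", n_var)
  samples <- samples %||% paste0("S", seq_len(n_samp))
  header <- c("##fileformat=VCFv4.2",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(n_var), function(i) {
    paste(c(chrom[i], pos[i], paste0("v", i), ref[i], alt[i], ".", "PASS",
            ".", "GT", strsplit(gt_rows[[i]], "\t")[[1]]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

toy_genotypes <- function(D, chrom = NULL, pos = NULL) {
  D <- as.matrix(D)
  m <- ncol(D)
  tibble::tibble(
    variant_id = paste0("v", seq_len(m)),
    chrom = chrom %||% rep("chr1", m),
    pos = as.integer(pos %||% (seq_len(m) * 1000L)),
    ref = "A", alt = "G",
    maf = pmin(colMeans(D, na.rm = TRUE) / 2, 1 - colMeans(D, na.rm = TRUE) / 2),
    missing_rate = colMeans(is.na(D))) |>
    genotype_matrix(dosages = D, sample_ids = paste0("S", seq_len(nrow(D))))
}

# dosage columns in {0,2} that are exactly pairwise orthogonal after centering
hadamard_genotypes <- function(k = 4, n_cols = 8) {
  H <- matrix(1)
  for (i in seq_len(k)) H <- rbind(cbind(H, H), cbind(H, -H))
  D <- H[, 1 + seq_len(n_cols), drop = FALSE] + 1
  toy_genotypes(D)
}

toy_expression <- function(counts, tissue, line_id = NULL,
                           gene_ids = NULL) {
  counts <- as.matrix(counts)
  gene_ids <- gene_ids %||% paste0("g", seq_len(ncol(counts)))
  n <- nrow(counts)
  line_id <- line_id %||% paste0("L", seq_len(n))
  expression_matrix(counts,
                    tibble::tibble(sample_id = paste0(line_id, "_", tissue),
                                   tissue = tissue, line_id = line_id),
                    gene_ids)
}

# two-cohort mediation scenario for SMR/HEIDI: a single causal variant
# drives expression, expression drives the trait; eQTL and GWAS summary
# statistics come from disjoint cohorts of the same population
heidi_mediation_stats <- function(seed, n = 4000, m = 30, eff = 0.2,
                                  gamma = 0.4, causal = 15,
                                  two_causals = FALSE) {
  Ga <- simulate_genotypes(n, m, block_size = m, switch_prob = 0.08, seed = seed)
  Gb <- simulate_genotypes(n, m, block_size = m, switch_prob = 0.08,
                           seed = seed + 500000L)
  set.seed(seed)
  xa <- eff * scale(Ga$dosages[, causal]) + stats::rnorm(n)
  xb <- eff * scale(Gb$dosages[, causal]) + stats::rnorm(n)
  if (two_causals) {
    # linkage, not mediation: the trait is driven by a second variant in
    # moderate LD (r2 ~ 0.5) with the expression-causal variant
    yb <- gamma * eff * scale(Gb$dosages[, causal + 5]) + stats::rnorm(n)
  } else {
    yb <- gamma * xb + stats::rnorm(n)
  }
  eq <- ols_scan(xa, Ga)
  gw <- ols_scan(yb, Gb)
  ld <- stats::cor(Ga$dosages)
  dimnames(ld) <- list(Ga$variants$variant_id, Ga$variants$variant_id)
  region <- tibble::tibble(variant_id = eq$variant_id,
                           b_gwas = gw$beta, se_gwas = gw$se,
                           b_eqtl = eq$beta, se_eqtl = eq$se, p_eqtl = eq$p)
  list(region = region, ld = ld,
       top = region$variant_id[which.min(region$p_eqtl)])
}
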