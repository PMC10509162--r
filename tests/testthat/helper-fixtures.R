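# Programmatic fixtures shared across tests.

# A small deterministic panel: 2 populations, explicit dosages.
make_tiny_panel <- function(n_per_pop = 10, n_snps = 12, seed = 11,
                            maf_low = 0.2, maf_high = 0.8) {
  set.seed(seed)
  n <- 2 * n_per_pop
  f <- runif(n_snps, maf_low, maf_high)
  dosage <- sapply(f, function(p) rbinom(n, 2, p))
  genotype_panel(
    dosage = dosage,
    snp_ids = paste0("rs", seq_len(n_snps)),
    chrom = rep("1", n_snps),
    pos = seq_len(n_snps) * 1000L,
    ref_allele = rep("A", n_snps),
    alt_allele = rep("G", n_snps),
    ancestral_allele = rep("A", n_snps),
    population = rep(c("P1", "P2"), each = n_per_pop)
  )
}

# Panel with exact genotype counts per population (HWE-style constructions).
# counts: list per population of c(n_ref_hom, n_het, n_alt_hom) per SNP
# (a matrix SNPs x 3 per population).
panel_from_counts <- function(counts_p1, counts_p2) {
  row_dosages <- function(cnt) unlist(mapply(
    function(a, b, c) c(rep(0, a), rep(1, b), rep(2, c)),
    cnt[, 1], cnt[, 2], cnt[, 3], SIMPLIFY = FALSE))
  p <- nrow(counts_p1)
  d1 <- matrix(row_dosages(counts_p1), ncol = p)
  d2 <- matrix(row_dosages(counts_p2), ncol = p)
  genotype_panel(
    dosage = rbind(d1, d2),
    snp_ids = paste0("rs", seq_len(p)),
    chrom = rep("1", p),
    pos = seq_len(p) * 1000L,
    ref_allele = rep("A", p),
    alt_allele = rep("G", p),
    population = rep(c("P1", "P2"), c(nrow(d1), nrow(d2)))
  )
}

# Write a small VCF by hand (3 records: 2 SNPs + 1 indel), with AA tags.
write_test_vcf <- function(path, lowercase_aa = FALSE) {
  aa2 <- if (lowercase_aa) "AA=g" else "AA=G"
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral Allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", "AA=A", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "rs2", "C", "T", ".", "PASS", aa2, "GT",
          "0/1", "./.", "0|0", sep = "\t"),
    paste("1", "300", "rs3", "CT", "C", ".", "PASS", ".", "GT",
          "0/0", "0/1", "0/0", sep = "\t")
  )
  writeLines(lines, path)
  path
}

# GWAS summary table on disk with configurable rows.
write_test_gwas <- function(path, df = NULL) {
  if (is.null(df)) {
    df <- data.frame(
      SNP = c("rs1", "rs2", "rs3", "rs4", "rs5"),
      CHR = "1", BP = c(100, 200, 300, 400, 500),
      A1 = c("G", "T", "G", "G", "G"), A2 = c("A", "C", "A", "A", "A"),
      OR = c(1.5, 0.8, 1.0, 1.2, 0.9), SE = 0.1,
      P = c(1e-4, 0.2, 0.5, 0.01, 0.9),
      INFO = c(0.99, 0.95, 0.8, 0.97, 0.99),
      FRQ = c(0.3, 0.4, 0.2, 0.25, 0.5)
    )
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# A cohort with a known signal: score column s1 truly associated.
make_test_cohort <- function(n = 300, n_snps = 20, seed = 5, beta = 0,
                             with_covariates = TRUE) {
  set.seed(seed)
  f <- runif(n_snps, 0.2, 0.8)
  dosage <- sapply(f, function(p) rbinom(n, 2, p))
  colnames(dosage) <- paste0("s", seq_len(n_snps))
  eta <- -0.2 + beta * scale(dosage[, 1])
  y <- rbinom(n, 1, plogis(eta))
  cov <- if (with_covariates)
    cbind(sex = rbinom(n, 1, 0.5), age = rnorm(n, 40, 10)) else NULL
  cohort_data(dosage, y, covariates = cov)
}
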