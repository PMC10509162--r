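test_that("read_genotypes keeps biallelic SNPs, drops indels, parses AA", {
  vcf <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"))
  panel <- read_genotypes(vcf)
  expect_s3_class(panel, "genotype_panel")
  expect_equal(panel$snp_ids, c("rs1", "rs2"))   # indel rs3 dropped
  expect_equal(panel$dosage[, 1], c(S1 = 0, S2 = 1, S3 = 2))
  expect_true(is.na(panel$dosage[2, 2]))         # ./. -> NA
  expect_equal(panel$ancestral_allele, c("A", "G"))
  expect_false(panel$aa_low_confidence[1])
})

test_that("lowercase ancestral calls are parsed and flagged low-confidence", {
  vcf <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"),
                        lowercase_aa = TRUE)
  panel <- read_genotypes(vcf)
  expect_equal(panel$ancestral_allele[2], "G")
  expect_true(panel$aa_low_confidence[2])
})

test_that("exclusion regions remove SNPs (half-open BED semantics)", {
  vcf <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"))
  # interval [99, 100) covers the 0-based coordinate of pos 100 only
  excl <- region_set("1", 99, 100)
  panel <- read_genotypes(vcf, region_excludes = excl)
  expect_equal(panel$snp_ids, "rs2")
  # an MHC-sized interval drops a SNP placed inside it
  mhc <- region_set("6", 28477796, 33448354, label = "MHC")
  expect_true(in_regions("6", 30000000L, mhc))
  expect_false(in_regions("6", 28477796L, mhc))  # pos 1-based: base 28477795
  expect_error(read_genotypes(vcf, region_set("1", 0, 1000)),
               "no biallelic SNPs")
})

test_that("read_gwas filters on INFO, converts BETA, validates schema", {
  path <- write_test_gwas(withr::local_tempfile(fileext = ".tsv"))
  g <- read_gwas(path, info_min = 0.9)
  expect_equal(nrow(g), 4)                       # INFO 0.8 row removed
  expect_false("rs3" %in% g$snp_id)

  # BETA accepted and exp-transformed; BETA = 0 -> OR 1
  df <- data.frame(SNP = "rs9", CHR = "2", BP = 1, A1 = "A", A2 = "G",
                   BETA = 0, SE = 0.1, P = 0.5, INFO = 0.99, FRQ = 0.3)
  p2 <- write_test_gwas(withr::local_tempfile(fileext = ".tsv"), df)
  expect_equal(read_gwas(p2)$or_effect, 1.0)

  df$BETA <- NULL
  p3 <- write_test_gwas(withr::local_tempfile(fileext = ".tsv"), df)
  expect_error(read_gwas(p3), "mandatory column")

  df$OR <- -2
  p4 <- write_test_gwas(withr::local_tempfile(fileext = ".tsv"), df)
  expect_error(read_gwas(p4), "non-positive OR.*rs9")
})

test_that("GWAS write -> read round trip is value-identical", {
  path <- write_test_gwas(withr::local_tempfile(fileext = ".tsv"))
  g <- read_gwas(path, info_min = 0)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_gwas(g, p2)
  g2 <- read_gwas(p2, info_min = 0)
  expect_equal(g, g2)
})

test_that("harmonize joins on position, matches alleles order-free, filters MAF", {
  panel <- make_tiny_panel()
  f <- alt_freq(panel)
  gwas <- data.frame(
    snp_id = paste0("x", seq_len(n_snps(panel))),  # ids differ: join by pos
    chrom = panel$chrom, pos = panel$pos,
    a1 = "G", a2 = "A",
    or_effect = 1.2, se = 0.1, p_assoc = 0.1, info = 0.99, freq_a1 = f,
    stringsAsFactors = FALSE)
  # swap a1/a2 for the first SNP: effect allele becomes the panel ref
  gwas$a1[1] <- "A"; gwas$a2[1] <- "G"
  # give the second SNP mismatching alleles
  gwas$a1[2] <- "C"; gwas$a2[2] <- "T"
  h <- harmonize(panel, gwas, maf_min = 0)
  expect_false(h$table$effect_is_alt[1])
  expect_true(all(h$table$effect_is_alt[-1]))
  expect_equal(h$report$n_allele_mismatch, 1)
  expect_false(panel$snp_ids[2] %in% h$table$snp_id)

  # MAF filter: a monomorphic-ish SNP is removed at maf_min = 0.05
  panel2 <- panel
  panel2$dosage[, 3] <- c(rep(0, n_samples(panel) - 1), 1)  # MAF 0.025
  h2 <- harmonize(panel2, gwas, maf_min = 0.05)
  expect_false(panel$snp_ids[3] %in% h2$table$snp_id)
  expect_equal(h2$report$n_maf_removed, 1)

  # output count bounded by both inputs
  expect_lte(nrow(h$table), min(n_snps(panel), nrow(gwas)))
})

test_that("variant filters commute: region, MAF and INFO order-independent", {
  set.seed(3)
  panel <- make_tiny_panel(n_snps = 30, maf_low = 0.01, maf_high = 0.6)
  gwas <- data.frame(
    snp_id = panel$snp_ids, chrom = panel$chrom, pos = panel$pos,
    a1 = "G", a2 = "A", or_effect = 1, se = 0.1, p_assoc = 0.5,
    info = runif(30, 0.7, 1), freq_a1 = 0.3, stringsAsFactors = FALSE)
  excl <- region_set("1", 5000, 12000)

  apply_filters <- function(order) {
    keep <- rep(TRUE, 30)
    for (f in order) {
      keep <- keep & switch(f,
        region = !in_regions(panel$chrom, panel$pos, excl),
        maf = panel_maf(panel) >= 0.05,
        info = gwas$info > 0.9)
    }
    panel$snp_ids[keep]
  }
  perms <- list(c("region", "maf", "info"), c("info", "region", "maf"),
                c("maf", "info", "region"))
  results <- lapply(perms, apply_filters)
  expect_equal(results[[1]], results[[2]])
  expect_equal(results[[2]], results[[3]])

  # the pipeline path (exclude at read + MAF at harmonize + INFO at read)
  # yields the same set as manual filtering
  manual <- results[[1]]
  h <- harmonize(panel, gwas[gwas$info > 0.9, ], maf_min = 0.05)
  pipeline_ids <- setdiff(h$table$snp_id,
                          panel$snp_ids[in_regions(panel$chrom, panel$pos,
                                                   excl)])
  expect_setequal(pipeline_ids, manual)
})

test_that("strand-ambiguous SNPs are flagged and optionally dropped", {
  panel <- make_tiny_panel(n_snps = 4)
  panel$ref_allele <- c("A", "A", "C", "G")
  panel$alt_allele <- c("T", "G", "G", "C")   # 1, 3, 4 are palindromic
  gwas <- data.frame(
    snp_id = panel$snp_ids, chrom = panel$chrom, pos = panel$pos,
    a1 = panel$alt_allele, a2 = panel$ref_allele,
    or_effect = 1, se = 0.1, p_assoc = 0.5, info = 1, freq_a1 = 0.3,
    stringsAsFactors = FALSE)
  h <- harmonize(panel, gwas, maf_min = 0)
  expect_equal(h$table$ambiguous, c(TRUE, FALSE, TRUE, TRUE))
  h2 <- harmonize(panel, gwas, maf_min = 0, drop_ambiguous = TRUE)
  expect_equal(nrow(h2$table), 1)
})
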