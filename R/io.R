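#' Genomic interval sets (BED dialect)
#'
#' Intervals follow BED conventions: 0-based, half-open \code{[start, end)}.
#' Used for exclusion regions (MHC, long-range LD) and gene annotations.
#'
#' @param chrom,start,end parallel vectors describing the intervals.
#' @param label a single descriptive label for the set.
#' @return a data.frame of class \code{region_set} with columns
#'   \code{chrom}, \code{start}, \code{end}, sorted by (chrom, start).
#' @export
region_set <- function(chrom, start, end, label = "regions") {
  chrom <- rep_len(as.character(chrom), max(length(start), length(end)))
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start >= end)) stop("region_set requires start < end for all intervals")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "label") <- label
  class(df) <- c("region_set", "data.frame")
  df
}

#' Read a BED file into a region_set
#'
#' @param path path to a (plain-text, uncompressed) BED file; only the first
#'   three columns are used.
#' @param label label for the set; defaults to the file name.
#' @return a \code{region_set}.
#' @export
read_regions_bed <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  region_set(df[[1]], df[[2]], df[[3]], label = label)
}

# TRUE where (chrom, pos) [1-based] falls inside any interval of the set
in_regions <- function(chrom, pos, regions) {
  hit <- logical(length(pos))
  if (is.null(regions) || nrow(regions) == 0L) return(hit)
  p0 <- pos - 1L  # 0-based coordinate of the base
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (chrom == regions$chrom[i] &
                    p0 >= regions$start[i] & p0 < regions$end[i])
  }
  hit
}

#' Read genotypes from a VCF file
#'
#' Reads a VCF (via \pkg{vcfR}), keeps biallelic SNPs only (indels and
#' multi-allelic records dropped), removes SNPs falling in any exclusion
#' region, and parses the ancestral allele from the INFO \code{AA} tag.
#' Lowercase ancestral calls (the 1000 Genomes low-confidence convention)
#' are accepted and flagged. Missing genotypes become \code{NA} dosages.
#'
#' @param vcf_path path to a VCF 4.x file with a GT FORMAT field.
#' @param region_excludes optional \code{region_set} of intervals to drop
#'   (e.g. the MHC).
#' @param population optional per-sample population labels, in VCF sample
#'   order; defaults to a single population.
#' @return a \code{genotype_panel}.
#' @export
read_genotypes <- function(vcf_path, region_excludes = NULL,
                           population = NULL) {
  if (!file.exists(vcf_path)) stop("VCF file not found: ", vcf_path)
  vcf <- tryCatch(vcfR::read.vcfR(vcf_path, verbose = FALSE),
                  error = function(e) stop("failed to parse VCF: ",
                                           conditionMessage(e)))
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  if (!is.null(region_excludes))
    keep <- keep & !in_regions(chrom, pos, region_excludes)
  if (!any(keep)) stop("no biallelic SNPs remain after filtering")

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  gt <- gt[keep, , drop = FALSE]
  # allele-separator agnostic dosage: count "1" alleles, NA on any "."
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  dos <- (a1 == "1") + (a2 == "1")
  dos[a1 == "." | a2 == "." | is.na(gt)] <- NA
  dosage <- t(dos)  # samples x SNPs

  info <- fix[keep, "INFO"]
  aa_raw <- sub(".*(?:^|;)AA=([^;|,]*).*", "\\1", info, perl = TRUE)
  aa_raw[!grepl("(^|;)AA=", info)] <- NA_character_
  aa_raw <- substr(aa_raw, 1, 1)
  aa_raw[!(aa_raw %in% c("A", "C", "G", "T", "a", "c", "g", "t"))] <-
    NA_character_

  ids <- fix[keep, "ID"]
  miss_id <- is.na(ids) | ids == "."
  ids[miss_id] <- paste0(chrom[keep][miss_id], ":", pos[keep][miss_id])

  genotype_panel(
    dosage = dosage,
    snp_ids = ids,
    chrom = chrom[keep],
    pos = pos[keep],
    ref_allele = ref[keep],
    alt_allele = alt[keep],
    ancestral_allele = aa_raw,
    sample_ids = colnames(gt),
    population = population
  )
}

.gwas_default_cols <- c(snp_id = "SNP", chrom = "CHR", pos = "BP",
                        a1 = "A1", a2 = "A2", or_effect = "OR", se = "SE",
                        p_assoc = "P", info = "INFO", freq_a1 = "FRQ")

#' Read GWAS summary statistics
#'
#' Reads a tab-separated summary-statistics file with a configurable column
#' map, applies the imputation-quality filter, and normalises the effect to
#' an odds ratio (a BETA column is accepted and converted via
#' \code{OR = exp(BETA)}).
#'
#' @param tsv_path path to the tab-separated file.
#' @param info_min records with INFO \code{<=} this value are removed
#'   (default 0.9, i.e. the usual "imputation quality > 0.9" filter).
#' @param col_map named character vector mapping internal field names
#'   (\code{snp_id, chrom, pos, a1, a2, or_effect, se, p_assoc, info,
#'   freq_a1}) to file column names. An \code{or_effect} column named
#'   \code{BETA} is auto-detected when \code{OR} is absent.
#' @return a data.frame of class \code{gwas_summary}, sorted by
#'   (chrom, pos).
#' @export
read_gwas <- function(tsv_path, info_min = 0.9,
                      col_map = .gwas_default_cols) {
  if (!file.exists(tsv_path)) stop("GWAS file not found: ", tsv_path)
  raw <- utils::read.table(tsv_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  cm <- .gwas_default_cols
  cm[names(col_map)] <- col_map
  beta_mode <- FALSE
  if (!(cm[["or_effect"]] %in% names(raw)) && "BETA" %in% names(raw)) {
    cm[["or_effect"]] <- "BETA"; beta_mode <- TRUE
  }
  missing_cols <- setdiff(unname(cm), names(raw))
  if (length(missing_cols))
    stop("GWAS file lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- data.frame(
    snp_id = as.character(raw[[cm[["snp_id"]]]]),
    chrom = as.character(raw[[cm[["chrom"]]]]),
    pos = as.integer(raw[[cm[["pos"]]]]),
    a1 = toupper(as.character(raw[[cm[["a1"]]]])),
    a2 = toupper(as.character(raw[[cm[["a2"]]]])),
    or_effect = as.numeric(raw[[cm[["or_effect"]]]]),
    se = as.numeric(raw[[cm[["se"]]]]),
    p_assoc = as.numeric(raw[[cm[["p_assoc"]]]]),
    info = as.numeric(raw[[cm[["info"]]]]),
    freq_a1 = as.numeric(raw[[cm[["freq_a1"]]]]),
    stringsAsFactors = FALSE
  )
  if (beta_mode) df$or_effect <- exp(df$or_effect)
  bad_or <- !is.na(df$or_effect) & df$or_effect <= 0
  if (any(bad_or))
    stop("non-positive OR for record(s): ",
         paste(utils::head(df$snp_id[bad_or], 10), collapse = ", "))
  df <- df[df$info > info_min, , drop = FALSE]
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gwas_summary", "data.frame")
  df
}

#' Write GWAS summary statistics
#'
#' Inverse of \code{\link{read_gwas}} with the default column names;
#' \code{read_gwas(write_gwas(x))} reproduces the records.
#'
#' @param gwas a \code{gwas_summary} data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gwas <- function(gwas, path) {
  out <- data.frame(SNP = gwas$snp_id, CHR = gwas$chrom, BP = gwas$pos,
                    A1 = gwas$a1, A2 = gwas$a2, OR = gwas$or_effect,
                    SE = gwas$se, P = gwas$p_assoc, INFO = gwas$info,
                    FRQ = gwas$freq_a1)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Harmonize a genotype panel with GWAS summary statistics
#'
#' Inner-joins panel and summary records on (chrom, pos), requires the
#' allele pairs to match irrespective of order, records whether the GWAS
#' effect allele is the panel's alternate or reference allele, flags
#' strand-ambiguous (A/T, C/G) SNPs, and removes SNPs whose panel MAF falls
#' below \code{maf_min}. SNPs with mismatching alleles are dropped and
#' counted in the report, not fatal.
#'
#' @param panel a \code{genotype_panel}.
#' @param gwas a \code{gwas_summary}.
#' @param maf_min minimum panel MAF (default 0.05, the usual common-variant
#'   filter).
#' @param drop_ambiguous drop strand-ambiguous SNPs instead of flagging
#'   (default \code{FALSE}).
#' @return a list of class \code{harmonized}: \code{table} (per-SNP joined
#'   data.frame with columns snp_id, chrom, pos, ref, alt, ancestral,
#'   aa_low_confidence, maf, effect_is_alt, ambiguous, or_effect, se,
#'   p_assoc, info, freq_a1), \code{panel} (the matching panel subset, same
#'   SNP order), and \code{report} (join/drop counts).
#' @export
harmonize <- function(panel, gwas, maf_min = 0.05, drop_ambiguous = FALSE) {
  key_p <- paste(panel$chrom, panel$pos)
  key_g <- paste(gwas$chrom, gwas$pos)
  m <- match(key_p, key_g)
  joined <- !is.na(m)
  gi <- m[joined]
  ref <- panel$ref_allele[joined]; alt <- panel$alt_allele[joined]
  a1 <- gwas$a1[gi]; a2 <- gwas$a2[gi]
  match_fwd <- a1 == alt & a2 == ref
  match_rev <- a1 == ref & a2 == alt
  allele_ok <- match_fwd | match_rev
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  ambiguous <- ref == unname(comp[alt])

  idx <- which(joined)[allele_ok]
  eff_alt <- match_fwd[allele_ok]
  amb <- ambiguous[allele_ok]
  gi2 <- gi[allele_ok]

  maf <- panel_maf(subset_snps(panel, idx))
  keep_maf <- maf >= maf_min
  n_maf_removed <- sum(!keep_maf)
  keep <- keep_maf
  n_amb <- sum(amb & keep)
  if (drop_ambiguous) keep <- keep & !amb

  idx <- idx[keep]; gi2 <- gi2[keep]
  sub <- subset_snps(panel, idx)
  tab <- data.frame(
    snp_id = sub$snp_ids,
    chrom = sub$chrom,
    pos = sub$pos,
    ref = sub$ref_allele,
    alt = sub$alt_allele,
    ancestral = sub$ancestral_allele,
    aa_low_confidence = sub$aa_low_confidence,
    maf = maf[keep],
    effect_is_alt = eff_alt[keep],
    ambiguous = amb[keep],
    or_effect = gwas$or_effect[gi2],
    se = gwas$se[gi2],
    p_assoc = gwas$p_assoc[gi2],
    info = gwas$info[gi2],
    freq_a1 = gwas$freq_a1[gi2],
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  structure(list(
    table = tab,
    panel = sub,
    report = list(
      n_panel = n_snps(panel),
      n_gwas = nrow(gwas),
      n_joined = sum(joined),
      n_allele_mismatch = sum(joined) - length(allele_ok[allele_ok]),
      n_maf_removed = n_maf_removed,
      n_ambiguous = n_amb,
      n_final = nrow(tab)
    )
  ), class = "harmonized")
}

#' @export
print.harmonized <- function(x, ...) {
  r <- x$report
  cat("harmonized panel/GWAS join:", r$n_final, "SNPs retained\n")
  cat(" joined on position:", r$n_joined,
      "| allele mismatches dropped:", r$n_allele_mismatch,
      "| MAF-filtered:", r$n_maf_removed,
      "| strand-ambiguous flagged:", r$n_ambiguous, "\n")
  invisible(x)
}
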