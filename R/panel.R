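#' Construct a genotype panel
#'
#' A genotype panel holds a samples x SNPs dosage matrix (counts of the
#' alternate allele, 0/1/2, \code{NA} for missing) together with per-SNP
#' metadata (chromosome, position, alleles, ancestral allele) and per-sample
#' population labels. It is the central genotype container consumed by the
#' selection scan, LD utilities and polygenic-score code.
#'
#' @param dosage numeric matrix, samples x SNPs, values in \{0, 1, 2, NA\}.
#' @param snp_ids character vector of SNP identifiers (one per column).
#' @param chrom per-SNP chromosome label.
#' @param pos per-SNP 1-based base-pair position; must be strictly
#'   increasing within each chromosome.
#' @param ref_allele,alt_allele per-SNP single-character nucleotides.
#' @param ancestral_allele per-SNP ancestral (human-primate common ancestor)
#'   nucleotide, or \code{NA} when unknown. Lowercase letters are accepted
#'   and flagged as low-confidence calls (the 1000 Genomes AA convention).
#' @param sample_ids per-sample identifiers (one per row).
#' @param population per-sample population label.
#'
#' @return An object of class \code{genotype_panel}: a list with the fields
#'   above plus \code{aa_low_confidence}, a logical per-SNP flag.
#' @export
genotype_panel <- function(dosage, snp_ids, chrom, pos, ref_allele, alt_allele,
                           ancestral_allele = NULL, sample_ids = NULL,
                           population = NULL) {
  dosage <- as.matrix(dosage)
  p <- ncol(dosage)
  n <- nrow(dosage)
  if (length(snp_ids) != p)
    stop("snp_ids length (", length(snp_ids), ") != dosage columns (", p, ")")
  stopifnot(length(chrom) == p, length(pos) == p,
            length(ref_allele) == p, length(alt_allele) == p)
  if (is.null(ancestral_allele)) ancestral_allele <- rep(NA_character_, p)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  if (is.null(population)) population <- rep("POP1", n)
  stopifnot(length(sample_ids) == n, length(population) == n)
  bad <- dosage[!is.na(dosage) & !(dosage %in% c(0, 1, 2))]
  if (length(bad))
    stop("dosage values must be 0, 1, 2 or NA; found e.g. ", bad[[1]])
  ord_ok <- tapply(pos, chrom, function(x) all(diff(x) > 0))
  if (!all(unlist(ord_ok)))
    stop("positions must be strictly increasing within each chromosome")
  low_conf <- !is.na(ancestral_allele) &
    ancestral_allele %in% c("a", "c", "g", "t")
  aa <- toupper(ancestral_allele)
  aa[!is.na(aa) & !(aa %in% c("A", "C", "G", "T"))] <- NA_character_
  structure(list(
    dosage = dosage,
    snp_ids = as.character(snp_ids),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref_allele = toupper(as.character(ref_allele)),
    alt_allele = toupper(as.character(alt_allele)),
    ancestral_allele = aa,
    aa_low_confidence = low_conf,
    sample_ids = as.character(sample_ids),
    population = as.character(population)
  ), class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", length(x$sample_ids), "samples x",
      length(x$snp_ids), "SNPs\n")
  tab <- table(x$population)
  cat("populations:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("ancestral allele known for",
      sum(!is.na(x$ancestral_allele)), "SNPs\n")
  invisible(x)
}

#' Number of SNPs / samples in a panel
#' @param panel a \code{genotype_panel}.
#' @return integer count.
#' @export
n_snps <- function(panel) length(panel$snp_ids)

#' @rdname n_snps
#' @export
n_samples <- function(panel) length(panel$sample_ids)

#' Subset a panel by SNP index
#'
#' @param panel a \code{genotype_panel}.
#' @param snp_idx integer or logical index over SNPs.
#' @return a \code{genotype_panel} restricted to the selected SNPs.
#' @export
subset_snps <- function(panel, snp_idx) {
  genotype_panel(
    dosage = panel$dosage[, snp_idx, drop = FALSE],
    snp_ids = panel$snp_ids[snp_idx],
    chrom = panel$chrom[snp_idx],
    pos = panel$pos[snp_idx],
    ref_allele = panel$ref_allele[snp_idx],
    alt_allele = panel$alt_allele[snp_idx],
    ancestral_allele = ifelse(panel$aa_low_confidence[snp_idx],
                              tolower(panel$ancestral_allele[snp_idx]),
                              panel$ancestral_allele[snp_idx]),
    sample_ids = panel$sample_ids,
    population = panel$population
  )
}

#' Alternate-allele frequency and MAF of panel SNPs
#'
#' Frequencies are computed over non-missing dosages; MAF folds the
#' alternate-allele frequency as \code{min(f, 1 - f)}.
#'
#' @param panel a \code{genotype_panel}.
#' @return numeric vector, one value per SNP.
#' @export
alt_freq <- function(panel) {
  colMeans(panel$dosage, na.rm = TRUE) / 2
}

#' @rdname alt_freq
#' @export
panel_maf <- function(panel) {
  f <- alt_freq(panel)
  pmin(f, 1 - f)
}
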