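#' Default GWAS thresholds for direction-bias tests
#' @export
direction_thresholds <- function()
  c(5e-10, 1e-9, 1e-8, 1e-7, 1e-6, 1e-5, 1e-4, 1e-3, 0.01, 0.05, 0.1,
    0.2, 0.5)

#' Re-orient association odds ratios to the derived allele
#'
#' Given harmonized per-SNP records carrying the GWAS effect allele
#' orientation and the panel's ancestral allele, computes the derived-allele
#' odds ratio: when the ancestral allele is the non-effect allele the effect
#' allele is the derived one and the OR is kept; when the ancestral allele
#' *is* the effect allele the OR is inverted; when the ancestral allele is
#' missing or matches neither allele the SNP is unpolarizable. Lowercase
#' ancestral calls were flagged low-confidence at parse time and are kept.
#'
#' @param harm a \code{harmonized} object (or its \code{$table}).
#' @return data.frame of class \code{polarized_summary}: \code{snp_id},
#'   \code{derived_or}, \code{log10_dor}, \code{polarization_status}
#'   (\code{effect_is_derived} / \code{effect_is_ancestral} /
#'   \code{unpolarizable}), \code{low_confidence}.
#' @export
polarize_to_derived <- function(harm) {
  tab <- if (inherits(harm, "harmonized")) harm$table else harm
  need <- c("snp_id", "ref", "alt", "ancestral", "effect_is_alt",
            "or_effect")
  stopifnot(all(need %in% names(tab)))
  eff <- ifelse(tab$effect_is_alt, tab$alt, tab$ref)
  oth <- ifelse(tab$effect_is_alt, tab$ref, tab$alt)
  aa <- tab$ancestral
  status <- rep("unpolarizable", nrow(tab))
  status[!is.na(aa) & aa == oth] <- "effect_is_derived"
  status[!is.na(aa) & aa == eff] <- "effect_is_ancestral"
  dor <- rep(NA_real_, nrow(tab))
  dor[status == "effect_is_derived"] <-
    tab$or_effect[status == "effect_is_derived"]
  dor[status == "effect_is_ancestral"] <-
    1 / tab$or_effect[status == "effect_is_ancestral"]
  out <- data.frame(
    snp_id = tab$snp_id,
    derived_or = dor,
    log10_dor = log10(dor),
    polarization_status = status,
    low_confidence = if ("aa_low_confidence" %in% names(tab))
      tab$aa_low_confidence else FALSE,
    stringsAsFactors = FALSE
  )
  class(out) <- c("polarized_summary", "data.frame")
  out
}

# one cell of the direction-bias table: counts and the one-sample t on
# log10(derived OR)
.direction_cell <- function(ldor) {
  n_prot <- sum(ldor < 0)
  n_risk <- sum(ldor > 0)
  n_neutral <- sum(ldor == 0)
  m <- mean(ldor)
  out <- list(n_protective = n_prot, n_risk = n_risk, n_neutral = n_neutral,
              n = length(ldor), mean_log10_dor = m,
              ci_lo = NA_real_, ci_hi = NA_real_, p_t_one_sample = NA_real_,
              flag = "")
  if (length(ldor) < 2) { out$flag <- "underpowered"; return(out) }
  if (stats::sd(ldor) == 0) { out$flag <- "zero-variance"; return(out) }
  tt <- stats::t.test(ldor, mu = 0)
  out$ci_lo <- tt$conf.int[1]; out$ci_hi <- tt$conf.int[2]
  out$p_t_one_sample <- tt$p.value
  out
}

#' Direction-bias tests on derived-allele odds ratios
#'
#' For each GWAS threshold and for markers and non-markers separately:
#' counts of derived-protective (OR < 1) and derived-risk (OR > 1) alleles
#' (OR exactly 1 tracked separately), the mean log10 derived OR with its
#' t-based 95\% CI and one-sample t-test against 0 (the CI containing 0 is
#' read as no direction bias), a Welch two-sample t-test marker vs
#' non-marker, and a chi-square test on the proportion-of-risk 2x2 table
#' (Fisher fallback when any expected count is below 5).
#'
#' @param polarized a \code{polarized_summary}.
#' @param annotation an \code{rns_annotation} over the LD-independent SNPs.
#' @param p_assoc named numeric vector of GWAS p-values per SNP id.
#' @param thresholds default \code{direction_thresholds()}.
#' @param min_cell cells with fewer polarizable SNPs are flagged
#'   underpowered (default 2).
#' @return data.frame of class \code{direction_bias_result}, one row per
#'   (threshold, group).
#' @export
direction_bias_tests <- function(polarized, annotation, p_assoc,
                                 thresholds = direction_thresholds(),
                                 min_cell = 2) {
  pol <- polarized[polarized$polarization_status != "unpolarizable", ,
                   drop = FALSE]
  pol <- pol[pol$snp_id %in% annotation$snp_id, , drop = FALSE]
  mk_ids <- annotation$snp_id[annotation$is_marker]
  pv <- p_assoc[pol$snp_id]
  is_mk <- pol$snp_id %in% mk_ids
  rows <- list()
  for (t in thresholds) {
    below <- !is.na(pv) & pv < t
    ld_m <- pol$log10_dor[below & is_mk]
    ld_n <- pol$log10_dor[below & !is_mk]
    cell_m <- .direction_cell(ld_m)
    cell_n <- .direction_cell(ld_n)
    # Welch two-sample t marker vs non-marker
    p_t2 <- if (length(ld_m) >= 2 && length(ld_n) >= 2 &&
                (stats::sd(ld_m) > 0 || stats::sd(ld_n) > 0))
      stats::t.test(ld_m, ld_n)$p.value else NA_real_
    # proportion-of-risk 2x2 (risk vs protective, marker vs non-marker)
    tab <- matrix(c(cell_m$n_risk, cell_m$n_protective,
                    cell_n$n_risk, cell_n$n_protective), 2, byrow = TRUE)
    p_chisq <- NA_real_
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      p_chisq <- if (any(expected < 5))
        stats::fisher.test(tab)$p.value
      else suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    }
    for (grp in c("marker", "non_marker")) {
      cell <- if (grp == "marker") cell_m else cell_n
      rows[[length(rows) + 1]] <- data.frame(
        threshold = t, group = grp, n = cell$n,
        n_protective = cell$n_protective, n_risk = cell$n_risk,
        n_neutral = cell$n_neutral,
        mean_log10_dor = cell$mean_log10_dor,
        ci_lo = cell$ci_lo, ci_hi = cell$ci_hi,
        p_t_one_sample = cell$p_t_one_sample,
        p_t_two_sample = p_t2, p_chisq_proportions = p_chisq,
        flag = if (cell$n < min_cell) "underpowered" else cell$flag,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("direction_bias_result", "data.frame")
  out
}
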