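# Squared Pearson correlation (composite LD) between two dosage vectors,
# dropping missing pairs. Returns 0 when either vector is constant.
dosage_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(0)
  va <- stats::var(a[ok]); vb <- stats::var(b[ok])
  if (va == 0 || vb == 0) return(0)
  stats::cor(a[ok], b[ok])^2
}

#' Greedy LD clumping
#'
#' PLINK-style clumping: repeatedly take the unabsorbed SNP with the
#' smallest p-value (ties broken by genomic order) as an index SNP and
#' absorb all unabsorbed SNPs on the same chromosome within
#' \code{window_kb} whose dosage r-squared with the index reaches
#' \code{r2_max}.
#'
#' @param snps data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos}, \code{p}.
#' @param panel a \code{genotype_panel} covering all \code{snps}.
#' @param r2_max clumping r-squared threshold (default 0.1).
#' @param window_kb window half-width in kb (default 500).
#' @param ranking_p label recording which p-value ranked the clump
#'   (e.g. \code{"p_assoc"} or \code{"p_rns"}).
#' @return an object of class \code{clumped_set}: \code{index_snps} (in
#'   selection order), \code{removed_by} (named character: absorbed SNP ->
#'   its index SNP), \code{ranking_p}.
#' @export
ld_clump <- function(snps, panel, r2_max = 0.1, window_kb = 500,
                     ranking_p = "p") {
  stopifnot(all(c("snp_id", "chrom", "pos", "p") %in% names(snps)))
  idx_in_panel <- match(snps$snp_id, panel$snp_ids)
  if (anyNA(idx_in_panel))
    stop("SNP(s) absent from panel: ",
         paste(utils::head(snps$snp_id[is.na(idx_in_panel)], 10),
               collapse = ", "))
  n <- nrow(snps)
  ord <- order(snps$p, snps$chrom, snps$pos)
  unabsorbed <- rep(TRUE, n)
  index_snps <- character(0)
  removed_by <- character(0)
  window_bp <- window_kb * 1000
  dos <- panel$dosage[, idx_in_panel, drop = FALSE]
  gord <- order(snps$chrom, snps$pos)
  if (!anyNA(dos)) {
    # fast path: compiled kernel on unit-norm centered columns in genomic
    # order (r = plain cross product)
    xs <- unit_norm_cols(scale(dos[, gord, drop = FALSE], center = TRUE,
                               scale = FALSE))
    rank_in_g <- integer(n); rank_in_g[gord] <- seq_len(n)
    ab <- .clump_kernel(xs, as.integer(factor(snps$chrom[gord])),
                        as.numeric(snps$pos[gord]),
                        rank_in_g[ord] - 1L, r2_max, window_bp)
    idx_g <- which(ab == -1L)
    # index SNPs in p-value selection order
    sel <- rank_in_g[ord]
    sel <- sel[sel %in% idx_g]
    index_snps <- snps$snp_id[gord][sel]
    absorbed_g <- which(ab >= 0L)
    removed_by <- stats::setNames(snps$snp_id[gord][ab[absorbed_g] + 1L],
                                  snps$snp_id[gord][absorbed_g])
    if (is.null(removed_by)) removed_by <- character(0)
    return(structure(list(index_snps = index_snps,
                          removed_by = removed_by,
                          ranking_p = ranking_p), class = "clumped_set"))
  }
  rank_of <- integer(n); rank_of[gord] <- seq_len(n)
  chrom_s <- snps$chrom[gord]; pos_s <- snps$pos[gord]
  for (i in ord) {
    if (!unabsorbed[i]) next
    unabsorbed[i] <- FALSE
    index_snps <- c(index_snps, snps$snp_id[i])
    ri <- rank_of[i]
    lo <- ri; hi <- ri
    while (lo > 1 && chrom_s[lo - 1] == chrom_s[ri] &&
           pos_s[ri] - pos_s[lo - 1] <= window_bp) lo <- lo - 1
    while (hi < n && chrom_s[hi + 1] == chrom_s[ri] &&
           pos_s[hi + 1] - pos_s[ri] <= window_bp) hi <- hi + 1
    cand <- gord[lo:hi]
    cand <- cand[unabsorbed[cand]]
    if (length(cand)) {
      r2 <- vapply(cand, function(j) dosage_r2(dos[, i], dos[, j]),
                   numeric(1))
      hit <- cand[r2 >= r2_max]
      if (length(hit)) {
        unabsorbed[hit] <- FALSE
        removed_by[snps$snp_id[hit]] <- snps$snp_id[i]
      }
    }
  }
  structure(list(index_snps = index_snps, removed_by = removed_by,
                 ranking_p = ranking_p), class = "clumped_set")
}

#' @export
print.clumped_set <- function(x, ...) {
  cat("clumped_set:", length(x$index_snps), "index SNPs,",
      length(x$removed_by), "absorbed (ranked by", x$ranking_p, ")\n")
  invisible(x)
}

#' Write a clumped set as a tab-separated table
#' @param clumped a \code{clumped_set}.
#' @param p named numeric vector of the ranking p-values per SNP id.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_clumps <- function(clumped, p, path) {
  absorbed <- split(names(clumped$removed_by), unname(clumped$removed_by))
  out <- data.frame(
    INDEX_SNP = clumped$index_snps,
    P = unname(p[clumped$index_snps]),
    N_ABSORBED = vapply(clumped$index_snps,
                        function(s) length(absorbed[[s]]), integer(1)),
    ABSORBED_IDS = vapply(clumped$index_snps, function(s)
      paste(absorbed[[s]], collapse = ","), character(1))
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-SNP genomic matching covariates
#'
#' Computes, for every panel SNP, the covariates used to draw matched
#' control SNPs: minor allele frequency, number of LD buddies (SNPs with
#' r-squared at least \code{buddy_r2} within \code{buddy_window_kb}),
#' distance in bp to the nearest gene interval (0 inside a gene,
#' \code{Inf} when no genes are given), and gene density (gene intervals
#' overlapping a \code{density_window_kb} window around the SNP).
#'
#' @param panel a \code{genotype_panel}.
#' @param genes optional \code{region_set} of gene intervals.
#' @param buddy_r2 LD-buddy r-squared cutoff (default 0.5).
#' @param buddy_window_kb LD-buddy window half-width (default 500).
#' @param density_window_kb gene-density window half-width (default 100).
#' @return data.frame with columns \code{snp_id}, \code{maf},
#'   \code{ld_buddies}, \code{gene_dist}, \code{gene_density}.
#' @export
annotate_properties <- function(panel, genes = NULL, buddy_r2 = 0.5,
                                buddy_window_kb = 500,
                                density_window_kb = 100) {
  p <- n_snps(panel)
  maf <- panel_maf(panel)
  buddy_bp <- buddy_window_kb * 1000
  dens_bp <- density_window_kb * 1000
  sc <- scale_dosage(panel$dosage)
  gord <- order(panel$chrom, panel$pos)
  xs <- unit_norm_cols(sc$x[, gord, drop = FALSE])
  buddies_g <- .buddies_kernel(xs, as.integer(factor(panel$chrom[gord])),
                               as.numeric(panel$pos[gord]),
                               buddy_r2, buddy_bp)
  buddies <- integer(p)
  buddies[gord] <- buddies_g
  gene_dist <- rep(Inf, p)
  gene_density <- integer(p)
  if (!is.null(genes) && nrow(genes)) {
    for (j in seq_len(p)) {
      g <- genes[genes$chrom == panel$chrom[j], , drop = FALSE]
      if (!nrow(g)) next
      pos0 <- panel$pos[j] - 1  # 0-based coordinate of the base
      gene_dist[j] <- min(pmax(g$start - pos0, pos0 - (g$end - 1), 0))
      gene_density[j] <- sum(g$start < pos0 + dens_bp &
                               g$end > pos0 - dens_bp)
    }
  }
  data.frame(snp_id = panel$snp_ids, maf = maf, ld_buddies = buddies,
             gene_dist = gene_dist, gene_density = gene_density,
             stringsAsFactors = FALSE)
}

# eligibility of pool rows for one target row under matching tolerances
.match_eligible <- function(target, pool, maf_tol, rel_tol, count_slack) {
  rel_ok <- function(pv, tv) {
    if (!is.finite(tv)) return(!is.finite(pv))
    if (tv == 0) return(pv <= count_slack)
    (pv >= tv * (1 - rel_tol) & pv <= tv * (1 + rel_tol)) |
      abs(pv - tv) <= count_slack
  }
  abs(pool$maf - target$maf) <= maf_tol &
    rel_ok(pool$ld_buddies, target$ld_buddies) &
    rel_ok(pool$gene_dist, target$gene_dist) &
    rel_ok(pool$gene_density, target$gene_density)
}

#' Draw matched SNP sets for empirical nulls
#'
#' For each target SNP, candidate pool SNPs must match on MAF (within
#' \code{maf_tol}, absolute) and on LD buddies, gene distance and gene
#' density (within \code{rel_tol} relative, with an absolute slack of
#' \code{count_slack} so zero-valued counts accept only near-zero values).
#' Each returned set draws one uniform candidate per target without
#' replacement within the set; sets are drawn independently.
#'
#' @param target_ids,pool_ids disjoint character vectors of SNP ids.
#' @param props matching covariates from \code{\link{annotate_properties}}
#'   covering both targets and pool.
#' @param n_sets number of sets to draw.
#' @param seed integer seed (draws are deterministic given it).
#' @param maf_tol absolute MAF tolerance (default 0.05).
#' @param rel_tol relative tolerance for count/distance covariates
#'   (default 0.5).
#' @param count_slack absolute slack added to relative bounds (default 1).
#' @return list of \code{n_sets} character vectors, each of
#'   \code{length(target_ids)} distinct pool SNP ids.
#' @export
draw_matched_sets <- function(target_ids, pool_ids, props, n_sets, seed,
                              maf_tol = 0.05, rel_tol = 0.5,
                              count_slack = 1) {
  if (n_sets < 1) stop("n_sets must be >= 1")
  if (length(intersect(target_ids, pool_ids)))
    stop("target and pool must be disjoint")
  rownames(props) <- props$snp_id
  tp <- props[target_ids, , drop = FALSE]
  pp <- props[pool_ids, , drop = FALSE]
  if (anyNA(tp$maf) || anyNA(pp$maf))
    stop("props must cover all target and pool SNPs")
  cand <- lapply(seq_along(target_ids), function(i)
    which(.match_eligible(tp[i, ], pp, maf_tol, rel_tol, count_slack)))
  empty <- lengths(cand) == 0
  if (any(empty))
    stop("matching infeasible: no pool candidate for target SNP(s) ",
         paste(utils::head(target_ids[empty], 10), collapse = ", "))
  set.seed(seed)
  ntar <- length(target_ids)
  # fill scarce targets first to minimise within-set collisions
  fill_order <- order(lengths(cand))
  lapply(seq_len(n_sets), function(s) {
    chosen <- integer(ntar)
    used <- logical(length(pool_ids))
    for (i in fill_order) {
      avail <- cand[[i]][!used[cand[[i]]]]
      if (!length(avail))
        stop("matching infeasible within a set for target SNP ",
             target_ids[i], " (candidates exhausted)")
      pick <- if (length(avail) == 1) avail else sample(avail, 1)
      chosen[i] <- pick
      used[pick] <- TRUE
    }
    pool_ids[chosen]
  })
}
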