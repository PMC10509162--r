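#' Default GWAS p-value thresholds for the enrichment cascade
#' @export
enrichment_thresholds <- function()
  c(5e-8, 1e-7, 1e-6, 1e-5, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.2, 0.5)

#' Define selection (RNS) markers from a clumped SNP set
#'
#' Markers are the \code{floor(top_fraction * N)} LD-independent index SNPs
#' with the smallest selection-scan p-values; boundary ties are broken by
#' genomic order (chrom, pos).
#'
#' @param clumped a \code{clumped_set}.
#' @param p_rns named numeric vector of scan p-values (must cover every
#'   index SNP).
#' @param top_fraction q in (0, 1), default 0.05.
#' @param chrom,pos optional named vectors used only for tie-breaking; when
#'   omitted ties are broken by the order of \code{clumped$index_snps}.
#' @return an object of class \code{rns_annotation}: data.frame with
#'   columns \code{snp_id}, \code{p_rns}, \code{is_marker};
#'   \code{attr(, "top_fraction")} records q.
#' @export
define_rns_markers <- function(clumped, p_rns, top_fraction = 0.05,
                               chrom = NULL, pos = NULL) {
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction >= 1)
    stop("top_fraction must lie strictly between 0 and 1")
  ids <- clumped$index_snps
  pv <- p_rns[ids]
  if (anyNA(pv)) stop("p_rns missing for some index SNPs")
  n_mark <- floor(top_fraction * length(ids))
  if (is.null(chrom)) {
    ord <- order(pv)  # stable: ties keep genomic input order
  } else {
    ord <- order(pv, chrom[ids], pos[ids])
  }
  is_marker <- logical(length(ids))
  is_marker[ord[seq_len(n_mark)]] <- TRUE
  out <- data.frame(snp_id = ids, p_rns = unname(pv), is_marker = is_marker,
                    stringsAsFactors = FALSE)
  attr(out, "top_fraction") <- top_fraction
  class(out) <- c("rns_annotation", "data.frame")
  out
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact conditional (hypergeometric) test with the usual two-sided rule
#' (sum of tables no more probable than the observed one), the conditional
#' maximum-likelihood odds ratio with an exact 95\% CI from inverting the
#' noncentral hypergeometric tails, and the sample odds ratio
#' \code{ad / bc} alongside.
#'
#' @param a,b,c,d nonnegative integer cell counts, row-wise:
#'   \code{matrix(c(a, b, c, d), 2, byrow = TRUE)}.
#' @param alternative \code{"two_sided"} (default), \code{"greater"} or
#'   \code{"less"}.
#' @return list with \code{p}, \code{or_sample}, \code{or_cmle},
#'   \code{ci95}, \code{degenerate} (TRUE when a margin is all zero, in
#'   which case p = 1 and the OR is undefined).
#' @export
fisher_exact_2x2 <- function(a, b, c, d,
                             alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells)))
    stop("cell counts must be nonnegative integers")
  tab <- matrix(cells, 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(p = 1, or_sample = NA_real_, or_cmle = NA_real_,
                ci95 = c(NA_real_, NA_real_), degenerate = TRUE))
  }
  alt <- switch(alternative, two_sided = "two.sided", greater = "greater",
                less = "less")
  ft <- stats::fisher.test(tab, alternative = alt, conf.int = TRUE)
  or_sample <- (a * d) / (b * c)
  list(p = unname(ft$p.value), or_sample = or_sample,
       or_cmle = unname(ft$estimate), ci95 = unname(ft$conf.int),
       degenerate = FALSE)
}

#' Marker enrichment across GWAS significance thresholds
#'
#' For each threshold t, builds the 2x2 table of (marker vs non-marker) x
#' (GWAS p below vs at/above t) over the LD-independent SNPs and tests it
#' with the two-sided Fisher exact test. A Wald CI on the sample log-OR is
#' reported next to the exact CI.
#'
#' @param annotation an \code{rns_annotation}.
#' @param p_assoc named numeric vector of GWAS p-values covering the index
#'   SNPs.
#' @param thresholds ascending threshold vector (default
#'   \code{enrichment_thresholds()}).
#' @return data.frame of class \code{enrichment_result} with one row per
#'   threshold: \code{threshold, a, b, c, d, or, ci_lo, ci_hi, wald_lo,
#'   wald_hi, p, underpowered}.
#' @export
threshold_enrichment <- function(annotation, p_assoc,
                                 thresholds = enrichment_thresholds()) {
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  pv <- p_assoc[annotation$snp_id]
  if (anyNA(pv)) stop("p_assoc missing for some index SNPs")
  mk <- annotation$is_marker
  rows <- lapply(thresholds, function(t) {
    below <- pv < t
    a <- sum(mk & below); b <- sum(mk & !below)
    c_ <- sum(!mk & below); d <- sum(!mk & !below)
    ft <- fisher_exact_2x2(a, b, c_, d, "two_sided")
    lor <- log((a * d) / (b * c_))
    se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
    data.frame(threshold = t, a = a, b = b, c = c_, d = d,
               or = if (b * c_ > 0) (a * d) / (b * c_) else
                 if (a == 0) 0 else Inf,
               ci_lo = ft$ci95[1], ci_hi = ft$ci95[2],
               wald_lo = exp(lor - 1.96 * se), wald_hi = exp(lor + 1.96 * se),
               p = ft$p, underpowered = (a + c_ == 0) || a == 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Write enrichment results as a tab-separated table
#' @param enr an \code{enrichment_result}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_enrichment <- function(enr, path) {
  out <- data.frame(THRESHOLD = enr$threshold, A = enr$a, B = enr$b,
                    C = enr$c, D = enr$d, OR = enr$or, CI_LO = enr$ci_lo,
                    CI_HI = enr$ci_hi, P = enr$p)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' One-sample Kolmogorov-Smirnov test against Uniform(0, 1)
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return list with \code{statistic} and \code{p}.
#' @export
ks_uniformity <- function(p) {
  if (!length(p)) stop("empty input")
  if (any(p <= 0 | p > 1)) stop("values must lie in (0, 1]")
  kt <- suppressWarnings(stats::ks.test(p, "punif"))
  list(statistic = unname(kt$statistic), p = unname(kt$p.value))
}

# partial Spearman: Pearson correlation of rank residuals after removing
# the (rank-transformed) covariate from both variables
.partial_spearman <- function(rx, ry, rc) {
  ex <- stats::lm.fit(cbind(1, rc), rx)$residuals
  ey <- stats::lm.fit(cbind(1, rc), ry)$residuals
  vx <- sum(ex^2); vy <- sum(ey^2)
  if (vx < 1e-12 || vy < 1e-12)
    stop("degenerate partial correlation: zero residual rank variance")
  sum(ex * ey) / sqrt(vx * vy)
}

#' MAF-controlled partial Spearman correlation with a permutation null
#'
#' Rank-transforms \code{x}, \code{y} and the covariate, computes the
#' partial correlation of the ranks given the covariate ranks by
#' residualisation, an asymptotic p-value from the t approximation with
#' n - 3 degrees of freedom, and a one-sided (greater) permutation p-value
#' obtained by permuting \code{x} against the fixed (\code{y},
#' \code{covar}) pairs.
#'
#' @param x,y numeric vectors (e.g. -log10 GWAS p and -log10 scan p).
#' @param covar numeric covariate (e.g. MAF).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @param add_one use the add-one-corrected estimate
#'   \code{(1 + r) / (n_perm + 1)} (default); otherwise \code{r / n_perm}
#'   with a floor of \code{1 / n_perm}.
#' @return an object of class \code{correlation_result}: \code{rho},
#'   \code{p_asymptotic}, \code{p_perm}, \code{n_perm}, \code{n}.
#' @export
partial_spearman_perm <- function(x, y, covar, n_perm = 10000, seed = 1,
                                  add_one = TRUE) {
  n <- length(x)
  stopifnot(length(y) == n, length(covar) == n)
  if (n < 10) stop("need at least 10 observations")
  if (n_perm < 1) stop("n_perm must be >= 1")
  rx <- rank(x); ry <- rank(y); rc <- rank(covar)
  rho <- .partial_spearman(rx, ry, rc)
  tstat <- rho * sqrt((n - 3) / (1 - rho^2))
  p_asym <- 2 * stats::pt(-abs(tstat), df = n - 3)
  set.seed(seed)
  # fast permutation path: with Q an orthonormal basis of span{1, rank(covar)}
  # and ey the residual of rank(y), the permuted partial correlation is
  # sum(xb * ey) / sqrt((sum(xb^2) - |Q'xb|^2) * sum(ey^2)), and sum(xb^2)
  # is permutation-invariant.
  Q <- qr.Q(qr(cbind(1, rc)))
  ey <- ry - Q %*% crossprod(Q, ry)
  vy <- sum(ey^2)
  sx2 <- sum(rx^2)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    xb <- sample(rx)
    qx <- crossprod(Q, xb)
    vxb <- sx2 - sum(qx^2)
    rho_b <- sum(xb * ey) / sqrt(vxb * vy)
    if (rho_b >= rho) exceed <- exceed + 1L
  }
  p_perm <- if (add_one) (1 + exceed) / (n_perm + 1)
  else max(exceed, 1) / n_perm
  structure(list(rho = rho, p_asymptotic = p_asym, p_perm = p_perm,
                 n_perm = n_perm, n = n), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("partial Spearman rho =", format(x$rho, digits = 4),
      "(n =", x$n, ")\n")
  cat("asymptotic p =", format(x$p_asymptotic, digits = 3),
      "| permutation p =", format(x$p_perm, digits = 3),
      "(", x$n_perm, "permutations )\n")
  invisible(x)
}
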