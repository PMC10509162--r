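# Scaled dosage matrix for PCA / z-score regression.
# Mean-imputes missing genotypes per SNP, centers each SNP by 2*p-hat and
# scales by sqrt(2*p-hat*(1-p-hat)). Monomorphic SNPs get an all-zero column
# (and are flagged), so downstream code can treat them explicitly.
scale_dosage <- function(dosage) {
  f <- colMeans(dosage, na.rm = TRUE) / 2
  n <- nrow(dosage)
  x <- dosage
  if (anyNA(x)) {
    na_idx <- which(is.na(x), arr.ind = TRUE)
    x[na_idx] <- 2 * f[na_idx[, 2]]
  }
  # flag both fixed alleles and constant columns (e.g. all-heterozygous)
  v <- colMeans(x^2) - colMeans(x)^2
  mono <- is.na(f) | f <= 0 | f >= 1 | v <= 0
  sd_ <- sqrt(2 * f * (1 - f))
  sd_[mono] <- 1
  x <- sweep(x, 2, 2 * f, "-")
  x <- sweep(x, 2, sd_, "/")
  x[, mono] <- 0
  list(x = x, freq = f, monomorphic = mono)
}

# unit-norm the columns of a (centered) matrix so r = plain cross product
unit_norm_cols <- function(x) {
  cn <- sqrt(colSums(x^2))
  cn[cn == 0] <- 1
  sweep(x, 2, cn, "/")
}

# Greedy LD thinning on a scaled dosage matrix: SNPs are visited in genomic
# order; a SNP is kept unless its squared correlation with an already-kept
# SNP among the previous `window` SNPs (same chromosome) reaches r2_max.
thin_mask_ld <- function(x_scaled, chrom, window, r2_max) {
  p <- ncol(x_scaled)
  if (r2_max >= 1) return(rep(TRUE, p))
  xs <- unit_norm_cols(x_scaled)
  .thin_kernel(xs, as.integer(factor(chrom)), as.integer(window), r2_max)
}

#' Fit the PCA model for the selection scan
#'
#' Standardises dosages (center \code{2p}, scale \code{sqrt(2p(1-p))}, mean
#' imputation of missing genotypes), LD-thins SNPs with a sliding window of
#' \code{thin_window_snps} SNPs at squared-correlation threshold
#' \code{thin_r2}, and computes the principal components of the thinned
#' matrix. When \code{k = "auto"} the number of retained components is picked
#' by an elbow (Cattell-style) rule: K is the last component before the first
#' relative drop in explained variance smaller than \code{elbow_tol}.
#'
#' @param panel a \code{genotype_panel}.
#' @param k number of components, or \code{"auto"}.
#' @param thin_window_snps sliding-window size in SNPs (default 200).
#' @param thin_r2 thinning r-squared threshold (default 0.1);
#'   \code{thin_r2 >= 1} disables thinning.
#' @param elbow_tol relative-drop tolerance for the auto rule (default 0.05).
#' @param k_max cap for auto K (default 10).
#' @param seed unused placeholder for interface symmetry; the fit is
#'   deterministic.
#' @return an object of class \code{pca_model} with fields \code{K},
#'   \code{scores} (samples x K coordinates), \code{u} (orthonormal left
#'   singular vectors), \code{singular_values}, \code{var_explained},
#'   \code{thin_mask}.
#' @export
fit_pca <- function(panel, k = 3, thin_window_snps = 200, thin_r2 = 0.1,
                    elbow_tol = 0.05, k_max = 10, seed = NULL) {
  sc <- scale_dosage(panel$dosage)
  poly <- !sc$monomorphic
  if (!any(poly)) stop("degenerate input: all SNPs are monomorphic")
  mask <- rep(FALSE, n_snps(panel))
  mask[poly] <- thin_mask_ld(sc$x[, poly, drop = FALSE],
                             panel$chrom[poly], thin_window_snps, thin_r2)
  x <- sc$x[, mask, drop = FALSE]
  n <- nrow(x)
  if (n < 2) stop("need at least 2 samples")
  # samples << SNPs: eigendecompose the n x n Gram matrix instead of a
  # full SVD of the n x p matrix
  ev <- eigen(tcrossprod(x), symmetric = TRUE)
  d <- sqrt(pmax(ev$values, 0))
  sv <- list(d = d, u = ev$vectors)
  ve <- d^2 / sum(d^2)
  rank_x <- sum(d > d[1] * 1e-8)
  if (identical(k, "auto")) {
    # elbow rule: the first pair of adjacent components whose explained
    # variance stops dropping (relative to the leading component) marks
    # the start of the noise floor; keep everything before that pair
    kk <- min(k_max, rank_x)
    for (j in 3:length(ve)) {
      if ((ve[j - 1] - ve[j]) / ve[1] < elbow_tol) { kk <- j - 2; break }
    }
    k <- max(1L, min(kk, k_max, rank_x))
  } else {
    k <- as.integer(k)
    if (k < 1) stop("k must be >= 1")
    if (k > rank_x) stop("k = ", k, " exceeds the rank of the thinned matrix (",
                         rank_x, ")")
  }
  if (sum(mask) < k + 1) stop("fewer than k + 1 SNPs remain after thinning")
  structure(list(
    K = k,
    scores = sv$u[, seq_len(k), drop = FALSE] %*%
      diag(d[seq_len(k)], nrow = k),
    u = sv$u[, seq_len(k), drop = FALSE],
    singular_values = d,
    var_explained = ve,
    thin_mask = mask
  ), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("pca_model: K =", x$K, "components,", sum(x$thin_mask),
      "SNPs after LD thinning\n")
  cat("variance explained:",
      paste(sprintf("%.3f", x$var_explained[seq_len(min(x$K, 6))]),
            collapse = " "), "\n")
  invisible(x)
}

#' Mahalanobis outlier statistics from a z-score matrix
#'
#' Low-level worker shared by \code{\link{scan_pvalues}}: squared Mahalanobis
#' distance of each row of \code{z} from \code{center} under \code{scatter},
#' and the inflation-corrected chi-square upper-tail p-values.
#'
#' @param z SNPs x K matrix of z-scores.
#' @param center length-K location.
#' @param scatter K x K scatter matrix.
#' @param lambda genomic inflation factor; \code{NULL} recomputes it as
#'   \code{median(d2) / qchisq(0.5, K)}.
#' @return list with \code{d2}, \code{lambda}, \code{p}.
#' @export
mahalanobis_scan <- function(z, center, scatter, lambda = NULL) {
  z <- as.matrix(z)
  k <- ncol(z)
  d2 <- stats::mahalanobis(z, center, scatter)
  if (is.null(lambda)) lambda <- stats::median(d2) / stats::qchisq(0.5, k)
  p <- stats::pchisq(d2 / lambda, df = k, lower.tail = FALSE)
  list(d2 = d2, lambda = lambda, p = p)
}

#' Per-SNP selection scan p-values
#'
#' Regresses every SNP's standardised dosage vector on the K principal
#' component axes, forming a length-K z-score vector per SNP; estimates a
#' robust center and scatter of the z rows (Minimum Covariance Determinant
#' with support fraction 0.75; median/MAD when K = 1); computes squared
#' Mahalanobis distances, the genomic inflation factor
#' \eqn{\lambda = median(D^2) / median(\chi^2_K)}, and upper-tail
#' chi-square(K) p-values of \eqn{D^2/\lambda}. Monomorphic SNPs get
#' \code{p_rns = 1} so downstream joins keep them.
#'
#' @param panel the \code{genotype_panel} the model was fit on.
#' @param model a \code{pca_model}.
#' @param robust use MCD center/scatter (default \code{TRUE}); otherwise the
#'   classical mean/covariance.
#' @param seed integer seed making the MCD subsampling deterministic.
#' @return an object of class \code{selection_scan}: \code{snp_id}, \code{z}
#'   (SNPs x K), \code{d2}, \code{lambda_gc}, \code{p_rns},
#'   \code{robust_center}, \code{robust_scatter}, \code{monomorphic}.
#' @export
scan_pvalues <- function(panel, model, robust = TRUE, seed = 1) {
  if (nrow(model$u) != n_samples(panel))
    stop("model was fit on a different sample set")
  k <- model$K
  if (k < 1) stop("model has K = 0 components")
  sc <- scale_dosage(panel$dosage)
  y <- sc$x
  u <- model$u                      # n x K, orthonormal columns
  n <- nrow(y)
  beta <- crossprod(u, y)           # K x p (since U'U = I)
  rss <- pmax(colSums(y^2) - colSums(beta^2), 0)
  sigma <- sqrt(rss / (n - k))
  z <- t(beta) / ifelse(sigma > 0, sigma, Inf)  # p x K
  z[sc$monomorphic, ] <- 0

  zz <- z[!sc$monomorphic & sigma > 0, , drop = FALSE]
  if (nrow(zz) < k + 1) stop("too few polymorphic SNPs for scatter estimation")
  if (robust) {
    if (k == 1) {
      center <- stats::median(zz)
      scatter <- matrix(stats::mad(zz)^2, 1, 1)
    } else {
      set.seed(seed)
      rob <- MASS::cov.rob(zz, method = "mcd",
                           quantile.used = floor(0.75 * nrow(zz)),
                           nsamp = 500)
      center <- rob$center
      scatter <- rob$cov
    }
  } else {
    center <- colMeans(zz)
    scatter <- stats::cov(zz)
  }
  if (!all(is.finite(scatter)) ||
      inherits(try(solve(scatter), silent = TRUE), "try-error") ||
      abs(det(scatter)) < 1e-300) {
    warning("singular scatter matrix; falling back to diagonal scatter")
    scatter <- diag(pmax(apply(zz, 2, stats::var), 1e-12), k)
  }
  ms <- mahalanobis_scan(z, center, scatter)
  p <- ms$p
  p[sc$monomorphic] <- 1
  structure(list(
    snp_id = panel$snp_ids,
    z = z,
    d2 = ms$d2,
    lambda_gc = ms$lambda,
    p_rns = p,
    robust_center = center,
    robust_scatter = scatter,
    monomorphic = sc$monomorphic,
    K = k
  ), class = "selection_scan")
}

#' @export
print.selection_scan <- function(x, ...) {
  cat("selection_scan:", length(x$p_rns), "SNPs, K =", x$K, "\n")
  cat("lambda_gc =", format(x$lambda_gc, digits = 4),
      "| SNPs with p_rns < 0.05:", sum(x$p_rns < 0.05), "\n")
  invisible(x)
}

#' @export
summary.selection_scan <- function(object, ...) {
  out <- list(
    n_snps = length(object$p_rns),
    K = object$K,
    lambda_gc = object$lambda_gc,
    frac_below_05 = mean(object$p_rns < 0.05),
    d2_quantiles = stats::quantile(object$d2, c(.5, .9, .99, 1))
  )
  class(out) <- "summary.selection_scan"
  out
}

#' @export
print.summary.selection_scan <- function(x, ...) {
  cat("selection scan over", x$n_snps, "SNPs (K =", x$K, ")\n")
  cat("lambda_gc:", format(x$lambda_gc, digits = 4), "\n")
  cat("fraction p_rns < 0.05:", format(x$frac_below_05, digits = 3), "\n")
  print(x$d2_quantiles)
  invisible(x)
}

#' QQ plot of scan p-values
#' @param x a \code{selection_scan}.
#' @param ... passed to \code{plot}.
#' @export
plot.selection_scan <- function(x, ...) {
  p <- sort(x$p_rns)
  n <- length(p)
  exp_q <- -log10((seq_len(n) - 0.5) / n)
  plot(exp_q, -log10(p), xlab = "expected -log10 p",
       ylab = "observed -log10 p", main = "selection scan QQ", ...)
  graphics::abline(0, 1, col = "grey50")
  invisible(x)
}

#' Weir-Cockerham FST between two populations
#'
#' Per-SNP Weir-Cockerham (1984) theta-hat \code{a / (a + b + c)} from the
#' standard variance components for r = 2 populations and diploid genotype
#' counts. SNPs monomorphic in both populations get \code{NA}.
#'
#' @param panel a \code{genotype_panel}.
#' @param pop_a,pop_b population labels present in \code{panel$population}.
#' @return data.frame with columns \code{snp_id}, \code{theta}.
#' @export
wc_fst <- function(panel, pop_a, pop_b) {
  pops <- panel$population
  for (p_ in c(pop_a, pop_b)) {
    if (sum(pops == p_) < 2)
      stop("population label '", p_, "' absent or has < 2 samples")
  }
  comp <- function(label) {
    d <- panel$dosage[pops == label, , drop = FALSE]
    n <- colSums(!is.na(d))
    list(n = n, p = colMeans(d, na.rm = TRUE) / 2,
         h = colMeans(d == 1, na.rm = TRUE))
  }
  A <- comp(pop_a); B <- comp(pop_b)
  r <- 2
  nbar <- (A$n + B$n) / r
  pbar <- (A$n * A$p + B$n * B$p) / (r * nbar)
  hbar <- (A$n * A$h + B$n * B$h) / (r * nbar)
  nc <- (r * nbar - (A$n^2 + B$n^2) / (r * nbar)) / (r - 1)
  s2 <- (A$n * (A$p - pbar)^2 + B$n * (B$p - pbar)^2) / ((r - 1) * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  theta <- a / (a + b + cc)
  theta[pbar <= 0 | pbar >= 1] <- NA_real_
  data.frame(snp_id = panel$snp_ids, theta = theta, stringsAsFactors = FALSE)
}

#' Trimmed chi-square null fit for FST outlier detection
#'
#' Fits a rescaled chi-square null to the bulk of theta-hat values in the
#' style of OutFLANK: the lowest and highest \code{trim_fraction} of values
#' are discarded, and the degrees of freedom \code{df'} and mean are fit by
#' maximum likelihood under \eqn{\hat\theta \cdot df' / mean \sim \chi^2_{df'}},
#' with the likelihood normalised for the truncation at the empirical trim
#' bounds (so the fit is consistent despite trimming). Right-tail p-values
#' under the fitted null are returned for all SNPs.
#'
#' @param theta numeric vector of Weir-Cockerham theta-hat values (NAs
#'   allowed; at least 100 finite values required).
#' @param trim_fraction fraction trimmed from each tail (default 0.05).
#' @return an object of class \code{fst_fit}: \code{dfprime}, \code{fst_mean}
#'   (trimmed mean), \code{p_fst} (aligned with \code{theta}),
#'   \code{trim_bounds}, \code{n_core}.
#' @export
fst_outlier_fit <- function(theta, trim_fraction = 0.05) {
  th <- theta[is.finite(theta)]
  if (length(th) < 100)
    stop("need >= 100 finite theta values (got ", length(th), ")")
  if (stats::sd(th) == 0) stop("degenerate input: all theta values identical")
  qs <- stats::quantile(th, c(trim_fraction, 1 - trim_fraction))
  lo <- qs[[1]]; hi <- qs[[2]]
  core <- th[th > lo & th < hi]
  core <- core[core > 0]
  if (length(core) < 50)
    stop("too few positive theta values in the trimmed core")
  lo_pos <- max(lo, 0)
  negll <- function(par) {
    df <- exp(par[1]); mu <- exp(par[2])
    s <- df / mu
    ll <- sum(stats::dchisq(core * s, df, log = TRUE) + log(s))
    norm <- stats::pchisq(hi * s, df) - stats::pchisq(lo_pos * s, df)
    if (!is.finite(ll) || norm <= 0) return(1e10)
    -(ll - length(core) * log(norm))
  }
  fit <- stats::optim(c(log(2), log(mean(core))), negll, method = "Nelder-Mead",
                      control = list(maxit = 2000))
  if (fit$convergence != 0) {
    e <- simpleError(paste0("chi-square null fit did not converge; last df' = ",
                            format(exp(fit$par[1]), digits = 4)))
    e$last_iterate <- list(dfprime = exp(fit$par[1]), mean = exp(fit$par[2]))
    stop(e)
  }
  dfprime <- exp(fit$par[1]); mu <- exp(fit$par[2])
  p <- stats::pchisq(theta * dfprime / mu, dfprime, lower.tail = FALSE)
  structure(list(
    dfprime = dfprime,
    fst_mean = mean(th[th > lo & th < hi]),
    fitted_mean = mu,
    p_fst = p,
    trim_bounds = c(lo, hi),
    n_core = length(core)
  ), class = "fst_fit")
}

#' Write scan results as a tab-separated table
#'
#' Columns SNP, CHR, BP, D2, P_RNS and, when FST results are supplied,
#' THETA and P_FST.
#'
#' @param scan a \code{selection_scan}.
#' @param panel the matching \code{genotype_panel} (for CHR/BP).
#' @param path output path.
#' @param fst optional \code{\link{wc_fst}} result aligned with the panel.
#' @param fst_fit optional \code{\link{fst_outlier_fit}} on \code{fst}.
#' @return \code{path}, invisibly.
#' @export
write_scan <- function(scan, panel, path, fst = NULL, fst_fit = NULL) {
  stopifnot(identical(scan$snp_id, panel$snp_ids))
  out <- data.frame(SNP = scan$snp_id, CHR = panel$chrom, BP = panel$pos,
                    D2 = scan$d2, P_RNS = scan$p_rns)
  if (!is.null(fst)) {
    out$THETA <- fst$theta[match(out$SNP, fst$snp_id)]
    if (!is.null(fst_fit)) out$P_FST <- fst_fit$p_fst
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.fst_fit <- function(x, ...) {
  cat("fst_fit: df' =", format(x$dfprime, digits = 4),
      "| trimmed mean theta =", format(x$fst_mean, digits = 4),
      "| core n =", x$n_core, "\n")
  invisible(x)
}
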