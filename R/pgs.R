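#' Construct a case-control cohort container
#'
#' @param dosage samples x SNPs matrix of alternate-allele dosages (0/1/2,
#'   NA for missing); column names are SNP ids.
#' @param phenotype binary vector (1 = case, 0 = control).
#' @param covariates optional numeric matrix/data.frame of per-sample
#'   covariates (sex, age, ancestry components, ...); no missing values.
#' @param snp_ids optional SNP ids (defaults to \code{colnames(dosage)}).
#' @return an object of class \code{cohort_data}.
#' @export
cohort_data <- function(dosage, phenotype, covariates = NULL,
                        snp_ids = colnames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(snp_ids)) stop("snp_ids required (or name the dosage columns)")
  colnames(dosage) <- snp_ids
  phenotype <- as.integer(phenotype)
  if (!all(phenotype %in% c(0L, 1L)))
    stop("phenotype must be binary 0/1")
  if (length(phenotype) != nrow(dosage))
    stop("phenotype length != number of samples")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (anyNA(covariates)) stop("covariates must be complete (no missing)")
    if (nrow(covariates) != nrow(dosage))
      stop("covariates rows != number of samples")
  }
  structure(list(dosage = dosage, phenotype = phenotype,
                 covariates = covariates),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat("cohort_data:", sum(x$phenotype == 1), "cases /",
      sum(x$phenotype == 0), "controls,", ncol(x$dosage), "SNPs,",
      if (is.null(x$covariates)) 0 else ncol(x$covariates), "covariates\n")
  invisible(x)
}

#' Read a case-control cohort from VCF + phenotype/covariate TSV
#'
#' The TSV needs columns IID and PHENO (1 = case, 0 = control); any
#' further numeric columns (SEX, AGE, PC1..PC10, ...) become covariates.
#' Samples are matched to the VCF by IID.
#'
#' @param vcf_path genotypes VCF.
#' @param tsv_path phenotype/covariate TSV.
#' @return a \code{cohort_data}.
#' @export
read_cohort <- function(vcf_path, tsv_path) {
  panel <- read_genotypes(vcf_path)
  ph <- utils::read.table(tsv_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("IID", "PHENO") %in% names(ph)))
    stop("cohort TSV needs IID and PHENO columns")
  m <- match(panel$sample_ids, ph$IID)
  if (anyNA(m))
    stop("sample(s) in VCF missing from cohort TSV: ",
         paste(utils::head(panel$sample_ids[is.na(m)], 5), collapse = ", "))
  ph <- ph[m, , drop = FALSE]
  covars <- ph[, setdiff(names(ph), c("IID", "PHENO")), drop = FALSE]
  dosage <- panel$dosage
  colnames(dosage) <- panel$snp_ids
  cohort_data(dosage, ph$PHENO,
              covariates = if (ncol(covars)) as.matrix(covars) else NULL)
}

#' Compute a (standardized) polygenic score
#'
#' Score = sum over SNPs of dosage x log(OR). Missing dosages contribute
#' their expectation \code{2 x freq x log(OR)} (mean imputation). The score
#' is standardized to mean 0 / SD 1 across the cohort unless
#' \code{standardize = FALSE}.
#'
#' @param cohort a \code{cohort_data} whose dosages are oriented to the
#'   weights' effect alleles (harmonize upstream).
#' @param weights named numeric vector of log odds ratios per SNP id; only
#'   SNPs present in the cohort are used.
#' @param freq optional named alternate-allele frequencies for imputation;
#'   defaults to the cohort's observed frequencies.
#' @param standardize logical (default TRUE).
#' @param allow_zero_variance return the raw all-equal score instead of
#'   erroring when the score has zero variance (default FALSE).
#' @return numeric per-sample score vector.
#' @export
compute_pgs <- function(cohort, weights, freq = NULL, standardize = TRUE,
                        allow_zero_variance = FALSE) {
  ids <- intersect(names(weights), colnames(cohort$dosage))
  if (!length(ids)) stop("no weight SNPs present in the cohort")
  d <- cohort$dosage[, ids, drop = FALSE]
  if (is.null(freq)) freq <- colMeans(d, na.rm = TRUE) / 2
  else freq <- freq[ids]
  if (anyNA(d)) {
    na_idx <- which(is.na(d), arr.ind = TRUE)
    d[na_idx] <- 2 * freq[na_idx[, 2]]
  }
  raw <- drop(d %*% weights[ids])
  if (!standardize) return(raw)
  s <- stats::sd(raw)
  if (s == 0) {
    if (allow_zero_variance) return(raw)
    stop("cannot standardize a zero-variance score")
  }
  (raw - mean(raw)) / s
}

# Nagelkerke pseudo-R2 of a fitted binomial glm against the intercept-only
# model: [1 - exp((2/n)(ll0 - ll1))] / [1 - exp((2/n) ll0)]
nagelkerke_r2 <- function(ll_model, ll_null, n) {
  (1 - exp((2 / n) * (ll_null - ll_model))) /
    (1 - exp((2 / n) * ll_null))
}

.fit_logistic <- function(y, x) {
  df <- if (is.null(x)) data.frame(y = y)
  else data.frame(y = y, x, check.names = TRUE)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                     family = stats::binomial()))
  fit
}

#' Evaluate a polygenic score on a cohort
#'
#' Fits logistic regressions of case-control status on covariates alone and
#' on covariates plus the score; reports the increment in Nagelkerke
#' pseudo-R2 (each model measured against the intercept-only null), the
#' Wald p-value of the score term and its log-odds coefficient (per SD when
#' the score is standardized).
#'
#' @param score per-sample numeric score.
#' @param cohort a \code{cohort_data}.
#' @param min_n warn below this many cases or controls (default 50).
#' @param baseline optional precomputed \code{\link{pgs_baseline}} for the
#'   cohort, avoiding refits of the covariate-only model in resampling
#'   loops.
#' @return an object of class \code{pgs_evaluation}: \code{pseudo_r2_full},
#'   \code{pseudo_r2_covariates}, \code{pseudo_r2_increment},
#'   \code{p_assoc_pgs}, \code{beta_pgs}, \code{separation}.
#' @export
evaluate_pgs <- function(score, cohort, min_n = 50, baseline = NULL) {
  y <- cohort$phenotype
  if (min(sum(y == 1), sum(y == 0)) < min_n)
    warning("fewer than ", min_n, " cases or controls")
  n <- length(y)
  cov <- cohort$covariates
  if (is.null(baseline)) baseline <- pgs_baseline(cohort)
  xfull <- if (is.null(cov)) cbind(score = score)
  else cbind(cov, score = score)
  fitf <- .fit_logistic(y, xfull)
  separation <- !fitf$converged || any(abs(fitf$coefficients) > 15,
                                       na.rm = TRUE)
  ll0 <- baseline$ll0
  llf <- as.numeric(stats::logLik(fitf))
  r2c <- baseline$r2c
  r2f <- nagelkerke_r2(llf, ll0, n)
  sm <- summary(fitf)$coefficients
  srow <- grep("^score$", rownames(sm))
  structure(list(
    pseudo_r2_full = r2f,
    pseudo_r2_covariates = r2c,
    pseudo_r2_increment = r2f - r2c,
    p_assoc_pgs = if (length(srow)) sm[srow, 4] else NA_real_,
    beta_pgs = if (length(srow)) sm[srow, 1] else NA_real_,
    separation = separation
  ), class = "pgs_evaluation")
}

#' @export
print.pgs_evaluation <- function(x, ...) {
  cat("PGS evaluation: Nagelkerke pseudo-R2 increment =",
      format(x$pseudo_r2_increment, digits = 4),
      "| p =", format(x$p_assoc_pgs, digits = 3), "\n")
  if (x$separation) cat("warning: separation suspected\n")
  invisible(x)
}

#' Baseline (covariate-only) model fit for PGS evaluation
#'
#' Precomputes the intercept-only and covariate-only logistic fits used by
#' \code{\link{evaluate_pgs}}, so resampling analyses can reuse them.
#'
#' @param cohort a \code{cohort_data}.
#' @return list with \code{ll0}, \code{llc}, \code{r2c}.
#' @export
pgs_baseline <- function(cohort) {
  y <- cohort$phenotype
  n <- length(y)
  cov <- cohort$covariates
  fit0 <- .fit_logistic(y, NULL)
  ll0 <- as.numeric(stats::logLik(fit0))
  if (is.null(cov)) return(list(ll0 = ll0, llc = ll0, r2c = 0))
  fitc <- .fit_logistic(y, cov)
  llc <- as.numeric(stats::logLik(fitc))
  list(ll0 = ll0, llc = llc, r2c = nagelkerke_r2(llc, ll0, n))
}

# increment-only helper used by the resampling analyses
.pgs_increment <- function(ids, cohort, weights, baseline = NULL) {
  sc <- compute_pgs(cohort, weights[intersect(ids, names(weights))])
  suppressWarnings(evaluate_pgs(sc, cohort, min_n = 0,
                                baseline = baseline)$pseudo_r2_increment)
}

#' Explained-variance trend across selection quantiles
#'
#' Takes the LD-independent SNPs with GWAS p below \code{p_t}, sorts them by
#' scan p-value ascending, splits them into \code{n_quantiles} contiguous
#' equal-size bins (remainder to the last), computes a per-bin polygenic
#' score and its Nagelkerke pseudo-R2 increment on the cohort, and fits an
#' ordinary least-squares line of increment on bin rank.
#'
#' @param p_assoc,p_rns named numeric vectors over the candidate SNP ids.
#' @param snp_ids SNP ids to use (typically clumped index SNPs present in
#'   the cohort).
#' @param cohort a \code{cohort_data}.
#' @param weights named log-OR weights.
#' @param n_quantiles default 20.
#' @param p_t GWAS p-value cutoff (default 0.2).
#' @return an object of class \code{quantile_trend}: \code{per_quantile}
#'   data.frame (quantile, n_snps, pseudo_r2_increment, p_assoc_pgs),
#'   \code{slope}, \code{t_stat}, \code{p_trend}.
#' @export
quantile_trend <- function(p_assoc, p_rns, snp_ids, cohort, weights,
                           n_quantiles = 20, p_t = 0.2) {
  ids <- snp_ids[!is.na(p_assoc[snp_ids]) & p_assoc[snp_ids] < p_t]
  ids <- ids[!is.na(p_rns[ids])]
  if (length(ids) < n_quantiles)
    stop("fewer SNPs (", length(ids), ") than quantiles")
  ids <- ids[order(p_rns[ids])]
  baseline <- pgs_baseline(cohort)
  size <- floor(length(ids) / n_quantiles)
  bins <- rep(n_quantiles, length(ids))
  bins[seq_len(size * n_quantiles)] <- rep(seq_len(n_quantiles), each = size)
  per_q <- lapply(seq_len(n_quantiles), function(q) {
    bid <- ids[bins == q]
    sc <- compute_pgs(cohort, weights[intersect(bid, names(weights))])
    ev <- suppressWarnings(evaluate_pgs(sc, cohort, min_n = 0,
                                        baseline = baseline))
    data.frame(quantile = q, n_snps = length(bid),
               pseudo_r2_increment = ev$pseudo_r2_increment,
               p_assoc_pgs = ev$p_assoc_pgs)
  })
  per_q <- do.call(rbind, per_q)
  r2 <- per_q$pseudo_r2_increment
  if (stats::sd(r2) == 0) {
    slope <- 0; tstat <- 0; p <- 1
  } else {
    lmfit <- stats::lm(r2 ~ seq_len(n_quantiles))
    cf <- summary(lmfit)$coefficients
    slope <- cf[2, 1]; tstat <- cf[2, 3]; p <- cf[2, 4]
  }
  structure(list(per_quantile = per_q, slope = slope, t_stat = tstat,
                 p_trend = p, n_quantiles = n_quantiles, p_t = p_t),
            class = "quantile_trend")
}

#' @export
print.quantile_trend <- function(x, ...) {
  cat("quantile_trend over", x$n_quantiles, "quantiles (GWAS p <",
      x$p_t, ")\n")
  cat("slope =", format(x$slope, digits = 4),
      "| t =", format(x$t_stat, digits = 4),
      "| p =", format(x$p_trend, digits = 3), "\n")
  invisible(x)
}

#' @export
plot.quantile_trend <- function(x, ...) {
  plot(x$per_quantile$quantile, 100 * x$per_quantile$pseudo_r2_increment,
       xlab = "selection quantile (increasing scan p)",
       ylab = "pseudo-R2 increment (%)", ...)
  graphics::abline(stats::lm(100 * x$per_quantile$pseudo_r2_increment ~
                               x$per_quantile$quantile), col = "grey40")
  invisible(x)
}

#' Matched-SNP empirical null for a target SNP set's predictive power
#'
#' Computes the Nagelkerke pseudo-R2 increment for the target set and for
#' each matched control set; the empirical p-value is
#' \code{(1 + #\{null >= target\}) / (n_sets + 1)}.
#'
#' @param target_ids SNP ids of the target set (e.g. the first selection
#'   quantile).
#' @param matched_sets list of matched SNP-id sets from
#'   \code{\link{draw_matched_sets}}.
#' @param cohort a \code{cohort_data}.
#' @param weights named log-OR weights.
#' @param max_fail_frac abort when more than this fraction of null sets
#'   fails to evaluate (default 0.05).
#' @return list of class \code{matched_null_result}: \code{target_r2},
#'   \code{null_r2}, \code{p_empirical}, \code{n_sets}.
#' @export
matched_null_pgs <- function(target_ids, matched_sets, cohort, weights,
                             max_fail_frac = 0.05) {
  n_sets <- length(matched_sets)
  if (n_sets < 1) stop("need at least one matched set")
  baseline <- pgs_baseline(cohort)
  target_r2 <- .pgs_increment(target_ids, cohort, weights, baseline)
  null_r2 <- vapply(matched_sets, function(ids)
    tryCatch(.pgs_increment(ids, cohort, weights, baseline),
             error = function(e) NA_real_), numeric(1))
  n_fail <- sum(is.na(null_r2))
  if (n_fail > max_fail_frac * n_sets)
    stop(n_fail, " of ", n_sets, " null sets failed to evaluate")
  ok <- null_r2[!is.na(null_r2)]
  p_emp <- (1 + sum(ok >= target_r2)) / (length(ok) + 1)
  structure(list(target_r2 = target_r2, null_r2 = null_r2,
                 p_empirical = p_emp, n_sets = n_sets, n_failed = n_fail),
            class = "matched_null_result")
}

#' @export
print.matched_null_result <- function(x, ...) {
  cat("matched-SNP null: target pseudo-R2 increment =",
      format(x$target_r2, digits = 4), "\n")
  cat("empirical p =", format(x$p_empirical, digits = 3), "over",
      x$n_sets - x$n_failed, "null sets\n")
  invisible(x)
}

#' Direction-stratified polygenic-score resampling
#'
#' Splits SNPs into four strata (marker / non-marker x derived-protective /
#' derived-risk), repeatedly draws random subsets of
#' \code{n_snps_per_draw} SNPs within each stratum (without replacement
#' within a draw, independently across draws), evaluates the pseudo-R2
#' increment per draw, and compares risk vs protective distributions within
#' markers and within non-markers by two-sided Wilcoxon rank-sum tests.
#' Draws share SNPs across replicates, so the Wilcoxon p-values are
#' anti-conservative; the stratum medians are the robust summary.
#'
#' @param polarized a \code{polarized_summary}.
#' @param annotation an \code{rns_annotation}.
#' @param cohort a \code{cohort_data}.
#' @param weights named log-OR weights.
#' @param n_draws draws per stratum (default 1000).
#' @param n_snps_per_draw SNPs per draw (default 1000).
#' @param seed integer seed.
#' @return list of class \code{direction_pgs_result}: \code{r2} (data.frame
#'   draw x stratum), \code{medians}, \code{p_wilcoxon_markers},
#'   \code{p_wilcoxon_nonmarkers}.
#' @export
direction_stratified_pgs <- function(polarized, annotation, cohort, weights,
                                     n_draws = 1000, n_snps_per_draw = 1000,
                                     seed = 1) {
  pol <- polarized[polarized$polarization_status != "unpolarizable" &
                     polarized$derived_or != 1, , drop = FALSE]
  mk_ids <- annotation$snp_id[annotation$is_marker]
  nm_ids <- annotation$snp_id[!annotation$is_marker]
  strata <- list(
    marker_risk = pol$snp_id[pol$snp_id %in% mk_ids & pol$derived_or > 1],
    marker_protective = pol$snp_id[pol$snp_id %in% mk_ids &
                                     pol$derived_or < 1],
    nonmarker_risk = pol$snp_id[pol$snp_id %in% nm_ids & pol$derived_or > 1],
    nonmarker_protective = pol$snp_id[pol$snp_id %in% nm_ids &
                                        pol$derived_or < 1]
  )
  small <- vapply(strata, length, integer(1)) < n_snps_per_draw
  if (any(small))
    stop("stratum too small for draws of ", n_snps_per_draw, ": ",
         paste(names(strata)[small], collapse = ", "))
  set.seed(seed)
  baseline <- pgs_baseline(cohort)
  r2 <- sapply(strata, function(ids)
    vapply(seq_len(n_draws), function(b)
      .pgs_increment(sample(ids, n_snps_per_draw), cohort, weights,
                     baseline),
      numeric(1)))
  r2 <- as.data.frame(r2)
  wt <- function(a, b) stats::wilcox.test(a, b, exact = FALSE)$p.value
  structure(list(
    r2 = r2,
    medians = vapply(r2, stats::median, numeric(1)),
    p_wilcoxon_markers = wt(r2$marker_risk, r2$marker_protective),
    p_wilcoxon_nonmarkers = wt(r2$nonmarker_risk, r2$nonmarker_protective),
    n_draws = n_draws, n_snps_per_draw = n_snps_per_draw
  ), class = "direction_pgs_result")
}

#' @export
print.direction_pgs_result <- function(x, ...) {
  cat("direction-stratified PGS (", x$n_draws, "draws of",
      x$n_snps_per_draw, "SNPs )\n")
  print(round(x$medians, 5))
  cat("Wilcoxon risk vs protective: markers p =",
      format(x$p_wilcoxon_markers, digits = 3),
      "| non-markers p =", format(x$p_wilcoxon_nonmarkers, digits = 3), "\n")
  invisible(x)
}
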