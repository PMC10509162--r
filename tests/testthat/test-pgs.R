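test_that("polygenic score follows its definition and linearity", {
  coh <- make_test_cohort(n = 50)
  w <- c(s1 = log(1.5))
  raw <- compute_pgs(coh, w, standardize = FALSE)
  expect_equal(raw, coh$dosage[, "s1"] * log(1.5))
  expect_equal(raw[coh$dosage[, "s1"] == 2][1], 2 * log(1.5))

  # flipping weights negates raw scores
  w2 <- stats::setNames(rnorm(5), paste0("s", 1:5))
  expect_equal(compute_pgs(coh, -w2, standardize = FALSE),
               -compute_pgs(coh, w2, standardize = FALSE))

  # order invariance and additivity over disjoint sets
  wa <- w2[1:2]; wb <- w2[3:5]
  expect_equal(compute_pgs(coh, w2[sample(names(w2))], standardize = FALSE),
               compute_pgs(coh, w2, standardize = FALSE))
  expect_equal(compute_pgs(coh, wa, standardize = FALSE) +
                 compute_pgs(coh, wb, standardize = FALSE),
               compute_pgs(coh, w2, standardize = FALSE))

  # zero weights cannot be standardized
  expect_error(compute_pgs(coh, c(s1 = 0, s2 = 0)), "zero-variance")
  expect_equal(compute_pgs(coh, c(s1 = 0), allow_zero_variance = TRUE),
               rep(0, 50))

  # standardization
  s <- compute_pgs(coh, w2)
  expect_equal(mean(s), 0, tolerance = 1e-12)
  expect_equal(stats::sd(s), 1, tolerance = 1e-12)

  # missing dosages are mean-imputed with 2 * freq * weight
  coh2 <- coh
  coh2$dosage[1, "s1"] <- NA
  f <- mean(coh2$dosage[-1, "s1"]) / 2
  raw2 <- compute_pgs(coh2, w, freq = c(s1 = f), standardize = FALSE)
  expect_equal(raw2[1], 2 * f * log(1.5))
})

test_that("Nagelkerke pseudo-R2 matches direct likelihood optimization", {
  set.seed(20)
  for (i in 1:12) {
    n <- sample(15:30, 1)
    x <- rnorm(n)
    y <- rbinom(n, 1, stats::plogis(0.5 * x))
    if (length(unique(y)) < 2) next
    coh <- cohort_data(matrix(rbinom(n, 2, 0.5), ncol = 1,
                              dimnames = list(NULL, "s1")), y)
    ev <- suppressWarnings(evaluate_pgs(x, coh, min_n = 0))
    expect_equal(ev$pseudo_r2_full, nagelkerke_direct(y, x),
                 tolerance = 1e-6)
  }
})

test_that("pseudo-R2 increment is 0 for an uninformative score and ~1 at separation", {
  set.seed(22)
  coh <- make_test_cohort(n = 200, with_covariates = FALSE)
  y <- coh$phenotype
  # identical likelihoods: score orthogonal in the model (all-equal score
  # dropped by glm) -> increment 0
  ev0 <- suppressWarnings(
    evaluate_pgs(rep(0, 200), coh, min_n = 0))
  expect_equal(ev0$pseudo_r2_increment, 0, tolerance = 1e-8)

  # perfectly separating score
  ev1 <- suppressWarnings(evaluate_pgs(ifelse(y == 1, 10, -10), coh,
                                       min_n = 0))
  expect_gt(ev1$pseudo_r2_full, 0.95)
  expect_true(ev1$separation)
})

test_that("null scores give calibrated evaluation p-values", {
  set.seed(33)
  pvals <- replicate(200, {
    coh <- make_test_cohort(n = 400, seed = sample.int(1e6, 1),
                            with_covariates = FALSE)
    suppressWarnings(evaluate_pgs(rnorm(400), coh, min_n = 0))$p_assoc_pgs
  })
  rej <- mean(pvals < 0.05)
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("quantile bins partition the SNP set with remainder in the last", {
  set.seed(25)
  coh <- make_test_cohort(n = 200, n_snps = 205)
  ids <- colnames(coh$dosage)
  p_assoc <- stats::setNames(runif(205, 0, 0.19), ids)
  p_rns <- stats::setNames(runif(205), ids)
  w <- stats::setNames(rnorm(205, 0, 0.05), ids)
  qt <- quantile_trend(p_assoc, p_rns, ids, coh, w, n_quantiles = 20,
                       p_t = 0.2)
  expect_equal(nrow(qt$per_quantile), 20)
  expect_equal(qt$per_quantile$n_snps,
               c(rep(10, 19), 15))  # 205 = 19 x 10 + 15
  expect_equal(sum(qt$per_quantile$n_snps), 205)
  expect_error(quantile_trend(p_assoc, p_rns, ids[1:5], coh, w,
                              n_quantiles = 20), "fewer SNPs")
})

test_that("matched-null empirical p behaves at the extremes", {
  set.seed(26)
  coh <- make_test_cohort(n = 300, n_snps = 40, beta = 1.2)
  ids <- colnames(coh$dosage)
  w <- stats::setNames(c(1, rnorm(39, 0, 0.01)), ids)  # s1 dominates
  target <- "s1"
  null_sets <- replicate(20, sample(ids[-1], 1), simplify = FALSE)
  r <- matched_null_pgs(target, null_sets, coh, w)
  expect_equal(r$p_empirical, 1 / 21)
  expect_equal(r$n_sets, 20)
  expect_error(matched_null_pgs(target, list(), coh, w), "at least one")
})

test_that("direction-stratified draws are deterministic and sized", {
  set.seed(27)
  n_snps <- 120
  coh <- make_test_cohort(n = 200, n_snps = n_snps)
  ids <- colnames(coh$dosage)
  ann <- data.frame(snp_id = ids,
                    p_rns = runif(n_snps),
                    is_marker = rep(c(TRUE, FALSE), each = 60))
  class(ann) <- c("rns_annotation", "data.frame")
  pol <- data.frame(snp_id = ids,
                    derived_or = exp(rnorm(n_snps, 0, 0.2)),
                    polarization_status = "effect_is_derived",
                    low_confidence = FALSE)
  w <- stats::setNames(rnorm(n_snps, 0, 0.05), ids)
  r1 <- direction_stratified_pgs(pol, ann, coh, w, n_draws = 20,
                                 n_snps_per_draw = 10, seed = 9)
  r2 <- direction_stratified_pgs(pol, ann, coh, w, n_draws = 20,
                                 n_snps_per_draw = 10, seed = 9)
  expect_identical(r1$r2, r2$r2)
  expect_equal(nrow(r1$r2), 20)
  expect_error(
    direction_stratified_pgs(pol, ann, coh, w, n_draws = 5,
                             n_snps_per_draw = 1000, seed = 1),
    "stratum too small")
})

test_that("exchangeable strata give similar resampled medians", {
  set.seed(28)
  n_snps <- 160
  coh <- make_test_cohort(n = 300, n_snps = n_snps)
  ids <- colnames(coh$dosage)
  ann <- data.frame(snp_id = ids, p_rns = runif(n_snps),
                    is_marker = rep(c(TRUE, FALSE), each = 80))
  class(ann) <- c("rns_annotation", "data.frame")
  pol <- data.frame(snp_id = ids,
                    derived_or = exp(rnorm(n_snps, 0, 0.2)),
                    polarization_status = "effect_is_derived",
                    low_confidence = FALSE)
  w <- stats::setNames(rnorm(n_snps, 0, 0.03), ids)
  r <- direction_stratified_pgs(pol, ann, coh, w, n_draws = 100,
                                n_snps_per_draw = 30, seed = 2)
  # no planted difference: medians agree within a small tolerance
  expect_lt(abs(r$medians["marker_risk"] -
                  r$medians["marker_protective"]), 0.02)
})

test_that("cohort VCF + TSV round-trips into cohort_data", {
  set.seed(55)
  n <- 20; p <- 8
  f <- runif(p, 0.2, 0.8)
  dosage <- sapply(f, function(pr) rbinom(n, 2, pr))
  panel <- genotype_panel(dosage, paste0("c", 1:p), rep("1", p),
                          (1:p) * 1000L, rep("A", p), rep("G", p),
                          sample_ids = sprintf("I%04d", 1:n))
  coh <- cohort_data(`colnames<-`(dosage, paste0("c", 1:p)),
                     rep(c(1, 0), each = 10),
                     covariates = cbind(SEX = rbinom(n, 1, 0.5),
                                        AGE = rnorm(n, 40, 5)))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_panel_vcf(panel, vcf)
  write_cohort_tsv(coh, tsv)
  back <- read_cohort(vcf, tsv)
  expect_equal(unname(back$dosage), unname(coh$dosage))
  expect_equal(back$phenotype, coh$phenotype)
  expect_equal(colnames(back$covariates), c("SEX", "AGE"))
})
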