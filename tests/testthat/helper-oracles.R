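# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and stats::fisher.test) so that implementation
# and oracle stay separate routes.

# Exact conditional 2x2 test by full enumeration of tables with fixed
# margins, using hypergeometric point probabilities.
fisher_enum <- function(a, b, c, d,
                        alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  switch(alternative,
    two_sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
    greater = sum(probs[support >= a]),
    less = sum(probs[support <= a]))
}

# Naive greedy clump on a tiny instance: straight transcription of the
# rule, quadratic, pairwise-complete correlations.
clump_brute <- function(snps, dosage, r2_max, window_kb) {
  n <- nrow(snps)
  ord <- order(snps$p, snps$chrom, snps$pos)
  state <- rep("free", n)
  absorbed_by <- rep(NA_character_, n)
  for (i in ord) {
    if (state[i] != "free") next
    state[i] <- "index"
    for (j in seq_len(n)) {
      if (state[j] != "free") next
      if (snps$chrom[j] != snps$chrom[i]) next
      if (abs(snps$pos[j] - snps$pos[i]) > window_kb * 1000) next
      ok <- stats::complete.cases(dosage[, i], dosage[, j])
      if (sum(ok) < 2) next
      if (stats::sd(dosage[ok, i]) == 0 || stats::sd(dosage[ok, j]) == 0)
        next
      r2 <- stats::cor(dosage[ok, i], dosage[ok, j])^2
      if (r2 >= r2_max) {
        state[j] <- "absorbed"
        absorbed_by[j] <- snps$snp_id[i]
      }
    }
  }
  list(index = snps$snp_id[state == "index"], absorbed_by = absorbed_by)
}

# Nagelkerke pseudo-R2 by direct likelihood maximisation with optim
# (no glm): model y ~ intercept + columns of x.
nagelkerke_direct <- function(y, x) {
  negll <- function(beta, mm) {
    eta <- drop(mm %*% beta)
    -sum(y * eta - log1p(exp(eta)))
  }
  fit_ll <- function(mm) {
    o <- stats::optim(rep(0, ncol(mm)), negll, mm = mm, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
    -o$value
  }
  n <- length(y)
  ll0 <- fit_ll(matrix(1, n, 1))
  ll1 <- fit_ll(cbind(1, x))
  (1 - exp((2 / n) * (ll0 - ll1))) / (1 - exp((2 / n) * ll0))
}

# Weir-Cockerham theta for two populations from summary quantities
# (sample sizes, allele frequencies, observed het proportions).
wc_theta_direct <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}
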