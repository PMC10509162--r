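# rnscan

Genome scans for recent natural selection (RNS) and their overlap with
GWAS predisposing variation.

Complex disorders that reduce fitness — schizophrenia is the motivating
case — pose an evolutionary puzzle: common predisposing alleles persist in
every human population despite an expected purge by negative selection.
One way to interrogate this is to ask whether the variants that changed
frequency fastest since human populations dispersed out of Africa (markers
of *recent natural selection*) are enriched among disease-associated loci,
and whether the *derived* alleles at those loci (the alleles that arose
during human evolution) tend to protect against or predispose to the
disorder. `rnscan` implements that analysis cascade as a tested, reusable
R package, together with a synthetic-data generator that makes every step
verifiable against known ground truth.

## What the package computes

**Selection scan.** For a multi-population genotype panel, each SNP's
standardized dosage vector is regressed on the leading K principal
components of an LD-thinned genotype matrix (thin window 200 SNPs,
r² < 0.1; K = 3 by default, with an elbow rule available), giving a
z-score vector z ∈ R^K per SNP. A robust center μ and scatter Σ (Minimum
Covariance Determinant, support fraction 0.75) define the outlier
statistic

  D² = (z − μ)ᵀ Σ⁻¹ (z − μ),   λ = median(D²) / median(χ²_K),
  p_RNS = P(χ²_K ≥ D²/λ).

A Weir–Cockerham F_ST scan (the 1984 variance-components estimator
θ̂ = a/(a+b+c) for two populations) with a trimmed, truncation-aware
chi-square null fit cross-validates the outlier set.

**Enrichment cascade.** RNS markers are the top 5% of LD-independent SNPs
(greedy PLINK-style clumping, r² 0.1 / 500 kb, ranked either by GWAS or
by scan p-values — both flows are first class) with the smallest p_RNS.
The package tests marker enrichment across GWAS significance thresholds
(Fisher's exact test with exact CIs), p-value uniformity (one-sample
Kolmogorov–Smirnov), and the MAF-controlled partial Spearman correlation
between −log₁₀ p_GWAS and −log₁₀ p_RNS with a 10,000-permutation null.

**Derived-allele direction bias.** Association odds ratios are re-oriented
to the derived allele using the panel's ancestral-allele (AA) annotation;
per threshold and per group (marker / non-marker) the package reports
protective/risk counts, mean log₁₀ derived-OR with its 95% CI, one- and
two-sample t-tests and a chi-square proportion test.

**Selection-stratified polygenic scores.** Standardized PGS (Σ dosage ×
logOR) are evaluated on a case–control cohort by the increment in
Nagelkerke pseudo-R² over a covariate-only logistic model; the cascade
includes the 20-quantile p_RNS trend with an OLS slope test, empirical
nulls from 1000 matched SNP sets (matching on MAF, LD buddies, gene
distance, gene density), and risk-vs-protective resampling comparisons
(1000 draws of 1000 SNPs, Wilcoxon rank-sum).

**Synthetic data.** Balding–Nichols populations (freq ~ Beta(p₀(1−F)/F,
(1−p₀)(1−F)/F)) with planted high-differentiation loci, optional LD
blocks, a discovery GWAS with planted effects partially overlapping the
selected loci and a configurable derived-protective bias, and a
liability-threshold case–control cohort.

## Worked example

```r
library(rnscan)

cfg   <- sim_scenario("planted", seed = 301)      # 20,000 SNPs, 4 pops x 100
sim   <- simulate_populations(cfg)
gwas  <- simulate_gwas_summary(sim$panel, sim$truth, seed = 301)
harm  <- harmonize(sim$panel, gwas, maf_min = 0.05)

model <- fit_pca(harm$panel, k = 3)
scan  <- scan_pvalues(harm$panel, model, seed = 301)
print(scan)
#> selection_scan: 19108 SNPs, K = 3
#> lambda_gc = 1.077 | SNPs with p_rns < 0.05: 1171

tab     <- harm$table
p_rns   <- setNames(scan$p_rns, scan$snp_id)[tab$snp_id]
p_assoc <- setNames(tab$p_assoc, tab$snp_id)
clumped <- ld_clump(data.frame(snp_id = tab$snp_id, chrom = tab$chrom,
                               pos = tab$pos, p = unname(p_assoc)),
                    harm$panel)
ann <- define_rns_markers(clumped, p_rns)        # top 5% of index SNPs
enr <- threshold_enrichment(ann, p_assoc, thresholds = 5e-8)
enr[, c("threshold", "a", "b", "c", "d", "or", "p")]
#>   threshold  a   b  c    d       or            p
#> 1     5e-08 36 147 92 3400 9.050577 7.452403e-19
```

The enrichment odds ratio of 9.1 at the genome-wide-significant
threshold says marker SNPs are ~9 times more likely than other
LD-independent SNPs to be genome-wide-significant — the planted overlap
between selected and causal loci, recovered: 36 of the 183 markers sit
below p = 5e-8 versus 92 of the 3,492 remaining index SNPs. `polarize_to_derived()` + `direction_bias_tests()`
then show the planted protective bias (negative mean log₁₀ derived-OR in
the marker group), and `quantile_trend()` the declining explained variance
across p_RNS quantiles on a simulated cohort.

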