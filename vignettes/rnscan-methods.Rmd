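---
title: "Methods: selection scans, enrichment cascades and stratified polygenic scores in rnscan"
author: "rnscan maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection scans, enrichment cascades and stratified polygenic scores in rnscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rnscan` links signatures of recent natural selection (RNS) — extreme
allele-frequency differentiation between human populations — to disease
predisposing variation from GWAS summary statistics. This vignette is the
package's own account of the models and the numerical and design choices
behind each stage. Nothing here reports an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The PCA outlier scan

The scan asks, SNP by SNP, whether a variant's allele-frequency pattern
across individuals is more strongly aligned with population structure
than drift alone would produce.

Dosages (counts of the alternate allele) are mean-imputed per SNP,
centered by $2\hat p$ and scaled by $\sqrt{2\hat p(1-\hat p)}$, the usual
binomial standardisation. Population structure is estimated by PCA on an
LD-thinned matrix: SNPs are visited in genomic order and kept unless
their squared correlation with an already-kept SNP among the previous
`thin_window_snps` (default 200) reaches `thin_r2` (default 0.1). The
sliding-window greedy rule mirrors common practice and keeps the pass
single-scan; both parameters are config keys.

Each SNP's standardized dosage vector is regressed on the $K$ leading
left singular vectors, giving a z-score vector per SNP
(coefficient/standard error; the axes are orthonormal, so the regression
is a projection). The outlier statistic is the squared Mahalanobis
distance of the z rows,
$$D^2 = (z-\mu)^\top \Sigma^{-1} (z-\mu),$$
with $\mu, \Sigma$ estimated robustly by Minimum Covariance Determinant
(MCD). Tail p-values come from a genomic-control-corrected chi-square:
$\lambda = \mathrm{median}(D^2)/\mathrm{median}(\chi^2_K)$ and
$p_{\mathrm{RNS}} = P(\chi^2_K \ge D^2/\lambda)$.

Choices worth stating:

* **Full-matrix MCD, support fraction 0.75, seeded.** The Mahalanobis
  test needs a scatter estimate that ignores the selected outliers; MCD
  with 75% support tolerates far more contamination than this use case
  ever sees. The subsampling is made deterministic by an explicit seed,
  and the number of starting subsets is capped (500) — with tens of
  thousands of clean rows, extra subsets change the estimate by far less
  than Monte-Carlo noise in any downstream statistic. For $K=1$ the
  median/MAD² pair replaces MCD.
* **$K = 3$ is the pipeline default;** `k = "auto"` implements an elbow
  (Cattell-style) rule: the first adjacent pair of components whose
  explained-variance drop, relative to the leading component, falls below
  `elbow_tol = 0.05` marks the start of the noise floor, and everything
  before that pair is kept (capped at `k_max = 10`). For two populations
  this yields $K=1$; for four, $K=3$.
* **Degenerate inputs.** Monomorphic and constant SNPs get $z = 0$ and
  $p_{\mathrm{RNS}} = 1$ rather than missing, so downstream joins keep
  them; an all-degenerate panel is an error. A singular scatter falls
  back to its diagonal with a warning.
* **λ correction divides $D^2$ before the tail**, the genomic-control
  convention; under neutral simulations the re-computed inflation of the
  corrected statistics is 1 within ±0.1 (tested).

## 2. The Weir–Cockerham cross-check

PCA-based scans can produce false positives when the component space is
discontinuous, so a per-SNP Weir–Cockerham (1984) $\hat\theta$ between two
chosen populations cross-validates the outlier set. The null for
$\hat\theta$ is fit in the style of OutFLANK: after discarding the lowest
and highest 5% of values, `dfprime` and the mean are estimated by maximum
likelihood under $\hat\theta \cdot df'/\mu \sim \chi^2_{df'}$. The
likelihood is **normalized for the truncation at the empirical trim
bounds** — without that correction the trimming biases $df'$ upward, and
the parameter-recovery test (true $df = 5$ recovered within $[4, 6]$ at
$n = 10^4$) fails. Fitting uses Nelder–Mead on log-parameters;
non-convergence is an error carrying the last iterate. SNPs monomorphic
in both populations get a missing $\hat\theta$.

The concordance property tested at scenario scale — at least 70% of the
top-100 $\hat\theta$ SNPs inside the top-5% $p_{\mathrm{RNS}}$ tail —
mirrors the level of agreement such dual scans show on real panels.

## 3. LD clumping, genomic covariates, matched draws

Clumping is the greedy PLINK rule: repeatedly promote the unabsorbed SNP
with the smallest ranking p-value (ties broken by genomic order, for
determinism) and absorb unabsorbed SNPs within ±500 kb whose dosage
$r^2 \ge 0.1$. $r^2$ is the squared Pearson correlation of dosage
vectors (composite LD — no phasing needed); with missing genotypes the
correlation uses pairwise-complete observations, and with complete data a
compiled kernel computes the same quantity from unit-normed centered
columns. Both ranking flows (by GWAS p and by scan p) are first class,
and `ranking_p` records which was used. The greedy result is tested for
exact equality against a naive brute-force transcription of the rule on
hundreds of random small instances.

Matching covariates per SNP: folded MAF; LD buddies ($r^2 \ge 0.5$
within ±500 kb); distance to the nearest gene interval (0 inside,
infinite when no genes are supplied); gene density (intervals overlapping
±100 kb). Matched null sets draw, per target SNP, uniformly among pool
SNPs within MAF ±0.05 (absolute) and ±50% (relative) on the other three
covariates, with an absolute slack of +1 so that zero counts accept only
near-zero counts; draws are without replacement within a set, independent
across sets, and deterministic given the seed. Scarcer targets are filled
first to minimise within-set collisions; an empty candidate list is an
error naming the SNP, so callers can widen tolerances deliberately rather
than silently.

## 4. The enrichment cascade

RNS markers are the $\lfloor qN \rfloor$ LD-independent SNPs with the
smallest $p_{\mathrm{RNS}}$ ($q = 0.05$ by default; boundary ties broken
by genomic order). Enrichment across GWAS thresholds uses Fisher's exact
test on the marker × below-threshold table; the sample odds ratio
$ad/bc$ is reported with both the exact (noncentral hypergeometric) CI
and a Wald CI for comparability, since published headline intervals are
often Wald-like. Empty marker cells yield OR 0 and an `underpowered`
flag, not an error.

The partial Spearman correlation rank-transforms both $-\log_{10} p$
vectors and the MAF covariate, residualises the first two on the third,
and correlates the residuals. The permutation null permutes the GWAS
ranks against the fixed (scan, MAF) pairs; the one-sided (greater)
p-value uses the add-one convention $(1+r)/(B+1)$, with an `add_one`
flag exposing the plain $r/B$ convention some reports use. The MAF used
is the harmonized-panel MAF — a global-panel choice, documented because a
per-population MAF would be equally defensible.

## 5. Derived-allele polarization and direction bias

The ancestral allele (the state of the human–primate common ancestor)
comes from the VCF `AA` tag; lowercase calls — the 1000 Genomes
convention for low-confidence assignments — are accepted and flagged,
included by default, with a switch to drop them for sensitivity
analyses. If the ancestral allele equals the non-effect allele the
effect allele is derived and the OR is kept; if it equals the effect
allele the OR is inverted; anything else (missing, third allele) is
unpolarizable and reported as such. The transformation is exactly
involutive under allele-label swap, which the suite tests.

Direction-bias tests run per GWAS threshold and group (marker /
non-marker) on $\log_{10}$ derived-OR — the Results-style scale; the
Methods-style raw-OR average is recoverable but the log scale makes
protective/risk symmetric around 0. ORs exactly 1 are counted separately
(the protective/risk dichotomy leaves them undefined). The two-sample
test is Welch's, because group sizes differ by construction (~19:1). The
proportion test is chi-square without continuity correction, with a
Fisher fallback when any expected count drops below 5.

## 6. Polygenic scores

Scores are $\sum_j d_{ij}\,\log \mathrm{OR}_j$ with mean imputation
$2 f_j \log \mathrm{OR}_j$ for missing dosages, standardized across the
cohort. Explained variance is the increment in Nagelkerke pseudo-R²,
$$R^2 = \frac{1-\exp\{\tfrac2n(\ell_0-\ell_1)\}}{1-\exp\{\tfrac2n \ell_0\}},$$
between covariate-only and covariate-plus-score logistic models (each
measured against the intercept-only null). The increment is against the
covariate-only model, not the null — matching the "with and without the
score" definition. Separation is flagged (not fatal) by non-convergence
or absurd coefficients. The implementation is tested against direct
likelihood maximisation by `optim` to $10^{-6}$ on small data.

The quantile trend sorts clumped SNPs with GWAS $p < 0.2$ by
$p_{\mathrm{RNS}}$, splits them into 20 contiguous equal bins (remainder
to the last), evaluates each bin's score, and fits OLS of the pseudo-R²
increment on bin rank. Matched-SNP nulls give
$(1+\#\{R^2_{\mathrm{null}} \ge R^2_{\mathrm{target}}\})/(B+1)$.
Direction-stratified resampling draws 1000 subsets of 1000 SNPs per
stratum and compares risk vs protective by Wilcoxon rank-sum
(normal approximation with tie correction). **Caveat, by design:** the
resampled draws share SNPs, so they are dependent and the Wilcoxon
p-values are anti-conservative; the procedure is implemented as
described, the medians are reported alongside, and the calibration test
asserts only median agreement under exchangeable strata — not p-value
uniformity.

Discovery/target separation matters: weights should come from a GWAS
independent of the evaluation cohort. The generator can produce an
independent discovery GWAS for exactly this reason.

## 7. The synthetic-data generator

The generator is first-class, tested code; it produces every input the
pipeline reads (VCF with `AA`, GWAS TSV, phenotype/covariate TSV, gene
BED) with known ground truth.

* **Populations.** Ancestral frequencies $p_0 \sim U(0.05, 0.95)$;
  population frequencies follow the Balding–Nichols model
  $\mathrm{Beta}(p_0(1-F)/F,\,(1-p_0)(1-F)/F)$ with per-population drift
  $F$ (default 0.1, a continental-scale value). The variance identity
  $\mathrm{Var}(f) = F p_0(1-p_0)$ is verified to ±10% at $10^4$ SNPs.
  Genotypes are $\mathrm{Binomial}(2, f)$.
* **LD.** Blocks of `ld_block_snps` adjacent SNPs (default 5) copy a
  shared latent genotype, each genotype independently redrawn with
  probability `ld_copy_error` (default 0.15), giving within-block
  $r^2 \approx 0.7$ — enough to exercise thinning, clumping and the
  buddy counts. Across blocks SNPs are independent; the cohort draws
  (single population) carry no LD, a simplification that leaves the
  clump-then-score flow conservative rather than optimistic.
* **Planted selection.** Selected loci shift the last population's
  frequency by `delta_sel` *away from the consensus of the other
  populations* (directional selection amplifying existing
  differentiation), clipped to $[0.01, 0.99]$. The planted scenario uses
  `delta_sel = 0.5`, placing planted loci beyond the drift tail —
  "strong" differentiation in the sense the scan targets; a random shift
  direction at smaller magnitudes leaves many planted loci
  indistinguishable from drift, which is a property of the model worth
  knowing, not a bug of the scan.
* **Association effects.** Causal loci get derived-allele log-odds
  $\pm|N(0, \texttt{beta\_sd})|$; the planted scenario uses
  `beta_sd = 0.15` (odds ratios ~1.1–1.3, the scale of
  genome-wide-significant hits). At selected-causal loci the derived
  allele is protective (negative) with probability `pi_prot`; elsewhere
  the sign is fair. Summary statistics are
  $\hat\beta \sim N(\beta, 1/(2f(1-f)n_{\mathrm{eff}}))$ with
  $n_{\mathrm{eff}} = 10^5$ by default.
* **Cohort.** Liability = genetic score (variance scaled to
  `h2_liability`) + Gaussian noise; case iff liability exceeds
  $\Phi^{-1}(1-\mathrm{prevalence})$. Rejection sampling operates on the
  causal genotypes only — non-causal genotypes are independent of the
  phenotype and are filled in afterwards, which is exact and keeps the
  cost linear. Default cohort size is 1927 cases / 1561 controls, the
  scale of the real target cohorts this emulates. Ancestry covariates
  are leading PCs of a 4,000-SNP subset (sufficient for covariate
  adjustment in a single-population cohort); sex and age are unlinked to
  the phenotype by default.

**Scenarios.** `sim_scenario("null")` (no selection/association overlap,
no direction bias) drives the calibration tests: scan tail mass,
enrichment, permutation and PGS p-values all reject at the nominal 5%
within ±2 points. `sim_scenario("planted")` (100 selected loci,
`overlap_frac = 0.5`, `pi_prot = 0.8`, 20,000 SNPs, 4 populations × 100)
drives the recovery tests: enrichment OR > 1 at the genome-wide
threshold, negative marker-group mean log₁₀ derived-OR with CI below 0
at $p < 10^{-4}$, negative quantile trend, and ≥70% top-100 $F_{ST}$ /
top-5% $p_{\mathrm{RNS}}$ concordance, each in ≥80% of 25 replicates.

**What passing these tests does and does not show.** The generator
reproduces the *structure* the pipeline exploits — drift-driven
population differentiation, planted frequency shifts, effect/selection
overlap, direction bias, liability-threshold ascertainment — but not
realistic demography, recombination maps, haplotype-scale LD, imputation
noise beyond an INFO column, or cross-ancestry weight portability. Green
tests certify the machinery and its calibration, not any empirical claim
about real cohorts.

## 8. Problem sizes in the test suite

The suites run at sizes chosen for the package's own regression testing:
the calibration suite uses a 5,000-SNP neutral genome with 200 samples
and 200-replicate loops for the scalar tests (400-sample cohorts for the
PGS calibration, where the Wald test is closest to nominal); the
recovery suite runs 25 replicates of the full planted scenario with a
600 + 600 cohort; oracle equivalences use 1,000 random 2×2 tables, 500
random clump instances and 30 small likelihood problems. These sizes
make the Monte-Carlo bands in the assertions meaningful without making
the suite a burden to run routinely.

## 9. Known limitations

* The scan models outliers in PC-regression z-space; selection signals
  that do not differentiate populations (e.g. soft sweeps within a
  population) are invisible to it, as are loci whose shift direction
  happens to track drift.
* Fisher's exact test is conservative at small margins; the enrichment
  calibration sits slightly below nominal by construction.
* The direction-stratified Wilcoxon comparisons are anti-conservative
  (overlapping resamples); treat the medians as the primary summary.
* The matched-set tolerances are documented approximations of common
  matching defaults; real analyses should treat them as config, not
  truth.
* VCF parsing is biallelic-SNP-only by design; indels and multiallelics
  are dropped at read time.
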