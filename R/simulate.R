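#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator: a Balding-Nichols
#' multi-population genotype panel with planted high-differentiation loci,
#' a discovery GWAS with planted associations partially overlapping the
#' selected loci and a configurable derived-protective bias, and a
#' liability-threshold case-control target cohort.
#'
#' @param n_pops number of populations (default 4, mirroring the
#'   African / European / South-Asian / East-Asian panel structure).
#' @param n_per_pop samples per population (default 100).
#' @param n_snps number of SNPs (default 20000).
#' @param fst_drift per-population drift parameter F in (0,1); recycled to
#'   \code{n_pops} (default 0.1, a typical continental-scale value).
#' @param p0_min,p0_max range of the ancestral-frequency sampler
#'   Uniform(p0_min, p0_max) (default 0.05-0.95).
#' @param n_selected planted high-differentiation loci (default 100).
#' @param delta_sel frequency shift applied to selected loci in the last
#'   population, clipped to [0.01, 0.99] (default 0.35, strong enough to
#'   stand out of F = 0.1 drift noise).
#' @param n_causal loci with nonzero association effect (default 200).
#' @param overlap_frac fraction of causal loci drawn from the selected set
#'   (default 0.5 in the planted scenario; 0 under the null).
#' @param beta_sd effect-size scale on the liability log-odds (default
#'   0.08).
#' @param pi_prot probability that the derived allele at a selected-causal
#'   locus is protective (default 0.5 = no direction bias).
#' @param h2_liability genetic fraction of liability variance (default
#'   0.3).
#' @param prevalence population case prevalence (default 0.01).
#' @param ld_block_snps adjacent SNPs forming an LD block: members copy a
#'   shared latent genotype (1 disables; default 5).
#' @param ld_copy_error per-genotype probability that a block member is
#'   redrawn independently instead of copying the block's latent genotype
#'   (default 0.15, giving within-block r-squared around 0.7).
#' @param aa_missing_frac fraction of SNPs with no ancestral-allele call
#'   (default 0.02, matching the ~98\% AA availability of real panels).
#' @param aa_lowercase_frac fraction of called ancestral alleles recorded
#'   lowercase / low-confidence (default 0.05).
#' @param n_cases,n_controls target-cohort defaults (1927 / 1561, the
#'   scale of the case-control cohort the pipeline emulates).
#' @param seed integer seed.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_pops = 4, n_per_pop = 100, n_snps = 20000,
                       fst_drift = 0.1, p0_min = 0.05, p0_max = 0.95,
                       n_selected = 100, delta_sel = 0.35, n_causal = 200,
                       overlap_frac = 0.5, beta_sd = 0.08, pi_prot = 0.5,
                       h2_liability = 0.3, prevalence = 0.01,
                       ld_block_snps = 5, ld_copy_error = 0.15,
                       aa_missing_frac = 0.02,
                       aa_lowercase_frac = 0.05, n_cases = 1927,
                       n_controls = 1561, seed = 1) {
  stopifnot(overlap_frac >= 0, overlap_frac <= 1,
            pi_prot >= 0, pi_prot <= 1,
            h2_liability > 0, h2_liability < 1,
            all(fst_drift > 0), all(fst_drift < 1))
  cfg <- list(n_pops = n_pops, n_per_pop = n_per_pop, n_snps = n_snps,
              fst_drift = rep_len(fst_drift, n_pops), p0_min = p0_min,
              p0_max = p0_max, n_selected = n_selected,
              delta_sel = delta_sel, n_causal = n_causal,
              overlap_frac = overlap_frac, beta_sd = beta_sd,
              pi_prot = pi_prot, h2_liability = h2_liability,
              prevalence = prevalence, ld_block_snps = ld_block_snps,
              ld_copy_error = ld_copy_error,
              aa_missing_frac = aa_missing_frac,
              aa_lowercase_frac = aa_lowercase_frac,
              n_cases = n_cases, n_controls = n_controls, seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Scenario presets for the generator
#'
#' \code{"null"}: no selection/association overlap and no direction bias
#' (calibration scenario). \code{"planted"}: 100 selected loci, half of the
#' causal loci selected, 80\% derived-protective bias at selected-causal
#' loci (recovery scenario).
#'
#' @param name \code{"null"} or \code{"planted"}.
#' @param ... overrides passed to \code{\link{sim_config}}.
#' @return a \code{sim_config}.
#' @export
sim_scenario <- function(name = c("null", "planted"), ...) {
  name <- match.arg(name)
  over <- list(...)
  base <- switch(name,
    null = list(overlap_frac = 0, pi_prot = 0.5),
    planted = list(n_selected = 100, overlap_frac = 0.5, pi_prot = 0.8,
                   delta_sel = 0.5, beta_sd = 0.15))
  do.call(sim_config, utils::modifyList(base, over))
}

#' Simulate a structured multi-population genotype panel
#'
#' Draws ancestral frequencies p0 ~ Uniform(p0_min, p0_max) per SNP, then
#' population frequencies from the Balding-Nichols model
#' Beta(p0 (1-F)/F, (1-p0)(1-F)/F). Planted selected loci get an extra
#' frequency shift of +/- delta_sel in the last population (clipped to
#' [0.01, 0.99]). Genotypes are Binomial(2, p_pop). Optional LD is induced
#' by letting adjacent SNPs in a block copy a shared latent genotype with a
#' per-genotype copy-error rate. Ancestral alleles are recorded (REF when the
#' alternate allele is the derived one), with configurable missing and
#' low-confidence fractions. Gene intervals are laid out along the
#' synthetic map.
#'
#' @param cfg a \code{sim_config}.
#' @return list with \code{panel} (a \code{genotype_panel}), \code{truth}
#'   (class \code{ground_truth}: \code{selected_ids}, \code{causal_ids},
#'   \code{beta_true} named per-causal-SNP derived-allele log-odds,
#'   \code{derived_is_alt}, \code{pop_freq} SNPs x pops, \code{p0}), and
#'   \code{genes} (a \code{region_set}).
#' @export
simulate_populations <- function(cfg) {
  set.seed(cfg$seed)
  p <- cfg$n_snps
  K <- cfg$n_pops
  n <- cfg$n_per_pop * K

  block <- max(1L, as.integer(cfg$ld_block_snps))
  n_blocks <- ceiling(p / block)
  block_id <- rep(seq_len(n_blocks), each = block)[seq_len(p)]
  p0_block <- stats::runif(n_blocks, cfg$p0_min, cfg$p0_max)
  p0 <- p0_block[block_id]

  pop_freq <- matrix(NA_real_, p, K)
  freq_block <- matrix(NA_real_, n_blocks, K)
  for (j in seq_len(K)) {
    f <- cfg$fst_drift[j]
    a <- p0_block * (1 - f) / f
    b <- (1 - p0_block) * (1 - f) / f
    fb <- pmin(pmax(stats::rbeta(n_blocks, a, b), 0.005), 0.995)
    freq_block[, j] <- fb
    pop_freq[, j] <- fb[block_id]
  }

  sel_idx <- if (cfg$n_selected > 0)
    sort(sample.int(p, cfg$n_selected)) else integer(0)
  if (length(sel_idx)) {
    # directional selection amplifies the existing differentiation: shift
    # away from the consensus of the remaining populations (ties: away
    # from 0.5), clipped to [0.01, 0.99]
    consensus <- if (K > 1)
      rowMeans(pop_freq[sel_idx, -K, drop = FALSE]) else 0.5
    cur <- pop_freq[sel_idx, K]
    sgn <- ifelse(cur >= consensus, 1, -1)
    shifted <- pmin(pmax(cur + sgn * cfg$delta_sel, 0.01), 0.99)
    pop_freq[sel_idx, K] <- shifted
  }

  dosage <- matrix(NA_real_, n, p)
  for (j in seq_len(K)) {
    rows <- ((j - 1) * cfg$n_per_pop + 1):(j * cfg$n_per_pop)
    indep <- matrix(
      stats::rbinom(cfg$n_per_pop * p, 2, rep(pop_freq[, j],
                                              each = cfg$n_per_pop)),
      nrow = cfg$n_per_pop)
    if (block > 1) {
      # LD blocks: members copy a latent per-individual block genotype,
      # except with probability ld_copy_error (and always at loci whose
      # frequency was shifted away from the block frequency)
      latent <- matrix(
        stats::rbinom(cfg$n_per_pop * n_blocks, 2,
                      rep(freq_block[, j], each = cfg$n_per_pop)),
        nrow = cfg$n_per_pop)
      copy <- matrix(stats::runif(cfg$n_per_pop * p) >= cfg$ld_copy_error,
                     nrow = cfg$n_per_pop)
      shifted_snp <- pop_freq[, j] != freq_block[block_id, j]
      copy[, shifted_snp] <- FALSE
      lat_exp <- latent[, block_id, drop = FALSE]
      indep[copy] <- lat_exp[copy]
    }
    dosage[rows, ] <- indep
  }

  # synthetic map: one chromosome per ~5000 SNPs, 1 kb spacing
  per_chr <- 5000L
  chrom <- as.character((seq_len(p) - 1L) %/% per_chr + 1L)
  pos <- ((seq_len(p) - 1L) %% per_chr + 1L) * 1000L

  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, p, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1),
                character(1))

  # derived allele: alt for half the SNPs; ancestral allele = the other one
  derived_is_alt <- sample(c(TRUE, FALSE), p, replace = TRUE)
  aa <- ifelse(derived_is_alt, ref, alt)
  lower <- stats::runif(p) < cfg$aa_lowercase_frac
  aa[lower] <- tolower(aa[lower])
  aa[stats::runif(p) < cfg$aa_missing_frac] <- NA_character_

  snp_ids <- sprintf("snp%06d", seq_len(p))
  panel <- genotype_panel(
    dosage = dosage, snp_ids = snp_ids, chrom = chrom, pos = pos,
    ref_allele = ref, alt_allele = alt, ancestral_allele = aa,
    sample_ids = sprintf("I%04d", seq_len(n)),
    population = rep(paste0("POP", seq_len(K)), each = cfg$n_per_pop)
  )

  n_overlap <- round(cfg$overlap_frac * cfg$n_causal)
  n_overlap <- min(n_overlap, length(sel_idx))
  causal_sel <- if (n_overlap > 0) sample(sel_idx, n_overlap) else integer(0)
  other_pool <- setdiff(seq_len(p), sel_idx)
  if (cfg$n_causal - n_overlap > length(other_pool))
    stop("n_causal = ", cfg$n_causal, " exceeds the available loci (",
         length(other_pool), " non-selected SNPs); reduce n_causal or ",
         "increase n_snps")
  causal_other <- sample(other_pool, cfg$n_causal - n_overlap)
  causal_idx <- sort(c(causal_sel, causal_other))

  # derived-allele-oriented effects; direction bias only at selected-causal
  beta_mag <- abs(stats::rnorm(length(causal_idx), 0, cfg$beta_sd))
  is_selc <- causal_idx %in% causal_sel
  prot <- ifelse(is_selc, stats::runif(length(causal_idx)) < cfg$pi_prot,
                 stats::runif(length(causal_idx)) < 0.5)
  beta_true <- ifelse(prot, -beta_mag, beta_mag)
  names(beta_true) <- snp_ids[causal_idx]

  # genes: one interval per 20 SNPs covering half of each 20 kb tile
  gene_start <- seq(0, max(pos), by = 20000)
  genes <- region_set(chrom = rep(unique(chrom),
                                  each = length(gene_start)),
                      start = rep(gene_start, length(unique(chrom))),
                      end = rep(gene_start + 10000, length(unique(chrom))),
                      label = "synthetic_genes")

  truth <- structure(list(
    selected_ids = snp_ids[sel_idx],
    causal_ids = snp_ids[causal_idx],
    beta_true = beta_true,
    derived_is_alt = stats::setNames(derived_is_alt, snp_ids),
    pop_freq = `rownames<-`(pop_freq, snp_ids),
    p0 = stats::setNames(p0, snp_ids)
  ), class = "ground_truth")

  list(panel = panel, truth = truth, genes = genes)
}

#' Simulate discovery GWAS summary statistics
#'
#' Per SNP, the estimated log-odds is Normal(beta_true_effect, se^2) with
#' se = 1 / sqrt(2 p (1 - p) n_eff), where p is the pooled panel frequency
#' and beta_true is oriented from its derived-allele definition to the
#' effect allele (the panel's alternate allele). p-values come from the
#' Wald z statistic and OR = exp(estimate).
#'
#' @param panel the simulated \code{genotype_panel}.
#' @param truth the matching \code{ground_truth}.
#' @param n_eff effective GWAS sample size (default 100000).
#' @param info_range range of the simulated imputation-quality column
#'   (default c(0.92, 1), i.e. post-QC records).
#' @param seed integer seed.
#' @return a \code{gwas_summary} data.frame (effect allele = panel alt).
#' @export
simulate_gwas_summary <- function(panel, truth, n_eff = 1e5,
                                  info_range = c(0.92, 1), seed = 1) {
  if (n_eff <= 0) stop("n_eff must be positive")
  set.seed(seed + 1L)
  p <- n_snps(panel)
  f <- alt_freq(panel)
  f <- pmin(pmax(f, 0.01), 0.99)
  se <- 1 / sqrt(2 * f * (1 - f) * n_eff)
  beta_derived <- stats::setNames(rep(0, p), panel$snp_ids)
  beta_derived[names(truth$beta_true)] <- truth$beta_true
  # orient to the alt (effect) allele
  beta_alt <- ifelse(truth$derived_is_alt[panel$snp_ids], beta_derived,
                     -beta_derived)
  est <- stats::rnorm(p, beta_alt, se)
  z <- est / se
  df <- data.frame(
    snp_id = panel$snp_ids,
    chrom = panel$chrom,
    pos = panel$pos,
    a1 = panel$alt_allele,
    a2 = panel$ref_allele,
    or_effect = exp(est),
    se = se,
    p_assoc = 2 * stats::pnorm(-abs(z)),
    info = stats::runif(p, info_range[1], info_range[2]),
    freq_a1 = f,
    stringsAsFactors = FALSE
  )
  class(df) <- c("gwas_summary", "data.frame")
  df
}

#' Simulate a liability-threshold case-control target cohort
#'
#' Individuals are drawn from one population's allele frequencies. Latent
#' liability is the centered genetic score over causal SNPs plus Gaussian
#' noise scaled so the genetic fraction equals \code{h2_liability}; a case
#' is declared when liability exceeds the prevalence threshold. Sampling is
#' by rejection on the causal genotypes only (non-causal genotypes are
#' independent of the phenotype and are filled in afterwards), which is
#' exact and keeps the cost linear. Covariates are sex, age and ancestry
#' scores (principal components of the cohort genotypes).
#'
#' @param cfg a \code{sim_config} (uses h2_liability, prevalence and the
#'   population frequencies' last column by default).
#' @param truth the \code{ground_truth} from
#'   \code{\link{simulate_populations}}.
#' @param n_cases,n_controls cohort sizes (defaults from \code{cfg}).
#' @param pop column of \code{truth$pop_freq} to draw from (default 1,
#'   an unshifted population so selected loci are not confounded).
#' @param n_ancestry_pcs ancestry covariates to attach (default 10).
#' @param seed integer seed.
#' @param max_iter cap on rejection-sampling rounds (default 200).
#' @return a \code{cohort_data} with dosages oriented to the panel alt
#'   allele.
#' @export
simulate_target_cohort <- function(cfg, truth, n_cases = cfg$n_cases,
                                   n_controls = cfg$n_controls, pop = 1,
                                   n_ancestry_pcs = 10, seed = 1,
                                   max_iter = 200) {
  set.seed(seed + 2L)
  freq <- truth$pop_freq[, pop]
  snp_ids <- rownames(truth$pop_freq)
  causal <- names(truth$beta_true)
  beta_d <- truth$beta_true
  # orient derived-allele effects to the alt allele
  beta_alt <- ifelse(truth$derived_is_alt[causal], beta_d, -beta_d)
  fc <- freq[causal]
  var_g <- sum(2 * fc * (1 - fc) * beta_alt^2)
  if (var_g <= 0) var_g <- 1e-12
  # rescale the genetic score to variance h2 and add N(0, 1 - h2) noise,
  # so total liability has unit variance and threshold qnorm(1 - prev)
  g_scale <- sqrt(cfg$h2_liability / var_g)
  sd_e <- sqrt(1 - cfg$h2_liability)
  thr <- stats::qnorm(1 - cfg$prevalence)

  need_case <- n_cases; need_ctrl <- n_controls
  acc_dos <- list(); acc_phe <- integer(0)
  batch <- max(20000L, 4L * (n_cases + n_controls))
  iter <- 0
  while ((need_case > 0 || need_ctrl > 0) && iter < max_iter) {
    iter <- iter + 1
    d <- matrix(stats::rbinom(batch * length(causal), 2,
                              rep(fc, each = batch)), nrow = batch)
    g <- drop(sweep(d, 2, 2 * fc, "-") %*% beta_alt) * g_scale
    liab <- g + stats::rnorm(batch, 0, sd_e)
    is_case <- liab > thr
    take_case <- which(is_case)[seq_len(min(need_case, sum(is_case)))]
    take_ctrl <- which(!is_case)[seq_len(min(need_ctrl, sum(!is_case)))]
    take <- c(take_case, take_ctrl)
    if (length(take)) {
      acc_dos[[length(acc_dos) + 1]] <- d[take, , drop = FALSE]
      acc_phe <- c(acc_phe, as.integer(is_case[take]))
      need_case <- need_case - length(take_case)
      need_ctrl <- need_ctrl - length(take_ctrl)
    }
  }
  if (need_case > 0 || need_ctrl > 0)
    stop("case sampling exceeded the iteration cap; prevalence too low ",
         "for the requested cohort size")
  d_causal <- do.call(rbind, acc_dos)
  n <- nrow(d_causal)
  # non-causal genotypes are independent of phenotype: fill in afterwards
  noncausal <- setdiff(snp_ids, causal)
  d_other <- matrix(stats::rbinom(n * length(noncausal), 2,
                                  rep(freq[noncausal], each = n)), nrow = n)
  dosage <- matrix(NA_real_, n, length(snp_ids),
                   dimnames = list(NULL, snp_ids))
  dosage[, causal] <- d_causal
  dosage[, noncausal] <- d_other

  # covariates: sex, age, leading genotype PCs
  sexv <- stats::rbinom(n, 1, 0.5)
  age <- stats::rnorm(n, 40, 12)
  # ancestry scores from a SNP subset (cheap and sufficient for covariate
  # adjustment in a single-population cohort)
  pc_snps <- if (length(snp_ids) > 4000)
    sort(sample(seq_along(snp_ids), 4000)) else seq_along(snp_ids)
  sc <- scale_dosage(dosage[, pc_snps, drop = FALSE])
  npc <- min(n_ancestry_pcs, n - 1)
  eg <- eigen(tcrossprod(sc$x), symmetric = TRUE)
  pcs <- eg$vectors[, seq_len(npc), drop = FALSE]
  covars <- cbind(sex = sexv, age = age,
                  `colnames<-`(pcs, paste0("PC", seq_len(npc))))
  cohort_data(dosage, acc_phe, covariates = covars)
}

#' Write a genotype panel as VCF
#'
#' Emits a minimal valid VCF 4.2 file (GT genotypes, INFO AA tag when the
#' ancestral allele is known, preserving the lowercase low-confidence
#' convention). Deterministic: the same panel writes byte-identical output.
#'
#' @param panel a \code{genotype_panel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral Allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t")
  ), con)
  aa <- panel$ancestral_allele
  aa_out <- ifelse(panel$aa_low_confidence, tolower(aa), aa)
  info <- ifelse(is.na(aa), ".", paste0("AA=", aa_out))
  gt_code <- c("0/0", "0/1", "1/1")
  p <- n_snps(panel)
  chunk <- 2000L
  for (start in seq(1L, p, by = chunk)) {
    idx <- start:min(start + chunk - 1L, p)
    d <- panel$dosage[, idx, drop = FALSE]
    gt <- matrix(gt_code[d + 1], nrow = nrow(d))
    gt[is.na(d)] <- "./."
    lines <- paste(panel$chrom[idx], panel$pos[idx], panel$snp_ids[idx],
                   panel$ref_allele[idx], panel$alt_allele[idx], ".",
                   "PASS", info[idx], "GT",
                   apply(gt, 2, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write cohort phenotype/covariate table
#'
#' Companion TSV for a simulated cohort: IID, PHENO, then covariates.
#'
#' @param cohort a \code{cohort_data}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_cohort_tsv <- function(cohort, path) {
  out <- data.frame(IID = sprintf("I%04d", seq_along(cohort$phenotype)),
                    PHENO = cohort$phenotype)
  if (!is.null(cohort$covariates))
    out <- cbind(out, as.data.frame(cohort$covariates))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a region set as BED
#' @param regions a \code{region_set}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  utils::write.table(
    data.frame(regions$chrom, format(regions$start, scientific = FALSE,
                                     trim = TRUE),
               format(regions$end, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
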