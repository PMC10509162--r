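.pipeline_defaults <- function() list(
  genotypes = NULL, gwas = NULL, genes = NULL, excludes = NULL,
  cohort_vcf = NULL, cohort_tsv = NULL, discovery_gwas = NULL,
  population = NULL,
  maf_min = 0.05, info_min = 0.9,
  thin_window_snps = 200, thin_r2 = 0.1, k = 3, robust = TRUE,
  clump_r2 = 0.1, clump_kb = 500,
  top_fraction = 0.05,
  thresholds = enrichment_thresholds(),
  direction_thresholds = direction_thresholds(),
  n_perm = 10000,
  p_t = 0.2, n_quantiles = 20, n_sets = 1000, n_draws = 1000,
  n_snps_per_draw = 1000,
  flow = "clump_by_assoc",
  seed = NULL
)

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a named list), fills defaults (thin window
#' 200 SNPs / r2 0.1, K = 3, top 5\%, clump r2 0.1 / 500 kb, p_t 0.2, 20
#' quantiles, 1000 sets/draws, 10000 permutations), rejects unknown keys,
#' and checks that mandatory paths and the seed are present.
#'
#' @param config path to a YAML file, or a named list.
#' @param require_paths require \code{genotypes} and \code{gwas} paths to
#'   be set and existing (default TRUE; set FALSE when the panel and
#'   summary objects are passed to \code{\link{run_pipeline}} directly).
#' @return a validated list of class \code{pipeline_config}.
#' @export
validate_config <- function(config, require_paths = TRUE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  defaults <- .pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (!cfg$flow %in% c("clump_by_assoc", "clump_by_rns", "both"))
    stop("flow must be clump_by_assoc, clump_by_rns or both")
  if (require_paths) {
    missing_paths <- c("genotypes", "gwas")[
      vapply(c("genotypes", "gwas"),
             function(k) is.null(cfg[[k]]), logical(1))]
    if (length(missing_paths))
      stop("mandatory path(s) missing from config: ",
           paste(missing_paths, collapse = ", "))
    for (k in c("genotypes", "gwas", "genes", "excludes", "cohort_vcf",
                "cohort_tsv", "discovery_gwas")) {
      if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
        stop("config path does not exist: ", k, " = ", cfg[[k]])
    }
  }
  if (is.null(cfg$seed))
    stop("seed is mandatory (stochastic stages: MCD, permutations, draws)")
  class(cfg) <- "pipeline_config"
  cfg
}

# one clump flow: clump, define markers, enrichment cascade, polarization
.run_flow <- function(flow, harm, scan, cfg) {
  tab <- harm$table
  p_rns <- stats::setNames(scan$p_rns[match(tab$snp_id, scan$snp_id)],
                           tab$snp_id)
  p_assoc <- stats::setNames(tab$p_assoc, tab$snp_id)
  rank_p <- if (flow == "clump_by_rns") p_rns else p_assoc
  clumped <- ld_clump(
    data.frame(snp_id = tab$snp_id, chrom = tab$chrom, pos = tab$pos,
               p = unname(rank_p[tab$snp_id]), stringsAsFactors = FALSE),
    harm$panel, r2_max = cfg$clump_r2, window_kb = cfg$clump_kb,
    ranking_p = if (flow == "clump_by_rns") "p_rns" else "p_assoc")
  chrom <- stats::setNames(tab$chrom, tab$snp_id)
  pos <- stats::setNames(tab$pos, tab$snp_id)
  annotation <- define_rns_markers(clumped, p_rns, cfg$top_fraction,
                                   chrom = chrom, pos = pos)
  enr <- threshold_enrichment(annotation, p_assoc, cfg$thresholds)
  idx <- annotation$snp_id
  nominal <- idx[p_assoc[idx] < 0.05]
  corr <- NULL
  if (length(nominal) >= 10) {
    maf <- stats::setNames(tab$maf, tab$snp_id)
    corr <- partial_spearman_perm(
      x = -log10(p_assoc[nominal]), y = -log10(p_rns[nominal]),
      covar = maf[nominal], n_perm = cfg$n_perm, seed = cfg$seed)
  }
  polarized <- polarize_to_derived(harm)
  bias <- direction_bias_tests(polarized, annotation, p_assoc,
                               cfg$direction_thresholds)
  list(flow = flow, clumped = clumped, annotation = annotation,
       enrichment = enr, correlation = corr, polarized = polarized,
       direction_bias = bias)
}

#' Run the full analysis pipeline
#'
#' Executes harmonize -> selection scan -> LD clump (per flow) -> marker
#' definition -> enrichment, KS uniformity and MAF-controlled partial
#' Spearman -> derived-allele polarization and direction-bias tests ->
#' (when a cohort is supplied) quantile trend, matched-SNP null and
#' direction-stratified polygenic scores.
#'
#' Inputs can be given as file paths in the config, or as in-memory
#' objects.
#'
#' @param cfg a \code{pipeline_config} from \code{\link{validate_config}}.
#' @param panel optional \code{genotype_panel} (else read from
#'   \code{cfg$genotypes}).
#' @param gwas optional \code{gwas_summary} (else read from
#'   \code{cfg$gwas}).
#' @param genes optional \code{region_set}.
#' @param cohort optional \code{cohort_data} for the PGS stages.
#' @param pgs_weights optional named log-OR weight vector for PGS stages
#'   (oriented to panel alt alleles); defaults to the harmonized GWAS
#'   effects. Use an independent discovery GWAS to avoid overlap with the
#'   cohort.
#' @return an object of class \code{pipeline_report}.
#' @export
run_pipeline <- function(cfg, panel = NULL, gwas = NULL, genes = NULL,
                         cohort = NULL, pgs_weights = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  excludes <- if (!is.null(cfg$excludes)) read_regions_bed(cfg$excludes)
  if (is.null(panel)) panel <- read_genotypes(cfg$genotypes, excludes)
  if (is.null(gwas)) gwas <- read_gwas(cfg$gwas, info_min = cfg$info_min)
  if (is.null(genes) && !is.null(cfg$genes))
    genes <- read_regions_bed(cfg$genes)
  if (is.null(cohort) && !is.null(cfg$cohort_vcf) &&
      !is.null(cfg$cohort_tsv))
    cohort <- read_cohort(cfg$cohort_vcf, cfg$cohort_tsv)

  harm <- harmonize(panel, gwas, maf_min = cfg$maf_min)
  model <- fit_pca(harm$panel, k = cfg$k,
                   thin_window_snps = cfg$thin_window_snps,
                   thin_r2 = cfg$thin_r2, seed = cfg$seed)
  scan <- scan_pvalues(harm$panel, model, robust = cfg$robust,
                       seed = cfg$seed)
  ks <- ks_uniformity(scan$p_rns)

  flows <- if (cfg$flow == "both") c("clump_by_assoc", "clump_by_rns")
  else cfg$flow
  flow_results <- lapply(flows, .run_flow, harm = harm, scan = scan,
                         cfg = cfg)
  names(flow_results) <- flows
  overlap <- NULL
  if (length(flow_results) == 2) {
    m1 <- flow_results[[1]]$annotation
    m2 <- flow_results[[2]]$annotation
    overlap <- length(intersect(m1$snp_id[m1$is_marker],
                                m2$snp_id[m2$is_marker]))
  }

  pgs <- NULL
  if (!is.null(cohort)) {
    fr <- flow_results[[1]]
    tab <- harm$table
    if (is.null(pgs_weights)) {
      beta_alt <- ifelse(tab$effect_is_alt, log(tab$or_effect),
                         -log(tab$or_effect))
      pgs_weights <- stats::setNames(beta_alt, tab$snp_id)
    }
    p_assoc <- stats::setNames(tab$p_assoc, tab$snp_id)
    p_rns <- stats::setNames(scan$p_rns[match(tab$snp_id, scan$snp_id)],
                             tab$snp_id)
    idx <- intersect(fr$annotation$snp_id, colnames(cohort$dosage))
    trend <- quantile_trend(p_assoc, p_rns, idx, cohort, pgs_weights,
                            n_quantiles = cfg$n_quantiles, p_t = cfg$p_t)
    pgs <- list(trend = trend)
  }

  structure(list(
    config = cfg,
    harmonization = harm$report,
    pca = list(K = model$K,
               var_explained = model$var_explained[seq_len(model$K)],
               n_thinned = sum(model$thin_mask)),
    lambda_gc = scan$lambda_gc,
    ks_uniformity = ks,
    flows = flow_results,
    marker_overlap = overlap,
    pgs = pgs,
    scan = scan
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("=== selection / GWAS pipeline report ===\n")
  cat("harmonized SNPs:", x$harmonization$n_final,
      "| K =", x$pca$K, "| lambda_gc =", format(x$lambda_gc, digits = 4),
      "\n")
  cat("KS uniformity of scan p-values: D =",
      format(x$ks_uniformity$statistic, digits = 3),
      "p =", format(x$ks_uniformity$p, digits = 3), "\n")
  for (fr in x$flows) {
    cat("\n--- flow:", fr$flow, "---\n")
    cat("index SNPs:", length(fr$clumped$index_snps),
        "| markers:", sum(fr$annotation$is_marker), "\n")
    top <- fr$enrichment[1, ]
    cat("enrichment at p <", format(top$threshold, digits = 2), ": OR =",
        format(top$or, digits = 3), "p =", format(top$p, digits = 3), "\n")
    if (!is.null(fr$correlation))
      cat("partial Spearman rho =", format(fr$correlation$rho, digits = 3),
          "p_perm =", format(fr$correlation$p_perm, digits = 3), "\n")
  }
  if (!is.null(x$marker_overlap))
    cat("\nmarker overlap between flows:", x$marker_overlap, "\n")
  if (!is.null(x$pgs)) {
    cat("\nPGS quantile trend: t =", format(x$pgs$trend$t_stat, digits = 3),
        "p =", format(x$pgs$trend$p_trend, digits = 3), "\n")
  }
  invisible(x)
}
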