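test_that("ld_clump handles the canonical small cases", {
  panel <- make_tiny_panel(n_snps = 3, seed = 2)
  # single SNP is its own index
  one <- data.frame(snp_id = "rs1", chrom = "1", pos = 1000, p = 0.5)
  cl <- ld_clump(one, panel)
  expect_equal(cl$index_snps, "rs1")
  expect_length(cl$removed_by, 0)

  # perfect-LD pair: stronger p absorbs the weaker
  panel$dosage[, 2] <- panel$dosage[, 1]
  two <- data.frame(snp_id = c("rs1", "rs2"), chrom = "1",
                    pos = c(1000, 11000), p = c(1e-8, 1e-4))
  cl2 <- ld_clump(two, panel, r2_max = 0.1, window_kb = 500)
  expect_equal(cl2$index_snps, "rs1")
  expect_equal(unname(cl2$removed_by["rs2"]), "rs1")

  expect_error(ld_clump(data.frame(snp_id = "nope", chrom = "1", pos = 1,
                                   p = 0.1), panel), "absent")
})

test_that("ld_clump keeps independent SNPs as separate indices", {
  # A and B correlated (r2 ~ 0.5), C independent
  set.seed(7)
  a <- rbinom(400, 2, 0.5)
  b <- ifelse(runif(400) < 0.75, a, rbinom(400, 2, 0.5))
  cc <- rbinom(400, 2, 0.5)
  r2_ab <- cor(a, b)^2
  expect_gt(r2_ab, 0.3)
  panel <- genotype_panel(cbind(a, b, cc), snp_ids = c("A", "B", "C"),
                          chrom = rep("1", 3), pos = c(1e4, 2e4, 3e4),
                          ref_allele = rep("A", 3), alt_allele = rep("G", 3))
  snps <- data.frame(snp_id = c("A", "B", "C"), chrom = "1",
                     pos = c(1e4, 2e4, 3e4), p = c(1e-8, 1e-4, 1e-3))
  cl <- ld_clump(snps, panel, r2_max = 0.1, window_kb = 500)
  expect_setequal(cl$index_snps, c("A", "C"))
  expect_equal(cl$index_snps[1], "A")  # selection order follows p
})

test_that("greedy clump equals the brute-force oracle on random instances", {
  set.seed(19)
  for (rep in 1:60) {
    n_snps <- sample(2:20, 1)
    n <- 60
    base <- rbinom(n, 2, runif(1, 0.2, 0.8))
    dosage <- sapply(seq_len(n_snps), function(j) {
      if (runif(1) < 0.5) ifelse(runif(n) < 0.6, base, rbinom(n, 2, 0.5))
      else rbinom(n, 2, runif(1, 0.1, 0.9))
    })
    snps <- data.frame(
      snp_id = paste0("v", seq_len(n_snps)), chrom = "1",
      pos = sort(sample.int(2e6, n_snps)),
      p = round(runif(n_snps), 3))  # rounding creates occasional ties
    panel <- genotype_panel(dosage, snps$snp_id, snps$chrom, snps$pos,
                            rep("A", n_snps), rep("G", n_snps))
    r2m <- sample(c(0.1, 0.3, 0.8), 1)
    wkb <- sample(c(50, 500, 1500), 1)
    got <- ld_clump(snps, panel, r2_max = r2m, window_kb = wkb)
    want <- clump_brute(snps, dosage, r2_max = r2m, window_kb = wkb)
    expect_setequal(got$index_snps, want$index)
    absorbed <- setdiff(snps$snp_id, want$index)
    expect_setequal(names(got$removed_by), absorbed)
  }
})

test_that("clump index SNPs are mutually sub-threshold within the window", {
  cfg <- sim_config(n_pops = 2, n_per_pop = 60, n_snps = 600,
                    n_selected = 0, seed = 31)
  sim <- simulate_populations(cfg)
  snps <- data.frame(snp_id = sim$panel$snp_ids, chrom = sim$panel$chrom,
                     pos = sim$panel$pos,
                     p = runif(n_snps(sim$panel)))
  cl <- ld_clump(snps, sim$panel, r2_max = 0.2, window_kb = 100)
  idx <- match(cl$index_snps, sim$panel$snp_ids)
  d <- sim$panel$dosage[, idx, drop = FALSE]
  pos <- sim$panel$pos[idx]
  viol <- 0
  for (i in seq_along(idx)) {
    near <- which(abs(pos - pos[i]) <= 1e5 & seq_along(idx) != i)
    for (j in near) if (cor(d[, i], d[, j])^2 >= 0.2) viol <- viol + 1
  }
  expect_equal(viol, 0)
  # every input SNP is an index or absorbed by exactly one
  expect_equal(sort(c(cl$index_snps, names(cl$removed_by))),
               sort(snps$snp_id))
})

test_that("annotate_properties computes MAF, buddies, gene metrics", {
  cfg <- sim_config(n_pops = 1, n_per_pop = 200, n_snps = 40,
                    n_selected = 0, n_causal = 5, ld_block_snps = 1,
                    seed = 17)
  sim <- simulate_populations(cfg)
  genes <- region_set("1", c(0, 50000), c(2500, 60000))
  pr <- annotate_properties(sim$panel, genes)
  expect_true(all(pr$maf <= 0.5))
  expect_equal(pr$maf, panel_maf(sim$panel))
  # independent SNPs: no buddies at r2 >= 0.5
  expect_true(all(pr$ld_buddies == 0))
  # SNP at pos 1000 (0-based 999) inside [0, 2500)
  expect_equal(pr$gene_dist[1], 0)
  # SNP at pos 5000 -> 0-based 4999; nearest gene edge: 2500 -> dist 2500
  expect_equal(pr$gene_dist[5], 4999 - 2499)
  # no genes: infinite distance, zero density
  pr2 <- annotate_properties(sim$panel, NULL)
  expect_true(all(is.infinite(pr2$gene_dist)))
  expect_true(all(pr2$gene_density == 0))
  # MAF folding
  panel2 <- sim$panel
  panel2$dosage[, 1] <- rbinom(200, 2, 0.7)
  pr3 <- annotate_properties(panel2, NULL)
  expect_lt(abs(pr3$maf[1] - 0.3), 0.07)
})

test_that("LD blocks produce buddies and clumping absorbs block mates", {
  cfg <- sim_config(n_pops = 2, n_per_pop = 100, n_snps = 500,
                    n_selected = 0, ld_block_snps = 5, seed = 23)
  sim <- simulate_populations(cfg)
  pr <- annotate_properties(sim$panel, NULL)
  expect_gt(mean(pr$ld_buddies), 1)
})

test_that("draw_matched_sets respects tolerances and determinism", {
  props <- data.frame(
    snp_id = paste0("s", 1:12),
    maf = c(0.10, 0.30, 0.14, 0.16, 0.32, 0.28, 0.12, 0.31, 0.09, 0.33,
            0.11, 0.29),
    ld_buddies = c(2, 4, 2, 2, 4, 4, 2, 4, 2, 4, 2, 4),
    gene_dist = c(0, 1e4, 0, 0, 1.2e4, 0.9e4, 0, 1.1e4, 0, 1e4, 0, 1e4),
    gene_density = c(1, 2, 1, 1, 2, 2, 1, 2, 1, 2, 1, 2))
  targets <- c("s1", "s2")
  pool <- setdiff(props$snp_id, targets)

  sets1 <- draw_matched_sets(targets, pool, props, n_sets = 5, seed = 7)
  sets2 <- draw_matched_sets(targets, pool, props, n_sets = 5, seed = 7)
  expect_identical(sets1, sets2)
  expect_true(all(vapply(sets1, length, integer(1)) == 2))
  expect_true(all(vapply(sets1, anyDuplicated, integer(1)) == 0))

  # MAF boundary: target 0.10 accepts 0.14 but not 0.16
  for (s in sets1) {
    m1 <- props$maf[match(s, props$snp_id)]
    expect_true(all(abs(sort(m1) - sort(props$maf[1:2])) <= 0.05 + 1e-12))
  }

  # infeasible target errors with its name
  props2 <- props; props2$maf[1] <- 0.49
  expect_error(draw_matched_sets(targets, pool, props2, 2, seed = 1),
               "matching infeasible.*s1")
  expect_error(draw_matched_sets(targets, props$snp_id, props, 1, seed = 1),
               "disjoint")
})

test_that("matched sets track target MAF in aggregate", {
  set.seed(9)
  n_pool <- 400
  props <- data.frame(
    snp_id = c(paste0("t", 1:20), paste0("p", 1:n_pool)),
    maf = c(runif(20, 0.1, 0.4), runif(n_pool, 0.05, 0.5)),
    ld_buddies = 0, gene_dist = 0, gene_density = 0)
  targets <- paste0("t", 1:20)
  pool <- paste0("p", 1:n_pool)
  sets <- draw_matched_sets(targets, pool, props, n_sets = 20, seed = 3)
  tmaf <- mean(props$maf[1:20])
  for (s in sets) {
    smaf <- mean(props$maf[match(s, props$snp_id)])
    expect_lte(abs(smaf - tmaf), 0.05)
  }
})
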