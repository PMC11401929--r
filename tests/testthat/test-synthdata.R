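test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- sim_config(n_individuals = 400, n_blocks = 4, snps_per_block = 6,
                    classes = locus_classes(data.frame(
                      class = "ratio_specific", count = 1L,
                      beta_tg_f = 0.2, beta_hdl_f = -0.2,
                      beta_tg_m = 0.2, beta_hdl_m = -0.2)),
                    seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort$genotypes, b$cohort$genotypes)
  expect_identical(a$cohort$phenotypes, b$cohort$phenotypes)
  expect_identical(a$cohort$rare_genotypes, b$cohort$rare_genotypes)
  expect_identical(a$truth$loci, b$truth$loci)
  c2 <- simulate_cohort(sim_config(n_individuals = 400, n_blocks = 4,
                                   snps_per_block = 6,
                                   classes = cfg$classes, seed = 100))
  expect_false(identical(a$cohort$genotypes, c2$cohort$genotypes))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(ld_decay = 1), "ld_decay")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  # more planted loci than blocks can host
  big <- locus_classes(data.frame(class = "null", count = 30L,
                                  beta_tg_f = 0, beta_hdl_f = 0,
                                  beta_tg_m = 0, beta_hdl_m = 0))
  expect_error(sim_config(n_blocks = 10, classes = big), "exceed")
  expect_error(locus_classes(data.frame(
    class = "ratio_specific", count = 1L,
    beta_tg_f = 0.2, beta_hdl_f = 0.2,   # same sign: not ratio-specific
    beta_tg_m = 0.2, beta_hdl_m = 0.2)), "opposite-signed")
})

test_that("dosage bounds, allele frequencies and genotype integrity hold", {
  sim <- small_sim()
  G <- sim$cohort$genotypes
  expect_true(all(G %in% 0:2))
  expect_true(all(sim$cohort$snp_map$eaf > 0 & sim$cohort$snp_map$eaf < 1))
  expect_true(all(sim$cohort$phenotypes$TG > 0))
  expect_true(all(sim$cohort$phenotypes$HDL > 0))
  # every planted causal SNP exists in the genotype matrix
  expect_true(all(sim$truth$loci$causal_snp %in% colnames(G)))
  # ratio-specific loci have opposite-signed component effects
  rs <- sim$truth$loci[sim$truth$loci$class == "ratio_specific", ]
  expect_true(all(sign(rs$beta_tg_f) == -sign(rs$beta_hdl_f)))
})

test_that("adjacent-SNP dosage correlation is calibrated to ld_decay", {
  for (target in c(0.5, 0.9)) {
    cfg <- sim_config(n_individuals = 5000, n_blocks = 3, snps_per_block = 8,
                      ld_decay = target,
                      classes = locus_classes(data.frame(
                        class = "null", count = 1L, beta_tg_f = 0,
                        beta_hdl_f = 0, beta_tg_m = 0, beta_hdl_m = 0)),
                      seed = 7 + round(100 * target))
    G <- simulate_cohort(cfg)$cohort$genotypes
    m <- cfg$snps_per_block
    for (b in 1:3) {
      idx <- ((b - 1) * m + 1):(b * m)
      adj <- vapply(seq_len(m - 1), function(j)
        stats::cor(G[, idx[j]], G[, idx[j + 1]]), numeric(1))
      expect_lt(abs(mean(adj) - target), 0.05)
    }
  }
})

test_that("regression on the planted SNP recovers the ratio effect", {
  # log(TG/HDL) on the generating genotype recovers beta_TG - beta_HDL
  hits <- 0L
  n_seeds <- 30L
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(n_individuals = 1500, n_blocks = 2, snps_per_block = 6,
                      classes = locus_classes(data.frame(
                        class = "ratio_specific", count = 1L,
                        beta_tg_f = 0.3, beta_hdl_f = -0.3,
                        beta_tg_m = 0.3, beta_hdl_m = -0.3)),
                      seed = 1000 + s)
    sim <- simulate_cohort(cfg)
    ph <- sim$cohort$phenotypes
    g <- sim$cohort$genotypes[, sim$truth$loci$causal_snp[1]]
    p <- mean(g) / 2
    gs <- (g - 2 * p) / sqrt(2 * p * (1 - p))
    fit <- summary(stats::lm(log(ph$TG) - log(ph$HDL) ~ gs))$coef["gs", ]
    if (abs(fit["Estimate"] - 0.6) < 3 * fit["Std. Error"]) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.9 * n_seeds))
})

test_that("an all-null architecture shows no genomic inflation", {
  cfg <- sim_config(n_individuals = 3000, n_blocks = 12, snps_per_block = 10,
                    ld_decay = 0,
                    classes = locus_classes(data.frame(
                      class = "null", count = 4L, beta_tg_f = 0,
                      beta_hdl_f = 0, beta_tg_m = 0, beta_hdl_m = 0)),
                    seed = 5)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  ph <- log_transform_traits(co$phenotypes)
  y <- inverse_rank_normal(ph$trait_TGHDL)
  covars <- data.frame(age = ph$age, age2 = ph$age^2, sex = ph$sex)
  ss <- assoc_scan(co$genotypes, y, co$snp_map, covariates = covars,
                   sex = ph$sex)
  lam <- genomic_control(ss$p_value)$lambda_gc
  expect_gt(lam, 0.7)
  expect_lt(lam, 1.3)
})

test_that("rare variants are rare, unlinked and reproducible", {
  rv <- simulate_rare_variants(2000, rare_variant_spec(), seed = 3)
  rv2 <- simulate_rare_variants(2000, rare_variant_spec(), seed = 3)
  expect_identical(rv$genotypes, rv2$genotypes)
  expect_true(all(rv$variants$maf < 0.01))
  expect_true(all(rv$variants$votes[rv$variants$plof] == 5))
  expect_identical(sort(unique(rv$variants$gene)), c("RVG1", "RVG2"))
})

test_that("fixtures round-trip exactly and refuse silent overwrite", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  write_fixtures(sim$cohort, sim$truth, dir)
  expect_error(write_fixtures(sim$cohort, sim$truth, dir), "refusing")
  expect_silent(write_fixtures(sim$cohort, sim$truth, dir, force = TRUE))
  back <- read_fixtures(dir)
  expect_equal(back$genotypes, sim$cohort$genotypes,
               ignore_attr = TRUE)
  expect_equal(back$phenotypes, sim$cohort$phenotypes, tolerance = 1e-12)
  expect_equal(back$snp_map, sim$cohort$snp_map, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$rare_variants, sim$cohort$rare_variants,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$truth_loci, as.data.frame(sim$truth$loci),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("BED gene models convert 0-based half-open to 1-based closed", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  write_fixtures(sim$cohort, sim$truth, dir)
  gm <- read_gene_models(file.path(dir, "gene_models.bed"))
  bed <- utils::read.table(file.path(dir, "gene_models.bed"), sep = "\t")
  # brute-force interval check: SNP at 1-based position p overlaps gene
  # [s, e) in BED coordinates iff s < p <= e
  for (k in seq_len(min(6, nrow(gm)))) {
    s_bed <- bed$V2[k]; e_bed <- bed$V3[k]
    for (p in c(s_bed, s_bed + 1, e_bed, e_bed + 1)) {
      bed_overlap <- s_bed < p & p <= e_bed
      closed_overlap <- gm$start[k] <= p & p <= gm$end[k]
      expect_identical(bed_overlap, closed_overlap)
    }
  }
})

test_that("a cohort with zero planted loci writes a header-only truth table", {
  cfg <- sim_config(n_individuals = 200, n_blocks = 2, snps_per_block = 6,
                    classes = locus_classes(data.frame(
                      class = "null", count = 0L, beta_tg_f = 0,
                      beta_hdl_f = 0, beta_tg_m = 0, beta_hdl_m = 0)),
                    seed = 1)
  sim <- simulate_cohort(cfg)
  expect_identical(nrow(sim$truth$loci), 0L)
  dir <- withr::local_tempdir()
  write_fixtures(sim$cohort, sim$truth, dir)
  lines <- readLines(file.path(dir, "truth_loci.tsv"))
  expect_length(lines, 1L)  # header only
})
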