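# Synthetic cohort generator: LD-block genotypes via a Gaussian copula,
# two correlated log-lipid phenotypes with planted locus classes, rare
# deleterious coding variants for burden testing, an expression proxy and a
# BMI-like mediator, plus the planted ground truth needed for recovery tests.

#' Locus class table describing the planted genetic architecture
#'
#' Each row plants `count` loci of one class, one locus per LD block, with
#' per-trait, per-sex effects in phenotype-SD units applied to the
#' standardized dosage of the block's central SNP.
#'
#' Classes follow the ratio-trait design: `ratio_specific` loci have
#' opposite-signed TG and HDL effects (so the log-ratio effect is their
#' difference), `shared_lipid` loci move both lipids the same way (the
#' ratio effect cancels), `tg_only`/`hdl_only` move one component,
#' `sex_dimorphic` loci have female effects larger than male, and `null`
#' loci carry no effect.
#'
#' @param classes data.frame with columns `class`, `count`, `beta_tg_f`,
#'   `beta_hdl_f`, `beta_tg_m`, `beta_hdl_m`. Defaults plant 20 loci:
#'   4 ratio-specific, 3 TG-only, 3 HDL-only, 4 shared-lipid,
#'   2 sex-dimorphic, 4 null.
#' @return validated locus-class data.frame.
#' @export
locus_classes <- function(classes = NULL) {
  if (is.null(classes)) {
    classes <- data.frame(
      class      = c("ratio_specific", "tg_only", "hdl_only", "shared_lipid",
                     "sex_dimorphic", "null"),
      count      = c(4L, 3L, 3L, 4L, 2L, 4L),
      beta_tg_f  = c(0.15, 0.15, 0.00, 0.15, 0.15, 0),
      beta_hdl_f = c(-0.15, 0.00, 0.15, 0.15, -0.15, 0),
      beta_tg_m  = c(0.15, 0.15, 0.00, 0.15, 0.03, 0),
      beta_hdl_m = c(-0.15, 0.00, 0.15, 0.15, -0.03, 0),
      stringsAsFactors = FALSE
    )
  }
  need <- c("class", "count", "beta_tg_f", "beta_hdl_f", "beta_tg_m", "beta_hdl_m")
  assert_that(all(need %in% names(classes)),
              paste("locus class table needs columns:", paste(need, collapse = ", ")))
  known <- c("ratio_specific", "tg_only", "hdl_only", "shared_lipid",
             "sex_dimorphic", "null")
  assert_that(all(classes$class %in% known), "unknown locus class label")
  assert_that(all(classes$count >= 0), "locus class counts must be >= 0")
  betas <- as.matrix(classes[, need[-(1:2)]])
  assert_that(all(is.finite(betas)), "locus effect sizes must be finite")
  rs <- classes$class == "ratio_specific" & classes$beta_tg_f != 0
  assert_that(all(sign(classes$beta_tg_f[rs]) == -sign(classes$beta_hdl_f[rs])),
              "ratio_specific loci must have opposite-signed TG and HDL effects")
  classes
}

#' Rare-variant specification for burden-test simulation
#'
#' Rare coding variants are simulated unlinked (independent binomial
#' dosages), separate from the common-variant LD blocks, reflecting an
#' exome-style call set. Each simulated gene carries `n_variants` variants
#' with deleteriousness votes from 0 to 5 prediction tools and a
#' protein-truncating (pLOF) flag on a subset. The planted burden effect is
#' applied to the log lipid ratio through the "maximum" collapsed genotype
#' over deleterious (>= 1 vote or pLOF) variants.
#'
#' @param n_variants variants per gene.
#' @param maf_range minor allele frequency range (all < 0.01 by default so
#'   every variant is burden-eligible).
#' @param burden_beta named numeric: planted per-gene burden effect on the
#'   log ratio, in phenotype-SD units. Defaults plant one effect gene
#'   (`RVG1`, 0.2 SD) and one null gene (`RVG2`).
#' @param n_plof number of pLOF-flagged variants per gene (these get 5/5
#'   votes).
#' @return list spec.
#' @export
rare_variant_spec <- function(n_variants = 12L,
                              maf_range = c(1e-4, 1e-3),
                              burden_beta = c(RVG1 = 0.2, RVG2 = 0),
                              n_plof = 2L) {
  assert_that(n_variants >= 1, "n_variants must be positive")
  assert_that(length(maf_range) == 2 && maf_range[1] > 0 && maf_range[2] < 0.5,
              "maf_range must lie in (0, 0.5)")
  assert_that(!is.null(names(burden_beta)) && all(nzchar(names(burden_beta))),
              "burden_beta must be a named numeric vector (one entry per gene)")
  assert_that(n_plof >= 0 && n_plof <= n_variants, "n_plof out of range")
  list(n_variants = as.integer(n_variants), maf_range = maf_range,
       burden_beta = burden_beta, n_plof = as.integer(n_plof))
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic cohort. Defaults describe the
#' reference study condition used throughout the package: 20,000 unrelated
#' individuals, 24 LD blocks of 20 SNPs with adjacent-SNP dosage
#' correlation 0.95 (emulating a dense imputed panel), block allele
#' frequencies drawn from (0.05, 0.5), 20 planted loci
#' (see [locus_classes()]), unit residual SD on the log-lipid scale, 54%
#' female, ages 40-69.
#'
#' @param n_individuals cohort size.
#' @param n_blocks number of LD blocks; planted loci occupy the first
#'   blocks, the final block hosts the expression-weight gene.
#' @param snps_per_block SNPs per block.
#' @param ld_decay target correlation between adjacent SNP dosages within a
#'   block, in `[0, 1)`; correlation decays approximately as
#'   `ld_decay^|i-j|` with distance.
#' @param maf_range range of the per-block effect-allele frequency (one
#'   frequency per block; SNPs in strong LD share allele frequencies).
#' @param classes locus-class table from [locus_classes()].
#' @param noise_sd residual SD of the log-lipid phenotypes.
#' @param rare rare-variant spec from [rare_variant_spec()].
#' @param mediation list with `a` (exposure to mediator path), `b`
#'   (mediator to outcome) and `c_direct` (direct path); defaults plant a
#'   mediated fraction `a*b / (a*b + c_direct)` of 0.5, the
#'   expression/adiposity scenario.
#' @param h2_expr heritability of the tissue-expression proxy.
#' @param seed integer RNG seed; identical configs with identical seeds
#'   reproduce the cohort exactly.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 20000L,
                       n_blocks = 24L,
                       snps_per_block = 20L,
                       ld_decay = 0.95,
                       maf_range = c(0.05, 0.5),
                       classes = locus_classes(),
                       noise_sd = 1,
                       rare = rare_variant_spec(),
                       mediation = list(a = 0.5, b = 0.4, c_direct = 0.2),
                       h2_expr = 0.3,
                       seed = 1L) {
  assert_that(n_individuals >= 2, "n_individuals must be >= 2")
  assert_that(n_blocks >= 1 && snps_per_block >= 1, "block dimensions must be positive")
  assert_that(is_scalar_number(ld_decay) && abs(ld_decay) < 1,
              "ld_decay must satisfy |ld_decay| < 1")
  assert_that(length(maf_range) == 2 && maf_range[1] > 0 && maf_range[2] <= 0.5,
              "maf_range must lie in (0, 0.5]")
  assert_that(is_scalar_number(noise_sd) && noise_sd > 0, "noise_sd must be > 0")
  classes <- locus_classes(classes)
  n_loci <- sum(classes$count)
  # one block per locus, and the last block is reserved for the expression gene
  if (n_loci > n_blocks - 1L)
    stop(sprintf("planted loci (%d) exceed available blocks (%d; one block is reserved for the expression gene)",
                 n_loci, n_blocks - 1L))
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_blocks = as.integer(n_blocks),
    snps_per_block = as.integer(snps_per_block),
    ld_decay = ld_decay, maf_range = maf_range,
    classes = classes, noise_sd = noise_sd, rare = rare,
    mediation = mediation, h2_expr = h2_expr,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# ---- Gaussian copula machinery ---------------------------------------------

# P(Z1 < t, Z2 < t) for standard bivariate normal with correlation a,
# by 1-D quadrature over the conditional normal.
#' @noRd
bvn_lower <- function(t, a) {
  if (abs(a) < 1e-12) return(stats::pnorm(t)^2)
  s <- sqrt(1 - a^2)
  f <- function(x) stats::pnorm((t - a * x) / s) * stats::dnorm(x)
  stats::integrate(f, -Inf, t, rel.tol = 1e-10)$value
}

#' Latent AR coefficient reproducing a target dosage correlation
#'
#' Thresholding a latent Gaussian at `qnorm(maf)` attenuates correlation,
#' so the latent AR(1) coefficient must exceed the target dosage
#' correlation. Solved by root finding on the tetrachoric-induced
#' indicator correlation (dosages are sums of two independent haplotype
#' indicators, which leaves the correlation unchanged).
#'
#' @param target desired correlation between adjacent SNP dosages.
#' @param maf shared allele frequency of the SNP pair.
#' @return latent correlation in `[0, 1)`.
#' @keywords internal
latent_ar_coef <- function(target, maf) {
  if (target == 0) return(0)
  assert_that(target > 0 && target < 1, "target dosage correlation must be in [0, 1)")
  t <- stats::qnorm(maf)
  v <- maf * (1 - maf)
  f <- function(a) (bvn_lower(t, a) - maf^2) / v - target
  stats::uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-9)$root
}

# Simulate one LD block of hard-call dosages for n individuals:
# two independent haplotype layers, each a latent AR(1) chain thresholded
# at qnorm(maf).
#' @noRd
simulate_block <- function(n, m, a, maf) {
  t <- stats::qnorm(maf)
  geno <- matrix(0L, n, m)
  s <- sqrt(1 - a^2)
  for (h in 1:2) {
    z <- stats::rnorm(n)
    geno[, 1] <- geno[, 1] + (z < t)
    if (m > 1) for (j in 2:m) {
      z <- a * z + s * stats::rnorm(n)
      geno[, j] <- geno[, j] + (z < t)
    }
  }
  geno
}

#' @noRd
standardize_dosage <- function(g, p) (g - 2 * p) / sqrt(2 * p * (1 - p))

#' Simulate unlinked rare coding variants for burden testing
#'
#' @param n number of individuals.
#' @param spec a [rare_variant_spec()].
#' @param seed optional seed (set it when calling outside
#'   [simulate_cohort()], which manages the RNG itself).
#' @return list with `genotypes` (n x variants integer dosage matrix),
#'   `variants` (data.frame: variant_id, gene, maf, votes, plof) and
#'   `burden_true` (n-vector of the planted max-collapsed deleterious
#'   genotype per gene, as a matrix with one column per gene).
#' @export
simulate_rare_variants <- function(n, spec = rare_variant_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- names(spec$burden_beta)
  tabs <- list(); mats <- list()
  for (g in genes) {
    k <- spec$n_variants
    maf <- stats::runif(k, spec$maf_range[1], spec$maf_range[2])
    plof <- rep(FALSE, k)
    if (spec$n_plof > 0) plof[seq_len(spec$n_plof)] <- TRUE
    votes <- ifelse(plof, 5L, sample(0:5, k, replace = TRUE))
    gm <- vapply(maf, function(p) stats::rbinom(n, 2L, p), integer(n))
    ids <- sprintf("%s_rv%02d", g, seq_len(k))
    colnames(gm) <- ids
    tabs[[g]] <- data.frame(variant_id = ids, gene = g, maf = maf,
                            votes = votes, plof = plof,
                            stringsAsFactors = FALSE)
    mats[[g]] <- gm
  }
  variants <- do.call(rbind, tabs); rownames(variants) <- NULL
  genotypes <- do.call(cbind, mats)
  burden_true <- vapply(genes, function(g) {
    v <- tabs[[g]]
    del <- v$variant_id[(v$plof | v$votes >= 1) & v$maf < 0.01]
    if (!length(del)) rep(0L, n) else
      apply(genotypes[, del, drop = FALSE], 1L, max)
  }, numeric(n))
  list(genotypes = genotypes, variants = variants, burden_true = burden_true)
}

#' Simulate a synthetic lipid-ratio cohort with planted ground truth
#'
#' Generates hard-call genotype dosages in LD blocks (Gaussian copula with
#' a calibrated latent AR(1) chain, thresholded to two haplotypes), then
#' builds `log(TG)` and `log(HDL)` as linear combinations of planted
#' per-sex SNP effects, covariate effects (age, sex), a mediated
#' expression/adiposity path, rare-variant burden effects, and Gaussian
#' noise. `TG` and `HDL` are returned on the natural (exponentiated)
#' scale, strictly positive. The ratio trait is never simulated directly;
#' it arises downstream as `log(TG) - log(HDL)`.
#'
#' @param config a [sim_config()].
#' @return list with elements `cohort` (fields `genotypes`, `phenotypes`,
#'   `snp_map`, `rare_genotypes`, `rare_variants`, `blocks`) and `truth`
#'   (fields `loci`, `genes`, `expression_weights`, `annotations`,
#'   `gene_models`, `config`). Deterministic given `config$seed`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  m <- config$snps_per_block
  B <- config$n_blocks

  # --- block layout: 4 blocks per chromosome, 5 kb SNP spacing -------------
  block_chr <- ((seq_len(B) - 1L) %/% 4L) + 1L
  block_off <- ((seq_len(B) - 1L) %% 4L) * 2000000L + 100000L
  maf_block <- stats::runif(B, config$maf_range[1], config$maf_range[2])

  geno <- matrix(0L, n, B * m)
  snp_map <- vector("list", B)
  for (b in seq_len(B)) {
    a <- latent_ar_coef(config$ld_decay, maf_block[b])
    idx <- ((b - 1L) * m + 1L):(b * m)
    geno[, idx] <- simulate_block(n, m, a, maf_block[b])
    pos <- block_off[b] + (seq_len(m) - 1L) * 5000L
    snp_map[[b]] <- data.frame(
      snp_id = paste0("rs", b * 1000L + seq_len(m)),
      chr = block_chr[b], pos = pos,
      ea = "A", oa = "G", eaf = NA_real_, block = b,
      stringsAsFactors = FALSE
    )
  }
  snp_map <- do.call(rbind, snp_map)
  colnames(geno) <- snp_map$snp_id
  snp_map$eaf <- colMeans(geno) / 2

  # --- covariates -----------------------------------------------------------
  sex <- ifelse(stats::runif(n) < 0.54, "female", "male")
  age <- sample(40:69, n, replace = TRUE)
  female <- sex == "female"

  # --- planted common-variant effects --------------------------------------
  cls <- config$classes
  loci <- cls[rep(seq_len(nrow(cls)), cls$count), , drop = FALSE]
  n_loci <- nrow(loci)
  loci$count <- NULL
  loci$block <- seq_len(n_loci)
  loci$locus_id <- sprintf("L%02d", seq_len(n_loci))
  causal_idx <- (loci$block - 1L) * m + (m %/% 2L + 1L)
  loci$causal_snp <- snp_map$snp_id[causal_idx]
  loci$chr <- snp_map$chr[causal_idx]
  loci$pos <- snp_map$pos[causal_idx]
  loci$target_gene <- sprintf("GENE%02dA", loci$block)
  rownames(loci) <- NULL

  g_tg <- rep(0, n); g_hdl <- rep(0, n)
  for (i in seq_len(n_loci)) {
    gs <- standardize_dosage(geno[, causal_idx[i]], maf_block[loci$block[i]])
    bt <- ifelse(female, loci$beta_tg_f[i], loci$beta_tg_m[i])
    bh <- ifelse(female, loci$beta_hdl_f[i], loci$beta_hdl_m[i])
    g_tg <- g_tg + bt * gs
    g_hdl <- g_hdl + bh * gs
  }

  # --- expression proxy, mediator ------------------------------------------
  expr_block <- B
  w <- c(0.5, -0.3, 0.4, 0.2)[seq_len(min(4L, m))]
  w_idx <- (expr_block - 1L) * m + seq_along(w)
  expr_snps <- snp_map$snp_id[w_idx]
  raw_score <- as.numeric(geno[, w_idx, drop = FALSE] %*% w)
  sc <- stats::sd(raw_score)
  score_std <- if (sc > 0) (raw_score - mean(raw_score)) / sc else raw_score * 0
  h2 <- config$h2_expr
  expr <- sqrt(h2) * score_std + sqrt(1 - h2) * stats::rnorm(n)
  med <- config$mediation
  bmi_std <- med$a * expr + sqrt(max(1 - med$a^2, 0)) * stats::rnorm(n)
  bmi <- 27 + 3 * bmi_std
  ratio_med <- med$b * bmi_std + med$c_direct * expr

  # --- rare-variant burden --------------------------------------------------
  rare <- simulate_rare_variants(n, config$rare)
  burden_beta <- config$rare$burden_beta
  ratio_burden <- as.numeric(rare$burden_true %*% burden_beta)

  # --- assemble phenotypes --------------------------------------------------
  ns <- config$noise_sd
  male <- as.numeric(!female)
  log_tg <- log(1.5) + 0.02 * (age - 55) / 10 + 0.10 * male +
    g_tg + (ratio_med + ratio_burden) / 2 + ns * stats::rnorm(n)
  log_hdl <- log(1.4) - 0.01 * (age - 55) / 10 - 0.08 * male +
    g_hdl - (ratio_med + ratio_burden) / 2 + ns * stats::rnorm(n)

  phenotypes <- data.frame(
    iid = sprintf("I%06d", seq_len(n)),
    TG = exp(log_tg), HDL = exp(log_hdl),
    sex = sex, age = age, bmi = bmi, expr = expr,
    stringsAsFactors = FALSE
  )

  # --- gene models (two genes per block, BED-style coordinates kept 1-based
  #     closed here; write_fixtures converts to BED6) ------------------------
  gm <- do.call(rbind, lapply(seq_len(B), function(b) {
    centre <- block_off[b] + (m %/% 2L) * 5000L
    data.frame(
      gene = c(sprintf("GENE%02dA", b), sprintf("GENE%02dB", b)),
      chr = block_chr[b],
      start = c(centre - 12000L, centre + 60000L),
      end = c(centre + 12000L, centre + 90000L),
      strand = c("+", "-"),
      stringsAsFactors = FALSE
    )
  }))

  # --- annotations for planted causal SNPs ---------------------------------
  ann_cat <- c(ratio_specific = "exonic_missense", tg_only = "promoter",
               hdl_only = "regulatory", shared_lipid = "finemapped_eqtl",
               sex_dimorphic = "none", null = "none")
  loci$annotation <- unname(ann_cat[loci$class])
  ann <- loci[loci$annotation != "none", c("causal_snp", "annotation", "target_gene")]
  annotations <- data.frame(
    snp_id = ann$causal_snp,
    category = ann$annotation,
    gene = ann$target_gene,
    votes = ifelse(ann$annotation == "exonic_missense", 5L, 0L),
    eqtl_beta = ifelse(ann$annotation == "finemapped_eqtl", 0.3, NA_real_),
    tissue = ifelse(ann$annotation == "finemapped_eqtl", "adipose", NA_character_),
    stringsAsFactors = FALSE
  )
  rownames(annotations) <- NULL

  expr_gene <- sprintf("GENE%02dA", expr_block)
  expression_weights <- data.frame(
    gene = expr_gene, tissue = "adipose",
    snp_id = expr_snps, ea = "A", weight = w,
    hsq = h2, hsq_p = 1e-4,
    stringsAsFactors = FALSE
  )

  med_frac <- med$a * med$b / (med$a * med$b + med$c_direct)
  genes_truth <- data.frame(
    gene = c(names(burden_beta), expr_gene),
    role = c(rep("burden", length(burden_beta)), "expression"),
    burden_beta = c(unname(burden_beta), NA_real_),
    mediated_fraction = c(rep(NA_real_, length(burden_beta)), med_frac),
    stringsAsFactors = FALSE
  )

  list(
    cohort = structure(list(
      genotypes = geno, phenotypes = phenotypes, snp_map = snp_map,
      rare_genotypes = rare$genotypes, rare_variants = rare$variants,
      blocks = data.frame(block = seq_len(B), chr = block_chr,
                          maf = maf_block, start = block_off)
    ), class = "cohort_data"),
    truth = structure(list(
      loci = loci[, c("locus_id", "class", "block", "chr", "pos", "causal_snp",
                      "beta_tg_f", "beta_hdl_f", "beta_tg_m", "beta_hdl_m",
                      "target_gene", "annotation")],
      genes = genes_truth,
      expression_weights = expression_weights,
      annotations = annotations,
      gene_models = gm,
      config = config
    ), class = "truth_set")
  )
}

#' Empirical LD matrix from cohort genotypes
#'
#' Pearson correlation (r, not r-squared) between dosages, the in-sample
#' analogue of a PLINK `--r square` matrix. Monomorphic SNPs get zero
#' off-diagonal correlation and unit diagonal.
#'
#' @param genotypes dosage matrix with SNP-id column names.
#' @param snps optional subset of SNP ids.
#' @return square correlation matrix with dimnames.
#' @export
ld_from_genotypes <- function(genotypes, snps = NULL) {
  if (!is.null(snps)) {
    missing <- setdiff(snps, colnames(genotypes))
    assert_that(!length(missing),
                paste("SNPs absent from genotypes:", paste(missing, collapse = ", ")))
    genotypes <- genotypes[, snps, drop = FALSE]
  }
  sds <- apply(genotypes, 2L, stats::sd)
  R <- suppressWarnings(stats::cor(genotypes))
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  R
}
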