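# Shared fixtures: everything is generated in code at test time.

# A small mixed-architecture cohort reused across test files (built once).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cls <- locus_classes(data.frame(
        class      = c("ratio_specific", "shared_lipid", "tg_only",
                       "hdl_only", "sex_dimorphic", "null"),
        count      = c(2L, 2L, 1L, 1L, 1L, 1L),
        beta_tg_f  = c(0.15, 0.15, 0.15, 0.00, 0.15, 0),
        beta_hdl_f = c(-0.15, 0.15, 0.00, 0.15, -0.15, 0),
        beta_tg_m  = c(0.15, 0.15, 0.15, 0.00, 0.03, 0),
        beta_hdl_m = c(-0.15, 0.15, 0.00, 0.15, -0.03, 0)))
      cfg <- sim_config(n_individuals = 3000, n_blocks = 10,
                        snps_per_block = 10, classes = cls, seed = 42)
      cache <<- simulate_cohort(cfg)
    }
    cache
  }
})

# Hand-built summary-statistic rows for locus-module tests.
toy_sumstats <- function(snp_id, chr, pos, beta, p,
                         ea = "A", oa = "G", eaf = 0.3, n = 1000,
                         trait = "TGHDL", stratum = "all") {
  data.frame(snp_id = snp_id, chromosome = chr, base_pair_location = pos,
             effect_allele = ea, other_allele = oa,
             effect_allele_frequency = eaf,
             beta = beta, standard_error = abs(beta) / sqrt(stats::qchisq(p, 1, lower.tail = FALSE)),
             p_value = p, mlog10_p = -log10(p), n = n,
             trait = trait, stratum = stratum, method = "ols", flag = "",
             stringsAsFactors = FALSE)
}

# Identity-ish LD matrix builder from explicit r values.
toy_ld <- function(ids, r = NULL) {
  p <- length(ids)
  R <- diag(p)
  dimnames(R) <- list(ids, ids)
  if (!is.null(r)) {
    for (k in seq_len(nrow(r))) {
      R[r$a[k], r$b[k]] <- R[r$b[k], r$a[k]] <- r$r[k]
    }
  }
  R
}

# Random PSD LD matrix from sampled genotypes (for fine-mapping oracles).
random_ld <- function(p, n = 400) {
  maf <- stats::runif(p, 0.1, 0.5)
  base <- stats::rbinom(n, 2, 0.5)
  G <- vapply(maf, function(q) {
    mix <- stats::rbinom(n, 1, 0.5)
    ifelse(mix == 1, base, stats::rbinom(n, 2, q))
  }, numeric(n))
  R <- stats::cor(G)
  dimnames(R) <- list(paste0("s", seq_len(p)), paste0("s", seq_len(p)))
  R
}

# Exhaustive single-causal-variant posterior: for each SNP j, the marginal
# likelihood of the full z vector under z ~ N(0, R + V r_j r_j'), against
# a uniform prior over j. Independent of the susie_rss code path.
enum_single_effect <- function(z, R, V) {
  p <- length(z)
  logdens <- function(S) {
    ch <- chol(S + diag(1e-10, p))
    -sum(log(diag(ch))) - 0.5 * sum(backsolve(ch, z, transpose = TRUE)^2)
  }
  lml <- vapply(seq_len(p), function(j) {
    rj <- R[, j]
    logdens(R + V * tcrossprod(rj))
  }, numeric(1))
  a <- exp(lml - max(lml))
  a / sum(a)
}
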