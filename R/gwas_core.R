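# Phenotype preparation, per-SNP association scan and genomic control.
# The scan is per-SNP OLS with covariates on an unrelated simulated cohort;
# outputs declare method = "ols" so downstream consumers know no
# whole-genome ridge / mixed-model machinery was applied.

#' Log-transform lipid traits and derive the ratio trait
#'
#' `TG` and the ratio trait are natural-log transformed; `HDL` is kept on
#' its raw scale (all three are subsequently inverse-rank normalized, so
#' monotone transforms of HDL are immaterial there). The ratio trait is
#' defined as `log(TG) - log(HDL)` and never computed from a simulated
#' ratio.
#'
#' @param phenotypes data.frame with strictly positive `TG` and `HDL`
#'   columns and an `iid` identifier.
#' @return the input with columns `trait_TG = log(TG)`, `trait_HDL = HDL`,
#'   `trait_TGHDL = log(TG) - log(HDL)` appended.
#' @export
log_transform_traits <- function(phenotypes) {
  assert_that(all(c("TG", "HDL") %in% names(phenotypes)),
              "phenotypes must have TG and HDL columns")
  bad <- which(!(phenotypes$TG > 0) | !(phenotypes$HDL > 0))
  if (length(bad)) {
    who <- if ("iid" %in% names(phenotypes)) phenotypes$iid[bad[1]] else bad[1]
    stop(sprintf("non-positive TG or HDL for individual %s (and %d others)",
                 who, length(bad) - 1L))
  }
  phenotypes$trait_TG <- log(phenotypes$TG)
  phenotypes$trait_HDL <- phenotypes$HDL
  phenotypes$trait_TGHDL <- log(phenotypes$TG) - log(phenotypes$HDL)
  phenotypes
}

#' Inverse rank-normal transformation (rankit)
#'
#' Maps the value of rank `r` among `n` to `qnorm((r - 0.5) / n)`; ties
#' share the mean of their ranks; output order matches input order.
#'
#' @param values numeric vector (>= 2 finite values, not all identical).
#' @return transformed vector, `NA` preserved in place.
#' @export
inverse_rank_normal <- function(values) {
  ok <- is.finite(values)
  x <- values[ok]
  assert_that(length(x) >= 2, "need at least 2 finite values")
  if (max(x) == min(x)) stop("rank transform undefined: all values identical")
  r <- rank(x, ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm((r - 0.5) / length(x))
  out
}

#' Per-SNP association scan by ordinary least squares
#'
#' For each SNP, fits `phenotype ~ dosage + covariates` and reports the
#' per-allele effect, its standard error and a two-sided p-value from the
#' large-sample normal. In sex strata the scan filters individuals and
#' drops sex from the covariates. Monomorphic SNPs are emitted with `NA`
#' effect and `flag = "monomorphic"` rather than dropped.
#'
#' P-values are carried both as `p_value` and `mlog10_p`
#' (`-log10 p`, computed from the normal log-tail so extreme associations
#' never underflow).
#'
#' @param genotypes dosage matrix (individuals x SNPs, SNP-id colnames).
#' @param phenotype numeric vector, already transformed and normalized.
#' @param snp_map data.frame with snp_id, chr, pos, ea, oa, eaf.
#' @param covariates optional data.frame/matrix; a `sex` column (factor or
#'   character) is expanded to an indicator and removed in sex strata.
#' @param stratum one of "all", "female", "male".
#' @param sex character vector ("female"/"male") required when
#'   `stratum != "all"` or when covariates include sex.
#' @param trait trait label stored in the output ("TG", "HDL", "TGHDL").
#' @return data.frame in the package's GWAS-SSF-like layout
#'   (see [write_sumstats()]).
#' @export
assoc_scan <- function(genotypes, phenotype, snp_map,
                       covariates = NULL, stratum = c("all", "female", "male"),
                       sex = NULL, trait = "TGHDL") {
  stratum <- match.arg(stratum)
  n_all <- nrow(genotypes)
  assert_that(length(phenotype) == n_all, "phenotype length != genotype rows")
  keep <- rep(TRUE, n_all)
  if (stratum != "all") {
    assert_that(!is.null(sex), "sex vector required for sex-stratified scans")
    keep <- sex == stratum
  }
  C <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if ("sex" %in% names(covariates)) {
      if (stratum == "all") {
        covariates$sex <- as.numeric(covariates$sex == "female")
      } else {
        covariates$sex <- NULL  # sex removed as a covariate in sex strata
      }
    }
    if (ncol(covariates)) C <- as.matrix(covariates[keep, , drop = FALSE])
  }
  y <- phenotype[keep]
  G <- genotypes[keep, , drop = FALSE]
  n <- length(y)

  # Frisch-Waugh: residualize once against (intercept, covariates)
  qrC <- qr(cbind(rep(1, n), C))
  assert_that(qrC$rank == ncol(cbind(rep(1, n), C)), "covariate matrix not full rank")
  yr <- qr.resid(qrC, y)
  Gr <- qr.resid(qrC, G)
  sxx <- colSums(Gr^2)
  sxy <- colSums(Gr * yr)
  syy <- sum(yr^2)
  mono <- apply(G, 2L, function(g) max(g) == min(g))
  df <- n - qrC$rank - 1L
  beta <- ifelse(mono, NA_real_, sxy / sxx)
  rss <- pmax(syy - ifelse(mono, 0, beta^2 * sxx), 0)
  se <- ifelse(mono, NA_real_, sqrt(rss / df / sxx))
  z <- beta / se
  logp <- stats::pnorm(-abs(z), log.p = TRUE) + log(2)
  mlog10 <- -logp / log(10)

  idx <- match(colnames(genotypes), snp_map$snp_id)
  assert_that(!anyNA(idx), "genotype columns missing from snp_map")
  out <- data.frame(
    snp_id = colnames(genotypes),
    chromosome = snp_map$chr[idx],
    base_pair_location = snp_map$pos[idx],
    effect_allele = snp_map$ea[idx],
    other_allele = snp_map$oa[idx],
    effect_allele_frequency = colMeans(G) / 2,
    beta = beta,
    standard_error = se,
    p_value = exp(logp),
    mlog10_p = mlog10,
    n = n,
    trait = trait,
    stratum = stratum,
    method = "ols",
    flag = ifelse(mono, "monomorphic", ""),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# ---- quality control -------------------------------------------------------

#' Exact Hardy-Weinberg mid-p value from hard genotype counts
#'
#' Wigginton-style exact test on the number of heterozygotes conditional
#' on allele counts, reported as a mid-p (half weight on the observed
#' configuration).
#'
#' @param n_aa,n_ab,n_bb genotype counts.
#' @return two-sided mid-p value.
#' @export
hwe_exact_midp <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  rare <- min(n_a, 2 * n - n_a)
  het_obs <- n_ab
  hets <- seq(rare %% 2, rare, by = 2)
  logprob <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    # h-dependent part of the conditional multinomial; constants in h cancel
    # in the normalization below
    lchoose(n, h) + lchoose(n - h, hom_r) + h * log(2)
  }, numeric(1))
  # normalize in log space, then mid-p over configurations as extreme as obs
  logprob <- logprob - logsumexp(logprob)
  p <- exp(logprob)
  p_obs <- p[hets == het_obs]
  sum(p[p < p_obs]) + 0.5 * p_obs + 0.5 * sum(p[p == p_obs & hets != het_obs])
}

#' Cohort and summary-statistic quality control
#'
#' Applies the standard lipid-GWAS filters with defaults: SNP call rate
#' > 0.98, MAF > 0.001, Hardy-Weinberg exact mid-p > 5e-8 (hard calls;
#' a chi-square 1-df test would be used if only expected dosages existed),
#' sample call rate > 0.95, sample heterozygosity < median + 3 IQR. An
#' INFO-score threshold is accepted for interface compatibility but inert
#' on hard-call synthetic genotypes. Surviving records are returned
#' unchanged; only membership changes.
#'
#' @param cohort a `cohort_data` object (or a list with `genotypes`,
#'   `snp_map`, `phenotypes`).
#' @param snp_call_rate,maf_min,hwe_p_min,sample_call_rate,het_iqr_mult,info_min
#'   thresholds.
#' @return list with filtered `genotypes`, `snp_map`, `phenotypes`,
#'   `sample_keep` logical, and `exclusions` (a per-filter count log).
#' @export
qc_filter <- function(cohort,
                      snp_call_rate = 0.98, maf_min = 0.001, hwe_p_min = 5e-8,
                      sample_call_rate = 0.95, het_iqr_mult = 3,
                      info_min = 0.4) {
  G <- cohort$genotypes
  n <- nrow(G)
  # sample filters first (mirrors the usual order: samples, then SNPs)
  s_call <- rowMeans(!is.na(G))
  het <- rowMeans(G == 1, na.rm = TRUE)
  het_cut <- stats::median(het) + het_iqr_mult * stats::IQR(het)
  keep_s <- s_call > sample_call_rate & het <= het_cut
  n_low_call_s <- sum(s_call <= sample_call_rate)
  n_high_het <- sum(het > het_cut & s_call > sample_call_rate)
  G2 <- G[keep_s, , drop = FALSE]

  call <- colMeans(!is.na(G2))
  eaf <- colMeans(G2, na.rm = TRUE) / 2
  maf <- pmin(eaf, 1 - eaf)
  hwe <- vapply(seq_len(ncol(G2)), function(j) {
    g <- G2[, j]; g <- g[!is.na(g)]
    cnt <- tabulate(g + 1L, nbins = 3L)
    if (min(cnt[1], cnt[3]) == (cnt[1] + cnt[2] + cnt[3])) return(1)
    hwe_exact_midp(cnt[3], cnt[2], cnt[1])
  }, numeric(1))

  fail_call <- call <= snp_call_rate
  fail_maf <- !fail_call & maf <= maf_min
  fail_hwe <- !fail_call & !fail_maf & hwe <= hwe_p_min
  keep_v <- !(fail_call | fail_maf | fail_hwe)

  exclusions <- data.frame(
    filter = c("sample_call_rate", "sample_heterozygosity",
               "snp_call_rate", "snp_maf", "snp_hwe"),
    threshold = c(sample_call_rate, het_cut, snp_call_rate, maf_min, hwe_p_min),
    n_excluded = c(n_low_call_s, n_high_het,
                   sum(fail_call), sum(fail_maf), sum(fail_hwe)),
    stringsAsFactors = FALSE
  )
  list(
    genotypes = G2[, keep_v, drop = FALSE],
    snp_map = cohort$snp_map[match(colnames(G2)[keep_v], cohort$snp_map$snp_id), ,
                             drop = FALSE],
    phenotypes = if (!is.null(cohort$phenotypes))
      cohort$phenotypes[keep_s, , drop = FALSE] else NULL,
    sample_keep = keep_s,
    exclusions = exclusions
  )
}

#' Genomic control correction
#'
#' The inflation factor is the median 1-df chi-square statistic implied by
#' the p-values divided by the null median `qchisq(0.5, 1)` (0.4549364).
#' When lambda > 1 every statistic is divided by lambda and p-values are
#' recomputed; no deflation is applied when lambda <= 1.
#'
#' @param pvalues numeric vector in (0, 1].
#' @return list with `lambda_gc`, `p_corrected`, `chisq`, `chisq_corrected`.
#' @export
genomic_control <- function(pvalues) {
  assert_that(length(pvalues) > 0, "empty p-value vector")
  assert_that(all(pvalues > 0 & pvalues <= 1), "p-values must lie in (0, 1]")
  chisq <- stats::qchisq(pvalues, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  if (lambda > 1) {
    chisq_c <- chisq / lambda
    p_c <- stats::pchisq(chisq_c, df = 1, lower.tail = FALSE)
  } else {
    chisq_c <- chisq
    p_c <- pvalues
  }
  list(lambda_gc = lambda, p_corrected = p_c,
       chisq = chisq, chisq_corrected = chisq_c)
}
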