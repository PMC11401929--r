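# The two bespoke locus-level statistics: the ratio "boost score" with
# top-quartile selection, and the sex-dimorphism contrast on stratified
# effect estimates. All p-value arithmetic runs in -log10 space so
# associations far below double-precision underflow (p ~ 1e-1952) remain
# exactly representable.

#' Ratio boost score
#'
#' `BS = -log10(p_ratio) - max(-log10(p_TG), -log10(p_HDL))` at a locus
#' lead SNP. Positive scores mean the ratio trait is more strongly
#' associated than either component lipid, the signature of an
#' insulin-resistance (rather than pure lipid) locus.
#'
#' Inputs may be p-values or, to avoid underflow for extreme associations,
#' `-log10 p` directly (`log10p = TRUE`). `p = 0` is an error on the
#' p-value path; pass the exponent via the `-log10` path instead.
#'
#' @param p_ratio,p_tg,p_hdl p-values (or `-log10` p-values) for the
#'   ratio and component traits; vectorized.
#' @param log10p if `TRUE` inputs are already `-log10 p`.
#' @return numeric boost score(s).
#' @export
boost_score <- function(p_ratio, p_tg, p_hdl, log10p = FALSE) {
  if (!log10p) {
    for (p in list(p_ratio, p_tg, p_hdl))
      assert_that(all(p > 0 & p <= 1),
                  "p-values must lie in (0, 1]; for p below underflow use log10p = TRUE")
    p_ratio <- -log10(p_ratio); p_tg <- -log10(p_tg); p_hdl <- -log10(p_hdl)
  }
  p_ratio - pmax(p_tg, p_hdl)
}

#' Rank loci by boost score and flag the top quartile
#'
#' Loci are ranked descending by boost score and the top `floor(n * (1 -
#' quartile))` are flagged (for the default quartile 0.75, the top
#' `floor(n/4)`). Ties at the cutoff are broken in favour of the smaller
#' ratio p-value (larger `mlog10p_tghdl`). The implied boost-score
#' threshold (minimum flagged score) and the count of positive scores are
#' reported as attributes.
#'
#' @param boost data.frame with columns `locus_id`, `boost_score` and
#'   (for tie-breaking) `mlog10p_tghdl`.
#' @param quartile selection quantile; 0.75 keeps the top quarter.
#' @return the input with `rank` and `top_quartile` columns, ordered by
#'   rank; attributes `threshold` (implied boost cutoff), `n_flagged`,
#'   `n_positive`.
#' @export
select_boosted <- function(boost, quartile = 0.75) {
  n <- nrow(boost)
  assert_that(n >= 1, "need at least one locus")
  tie <- if ("mlog10p_tghdl" %in% names(boost)) -boost$mlog10p_tghdl else
    seq_len(n)
  ord <- order(-boost$boost_score, tie, boost$locus_id)
  boost <- boost[ord, , drop = FALSE]
  boost$rank <- seq_len(n)
  k <- floor(n * (1 - quartile))
  boost$top_quartile <- boost$rank <= k
  rownames(boost) <- NULL
  attr(boost, "threshold") <- if (k >= 1) boost$boost_score[k] else NA_real_
  attr(boost, "n_flagged") <- k
  attr(boost, "n_positive") <- sum(boost$boost_score > 0)
  boost
}

#' Sex-dimorphism t-statistic
#'
#' Contrast of female and male stratified effect estimates:
#' `t = (beta_f - beta_m) / sqrt(se_f^2 + se_m^2)`. A positive statistic
#' indicates a larger (more trait-raising) effect in females.
#'
#' @param beta_f,se_f,beta_m,se_m stratified effects and standard errors
#'   (vectorized; `se > 0`).
#' @return t-statistic(s).
#' @export
sexdim_t <- function(beta_f, se_f, beta_m, se_m) {
  assert_that(all(se_f > 0) && all(se_m > 0), "standard errors must be > 0")
  (beta_f - beta_m) / sqrt(se_f^2 + se_m^2)
}

#' Sex-dimorphism p-value and Bonferroni call
#'
#' Two-sided tail of the standard normal at `|t|` (the large-sample limit
#' of the Student contrast; GWAS degrees of freedom make the two
#' indistinguishable). Significance is declared at `alpha / n_loci`.
#'
#' @param t t-statistic(s) from [sexdim_t()].
#' @param n_loci number of loci tested (Bonferroni denominator).
#' @param alpha family-wise level.
#' @return data.frame with `t`, `p`, `significant`.
#' @export
sexdim_p <- function(t, n_loci, alpha = 0.05) {
  assert_that(all(is.finite(t)), "t must be finite")
  p <- 2 * stats::pnorm(-abs(t))
  data.frame(t = t, p = p, significant = p < alpha / n_loci)
}

#' Sex-dimorphism test for a locus table
#'
#' Convenience wrapper: looks up each locus lead SNP in the female and
#' male stratified scans and applies [sexdim_t()] / [sexdim_p()].
#'
#' @param loci a `locus_set`.
#' @param ss_f,ss_m female and male stratified summary statistics.
#' @param alpha family-wise level for the Bonferroni call over the loci.
#' @return data.frame: locus_id, lead_snp, beta_f, se_f, beta_m, se_m,
#'   t, p, significant.
#' @export
sexdim_test <- function(loci, ss_f, ss_m, alpha = 0.05) {
  tab <- loci$table
  fi <- match(tab$lead_snp, ss_f$snp_id)
  mi <- match(tab$lead_snp, ss_m$snp_id)
  beta_f <- ss_f$beta[fi]; se_f <- ss_f$standard_error[fi]
  beta_m <- ss_m$beta[mi]; se_m <- ss_m$standard_error[mi]
  ok <- is.finite(beta_f) & is.finite(beta_m) & se_f > 0 & se_m > 0
  t <- rep(NA_real_, nrow(tab))
  t[ok] <- sexdim_t(beta_f[ok], se_f[ok], beta_m[ok], se_m[ok])
  p <- 2 * stats::pnorm(-abs(t))
  data.frame(locus_id = tab$locus_id, lead_snp = tab$lead_snp,
             beta_f = beta_f, se_f = se_f, beta_m = beta_m, se_m = se_m,
             t = t, p = p,
             significant = !is.na(p) & p < alpha / nrow(tab),
             stringsAsFactors = FALSE)
}
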