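# Orthogonal gene-level corroboration: nested rare-variant burden masks
# and tests, predicted-expression (TWAS-style) association, and the
# proportion of an exposure effect mediated by an intermediate variable.

#' Build nested loss-of-function burden masks
#'
#' Four masks of decreasing stringency per gene, all restricted to
#' `maf < maf_cap` (the uniform cap guarantees nesting):
#' \describe{
#'   \item{plof}{protein-truncating variants only}
#'   \item{high_confidence}{pLOF plus variants called deleterious by all
#'     five prediction tools (votes = 5)}
#'   \item{moderate_confidence}{pLOF plus variants called deleterious by
#'     at least one tool (votes >= 1)}
#'   \item{all_rare}{every rare variant}
#' }
#'
#' @param variants data.frame: variant_id, gene, maf, votes (0-5), plof
#'   (logical).
#' @param maf_cap uniform frequency cap (default 0.01).
#' @return data.frame of masks: gene, stringency, n_variants, maf_cap,
#'   with a `variant_ids` list-column.
#' @export
build_masks <- function(variants, maf_cap = 0.01) {
  assert_that(all(c("variant_id", "gene", "maf", "votes", "plof") %in%
                    names(variants)), "variant table missing required columns")
  assert_that(all(variants$votes >= 0 & variants$votes <= 5),
              "votes must lie in 0..5")
  rare <- variants[variants$maf < maf_cap, , drop = FALSE]
  rows <- list()
  for (g in unique(variants$gene)) {
    v <- rare[rare$gene == g, , drop = FALSE]
    sets <- list(
      plof = v$variant_id[v$plof],
      high_confidence = v$variant_id[v$plof | v$votes == 5],
      moderate_confidence = v$variant_id[v$plof | v$votes >= 1],
      all_rare = v$variant_id
    )
    for (s in names(sets)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, stringency = s, n_variants = length(sets[[s]]),
        maf_cap = maf_cap, stringsAsFactors = FALSE)
      rows[[length(rows)]]$variant_ids <- list(sets[[s]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Collapse a mask to a per-individual burden genotype ("maximum method")
#'
#' `burden_i = max_j dosage_ij` over the mask's variants: carrier status
#' on the 0/1/2 dosage scale, not an allele count sum.
#'
#' @param genotypes rare-variant dosage matrix (individuals x variants,
#'   variant-id colnames).
#' @param variant_ids character vector of mask member variants (non-empty).
#' @return integer vector in 0..2.
#' @export
burden_collapse <- function(genotypes, variant_ids) {
  assert_that(length(variant_ids) >= 1,
              "empty mask: no variants to collapse (distinct from a zero-carrier result)")
  missing <- setdiff(variant_ids, colnames(genotypes))
  assert_that(!length(missing),
              paste("mask variants absent from genotypes:", paste(missing, collapse = ", ")))
  G <- genotypes[, variant_ids, drop = FALSE]
  apply(G, 1L, max)
}

#' Burden association test
#'
#' OLS of the (inverse-rank-normalized) phenotype on the collapsed burden
#' genotype plus covariates, optionally conditioning on named common
#' variants by adding their dosages as covariates.
#'
#' @param burden collapsed burden genotype from [burden_collapse()].
#' @param phenotype transformed phenotype vector.
#' @param covariates optional covariate matrix/data.frame.
#' @param condition_on optional dosage matrix of common variants to
#'   condition on (columns named by snp_id).
#' @return list: beta, se, p, n, n_carriers, conditioned_on; all-`NA`
#'   effect with `reason = "zero carriers"` when nobody carries the mask.
#' @export
burden_test <- function(burden, phenotype, covariates = NULL,
                        condition_on = NULL) {
  n_carriers <- sum(burden > 0, na.rm = TRUE)
  cond_names <- if (!is.null(condition_on)) colnames(condition_on) else character(0)
  if (n_carriers == 0) {
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                n = length(phenotype), n_carriers = 0L,
                conditioned_on = cond_names, reason = "zero carriers"))
  }
  C <- covariates
  if (!is.null(condition_on)) {
    C <- if (is.null(C)) as.matrix(condition_on) else
      cbind(as.matrix(C), as.matrix(condition_on))
  }
  fit <- ols_single(phenotype, burden, C)
  list(beta = fit$beta, se = fit$se, p = fit$p, n = fit$n,
       n_carriers = n_carriers, conditioned_on = cond_names, reason = NULL)
}

#' Predicted gene-expression score per individual
#'
#' FUSION-style linear score: the weighted sum of effect-allele dosages
#' over the weight SNPs divided by each individual's count of non-missing
#' weight SNPs. Genotype orientation is harmonized to the weight's effect
#' allele (dosage flipped to `2 - g` when the alleles are swapped).
#'
#' @param weights data.frame: snp_id, ea, weight (one gene/tissue).
#' @param genotypes dosage matrix with snp_id colnames.
#' @param snp_map data.frame with snp_id, ea, oa giving the genotype
#'   orientation; if `NULL`, genotypes are assumed weight-oriented.
#' @return numeric score vector (one per individual).
#' @export
predict_expression <- function(weights, genotypes, snp_map = NULL) {
  present <- weights$snp_id %in% colnames(genotypes)
  if (!any(present))
    stop("no weight SNPs present in genotypes; missing: ",
         paste(weights$snp_id, collapse = ", "))
  w <- weights[present, , drop = FALSE]
  G <- genotypes[, w$snp_id, drop = FALSE]
  if (!is.null(snp_map)) {
    gm <- snp_map[match(w$snp_id, snp_map$snp_id), , drop = FALSE]
    flip <- !is.na(gm$ea) & gm$ea != w$ea & gm$oa == w$ea
    bad <- !is.na(gm$ea) & gm$ea != w$ea & gm$oa != w$ea
    assert_that(!any(bad), paste("allele mismatch for weight SNP(s):",
                                 paste(w$snp_id[bad], collapse = ", ")))
    if (any(flip)) G[, flip] <- 2 - G[, flip]
  }
  nonmiss <- rowSums(!is.na(G))
  Gz <- G
  Gz[is.na(Gz)] <- 0
  num <- as.numeric(Gz %*% w$weight)
  ifelse(nonmiss > 0, num / nonmiss, NA_real_)
}

#' Association of predicted expression with a phenotype
#'
#' OLS of the normalized phenotype on the predicted-expression score plus
#' covariates. A negative t-statistic means higher predicted expression
#' accompanies a lower trait value.
#'
#' @param scores predicted-expression scores from [predict_expression()].
#' @param phenotype transformed phenotype.
#' @param covariates optional covariates.
#' @param obs_weights optional observation weights (hook for weighted
#'   least squares; default unweighted).
#' @return list: beta, se, t, p, n; `NA` with a reason for constant
#'   scores.
#' @export
twas_assoc <- function(scores, phenotype, covariates = NULL,
                       obs_weights = NULL) {
  if (max(scores, na.rm = TRUE) == min(scores, na.rm = TRUE)) {
    return(list(beta = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_,
                n = sum(is.finite(scores)), reason = "constant scores"))
  }
  if (!is.null(obs_weights)) {
    sw <- sqrt(obs_weights)
    fit <- ols_single(phenotype * sw, scores * sw,
                      if (is.null(covariates)) matrix(sw) else
                        cbind(as.matrix(covariates) * sw, sw))
  } else {
    fit <- ols_single(phenotype, scores, covariates)
  }
  list(beta = fit$beta, se = fit$se, t = fit$z, p = fit$p, n = fit$n,
       reason = NULL)
}

#' Proportion of an exposure effect mediated by an intermediate variable
#'
#' Difference-of-coefficients estimator over nested linear models: the
#' total effect `c` from `outcome ~ exposure`, the direct effect `c'`
#' from `outcome ~ exposure + mediator`, and
#' `proportion = (c - c') / c`, with a seeded nonparametric bootstrap
#' percentile interval. For purely linear models this point estimate
#' coincides with the product-of-paths estimator.
#'
#' @param outcome,exposure,mediator numeric vectors (n > 10).
#' @param n_boot bootstrap resamples for the CI.
#' @param seed RNG seed for the bootstrap.
#' @param conf CI level.
#' @param tol minimum |total effect| below which the proportion is
#'   undefined.
#' @return list: proportion, ci (length 2), total, direct, undefined
#'   flag.
#' @export
mediation_proportion <- function(outcome, exposure, mediator,
                                 n_boot = 1000, seed = 1, conf = 0.95,
                                 tol = 1e-8) {
  n <- length(outcome)
  assert_that(n > 10 && length(exposure) == n && length(mediator) == n,
              "need n > 10 observations with matching lengths")
  est <- function(idx) {
    y <- outcome[idx]; x <- exposure[idx]; m <- mediator[idx]
    cc <- ols_single(y, x)$beta
    cp <- ols_single(y, x, cbind(m))$beta
    c(total = cc, direct = cp)
  }
  e <- est(seq_len(n))
  if (!is.finite(e["total"]) || abs(e["total"]) < tol) {
    warning("total effect below tolerance; proportion mediated undefined")
    return(list(proportion = NA_real_, ci = c(NA_real_, NA_real_),
                total = e[["total"]], direct = e[["direct"]],
                undefined = TRUE))
  }
  prop <- (e[["total"]] - e[["direct"]]) / e[["total"]]
  if (n_boot > 0) {
    set.seed(seed)
    boots <- replicate(n_boot, {
      idx <- sample.int(n, n, replace = TRUE)
      b <- est(idx)
      if (abs(b["total"]) < tol) NA_real_ else
        (b[["total"]] - b[["direct"]]) / b[["total"]]
    })
    a <- (1 - conf) / 2
    ci <- stats::quantile(boots, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  list(proportion = prop, ci = ci, total = e[["total"]],
       direct = e[["direct"]], undefined = FALSE)
}
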