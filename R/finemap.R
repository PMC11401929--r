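# Summary-statistic Bayesian fine-mapping: the sum of single effects
# model fitted to z-scores and an LD matrix over a 1 Mb locus window,
# yielding per-SNP posterior inclusion probabilities and 95% credible
# sets filtered by LD purity.

#' Extract the fine-mapping window around a lead SNP
#'
#' Takes every SNP within `window/2` of the lead (closed interval, same
#' chromosome), forms `z = beta / se`, and aligns both z and the LD
#' submatrix to the LD matrix ordering. SNPs present in the summary
#' statistics but absent from the LD matrix (or with undefined z) are
#' dropped with a logged count.
#'
#' @param sumstats summary-statistic data.frame.
#' @param lead_snp snp_id of the lead SNP (must be present).
#' @param ld square LD (r) matrix with SNP-id dimnames.
#' @param window total window width in bp (1 Mb default: lead +/- 500 kb).
#' @return list with `z` (named vector), `R` (aligned LD submatrix),
#'   `snp_ids`, `lead_snp`, `n_dropped`.
#' @export
extract_window <- function(sumstats, lead_snp, ld, window = 1e6) {
  li <- match(lead_snp, sumstats$snp_id)
  assert_that(!is.na(li), paste("lead SNP not in sumstats:", lead_snp))
  chr <- sumstats$chromosome[li]
  pos <- sumstats$base_pair_location[li]
  half <- window / 2
  inw <- sumstats$chromosome == chr &
    abs(sumstats$base_pair_location - pos) <= half
  win <- sumstats[inw, , drop = FALSE]
  win$z <- win$beta / win$standard_error
  usable <- win$snp_id[is.finite(win$z) & win$snp_id %in% colnames(ld)]
  n_dropped <- nrow(win) - length(usable)
  if (n_dropped > 0)
    message(sprintf("extract_window: dropped %d SNP(s) absent from LD or with undefined z",
                    n_dropped))
  ord <- colnames(ld)[colnames(ld) %in% usable]  # LD matrix ordering
  z <- win$z[match(ord, win$snp_id)]
  names(z) <- ord
  list(z = z, R = ld[ord, ord, drop = FALSE], snp_ids = ord,
       lead_snp = lead_snp, n_dropped = n_dropped)
}

#' Sum of single effects fine-mapping from summary statistics
#'
#' Iterative Bayesian single-effect regression on z-scores: the model is a
#' sum of `L` single effects, each placing all its mass on one SNP. For
#' effect `l` the algorithm residualizes z against the other effects'
#' posterior means, computes a per-SNP Bayes factor under a normal effect
#' prior, and sets the effect's inclusion vector proportional to prior
#' times Bayes factor. Deterministic; convergence is declared when the
#' maximum absolute change in PIP drops below `tol`. A variational
#' objective trace is recorded for diagnostics.
#'
#' The effect-size prior variance is specified on the standardized
#' (`z/sqrt(n)`) scale; internally the z-scale prior variance is
#' `n * prior_variance`, or `z_prior_variance` directly when the sample
#' size is not supplied. With `estimate_prior_variance = TRUE` each
#' effect's prior variance is instead estimated by maximizing its
#' single-effect Bayes factor, and an effect whose best Bayes factor does
#' not beat the null is zeroed out (so it reports no credible set) — the
#' behaviour of the reference implementation's default.
#'
#' @param z named z-score vector.
#' @param R LD (r) matrix aligned to `z`; symmetric with unit diagonal.
#'   Non-positive-semidefinite input is ridge-regularized (diagonal
#'   + 1e-6) with a warning.
#' @param n GWAS sample size behind `z` (sets the prior scale).
#' @param L maximum number of effects.
#' @param prior_variance per-effect prior variance on the standardized
#'   scale (default 0.04).
#' @param z_prior_variance z-scale prior variance used when `n` is
#'   missing (default 200).
#' @param estimate_prior_variance estimate each effect's prior variance
#'   from the data (with a null check) instead of using the fixed value.
#' @param coverage credible-set coverage level.
#' @param min_purity minimum absolute pairwise correlation within a
#'   reported credible set.
#' @param tol convergence tolerance on the max absolute PIP change.
#' @param max_iter iteration cap; non-convergence returns the partial fit
#'   with `converged = FALSE`.
#' @return object of class `susie_fit`: `alpha` (L x p inclusion matrix,
#'   rows sum to 1), `mu` (posterior effect means, z scale),
#'   `pip` (`1 - prod_l(1 - alpha_lj)`), `credible_sets` (list of sets
#'   with achieved coverage and purity), `lbf_effect` (per-effect log
#'   Bayes factor), `n_iter`, `converged`, `elbo`.
#' @export
susie_rss <- function(z, R, n = NULL, L = 10,
                      prior_variance = 0.04, z_prior_variance = 200,
                      estimate_prior_variance = FALSE,
                      coverage = 0.95, min_purity = 0.5,
                      tol = 1e-3, max_iter = 100) {
  p <- length(z)
  assert_that(p >= 1 && all(is.finite(z)), "z must be finite and non-empty")
  assert_that(L >= 1, "L must be >= 1")
  R <- as.matrix(R)
  assert_that(nrow(R) == p && ncol(R) == p, "R dimensions must match z")
  assert_that(max(abs(R - t(R))) < 1e-8, "R must be symmetric")
  ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) {
    warning("LD matrix not positive semidefinite; ridge-regularizing diagonal by 1e-6")
    R <- R + diag(1e-6, p)
  }
  V0 <- if (!is.null(n)) n * prior_variance else z_prior_variance
  L <- min(L, p) # cannot support more single effects than SNPs

  # total log BF of one single effect with prior variance v, given
  # residualized z-scores r (uniform prior over SNPs)
  lbf_total <- function(v, r) {
    if (v <= 0) return(0)
    logsumexp(-0.5 * log1p(v) + 0.5 * (v / (1 + v)) * r^2) - log(p)
  }

  alpha <- matrix(1 / p, L, p)
  mu <- matrix(0, L, p)
  b <- alpha * mu                # per-effect posterior mean vectors
  bbar <- colSums(b)
  pip_old <- rep(0, p)
  elbo <- numeric(0)
  converged <- FALSE
  it <- 0L

  V_l <- rep(V0, L)        # per-effect prior variance (z scale)
  lbf_effect <- rep(0, L)  # per-effect total log Bayes factor vs null
  for (it in seq_len(max_iter)) {
    for (l in seq_len(L)) {
      r_l <- z - as.numeric(R %*% (bbar - b[l, ]))
      if (estimate_prior_variance) {
        opt <- stats::optimize(function(lv) -lbf_total(exp(lv), r_l),
                               interval = c(-10, 12))
        v <- exp(opt$minimum)
        # null check: keep the effect only if its best BF beats the null
        V_l[l] <- if (-opt$objective > 0) v else 0
      }
      v <- V_l[l]
      if (v == 0) {
        lbf_effect[l] <- 0
        alpha[l, ] <- 1 / p
        mu[l, ] <- 0
        bbar <- bbar - b[l, ]
        b[l, ] <- 0
        next
      }
      shrink <- v / (1 + v)
      lbf <- -0.5 * log1p(v) + 0.5 * shrink * r_l^2
      lbf_effect[l] <- logsumexp(lbf) - log(p)
      a <- exp(lbf - logsumexp(lbf))
      a <- a / sum(a)
      alpha[l, ] <- a
      mu[l, ] <- shrink * r_l
      bnew <- a * mu[l, ]
      bbar <- bbar - b[l, ] + bnew
      b[l, ] <- bnew
    }
    # variational objective (up to a constant in z)
    quad <- as.numeric(t(bbar) %*% R %*% bbar)
    kl <- 0
    for (l in seq_len(L)) {
      if (V_l[l] == 0) next
      s2 <- V_l[l] / (1 + V_l[l])
      quad <- quad - as.numeric(t(b[l, ]) %*% R %*% b[l, ]) +
        sum(alpha[l, ] * (mu[l, ]^2 + s2))
      a <- alpha[l, ]
      nz <- a > 0
      kl <- kl + sum(a[nz] * (log(a[nz] * p) +
        0.5 * (log(V_l[l] / s2) + (s2 + mu[l, nz]^2) / V_l[l] - 1)))
    }
    elbo <- c(elbo, sum(z * bbar) - 0.5 * quad - kl)

    pip <- 1 - apply(1 - alpha, 2L, prod)
    if (max(abs(pip - pip_old)) < tol) { converged <- TRUE; break }
    pip_old <- pip
  }
  pip <- 1 - apply(1 - alpha, 2L, prod)
  names(pip) <- names(z)
  colnames(alpha) <- names(z)
  colnames(mu) <- names(z)

  # with a fixed prior variance every effect reports a (purity-filtered)
  # set, as in the reference implementation; the null check only applies
  # when the prior variance is estimated
  lbf_filter <- if (estimate_prior_variance) lbf_effect else NULL
  credible_sets <- build_credible_sets(alpha, R, coverage, min_purity,
                                       lbf_filter)
  structure(list(alpha = alpha, mu = mu, pip = pip,
                 credible_sets = credible_sets, lbf_effect = lbf_effect,
                 n_iter = it, converged = converged, elbo = elbo,
                 prior_variance = prior_variance, z_prior_variance = V_l,
                 estimate_prior_variance = estimate_prior_variance,
                 coverage = coverage, min_purity = min_purity),
            class = "susie_fit")
}

# Per-effect minimal-cardinality sets reaching the coverage level,
# filtered by LD purity (min |r| among members) and by the effect's
# single-effect Bayes factor against the null, deduplicated.
#' @noRd
build_credible_sets <- function(alpha, R, coverage, min_purity,
                                lbf_effect = NULL, null_threshold = 0) {
  sets <- list()
  seen <- character(0)
  for (l in seq_len(nrow(alpha))) {
    if (!is.null(lbf_effect) && lbf_effect[l] <= null_threshold) next
    a <- alpha[l, ]
    ord <- order(a, decreasing = TRUE)
    k <- which(cumsum(a[ord]) >= coverage)[1]
    if (is.na(k)) k <- length(a)
    idx <- sort(ord[seq_len(k)])
    purity <- if (length(idx) == 1) 1 else
      min(abs(R[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))]))
    if (purity < min_purity) next
    key <- paste(idx, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    sets[[length(sets) + 1L]] <- list(
      cs_id = sprintf("cs_%d", length(sets) + 1L),
      effect = l,
      snps = colnames(alpha)[idx],
      coverage = sum(a[idx]),
      purity = purity)
  }
  sets
}

#' @export
print.susie_fit <- function(x, ...) {
  cat(sprintf("susie_fit: %d SNPs, %d effect(s), %d credible set(s), %s after %d iteration(s)\n",
              ncol(x$alpha), nrow(x$alpha), length(x$credible_sets),
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Flag putative causal variants by posterior inclusion probability
#'
#' @param fit a `susie_fit`.
#' @param pip_threshold strict threshold; SNPs with `pip > threshold` are
#'   returned (a PIP of exactly the threshold is not flagged).
#' @return character vector of snp_ids (possibly empty: no causal variant
#'   at the locus).
#' @export
causal_variants <- function(fit, pip_threshold = 0.1) {
  stopifnot(inherits(fit, "susie_fit"))
  names(fit$pip)[fit$pip > pip_threshold]
}

#' Tabulate a fine-mapping fit as TSV-ready data.frames
#'
#' @param fit a `susie_fit`.
#' @return list with `snps` (snp_id, pip, cs_id) and `sets`
#'   (cs_id, coverage, purity, n_snps, members).
#' @export
finemap_tables <- function(fit) {
  cs_of <- rep(NA_character_, length(fit$pip))
  names(cs_of) <- names(fit$pip)
  for (s in fit$credible_sets) cs_of[s$snps] <- s$cs_id
  snps <- data.frame(snp_id = names(fit$pip), pip = unname(fit$pip),
                     cs_id = unname(cs_of), stringsAsFactors = FALSE)
  sets <- if (length(fit$credible_sets)) do.call(rbind, lapply(fit$credible_sets,
    function(s) data.frame(cs_id = s$cs_id, coverage = s$coverage,
                           purity = s$purity, n_snps = length(s$snps),
                           members = paste(s$snps, collapse = ","),
                           stringsAsFactors = FALSE)))
  else data.frame(cs_id = character(), coverage = numeric(),
                  purity = numeric(), n_snps = integer(),
                  members = character(), stringsAsFactors = FALSE)
  list(snps = snps, sets = sets)
}
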