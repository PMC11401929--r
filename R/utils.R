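# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, stable in log space
#' @noRd
logdiffexp <- function(a, b) {
  if (b > a) stop("logdiffexp: b > a")
  if (b == -Inf) return(a)
  d <- 1 - exp(b - a)
  if (d <= 0) return(-Inf)
  a + log(d)
}

#' Closed-form OLS for a single focal regressor plus covariates
#'
#' Fits `y ~ x + covariates (+ intercept)` and returns the coefficient of
#' `x` with its standard error and a two-sided p-value from the
#' large-sample normal. Residual variance uses the full-model degrees of
#' freedom. Used by the association scan, burden tests and the
#' predicted-expression association so all three report identical
#' conventions.
#'
#' @param y numeric response.
#' @param x numeric focal regressor.
#' @param covariates optional numeric matrix/data.frame of covariates
#'   (intercept added automatically).
#' @return list with `beta`, `se`, `z`, `p`, `n`, `df`.
#' @noRd
ols_single <- function(y, x, covariates = NULL) {
  ok <- is.finite(y) & is.finite(x)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & apply(is.finite(covariates), 1L, all)
    covariates <- covariates[ok, , drop = FALSE]
  }
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  C <- cbind(intercept = rep(1, n), covariates)
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) stop("covariate matrix is rank deficient")
  yr <- qr.resid(qrC, y)
  xr <- qr.resid(qrC, x)
  sxx <- sum(xr^2)
  if (sxx < n * 1e-12) {
    return(list(beta = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
                n = n, df = NA_integer_, degenerate = TRUE))
  }
  beta <- sum(xr * yr) / sxx
  df <- n - qrC$rank - 1L
  rss <- sum(yr^2) - beta^2 * sxx
  sigma2 <- max(rss, 0) / df
  se <- sqrt(sigma2 / sxx)
  z <- beta / se
  list(beta = beta, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
       n = n, df = df, degenerate = FALSE)
}

#' @noRd
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' @noRd
assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
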