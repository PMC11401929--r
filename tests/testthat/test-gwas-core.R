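test_that("trait transforms match their defining identities", {
  ph <- data.frame(iid = c("a", "b"), TG = c(1, 2), HDL = c(1, 0.5))
  out <- log_transform_traits(ph)
  expect_equal(out$trait_TG, c(0, log(2)))
  expect_equal(out$trait_HDL, c(1, 0.5))
  expect_equal(out$trait_TGHDL, c(0, log(4)))

  set.seed(1)
  tg <- stats::rlnorm(1000); hdl <- stats::rlnorm(1000)
  out <- log_transform_traits(data.frame(iid = seq_len(1000), TG = tg, HDL = hdl))
  expect_equal(out$trait_TGHDL, log(tg) - log(hdl), tolerance = 1e-12)

  expect_error(log_transform_traits(
    data.frame(iid = c("x1", "x2"), TG = c(1, -1), HDL = c(1, 1))), "x2")
})

test_that("inverse rank normal maps ranks to rankit normal quantiles", {
  expect_equal(inverse_rank_normal(c(5, 1, 3)),
               stats::qnorm(c(2.5, 0.5, 1.5) / 3), tolerance = 1e-12)
  expect_equal(inverse_rank_normal(c(5, 1, 3))[3], 0)
  # ties share the mean of their ranks
  expect_equal(inverse_rank_normal(c(1, 1, 2)),
               stats::qnorm(c(1, 1, 2.5) / 3), tolerance = 1e-12)
  # monotone in, monotone out; symmetric ranks center at zero
  set.seed(2)
  x <- sort(stats::rnorm(50))
  y <- inverse_rank_normal(x)
  expect_true(all(diff(y) > 0))
  expect_lt(abs(mean(y)), 1e-6)
  expect_error(inverse_rank_normal(c(2, 2, 2)), "identical")
})

test_that("assoc_scan matches the normal-equations closed form", {
  # 6-individual worked example, checked against (X'X)^-1 X'y by hand
  g <- c(0, 1, 2, 0, 1, 2)
  cov1 <- c(5, 3, 8, 2, 9, 4)
  y <- c(0.3, 1.1, 2.2, -0.4, 1.5, 1.9)
  X <- cbind(1, cov1, g)
  bh <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% bh
  sigma2 <- sum(res^2) / (6 - 3)
  se_g <- sqrt(sigma2 * solve(t(X) %*% X)[3, 3])

  map <- data.frame(snp_id = "s1", chr = 1, pos = 100, ea = "A", oa = "G",
                    eaf = 0.5)
  ss <- assoc_scan(matrix(g, ncol = 1, dimnames = list(NULL, "s1")), y, map,
                   covariates = data.frame(cov1 = cov1))
  expect_equal(ss$beta, bh[3], tolerance = 1e-10)
  expect_equal(ss$standard_error, se_g, tolerance = 1e-10)
  expect_equal(ss$p_value, 2 * stats::pnorm(-abs(bh[3] / se_g)),
               tolerance = 1e-10)
})

test_that("assoc_scan handles perfect fit and monomorphic SNPs", {
  g <- c(0, 1, 2, 1, 0, 2, 1, 0)
  G <- cbind(s1 = g, s2 = rep(1, 8))
  map <- data.frame(snp_id = c("s1", "s2"), chr = 1, pos = c(1, 2),
                    ea = "A", oa = "G", eaf = 0.5)
  ss <- assoc_scan(G, as.numeric(g), map)
  expect_equal(ss$beta[1], 1, tolerance = 1e-8)
  expect_true(is.na(ss$beta[2]))
  expect_identical(ss$flag[2], "monomorphic")
  expect_identical(nrow(ss), 2L)  # emitted, not dropped
})

test_that("scan betas equal partial correlation times residual SD ratio", {
  set.seed(3)
  n <- 200
  cvr <- stats::rnorm(n)
  g <- stats::rbinom(n, 2, 0.4) + 0.3 * cvr
  y <- 0.5 * g + cvr + stats::rnorm(n)
  qrC <- qr(cbind(1, cvr))
  yr <- qr.resid(qrC, y); gr <- qr.resid(qrC, g)
  expected <- stats::cor(yr, gr) * stats::sd(yr) / stats::sd(gr)
  map <- data.frame(snp_id = "s1", chr = 1, pos = 1, ea = "A", oa = "G",
                    eaf = 0.4)
  ss <- assoc_scan(matrix(g, ncol = 1, dimnames = list(NULL, "s1")), y, map,
                   covariates = data.frame(cvr = cvr))
  expect_equal(ss$beta, expected, tolerance = 1e-10)
})

test_that("null scans have calibrated type-I error", {
  set.seed(4)
  n <- 400; p <- 2000
  G <- matrix(stats::rbinom(n * p, 2, 0.3), n, p,
              dimnames = list(NULL, paste0("s", 1:p)))
  y <- stats::rnorm(n)
  map <- data.frame(snp_id = paste0("s", 1:p), chr = 1, pos = 1:p,
                    ea = "A", oa = "G", eaf = 0.3)
  ss <- assoc_scan(G, y, map)
  frac <- mean(ss$p_value < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("sex strata filter individuals and drop sex from covariates", {
  sim <- small_sim()
  co <- sim$cohort
  ph <- log_transform_traits(co$phenotypes)
  y <- rep(NA_real_, nrow(co$genotypes))
  f <- ph$sex == "female"
  y[f] <- inverse_rank_normal(ph$trait_TGHDL[f])
  covars <- data.frame(age = ph$age, age2 = ph$age^2, sex = ph$sex)
  ss_f <- assoc_scan(co$genotypes[, 1:4], y, co$snp_map,
                     covariates = covars, stratum = "female", sex = ph$sex)
  expect_identical(unique(ss_f$stratum), "female")
  expect_identical(unique(ss_f$n), sum(f))
  # same result if sex column never supplied (it must have been dropped)
  ss_f2 <- assoc_scan(co$genotypes[, 1:4], y, co$snp_map,
                      covariates = covars[, c("age", "age2")],
                      stratum = "female", sex = ph$sex)
  expect_equal(ss_f$beta, ss_f2$beta, tolerance = 1e-12)
})

test_that("qc_filter excludes exactly the designed failures", {
  set.seed(5)
  n <- 200
  clean <- matrix(stats::rbinom(n * 50, 2, 0.3), n, 50)
  bad_call <- stats::rbinom(n, 2, 0.3); bad_call[1:6] <- NA  # call rate 0.97
  bad_maf <- rep(0L, n)                                      # MAF 0
  bad_hwe <- rep(1L, n)                                      # all heterozygous
  G <- cbind(clean, snp_call = bad_call, snp_maf = bad_maf, snp_hwe = bad_hwe)
  colnames(G)[1:50] <- paste0("ok", 1:50)
  # one sample with terrible call rate, one with extreme heterozygosity
  G[7, 1:20] <- NA
  G[8, 1:50] <- 1L
  map <- data.frame(snp_id = colnames(G), chr = 1, pos = seq_len(ncol(G)),
                    ea = "A", oa = "G", eaf = 0.3)
  res <- qc_filter(list(genotypes = G, snp_map = map, phenotypes = NULL))
  ex <- res$exclusions
  expect_identical(ex$n_excluded[ex$filter == "sample_call_rate"], 1L)
  expect_identical(ex$n_excluded[ex$filter == "sample_heterozygosity"], 1L)
  expect_identical(ex$n_excluded[ex$filter == "snp_call_rate"], 1L)
  expect_identical(ex$n_excluded[ex$filter == "snp_maf"], 1L)
  expect_identical(ex$n_excluded[ex$filter == "snp_hwe"], 1L)
  expect_false(any(c("snp_call", "snp_maf", "snp_hwe") %in%
                     colnames(res$genotypes)))
  # survivors unchanged in value, only membership differs
  expect_identical(res$genotypes[, "ok1"], G[res$sample_keep, "ok1"])
})

test_that("qc_filter leaves a fully clean cohort untouched", {
  set.seed(6)
  G <- matrix(stats::rbinom(150 * 20, 2, 0.4), 150, 20,
              dimnames = list(NULL, paste0("s", 1:20)))
  map <- data.frame(snp_id = colnames(G), chr = 1, pos = 1:20,
                    ea = "A", oa = "G", eaf = 0.4)
  res <- qc_filter(list(genotypes = G, snp_map = map, phenotypes = NULL))
  expect_identical(sum(res$exclusions$n_excluded[
    res$exclusions$filter %in% c("sample_call_rate", "sample_heterozygosity")]), 0L)
  expect_identical(dim(res$genotypes), dim(G))
})

test_that("genomic control matches its defining arithmetic", {
  # all p = 0.5 sits exactly at the null median
  gc <- genomic_control(rep(0.5, 11))
  expect_equal(gc$lambda_gc, 1, tolerance = 1e-12)
  expect_equal(gc$p_corrected, rep(0.5, 11))

  # median chi-square 0.6155 implies lambda 1.35
  chis <- c(0.2, 0.6155, 1.4)
  p <- stats::pchisq(chis, 1, lower.tail = FALSE)
  expect_equal(genomic_control(p)$lambda_gc, 0.6155 / stats::qchisq(0.5, 1),
               tolerance = 1e-9)
  expect_equal(genomic_control(p)$lambda_gc, 1.35, tolerance = 0.01)

  expect_error(genomic_control(numeric(0)), "empty")
  expect_error(genomic_control(c(0.5, 0)), "0, 1")
})

test_that("genomic control never deflates and is idempotent", {
  set.seed(7)
  p_infl <- stats::pchisq(1.8 * stats::rchisq(5000, 1), 1, lower.tail = FALSE)
  gc <- genomic_control(p_infl)
  expect_gt(gc$lambda_gc, 1)
  gc2 <- genomic_control(gc$p_corrected)
  expect_equal(gc2$lambda_gc, 1, tolerance = 1e-6)
  expect_equal(gc2$p_corrected, gc$p_corrected)
  # deflation-free: lambda < 1 leaves p untouched
  p_defl <- stats::pchisq(0.5 * stats::rchisq(2000, 1), 1, lower.tail = FALSE)
  gcd <- genomic_control(p_defl)
  expect_lt(gcd$lambda_gc, 1)
  expect_identical(gcd$p_corrected, p_defl)
})

test_that("exact Hardy-Weinberg mid-p behaves sensibly", {
  # equilibrium-looking counts: comfortably non-significant
  expect_gt(hwe_exact_midp(360, 480, 160), 0.05)
  # gross heterozygote excess: extreme
  expect_lt(hwe_exact_midp(0, 200, 0), 1e-8)
  # symmetric under allele relabeling
  expect_equal(hwe_exact_midp(5, 50, 445), hwe_exact_midp(445, 50, 5),
               tolerance = 1e-12)
  p <- hwe_exact_midp(10, 40, 50)
  expect_gt(p, 0); expect_lte(p, 1)
})
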