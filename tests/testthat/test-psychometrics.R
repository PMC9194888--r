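test_that("correlation method follows the skewness/kurtosis rule", {
  d <- withr::with_seed(61, tibble::tibble(
    x = rnorm(200),
    z = rexp(200)^2  # strongly right-skewed
  ))
  d$y <- d$x + withr::with_seed(62, rnorm(200, 0, 0.5))
  out <- correlate_scores(d, vars = c("x", "y", "z"))
  expect_equal(out$method[out$var1 == "x" & out$var2 == "y"], "pearson")
  # any pair involving the skewed column falls back to Spearman
  expect_true(all(out$method[out$var1 == "z" | out$var2 == "z"] == "spearman"))
})

test_that("a perfect correlation is recovered with a vanishing p-value", {
  d <- tibble::tibble(x = seq_len(50), y = seq_len(50))
  out <- correlate_scores(d, vars = c("x", "y"))
  expect_equal(out$estimate, 1)
  expect_lt(out$p_value, 1e-10)
})

test_that("Bonferroni adjustment uses the explicit family size", {
  d <- withr::with_seed(63, tibble::tibble(a = rnorm(60), b = rnorm(60), c = rnorm(60)))
  out <- correlate_scores(d, family_size = 3)
  expect_equal(unique(out$alpha_adjusted), 0.05 / 3)
  expect_equal(round(unique(out$alpha_adjusted), 4), 0.0167)
})

test_that("constant columns give undefined correlations, not errors", {
  d <- tibble::tibble(x = rnorm(20), y = rep(1, 20))
  out <- correlate_scores(d, vars = c("x", "y"))
  expect_equal(out$method, "undefined")
  expect_true(is.na(out$estimate))
})

test_that("ICC is 1 for identical ratings and distinguishes agreement from consistency", {
  x <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), ncol = 2,
              dimnames = NULL)
  same <- cbind(x[, 1], x[, 1])
  same <- rbind(same, c(9, 9))  # 5 subjects minimum
  expect_equal(icc_reliability(same)$value, 1)
  expect_equal(icc_reliability(same, type = "consistency")$value, 1)

  shifted <- cbind(same[, 1], same[, 1] + 2)
  expect_equal(icc_reliability(shifted, type = "consistency")$value, 1)
  expect_lt(icc_reliability(shifted, type = "agreement")$value, 1)
})

test_that("ICC recovers the generating variance-component ratio", {
  # subject variance 4, error variance 1 -> true ICC 0.8 (integer rounding
  # of the ratings adds ~1/12 to the error variance, a ~1% attenuation)
  r <- simulate_raters(n_subjects = 1000, icc_target = 0.8, n_raters = 2,
                       seed = 6, total_sd = sqrt(5))
  est <- icc_reliability(r)
  expect_lt(abs(est$value - 0.80), 0.03)
  expect_true(est$ci95[1] < est$value && est$value < est$ci95[2])
})

test_that("ICC confidence intervals cover the generating value", {
  hits <- vapply(1:120, function(i) {
    r <- simulate_raters(n_subjects = 60, icc_target = 0.75, n_raters = 2,
                         seed = 3000 + i, total_sd = 4)
    ci <- icc_reliability(r)$ci95
    ci[1] <= 0.75 && 0.75 <= ci[2]
  }, logical(1))
  # nominal 95% coverage, allowing Monte-Carlo slack at 120 replicates
  expect_gt(mean(hits), 0.88)
})

test_that("zero between-subject variance warns and reports ICC 0", {
  same_everywhere <- matrix(5, 10, 2)
  expect_warning(res <- icc_reliability(same_everywhere), "ICC reported as 0")
  expect_equal(res$value, 0)
})

test_that("PCA reproduces the equicorrelation closed form", {
  R <- matrix(0.3, 4, 4); diag(R) <- 1
  p <- pca_structure(cor_mat = R)
  expect_equal(p$eigenvalues[1], 1 + 3 * 0.3, tolerance = 1e-12)
  expect_equal(p$pct_variance_pc1, 47.5, tolerance = 1e-9)
  expect_equal(p$n_retained, 1)
})

test_that("PCA of duplicated columns is a single perfect component", {
  x <- withr::with_seed(67, rnorm(100))
  d <- tibble::tibble(a = x, b = x, c = x, d = x)
  expect_warning(p <- pca_structure(d), "rank deficient")
  expect_equal(p$pct_variance_pc1, 100)
  expect_equal(p$n_retained, 1)
  expect_true(all(p$loadings_pc1 > 0))  # sign convention: positive loading sum
})

test_that("PCA of independent columns spreads variance evenly", {
  d <- withr::with_seed(68, as.data.frame(matrix(rnorm(4e5), ncol = 4)))
  p <- pca_structure(d)
  expect_lt(abs(p$pct_variance_pc1 - 25), 1)
  expect_equal(sum(p$eigenvalues), 4, tolerance = 1e-9)
})

test_that("PCA eigenvalues always sum to the number of variables", {
  for (s in 1:5) {
    d <- withr::with_seed(700 + s, {
      n <- 50 + 10 * s
      base <- rnorm(n)
      tibble::tibble(a = base + rnorm(n), b = base + rnorm(n),
                     c = rnorm(n), d = 0.5 * base + rnorm(n), e = rnorm(n))
    })
    p <- pca_structure(d)
    expect_equal(sum(p$eigenvalues), 5, tolerance = 1e-9)
  }
})

test_that("TOST gives p = 0.5 when the mean difference sits on a bound", {
  z <- withr::with_seed(69, rnorm(40))
  d <- (z - mean(z)) / sd(z)       # mean 0, sd 1 exactly
  dat <- tibble::tibble(x = d + 0.5, y = 0)  # differences: mean 0.5, sd 1
  res <- tost_paired(dat, x, y, bounds_dz = 0.5)
  expect_equal(res$t_upper, 0, tolerance = 1e-12)
  expect_equal(res$p_upper, 0.5, tolerance = 1e-12)
})

test_that("TOST decisions are invariant under swapping the pair order", {
  d <- withr::with_seed(71, tibble::tibble(x = rnorm(52, 10, 1.2),
                                           y = rnorm(52, 10, 1.2)))
  a <- tost_paired(d, x, y)
  b <- tost_paired(d, y, x)
  expect_equal(a$equivalent, b$equivalent)
  expect_equal(a$dz, -b$dz)
  expect_equal(max(a$p_lower, a$p_upper), max(b$p_lower, b$p_upper))
})

test_that("TOST matches its exact closed-form equivalence rate", {
  # with bounds scaled by the sample SD, the joint rejection region reduces
  # to |t| < bound*sqrt(n) - t_{1-alpha,n-1}: an exact rate of
  # 2*pt(...) - 1, which a decision-level Monte Carlo must reproduce
  n <- 52
  exact <- 2 * pt(0.5 * sqrt(n) - qt(0.95, n - 1), n - 1) - 1
  B <- 2000
  dec <- withr::with_seed(73, {
    vapply(seq_len(B), function(i) {
      d <- tibble::tibble(x = rnorm(n), y = 0)
      tost_paired(d, x, y)$equivalent
    }, logical(1))
  })
  expect_lt(abs(mean(dec) - exact), 3 * sqrt(exact * (1 - exact) / B))
})

test_that("TOST rejects degenerate inputs", {
  expect_error(tost_paired(tibble::tibble(x = c(1, 2), y = c(1, 2)), x, y),
               class = "tfab_domain_error")
  expect_error(tost_paired(tibble::tibble(x = rep(3, 10), y = rep(1, 10)), x, y),
               class = "tfab_domain_error")
})

test_that("TOST sample size reproduces the designed pair counts", {
  expect_equal(tost_sample_size(0.5, 0.05, 0.95), 52L)
  expect_equal(tost_sample_size(0.5, 0.05, 0.80), 35L)
  expect_warning(n_big <- tost_sample_size(10), "minimum usable")
  expect_equal(n_big, 2L)
  expect_error(tost_sample_size(0), class = "tfab_domain_error")
})

test_that("TOST sample size is monotone in bound and power", {
  bounds <- c(0.2, 0.3, 0.5, 0.8)
  ns <- vapply(bounds, function(b) tost_sample_size(b), integer(1))
  expect_true(all(diff(ns) < 0))
  powers <- c(0.5, 0.8, 0.9, 0.95, 0.99)
  np <- vapply(powers, function(p) tost_sample_size(power = p), integer(1))
  expect_true(all(diff(np) > 0))
  # the exact t-based iteration never returns fewer pairs than the
  # normal approximation
  expect_gte(tost_sample_size(exact = TRUE), 52L)
})

test_that("regression sample size achieves the target power minimally", {
  for (case in list(c(0.05, 3, 0.95), c(0.05, 1, 0.95), c(0.15, 3, 0.80))) {
    f2 <- case[1]; u <- case[2]; pw <- case[3]
    n <- regression_sample_size(f2, u, power = pw)
    v <- n - u - 1
    expect_gte(regression_power(f2, u, v), pw)
    expect_lt(regression_power(f2, u, v - 1), pw)
  }
})

test_that("regression sample size matches the chi-square limit for one predictor", {
  # for u = 1 the noncentral F power converges to the chi-square(1)
  # approximation lambda = (z_{1-alpha/2} + z_{power})^2
  n_exact <- regression_sample_size(0.05, 1, 0.05, 0.95)
  n_approx <- ceiling((qnorm(0.975) + qnorm(0.95))^2 / 0.05) + 1 + 1
  expect_lte(abs(n_exact - n_approx), 1)
})

test_that("regression sample size is monotone in effect size and power", {
  expect_gt(regression_sample_size(0.02, 3), regression_sample_size(0.05, 3))
  expect_gt(regression_sample_size(0.05, 3, power = 0.95),
            regression_sample_size(0.05, 3, power = 0.80))
  # degenerate power just above alpha needs almost nothing
  expect_lt(regression_sample_size(0.5, 3, power = 0.06), 10)
})
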