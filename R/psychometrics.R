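# Construct validity, reliability and factorial structure: correlations with
# a distribution-driven choice of method, intraclass correlations by variance
# components, and a principal-component summary of the task scores.

moment_skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 == 0) return(NA_real_)
  mean((x - m)^3) / s2^1.5
}

moment_kurtosis_excess <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 == 0) return(NA_real_)
  mean((x - m)^4) / s2^2 - 3
}

passes_normality_rule <- function(x, skew_max = 1, kurt_max = 3) {
  sk <- moment_skewness(x); ku <- moment_kurtosis_excess(x)
  !is.na(sk) && !is.na(ku) && abs(sk) < skew_max && abs(ku) < kurt_max
}

#' Pairwise correlations with distribution-driven method choice
#'
#' For each pair of variables, Pearson's correlation is used when both
#' variables look normal by the moment rule (|skewness| < 1 and |excess
#' kurtosis| < 3); otherwise Spearman's rank correlation. Significance is
#' flagged at the Bonferroni-adjusted level `alpha / family_size`.
#'
#' @param data A data frame.
#' @param vars Columns to correlate (character); default: all numeric columns.
#' @param family_size Number of simultaneous tests for the Bonferroni
#'   adjustment; defaults to the number of pairs. The adjusted level is
#'   reported in the output so the family used is always explicit.
#' @param alpha Base two-tailed level (default 0.05).
#' @param skew_max,kurt_max Normality-rule thresholds.
#' @return A tibble with one row per pair: `var1`, `var2`, `method`,
#'   `estimate`, `p_value`, `n`, `alpha_adjusted`, `significant`. Pairs with a
#'   constant variable get `NA` estimates with method `"undefined"`.
#' @examples
#' cohort <- compute_scores(simulate_normative(n = 346, seed = 3))
#' correlate_scores(cohort, vars = c("tfab_m", "tfab_v", "tfab_1"))
#' @export
correlate_scores <- function(data, vars = NULL, family_size = NULL,
                             alpha = 0.05, skew_max = 1, kurt_max = 3) {
  data <- as_tibble(data)
  if (is.null(vars)) {
    vars <- names(data)[purrr::map_lgl(data, is.numeric)]
  }
  stopifnot(length(vars) >= 2)
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  if (is.null(family_size)) family_size <- length(pairs)
  stopifnot(family_size >= 1, alpha > 0, alpha < 1)
  alpha_adj <- alpha / family_size
  purrr::map_dfr(pairs, function(pr) {
    x <- data[[pr[1]]]; y <- data[[pr[2]]]
    ok <- !is.na(x) & !is.na(y)
    xx <- x[ok]; yy <- y[ok]
    if (length(xx) < 4 || var(xx) == 0 || var(yy) == 0) {
      return(tibble(var1 = pr[1], var2 = pr[2], method = "undefined",
                    estimate = NA_real_, p_value = NA_real_, n = length(xx),
                    alpha_adjusted = alpha_adj, significant = NA))
    }
    method <- if (passes_normality_rule(xx, skew_max, kurt_max) &&
                  passes_normality_rule(yy, skew_max, kurt_max)) "pearson" else "spearman"
    ct <- suppressWarnings(cor.test(xx, yy, method = method, exact = FALSE))
    tibble(var1 = pr[1], var2 = pr[2], method = method,
           estimate = unname(ct$estimate), p_value = ct$p.value, n = length(xx),
           alpha_adjusted = alpha_adj, significant = ct$p.value < alpha_adj)
  })
}

#' Intraclass correlation for reliability designs
#'
#' Single-rater intraclass correlation from a subjects x raters (or
#' occasions) matrix, computed from the two-way ANOVA mean squares. The
#' default is the two-way random-effects, absolute-agreement coefficient
#' ICC(A,1); `type = "consistency"` gives the two-way mixed, consistency
#' coefficient ICC(C,1), which ignores systematic rater offsets. Confidence
#' intervals follow the F-distribution bounds of McGraw & Wong.
#'
#' @param ratings A matrix or data frame, one row per subject, one column per
#'   rater/occasion; complete cases only.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @param alpha Two-sided CI level complement (default 0.05 for a 95% CI).
#' @return A `tfab_icc` object with `value`, `ci95`, `type`, `n_subjects`,
#'   `n_raters` and the mean squares.
#' @examples
#' r <- simulate_raters(n_subjects = 30, icc_target = 0.85, seed = 5)
#' icc_reliability(r)
#' @export
icc_reliability <- function(ratings, type = c("agreement", "consistency"),
                            alpha = 0.05) {
  type <- match.arg(type)
  x <- as.matrix(ratings)
  x <- x[complete.cases(x), , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  if (k < 2) abort("Need at least 2 raters/occasions.", class = "tfab_domain_error")
  if (n < 5) abort("Need at least 5 subjects.", class = "tfab_domain_error")
  grand <- mean(x)
  rm <- rowMeans(x); cm <- colMeans(x)
  ssr <- k * sum((rm - grand)^2)
  ssc <- n * sum((cm - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- max(0, sst - ssr - ssc)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= mse) {
    warn("No between-subject variance beyond error; ICC reported as 0.")
    value <- 0
  } else {
    value <- switch(type,
      agreement = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
      consistency = (msr - mse) / (msr + (k - 1) * mse))
  }
  ci <- icc_ci(value, msr, msc, mse, n, k, type, alpha)
  structure(list(value = value, ci95 = ci, type = type, n_subjects = n,
                 n_raters = k, msr = msr, msc = msc, mse = mse, alpha = alpha),
            class = "tfab_icc")
}

icc_ci <- function(r, msr, msc, mse, n, k, type, alpha = 0.05) {
  if (mse == 0 && msc <= mse) return(c(1, 1))
  if (type == "consistency") {
    if (mse == 0) return(c(1, 1))
    f <- msr / mse
    fu <- qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fl <- qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lo <- (f / fu - 1) / (f / fu + k - 1)
    hi <- (f * fl - 1) / (f * fl + k - 1)
  } else {
    # Satterthwaite df for the ICC(A,1) interval (McGraw & Wong 1996)
    a <- k * r / (n * (1 - r))
    b <- 1 + k * r * (n - 1) / (n * (1 - r))
    denom <- (a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1))
    if (!is.finite(denom) || denom <= 0) return(c(NA_real_, NA_real_))
    v <- (a * msc + b * mse)^2 / denom
    fu <- qf(1 - alpha / 2, n - 1, v)
    fl <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - fu * mse) / (fu * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (fl * msr - mse) / (k * msc + (k * n - k - n) * mse + n * fl * msr)
  }
  c(max(-1, min(lo, hi)), min(1, max(lo, hi)))
}

#' @export
print.tfab_icc <- function(x, ...) {
  cat(sprintf("<tfab ICC> %s, single rater: %.3f (95%% CI %.3f-%.3f)\n",
              x$type, x$value, x$ci95[1], x$ci95[2]))
  cat(sprintf("  %d subjects x %d raters\n", x$n_subjects, x$n_raters))
  invisible(x)
}

#' Principal-component structure of the task scores
#'
#' Eigendecomposition of the task-score correlation matrix, retaining
#' components with eigenvalue > 1. First-component loadings are the leading
#' eigenvector scaled by the square root of its eigenvalue, with the sign
#' fixed so the loading sum is positive. A single retained component with
#' uniformly positive loadings is the mono-component ("global frontal
#' efficiency") structure expected of the battery.
#'
#' @param data Data frame of task scores (one column per task), or `NULL`
#'   when `cor_mat` is given.
#' @param vars Columns to use; default: all numeric columns.
#' @param cor_mat Optionally, a correlation matrix to decompose directly.
#' @param use Missing-data handling passed to [stats::cor()].
#' @return A `tfab_pca` object: `eigenvalues`, `pct_variance_pc1`,
#'   `loadings_pc1`, `n_retained`, `p`.
#' @examples
#' cohort <- simulate_normative(n = 346, seed = 9)
#' pca_structure(cohort, vars = c("conceptualization", "mental_flexibility",
#'                                "interference_m", "inhibition_m"))
#' @export
pca_structure <- function(data = NULL, vars = NULL, cor_mat = NULL,
                          use = "pairwise.complete.obs") {
  if (is.null(cor_mat)) {
    data <- as_tibble(data)
    if (is.null(vars)) vars <- names(data)[purrr::map_lgl(data, is.numeric)]
    stopifnot(length(vars) >= 2)
    degenerate <- vars[purrr::map_lgl(data[vars], ~ var(.x, na.rm = TRUE) == 0)]
    if (length(degenerate)) {
      abort(paste0("Constant column(s): ", paste(degenerate, collapse = ", ")),
            class = "tfab_domain_error")
    }
    cor_mat <- cor(data[vars], use = use)
  }
  p <- ncol(cor_mat)
  ev <- eigen(cor_mat, symmetric = TRUE)
  values <- ev$values
  if (any(values < 1e-10 * max(values))) {
    warn("Correlation matrix is rank deficient; near-zero eigenvalues clipped.")
  }
  values <- pmax(values, 0)
  load1 <- ev$vectors[, 1] * sqrt(values[1])
  if (sum(load1) < 0) load1 <- -load1
  names(load1) <- colnames(cor_mat)
  structure(list(eigenvalues = values,
                 pct_variance_pc1 = 100 * values[1] / p,
                 loadings_pc1 = load1,
                 n_retained = sum(values > 1), p = p),
            class = "tfab_pca")
}

#' @export
print.tfab_pca <- function(x, ...) {
  cat(sprintf("<tfab PCA> %d variables; PC1 explains %.1f%% of variance; %d component(s) with eigenvalue > 1\n",
              x$p, x$pct_variance_pc1, x$n_retained))
  cat("  PC1 loadings:", paste(sprintf("%.2f", x$loadings_pc1), collapse = ", "), "\n")
  invisible(x)
}

#' Two one-sided tests (TOST) of equivalence for paired scores
#'
#' Tests whether the standardized paired difference `dz = mean(d)/sd(d)` lies
#' within symmetric equivalence bounds (default +-0.5 in dz units; the raw
#' bounds are the dz bounds times the sample SD of the differences). The two
#' one-sided t statistics are
#' `t_lower = (mean_diff - lower_raw)/(sd_diff/sqrt(n))` and analogously for
#' the upper bound; equivalence is declared when both one-sided p-values fall
#' below `alpha`. A companion paired t-test of the difference against zero is
#' reported alongside.
#'
#' @param data Data frame with the two paired score columns.
#' @param x,y Column names (tidy-eval) of the paired scores.
#' @param bounds_dz Symmetric standardized equivalence bound (positive).
#' @param alpha One-sided level for each test (default 0.05).
#' @return A `tfab_tost` object.
#' @examples
#' cohort <- compute_scores(simulate_normative(n = 346, seed = 13))
#' tost_paired(cohort, tfab_m, tfab_v)
#' @export
tost_paired <- function(data, x, y, bounds_dz = 0.5, alpha = 0.05) {
  data <- as_tibble(data)
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ok <- !is.na(xv) & !is.na(yv)
  d <- xv[ok] - yv[ok]
  n <- length(d)
  if (n < 3) abort("Need at least 3 complete pairs.", class = "tfab_domain_error")
  stopifnot(bounds_dz > 0, alpha > 0, alpha < 1)
  m <- mean(d); s <- sd(d)
  if (s == 0) abort("All paired differences identical; TOST undefined.",
                    class = "tfab_domain_error")
  se <- s / sqrt(n)
  df <- n - 1
  lower_raw <- -bounds_dz * s
  upper_raw <- bounds_dz * s
  t_lower <- (m - lower_raw) / se
  t_upper <- (m - upper_raw) / se
  p_lower <- pt(t_lower, df, lower.tail = FALSE)
  p_upper <- pt(t_upper, df)
  t_zero <- m / se
  p_zero <- 2 * pt(abs(t_zero), df, lower.tail = FALSE)
  structure(list(n = n, mean_diff = m, sd_diff = s, dz = m / s,
                 bounds_dz = c(-bounds_dz, bounds_dz),
                 bounds_raw = c(lower_raw, upper_raw),
                 t_lower = t_lower, t_upper = t_upper,
                 p_lower = p_lower, p_upper = p_upper, df = df, alpha = alpha,
                 equivalent = max(p_lower, p_upper) < alpha,
                 t_test = list(statistic = t_zero, df = df, p_value = p_zero)),
            class = "tfab_tost")
}

#' @export
print.tfab_tost <- function(x, ...) {
  cat(sprintf("<tfab TOST> n = %d pairs, dz = %.3f (bounds %+.2f/%+.2f)\n",
              x$n, x$dz, x$bounds_dz[1], x$bounds_dz[2]))
  cat(sprintf("  lower: t(%d) = %.2f, p = %.3g | upper: t(%d) = %.2f, p = %.3g\n",
              x$df, x$t_lower, x$p_lower, x$df, x$t_upper, x$p_upper))
  cat(sprintf("  paired t-test vs 0: t(%d) = %.2f, p = %.3g\n",
              x$df, x$t_test$statistic, x$t_test$p_value))
  cat("  decision:", if (x$equivalent) "equivalent" else "not shown equivalent", "\n")
  invisible(x)
}
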