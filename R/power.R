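# Design sample-size calculators used to plan the standardization study:
# paired TOST equivalence, multiple-regression power via the noncentral F,
# and the Obuchowski binormal-variance ROC formula.

#' Sample size for a paired-samples TOST equivalence design
#'
#' Normal-approximation formula for a true effect of zero and symmetric
#' standardized bounds: `n = ceil[(z_{1-alpha} + z_{1-(1-power)/2})^2 /
#' bounds_dz^2]`. At the defaults (bounds +-0.5, alpha 0.05, power 0.95)
#' this gives 52 pairs. With `exact = TRUE` the smallest `n` whose exact
#' t-based equivalence rate reaches `power` is found by iteration instead;
#' the exact rate at sample size `n` is
#' `2 * pt(bounds_dz * sqrt(n) - qt(1 - alpha, n - 1), n - 1) - 1`, which
#' runs slightly below the normal approximation's nominal power.
#'
#' @param bounds_dz Symmetric standardized equivalence bound (positive).
#' @param alpha One-sided level of each test.
#' @param power Target probability of declaring equivalence when the true
#'   effect is zero.
#' @param exact Use the exact t-based iteration instead of the normal
#'   approximation.
#' @return Number of pairs (integer, at least 2).
#' @examples
#' tost_sample_size()                 # 52
#' tost_sample_size(power = 0.80)     # 35
#' @export
tost_sample_size <- function(bounds_dz = 0.5, alpha = 0.05, power = 0.95,
                             exact = FALSE) {
  stopifnot(alpha > 0, alpha < 1, power > alpha, power < 1)
  if (bounds_dz == 0) {
    abort("Zero equivalence bound: required n is infinite.", class = "tfab_domain_error")
  }
  bounds_dz <- abs(bounds_dz)
  if (exact) {
    n <- 3
    rate <- function(n) 2 * pt(bounds_dz * sqrt(n) - qt(1 - alpha, n - 1), n - 1) - 1
    while (rate(n) < power && n < 1e7) n <- n + 1
    return(as.integer(n))
  }
  n <- ceiling((qnorm(1 - alpha) + qnorm(1 - (1 - power) / 2))^2 / bounds_dz^2)
  if (n < 2) {
    warn("Formula yields n < 2; returning the minimum usable n = 2.")
    n <- 2
  }
  as.integer(n)
}

#' Power of a multiple-regression F test
#'
#' @param f2 Cohen's f-squared effect size.
#' @param u Numerator degrees of freedom (number of tested predictors).
#' @param v Denominator degrees of freedom.
#' @param alpha Test level.
#' @return Power of the level-`alpha` F test under noncentrality
#'   `lambda = f2 * (u + v + 1)`.
#' @export
regression_power <- function(f2, u, v, alpha = 0.05) {
  pf(qf(1 - alpha, u, v), u, v, ncp = f2 * (u + v + 1), lower.tail = FALSE)
}

#' Sample size for a multiple-regression F test
#'
#' Smallest total `n = u + v + 1` such that the level-`alpha` F test with `u`
#' numerator and `v` denominator degrees of freedom reaches the requested
#' power under the noncentrality convention `lambda = f2 * (u + v + 1)`.
#'
#' @inheritParams regression_power
#' @param power Target power.
#' @return Total sample size (integer).
#' @examples
#' regression_sample_size(f2 = 0.05, u = 3, power = 0.95)
#' @export
regression_sample_size <- function(f2, u, alpha = 0.05, power = 0.95) {
  stopifnot(f2 > 0, u >= 1, alpha > 0, alpha < 1, power > alpha, power < 1)
  # bracket by doubling, then bisect on the (monotone in v) power curve
  lo <- 1; hi <- 2
  while (regression_power(f2, u, hi, alpha) < power) {
    lo <- hi
    hi <- hi * 2
    if (hi > 1e8) abort("Required sample size exceeds 1e8.", class = "tfab_domain_error")
  }
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (regression_power(f2, u, mid, alpha) >= power) hi <- mid else lo <- mid
  }
  as.integer(u + hi + 1)
}

#' Obuchowski sample size for a single-test ROC study
#'
#' Binormal-variance method for detecting an AUC of `auc_alt` against the
#' null 0.5 with a `kappa`:1 control:case allocation. With
#' `a = qnorm(auc_alt) * sqrt(2)`, the alternative-hypothesis variance is
#' `V_A = 0.0099 * exp(-a^2/2) * ((5 a^2 + 8) + (a^2 + 8)/kappa)` and the
#' null variance `V_0 = 0.0792 * (1 + 1/kappa)`; the case count is
#' `ceil[(z_{1-alpha} sqrt(V_0) + z_{power} sqrt(V_A))^2 / (auc_alt - 0.5)^2]`
#' and controls are `ceil(kappa * n_cases)`.
#'
#' The level is one-sided by default, which reproduces the published design
#' (19 cases, 190 controls at AUC 0.7, kappa 10, power 0.90); `sided = "two"`
#' is available for the conservative variant.
#'
#' @param auc_alt Alternative AUC (in (0.5, 1)).
#' @param kappa Controls-per-case allocation ratio (> 0).
#' @param alpha Test level.
#' @param power Target power.
#' @param sided `"one"` (default) or `"two"`.
#' @return A list with `n_cases` and `n_controls`.
#' @examples
#' roc_sample_size(auc_alt = 0.7, kappa = 10, power = 0.90)
#' @export
roc_sample_size <- function(auc_alt, kappa = 1, alpha = 0.05, power = 0.90,
                            sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot(kappa > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  if (auc_alt <= 0.5 || auc_alt >= 1) {
    abort("`auc_alt` must lie strictly between 0.5 and 1.", class = "tfab_domain_error")
  }
  a <- qnorm(auc_alt) * sqrt(2)
  v_alt <- 0.0099 * exp(-a^2 / 2) * ((5 * a^2 + 8) + (a^2 + 8) / kappa)
  v_null <- 0.0792 * (1 + 1 / kappa)
  z_a <- if (sided == "one") qnorm(1 - alpha) else qnorm(1 - alpha / 2)
  z_b <- qnorm(power)
  n_cases <- ceiling((z_a * sqrt(v_null) + z_b * sqrt(v_alt))^2 / (auc_alt - 0.5)^2)
  list(n_cases = as.integer(n_cases),
       n_controls = as.integer(ceiling(kappa * n_cases)))
}
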