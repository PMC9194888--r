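# Non-parametric tolerance limits on ranked adjusted scores.
#
# The outer tolerance limit (oTL) is the order statistic that bounds, with
# 95% confidence, the worst 5% of the population from below: a score below
# the oTL is confidently within the impaired tail. The inner limit (iTL)
# bounds the same tail from above. Ranks come from the exact binomial CDF:
# no normal approximation is used at any sample size.

#' Order-statistic ranks for non-parametric tolerance limits
#'
#' For a sample of size `n`, the outer rank is the largest `r` such that
#' `P[Binomial(n, coverage) >= r] >= confidence` (the r-th smallest value lies
#' below the population `coverage` quantile with at least `confidence`
#' probability); the inner rank is the smallest `s` such that
#' `P[Binomial(n, coverage) <= s - 1] >= confidence`. Both are computed by
#' exact binomial CDF enumeration.
#'
#' No outer rank exists below `n = 59` at the default 5% coverage / 95%
#' confidence (`1 - 0.95^58 < 0.95 <= 1 - 0.95^59`); `rank_outer` is then `NA`
#' and downstream models are flagged rather than silently defaulted.
#'
#' @param n Sample size (>= 1).
#' @param coverage Population tail fraction bounded by the limits (default 0.05).
#' @param confidence Confidence level for the bound (default 0.95).
#' @return A list with `rank_outer` (integer or `NA`), `rank_inner`, `n`,
#'   `coverage`, `confidence`.
#' @examples
#' tolerance_limit_ranks(346)
#' tolerance_limit_ranks(58)$rank_outer  # NA: no outer limit
#' @export
tolerance_limit_ranks <- function(n, coverage = 0.05, confidence = 0.95) {
  stopifnot(length(n) == 1, n >= 1, coverage > 0, coverage < 1,
            confidence > 0, confidence < 1)
  n <- as.integer(n)
  r <- seq_len(n)
  # P[X >= r] and P[X <= s - 1] for X ~ Binomial(n, coverage)
  surv <- pbinom(r - 1, n, coverage, lower.tail = FALSE)
  cdf <- pbinom(r - 1, n, coverage)
  rank_outer <- if (any(surv >= confidence)) max(r[surv >= confidence]) else NA_integer_
  rank_inner <- if (any(cdf >= confidence)) min(r[cdf >= confidence]) else NA_integer_
  list(rank_outer = as.integer(rank_outer), rank_inner = as.integer(rank_inner),
       n = n, coverage = coverage, confidence = confidence)
}

#' Tolerance limit values for a sample of adjusted scores
#'
#' Sorts the adjusted scores ascending (stable, tie-broken by `ids` when
#' given, so repeated runs are reproducible) and reads the order statistics
#' at the ranks from [tolerance_limit_ranks()].
#'
#' @param adjusted Numeric vector of adjusted scores.
#' @param ids Optional tie-break key of the same length (e.g. participant ids).
#' @inheritParams tolerance_limit_ranks
#' @return A list with `otl`, `itl` (values; `otl` is `NA` when no outer rank
#'   exists), the ranks, `n`, `coverage` and `confidence`.
#' @export
tolerance_limits <- function(adjusted, ids = NULL, coverage = 0.05,
                             confidence = 0.95) {
  keep <- is.finite(adjusted)
  adjusted <- adjusted[keep]
  if (!is.null(ids)) ids <- ids[keep]
  n <- length(adjusted)
  if (n < 1) abort("Need at least one finite adjusted score.", class = "tfab_domain_error")
  ord <- if (is.null(ids)) order(adjusted) else order(adjusted, ids)
  sorted <- adjusted[ord]
  rk <- tolerance_limit_ranks(n, coverage, confidence)
  otl <- if (is.na(rk$rank_outer)) NA_real_ else sorted[rk$rank_outer]
  itl <- if (is.na(rk$rank_inner)) NA_real_ else sorted[rk$rank_inner]
  list(otl = otl, itl = itl, rank_outer = rk$rank_outer,
       rank_inner = rk$rank_inner, n = n, coverage = coverage,
       confidence = confidence)
}
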