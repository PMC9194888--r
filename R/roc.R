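# ROC discrimination of clinical cases from normative controls. The AUC is
# the tie-corrected Mann-Whitney probability that a random case ranks more
# case-like than a random control; impairment lowers battery scores, so the
# default orientation treats lower scores as case-like.

#' ROC area under the curve with DeLong or Hanley-McNeil standard error
#'
#' @param cases,controls Numeric score vectors for the two groups.
#' @param direction `"lower_score_is_case"` (default: low scores indicate
#'   impairment) or `"higher_score_is_case"`.
#' @param se_method `"delong"` (default) or `"hanley"` (Hanley-McNeil, kept
#'   for comparability with spreadsheet ROC calculators).
#' @param conf_level Confidence level of the Wald interval (clipped to [0, 1]).
#' @return A `tfab_roc` object with `auc`, `se`, `ci95`, `n_cases`,
#'   `n_controls`, `direction` and the oriented scores (used by
#'   [autoplot.tfab_roc()]).
#' @examples
#' hp <- compute_scores(simulate_normative(n = 346, seed = 17))
#' cl <- compute_scores(simulate_clinical("pooled", seed = 17))
#' roc_auc(cl$tfab_m, hp$tfab_m)
#' @export
roc_auc <- function(cases, controls,
                    direction = c("lower_score_is_case", "higher_score_is_case"),
                    se_method = c("delong", "hanley"), conf_level = 0.95) {
  direction <- match.arg(direction)
  se_method <- match.arg(se_method)
  cases <- cases[!is.na(cases)]
  controls <- controls[!is.na(controls)]
  n1 <- length(cases); n2 <- length(controls)
  if (n1 < 1 || n2 < 1) abort("Both groups need at least one score.",
                              class = "tfab_domain_error")
  # orient so cases tend high, then AUC = P[case > control] + 0.5 P[tie]
  x <- if (direction == "lower_score_is_case") -cases else cases
  y <- if (direction == "lower_score_is_case") -controls else controls
  r <- rank(c(x, y))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  # placement values (exact, tie-corrected)
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(cmp)  # per-case placement
  v01 <- colMeans(cmp)  # per-control placement
  se <- if (se_method == "delong") {
    if (n1 > 1 && n2 > 1) sqrt(var(v10) / n1 + var(v01) / n2) else NA_real_
  } else {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
            (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- if (is.na(se)) c(NA_real_, NA_real_) else
    c(max(0, auc - z * se), min(1, auc + z * se))
  structure(list(auc = auc, se = se, ci95 = ci, n_cases = n1, n_controls = n2,
                 direction = direction, se_method = se_method,
                 unstable = n1 < 2 || n2 < 2,
                 scores_cases = x, scores_controls = y),
            class = "tfab_roc")
}

#' @export
print.tfab_roc <- function(x, ...) {
  cat(sprintf("<tfab ROC> AUC = %.3f (SE %.3f, 95%% CI %.3f-%.3f)\n",
              x$auc, x$se, x$ci95[1], x$ci95[2]))
  cat(sprintf("  %d cases vs %d controls, %s, %s SE%s\n",
              x$n_cases, x$n_controls, x$direction, x$se_method,
              if (x$unstable) " [unstable: group with < 2 members]" else ""))
  invisible(x)
}

#' Per-group ROC table against a reference (normative) group
#'
#' Mirrors the clinical-usability layout: one ROC analysis per non-reference
#' group per outcome, each against the reference group. Optional subgroup
#' splits (e.g. by a companion screening band) can be expressed by recoding
#' the grouping column beforehand.
#'
#' @param data A cohort data frame with score columns and a grouping column.
#' @param scores Character vector of score columns (default total scores of
#'   the two battery versions).
#' @param group Name of the grouping column (default `"group"`).
#' @param reference Reference (control) group label (default `"HP"`).
#' @inheritParams roc_auc
#' @return A tibble with one row per group x score: `group`, `outcome`, `n`,
#'   `auc`, `se`, `ci_low`, `ci_high`, `unstable`. Groups with fewer than 2
#'   members are still computed but flagged unstable.
#' @examples
#' hp <- compute_scores(simulate_normative(n = 100, seed = 19))
#' cl <- compute_scores(simulate_clinical("pooled", seed = 19))
#' roc_table(dplyr::bind_rows(hp, cl))
#' @export
roc_table <- function(data, scores = c("tfab_m", "tfab_v"), group = "group",
                      reference = "HP",
                      direction = c("lower_score_is_case", "higher_score_is_case"),
                      se_method = c("delong", "hanley")) {
  direction <- match.arg(direction)
  se_method <- match.arg(se_method)
  data <- as_tibble(data)
  stopifnot(group %in% names(data))
  g <- data[[group]]
  if (!reference %in% g) {
    abort(paste0("Reference group '", reference, "' not found."),
          class = "tfab_validation_error")
  }
  others <- setdiff(unique(g[!is.na(g)]), reference)
  purrr::map_dfr(others, function(lvl) {
    purrr::map_dfr(scores, function(sc) {
      rr <- roc_auc(data[[sc]][g == lvl], data[[sc]][g == reference],
                    direction = direction, se_method = se_method)
      tibble(group = lvl, outcome = sc, n = rr$n_cases, auc = rr$auc,
             se = rr$se, ci_low = rr$ci95[1], ci_high = rr$ci95[2],
             unstable = rr$unstable)
    })
  })
}
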