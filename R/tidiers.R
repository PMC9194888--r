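# broom-style tidiers for the package's result objects.

#' Tidy a normative model
#'
#' @param x A `tfab_model`.
#' @param ... Unused.
#' @return One row per outcome x adjustment term, with the tolerance limits
#'   and ES boundaries repeated per outcome.
#' @export
tidy.tfab_model <- function(x, ...) {
  purrr::imap_dfr(x$outcomes, function(o, nm) {
    terms <- o$equation$terms
    if (nrow(terms) == 0) {
      terms <- tibble(variable = NA_character_, transform = NA_character_,
                      coefficient = NA_real_, center = NA_real_)
    }
    terms %>%
      mutate(outcome = nm, otl = o$tl$otl, itl = o$tl$itl,
             es4_from = o$es$boundaries[4], .before = 1)
  })
}

#' @rdname tidy.tfab_model
#' @export
glance.tfab_model <- function(x, ...) {
  tibble(source = x$meta$source %||% "user-derived", n = x$meta$n,
         n_outcomes = length(x$outcomes),
         age_min = x$meta$age_range[1], age_max = x$meta$age_range[2],
         education_min = x$meta$education_range[1],
         education_max = x$meta$education_range[2],
         flags = paste(x$meta$flags %||% character(), collapse = "; "))
}

#' Tidy a stepwise adjustment fit
#'
#' @param x A `tfab_adjustment` from [fit_adjustment()].
#' @param ... Unused.
#' @export
tidy.tfab_adjustment <- function(x, ...) {
  if (nrow(x$steps) == 0) {
    return(tibble(variable = character(), transform = character(),
                  slope = numeric(), coefficient = numeric(),
                  center = numeric(), p_value = numeric()))
  }
  x$steps %>%
    mutate(coefficient = -.data$slope) %>%
    select("variable", "transform", "slope", "coefficient", "center", "p_value")
}

#' @rdname tidy.tfab_adjustment
#' @export
glance.tfab_adjustment <- function(x, ...) {
  tibble(outcome = x$outcome, n = x$n, r_squared = x$r_squared,
         n_terms = nrow(x$steps), entry_alpha = x$entry_alpha)
}

#' Tidy a paired TOST result
#'
#' @param x A `tfab_tost`.
#' @param ... Unused.
#' @return One row per one-sided bound plus the companion zero-difference
#'   t-test.
#' @export
tidy.tfab_tost <- function(x, ...) {
  tibble(test = c("lower bound", "upper bound", "difference vs 0"),
         statistic = c(x$t_lower, x$t_upper, x$t_test$statistic),
         df = x$df,
         p_value = c(x$p_lower, x$p_upper, x$t_test$p_value))
}

#' @rdname tidy.tfab_tost
#' @export
glance.tfab_tost <- function(x, ...) {
  tibble(n = x$n, mean_diff = x$mean_diff, sd_diff = x$sd_diff, dz = x$dz,
         bound_dz = x$bounds_dz[2], alpha = x$alpha, equivalent = x$equivalent)
}

#' Tidy an intraclass correlation result
#'
#' @param x A `tfab_icc`.
#' @param ... Unused.
#' @export
tidy.tfab_icc <- function(x, ...) {
  tibble(type = x$type, icc = x$value, ci_low = x$ci95[1], ci_high = x$ci95[2],
         n_subjects = x$n_subjects, n_raters = x$n_raters)
}

#' Tidy a principal-component structure result
#'
#' @param x A `tfab_pca`.
#' @param ... Unused.
#' @return One row per variable with its first-component loading.
#' @export
tidy.tfab_pca <- function(x, ...) {
  tibble(variable = names(x$loadings_pc1) %||% paste0("v", seq_along(x$loadings_pc1)),
         loading_pc1 = unname(x$loadings_pc1))
}

#' @rdname tidy.tfab_pca
#' @export
glance.tfab_pca <- function(x, ...) {
  tibble(p = x$p, pct_variance_pc1 = x$pct_variance_pc1,
         n_retained = x$n_retained, eigenvalue_1 = x$eigenvalues[1])
}

#' Tidy a ROC result
#'
#' @param x A `tfab_roc`.
#' @param ... Unused.
#' @export
tidy.tfab_roc <- function(x, ...) {
  tibble(auc = x$auc, se = x$se, ci_low = x$ci95[1], ci_high = x$ci95[2],
         n_cases = x$n_cases, n_controls = x$n_controls,
         direction = x$direction, se_method = x$se_method,
         unstable = x$unstable)
}
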