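# Deriving a normative model from a cohort: stepwise selection of
# demographic confounders (with per-variable transform pre-screen),
# tolerance limits on the ranked adjusted scores, Equivalent Score
# thresholds between the outer limit and the median.

default_candidates <- function() {
  list(age = c("identity", "square", "cube"),
       education = c("identity", "log10", "ln", "reciprocal"),
       sex = "identity")
}

#' Fit a demographic adjustment equation by forward stepwise selection
#'
#' For each demographic variable (age, education, sex) the best-fitting
#' candidate transform (largest residual-sum-of-squares reduction given the
#' terms already entered) is found; across variables, the best candidate
#' enters the model if its coefficient is significant at `entry_alpha`.
#' Selection stops when no remaining candidate is significant.
#'
#' The returned equation corrects towards the cohort-average profile:
#' term coefficients are the *negated* regression slopes and centers are the
#' cohort means of the transformed variables, so
#' `AS = RS - slope * (f(x) - mean(f(x)))`.
#'
#' @param data Cohort data frame with `age`, `education`, `sex` and the
#'   outcome column; rows with missing values or non-positive education are
#'   dropped.
#' @param outcome Name of the score column to model.
#' @param entry_alpha Significance level for a term to enter (default 0.05).
#' @param candidates Named list of candidate transforms per variable; defaults
#'   to age: identity/square/cube, education: identity/log10/ln/reciprocal,
#'   sex: indicator.
#' @return A `tfab_adjustment` object: `equation` ([adjustment_equation()]),
#'   `steps` (per-step tibble with slope, p-value, R2), `n`, `r_squared`.
#' @examples
#' cohort <- simulate_normative(n = 400, seed = 7)
#' cohort <- compute_scores(cohort)
#' fit_adjustment(cohort, "tfab_m")
#' @export
fit_adjustment <- function(data, outcome, entry_alpha = 0.05,
                           candidates = default_candidates()) {
  data <- as_tibble(data)
  stopifnot(outcome %in% names(data))
  keep <- complete.cases(data[, intersect(c(outcome, "age", "education", "sex"),
                                          names(data))])
  if ("education" %in% names(data)) keep <- keep & data$education > 0
  d <- data[keep, ]
  n <- nrow(d)
  if (n < 30) {
    abort("Need at least 30 complete records to fit an adjustment.",
          class = "tfab_domain_error")
  }
  y <- d[[outcome]]
  if (var(y) == 0) {
    abort(paste0("Outcome `", outcome, "` has zero variance."),
          class = "tfab_domain_error")
  }

  # candidate design columns, dropping degenerate (zero-variance) predictors
  cand <- purrr::imap_dfr(candidates, function(transforms, variable) {
    if (!variable %in% names(d)) return(tibble())
    x0 <- equation_variable(variable, d$age, d$education, d$sex)
    purrr::map_dfr(transforms, function(tr) {
      tibble(variable = variable, transform = tr,
             values = list(apply_transform(tr, x0)))
    })
  })
  degenerate <- purrr::map_lgl(cand$values, ~ var(.x) == 0)
  if (any(degenerate)) {
    warn(paste0("Dropping zero-variance candidate(s): ",
                paste(unique(cand$variable[degenerate]), collapse = ", ")))
    cand <- cand[!degenerate, ]
  }

  selected <- tibble(variable = character(), transform = character(),
                     slope = numeric(), p_value = numeric(),
                     r_squared = numeric(), center = numeric())
  X <- matrix(1, n, 1)
  repeat {
    remaining <- cand[!cand$variable %in% selected$variable, ]
    if (nrow(remaining) == 0) break
    rss <- purrr::map_dbl(remaining$values, function(v) {
      fit <- stats::lm.fit(cbind(X, v), y)
      sum(fit$residuals^2)
    })
    # ties (e.g. log10 vs ln, identical up to scale) break to the first
    # candidate in declared order, so selection is deterministic
    best <- which(rss <= min(rss) * (1 + 1e-9))[1]
    v <- remaining$values[[best]]
    fit <- lm(y ~ X - 1 + v)
    sm <- summary(fit)
    pcoef <- sm$coefficients
    p <- pcoef[nrow(pcoef), 4]
    if (!is.finite(p) || p >= entry_alpha) break
    selected <- bind_rows(selected, tibble(
      variable = remaining$variable[[best]],
      transform = remaining$transform[[best]],
      slope = unname(pcoef[nrow(pcoef), 1]), p_value = unname(p),
      r_squared = sm$r.squared, center = mean(v)
    ))
    X <- cbind(X, v)
  }

  # refit jointly so reported slopes/centers come from the final model
  if (nrow(selected)) {
    vals <- purrr::map2(selected$variable, selected$transform, function(va, tr) {
      apply_transform(tr, equation_variable(va, d$age, d$education, d$sex))
    })
    Xf <- do.call(cbind, vals)
    fit <- lm(y ~ Xf)
    sm <- summary(fit)
    selected$slope <- unname(coef(fit)[-1])
    selected$p_value <- unname(sm$coefficients[-1, 4])
    selected$center <- purrr::map_dbl(vals, mean)
    r2 <- sm$r.squared
  } else {
    r2 <- 0
  }

  eq <- adjustment_equation(outcome, tibble(
    variable = selected$variable, transform = selected$transform,
    coefficient = -selected$slope, center = selected$center
  ))
  structure(list(equation = eq, steps = selected, n = n, outcome = outcome,
                 r_squared = r2, entry_alpha = entry_alpha),
            class = "tfab_adjustment")
}

#' @export
print.tfab_adjustment <- function(x, ...) {
  cat("<tfab stepwise adjustment fit> outcome:", x$outcome,
      sprintf("(n = %d, R2 = %.3f)\n", x$n, x$r_squared))
  if (nrow(x$steps) == 0) {
    cat("  no significant demographic predictors; AS = RS\n")
  } else {
    for (i in seq_len(nrow(x$steps))) {
      s <- x$steps[i, ]
      cat(sprintf("  %s(%s): slope %+.6g, p = %.3g\n",
                  s$transform, s$variable, s$slope, s$p_value))
    }
  }
  invisible(x)
}

#' Equivalent Score thresholds from a sample of adjusted scores
#'
#' Places the four ES cut points on the derivation sample: ES0 ends at the
#' outer tolerance limit; ES4 starts at the sample median; the two
#' intermediate cut points are the order statistics at the centiles obtained
#' by splitting the standard-normal interval from z = -1.645 to z = 0 into
#' four equal z-segments (defaults 0.1086 and 0.2054). Boundaries are
#' reported at 2-decimal resolution.
#'
#' @param adjusted Numeric vector of adjusted scores (derivation sample).
#' @param tl Tolerance limits from [tolerance_limits()] computed on the same
#'   sample; computed on the fly when omitted.
#' @param centiles Two ascending centiles in (coverage, 0.5) for the lower
#'   edges of bands ES2 and ES3.
#' @return An [es_table()]; `es0_defined` is `FALSE` when the sample is too
#'   small for an outer tolerance limit (the ES0 cut then falls back to the
#'   first order statistic minus one resolution step so the table remains
#'   well-formed, but ES0 classifications are reported as `NA`).
#' @export
derive_es_thresholds <- function(adjusted, tl = NULL,
                                 centiles = c(0.1086, 0.2054)) {
  adjusted <- adjusted[is.finite(adjusted)]
  n <- length(adjusted)
  if (n < 4) abort("Need at least 4 adjusted scores.", class = "tfab_domain_error")
  stopifnot(length(centiles) == 2, diff(centiles) > 0)
  if (is.null(tl)) tl <- tolerance_limits(adjusted)
  sorted <- sort(adjusted)
  pick <- function(p) sorted[min(n, max(1, round(n * p)))]
  es0_defined <- !is.na(tl$otl)
  b01 <- if (es0_defined) round(tl$otl, 2) else round(sorted[1], 2) - 0.01
  b12 <- round(pick(centiles[1]), 2) + 0.01
  b23 <- round(pick(centiles[2]), 2) + 0.01
  b34 <- round(median(adjusted), 2)
  b <- c(b01, b12, b23, b34)
  if (any(diff(b) <= 0)) {
    abort(paste0("Too few distinct adjusted values: ES bands collapse (cuts ",
                 paste(sprintf("%.2f", b), collapse = ", "), ")."),
          class = "tfab_collapsed_band_error")
  }
  es_table(b, es0_defined = es0_defined)
}

#' Derive a complete normative model from a cohort
#'
#' Composes the full norming pipeline per outcome: stepwise demographic
#' adjustment ([fit_adjustment()]), adjustment of every record, exact
#' binomial tolerance limits on the ranked adjusted scores
#' ([tolerance_limits()]) and ES thresholds ([derive_es_thresholds()]).
#' Deterministic given the cohort and settings.
#'
#' @param data Cohort data frame; task columns are expanded to outcome scores
#'   with [compute_scores()] when present.
#' @param outcomes Score columns to norm (default: the five battery scores).
#' @param entry_alpha Stepwise entry level.
#' @param centiles Intermediate ES centiles, see [derive_es_thresholds()].
#' @param coverage,confidence Tolerance-limit parameters.
#' @return A `tfab_model`. When the cohort is smaller than the minimal size
#'   admitting an outer tolerance limit the model carries
#'   `meta$flags = "no outer TL"` and ES0 is undefined for every outcome.
#' @examples
#' cohort <- compute_scores(simulate_normative(n = 346, seed = 11))
#' m <- build_normative_model(cohort, outcomes = c("tfab_m", "tfab_v"))
#' m
#' @export
build_normative_model <- function(data, outcomes = tfab_outcomes,
                                  entry_alpha = 0.05,
                                  centiles = c(0.1086, 0.2054),
                                  coverage = 0.05, confidence = 0.95) {
  data <- as_tibble(data)
  if (all(tfab_task_cols %in% names(data)) &&
      !all(outcomes %in% names(data))) {
    data <- compute_scores(data)
  }
  outcomes <- intersect(outcomes, names(data))
  if (!length(outcomes)) {
    abort("None of the requested outcome columns are present.",
          class = "tfab_validation_error")
  }
  if (!"id" %in% names(data)) data$id <- as.character(seq_len(nrow(data)))
  fitted <- purrr::map(outcomes, function(outc) {
    fit <- fit_adjustment(data, outc, entry_alpha = entry_alpha)
    keep <- !is.na(data[[outc]]) & is.finite(data$education) & data$education > 0 &
      is.finite(data$age)
    adj <- adjust_score(fit$equation, data[[outc]][keep], age = data$age[keep],
                        education = data$education[keep], sex = data$sex[keep])
    tl <- tolerance_limits(adj, ids = data$id[keep], coverage = coverage,
                           confidence = confidence)
    es <- derive_es_thresholds(adj, tl, centiles = centiles)
    model_outcome(fit$equation, tl, es, fit = fit$steps)
  })
  names(fitted) <- outcomes
  flags <- character()
  if (any(purrr::map_lgl(fitted, ~ is.na(.x$tl$otl)))) flags <- c(flags, "no outer TL")
  new_tfab_model(fitted, meta = list(
    source = "user-derived", n = nrow(data),
    age_range = range(data$age, na.rm = TRUE),
    education_range = range(data$education, na.rm = TRUE),
    settings = list(entry_alpha = entry_alpha, centiles = centiles,
                    coverage = coverage, confidence = confidence),
    flags = flags
  ))
}
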