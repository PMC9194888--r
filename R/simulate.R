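# Seeded synthetic cohorts with the statistical structure the analyses
# assume: a normative sample stratified by age band x education band x sex,
# discrete 0-12 totals with a heavy ceiling at 12 (calibrated by a
# deterministic bisection on the seeded sample), education effects on every
# score and an age effect on the motor-response scores only (inherited from
# the published adjustment equations used as the generating truth), and
# clinical cohorts reproducing the reported group means and SDs.

# Normative stratification: counts per education band (rows: <=5, 6-8, 9-12,
# 13-16, >=17) x age band (<=30, 31-45, 46-60, 61-70, 71-80, >=81) x sex.
tfab_strata_counts <- local({
  age_bands <- c("18-30", "31-45", "46-60", "61-70", "71-80", "81-96")
  edu_bands <- c("4-5", "6-8", "9-12", "13-16", "17-23")
  m <- c(0, 0, 0, 1, 1, 1,
         5, 2, 8, 4, 3, 2,
         1, 0, 2, 4, 3, 1,
         33, 9, 21, 5, 1, 0,
         13, 4, 9, 7, 2, 1)
  f <- c(0, 0, 0, 2, 2, 8,
         0, 2, 13, 2, 4, 3,
         1, 1, 12, 5, 2, 1,
         29, 11, 43, 13, 3, 1,
         20, 5, 11, 7, 0, 2)
  grid <- expand.grid(age_band = age_bands, edu_band = edu_bands,
                      stringsAsFactors = FALSE)
  tibble::tibble(
    edu_band = rep(grid$edu_band, 2), age_band = rep(grid$age_band, 2),
    sex = rep(c("M", "F"), each = nrow(grid)), count = c(m, f)
  )
})

band_limits <- function(band) as.numeric(strsplit(band, "-")[[1]])

sample_in_band <- function(bands) {
  lims <- vapply(bands, band_limits, numeric(2))
  lo <- lims[1, ]; hi <- lims[2, ]
  floor(runif(length(bands), lo, hi + 1))
}

# Split a subtest total k (0-6) into two task scores greedily (3, then the
# remainder): arbitrary but deterministic; analyses use subtests and totals.
split_tasks <- function(k) {
  first <- pmin(3, k)
  cbind(first, k - first)
}

# Shared-subtest decomposition: subtest 1 is common to both versions, so it
# must fit under both totals; the target value floor((M + V) / 4) is clamped
# into the feasible window.
decompose_totals <- function(m_total, v_total) {
  lo <- pmax(0, m_total - 6, v_total - 6)
  hi <- pmin(6, m_total, v_total)
  t1 <- pmin(hi, pmax(lo, floor((m_total + v_total) / 4)))
  list(tfab_1 = t1, tfab_2m = m_total - t1, tfab_2v = v_total - t1)
}

round_clamp <- function(x, lo, hi) pmin(hi, pmax(lo, round(x)))

# Deterministic ceiling calibration: with demographics and noise fixed, the
# fraction of discretized totals at the maximum is monotone in the anchor;
# bisect the anchor until the target ceiling rate is met.
calibrate_anchor <- function(effect, noise, target, max_score = 12) {
  frac <- function(a) mean(round_clamp(a + effect + noise, 0, max_score) == max_score)
  lo <- 0; hi <- 40
  if (frac(hi) < target) abort("Infeasible ceiling target.", class = "tfab_spec_error")
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (frac(mid) < target) lo <- mid else hi <- mid
  }
  hi
}

#' Simulate a normative cohort
#'
#' Generates demographics from the normative stratification table (age band x
#' education band x sex), then builds, for each battery version, a continuous
#' latent propensity `anchor - adjustment(age, education) + noise` using the
#' published adjustment equations as the generating truth (so education
#' affects every score and age only the motor-response scores), discretizes
#' by rounding and truncation to 0-12, and decomposes totals into shared
#' subtest-1 and version-specific subtest-2 task scores. The anchors are
#' calibrated by a deterministic bisection on the seeded sample so the
#' fraction of totals at 12 matches the observed ceiling rates (35.8% motor,
#' 39.3% verbal) to well within +-0.02.
#'
#' @param n Cohort size (default 346, the normative sample size).
#' @param seed Integer seed; required, so cohorts never drift silently.
#' @param latent_sd Residual SD of the latent propensity, in score points
#'   (default 1.3, chosen so the discretized totals show a marginal SD near
#'   the observed 1.2-1.5 once the ceiling takes its mass).
#' @param version_cor Correlation of the two versions' latent residuals
#'   (default 0.6; the within-person motor-verbal correlation is not
#'   published and is exposed as a free parameter).
#' @param ceiling_m,ceiling_v Target ceiling fractions for the motor and
#'   verbal totals.
#' @param model Normative model supplying the generating adjustment
#'   equations (default [tfab_norms]).
#' @param discretize If `FALSE`, returns the continuous latent scores
#'   (columns `tfab_m`, `tfab_v`, ...) without rounding, truncation or task
#'   decomposition — the uncensored regime for studying the norming
#'   estimators themselves.
#' @return A tibble of participant records: `id`, `age`, `education`, `sex`,
#'   six task columns (when discretized) and `group = "HP"`.
#' @examples
#' cohort <- simulate_normative(n = 346, seed = 1)
#' mean(compute_scores(cohort)$tfab_m == 12)
#' @export
simulate_normative <- function(n = 346, seed, latent_sd = 1.3,
                               version_cor = 0.6,
                               ceiling_m = 0.358, ceiling_v = 0.393,
                               model = tfab_norms, discretize = TRUE) {
  if (missing(seed)) abort("`seed` is required.", class = "tfab_spec_error")
  stopifnot(n >= 1, latent_sd > 0, version_cor >= 0, version_cor < 1)
  if (ceiling_m >= 1 || ceiling_v >= 1 || ceiling_m <= 0 || ceiling_v <= 0) {
    abort("Ceiling targets must lie in (0, 1).", class = "tfab_spec_error")
  }
  withr::local_seed(seed)
  strata <- tfab_strata_counts
  idx <- sample(nrow(strata), n, replace = TRUE, prob = strata$count)
  age <- sample_in_band(strata$age_band[idx])
  education <- sample_in_band(strata$edu_band[idx])
  sex <- strata$sex[idx]

  adj <- purrr::map(model$outcomes, function(o) {
    adjust_score(o$equation, 0, age = age, education = education, sex = sex)
  })
  z0 <- rnorm(n); zm <- rnorm(n); zv <- rnorm(n)
  mix <- function(zi) latent_sd * (sqrt(version_cor) * z0 +
                                     sqrt(1 - version_cor) * zi)
  e_m <- mix(zm); e_v <- mix(zv)

  if (!discretize) {
    a_m <- 12.2; a_v <- 12.4  # uncensored regime: anchors near the ceiling
    out <- tibble(
      id = sprintf("HP%04d", seq_len(n)), age = age, education = education,
      sex = sex,
      tfab_m = a_m - adj$tfab_m + e_m,
      tfab_v = a_v - adj$tfab_v + e_v,
      tfab_1 = (a_m + a_v) / 4 - adj$tfab_1 + (e_m + e_v) / 4,
      tfab_2m = a_m / 2 - adj$tfab_2m + e_m / 2,
      tfab_2v = a_v / 2 - adj$tfab_2v + e_v / 2,
      group = "HP"
    )
    return(out)
  }

  a_m <- calibrate_anchor(-adj$tfab_m, e_m, ceiling_m)
  a_v <- calibrate_anchor(-adj$tfab_v, e_v, ceiling_v)
  m_total <- round_clamp(a_m - adj$tfab_m + e_m, 0, 12)
  v_total <- round_clamp(a_v - adj$tfab_v + e_v, 0, 12)
  parts <- decompose_totals(m_total, v_total)
  t1 <- split_tasks(parts$tfab_1)
  t2m <- split_tasks(parts$tfab_2m)
  t2v <- split_tasks(parts$tfab_2v)
  tibble(
    id = sprintf("HP%04d", seq_len(n)), age = age, education = education,
    sex = sex,
    conceptualization = t1[, 1], mental_flexibility = t1[, 2],
    interference_m = t2m[, 1], inhibition_m = t2m[, 2],
    interference_v = t2v[, 1], inhibition_v = t2v[, 2],
    group = "HP"
  )
}

#' Reference parameters of the clinical cohorts
#'
#' Group-level demographic and score means/SDs (with observed ranges) of the
#' neurological cohorts used as simulation defaults: extra-pyramidal disease
#' (EPD), small-vessel disease split by companion-MMSE band, left/right
#' hemispheric stroke, mixed dementia (MD), and the pooled cohort.
#'
#' @return A tibble with one row per group.
#' @export
clinical_defaults <- function() {
  tibble::tribble(
    ~group, ~n, ~age_mean, ~age_sd, ~age_min, ~age_max,
    ~edu_mean, ~edu_sd, ~edu_min, ~edu_max,
    ~fabm_mean, ~fabm_sd, ~fabv_mean, ~fabv_sd,
    "pooled",            40, 73.10, 11.50, 38, 91, 13.3, 4.39, 5, 18, 8.63, 2.66, 9.30, 2.17,
    "EPD",                6, 76.00,  5.06, 70, 82, 14.0, 5.18, 5, 18, 9.00, 3.23, 9.50, 3.02,
    "SVD_mmse_normal",   14, 76.07,  8.87, 56, 87, 12.0, 4.37, 5, 18, 9.43, 1.99, 10.00, 1.71,
    "SVD_mmse_impaired",  6, 81.33,  7.97, 68, 91, 14.5, 3.94, 8, 18, 7.50, 3.89, 8.67, 2.25,
    "stroke_L",           5, 54.60, 12.42, 38, 67, 14.0, 4.18, 8, 18, 10.00, 2.35, 9.80, 1.79,
    "stroke_R",           5, 68.80,  9.73, 54, 78, 13.8, 5.31, 8, 18, 7.40, 1.67, 9.40, 1.67,
    "MD",                 4, 74.50,  9.98, 60, 82, 13.5, 4.80, 8, 18, 6.75, 2.22, 6.75, 2.22
  )
}

#' Simulate a clinical cohort
#'
#' Draws total scores from a bivariate normal with the group's reported
#' motor/verbal means and SDs (correlation `version_cor`), rounds and
#' truncates to 0-12, decomposes into task scores, and attaches demographics
#' drawn from the group's reported age/education distributions (clamped to
#' the observed ranges).
#'
#' @param group One of the rows of [clinical_defaults()] (`"pooled"`,
#'   `"EPD"`, `"SVD_mmse_normal"`, `"SVD_mmse_impaired"`, `"stroke_L"`,
#'   `"stroke_R"`, `"MD"`), or any label when all parameters are overridden.
#' @param seed Integer seed; required.
#' @param n Cohort size; defaults to the group's reported size.
#' @param fabm_mean,fabm_sd,fabv_mean,fabv_sd Optional overrides of the score
#'   distribution.
#' @param version_cor Latent correlation between the two versions.
#' @param label Group label written to the `group` column (defaults to
#'   `group`, with the two small-vessel bands collapsed to `"SVD"`).
#' @return A tibble of participant records in the same shape as
#'   [simulate_normative()].
#' @examples
#' simulate_clinical("MD", seed = 2)
#' @export
simulate_clinical <- function(group = "pooled", seed, n = NULL,
                              fabm_mean = NULL, fabm_sd = NULL,
                              fabv_mean = NULL, fabv_sd = NULL,
                              version_cor = 0.6, label = NULL) {
  if (missing(seed)) abort("`seed` is required.", class = "tfab_spec_error")
  defs <- clinical_defaults()
  if (!group %in% defs$group) {
    abort(paste0("Unknown clinical group '", group, "'."), class = "tfab_spec_error")
  }
  p <- defs[defs$group == group, ]
  n <- n %||% p$n
  stopifnot(n >= 1)
  fabm_mean <- fabm_mean %||% p$fabm_mean
  fabm_sd <- fabm_sd %||% p$fabm_sd
  fabv_mean <- fabv_mean %||% p$fabv_mean
  fabv_sd <- fabv_sd %||% p$fabv_sd
  if (fabm_sd <= 0 || fabv_sd <= 0) abort("Score SDs must be > 0.", class = "tfab_spec_error")
  label <- label %||% sub("_mmse.*$", "", group)
  withr::local_seed(seed)
  age <- round_clamp(rnorm(n, p$age_mean, p$age_sd), p$age_min, p$age_max)
  education <- round_clamp(rnorm(n, p$edu_mean, p$edu_sd), p$edu_min, p$edu_max)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  z0 <- rnorm(n); zm <- rnorm(n); zv <- rnorm(n)
  mix <- function(zi) sqrt(version_cor) * z0 + sqrt(1 - version_cor) * zi
  m_total <- round_clamp(fabm_mean + fabm_sd * mix(zm), 0, 12)
  v_total <- round_clamp(fabv_mean + fabv_sd * mix(zv), 0, 12)
  parts <- decompose_totals(m_total, v_total)
  t1 <- split_tasks(parts$tfab_1)
  t2m <- split_tasks(parts$tfab_2m)
  t2v <- split_tasks(parts$tfab_2v)
  tibble(
    id = sprintf("%s%03d", gsub("[^A-Za-z]", "", label), seq_len(n)),
    age = age, education = education, sex = sex,
    conceptualization = t1[, 1], mental_flexibility = t1[, 2],
    interference_m = t2m[, 1], inhibition_m = t2m[, 2],
    interference_v = t2v[, 1], inhibition_v = t2v[, 2],
    group = label
  )
}

#' Simulate the full clinical cohort
#'
#' Binds the five clinical groups (EPD, both small-vessel bands, left and
#' right stroke, mixed dementia) at their reported sizes into the 40-person
#' cohort, with per-group sub-seeds derived from `seed`.
#'
#' @param seed Integer seed; required.
#' @inheritParams simulate_clinical
#' @return A 40-row tibble with `group` in
#'   `{"EPD", "SVD", "stroke_L", "stroke_R", "MD"}` and an `mmse_band`
#'   column separating the two small-vessel bands.
#' @export
simulate_clinical_cohort <- function(seed, version_cor = 0.6) {
  if (missing(seed)) abort("`seed` is required.", class = "tfab_spec_error")
  groups <- setdiff(clinical_defaults()$group, "pooled")
  purrr::imap_dfr(setNames(groups, groups), function(g, nm) {
    out <- simulate_clinical(g, seed = seed + match(g, groups),
                             version_cor = version_cor)
    out$mmse_band <- if (g == "SVD_mmse_impaired") "ES <= 1"
                     else if (g == "SVD_mmse_normal") "ES > 1" else NA_character_
    out
  })
}

#' Simulate a subjects x raters reliability matrix
#'
#' Ratings are `mean + subject_effect + error`, rounded to integers, with the
#' subject and error variances chosen so that
#' `var_subject / (var_subject + var_error)` equals `icc_target`.
#'
#' @param n_subjects Number of subjects (default 25, the inter-rater
#'   subsample size).
#' @param icc_target Target intraclass correlation in (0, 1).
#' @param n_raters Number of raters/occasions (default 2).
#' @param seed Integer seed; required.
#' @param mean Grand mean of the ratings.
#' @param total_sd Total SD (subject + error) of a single rating before
#'   rounding (default 3).
#' @return An `n_subjects` x `n_raters` numeric matrix.
#' @examples
#' icc_reliability(simulate_raters(500, icc_target = 0.9, seed = 4))
#' @export
simulate_raters <- function(n_subjects = 25, icc_target, n_raters = 2, seed,
                            mean = 10, total_sd = 3) {
  if (missing(seed)) abort("`seed` is required.", class = "tfab_spec_error")
  if (icc_target <= 0 || icc_target >= 1) {
    abort("`icc_target` must lie in (0, 1).", class = "tfab_spec_error")
  }
  stopifnot(n_subjects >= 2, n_raters >= 2, total_sd > 0)
  withr::local_seed(seed)
  sd_s <- total_sd * sqrt(icc_target)
  sd_e <- total_sd * sqrt(1 - icc_target)
  subject <- rnorm(n_subjects, 0, sd_s)
  err <- matrix(rnorm(n_subjects * n_raters, 0, sd_e), n_subjects, n_raters)
  round(mean + subject + err)
}
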