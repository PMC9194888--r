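# A normative model bundles, per outcome, the demographic adjustment
# equation, the non-parametric tolerance limits and the Equivalent Score
# bands, plus cohort metadata (size, demographic coverage).

MODEL_SCHEMA <- "tfab-normative-model/1"

new_tfab_model <- function(outcomes, meta) {
  stopifnot(is.list(outcomes), length(names(outcomes)) == length(outcomes))
  structure(list(schema = MODEL_SCHEMA, outcomes = outcomes, meta = meta),
            class = "tfab_model")
}

model_outcome <- function(equation, tl, es, fit = NULL) {
  list(equation = equation, tl = tl, es = es, fit = fit)
}

#' @export
print.tfab_model <- function(x, ...) {
  cat("<tfab normative model>", x$meta$source %||% "user-derived", "\n")
  cat("  cohort n =", x$meta$n, "| age", paste(x$meta$age_range, collapse = "-"),
      "| education", paste(x$meta$education_range, collapse = "-"), "\n")
  for (nm in names(x$outcomes)) {
    o <- x$outcomes[[nm]]
    trm <- o$equation$terms
    vars <- if (nrow(trm)) paste0(trm$transform, "(", trm$variable, ")", collapse = " + ")
            else "none"
    otl <- if (is.na(o$tl$otl)) "none" else sprintf("%.2f", o$tl$otl)
    cat(sprintf("  %-8s adj: %-35s oTL %s  ES4 >= %.2f\n",
                nm, vars, otl, o$es$boundaries[4]))
  }
  invisible(x)
}

#' Published normative model for the telephone-based FAB
#'
#' The standardization model derived from the Italian normative sample
#' (n = 346, ages 18-96, education 4-23 years): per-outcome demographic
#' adjustment equations (printed at 6-decimal precision), outer/inner
#' tolerance limits and Equivalent Score bands for the five scores
#' `tfab_m`, `tfab_v`, `tfab_1`, `tfab_2m`, `tfab_2v`.
#'
#' Education predicts all five scores; age (as a cubic trend) additionally
#' affects the motor-response scores `tfab_m` and `tfab_2m` only.
#'
#' @format A `tfab_model` object; see [build_normative_model()] for the
#'   structure of user-derived models.
#' @examples
#' tfab_norms
#' score_participants(
#'   data.frame(id = "p1", age = 70, education = 8, sex = "F",
#'              conceptualization = 3, mental_flexibility = 2,
#'              interference_m = 2, inhibition_m = 2,
#'              interference_v = 3, inhibition_v = 2),
#'   tfab_norms
#' )
#' @export
tfab_norms <- local({
  eq <- function(outcome, ...) adjustment_equation(outcome, dplyr::bind_rows(...))
  trm <- function(variable, transform, coefficient, center) {
    tibble::tibble(variable = variable, transform = transform,
                   coefficient = coefficient, center = center)
  }
  age3_center <- 167162.855491
  log10_edu_center <- 1.106787
  rk <- tolerance_limit_ranks(346)
  tl <- function(otl, itl) {
    list(otl = otl, itl = itl, rank_outer = rk$rank_outer,
         rank_inner = rk$rank_inner, n = 346L, coverage = 0.05, confidence = 0.95)
  }
  outcomes <- list(
    tfab_m = model_outcome(
      eq("tfab_m",
         trm("age", "cube", 0.000002, age3_center),
         trm("education", "log10", -3.484874, log10_edu_center)),
      tl(8.07, 8.77), es_table(c(8.07, 9.46, 10.51, 11.04))),
    tfab_v = model_outcome(
      eq("tfab_v", trm("education", "reciprocal", 15.62586, 0.083175)),
      tl(8.48, 9.00), es_table(c(8.48, 9.84, 10.69, 10.94))),
    tfab_1 = model_outcome(
      eq("tfab_1", trm("education", "ln", -1.020062, 2.548471)),
      tl(3.54, 4.07), es_table(c(3.54, 4.50, 4.85, 5.46))),
    tfab_2m = model_outcome(
      eq("tfab_2m",
         trm("age", "cube", 0.000001, age3_center),
         trm("education", "log10", -1.462853, log10_edu_center)),
      tl(3.16, 4.00), es_table(c(3.16, 4.91, 5.67, 5.85))),
    tfab_2v = model_outcome(
      eq("tfab_2v", trm("education", "reciprocal", 5.921931, 0.083175)),
      tl(3.00, 5.00), es_table(c(3.00, 5.78, 5.87, 6.00)))
  )
  new_tfab_model(outcomes, meta = list(
    source = "published-norms-v1", n = 346L,
    age_range = c(18, 96), education_range = c(4, 23),
    settings = list(coverage = 0.05, confidence = 0.95)
  ))
})
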