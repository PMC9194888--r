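# Demographic adjustment equations: a raw score is corrected by adding
# coefficient * (transform(variable) - centering constant) terms, where the
# centering constants are normative-cohort means of the transformed variable.
# A participant at the centering profile is left untouched.

.tfab_transforms <- list(
  identity   = function(x) x,
  square     = function(x) x^2,
  cube       = function(x) x^3,
  log10      = function(x) log10(x),
  ln         = function(x) log(x),
  reciprocal = function(x) 1 / x
)

transform_names <- function() names(.tfab_transforms)

apply_transform <- function(transform, x) {
  fn <- .tfab_transforms[[transform]]
  if (is.null(fn)) {
    abort(paste0("Unknown transform '", transform, "'."), class = "tfab_config_error")
  }
  fn(x)
}

#' Create a demographic adjustment equation
#'
#' An adjustment equation corrects a raw test score to a reference demographic
#' profile: `AS = RS + sum(coefficient * (transform(variable) - center))`.
#' Centers are the normative-sample means of the transformed variables, so the
#' adjustment is exactly zero at the cohort-average profile.
#'
#' @param outcome Name of the score the equation applies to (e.g. `"tfab_m"`).
#' @param terms A data frame with columns `variable` (`"age"`, `"education"` or
#'   `"sex"`), `transform` (one of identity, square, cube, log10, ln,
#'   reciprocal), `coefficient` and `center`. May have zero rows (no
#'   demographic effect).
#' @return An object of class `tfab_equation`.
#' @examples
#' eq <- adjustment_equation(
#'   "tfab_v",
#'   data.frame(variable = "education", transform = "reciprocal",
#'              coefficient = 15.62586, center = 0.083175)
#' )
#' adjust_score(eq, rs = 10, education = 5)
#' @export
adjustment_equation <- function(outcome, terms) {
  terms <- as_tibble(terms)
  needed <- c("variable", "transform", "coefficient", "center")
  if (!all(needed %in% names(terms))) {
    abort(paste0("Equation terms need columns: ", paste(needed, collapse = ", ")),
          class = "tfab_config_error")
  }
  terms <- terms[needed]
  bad <- setdiff(terms$transform, transform_names())
  if (length(bad)) {
    abort(paste0("Unknown transform '", bad[[1]], "'."), class = "tfab_config_error")
  }
  if (!all(terms$variable %in% c("age", "education", "sex"))) {
    abort("Equation variables must be 'age', 'education' or 'sex'.",
          class = "tfab_config_error")
  }
  if (any(!is.finite(terms$coefficient)) || any(!is.finite(terms$center))) {
    abort("Equation coefficients and centers must be finite.",
          class = "tfab_config_error")
  }
  structure(list(outcome = outcome, terms = terms), class = "tfab_equation")
}

# Sex enters equations as an indicator (female = 1, male = 0).
sex_indicator <- function(sex) as.numeric(sex == "F")

equation_variable <- function(variable, age, education, sex) {
  switch(variable,
    age = age,
    education = education,
    sex = sex_indicator(sex),
    abort(paste0("Unknown variable '", variable, "'."), class = "tfab_config_error")
  )
}

#' Evaluate a demographic adjustment
#'
#' Returns the additive correction (for `rs = 0`) or the adjusted score.
#' Education must be strictly positive because the published transforms include
#' logarithms and reciprocals of education.
#'
#' @param eq A [adjustment_equation()] object.
#' @param rs Raw score(s); vectorised.
#' @param age,education,sex Demographics; vectorised, recycled against `rs`.
#' @return Numeric vector of adjusted scores (unrounded; the conventional
#'   2-decimal presentation is applied at reporting time). Adjusted scores are
#'   deliberately not clamped to the raw score range: the adjusted scale is an
#'   open regression scale.
#' @export
adjust_score <- function(eq, rs, age = NULL, education = NULL, sex = NULL) {
  stopifnot(inherits(eq, "tfab_equation"))
  vars <- unique(eq$terms$variable)
  if ("education" %in% vars) {
    if (is.null(education)) abort("Equation needs `education`.", class = "tfab_domain_error")
    if (any(education <= 0, na.rm = TRUE)) {
      abort("`education` must be > 0 (log/reciprocal transforms).",
            class = "tfab_domain_error")
    }
  }
  if ("age" %in% vars && is.null(age)) abort("Equation needs `age`.", class = "tfab_domain_error")
  if ("sex" %in% vars && is.null(sex)) abort("Equation needs `sex`.", class = "tfab_domain_error")
  adj <- 0
  for (i in seq_len(nrow(eq$terms))) {
    trm <- eq$terms[i, ]
    x <- equation_variable(trm$variable, age, education, sex)
    adj <- adj + trm$coefficient * (apply_transform(trm$transform, x) - trm$center)
  }
  rs + adj
}

#' @export
print.tfab_equation <- function(x, ...) {
  cat("<tfab adjustment equation> outcome:", x$outcome, "\n")
  if (nrow(x$terms) == 0) {
    cat("  AS = RS (no demographic terms)\n")
  } else {
    rhs <- paste0(
      sprintf("%+g", x$terms$coefficient), "*[", x$terms$transform, "(",
      x$terms$variable, ") - ", format(x$terms$center), "]", collapse = " "
    )
    cat("  AS = RS ", rhs, "\n", sep = "")
  }
  invisible(x)
}
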