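# Cohort CSV input with row-level validation, and JSON round-tripping of
# normative models (schema-versioned, full numeric precision, no run
# metadata, so identical derivations write identical bytes).

cohort_required_cols <- function() c("id", "age", "education", "sex", tfab_task_cols)

#' Read and validate a cohort CSV
#'
#' Expects the flat per-participant layout: columns `id`, `age`, `education`,
#' `sex`, the six task scores, optionally `group` and companion test scores
#' (any extra numeric columns are preserved). Column names are matched
#' case-insensitively. Row-level problems (missing demographics,
#' non-positive education, out-of-range task scores) are collected in an
#' issue report — out-of-range task values are set to `NA` — and are fatal
#' only under `strict = TRUE`; missing mandatory columns are always fatal.
#'
#' @param path Path to a CSV file.
#' @param strict Abort on any row-level issue.
#' @return A tibble of records with the issue report attached as
#'   `attr(, "issues")`; retrieve it with [validation_issues()].
#' @export
read_cohort <- function(path, strict = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "tfab_io_error")
  }
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(data) <- tolower(names(data))
  missing_cols <- setdiff(cohort_required_cols(), names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "tfab_io_error")
  }
  data$id <- as.character(data$id)
  issues <- list()
  note <- function(rows, column, problem) {
    if (length(rows)) {
      issues[[length(issues) + 1]] <<- tibble(row = rows, column = column,
                                              problem = problem)
    }
  }
  note(which(is.na(data$age)), "age", "missing")
  note(which(is.na(data$education)), "education", "missing")
  note(which(!is.na(data$education) & data$education <= 0), "education",
       "non-positive: excluded from adjustment-based analyses")
  note(which(!data$sex %in% c("M", "F")), "sex", "not M/F")
  for (col in tfab_task_cols) {
    x <- data[[col]]
    bad <- which(!is.na(x) & (x %% 1 != 0 | x < 0 | x > 3))
    note(bad, col, "outside 0..3: set to NA")
    if (length(bad)) data[[col]][bad] <- NA
  }
  issues <- if (length(issues)) bind_rows(issues) %>% arrange(.data$row) else
    tibble(row = integer(), column = character(), problem = character())
  if (strict && nrow(issues)) {
    abort(paste0(nrow(issues), " validation issue(s); first: row ",
                 issues$row[1], " ", issues$column[1], " (", issues$problem[1], ")"),
          class = "tfab_validation_error")
  }
  attr(data, "issues") <- issues
  data
}

#' @rdname read_cohort
#' @param data A cohort read by [read_cohort()].
#' @export
validation_issues <- function(data) {
  attr(data, "issues") %||%
    tibble(row = integer(), column = character(), problem = character())
}

model_to_list <- function(model) {
  list(
    schema = model$schema,
    outcomes = purrr::map(model$outcomes, function(o) {
      list(
        terms = purrr::pmap(o$equation$terms, function(variable, transform,
                                                       coefficient, center) {
          list(transform = transform, variable = variable,
               coefficient = coefficient, center = center)
        }),
        otl = o$tl$otl, itl = o$tl$itl,
        rank_outer = o$tl$rank_outer, rank_inner = o$tl$rank_inner,
        coverage = o$tl$coverage, confidence = o$tl$confidence,
        es_boundaries = o$es$boundaries, es0_defined = o$es$es0_defined,
        n = o$tl$n
      )
    }),
    meta = model$meta
  )
}

#' Write / read a normative model as JSON
#'
#' The JSON document is schema-versioned
#' (`"tfab-normative-model/1"`), carries numbers at full precision and no
#' run metadata, so rebuilding a model from the same cohort and settings
#' writes byte-identical files. `read_model()` validates the schema version,
#' the transform names and the monotonicity of the ES boundaries before
#' reconstructing the model.
#'
#' @param model A `tfab_model`.
#' @param path Output / input path.
#' @return `write_model()` returns `path` invisibly; `read_model()` returns
#'   the reconstructed `tfab_model`.
#' @examples
#' p <- tempfile(fileext = ".json")
#' write_model(tfab_norms, p)
#' identical(read_model(p)$outcomes$tfab_m$es$boundaries,
#'           tfab_norms$outcomes$tfab_m$es$boundaries)
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "tfab_model"))
  jsonlite::write_json(model_to_list(model), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path), class = "tfab_io_error")
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(x$schema, MODEL_SCHEMA)) {
    abort(paste0("Unsupported model schema '", x$schema %||% "<missing>",
                 "'; this build reads ", MODEL_SCHEMA,
                 ". Migrate the file before loading."),
          class = "tfab_schema_error")
  }
  outcomes <- purrr::imap(x$outcomes, function(o, nm) {
    terms <- purrr::map_dfr(o$terms, function(t) {
      if (!t$transform %in% transform_names()) {
        abort(paste0("Unknown transform '", t$transform, "' in model file."),
              class = "tfab_schema_error")
      }
      tibble(variable = t$variable, transform = t$transform,
             coefficient = t$coefficient, center = t$center)
    })
    if (nrow(terms) == 0) {
      terms <- tibble(variable = character(), transform = character(),
                      coefficient = numeric(), center = numeric())
    }
    b <- as.numeric(unlist(o$es_boundaries))
    if (length(b) != 4 || any(diff(b) <= 0)) {
      abort("Model file has non-increasing ES boundaries.",
            class = "tfab_model_error")
    }
    model_outcome(
      adjustment_equation(nm, terms),
      list(otl = o$otl %||% NA_real_, itl = o$itl %||% NA_real_,
           rank_outer = o$rank_outer %||% NA_integer_,
           rank_inner = o$rank_inner %||% NA_integer_,
           n = o$n, coverage = o$coverage, confidence = o$confidence),
      es_table(b, es0_defined = isTRUE(o$es0_defined))
    )
  })
  meta <- x$meta
  meta$age_range <- as.numeric(unlist(meta$age_range))
  meta$education_range <- as.numeric(unlist(meta$education_range))
  meta$n <- as.integer(meta$n)
  if (!is.null(meta$flags)) meta$flags <- as.character(unlist(meta$flags))
  if (!is.null(meta$settings)) meta$settings <- lapply(meta$settings, unlist)
  new_tfab_model(outcomes, meta)
}
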