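# Raw score bookkeeping. The battery has four tasks scored 0-3 each;
# Sensitivity-to-interference and Inhibitory-control exist in a motor (M)
# and a verbal (V) response version. Subtest 1 (conceptualization +
# mental flexibility) is shared between versions, so:
#   tfab_1  = conceptualization + mental_flexibility        (0-6)
#   tfab_2m = interference_m + inhibition_m                 (0-6)
#   tfab_2v = interference_v + inhibition_v                 (0-6)
#   tfab_m  = tfab_1 + tfab_2m, tfab_v = tfab_1 + tfab_2v   (0-12)

tfab_task_cols <- c("conceptualization", "mental_flexibility",
                    "interference_m", "inhibition_m",
                    "interference_v", "inhibition_v")
tfab_outcomes <- c("tfab_m", "tfab_v", "tfab_1", "tfab_2m", "tfab_2v")

check_task_scores <- function(data) {
  for (col in intersect(tfab_task_cols, names(data))) {
    x <- data[[col]]
    bad <- !is.na(x) & (!is.numeric(x) | x %% 1 != 0 | x < 0 | x > 3)
    if (any(bad)) {
      abort(paste0("Task score `", col, "` must be an integer in 0..3 (",
                   sum(bad), " offending row(s))."),
            class = "tfab_validation_error")
    }
  }
  invisible(data)
}

#' Derive subtest and total scores from task scores
#'
#' Adds `tfab_1`, `tfab_2m`, `tfab_2v`, `tfab_m`, `tfab_v` columns. Missing
#' task scores propagate: a record without, say, `interference_m` gets `NA`
#' for the motor-version scores but is still scored on the verbal version.
#'
#' @param data A data frame with the six task-score columns
#'   (`conceptualization`, `mental_flexibility`, `interference_m`,
#'   `inhibition_m`, `interference_v`, `inhibition_v`), each integer 0-3 or `NA`.
#' @return The input as a tibble with the five derived score columns appended.
#' @examples
#' compute_scores(data.frame(
#'   conceptualization = 3, mental_flexibility = 2,
#'   interference_m = 3, inhibition_m = 2,
#'   interference_v = 2, inhibition_v = 2
#' ))
#' @export
compute_scores <- function(data) {
  data <- as_tibble(data)
  missing_cols <- setdiff(tfab_task_cols, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing task column(s): ", paste(missing_cols, collapse = ", ")),
          class = "tfab_validation_error")
  }
  check_task_scores(data)
  data %>%
    mutate(
      tfab_1 = .data$conceptualization + .data$mental_flexibility,
      tfab_2m = .data$interference_m + .data$inhibition_m,
      tfab_2v = .data$interference_v + .data$inhibition_v,
      tfab_m = .data$tfab_1 + .data$tfab_2m,
      tfab_v = .data$tfab_1 + .data$tfab_2v
    )
}

#' Score a cohort against a normative model
#'
#' The complete raw -> adjusted -> Equivalent Score pipeline: derives subtest
#' and total scores, applies each outcome's demographic adjustment, and
#' classifies the adjusted score into ES bands. Records whose demographics
#' fall outside the model's normative coverage are still scored but flagged
#' `extrapolated` so that clinical use degrades loudly, not silently.
#'
#' @param data A cohort data frame with `id`, `age`, `education`, `sex` and
#'   the six task columns (or precomputed outcome columns).
#' @param model A `tfab_model`; defaults to the published norms [tfab_norms].
#' @return A long tibble: one row per record x outcome with `raw`,
#'   `adjusted` (2 decimals), `adjusted_exact`, `es`, `label`, `extrapolated`.
#'   Rows with non-positive education get `NA` adjusted scores.
#' @examples
#' rec <- data.frame(id = "p1", age = 35, education = 5, sex = "M",
#'                   conceptualization = 3, mental_flexibility = 2,
#'                   interference_m = 3, inhibition_m = 2,
#'                   interference_v = 3, inhibition_v = 3)
#' score_participants(rec)
#' @export
score_participants <- function(data, model = tfab_norms) {
  stopifnot(inherits(model, "tfab_model"))
  data <- as_tibble(data)
  if (!"id" %in% names(data)) data$id <- as.character(seq_len(nrow(data)))
  for (col in c("age", "education")) {
    if (!col %in% names(data)) {
      abort(paste0("Missing column `", col, "`."), class = "tfab_validation_error")
    }
  }
  if (all(tfab_task_cols %in% names(data))) {
    data <- compute_scores(data)
  }
  present <- intersect(names(model$outcomes), names(data))
  if (!length(present)) {
    abort("No scoreable outcome columns found.", class = "tfab_validation_error")
  }
  ar <- model$meta$age_range
  er <- model$meta$education_range
  scoreable <- is.finite(data$education) & data$education > 0 & is.finite(data$age)
  extrapolated <- !(data$age >= ar[1] & data$age <= ar[2] &
                    data$education >= er[1] & data$education <= er[2])
  purrr::map_dfr(present, function(outc) {
    o <- model$outcomes[[outc]]
    raw <- data[[outc]]
    adj <- rep(NA_real_, nrow(data))
    ok <- scoreable & !is.na(raw)
    if (any(ok)) {
      adj[ok] <- adjust_score(o$equation, raw[ok], age = data$age[ok],
                              education = data$education[ok],
                              sex = data$sex[ok])
    }
    cls <- lookup_es(o$es, adj)
    cls$es[is.na(adj)] <- NA_integer_
    cls$label[is.na(adj)] <- NA_character_
    tibble(id = as.character(data$id), outcome = outc, raw = raw,
           adjusted = round(adj, 2), adjusted_exact = adj,
           es = cls$es, label = cls$label,
           extrapolated = extrapolated | !scoreable)
  })
}

#' Summarise Equivalent Score band occupancy
#'
#' @param scored Output of [score_participants()].
#' @return A tibble with per-outcome counts and proportions per ES band.
#' @export
es_summary <- function(scored) {
  scored %>%
    filter(!is.na(.data$es)) %>%
    group_by(.data$outcome, .data$es, .data$label) %>%
    summarise(n = dplyr::n(), .groups = "drop") %>%
    group_by(.data$outcome) %>%
    mutate(prop = .data$n / sum(.data$n)) %>%
    ungroup()
}
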