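# ggplot2 graphics for the main result types.

#' Plot a ROC curve
#'
#' Empirical ROC curve (sensitivity against 1 - specificity over all score
#' thresholds) with the chance diagonal and the AUC in the subtitle.
#'
#' @param object A `tfab_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tfab_roc <- function(object, ...) {
  thr <- sort(unique(c(object$scores_cases, object$scores_controls,
                       -Inf, Inf)), decreasing = TRUE)
  pts <- purrr::map_dfr(thr, function(t) {
    tibble(fpr = mean(object$scores_controls >= t),
           tpr = mean(object$scores_cases >= t))
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = "ROC curve",
      subtitle = sprintf("AUC = %.2f (95%% CI %.2f-%.2f), %d cases vs %d controls",
                         object$auc, object$ci95[1], object$ci95[2],
                         object$n_cases, object$n_controls)
    ) +
    ggplot2::theme_minimal()
}

#' Scree plot of a principal-component structure
#'
#' Eigenvalues of the task-score correlation matrix with the
#' eigenvalue-greater-than-one retention line.
#'
#' @param object A `tfab_pca` from [pca_structure()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tfab_pca <- function(object, ...) {
  d <- tibble(component = seq_along(object$eigenvalues),
              eigenvalue = object$eigenvalues)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$eigenvalue)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::scale_x_continuous(breaks = d$component) +
    ggplot2::labs(x = "Component", y = "Eigenvalue", title = "Scree plot",
                  subtitle = sprintf("PC1 explains %.1f%% of variance",
                                     object$pct_variance_pc1)) +
    ggplot2::theme_minimal()
}

#' Plot the Equivalent Score bands of a normative model
#'
#' One horizontal bar per outcome on the adjusted-score scale, segmented
#' into the five ES bands (impaired / borderline / normal).
#'
#' @param object A `tfab_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tfab_model <- function(object, ...) {
  bands <- purrr::imap_dfr(object$outcomes, function(o, nm) {
    b <- o$es$boundaries
    lo <- c(b[1] - 0.15 * (b[4] - b[1]), b[1], b[2], b[3], b[4])
    hi <- c(b[1], b[2], b[3], b[4], b[4] + 0.15 * (b[4] - b[1]))
    tibble(outcome = nm, es = factor(0:4), from = lo, to = hi)
  })
  ggplot2::ggplot(bands,
                  ggplot2::aes(xmin = .data$from, xmax = .data$to,
                               y = .data$outcome, fill = .data$es)) +
    ggplot2::geom_tile(ggplot2::aes(x = (.data$from + .data$to) / 2,
                                    width = .data$to - .data$from),
                       height = 0.7, colour = "white") +
    ggplot2::scale_fill_brewer(palette = "RdYlGn", name = "ES") +
    ggplot2::labs(x = "Adjusted score", y = NULL,
                  title = "Equivalent Score bands",
                  subtitle = "ES 0 = impaired, 1 = borderline, 2-4 = normal") +
    ggplot2::theme_minimal()
}

#' Plot a demographic adjustment surface
#'
#' Adjustment (added to the raw score) as a function of age for a set of
#' education levels — the graphical analogue of a printed correction grid.
#' Outcomes without an age term give flat lines.
#'
#' @param model A `tfab_model`.
#' @param outcome Outcome name (default `"tfab_m"`).
#' @param ages,educations Grid values.
#' @return A ggplot object.
#' @export
plot_adjustment_grid <- function(model, outcome = "tfab_m",
                                 ages = seq(35, 90, by = 5),
                                 educations = c(5, 8, 11, 13, 16, 18)) {
  stopifnot(inherits(model, "tfab_model"), outcome %in% names(model$outcomes))
  eq <- model$outcomes[[outcome]]$equation
  d <- tidyr::expand_grid(age = ages, education = educations) %>%
    mutate(adjustment = adjust_score(eq, 0, age = .data$age,
                                     education = .data$education),
           education = factor(.data$education))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age, y = .data$adjustment,
                                  colour = .data$education)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Age (years)", y = "Adjustment (points)",
                  colour = "Education\n(years)",
                  title = paste("Demographic adjustment:", outcome)) +
    ggplot2::theme_minimal()
}
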