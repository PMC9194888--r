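# Equivalent Score (ES) bands on the adjusted-score scale.
#
# Bands are stored as four ascending cut points (b01, b12, b23, b34) at
# 2-decimal resolution: ES0 (impaired) for AS <= b01, ES1 (borderline) for
# b01 < AS < b12, ES2 for b12 <= AS < b23, ES3 for b23 <= AS < b34 and ES4
# for AS >= b34. b01 is the outer tolerance limit; b12/b23/b34 are the lower
# edges of the ES2/ES3/ES4 bands, matching the printed closed intervals.

.es_labels <- c("impaired", "borderline", "normal", "normal", "normal")

#' Create an Equivalent Score table
#'
#' @param boundaries Four strictly increasing adjusted-score cut points
#'   `c(b01, b12, b23, b34)`: `b01` is the upper (closed) edge of the impaired
#'   band ES0 and equals the outer tolerance limit; `b12`, `b23`, `b34` are the
#'   lower (closed) edges of bands ES2, ES3 and ES4.
#' @param es0_defined Set to `FALSE` when the derivation sample was too small
#'   for an outer tolerance limit; classification then starts at ES1.
#' @return An object of class `tfab_es_table`.
#' @export
es_table <- function(boundaries, es0_defined = TRUE) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) != 4 || any(!is.finite(boundaries))) {
    abort("`boundaries` must be four finite cut points.", class = "tfab_model_error")
  }
  if (any(diff(boundaries) <= 0)) {
    abort("ES boundaries must be strictly increasing.", class = "tfab_model_error")
  }
  structure(list(boundaries = boundaries, es0_defined = isTRUE(es0_defined)),
            class = "tfab_es_table")
}

#' Classify adjusted scores into Equivalent Scores
#'
#' Adjusted scores are rounded to 2 decimals before lookup, because ES bands
#' are defined as closed intervals at 2-decimal resolution; this avoids gaps
#' between adjacent printed bands.
#'
#' @param table An [es_table()].
#' @param as Adjusted score(s); vectorised.
#' @return A tibble with columns `es` (integer 0-4) and `label`
#'   (`"impaired"`, `"borderline"`, `"normal"`).
#' @examples
#' lookup_es(tfab_norms$outcomes$tfab_m$es, c(8.07, 10.00, 11.04))
#' @export
lookup_es <- function(table, as) {
  stopifnot(inherits(table, "tfab_es_table"))
  r <- round(as, 2)
  b <- table$boundaries
  eps <- 1e-9
  es <- ifelse(r <= b[1] + eps, 0L,
        1L + (r >= b[2] - eps) + (r >= b[3] - eps) + (r >= b[4] - eps))
  es <- as.integer(es)
  if (!table$es0_defined) {
    es[es == 0L] <- NA_integer_
  }
  tibble(es = es, label = .es_labels[es + 1L])
}

#' @export
print.tfab_es_table <- function(x, ...) {
  b <- sprintf("%.2f", x$boundaries)
  cat("<tfab ES table>\n")
  cat("  ES0 <=", b[1], if (!x$es0_defined) "(undefined: no outer TL)" else "", "\n")
  cat("  ES1  (", b[1], ",", b[2], ")\n")
  cat("  ES2  [", b[2], ",", b[3], ")\n")
  cat("  ES3  [", b[3], ",", b[4], ")\n")
  cat("  ES4 >=", b[4], "\n")
  invisible(x)
}
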