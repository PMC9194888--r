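# Published correction grids: expected adjustment (for raw score 0) at each
# printed age x education combination, to 2 decimals. Motor-response scores
# vary with age and education; the remaining scores with education only.

grid_ages <- seq(35, 90, by = 5)
grid_educations <- c(5, 8, 11, 13, 16, 18)

grid_tfab_m <- matrix(c(
  1.17, 0.46, -0.02, -0.27, -0.59, -0.77,
  1.21, 0.50,  0.02, -0.23, -0.55, -0.72,
  1.27, 0.56,  0.08, -0.18, -0.49, -0.67,
  1.34, 0.63,  0.14, -0.11, -0.42, -0.60,
  1.42, 0.71,  0.23, -0.03, -0.34, -0.52,
  1.52, 0.81,  0.33,  0.07, -0.24, -0.42,
  1.64, 0.92,  0.44,  0.19, -0.12, -0.30,
  1.77, 1.06,  0.58,  0.33,  0.01, -0.17,
  1.93, 1.22,  0.74,  0.48,  0.17, -0.01,
  2.11, 1.40,  0.92,  0.66,  0.35,  0.17,
  2.32, 1.60,  1.12,  0.87,  0.55,  0.38,
  2.54, 1.83,  1.35,  1.10,  0.78,  0.61
), nrow = 12, byrow = TRUE, dimnames = list(grid_ages, grid_educations))

grid_tfab_2m <- matrix(c(
  0.47, 0.17, -0.03, -0.13, -0.27, -0.34,
  0.49, 0.19, -0.01, -0.11, -0.25, -0.32,
  0.52, 0.22,  0.02, -0.09, -0.22, -0.29,
  0.55, 0.26,  0.05, -0.05, -0.18, -0.26,
  0.60, 0.30,  0.09, -0.01, -0.14, -0.22,
  0.65, 0.35,  0.14,  0.04, -0.09, -0.17,
  0.70, 0.41,  0.20,  0.10, -0.03, -0.11,
  0.77, 0.47,  0.27,  0.17,  0.03, -0.04,
  0.85, 0.55,  0.35,  0.24,  0.11,  0.04,
  0.94, 0.64,  0.44,  0.33,  0.20,  0.13,
  1.04, 0.74,  0.54,  0.44,  0.30,  0.23,
  1.16, 0.86,  0.66,  0.55,  0.42,  0.34
), nrow = 12, byrow = TRUE, dimnames = list(grid_ages, grid_educations))

grid_education_only <- list(
  tfab_v  = c(1.83, 0.65, 0.12, -0.10, -0.32, -0.43),
  tfab_1  = c(0.96, 0.48, 0.15, -0.02, -0.23, -0.35),
  tfab_2v = c(0.69, 0.25, 0.05, -0.04, -0.12, -0.16)
)

# full published grid as one tidy table (row per cell)
published_grid <- local({
  age_part <- purrr::map_dfr(
    list(tfab_m = grid_tfab_m, tfab_2m = grid_tfab_2m),
    function(g) {
      tidyr::expand_grid(age = grid_ages, education = grid_educations) |>
        dplyr::mutate(expected = as.vector(t(g)))
    },
    .id = "outcome"
  )
  edu_part <- purrr::imap_dfr(grid_education_only, function(v, nm) {
    tibble::tibble(outcome = nm, age = 50, education = grid_educations,
                   expected = v)
  })
  dplyr::bind_rows(age_part, edu_part)
})
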