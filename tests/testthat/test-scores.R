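test_that("subtest and total scores are derived correctly", {
  # maximum, minimum, and a mixed profile
  top <- compute_scores(make_record())
  expect_equal(top$tfab_1, 6)
  expect_equal(top$tfab_2m, 6)
  expect_equal(top$tfab_2v, 6)
  expect_equal(top$tfab_m, 12)
  expect_equal(top$tfab_v, 12)

  zero <- compute_scores(make_record(conceptualization = 0, mental_flexibility = 0,
                                     interference_m = 0, inhibition_m = 0,
                                     interference_v = 0, inhibition_v = 0))
  expect_true(all(zero[c("tfab_1", "tfab_2m", "tfab_2v", "tfab_m", "tfab_v")] == 0))

  mixed <- compute_scores(make_record(conceptualization = 3, mental_flexibility = 2,
                                      interference_m = 3, inhibition_m = 2,
                                      interference_v = 2, inhibition_v = 2))
  expect_equal(mixed$tfab_1, 5)
  expect_equal(mixed$tfab_2m, 5)
  expect_equal(mixed$tfab_2v, 4)
  expect_equal(mixed$tfab_m, 10)
  expect_equal(mixed$tfab_v, 9)
})

test_that("invalid task scores fail validation naming the offending field", {
  expect_error(compute_scores(make_record(inhibition_v = 4)),
               "inhibition_v", class = "tfab_validation_error")
  expect_error(compute_scores(make_record(conceptualization = -1)),
               "conceptualization", class = "tfab_validation_error")
  expect_error(compute_scores(make_record(mental_flexibility = 1.5)),
               "mental_flexibility", class = "tfab_validation_error")
  expect_error(compute_scores(dplyr::select(make_record(), -interference_m)),
               "interference_m", class = "tfab_validation_error")
})

test_that("missing task scores propagate to their version only", {
  scored <- score_participants(make_record(interference_m = NA))
  m_fam <- scored[scored$outcome %in% c("tfab_m", "tfab_2m"), ]
  v_fam <- scored[scored$outcome %in% c("tfab_v", "tfab_2v", "tfab_1"), ]
  expect_true(all(is.na(m_fam$raw)))
  expect_true(all(is.na(m_fam$es)))
  expect_true(all(!is.na(v_fam$raw)))
  expect_true(all(!is.na(v_fam$es)))
})

test_that("adjustment is exactly zero at each equation's centering profile", {
  eqs <- purrr::map(tfab_norms$outcomes, "equation")
  expect_equal(adjust_score(eqs$tfab_m, 7, age = center_age,
                            education = center_education_log10), 7)
  expect_equal(adjust_score(eqs$tfab_2m, 7, age = center_age,
                            education = center_education_log10), 7)
  expect_equal(adjust_score(eqs$tfab_v, 7, education = center_education_recip), 7)
  expect_equal(adjust_score(eqs$tfab_2v, 7, education = center_education_recip), 7)
  expect_equal(adjust_score(eqs$tfab_1, 7, education = center_education_ln), 7)
})

test_that("adjustment matches the printed grid cells and adds to raw scores", {
  eq_m <- tfab_norms$outcomes$tfab_m$equation
  eq_v <- tfab_norms$outcomes$tfab_v$equation
  expect_equal(round(adjust_score(eq_m, 0, age = 35, education = 5), 2), 1.17)
  expect_equal(round(adjust_score(eq_v, 10, education = 5), 2), 11.83)
})

test_that("published adjustments are monotone in age and education", {
  ages <- 18:96
  edus <- 4:23
  for (nm in c("tfab_m", "tfab_2m")) {
    eq <- tfab_norms$outcomes[[nm]]$equation
    adj_by_age <- adjust_score(eq, 0, age = ages, education = 10)
    expect_true(all(diff(adj_by_age) > 0), info = paste(nm, "age"))
  }
  for (nm in tfab:::tfab_outcomes) {
    eq <- tfab_norms$outcomes[[nm]]$equation
    adj_by_edu <- adjust_score(eq, 0, age = 50, education = edus)
    expect_true(all(diff(adj_by_edu) < 0), info = paste(nm, "education"))
  }
})

test_that("education domain and transform names are validated", {
  eq <- tfab_norms$outcomes$tfab_v$equation
  expect_error(adjust_score(eq, 5, education = 0), class = "tfab_domain_error")
  expect_error(adjust_score(eq, 5, education = -3), class = "tfab_domain_error")
  expect_error(
    adjustment_equation("x", data.frame(variable = "age", transform = "sqrt",
                                        coefficient = 1, center = 0)),
    "sqrt", class = "tfab_config_error")
})

test_that("Equivalent Score lookup reproduces the printed bands", {
  es_m <- tfab_norms$outcomes$tfab_m$es
  got <- lookup_es(es_m, c(8.07, 8.08, 9.45, 9.46, 10.00, 10.50, 10.51, 11.03, 11.04))
  expect_equal(got$es, c(0L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 4L))
  expect_equal(got$label[1], "impaired")
  expect_equal(got$label[2], "borderline")
  expect_equal(got$label[9], "normal")
  # band edges of the remaining outcomes
  expect_equal(lookup_es(tfab_norms$outcomes$tfab_v$es, c(8.48, 8.49, 10.94))$es,
               c(0L, 1L, 4L))
  expect_equal(lookup_es(tfab_norms$outcomes$tfab_1$es, c(3.54, 4.50, 5.46))$es,
               c(0L, 2L, 4L))
  expect_equal(lookup_es(tfab_norms$outcomes$tfab_2m$es, c(3.16, 5.67, 5.85))$es,
               c(0L, 3L, 4L))
  expect_equal(lookup_es(tfab_norms$outcomes$tfab_2v$es, c(3.00, 3.01, 6.00))$es,
               c(0L, 1L, 4L))
})

test_that("ES classification is monotone non-decreasing in the adjusted score", {
  es_m <- tfab_norms$outcomes$tfab_m$es
  as_grid <- seq(-2, 15, by = 0.01)
  es <- lookup_es(es_m, as_grid)$es
  expect_true(all(diff(es) >= 0))
  expect_true(all(es %in% 0:4))
})

test_that("malformed ES tables are rejected", {
  expect_error(es_table(c(8, 7, 9, 10)), class = "tfab_model_error")
  expect_error(es_table(c(8, 8, 9, 10)), class = "tfab_model_error")
  expect_error(es_table(c(8, NA, 9, 10)), class = "tfab_model_error")
})

test_that("score_participants composes adjustment and classification", {
  # perfect scorer just below the centering educations stays in the top
  # band everywhere (above them, the verbal subtest-2 band ES4 >= 6.00 is
  # unreachable because the adjustment turns negative)
  perfect <- score_participants(make_record(age = 48, education = 12))
  expect_equal(nrow(perfect), 5)
  expect_true(all(perfect$es == 4))
  expect_false(any(perfect$extrapolated))

  # grid-cell participant: raw 10 at age 35, education 5 -> AS 11.17, ES 4
  scored <- score_participants(make_record(
    age = 35, education = 5,
    conceptualization = 3, mental_flexibility = 2,
    interference_m = 3, inhibition_m = 2,
    interference_v = 2, inhibition_v = 2
  ))
  m_row <- scored[scored$outcome == "tfab_m", ]
  expect_equal(m_row$raw, 10)
  expect_equal(m_row$adjusted, 11.17)
  expect_equal(m_row$es, 4L)

  # raw 7 at the same profile -> AS 8.17, ES 1 (borderline)
  scored7 <- score_participants(make_record(
    age = 35, education = 5,
    conceptualization = 2, mental_flexibility = 1,
    interference_m = 2, inhibition_m = 2,
    interference_v = 2, inhibition_v = 2
  ))
  m7 <- scored7[scored7$outcome == "tfab_m", ]
  expect_equal(m7$raw, 7)
  expect_equal(m7$adjusted, 8.17)
  expect_equal(m7$es, 1L)
  expect_equal(m7$label, "borderline")
})

test_that("demographics outside the normative coverage flag but still score", {
  scored <- score_participants(make_record(age = 17))
  expect_true(all(scored$extrapolated))
  expect_true(all(!is.na(scored$es)))
  inside <- score_participants(make_record(age = 18, education = 4))
  expect_false(any(inside$extrapolated))
})

test_that("es_summary reports per-outcome proportions that sum to one", {
  cohort <- compute_scores(simulate_normative(n = 200, seed = 31))
  summ <- es_summary(score_participants(cohort))
  sums <- summ |> dplyr::group_by(outcome) |> dplyr::summarise(p = sum(prop))
  expect_true(all(abs(sums$p - 1) < 1e-12))
})
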