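# Small in-code fixtures shared across tests.

make_record <- function(id = "p1", age = 48, education = 13, sex = "M",
                        conceptualization = 3, mental_flexibility = 3,
                        interference_m = 3, inhibition_m = 3,
                        interference_v = 3, inhibition_v = 3, ...) {
  tibble::tibble(id = id, age = age, education = education, sex = sex,
                 conceptualization = conceptualization,
                 mental_flexibility = mental_flexibility,
                 interference_m = interference_m, inhibition_m = inhibition_m,
                 interference_v = interference_v, inhibition_v = inhibition_v,
                 ...)
}

# demographic profile at the published centering constants: adjustment == 0
center_age <- 167162.855491^(1 / 3)
center_education_log10 <- 10^1.106787
center_education_recip <- 1 / 0.083175
center_education_ln <- exp(2.548471)

write_cohort_csv <- function(data, path = tempfile(fileext = ".csv")) {
  readr::write_csv(data, path)
  path
}
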