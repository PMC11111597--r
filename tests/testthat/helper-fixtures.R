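# Small cohort stratum table for fast tests
default_strata_for_test <- function(n_dem, n_cn) {
  data.frame(facility = "A",
             diagnosis = c("dementia", "cognitively_normal"),
             n = c(n_dem, n_cn),
             age_mean = c(80, 74), age_sd = c(9, 13),
             stringsAsFactors = FALSE)
}
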