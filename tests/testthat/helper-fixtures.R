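# Worked-example ROI values from the two illustrative cases (a metastatic
# and a non-metastatic node with their primary lesions), with the one-decimal
# spectral slopes as printed alongside them.
fig_case1 <- list(
  node   = list(att40 = 288, att70 = 108, ic = 31.8, wc = 1039, effz = 9.34,
                lambda_hu = 6.0),
  lesion = list(att40 = 284, att70 = 112, ic = 30.6, wc = 1030, effz = 9.28,
                lambda_hu = 5.7)
)
fig_case2 <- list(
  node   = list(att40 = 130, att70 = 39, ic = 16.2, wc = 1021, effz = 8.55,
                lambda_hu = 3.0),
  lesion = list(att40 = 240, att70 = 93, ic = 26, wc = 1032, effz = 9.09,
                lambda_hu = 4.9)
)

# Small deterministic cohort for schema-level tests.
tiny_cohort <- function(n = 8L, seed = 7L) {
  generate_cohort(cohort_config(n_patients = as.integer(n), seed = as.integer(seed)))
}
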