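# Small cohorts shared across test files (built once per test run).
rp_test_cache <- new.env(parent = emptyenv())

test_cohort <- function(n = 5, coupling = 0.6, noise_sd = 0.3, seed = 11,
                        intensity = 400, slides = c(1, 2)) {
  key <- paste(n, coupling, noise_sd, seed, intensity, paste(slides, collapse = "-"),
               sep = "|")
  if (is.null(rp_test_cache[[key]])) {
    rp_test_cache[[key]] <- generate_cohort(cohort_config(
      n_patients = n, coupling = coupling, noise_sd = noise_sd,
      nuclei_intensity = intensity, slides_per_patient = slides, seed = seed))
  }
  rp_test_cache[[key]]
}

# per-slide density field is irrelevant for many tests; a plain uniform point
# set keeps them fast
random_slide_points <- function(n, w = 600, h = 600) {
  cbind(x = runif(n, 0, w), y = runif(n, 0, h))
}
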