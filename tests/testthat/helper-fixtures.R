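# shared fixtures: everything is generated in code at test time

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# cache the noise-free default subjects; several files inspect them
noise_free <- local({
  cache <- list()
  function(name) {
    if (is.null(cache[[name]]))
      cache[[name]] <<- quiet(generate_subject(default_profile(name),
                                               seed = 1, noise = FALSE))
    cache[[name]]
  }
})

analyzed <- local({
  cache <- list()
  function(name) {
    if (is.null(cache[[name]]))
      cache[[name]] <<- quiet(analyze_subject(noise_free(name)$dataset))
    cache[[name]]
  }
})

# cluster features exactly as build_cohort_report derives them
cluster_features <- function(cohort) {
  t(vapply(cohort, function(s) {
    ds <- s$dataset
    pre <- ds$plasma_ratio$times <= 0
    p <- partition_glucose(ds$plasma_total_glucose, ds$plasma_ratio,
                           mean(ds$plasma_ratio$values[pre]), 0.99)
    hep <- dglc_concentration(ds$hepatic_dglc_amplitudes,
                              ds$water_reference_amplitude)
    c(plasma = iauc(p$exogenous, c(0, 180), 0)$value,
      hepatic = iauc(hep, c(0, 180), 0)$value)
  }, numeric(2)))
}
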