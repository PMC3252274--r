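# The standard scenario (the package's default sim_params) is exercised by
# several tests; fits and scans are memoised per seed so each is computed once
# per test run.
.standard_cache <- new.env(parent = emptyenv())

standard_run <- function(seed) {
  key <- paste0("seed", seed)
  if (is.null(.standard_cache[[key]])) {
    sim <- simulate_eqtl_study(sim_params(seed = seed))
    ds <- center_expression(sim$dataset)
    fit <- fit_panama(ds, fit_config())
    tab <- panama_scan(ds, build_covariance(fit, "panama", ds))
    .standard_cache[[key]] <- list(sim = sim, ds = ds, fit = fit, tab = tab)
  }
  .standard_cache[[key]]
}
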