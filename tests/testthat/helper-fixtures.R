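# Shared fixtures. Fits are cached per test run so several test files can
# reuse the same posterior without re-sampling.

.fit_cache <- new.env(parent = emptyenv())

# Noise-free population: degenerate hierarchy and zero measurement noise.
noise_free_population <- function(...) {
  population_params(sigma_mcv_old = 0, sigma_mcv_new = 0,
                    sigma_mchc_old = 0, sigma_mchc_new = 0,
                    sigma_n_old = 0, sigma_n_new = 0,
                    sigma_obs_mcv = 0, sigma_obs_mchc = 0, sigma_obs_n = 0,
                    ...)
}

# A small but realistic cohort + fit shared across diagnostics tests:
# 12 patients, moderate draws.
small_fit <- function() {
  if (!is.null(.fit_cache$small)) return(.fit_cache$small)
  coh <- generate_cohort(cohort_config(n_patients = 12, seed = 314))
  model <- build_rbc_model(coh$observations)
  fit <- fit_rbc_model(model, fit_config(n_chains = 2, n_warmup = 600,
                                         n_sampling = 600, seed = 99))
  .fit_cache$small <- list(cohort = coh, fit = fit)
  .fit_cache$small
}

# The calibrated full-size cohort fit used by the acceptance checks:
# 122 patients, reduced sampling (2 chains x 1000 warmup + 1000 draws).
acceptance_fit <- function() {
  if (!is.null(.fit_cache$acceptance)) return(.fit_cache$acceptance)
  config <- pipeline_config(
    cohort = cohort_config(seed = 20250505),
    fit = fit_config(n_chains = 2, n_warmup = 1000, n_sampling = 1000,
                     seed = 4242))
  .fit_cache$acceptance <- run_pipeline(config)
  .fit_cache$acceptance
}

# Small-cohort fits for the lifespan-coverage study: 30 patients with a
# fixed ~10-draw schedule (196-day durations).
coverage_cohort_config <- function(seed) {
  cohort_config(n_patients = 30, seed = seed,
                duration_meanlog = log(196 / 30.44), duration_sdlog = 0)
}

coverage_fits <- function(n_rep = 20) {
  if (!is.null(.fit_cache$coverage)) return(.fit_cache$coverage)
  fits <- lapply(seq_len(n_rep), function(r) {
    coh <- generate_cohort(coverage_cohort_config(seed = 5000 + r))
    model <- build_rbc_model(coh$observations)
    # 2 x (1000 + 1000): with shorter chains the interval endpoints are
    # dominated by Monte-Carlo error (ESS for mu_s can drop below 50)
    fit_rbc_model(model, fit_config(n_chains = 2, n_warmup = 1000,
                                    n_sampling = 1000, seed = 100 + r),
                  store_loglik = FALSE)
  })
  .fit_cache$coverage <- fits
  fits
}
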