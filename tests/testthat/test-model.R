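test_that("model bookkeeping: parameter count and input validation", {
  coh <- generate_cohort(cohort_config(n_patients = 7, seed = 50))
  m <- build_rbc_model(coh$observations)
  expect_equal(m$n_parameters, 6 * 7 + 12 + 3 + 3 + 2)
  expect_s3_class(m, "rbc_model")
  # fixing the survival law removes its two free parameters
  m0 <- build_rbc_model(coh$observations, fix_survival = survival_params())
  expect_equal(m0$n_parameters, 6 * 7 + 12 + 3 + 3)
  expect_error(build_rbc_model(coh$observations[0, ]),
               class = "rbclifespan_domain_error")
  bad <- coh$observations
  bad$mcv_fL[3] <- -1
  expect_error(build_rbc_model(bad), class = "rbclifespan_domain_error")
})

test_that("prior predictive MCV values are physiologically calibrated", {
  set.seed(123)
  pp <- prior_predictive(n = 2000)
  expect_gt(mean(pp$mcv_fL > 60 & pp$mcv_fL < 130), 0.9)
})

test_that("single-patient noise-free fit recovers the patient values", {
  # near-deterministic data with the survival law fixed to truth: patient
  # posteriors must collapse onto the generating values
  sp <- survival_params()
  pop <- noise_free_population()
  pop$sigma_obs_mcv <- 0.05; pop$sigma_obs_mchc <- 0.02
  pop$sigma_obs_n <- 0.005
  cfg <- cohort_config(n_patients = 1, seed = 61, population = pop,
                       duration_meanlog = log(400 / 30.44),
                       duration_sdlog = 0)
  coh <- generate_cohort(cfg)
  m <- build_rbc_model(coh$observations, fix_survival = sp)
  fit <- fit_rbc_model(m, fit_config(n_chains = 2, n_warmup = 500,
                                     n_sampling = 500, seed = 5),
                       store_loglik = FALSE)
  truth <- coh$patients
  for (par in c("mcv_old", "mcv_new", "mchc_old", "mchc_new", "n_old",
                "n_new")) {
    post <- mean(fit$pooled[, paste0(par, "[1]")])
    expect_lt(abs(post - truth[[par]]) / abs(truth[[par]]), 0.01)
  }
})

test_that("patient posteriors collapse onto truth with fixed survival and tiny noise", {
  sp <- survival_params()
  pop <- noise_free_population()
  pop$sigma_obs_mcv <- 0.02; pop$sigma_obs_mchc <- 0.01
  pop$sigma_obs_n <- 0.002
  cfg <- cohort_config(n_patients = 5, seed = 62, population = pop,
                       duration_meanlog = log(400 / 30.44),
                       duration_sdlog = 0)
  coh <- generate_cohort(cfg)
  m <- build_rbc_model(coh$observations, fix_survival = sp)
  fit <- fit_rbc_model(m, fit_config(n_chains = 2, n_warmup = 500,
                                     n_sampling = 500, seed = 6),
                       store_loglik = FALSE)
  for (par in c("mcv_old", "mcv_new", "mchc_old", "mchc_new", "n_old",
                "n_new")) {
    post <- colMeans(fit$pooled[, paste0(par, "[", 1:5, "]")])
    truth <- coh$patients[[par]]
    expect_lt(max(abs(post - truth) / abs(truth)), 0.005)
  }
})

test_that("fits are exactly reproducible given seed and backend", {
  coh <- generate_cohort(cohort_config(n_patients = 4, seed = 70))
  m <- build_rbc_model(coh$observations)
  cfg <- fit_config(n_chains = 2, n_warmup = 300, n_sampling = 200,
                    seed = 17)
  f1 <- fit_rbc_model(m, cfg, store_loglik = FALSE)
  f2 <- fit_rbc_model(m, cfg, store_loglik = FALSE)
  expect_identical(f1$summaries, f2$summaries)
})

test_that("a deliberately mis-scaled survival prior biases the lifespan", {
  # negative control for the prior-sensitivity harness: an essentially
  # point-mass prior far from truth must drag the lifespan with it
  coh <- generate_cohort(cohort_config(n_patients = 6, seed = 71))
  bad_priors <- rbc_priors(survival_mu_mean = log(60),
                           survival_mu_sd = 1e-6)
  m <- build_rbc_model(coh$observations, priors = bad_priors)
  fit <- fit_rbc_model(m, fit_config(n_chains = 2, n_warmup = 300,
                                     n_sampling = 300, seed = 8),
                       store_loglik = FALSE)
  ls <- fit$summaries$median[fit$summaries$term == "lifespan_days"]
  expect_lt(ls, 80) # generating truth is 118 d
})

test_that("posterior summaries and broom methods are coherent", {
  sf <- small_fit()
  fit <- sf$fit
  td <- tidy(fit)
  expect_true(all(td$conf.low <= td$median & td$median <= td$conf.high))
  g <- glance(fit)
  expect_equal(g$n_patients, 12)
  expect_equal(g$n_divergences, 0)
  rep <- summarize_posterior(fit)
  # contrasts are per-draw: medians of differences match the stored draws
  expect_equal(rep$median[rep$quantity == "mcv_delta"],
               median(fit$derived$mcv_delta))
  expect_equal(rep$median[rep$quantity == "hgb_delta"],
               median(fit$derived$hgb_post - fit$derived$hgb_pre))
  # lifespan summary equals the closed form applied draw by draw
  expect_equal(fit$derived$lifespan_days,
               exp(fit$pooled[, "mu_s"] + fit$pooled[, "sigma_s"]^2 / 2))
})
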