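test_that("duration law matches the reported cohort quantiles", {
  f <- fit_duration_lognormal()
  expect_equal(f$median, 7.2, tolerance = 1e-6)
  # quartiles are approximated in least squares, not matched exactly
  expect_equal(f$q25, 3.4, tolerance = 0.2)
  expect_equal(f$q75, 13.3, tolerance = 0.15)
})

test_that("patient-level draws follow the population hierarchy", {
  # degenerate hierarchy collapses onto the population means
  pop0 <- noise_free_population()
  set.seed(1)
  p <- draw_patient_params(pop0, 5)
  expect_true(all(p$mcv_old == pop0$mu_mcv_old))
  expect_true(all(p$n_new == pop0$mu_n_new))
  # law of large numbers at the default calibration
  pop <- population_params()
  set.seed(2)
  big <- draw_patient_params(pop, 1e4)
  expect_lt(abs(mean(big$mcv_old) - 87.8),
            3 * pop$sigma_mcv_old / sqrt(1e4))
  # identical seeds give identical parameter streams
  set.seed(33); a <- draw_patient_params(pop, 10)
  set.seed(33); b <- draw_patient_params(pop, 10)
  expect_identical(a, b)
})

test_that("sampling schedule is baseline + biweekly(2 months) + monthly", {
  expect_equal(sampling_schedule(60, baseline_time = -7),
               c(-7, 14, 28, 42, 56))
  expect_equal(sampling_schedule(180, baseline_time = -14),
               c(-14, 14, 28, 42, 56, 84, 112, 140, 168))
  expect_equal(sampling_schedule(10, baseline_time = -3), -3)
  expect_error(sampling_schedule(0), class = "rbclifespan_domain_error")
  set.seed(5)
  for (d in c(30, 100, 400, 900)) {
    s <- sampling_schedule(d)
    expect_true(all(diff(s) > 0))
    expect_true(all(s <= d))
    expect_true(s[1] >= -28 && s[1] < 0)
  }
})

test_that("noise-free observations sit exactly on the mixture curve", {
  pop0 <- noise_free_population()
  sp <- survival_params()
  set.seed(4)
  pat <- draw_patient_params(pop0, 1)
  pre <- simulate_observation(-10, pat, pop0, sp)
  expect_equal(pre$mcv_fL, pat$mcv_old)
  expect_equal(pre$mchc_g_dL, pat$mchc_old)
  expect_equal(pre$rbc_1e12_per_L, pat$n_old)
  late <- simulate_observation(1e9, pat, pop0, sp)
  expect_equal(late$mcv_fL, pat$mcv_new, tolerance = 1e-9)
  # at the LogNormal median the old/new mixture is the midpoint
  mid <- simulate_observation(exp(sp$mu_survival), pat, pop0, sp)
  expect_equal(mid$mcv_fL, (pat$mcv_old + pat$mcv_new) / 2)
})

test_that("cohort generation is reproducible and honours the noise-free mode", {
  cfg <- cohort_config(n_patients = 6, seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$observations, b$observations)
  expect_identical(a$patients, b$patients)
  # noise-free single-patient cohort reproduces the deterministic MCV curve
  cfg0 <- cohort_config(n_patients = 1, seed = 12,
                        population = noise_free_population())
  coh0 <- generate_cohort(cfg0)
  w <- old_fraction(coh0$observations$t_days, cfg0$survival)
  expect_equal(coh0$observations$mcv_fL,
               mixture_mean(w, coh0$patients$mcv_old, coh0$patients$mcv_new))
  expect_equal(coh0$observations$rbc_1e12_per_L,
               mixture_mean(w, coh0$patients$n_old, coh0$patients$n_new))
})

test_that("empirical mean MCV converges to the population mixture curve", {
  # many patients measured at fixed times; between-patient spread and noise
  # average out to the population mixture-mean curve
  pop <- population_params()
  sp <- survival_params()
  set.seed(8)
  pats <- draw_patient_params(pop, 1e4)
  for (t in c(-14, 30, 120, 300)) {
    w <- old_fraction(t, sp)
    vals <- mixture_mean(w, pats$mcv_old, pats$mcv_new) +
      pop$sigma_obs_mcv * stats::rt(1e4, pop$nu_mcv)
    target <- mixture_mean(w, pop$mu_mcv_old, pop$mu_mcv_new)
    expect_lt(abs(mean(vals) - target), 3 * sd(vals) / sqrt(1e4))
  }
})

test_that("generated cohorts are eligible by construction", {
  coh <- generate_cohort(cohort_config(seed = 20250505))
  # lower duration truncation guarantees the five-draw minimum
  expect_true(all(coh$patients$n_draws >= 5))
  expect_true(all(coh$patients$duration_days >= 56))
  elig <- apply_eligibility(coh$observations,
                            durations = coh$patients[, c("patient_id",
                                                         "duration_days")])
  # the only possible exclusions are rare high baseline-MCV draws
  expect_true(all(elig$exclusions$reason == "baseline_macrocytosis"))
  expect_lt(nrow(elig$exclusions) / nrow(coh$patients), 0.05)
})

test_that("cohort CSV round-trips through the reader", {
  coh <- generate_cohort(cohort_config(n_patients = 4, seed = 21))
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  back <- read_cbc_table(paths[1])
  expect_equal(as.data.frame(back),
               as.data.frame(dplyr::arrange(coh$observations, patient_id,
                                            t_days)))
  cfg <- read_cohort_config(paths[3])
  expect_equal(cfg$seed, coh$config$seed)
  expect_equal(cfg$population$mu_mcv_old, coh$config$population$mu_mcv_old)
})
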