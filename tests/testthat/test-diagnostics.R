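test_that("split R-hat separates mixed from shifted chains", {
  set.seed(1)
  good <- cbind(rnorm(1000), rnorm(1000))
  expect_lt(abs(split_rhat(good) - 1), 0.02)
  shifted <- cbind(rnorm(1000), rnorm(1000) + 3)
  expect_gt(split_rhat(shifted), 1.5)
})

test_that("rank statistics flag a shifted chain and pass a null chain", {
  set.seed(2)
  null_case <- cbind(rnorm(2000), rnorm(2000))
  rs <- rank_statistics(null_case)
  thresh <- stats::qchisq(0.99, df = 19)
  expect_true(all(rs$scores$statistic < thresh))
  # conservation: bin counts sum to the draws per chain
  expect_equal(sum(rs$histogram$count[rs$histogram$chain == 1]), 2000)
  shifted <- cbind(rnorm(2000), rnorm(2000) + 5)
  rs2 <- rank_statistics(shifted)
  expect_true(any(rs2$scores$statistic > thresh))
  expect_error(rank_statistics(matrix(rnorm(100), ncol = 1)),
               class = "rbclifespan_domain_error")
})

test_that("rank-statistic false-positive rate is calibrated", {
  thresh <- stats::qchisq(0.99, df = 19)
  set.seed(3)
  flags <- vapply(1:20, function(i) {
    rs <- rank_statistics(cbind(rnorm(1000), rnorm(1000)))
    any(rs$scores$statistic > thresh)
  }, logical(1))
  expect_lte(mean(flags), 0.10)
})

test_that("generalized-Pareto tail-shape estimator recovers known shapes", {
  rgpd <- function(n, k, s) s * ((1 - runif(n))^(-k) - 1) / k
  set.seed(4)
  for (k_true in c(0.2, 0.5, 0.9)) {
    est <- vapply(1:20, function(i) gpd_fit(rgpd(500, k_true, 1))$k,
                  numeric(1))
    expect_lt(abs(mean(est) - k_true), 0.12)
  }
})

test_that("PSIS-LOO satisfies its structural invariants on a real fit", {
  fit <- small_fit()$fit
  loo <- loo_khat(fit)
  expect_equal(nrow(loo$pointwise), fit$model$data$J)
  # nesting of the k-hat threshold counts
  expect_lte(loo$counts[["khat_gt_1_0"]], loo$counts[["khat_gt_0_7"]])
  expect_lte(loo$counts[["khat_gt_0_7"]], nrow(loo$pointwise))
  # LOO penalizes: elpd_loo below the in-sample log predictive density
  expect_lt(loo$elpd, loo$lpd)
  expect_gt(loo$p_loo, 0)
  # per-observable option triples the point count
  loo3 <- loo_khat(fit, by = "observable")
  expect_equal(nrow(loo3$pointwise), 3 * fit$model$data$J)
})

test_that("duplicating a record changes the LOO point count by one", {
  coh <- generate_cohort(cohort_config(n_patients = 3, seed = 90))
  cfg <- fit_config(n_chains = 2, n_warmup = 200, n_sampling = 150, seed = 2)
  f1 <- fit_rbc_model(build_rbc_model(coh$observations), cfg)
  dup <- dplyr::bind_rows(coh$observations, coh$observations[1, ])
  f2 <- fit_rbc_model(build_rbc_model(dup), cfg)
  expect_equal(nrow(loo_khat(f2)$pointwise),
               nrow(loo_khat(f1)$pointwise) + 1)
})

test_that("LOO refuses to run without stored log-likelihoods", {
  coh <- generate_cohort(cohort_config(n_patients = 3, seed = 91))
  fit <- fit_rbc_model(build_rbc_model(coh$observations),
                       fit_config(n_chains = 2, n_warmup = 200,
                                  n_sampling = 150, seed = 3),
                       store_loglik = FALSE)
  expect_error(loo_khat(fit), regexp = "store_loglik",
               class = "rbclifespan_domain_error")
})

test_that("posterior predictive checks pass on well-specified data and
           detect an injected shift", {
  fit <- small_fit()$fit
  ppc <- posterior_predictive(fit, "mcv", n_rep = 100, seed = 11)
  inside <- with(ppc$summary, observed >= lower & observed <= upper)
  expect_gte(mean(inside), 0.95)
  # degenerate single replicate: a curve but no envelope
  p1 <- posterior_predictive(fit, "mcv", n_rep = 1, seed = 12)
  expect_true(all(is.na(p1$summary$lower)))
  expect_error(posterior_predictive(fit, "hemoglobin"),
               class = "rbclifespan_domain_error")
  # constructed misfit: +20 fL shift in 30% of the observed records
  fit2 <- fit
  set.seed(13)
  idx <- sample(fit2$model$data$J, round(0.3 * fit2$model$data$J))
  fit2$model$data$mcv[idx] <- fit2$model$data$mcv[idx] + 20
  ppc2 <- posterior_predictive(fit2, "mcv", n_rep = 100, seed = 14)
  outside2 <- with(ppc2$summary, observed < lower | observed > upper)
  expect_gt(mean(outside2), 0.10)
})

test_that("convergence verdict reports the three acceptance rules", {
  fit <- small_fit()$fit
  v <- check_convergence(fit)
  expect_equal(v$check, c("n_divergences", "max_split_rhat", "min_ess"))
  expect_true(v$pass[v$check == "n_divergences"])
  expect_type(attr(v, "pass"), "logical")
})
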