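#' Prior configuration for the hierarchical model
#'
#' All priors live in this one block. The residual-survival location is
#' anchored at the 118-day healthy lifespan (Normal(log 118, 0.3) on the
#' log-days scale) with a Half-Normal(0.5) scale; hierarchy means are
#' centred at ordinary physiologic values with broad SDs, shared between
#' the old- and new-cell populations so the pre/post contrast is driven by
#' the data; between-patient SDs and observation-noise scales get
#' Half-Normal priors at laboratory magnitudes; the Student-t degrees of
#' freedom get a Gamma(2, 0.1) prior truncated above 1.
#'
#' @param survival_mu_mean,survival_mu_sd Normal prior on the survival
#'   location (log-days).
#' @param survival_sigma_sd Half-Normal prior scale on the survival scale.
#' @param mcv_mean,mcv_sd,mchc_mean,mchc_sd,n_mean,n_sd Normal priors on
#'   the hierarchy means (fL, g/dL, 10^12/L).
#' @param hier_sd_mcv,hier_sd_mchc,hier_sd_n Half-Normal prior scales on
#'   the between-patient SDs.
#' @param obs_sd_mcv,obs_sd_mchc,obs_sd_n Half-Normal prior scales on the
#'   observation-noise scales.
#' @param nu_shape,nu_rate Gamma prior on the degrees of freedom,
#'   truncated to (1, Inf).
#' @return A named list of class `rbc_priors`.
#' @export
rbc_priors <- function(survival_mu_mean = log(118), survival_mu_sd = 0.3,
                       survival_sigma_sd = 0.5,
                       mcv_mean = 90, mcv_sd = 15,
                       mchc_mean = 33, mchc_sd = 5,
                       n_mean = 4.5, n_sd = 2,
                       hier_sd_mcv = 10, hier_sd_mchc = 2, hier_sd_n = 1,
                       obs_sd_mcv = 5, obs_sd_mchc = 2, obs_sd_n = 1,
                       nu_shape = 2, nu_rate = 0.1) {
  out <- as.list(environment())
  stopifnot(all(vapply(out, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))))
  scales <- out[setdiff(names(out), "survival_mu_mean")]
  stopifnot(all(unlist(scales) > 0))
  structure(out, class = "rbc_priors")
}

#' Sampler configuration
#'
#' @param n_chains Number of MCMC chains (>= 2; default 4).
#' @param n_warmup Warm-up (adaptation + burn-in) iterations per chain.
#' @param n_sampling Retained draws per chain (>= 100).
#' @param seed Integer seed controlling chain initialisation and the
#'   per-chain random-number streams.
#' @param target_acceptance,max_treedepth Hamiltonian Monte Carlo tuning
#'   knobs, accepted for interface compatibility; the bundled Gibbs/slice
#'   backend (JAGS) does not use them.
#' @return A named list of class `fit_config`.
#' @export
fit_config <- function(n_chains = 4, n_warmup = 2000, n_sampling = 2000,
                       seed = 1, target_acceptance = 0.9,
                       max_treedepth = 10) {
  stopifnot(n_chains >= 2, n_sampling >= 100, n_warmup >= 0)
  structure(list(n_chains = as.integer(n_chains),
                 n_warmup = as.integer(n_warmup),
                 n_sampling = as.integer(n_sampling),
                 seed = as.integer(seed),
                 target_acceptance = target_acceptance,
                 max_treedepth = as.integer(max_treedepth)),
            class = "fit_config")
}

POPULATION_PARS <- c("mu_s", "sigma_s",
                     "mu_mcv_old", "mu_mcv_new", "sd_mcv_old", "sd_mcv_new",
                     "mu_mchc_old", "mu_mchc_new", "sd_mchc_old", "sd_mchc_new",
                     "mu_n_old", "mu_n_new", "sd_n_old", "sd_n_new",
                     "sigma_mcv", "sigma_mchc", "sigma_n",
                     "nu_mcv", "nu_mchc", "nu_n")
PATIENT_PARS <- c("mcv_old", "mcv_new", "mchc_old", "mchc_new",
                  "n_old", "n_new")

jags_model_string <- function(fix_survival = FALSE) {
  survival_block <- if (fix_survival) "" else
    "  mu_s ~ dnorm(pr_mu_s_mean, pow(pr_mu_s_sd, -2))
  sigma_s ~ dnorm(0, pow(pr_sigma_s_sd, -2)) T(0,)\n"
  paste0("model {
  for (j in 1:J) {
    w[j] <- pre[j] + (1 - pre[j]) * (1 - pnorm((logt[j] - mu_s) / sigma_s, 0, 1))
    mcv[j]  ~ dt(w[j] * mcv_old[pid[j]]  + (1 - w[j]) * mcv_new[pid[j]],
                 pow(sigma_mcv, -2),  nu_mcv)
    mchc[j] ~ dt(w[j] * mchc_old[pid[j]] + (1 - w[j]) * mchc_new[pid[j]],
                 pow(sigma_mchc, -2), nu_mchc)
    n[j]    ~ dt(w[j] * n_old[pid[j]]    + (1 - w[j]) * n_new[pid[j]],
                 pow(sigma_n, -2),    nu_n)
  }
  for (p in 1:P) {
    mcv_old[p]  ~ dnorm(mu_mcv_old,  pow(sd_mcv_old, -2))
    mcv_new[p]  ~ dnorm(mu_mcv_new,  pow(sd_mcv_new, -2))
    mchc_old[p] ~ dnorm(mu_mchc_old, pow(sd_mchc_old, -2))
    mchc_new[p] ~ dnorm(mu_mchc_new, pow(sd_mchc_new, -2))
    n_old[p]    ~ dnorm(mu_n_old,    pow(sd_n_old, -2))
    n_new[p]    ~ dnorm(mu_n_new,    pow(sd_n_new, -2))
  }
", survival_block, "
  mu_mcv_old  ~ dnorm(pr_mcv_mean,  pow(pr_mcv_sd, -2))
  mu_mcv_new  ~ dnorm(pr_mcv_mean,  pow(pr_mcv_sd, -2))
  mu_mchc_old ~ dnorm(pr_mchc_mean, pow(pr_mchc_sd, -2))
  mu_mchc_new ~ dnorm(pr_mchc_mean, pow(pr_mchc_sd, -2))
  mu_n_old    ~ dnorm(pr_n_mean,    pow(pr_n_sd, -2))
  mu_n_new    ~ dnorm(pr_n_mean,    pow(pr_n_sd, -2))
  sd_mcv_old  ~ dnorm(0, pow(pr_hier_sd_mcv, -2)) T(0,)
  sd_mcv_new  ~ dnorm(0, pow(pr_hier_sd_mcv, -2)) T(0,)
  sd_mchc_old ~ dnorm(0, pow(pr_hier_sd_mchc, -2)) T(0,)
  sd_mchc_new ~ dnorm(0, pow(pr_hier_sd_mchc, -2)) T(0,)
  sd_n_old    ~ dnorm(0, pow(pr_hier_sd_n, -2)) T(0,)
  sd_n_new    ~ dnorm(0, pow(pr_hier_sd_n, -2)) T(0,)
  sigma_mcv   ~ dnorm(0, pow(pr_obs_sd_mcv, -2)) T(0,)
  sigma_mchc  ~ dnorm(0, pow(pr_obs_sd_mchc, -2)) T(0,)
  sigma_n     ~ dnorm(0, pow(pr_obs_sd_n, -2)) T(0,)
  nu_mcv  ~ dgamma(pr_nu_shape, pr_nu_rate) T(1,)
  nu_mchc ~ dgamma(pr_nu_shape, pr_nu_rate) T(1,)
  nu_n    ~ dgamma(pr_nu_shape, pr_nu_rate) T(1,)
  lifespan <- exp(mu_s + pow(sigma_s, 2) / 2)
}
")
}

#' Build the hierarchical Bayesian replacement-kinetics model
#'
#' Encodes the generative model for an eligible, time-aligned cohort: each
#' blood draw's RBC count, MCV and MCHC follow Student-t distributions
#' centred on the old/new mixture mean at that draw's old-cell fraction;
#' patient-level old/new values follow Normal hierarchies; the old-cell
#' fraction follows the LogNormal residual-survival law. The probabilistic
#' kernel is expressed in the JAGS modelling language and driven from R.
#'
#' @param records Canonical CBC tibble (`patient_id, t_days,
#'   rbc_1e12_per_L, mcv_fL, mchc_g_dL`), e.g. the `records` element of
#'   [apply_eligibility()] or a synthetic cohort's observations.
#' @param priors An [rbc_priors()] block.
#' @param fix_survival Optional [survival_params()]: fixes the survival law
#'   instead of estimating it (used in self-consistency checks).
#' @return An object of class `rbc_model`: the model code, the data block,
#'   the patient index, and the parameter count.
#' @export
build_rbc_model <- function(records, priors = rbc_priors(),
                            fix_survival = NULL) {
  stopifnot(inherits(priors, "rbc_priors"))
  stopifnot(all(CANONICAL_COLUMNS %in% names(records)))
  if (nrow(records) == 0) {
    rlang::abort("no records to fit.", class = "rbclifespan_domain_error")
  }
  num_cols <- setdiff(CANONICAL_COLUMNS, "patient_id")
  if (any(!is.finite(as.matrix(records[, num_cols])))) {
    rlang::abort("records contain missing or non-finite values.",
                 class = "rbclifespan_domain_error")
  }
  if (any(as.matrix(records[, setdiff(num_cols, "t_days")]) <= 0)) {
    rlang::abort("measured values must be strictly positive.",
                 class = "rbclifespan_domain_error")
  }
  records <- dplyr::arrange(records, .data$patient_id, .data$t_days)
  patients <- tibble(patient_id = sort(unique(records$patient_id)))
  patients$index <- seq_len(nrow(patients))
  pid <- patients$index[match(records$patient_id, patients$patient_id)]
  pr <- priors
  data <- list(
    J = nrow(records), P = nrow(patients), pid = pid,
    pre = as.numeric(records$t_days <= 0),
    logt = ifelse(records$t_days > 0, log(pmax(records$t_days, 1e-12)), 0),
    mcv = records$mcv_fL, mchc = records$mchc_g_dL,
    n = records$rbc_1e12_per_L,
    pr_mcv_mean = pr$mcv_mean, pr_mcv_sd = pr$mcv_sd,
    pr_mchc_mean = pr$mchc_mean, pr_mchc_sd = pr$mchc_sd,
    pr_n_mean = pr$n_mean, pr_n_sd = pr$n_sd,
    pr_hier_sd_mcv = pr$hier_sd_mcv, pr_hier_sd_mchc = pr$hier_sd_mchc,
    pr_hier_sd_n = pr$hier_sd_n,
    pr_obs_sd_mcv = pr$obs_sd_mcv, pr_obs_sd_mchc = pr$obs_sd_mchc,
    pr_obs_sd_n = pr$obs_sd_n,
    pr_nu_shape = pr$nu_shape, pr_nu_rate = pr$nu_rate)
  fixed <- !is.null(fix_survival)
  if (fixed) {
    stopifnot(inherits(fix_survival, "survival_params"))
    data$mu_s <- fix_survival$mu_survival
    data$sigma_s <- fix_survival$sigma_survival
  } else {
    data$pr_mu_s_mean <- pr$survival_mu_mean
    data$pr_mu_s_sd <- pr$survival_mu_sd
    data$pr_sigma_s_sd <- pr$survival_sigma_sd
  }
  structure(list(
    code = jags_model_string(fix_survival = fixed),
    data = data, records = as_tibble(records), patients = patients,
    priors = priors, survival_fixed = fixed,
    n_parameters = 6L * nrow(patients) + 12L + 3L + 3L + (!fixed) * 2L),
    class = "rbc_model")
}

#' @export
print.rbc_model <- function(x, ...) {
  cat(sprintf("<rbc_model> %d patients, %d blood draws, %d parameters%s\n",
              x$data$P, x$data$J, x$n_parameters,
              if (x$survival_fixed) " (survival law fixed)" else ""))
  invisible(x)
}

# Overdispersed chain initial values for the population-level parameters.
chain_inits <- function(model, config) {
  pr <- model$priors
  set.seed(config$seed)
  lapply(seq_len(config$n_chains), function(ch) {
    ini <- list(
      mu_mcv_old = rnorm(1, pr$mcv_mean, 3), mu_mcv_new = rnorm(1, pr$mcv_mean, 3),
      mu_mchc_old = rnorm(1, pr$mchc_mean, 0.7),
      mu_mchc_new = rnorm(1, pr$mchc_mean, 0.7),
      mu_n_old = rnorm(1, pr$n_mean, 0.4), mu_n_new = rnorm(1, pr$n_mean, 0.4),
      sd_mcv_old = runif(1, 1, 6), sd_mcv_new = runif(1, 1, 6),
      sd_mchc_old = runif(1, 0.2, 1.2), sd_mchc_new = runif(1, 0.2, 1.2),
      sd_n_old = runif(1, 0.1, 0.8), sd_n_new = runif(1, 0.1, 0.8),
      sigma_mcv = runif(1, 0.5, 3), sigma_mchc = runif(1, 0.2, 1.2),
      sigma_n = runif(1, 0.05, 0.4),
      nu_mcv = runif(1, 3, 20), nu_mchc = runif(1, 3, 20),
      nu_n = runif(1, 3, 20),
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = config$seed * 101L + ch)
    if (!model$survival_fixed) {
      ini$mu_s <- rnorm(1, pr$survival_mu_mean, 0.15)
      ini$sigma_s <- runif(1, 0.15, 0.5)
    }
    ini
  })
}

#' Fit the replacement-kinetics model by MCMC
#'
#' Runs the JAGS Gibbs/slice sampler: an adaptation phase and burn-in
#' totalling `config$n_warmup` iterations per chain, then
#' `config$n_sampling` retained draws per chain, with overdispersed
#' initial values and per-chain seeded random-number streams so a given
#' `(model, config)` pair is exactly reproducible.
#'
#' Alongside the raw draws the fit stores, per pooled draw, the derived
#' population quantities: the mean lifespan `exp(mu_s + sigma_s^2/2)`, the
#' post-minus-pre MCV and MCHC contrasts, the RBC-count decrease
#' (pre minus post), and the derived pre/post hemoglobin (product identity
#' applied draw by draw to the population means). Pointwise log-likelihoods
#' (the three observables summed per blood draw) are stored for LOO unless
#' `store_loglik = FALSE`.
#'
#' @param model An [build_rbc_model()] object.
#' @param config A [fit_config()].
#' @param store_loglik Store the pointwise log-likelihood matrix (needed by
#'   [loo_khat()] and [posterior_predictive()] penalty checks)?
#' @param quiet Suppress JAGS progress output?
#' @return An object of class `rbc_fit`; see [tidy.rbc_fit()],
#'   [glance.rbc_fit()], [summarize_posterior()].
#' @export
fit_rbc_model <- function(model, config = fit_config(), store_loglik = TRUE,
                          quiet = TRUE) {
  stopifnot(inherits(model, "rbc_model"), inherits(config, "fit_config"))
  n_adapt <- max(100L, min(1000L, config$n_warmup %/% 2L))
  n_burn <- max(0L, config$n_warmup - n_adapt)
  jm <- rjags::jags.model(textConnection(model$code), data = model$data,
                          inits = chain_inits(model, config),
                          n.chains = config$n_chains, n.adapt = n_adapt,
                          quiet = quiet)
  if (n_burn > 0) update(jm, n_burn, progress.bar = if (quiet) "none" else "text")
  monitors <- c(setdiff(POPULATION_PARS, if (model$survival_fixed)
    c("mu_s", "sigma_s") else character()), "lifespan", PATIENT_PARS)
  samples <- rjags::coda.samples(jm, variable.names = monitors,
                                 n.iter = config$n_sampling,
                                 progress.bar = if (quiet) "none" else "text")
  pooled <- do.call(rbind, lapply(samples, as.matrix))
  # coda drops the [1] index on length-one parameter vectors
  bare <- intersect(PATIENT_PARS, colnames(pooled))
  colnames(pooled)[match(bare, colnames(pooled))] <- paste0(bare, "[1]")
  if (model$survival_fixed) {
    pooled <- cbind(pooled, mu_s = model$data$mu_s,
                    sigma_s = model$data$sigma_s)
  }
  derived <- tibble(
    lifespan_days = exp(pooled[, "mu_s"] + pooled[, "sigma_s"]^2 / 2),
    mcv_delta = pooled[, "mu_mcv_new"] - pooled[, "mu_mcv_old"],
    mchc_delta = pooled[, "mu_mchc_new"] - pooled[, "mu_mchc_old"],
    rbc_decrease = pooled[, "mu_n_old"] - pooled[, "mu_n_new"],
    hgb_pre = derived_hemoglobin(pooled[, "mu_n_old"], pooled[, "mu_mcv_old"],
                                 pooled[, "mu_mchc_old"]),
    hgb_post = derived_hemoglobin(pooled[, "mu_n_new"], pooled[, "mu_mcv_new"],
                                  pooled[, "mu_mchc_new"]))
  derived$hgb_delta <- derived$hgb_post - derived$hgb_pre
  fit <- structure(list(
    samples = samples, pooled = pooled, derived = derived, model = model,
    config = config, pointwise_loglik = NULL, n_divergences = 0L),
    class = "rbc_fit")
  fit$summaries <- tidy(fit)
  diag_pars <- intersect(POPULATION_PARS, colnames(as.matrix(samples[[1]])))
  fit$diagnostics <- list(
    n_divergences = 0L,
    max_rhat = max(split_rhat(samples)[diag_pars]),
    min_ess = min(coda::effectiveSize(samples[, diag_pars])),
    n_chains = config$n_chains,
    n_draws = nrow(pooled))
  if (store_loglik) fit$pointwise_loglik <- pointwise_loglik_matrix(fit)
  fit
}

# Student-t location-scale log density.
dt_ls <- function(x, df, location, scale, log = TRUE) {
  out <- stats::dt((x - location) / scale, df = df, log = TRUE) - log(scale)
  if (log) out else exp(out)
}

# S x J matrix of per-draw, per-blood-draw log-likelihoods (three
# observables summed), computed in chunks to bound memory.
pointwise_loglik_matrix <- function(fit, chunk = 500L) {
  m <- fit$model
  pooled <- fit$pooled
  S <- nrow(pooled); J <- m$data$J
  pid <- m$data$pid
  logt <- m$data$logt; pre <- m$data$pre
  y_mcv <- m$data$mcv; y_mchc <- m$data$mchc; y_n <- m$data$n
  col <- function(stub) paste0(stub, "[", seq_len(m$data$P), "]")
  out <- matrix(NA_real_, S, J)
  for (s0 in seq(1, S, by = chunk)) {
    idx <- s0:min(s0 + chunk - 1L, S)
    z <- (matrix(logt, length(idx), J, byrow = TRUE) - pooled[idx, "mu_s"]) /
      pooled[idx, "sigma_s"]
    W <- stats::pnorm(z, lower.tail = FALSE)
    W[, pre == 1] <- 1
    ll <- matrix(0, length(idx), J)
    for (obs in list(list(stub_old = "mcv_old", stub_new = "mcv_new",
                          y = y_mcv, sig = "sigma_mcv", nu = "nu_mcv"),
                     list(stub_old = "mchc_old", stub_new = "mchc_new",
                          y = y_mchc, sig = "sigma_mchc", nu = "nu_mchc"),
                     list(stub_old = "n_old", stub_new = "n_new",
                          y = y_n, sig = "sigma_n", nu = "nu_n"))) {
      old <- pooled[idx, col(obs$stub_old), drop = FALSE][, pid, drop = FALSE]
      new <- pooled[idx, col(obs$stub_new), drop = FALSE][, pid, drop = FALSE]
      loc <- W * old + (1 - W) * new
      ll <- ll + dt_ls(matrix(obs$y, length(idx), J, byrow = TRUE),
                       df = pooled[idx, obs$nu], location = loc,
                       scale = pooled[idx, obs$sig])
    }
    out[idx, ] <- ll
  }
  out
}

#' Tidy posterior summaries of a fitted model
#'
#' One row per population-level parameter and derived quantity: posterior
#' median, central 95% credible interval, split-R-hat and effective sample
#' size (diagnostics are `NA` for quantities derived from pooled draws).
#'
#' @param x An `rbc_fit`.
#' @param patients Also include the per-patient latent values?
#' @param ... Unused.
#' @return A tibble with columns `term`, `median`, `conf.low`, `conf.high`,
#'   `rhat`, `ess`.
#' @export
tidy.rbc_fit <- function(x, patients = FALSE, ...) {
  pooled <- x$pooled
  keep <- intersect(POPULATION_PARS, colnames(pooled))
  if (patients) {
    keep <- c(keep, grep("\\[", colnames(pooled), value = TRUE))
  }
  rhat <- split_rhat(x$samples)
  ess <- coda::effectiveSize(x$samples)
  q <- function(v) stats::quantile(v, c(0.5, 0.025, 0.975), names = FALSE)
  base <- purrr::map(keep, function(p) {
    qq <- q(pooled[, p])
    tibble(term = p, median = qq[1], conf.low = qq[2], conf.high = qq[3],
           rhat = unname(rhat[p]), ess = unname(ess[p]))
  })
  der <- purrr::imap(as.list(x$derived), function(v, nm) {
    qq <- q(v)
    tibble(term = nm, median = qq[1], conf.low = qq[2], conf.high = qq[3],
           rhat = NA_real_, ess = NA_real_)
  })
  dplyr::bind_rows(c(base, der))
}

#' One-row fit diagnostics summary
#'
#' @param x An `rbc_fit`.
#' @param ... Unused.
#' @return A one-row tibble: cohort size, draw counts, maximum split-R-hat
#'   and minimum effective sample size over the population-level
#'   parameters, and the divergence count (identically 0 for the
#'   Gibbs/slice backend, which has no divergent-transition concept).
#' @export
glance.rbc_fit <- function(x, ...) {
  tibble(n_patients = x$model$data$P, n_records = x$model$data$J,
         n_parameters = x$model$n_parameters,
         n_chains = x$config$n_chains, n_draws = x$diagnostics$n_draws,
         max_rhat = x$diagnostics$max_rhat, min_ess = x$diagnostics$min_ess,
         n_divergences = x$diagnostics$n_divergences)
}

#' @export
print.rbc_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<rbc_fit> %d patients, %d draws x %d chains | max split-Rhat %.3f, min ESS %.0f\n",
    g$n_patients, x$config$n_sampling, g$n_chains, g$max_rhat, g$min_ess))
  ls <- x$summaries[x$summaries$term == "lifespan_days", ]
  cat(sprintf("  mean RBC lifespan: %.1f days (95%% CdI %.1f-%.1f)\n",
              ls$median, ls$conf.low, ls$conf.high))
  invisible(x)
}

#' Population-level report table
#'
#' The study-style summary: pre/post population means of MCV, MCHC, RBC
#' count and derived hemoglobin, the four contrasts (post minus pre; the
#' RBC contrast reported as a decrease, pre minus post), and the mean RBC
#' lifespan — each as posterior median with central 95% credible interval.
#' All contrasts are computed draw by draw, never from medians.
#'
#' @param fit An `rbc_fit`.
#' @return A tibble `quantity, unit, median, conf.low, conf.high`.
#' @export
summarize_posterior <- function(fit) {
  stopifnot(inherits(fit, "rbc_fit"))
  pooled <- fit$pooled; der <- fit$derived
  rows <- list(
    mcv_pre = list(pooled[, "mu_mcv_old"], "fL"),
    mcv_post = list(pooled[, "mu_mcv_new"], "fL"),
    mcv_delta = list(der$mcv_delta, "fL"),
    mchc_pre = list(pooled[, "mu_mchc_old"], "g/dL"),
    mchc_post = list(pooled[, "mu_mchc_new"], "g/dL"),
    mchc_delta = list(der$mchc_delta, "g/dL"),
    rbc_pre = list(pooled[, "mu_n_old"], "10^12/L"),
    rbc_post = list(pooled[, "mu_n_new"], "10^12/L"),
    rbc_decrease = list(der$rbc_decrease, "10^12/L"),
    hgb_pre = list(der$hgb_pre, "g/dL"),
    hgb_post = list(der$hgb_post, "g/dL"),
    hgb_delta = list(der$hgb_delta, "g/dL"),
    lifespan = list(der$lifespan_days, "days"))
  purrr::imap(rows, function(r, nm) {
    qq <- stats::quantile(r[[1]], c(0.5, 0.025, 0.975), names = FALSE)
    tibble(quantity = nm, unit = r[[2]], median = qq[1], conf.low = qq[2],
           conf.high = qq[3])
  }) |> dplyr::bind_rows()
}

#' Prior predictive simulation of measured MCV values
#'
#' Simulates blood-draw MCV measurements from the priors alone (hierarchy
#' means and SDs, observation noise, survival law, uniform draw times over
#' a typical observation span), for prior-calibration checks.
#'
#' @param n Number of simulated measurements.
#' @param priors An [rbc_priors()] block.
#' @param t_range Range of draw times sampled uniformly, days.
#' @return A tibble with columns `t_days`, `mcv_fL`.
#' @export
prior_predictive <- function(n = 1000, priors = rbc_priors(),
                             t_range = c(-28, 400)) {
  draw_halfnorm <- function(m, s) abs(rnorm(m, 0, s))
  draw_nu <- function(m) {
    out <- numeric(0)
    while (length(out) < m) {
      cand <- stats::rgamma(m, priors$nu_shape, priors$nu_rate)
      out <- c(out, cand[cand > 1])
    }
    out[seq_len(m)]
  }
  mu_s <- rnorm(n, priors$survival_mu_mean, priors$survival_mu_sd)
  sigma_s <- draw_halfnorm(n, priors$survival_sigma_sd)
  mu_old <- rnorm(n, priors$mcv_mean, priors$mcv_sd)
  mu_new <- rnorm(n, priors$mcv_mean, priors$mcv_sd)
  val_old <- rnorm(n, mu_old, draw_halfnorm(n, priors$hier_sd_mcv))
  val_new <- rnorm(n, mu_new, draw_halfnorm(n, priors$hier_sd_mcv))
  t <- runif(n, t_range[1], t_range[2])
  w <- ifelse(t <= 0, 1,
              stats::pnorm((log(pmax(t, 1e-12)) - mu_s) / sigma_s,
                           lower.tail = FALSE))
  loc <- w * val_old + (1 - w) * val_new
  mcv <- loc + draw_halfnorm(n, priors$obs_sd_mcv) * stats::rt(n, draw_nu(n))
  tibble(t_days = t, mcv_fL = mcv)
}
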