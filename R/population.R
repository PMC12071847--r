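#' Population-level parameters of the synthetic cohort
#'
#' Hierarchical means and standard deviations of the patient-level true
#' red-cell indices (old = made before treatment, new = made on treatment),
#' plus the Student-t observation-noise scale and degrees of freedom for
#' each observable.
#'
#' Default calibration. The old/new MCV means (87.8 and 100.2 fL), the MCHC
#' shift (+0.69 g/dL) and the RBC-count drop (-0.77 x 10^12/L) are the
#' population posterior medians reported for a 122-patient CDK4/6-inhibitor
#' cohort; the absolute MCHC and RBC anchors (33.0 g/dL, 4.5 x 10^12/L) are
#' ordinary physiologic values, since only the contrasts were reported.
#' Between-patient SDs and the observation-noise scales are not reported
#' anywhere and are free calibration constants chosen at realistic
#' laboratory magnitudes; override them as needed.
#'
#' Note that hemoglobin is derived, not simulated: with this calibration the
#' implied hemoglobin change is `derived_hemoglobin(4.5 - 0.77, 100.2,
#' 33.69) - derived_hemoglobin(4.5, 87.8, 33.0)`, about -0.45 g/dL. See the
#' methods vignette for why the four published contrasts cannot be made
#' simultaneously consistent with the hemoglobin identity at physiologic
#' anchors.
#'
#' @param mu_mcv_old,mu_mcv_new Population mean MCV (fL) of old/new cells.
#' @param sigma_mcv_old,sigma_mcv_new Between-patient SD of MCV (fL).
#' @param mu_mchc_old,mu_mchc_new Population mean MCHC (g/dL).
#' @param sigma_mchc_old,sigma_mchc_new Between-patient SD of MCHC (g/dL).
#' @param mu_n_old,mu_n_new Population mean RBC count (10^12/L).
#' @param sigma_n_old,sigma_n_new Between-patient SD of RBC count (10^12/L).
#' @param sigma_obs_mcv,sigma_obs_mchc,sigma_obs_n Student-t scale of the
#'   measurement noise, in the observable's units.
#' @param nu_mcv,nu_mchc,nu_n Student-t degrees of freedom (> 1) of the
#'   measurement noise.
#' @return An object of class `population_params` (named list).
#' @export
population_params <- function(mu_mcv_old = 87.8, sigma_mcv_old = 4.5,
                              mu_mcv_new = 100.2, sigma_mcv_new = 4.5,
                              mu_mchc_old = 33.0, sigma_mchc_old = 0.8,
                              mu_mchc_new = 33.69, sigma_mchc_new = 0.8,
                              mu_n_old = 4.5, sigma_n_old = 0.45,
                              mu_n_new = 3.73, sigma_n_new = 0.45,
                              sigma_obs_mcv = 1.5, sigma_obs_mchc = 0.6,
                              sigma_obs_n = 0.15,
                              nu_mcv = 5, nu_mchc = 5, nu_n = 5) {
  out <- as.list(environment())
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!all(vapply(out, num1, logical(1)))) {
    rlang::abort("all population parameters must be finite scalars.",
                 class = "rbclifespan_domain_error")
  }
  sds <- out[grepl("^sigma_(mcv|mchc|n)_(old|new)$", names(out))]
  if (any(unlist(sds) < 0)) {
    rlang::abort("hierarchical SDs must be >= 0.", class = "rbclifespan_domain_error")
  }
  if (any(unlist(out[grepl("^sigma_obs_", names(out))]) < 0)) {
    rlang::abort("observation-noise scales must be >= 0.",
                 class = "rbclifespan_domain_error")
  }
  if (any(unlist(out[grepl("^nu_", names(out))]) <= 1)) {
    rlang::abort("degrees of freedom must exceed 1.",
                 class = "rbclifespan_domain_error")
  }
  structure(out, class = "population_params")
}

DAYS_PER_MONTH <- 30.44

# Quantile of a LogNormal truncated to [lower, upper].
qlnorm_trunc <- function(p, meanlog, sdlog, lower, upper) {
  p_lo <- stats::plnorm(lower, meanlog, sdlog)
  p_hi <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(p_lo + p * (p_hi - p_lo), meanlog, sdlog)
}

#' Fit a truncated LogNormal treatment-duration law to reported quantiles
#'
#' Solves for `(meanlog, sdlog)` of a LogNormal duration distribution,
#' truncated to `[lower, upper]`, whose median matches `q50` exactly and
#' whose quartiles approximate `(q25, q75)` in least squares on the log
#' scale. The defaults are the reported cohort summaries of continuous
#' treatment duration — median 7.2 months, interquartile range 3.4-13.3 —
#' and the lower truncation point (56 days) is the shortest duration whose
#' blood-draw schedule yields the five measurements required for
#' eligibility, so every simulated patient is eligible by construction.
#'
#' @param q50 Target median, months (matched exactly).
#' @param q25,q75 Target quartiles, months (matched in least squares).
#' @param lower,upper Truncation bounds, in months.
#' @return Named list with `meanlog`, `sdlog` (log-months scale) and the
#'   implied `median`, `q25`, `q75` (months) of the truncated law.
#' @export
fit_duration_lognormal <- function(q50 = 7.2, q25 = 3.4, q75 = 13.3,
                                   lower = 56 / DAYS_PER_MONTH,
                                   upper = 1826 / DAYS_PER_MONTH) {
  stopifnot(q25 > lower, q50 > q25, q75 > q50, upper > q75)
  meanlog_for <- function(s) {
    stats::uniroot(function(m) qlnorm_trunc(0.5, m, s, lower, upper) - q50,
                   interval = log(q50) + c(-6, 6), tol = 1e-10)$root
  }
  obj <- function(s) {
    m <- meanlog_for(s)
    (log(qlnorm_trunc(0.25, m, s, lower, upper)) - log(q25))^2 +
      (log(qlnorm_trunc(0.75, m, s, lower, upper)) - log(q75))^2
  }
  sdlog <- stats::optimize(obj, interval = c(0.05, 3), tol = 1e-9)$minimum
  meanlog <- meanlog_for(sdlog)
  list(meanlog = meanlog, sdlog = sdlog,
       median = qlnorm_trunc(0.5, meanlog, sdlog, lower, upper),
       q25 = qlnorm_trunc(0.25, meanlog, sdlog, lower, upper),
       q75 = qlnorm_trunc(0.75, meanlog, sdlog, lower, upper))
}

#' Configuration of a synthetic longitudinal CBC cohort
#'
#' Bundles everything [generate_cohort()] needs: the cohort size, the
#' residual-survival law of pre-treatment cells, the population hierarchy
#' and noise model, the treatment-duration law and the sampling-schedule
#' bounds. Defaults emulate the reported study population: 122 patients,
#' median continuous treatment duration 7.2 months (IQR 3.4-13.3), one
#' baseline blood draw within 4 weeks before the first dose, then biweekly
#' draws for two months and monthly draws afterwards (a mean of about 16
#' draws per patient).
#'
#' @param n_patients Number of patients (>= 1).
#' @param survival A [survival_params()] object (generating truth).
#' @param population A [population_params()] object.
#' @param duration_meanlog,duration_sdlog LogNormal parameters of continuous
#'   treatment duration, on the log-months scale. Defaults are solved by
#'   [fit_duration_lognormal()] from the reported quartiles.
#' @param min_duration Lower truncation of duration, days. The default 56
#'   guarantees at least five scheduled draws per patient.
#' @param max_followup Upper truncation of duration, days (default five
#'   years, the span of the retrospective observation window).
#' @param baseline_window Baseline draws fall in `[-baseline_window, 0)`
#'   days; default 28.
#' @param seed Integer seed making the generated cohort reproducible.
#' @return An object of class `cohort_config` (named list).
#' @export
cohort_config <- function(n_patients = 122,
                          survival = survival_params(),
                          population = population_params(),
                          duration_meanlog = NULL,
                          duration_sdlog = NULL,
                          min_duration = 56,
                          max_followup = 1826,
                          baseline_window = 28,
                          seed = 20250505) {
  stopifnot(n_patients >= 1, inherits(survival, "survival_params"),
            inherits(population, "population_params"),
            min_duration > 0, max_followup > min_duration,
            baseline_window > 0)
  if (is.null(duration_meanlog) || is.null(duration_sdlog)) {
    fitted <- fit_duration_lognormal(lower = min_duration / DAYS_PER_MONTH,
                                     upper = max_followup / DAYS_PER_MONTH)
    duration_meanlog <- duration_meanlog %||% fitted$meanlog
    duration_sdlog <- duration_sdlog %||% fitted$sdlog
  }
  stopifnot(duration_sdlog >= 0)
  structure(list(n_patients = as.integer(n_patients), survival = survival,
                 population = population, duration_meanlog = duration_meanlog,
                 duration_sdlog = duration_sdlog, min_duration = min_duration,
                 max_followup = max_followup, baseline_window = baseline_window,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    paste0("<cohort_config> %d patients, duration LogNormal(%.3f, %.3f) ",
           "log-months on [%g, %g] d, baseline window %g d, seed %d\n"),
    x$n_patients, x$duration_meanlog, x$duration_sdlog, x$min_duration,
    x$max_followup, x$baseline_window, x$seed))
  invisible(x)
}
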