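# Student-t (location-scale) draw truncated to positive values: negative
# laboratory measurements are physically impossible, so pathological
# heavy-tail draws are rejected and redrawn.
rt_ls_positive <- function(n, df, location, scale) {
  if (all(scale == 0)) return(location)
  out <- location + scale * stats::rt(n, df)
  bad <- which(out <= 0)
  tries <- 0L
  while (length(bad) > 0L && tries < 1000L) {
    out[bad] <- location[bad] + scale * stats::rt(length(bad), df)
    bad <- bad[out[bad] <= 0]
    tries <- tries + 1L
  }
  out
}

#' Draw patient-level true red-cell indices from the population hierarchy
#'
#' Each patient carries six latent true values — the RBC count, MCV and MCHC
#' of their pre-treatment ("old") and on-treatment ("new") red cells — drawn
#' independently from Normal distributions with the population means and
#' between-patient SDs in `population`. Uses the current R random-number
#' state; seed upstream for reproducibility.
#'
#' @param population A [population_params()] object.
#' @param n Number of patients to draw.
#' @return A tibble with `n` rows and columns `mcv_old`, `mcv_new`,
#'   `mchc_old`, `mchc_new`, `n_old`, `n_new`.
#' @export
draw_patient_params <- function(population, n = 1) {
  stopifnot(inherits(population, "population_params"), n >= 1)
  p <- population
  tibble(
    mcv_old  = rnorm(n, p$mu_mcv_old,  p$sigma_mcv_old),
    mcv_new  = rnorm(n, p$mu_mcv_new,  p$sigma_mcv_new),
    mchc_old = rnorm(n, p$mu_mchc_old, p$sigma_mchc_old),
    mchc_new = rnorm(n, p$mu_mchc_new, p$sigma_mchc_new),
    n_old    = rnorm(n, p$mu_n_old,    p$sigma_n_old),
    n_new    = rnorm(n, p$mu_n_new,    p$sigma_n_new)
  )
}

#' Blood-draw schedule for one treated patient
#'
#' Mirrors routine CDK4/6-inhibitor monitoring: one baseline draw in the
#' four weeks before the first dose, then draws every 14 days through day
#' 56 (two months) and every 28 days afterwards, for as long as the patient
#' stays on drug.
#'
#' @param duration Days of continuous treatment (> 0).
#' @param baseline_window The baseline draw falls uniformly in
#'   `[-baseline_window, 0)` days.
#' @param baseline_time Optional fixed baseline time (negative days);
#'   drawn uniformly when `NULL`.
#' @return Strictly increasing draw times in days relative to first dose.
#' @examples
#' sampling_schedule(180, baseline_time = -14)
#' @export
sampling_schedule <- function(duration, baseline_window = 28,
                              baseline_time = NULL) {
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    rlang::abort("`duration` must be a positive scalar (days).",
                 class = "rbclifespan_domain_error")
  }
  baseline <- baseline_time %||% runif(1, -baseline_window, 0)
  stopifnot(baseline < 0, baseline >= -baseline_window)
  on_drug <- c(seq(14, 56, by = 14), seq(84, max(84, duration), by = 28))
  c(baseline, on_drug[on_drug <= duration])
}

#' Simulate one patient's measured blood counts at given times
#'
#' For each observable the measurement location is the old/new mixture mean
#' at the old-cell fraction `old_fraction(t, survival)`, and the measured
#' value adds Student-t noise with the population scale and degrees of
#' freedom (redrawn if non-positive). With zero noise scales the exact
#' mixture curve is returned.
#'
#' @param t Draw times in days relative to first dose (vector).
#' @param patient One row of [draw_patient_params()] (the patient's six
#'   true values).
#' @param population A [population_params()] object (noise model).
#' @param survival A [survival_params()] object.
#' @return A tibble with columns `t_days`, `rbc_1e12_per_L`, `mcv_fL`,
#'   `mchc_g_dL`.
#' @export
simulate_observation <- function(t, patient, population, survival) {
  stopifnot(is.numeric(t), nrow(patient) == 1L,
            inherits(population, "population_params"),
            inherits(survival, "survival_params"))
  w <- old_fraction(t, survival)
  m <- length(t)
  p <- population
  tibble(
    t_days = t,
    rbc_1e12_per_L = rt_ls_positive(
      m, p$nu_n, mixture_mean(w, patient$n_old, patient$n_new), p$sigma_obs_n),
    mcv_fL = rt_ls_positive(
      m, p$nu_mcv, mixture_mean(w, patient$mcv_old, patient$mcv_new),
      p$sigma_obs_mcv),
    mchc_g_dL = rt_ls_positive(
      m, p$nu_mchc, mixture_mean(w, patient$mchc_old, patient$mchc_new),
      p$sigma_obs_mchc)
  )
}

#' Generate a synthetic longitudinal CBC cohort
#'
#' Draws, for each patient: a continuous treatment duration from the
#' truncated LogNormal duration law; a monitoring schedule
#' ([sampling_schedule()]); latent true red-cell indices
#' ([draw_patient_params()]); and noisy measurements at every scheduled
#' time ([simulate_observation()]). The generating truth is returned next
#' to the data so parameter-recovery studies never re-derive it.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `rbc_cohort`: a list with
#'   \describe{
#'     \item{observations}{tibble `patient_id, t_days, rbc_1e12_per_L,
#'       mcv_fL, mchc_g_dL` — one row per blood draw;}
#'     \item{patients}{tibble of per-patient ground truth: the six latent
#'       index values, `duration_days`, `n_draws`;}
#'     \item{config}{the frozen configuration.}
#'   }
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 3, seed = 1))
#' coh$observations
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  lo <- config$min_duration / DAYS_PER_MONTH
  hi <- config$max_followup / DAYS_PER_MONTH
  duration_days <- DAYS_PER_MONTH *
    qlnorm_trunc(runif(n), config$duration_meanlog, config$duration_sdlog, lo, hi)
  patients <- draw_patient_params(config$population, n)
  patients$patient_id <- sprintf("P%04d", seq_len(n))
  patients$duration_days <- duration_days
  obs <- purrr::map(seq_len(n), function(i) {
    ts <- sampling_schedule(duration_days[i], config$baseline_window)
    out <- simulate_observation(ts, patients[i, ], config$population,
                                config$survival)
    out$patient_id <- patients$patient_id[i]
    out
  })
  observations <- dplyr::bind_rows(obs)[
    , c("patient_id", "t_days", "rbc_1e12_per_L", "mcv_fL", "mchc_g_dL")]
  patients$n_draws <- as.integer(table(observations$patient_id)[patients$patient_id])
  patients <- patients[, c("patient_id", "mcv_old", "mcv_new", "mchc_old",
                           "mchc_new", "n_old", "n_new", "duration_days",
                           "n_draws")]
  structure(list(observations = as_tibble(observations),
                 patients = as_tibble(patients), config = config),
            class = "rbc_cohort")
}

#' @export
print.rbc_cohort <- function(x, ...) {
  cat(sprintf(
    "<rbc_cohort> %d patients, %d blood draws (mean %.1f/patient), median duration %.1f months\n",
    nrow(x$patients), nrow(x$observations),
    nrow(x$observations) / nrow(x$patients),
    median(x$patients$duration_days) / DAYS_PER_MONTH))
  invisible(x)
}

#' Write a synthetic cohort to tidy CSV files
#'
#' Writes `observations.csv` (one row per blood draw, seed recorded in a
#' `#`-prefixed header comment), `truth.csv` (per-patient generating truth)
#' and `config.yaml` (the full cohort configuration) into `dir`.
#'
#' @param cohort An [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rbc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("observations.csv", "truth.csv", "config.yaml"))
  con <- file(paths[1], "w")
  writeLines(sprintf("# seed: %d", cohort$config$seed), con)
  close(con)
  readr::write_csv(cohort$observations, paths[1], append = TRUE,
                   col_names = TRUE)
  readr::write_csv(cohort$patients, paths[2])
  cfg <- cohort$config
  yaml::write_yaml(list(
    n_patients = cfg$n_patients,
    survival = unclass(cfg$survival),
    population = unclass(cfg$population),
    duration_meanlog = cfg$duration_meanlog,
    duration_sdlog = cfg$duration_sdlog,
    min_duration = cfg$min_duration,
    max_followup = cfg$max_followup,
    baseline_window = cfg$baseline_window,
    seed = cfg$seed), paths[3])
  invisible(paths)
}

#' Read a cohort configuration from YAML
#'
#' Inverse of the `config.yaml` written by [write_cohort()]; unknown fields
#' are rejected by the [cohort_config()] validator.
#'
#' @param path YAML file path.
#' @return A [cohort_config()] object.
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_config(
    n_patients = y$n_patients,
    survival = do.call(survival_params, y$survival),
    population = do.call(population_params, y$population),
    duration_meanlog = y$duration_meanlog,
    duration_sdlog = y$duration_sdlog,
    min_duration = y$min_duration %||% 56,
    max_followup = y$max_followup %||% 1826,
    baseline_window = y$baseline_window %||% 28,
    seed = y$seed %||% 20250505)
}
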