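#' Pipeline configuration
#'
#' Bundles the stages of a full analysis run: data source (a
#' [cohort_config()] for simulation mode, or a CSV path for real data),
#' eligibility thresholds, sampler settings, and an optional output
#' directory. Threshold defaults are the study's rules: at least 5 blood
#' counts, baseline MCV at most 98 fL, a 28-day pre-treatment window, and
#' a 30-day continuity gap.
#'
#' @param cohort A [cohort_config()] (simulation mode) or a path to a
#'   canonical CBC CSV (data mode).
#' @param schema Optional schema config for [read_cbc_table()].
#' @param dispensing Optional path to a dispensing CSV (`patient_id,
#'   t_days`) used by [continuous_duration()] in data mode.
#' @param min_cbc,baseline_mcv_max,baseline_window,gap_threshold
#'   Eligibility thresholds; see [apply_eligibility()] and
#'   [continuous_duration()].
#' @param fit A [fit_config()].
#' @param output_dir Optional directory; when given, every artifact
#'   (resolved config, filtered data, summaries, diagnostics, draws) is
#'   written there.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), schema = NULL,
                            dispensing = NULL, min_cbc = 5,
                            baseline_mcv_max = 98, baseline_window = 28,
                            gap_threshold = 30, fit = fit_config(),
                            output_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_config") ||
              (is.character(cohort) && length(cohort) == 1L))
  stopifnot(inherits(fit, "fit_config"))
  structure(list(cohort = cohort, schema = schema, dispensing = dispensing,
                 min_cbc = min_cbc, baseline_mcv_max = baseline_mcv_max,
                 baseline_window = baseline_window,
                 gap_threshold = gap_threshold, fit = fit,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full simulate/load - filter - fit - diagnose - report pipeline
#'
#' Executes every stage in order and aborts with the stage name on
#' failure (persisting partial artifacts when `output_dir` is set). Cohort
#' descriptors in the report are recomputed from the filtered data, never
#' copied from the configuration. In simulation mode the result includes a
#' recovery table juxtaposing the generating truth with the posterior
#' summaries.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `rbc_pipeline`: list with `descriptors`,
#'   `report` (posterior summary table), `recovery` (simulation mode only),
#'   `fit`, `eligibility`, `loo`, `convergence`, and the frozen `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  partial <- list(config = config)
  persist <- function() {
    if (!is.null(out_dir)) {
      saveRDS_safe <- function(obj, nm) {
        if (!is.null(obj) && inherits(obj, "data.frame")) {
          readr::write_csv(obj, file.path(out_dir, paste0(nm, ".csv")))
        }
      }
      saveRDS_safe(partial$records, "filtered_records")
      saveRDS_safe(partial$report, "summaries")
      saveRDS_safe(partial$recovery, "recovery")
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      persist()
      rlang::abort(sprintf("pipeline stage `%s` failed: %s", name,
                           conditionMessage(e)),
                   class = "rbclifespan_pipeline_error")
    })
  }

  simulate_mode <- inherits(config$cohort, "cohort_config")
  cohort <- NULL
  records <- stage("data", {
    if (simulate_mode) {
      cohort <- generate_cohort(config$cohort)
      if (!is.null(out_dir)) write_cohort(cohort, file.path(out_dir, "cohort"))
      cohort$observations
    } else {
      read_cbc_table(config$cohort, schema = config$schema)
    }
  })
  durations <- stage("durations", {
    if (simulate_mode) {
      cohort$patients[, c("patient_id", "duration_days")]
    } else if (!is.null(config$dispensing)) {
      disp <- readr::read_csv(config$dispensing, comment = "#",
                              show_col_types = FALSE, progress = FALSE)
      continuous_duration(disp, records,
                          gap_threshold = config$gap_threshold)
    } else {
      NULL
    }
  })
  elig <- stage("eligibility", apply_eligibility(
    records, durations = durations, min_cbc = config$min_cbc,
    baseline_mcv_max = config$baseline_mcv_max,
    baseline_window = config$baseline_window))
  partial$records <- elig$records

  descriptors <- stage("descriptors", {
    per_pat <- elig$records |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(n_cbc = dplyr::n(), last_t = max(.data$t_days),
                       .groups = "drop")
    dur <- if (!is.null(durations)) {
      durations$duration_days[match(per_pat$patient_id,
                                    durations$patient_id)]
    } else per_pat$last_t
    tibble(n_patients = nrow(per_pat),
           n_records = nrow(elig$records),
           mean_cbc_per_patient = mean(per_pat$n_cbc),
           median_duration_months = median(dur, na.rm = TRUE) /
             DAYS_PER_MONTH,
           n_excluded = nrow(elig$exclusions))
  })

  fit <- stage("fit", {
    model <- build_rbc_model(elig$records)
    fit_rbc_model(model, config$fit)
  })
  report <- stage("report", summarize_posterior(fit))
  partial$report <- report
  loo <- stage("diagnostics", loo_khat(fit))
  convergence <- stage("diagnostics", check_convergence(fit))

  recovery <- NULL
  if (simulate_mode) {
    recovery <- stage("report", {
      cc <- config$cohort
      p <- cc$population
      truth <- c(lifespan = mean_lifespan(cc$survival),
                 mcv_pre = p$mu_mcv_old, mcv_post = p$mu_mcv_new,
                 mcv_delta = p$mu_mcv_new - p$mu_mcv_old,
                 mchc_delta = p$mu_mchc_new - p$mu_mchc_old,
                 rbc_decrease = p$mu_n_old - p$mu_n_new,
                 hgb_delta = derived_hemoglobin(p$mu_n_new, p$mu_mcv_new,
                                                p$mu_mchc_new) -
                   derived_hemoglobin(p$mu_n_old, p$mu_mcv_old,
                                      p$mu_mchc_old))
      rec <- report[match(names(truth), report$quantity), ]
      rec$truth <- unname(truth)
      rec$covered <- rec$truth >= rec$conf.low & rec$truth <= rec$conf.high
      rec[, c("quantity", "unit", "truth", "median", "conf.low",
              "conf.high", "covered")]
    })
  }

  result <- structure(list(
    descriptors = descriptors, report = report, recovery = recovery,
    fit = fit, eligibility = elig, loo = loo, convergence = convergence,
    config = config), class = "rbc_pipeline")

  if (!is.null(out_dir)) {
    stage("write", {
      readr::write_csv(report, file.path(out_dir, "summaries.csv"))
      readr::write_csv(descriptors, file.path(out_dir, "descriptors.csv"))
      readr::write_csv(elig$exclusions, file.path(out_dir, "exclusions.csv"))
      if (!is.null(recovery)) {
        readr::write_csv(recovery, file.path(out_dir, "recovery.csv"))
      }
      draws <- as_tibble(as.data.frame(fit$pooled[
        , intersect(c(POPULATION_PARS, "lifespan"), colnames(fit$pooled))]))
      draws$.chain <- rep(seq_len(fit$config$n_chains),
                          each = fit$config$n_sampling)
      draws$.draw <- rep(seq_len(fit$config$n_sampling),
                         times = fit$config$n_chains)
      readr::write_csv(draws, file.path(out_dir, "draws.csv"))
      jsonlite::write_json(list(
        convergence = as.list(setNames(convergence$value,
                                       convergence$check)),
        convergence_pass = attr(convergence, "pass"),
        loo = list(elpd = loo$elpd, elpd_se = loo$elpd_se,
                   p_loo = loo$p_loo,
                   khat_gt_0_7 = unname(loo$counts["khat_gt_0_7"]),
                   khat_gt_1_0 = unname(loo$counts["khat_gt_1_0"])),
        r_version = R.version.string,
        jags_version = as.character(utils::packageVersion("rjags"))),
        file.path(out_dir, "diagnostics.json"), auto_unbox = TRUE,
        digits = NA)
      yaml::write_yaml(list(
        simulate_mode = simulate_mode,
        min_cbc = config$min_cbc,
        baseline_mcv_max = config$baseline_mcv_max,
        baseline_window = config$baseline_window,
        gap_threshold = config$gap_threshold,
        fit = unclass(config$fit)),
        file.path(out_dir, "pipeline_config.yaml"))
    })
  }
  result
}

#' @export
print.rbc_pipeline <- function(x, ...) {
  d <- x$descriptors
  cat(sprintf(
    "<rbc_pipeline> %d patients (%d records, mean %.1f CBCs/patient), median duration %.1f months\n",
    d$n_patients, d$n_records, d$mean_cbc_per_patient,
    d$median_duration_months))
  ls <- x$report[x$report$quantity == "lifespan", ]
  cat(sprintf("  mean RBC lifespan: %.1f days (95%% CdI %.1f-%.1f)\n",
              ls$median, ls$conf.low, ls$conf.high))
  cat(sprintf("  convergence: %s | khat > 1.0: %d\n",
              if (attr(x$convergence, "pass")) "pass" else "FAIL",
              unname(x$loo$counts["khat_gt_1_0"])))
  invisible(x)
}
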