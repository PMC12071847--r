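CANONICAL_COLUMNS <- c("patient_id", "t_days", "rbc_1e12_per_L", "mcv_fL",
                       "mchc_g_dL")

#' Read a longitudinal complete-blood-count table
#'
#' Reads a CSV export of blood draws into the canonical tidy schema
#' `patient_id, t_days, rbc_1e12_per_L, mcv_fL, mchc_g_dL` (one row per
#' draw; `t_days` counts days from the first CDK4/6-inhibitor dose,
#' negative before treatment). Lines starting with `#` are treated as
#' comments.
#'
#' Time alignment: if the file carries calendar dates instead of day
#' offsets, provide `date` and `first_dose_date` columns (or map them via
#' `schema`) and offsets are computed as `date - first_dose_date` in days.
#'
#' Duplicate `(patient_id, t_days)` rows are resolved by keeping the first
#' occurrence; the number dropped is reported via a message.
#'
#' @param path CSV file path.
#' @param schema Optional schema configuration: a named list (or path to a
#'   YAML file) with an element `columns`, a named character vector mapping
#'   canonical names (names) to the file's column names (values), and
#'   optionally `date_format` (a [base::strptime()] format for date
#'   columns).
#' @return A tibble in the canonical schema, sorted by patient and time.
#' @export
read_cbc_table <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path),
                 class = "rbclifespan_io_error")
  }
  if (is.character(schema) && length(schema) == 1L) {
    schema <- yaml::read_yaml(schema)
  }
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  cols <- schema$columns
  if (!is.null(cols)) {
    cols <- cols[unlist(cols) %in% names(raw)]
    names(raw)[match(unlist(cols), names(raw))] <- names(cols)
  }
  if (!"t_days" %in% names(raw)) {
    if (all(c("date", "first_dose_date") %in% names(raw))) {
      fmt <- schema$date_format %||% "%Y-%m-%d"
      to_date <- function(x) {
        if (inherits(x, "Date")) return(x)
        d <- as.Date(as.character(x), format = fmt)
        if (anyNA(d)) {
          rlang::abort(sprintf("unparseable date(s) at row(s): %s",
                               paste(which(is.na(d)), collapse = ", ")),
                       class = "rbclifespan_schema_error")
        }
        d
      }
      raw$t_days <- as.numeric(to_date(raw$date) - to_date(raw$first_dose_date))
    }
  }
  missing <- setdiff(CANONICAL_COLUMNS, names(raw))
  if (length(missing) > 0) {
    rlang::abort(sprintf("missing required column(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "rbclifespan_schema_error")
  }
  out <- raw[, CANONICAL_COLUMNS]
  for (col in setdiff(CANONICAL_COLUMNS, "patient_id")) {
    vals <- suppressWarnings(as.numeric(out[[col]]))
    if (anyNA(vals) && !all(is.na(out[[col]]) == is.na(vals))) {
      rlang::abort(sprintf("unparseable number(s) in `%s` at row(s): %s", col,
                           paste(which(is.na(vals) & !is.na(out[[col]])),
                                 collapse = ", ")),
                   class = "rbclifespan_schema_error")
    }
    out[[col]] <- vals
  }
  out$patient_id <- as.character(out$patient_id)
  n0 <- nrow(out)
  out <- dplyr::distinct(out, .data$patient_id, .data$t_days,
                         .keep_all = TRUE)
  if (nrow(out) < n0) {
    rlang::inform(sprintf("dropped %d duplicated (patient_id, t_days) row(s); kept first occurrence",
                          n0 - nrow(out)))
  }
  dplyr::arrange(out, .data$patient_id, .data$t_days)
}

#' Continuous treatment duration from dispensing records
#'
#' Treatment is considered continuous until the first gap of
#' `gap_threshold` days or more between consecutive dispensings; the first
#' continuous episode is assumed to end one dispensing cycle
#' (`cycle_length` days) after its last dispensing, since each dispensing
#' covers the following cycle.
#'
#' Patients present in `records` but absent from `dispensing` fall back to
#' the time of their last blood draw, flagged in the `assumed_from_records`
#' column.
#'
#' @param dispensing Tibble with columns `patient_id` and `t_days` (day
#'   offsets of drug dispensings, first dose at 0). May be `NULL`.
#' @param records Optional canonical CBC tibble used for the fallback.
#' @param gap_threshold Days; a gap of at least this length breaks
#'   continuity (default 30).
#' @param cycle_length Days covered by one dispensing (default 28).
#' @return A tibble `patient_id, duration_days, assumed_from_records`.
#' @examples
#' disp <- tibble::tibble(patient_id = "a", t_days = c(0, 28, 70))
#' continuous_duration(disp) # episode ends at 28 + 28 = 56
#' @export
continuous_duration <- function(dispensing, records = NULL,
                                gap_threshold = 30, cycle_length = 28) {
  out <- NULL
  if (!is.null(dispensing) && nrow(dispensing) > 0) {
    stopifnot(all(c("patient_id", "t_days") %in% names(dispensing)))
    out <- dispensing |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::arrange(.data$t_days, .by_group = TRUE) |>
      dplyr::summarise(duration_days = {
        ts <- .data$t_days
        gaps <- diff(ts)
        brk <- which(gaps >= gap_threshold)
        last_in_episode <- if (length(brk) > 0) ts[brk[1]] else ts[length(ts)]
        last_in_episode + cycle_length
      }, .groups = "drop") |>
      dplyr::mutate(assumed_from_records = FALSE)
  }
  if (!is.null(records)) {
    covered <- if (is.null(out)) character() else out$patient_id
    rest <- records |>
      dplyr::filter(!(.data$patient_id %in% covered)) |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(duration_days = max(.data$t_days), .groups = "drop") |>
      dplyr::mutate(assumed_from_records = TRUE)
    if (nrow(rest) > 0) {
      rlang::warn(sprintf(
        "no dispensing information for %d patient(s); using last blood-draw time as treatment end",
        nrow(rest)))
    }
    out <- dplyr::bind_rows(out, rest)
  }
  if (is.null(out)) {
    rlang::abort("provide `dispensing` and/or `records`.",
                 class = "rbclifespan_domain_error")
  }
  dplyr::arrange(out, .data$patient_id)
}

#' Apply the cohort eligibility and windowing rules
#'
#' Reproduces the study's inclusion rules on a canonical CBC table:
#' \enumerate{
#'   \item records are trimmed to the analysis window, from
#'     `baseline_window` days before the first dose to the end of
#'     continuous treatment (per-patient `durations`, or the last draw when
#'     unknown);
#'   \item patients with fewer than `min_cbc` in-window blood counts are
#'     excluded (`insufficient_cbc_count`);
#'   \item patients whose baseline MCV exceeds `baseline_mcv_max` fL are
#'     excluded (`baseline_macrocytosis`); the baseline is the latest draw
#'     at `t <= 0`, falling back to the earliest on-treatment draw within
#'     `baseline_fallback_days` days, else the patient is excluded
#'     (`no_baseline`).
#' }
#' Each excluded patient receives exactly one primary reason, assigned in
#' the order above. The operation is idempotent: re-applying it to its own
#' output changes nothing.
#'
#' @param records Canonical CBC tibble (see [read_cbc_table()]).
#' @param durations Optional tibble `patient_id, duration_days` (e.g. from
#'   [continuous_duration()] or a synthetic cohort's truth table).
#' @param min_cbc Minimum number of in-window blood counts (default 5).
#' @param baseline_mcv_max Exclusion threshold on baseline MCV, fL;
#'   exclusion is strict (`> 98` excluded, `= 98` kept).
#' @param baseline_window Days before first dose kept in the window
#'   (default 28).
#' @param baseline_fallback_days Latest on-treatment day usable as a
#'   baseline surrogate when no pre-treatment draw exists (default 14).
#' @return A list with class `rbc_eligibility`:
#'   \describe{
#'     \item{records}{in-window records of included patients;}
#'     \item{exclusions}{tibble `patient_id, reason`, one row per excluded
#'       patient;}
#'     \item{baseline}{tibble `patient_id, baseline_mcv, baseline_t`.}
#'   }
#' @export
apply_eligibility <- function(records, durations = NULL, min_cbc = 5,
                              baseline_mcv_max = 98, baseline_window = 28,
                              baseline_fallback_days = 14) {
  stopifnot(all(CANONICAL_COLUMNS %in% names(records)))
  records <- dplyr::arrange(records, .data$patient_id, .data$t_days)
  if (!is.null(durations)) {
    stopifnot(all(c("patient_id", "duration_days") %in% names(durations)))
    records <- records |>
      dplyr::left_join(durations[, c("patient_id", "duration_days")],
                       by = "patient_id")
    records$duration_days[is.na(records$duration_days)] <- Inf
  } else {
    records <- records |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::mutate(duration_days = max(.data$t_days)) |>
      dplyr::ungroup()
  }
  inwin <- records |>
    dplyr::filter(.data$t_days >= -baseline_window,
                  .data$t_days <= .data$duration_days) |>
    dplyr::select(-"duration_days")

  per_patient <- inwin |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(df, key) {
      pre <- df$t_days[df$t_days <= 0]
      post <- df$t_days[df$t_days > 0 & df$t_days <= baseline_fallback_days]
      bt <- if (length(pre) > 0) max(pre)
            else if (length(post) > 0) min(post) else NA_real_
      tibble(n_cbc = nrow(df), baseline_t = bt,
             baseline_mcv = if (is.na(bt)) NA_real_
                            else df$mcv_fL[match(bt, df$t_days)])
    }) |>
    dplyr::ungroup()

  per_patient$reason <- dplyr::case_when(
    per_patient$n_cbc < min_cbc ~ "insufficient_cbc_count",
    is.na(per_patient$baseline_t) ~ "no_baseline",
    per_patient$baseline_mcv > baseline_mcv_max ~ "baseline_macrocytosis",
    TRUE ~ NA_character_)
  # patients dropped entirely by the window trim
  gone <- setdiff(unique(records$patient_id), per_patient$patient_id)
  exclusions <- dplyr::bind_rows(
    per_patient |> dplyr::filter(!is.na(.data$reason)) |>
      dplyr::select("patient_id", "reason"),
    tibble(patient_id = gone,
           reason = rep("insufficient_cbc_count", length(gone)))) |>
    dplyr::arrange(.data$patient_id)
  included <- per_patient$patient_id[is.na(per_patient$reason)]
  structure(list(
    records = dplyr::filter(inwin, .data$patient_id %in% included),
    exclusions = exclusions,
    baseline = per_patient[, c("patient_id", "baseline_mcv", "baseline_t")]),
    class = "rbc_eligibility")
}

#' @export
print.rbc_eligibility <- function(x, ...) {
  cat(sprintf("<rbc_eligibility> %d patients included (%d records), %d excluded\n",
              dplyr::n_distinct(x$records$patient_id), nrow(x$records),
              nrow(x$exclusions)))
  if (nrow(x$exclusions) > 0) {
    tab <- table(x$exclusions$reason)
    for (r in names(tab)) cat(sprintf("  %s: %d\n", r, tab[[r]]))
  }
  invisible(x)
}
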