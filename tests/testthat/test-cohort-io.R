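make_records <- function(patient_id, t, mcv = 90, rbc = 4.5, mchc = 33) {
  tibble::tibble(patient_id = patient_id, t_days = t,
                 rbc_1e12_per_L = rbc, mcv_fL = mcv, mchc_g_dL = mchc)
}

test_that("reader enforces the schema and reports missing columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(make_records("a", c(-5, 14))[, -4], path)
  expect_error(read_cbc_table(path), class = "rbclifespan_schema_error",
               regexp = "mcv_fL")
  expect_error(read_cbc_table(file.path(tempdir(), "nope.csv")),
               class = "rbclifespan_io_error")
})

test_that("reader maps columns via a schema config and parses dates", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- tibble::tibble(id = "p1",
                       date = c("2020-01-03", "2020-02-14"),
                       first_dose_date = "2020-01-15",
                       rbc = 4.2, vol = 88, conc = 33.1)
  readr::write_csv(df, path)
  schema <- list(columns = c(patient_id = "id", rbc_1e12_per_L = "rbc",
                             mcv_fL = "vol", mchc_g_dL = "conc"))
  out <- read_cbc_table(path, schema)
  expect_equal(out$t_days, c(-12, 30))
  # a global calendar shift leaves the day offsets (and hence the model
  # inputs) unchanged
  df2 <- df
  df2$date <- as.character(as.Date(df$date) + 100)
  df2$first_dose_date <- as.character(as.Date(df$first_dose_date) + 100)
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df2, path2)
  out2 <- read_cbc_table(path2, schema)
  expect_identical(out$t_days, out2$t_days)
  m1 <- build_rbc_model(out); m2 <- build_rbc_model(out2)
  expect_identical(m1$data, m2$data)
})

test_that("duplicated (patient, time) rows keep the first occurrence", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- make_records(c("a", "a", "a"), c(0, 14, 14), mcv = c(90, 92, 95))
  readr::write_csv(df, path)
  expect_message(out <- read_cbc_table(path), "dropped 1 duplicated")
  expect_equal(nrow(out), 2)
  expect_equal(out$mcv_fL, c(90, 92))
})

test_that("continuous duration follows the 30-day interruption rule", {
  # uninterrupted dispensing: episode runs one cycle past the last pickup
  d1 <- tibble::tibble(patient_id = "a", t_days = c(0, 28, 56))
  expect_equal(continuous_duration(d1)$duration_days, 84)
  # a 42-day gap (>= 30) breaks continuity after day 28
  d2 <- tibble::tibble(patient_id = "b", t_days = c(0, 28, 70))
  expect_equal(continuous_duration(d2)$duration_days, 56)
  # single dispensing covers one cycle
  d3 <- tibble::tibble(patient_id = "c", t_days = 0)
  expect_equal(continuous_duration(d3)$duration_days, 28)
  # missing dispensing info falls back to the last blood draw, flagged
  recs <- make_records("d", c(-7, 14, 100))
  expect_warning(out <- continuous_duration(NULL, records = recs),
                 "no dispensing information")
  expect_equal(out$duration_days, 100)
  expect_true(out$assumed_from_records)
})

test_that("eligibility applies the count, baseline-MCV and window rules", {
  recs <- dplyr::bind_rows(
    make_records("few", c(-5, 14, 28, 42)),                 # 4 draws
    make_records("macro", c(-5, 14, 28, 42, 56), mcv = 99), # high baseline
    make_records("edge", c(-5, 14, 28, 42, 56), mcv = 98),  # boundary
    make_records("ok", c(-10, 14, 28, 42, 56), mcv = 92))
  elig <- apply_eligibility(recs)
  expect_setequal(unique(elig$records$patient_id), c("edge", "ok"))
  expect_equal(elig$exclusions$reason[elig$exclusions$patient_id == "few"],
               "insufficient_cbc_count")
  expect_equal(elig$exclusions$reason[elig$exclusions$patient_id == "macro"],
               "baseline_macrocytosis")
  # accounting: included + excluded = input; one primary reason each
  expect_equal(dplyr::n_distinct(elig$records$patient_id) +
                 nrow(elig$exclusions),
               dplyr::n_distinct(recs$patient_id))
  expect_equal(anyDuplicated(elig$exclusions$patient_id), 0)
})

test_that("records are trimmed to the analysis window", {
  recs <- make_records("a", c(-40, -5, 14, 28, 42, 56, 300))
  dur <- tibble::tibble(patient_id = "a", duration_days = 120)
  elig <- apply_eligibility(recs, durations = dur)
  expect_true(all(elig$records$t_days >= -28))
  expect_true(all(elig$records$t_days <= 120))
  expect_equal(nrow(elig$records), 5)
})

test_that("baseline falls back to an early on-treatment draw", {
  # no pre-treatment draw: day-10 value is used as the baseline surrogate
  ok <- make_records("s1", c(10, 30, 60, 90, 120), mcv = 92)
  expect_equal(nrow(apply_eligibility(ok)$exclusions), 0)
  high <- make_records("s2", c(10, 30, 60, 90, 120), mcv = 101)
  expect_equal(apply_eligibility(high)$exclusions$reason,
               "baseline_macrocytosis")
  # earliest draw after the fallback horizon: no usable baseline
  none <- make_records("s3", c(20, 40, 60, 90, 120), mcv = 92)
  expect_equal(apply_eligibility(none)$exclusions$reason, "no_baseline")
})

test_that("eligibility is idempotent", {
  set.seed(10)
  coh <- generate_cohort(cohort_config(n_patients = 15, seed = 10))
  dur <- coh$patients[, c("patient_id", "duration_days")]
  once <- apply_eligibility(coh$observations, durations = dur)
  twice <- apply_eligibility(once$records, durations = dur)
  expect_identical(as.data.frame(once$records), as.data.frame(twice$records))
  expect_equal(nrow(twice$exclusions), 0)
})
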