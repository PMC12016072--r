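test_that("invalid configurations are rejected naming the field", {
  expect_error(generator_config(mixture_proportion_adherent = 1.5),
               "mixture_proportion_adherent")
  expect_error(generator_config(hosp_rate_adherent = -1), "hosp_rate_adherent")
  expect_error(generator_config(ses_missing_rate = 2), "ses_missing_rate")
  expect_error(generator_config(observation_window = c("2019-01-01", "2017-01-01")),
               "observation_window")
  cfg <- generator_config(n_patients = 10)
  cfg$event_probs$adherent[["hba1c"]] <- 1.2
  expect_error(validate_generator_config(cfg), "event_probs")
})

test_that("identical config and seed give identical tables, different seeds differ", {
  cfg <- generator_config(n_patients = 60, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  for (nm in c("patients", "diagnoses", "events", "hospitalizations", "truth"))
    expect_identical(a[[nm]], b[[nm]])
  c <- generate_cohort(generator_config(n_patients = 60, seed = 12))
  expect_false(identical(a$events, c$events))
})

test_that("planted mixture proportion is recovered within binomial bounds", {
  tb <- generate_cohort(generator_config(n_patients = 900, seed = 3))
  n_adh <- sum(tb$truth$archetype == "adherent")
  # binomial 99% interval around 675
  expect_gt(n_adh, 675 - 35)
  expect_lt(n_adh, 675 + 35)
})

test_that("degenerate mixtures produce single-archetype cohorts", {
  all_adh <- generate_cohort(generator_config(n_patients = 30, seed = 4,
                                              mixture_proportion_adherent = 1))
  expect_true(all(all_adh$truth$archetype == "adherent"))
  all_gaps <- generate_cohort(generator_config(n_patients = 30, seed = 4,
                                               mixture_proportion_adherent = 0))
  expect_true(all(all_gaps$truth$archetype == "gaps"))
})

test_that("zero hospitalization rates emit no primary-diagnosis rows", {
  tb <- generate_cohort(generator_config(n_patients = 30, seed = 5,
                                         hosp_rate_adherent = 0,
                                         hosp_rate_gaps = 0,
                                         hosp_nonprimary_rate = 0))
  expect_identical(nrow(tb$hospitalizations), 0L)
})

test_that("per-quarter HbA1c rate is recovered within 3 standard errors", {
  cfg <- generator_config(n_patients = 5000, seed = 6)
  tb <- generate_cohort(cfg)
  seqs <- encode_cohort(tb$events, tb$patients$patient_id)
  has_h <- matrix(seqs$diagnostics %in% c("H", "HB"), nrow(seqs$diagnostics), 12)
  for (arch in c("adherent", "gaps")) {
    sel <- tb$truth$archetype == arch
    p_hat <- mean(has_h[sel, ])
    p <- cfg$event_probs[[arch]][["hba1c"]]
    se <- sqrt(p * (1 - p) / (sum(sel) * 12))
    expect_lt(abs(p_hat - p), 3 * se)
  }
})

test_that("SES missingness rate is recovered and jointly applied", {
  cfg <- generator_config(n_patients = 5000, seed = 7)
  tb <- generate_cohort(cfg)
  miss <- is.na(tb$patients$education_abitur)
  se <- sqrt(0.16 * 0.84 / 5000)
  expect_lt(abs(mean(miss) - 0.16), 3 * se)
  # the four parental fields are missing jointly
  expect_identical(miss, is.na(tb$patients$university_degree))
  expect_identical(miss, is.na(tb$patients$job_type))
  expect_identical(miss, is.na(tb$patients$unemployed))
})

test_that("every patient has a confirmable diagnosis pattern in the lookback year", {
  tb <- generate_cohort(generator_config(n_patients = 80, seed = 8))
  dx_by <- split(tb$diagnoses, tb$diagnoses$patient_id)
  ok <- vapply(tb$patients$patient_id,
               function(id) confirm_diagnosis(dx_by[[id]], 2016), logical(1))
  expect_true(all(ok))
  # both branches exercised: some inpatient-only, some outpatient pairs
  settings <- vapply(dx_by, function(d) d$setting[1], character(1))
  expect_true(any(settings == "inpatient") && any(settings == "outpatient"))
})

test_that("fixtures round-trip losslessly and writes are deterministic", {
  tb <- generate_cohort(generator_config(n_patients = 25, seed = 9))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture(tb, d1)
  write_fixture(tb, d2)
  back <- read_fixture(d1, truth = TRUE)
  for (nm in c("patients", "diagnoses", "events", "hospitalizations", "truth"))
    expect_identical(back[[nm]], tb[[nm]], info = nm)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
})

test_that("an empty patient set yields header-only CSVs", {
  tb <- generate_cohort(generator_config(n_patients = 1, seed = 10))
  tb$patients <- tb$patients[0, ]
  tb$diagnoses <- tb$diagnoses[0, ]
  tb$events <- tb$events[0, ]
  tb$hospitalizations <- tb$hospitalizations[0, ]
  tb$truth <- tb$truth[0, ]
  d <- withr::local_tempdir()
  write_fixture(tb, d)
  expect_identical(nrow(read_fixture(d)$patients), 0L)
  expect_length(readLines(file.path(d, "events.csv")), 1L)
})

test_that("planted SES coefficients drive archetype membership", {
  # strong positive DMP log-odds -> DMP enrollees more often adherent
  cfg <- generator_config(n_patients = 4000, seed = 12)
  tb <- generate_cohort(cfg)
  adh <- tb$truth$archetype == "adherent"
  p1 <- mean(adh[tb$patients$dmp_enrolled])
  p0 <- mean(adh[!tb$patients$dmp_enrolled])
  expect_gt(p1, p0)
  # marginal proportion still calibrated to the mixture target
  expect_lt(abs(mean(adh) - 0.75), 3 * sqrt(0.75 * 0.25 / 4000))
})
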