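#' Configuration for the synthetic claims generator
#'
#' Builds and validates the parameter set for [generate_cohort()]. The
#' defaults emulate the statistical structure of a published pediatric type 1
#' diabetes claims cohort: a two-archetype mixture (75% broadly
#' guideline-adherent care, 25% care with gaps), archetype-specific
#' per-quarter event probabilities, annual screening probabilities,
#' socioeconomic covariates whose log-odds of adherent-archetype membership
#' follow the reported odds-ratio structure, jointly missing parental
#' socioeconomic data for 16% of patients, and Poisson hospitalization counts
#' (means 1.11 vs 1.54 per 3 years).
#'
#' @param n_patients number of patients to simulate.
#' @param mixture_proportion_adherent marginal probability of the adherent
#'   archetype, in `[0, 1]`. 0 and 1 are allowed as degenerate mixtures.
#' @param event_probs named list with elements `adherent` and `gaps`, each a
#'   named numeric vector with per-quarter Bernoulli probabilities `contact`,
#'   `hba1c` and `strips` (a strips prescription totalling >= 200 units).
#' @param screening_probs named list (`adherent`, `gaps`) of per-year
#'   probabilities `retinopathy`, `cholesterol`, `thyroid`.
#' @param ses_logit_coefficients named numeric vector of log-odds
#'   contributions to adherent-archetype membership for
#'   `birth_year_centered`, `dmp`, `autoimmune`, `abitur`, `unemployed`.
#'   The intercept is calibrated at generation time so the marginal adherent
#'   proportion matches `mixture_proportion_adherent`.
#' @param hosp_rate_adherent,hosp_rate_gaps Poisson means of
#'   diabetes-primary hospitalizations over the 3-year window per archetype.
#' @param hosp_nonprimary_rate Poisson mean of additional hospitalizations
#'   without a diabetes primary diagnosis (exercises the primary-diagnosis
#'   filter downstream).
#' @param ses_missing_rate probability that the four parental socioeconomic
#'   fields (Abitur, university degree, job type, unemployment) are jointly
#'   missing.
#' @param low_quantity_strips_prob probability of an additional small strips
#'   prescription (quantity in 50..199) in a quarter where the >=200 strips
#'   event did not fire, so the threshold filter is exercised.
#' @param hospital_outpatient_fraction fraction of patients planted as
#'   hospital-outpatient cases (contact events in a hospital outpatient
#'   setting in 10 of 12 quarters), exercising the exclusion rule.
#' @param observation_window character vector `c(start, end)` of ISO dates,
#'   quarter-aligned; default 2017-01-01 to 2019-12-31.
#' @param lookback_year calendar year used for diagnosis confirmation.
#' @param birth_year_range integer vector `c(min, max)` of birth years.
#' @param covariate_marginals named list of marginal probabilities for the
#'   demographic and socioeconomic covariates; see defaults.
#' @param seed integer RNG seed; identical config + seed gives byte-identical
#'   output tables.
#' @return a validated list of class `"generator_config"`.
#' @export
generator_config <- function(n_patients = 900L,
                             mixture_proportion_adherent = 0.75,
                             event_probs = list(
                               adherent = c(contact = 0.97, hba1c = 0.85, strips = 0.65),
                               gaps     = c(contact = 0.92, hba1c = 0.35, strips = 0.25)),
                             screening_probs = list(
                               adherent = c(retinopathy = 0.75, cholesterol = 0.70, thyroid = 0.75),
                               gaps     = c(retinopathy = 0.30, cholesterol = 0.30, thyroid = 0.30)),
                             ses_logit_coefficients = c(
                               birth_year_centered = log(0.875),
                               dmp        = log(2.428),
                               autoimmune = log(1.695),
                               abitur     = log(1.387),
                               unemployed = log(0.433)),
                             hosp_rate_adherent = 1.11,
                             hosp_rate_gaps = 1.54,
                             hosp_nonprimary_rate = 0.2,
                             ses_missing_rate = 0.16,
                             low_quantity_strips_prob = 0.05,
                             hospital_outpatient_fraction = 0,
                             observation_window = c("2017-01-01", "2019-12-31"),
                             lookback_year = 2016L,
                             birth_year_range = c(2003L, 2006L),
                             covariate_marginals = list(
                               birth_year = c(`2003` = 0.279, `2004` = 0.274,
                                              `2005` = 0.230, `2006` = 0.217),
                               female = 0.480,
                               dmp = 0.478,
                               autoimmune = 0.142,
                               asthma = 0.092,
                               psychological = 0.306,
                               cardiovascular = 0.104,
                               abitur = 0.449,
                               university = 0.319,
                               job_type = c(unskilled = 0.072, specialist = 0.450,
                                            complex_specialist = 0.195,
                                            highly_complex = 0.283),
                               unemployed = 0.051,
                               migration = 0.059,
                               district = c(large_city = 0.246, urban = 0.474,
                                            rural_agglomeration = 0.141,
                                            sparse = 0.139)),
                             seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              mixture_proportion_adherent = mixture_proportion_adherent,
              event_probs = event_probs,
              screening_probs = screening_probs,
              ses_logit_coefficients = ses_logit_coefficients,
              hosp_rate_adherent = hosp_rate_adherent,
              hosp_rate_gaps = hosp_rate_gaps,
              hosp_nonprimary_rate = hosp_nonprimary_rate,
              ses_missing_rate = ses_missing_rate,
              low_quantity_strips_prob = low_quantity_strips_prob,
              hospital_outpatient_fraction = hospital_outpatient_fraction,
              observation_window = observation_window,
              lookback_year = as.integer(lookback_year),
              birth_year_range = as.integer(birth_year_range),
              covariate_marginals = covariate_marginals,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

config_error <- function(field, msg) {
  stop(sprintf("invalid generator configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

validate_generator_config <- function(cfg) {
  chk_prob <- function(x, field) {
    if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
      config_error(field, "must be a probability in [0, 1]")
  }
  if (!is.finite(cfg$n_patients) || cfg$n_patients < 1L)
    config_error("n_patients", "must be a positive integer")
  chk_prob(cfg$mixture_proportion_adherent, "mixture_proportion_adherent")
  for (arch in c("adherent", "gaps")) {
    ep <- cfg$event_probs[[arch]]
    if (is.null(ep) || !all(c("contact", "hba1c", "strips") %in% names(ep)))
      config_error(paste0("event_probs$", arch),
                   "must name probabilities 'contact', 'hba1c', 'strips'")
    chk_prob(ep, paste0("event_probs$", arch))
    sp <- cfg$screening_probs[[arch]]
    if (is.null(sp) || !all(c("retinopathy", "cholesterol", "thyroid") %in% names(sp)))
      config_error(paste0("screening_probs$", arch),
                   "must name probabilities 'retinopathy', 'cholesterol', 'thyroid'")
    chk_prob(sp, paste0("screening_probs$", arch))
  }
  for (field in c("hosp_rate_adherent", "hosp_rate_gaps", "hosp_nonprimary_rate")) {
    if (!is.numeric(cfg[[field]]) || is.na(cfg[[field]]) || cfg[[field]] < 0)
      config_error(field, "must be a nonnegative Poisson mean")
  }
  chk_prob(cfg$ses_missing_rate, "ses_missing_rate")
  chk_prob(cfg$low_quantity_strips_prob, "low_quantity_strips_prob")
  chk_prob(cfg$hospital_outpatient_fraction, "hospital_outpatient_fraction")
  w <- tryCatch(as_date_strict(cfg$observation_window, "observation_window"),
                error = function(e) config_error("observation_window", conditionMessage(e)))
  if (length(w) != 2L || w[1] > w[2])
    config_error("observation_window", "must be c(start, end) with start <= end")
  if (cfg$birth_year_range[1] > cfg$birth_year_range[2])
    config_error("birth_year_range", "must be c(min, max) with min <= max")
  invisible(cfg)
}

# Random day strictly inside each [start, end] date pair (vectorized).
runif_dates <- function(start, end) {
  start + floor(runif(length(start)) * (as.integer(end - start) + 1L))
}

# Calibrate the archetype-model intercept so that the mean of
# plogis(a + eta) over the realized covariates equals the target mixture
# proportion. Degenerate targets (0, 1) bypass the logistic model.
calibrate_intercept <- function(eta, target) {
  f <- function(a) mean(plogis(a + eta)) - target
  uniroot(f, lower = -30, upper = 30, tol = 1e-10)$root
}

#' Generate a synthetic claims cohort with planted pathway archetypes
#'
#' Simulates the four longitudinal input tables of the pipeline: patient
#' master records, diagnosis records for the lookback year, per-quarter /
#' per-year care events over the observation window, and hospitalization
#' records. Each patient is assigned a latent archetype ("adherent" or
#' "gaps") drawn from a logistic model of their socioeconomic covariates; all
#' event emissions are conditionally independent Bernoulli draws given the
#' archetype, and hospitalization counts are Poisson with archetype-specific
#' means. The latent archetype is returned in a separate `truth` table that
#' the analysis pipeline never consumes.
#'
#' Diagnosis confirmation patterns in the lookback year are planted so both
#' branches of the confirmation rule are exercised: 90% of patients receive
#' two outpatient diagnoses in distinct quarters, 10% a single inpatient
#' diagnosis.
#'
#' @param config a [generator_config()].
#' @return list with data.frames `patients`, `diagnoses`, `events`,
#'   `hospitalizations`, `truth`, plus the `config` used. All dates are ISO
#'   character strings.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  m <- config$covariate_marginals
  window <- as_date_strict(config$observation_window)

  ## --- patient master records ------------------------------------------
  patient_id <- sprintf("P%05d", seq_len(n))
  byr <- as.integer(names(m$birth_year))
  birth_year <- sample(byr, n, replace = TRUE, prob = m$birth_year)
  sex <- ifelse(runif(n) < m$female, "female", "male")
  dmp_enrolled <- runif(n) < m$dmp
  autoimmune <- runif(n) < m$autoimmune
  asthma <- runif(n) < m$asthma
  psychological <- runif(n) < m$psychological
  cardiovascular <- runif(n) < m$cardiovascular
  education_abitur <- runif(n) < m$abitur
  university_degree <- runif(n) < m$university
  job_type <- sample(names(m$job_type), n, replace = TRUE, prob = m$job_type)
  unemployed <- runif(n) < m$unemployed
  migration_history <- runif(n) < m$migration
  district_type <- sample(names(m$district), n, replace = TRUE, prob = m$district)

  ## --- latent archetype from the socioeconomic logistic model ----------
  p_adh <- config$mixture_proportion_adherent
  if (p_adh %in% c(0, 1)) {
    adherent <- rep(p_adh == 1, n)
  } else {
    beta <- config$ses_logit_coefficients
    eta <- beta[["birth_year_centered"]] * (birth_year - mean(birth_year)) +
      beta[["dmp"]] * dmp_enrolled +
      beta[["autoimmune"]] * autoimmune +
      beta[["abitur"]] * education_abitur +
      beta[["unemployed"]] * unemployed
    a <- calibrate_intercept(eta, p_adh)
    adherent <- runif(n) < plogis(a + eta)
  }
  archetype <- ifelse(adherent, "adherent", "gaps")

  ## --- joint missingness of parental SES -------------------------------
  ses_missing <- runif(n) < config$ses_missing_rate
  education_abitur[ses_missing] <- NA
  university_degree[ses_missing] <- NA
  job_type[ses_missing] <- NA
  unemployed[ses_missing] <- NA

  n_ho <- round(config$hospital_outpatient_fraction * n)
  ho_idx <- if (n_ho > 0) sort(sample.int(n, n_ho)) else integer(0)

  patients <- data.frame(
    patient_id = patient_id, birth_year = birth_year, sex = sex,
    dmp_enrolled = dmp_enrolled, autoimmune = autoimmune, asthma = asthma,
    psychological = psychological, cardiovascular = cardiovascular,
    education_abitur = education_abitur, university_degree = university_degree,
    job_type = job_type, unemployed = unemployed,
    migration_history = migration_history, district_type = district_type,
    coverage = "2016-01-01/2019-12-31",
    stringsAsFactors = FALSE)

  truth <- data.frame(patient_id = patient_id, archetype = archetype,
                      stringsAsFactors = FALSE)

  ## --- diagnosis confirmation patterns in the lookback year ------------
  two_outpatient <- runif(n) < 0.90
  yr <- config$lookback_year
  q_start <- as.Date(sprintf("%d-%02d-01", yr, c(1, 4, 7, 10)))
  q_end <- c(q_start[-1] - 1L, as.Date(sprintf("%d-12-31", yr)))
  idx2 <- which(two_outpatient)
  # two distinct quarters per patient
  qpair <- vapply(idx2, function(i) sort(sample.int(4L, 2L)), integer(2))
  dx_out <- data.frame(
    patient_id = rep(patient_id[idx2], each = 2L),
    date = as.character(runif_dates(q_start[as.vector(qpair)],
                                    q_end[as.vector(qpair)])),
    setting = rep("outpatient", 2L * length(idx2)),
    code = rep("E10", 2L * length(idx2)), stringsAsFactors = FALSE)
  idx1 <- which(!two_outpatient)
  dx_in <- data.frame(
    patient_id = patient_id[idx1],
    date = as.character(runif_dates(rep(q_start[1], length(idx1)),
                                    rep(q_end[4], length(idx1)))),
    setting = rep("inpatient", length(idx1)),
    code = rep("E10", length(idx1)), stringsAsFactors = FALSE)
  diagnoses <- rbind(dx_out, dx_in)
  diagnoses <- diagnoses[order(diagnoses$patient_id, diagnoses$date), ]
  rownames(diagnoses) <- NULL

  ## --- care events over the observation window -------------------------
  qt <- build_timeline(window, "quarter")
  yt <- build_timeline(window, "year")
  nq <- nrow(qt)
  ny <- nrow(yt)
  ep <- config$event_probs
  sp <- config$screening_probs
  arch_i <- ifelse(adherent, 1L, 2L)

  emit_quarterly <- function(p_by_arch, code) {
    p <- p_by_arch[arch_i]                       # per-patient probability
    fire <- matrix(runif(n * nq) < rep(p, nq), n, nq)
    hit <- which(fire, arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    data.frame(patient_id = patient_id[hit[, 1]],
               date = as.character(runif_dates(qt$start[hit[, 2]],
                                               qt$end[hit[, 2]] - 1L)),
               event_code = code, quantity = NA_real_,
               setting = "outpatient", stringsAsFactors = FALSE)
  }
  emit_annual <- function(p_by_arch, code) {
    p <- p_by_arch[arch_i]
    fire <- matrix(runif(n * ny) < rep(p, ny), n, ny)
    hit <- which(fire, arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    data.frame(patient_id = patient_id[hit[, 1]],
               date = as.character(runif_dates(yt$start[hit[, 2]],
                                               yt$end[hit[, 2]] - 1L)),
               event_code = code, quantity = NA_real_,
               setting = "outpatient", stringsAsFactors = FALSE)
  }

  ev <- list(
    emit_quarterly(c(ep$adherent[["contact"]], ep$gaps[["contact"]]),
                   "OUTPATIENT_CONTACT"),
    emit_quarterly(c(ep$adherent[["hba1c"]], ep$gaps[["hba1c"]]), "HBA1C"))

  # strips prescriptions: quantity >= 200 when the event fires, occasional
  # small prescription (50..199) otherwise so the threshold is exercised
  p_strips <- c(ep$adherent[["strips"]], ep$gaps[["strips"]])[arch_i]
  fire <- matrix(runif(n * nq) < rep(p_strips, nq), n, nq)
  hit <- which(fire, arr.ind = TRUE)
  if (nrow(hit)) {
    ev <- c(ev, list(data.frame(
      patient_id = patient_id[hit[, 1]],
      date = as.character(runif_dates(qt$start[hit[, 2]], qt$end[hit[, 2]] - 1L)),
      event_code = "STRIPS_RX",
      quantity = sample(seq(200, 600, by = 50), nrow(hit), replace = TRUE),
      setting = "outpatient", stringsAsFactors = FALSE)))
  }
  low <- which(!fire & matrix(runif(n * nq) < config$low_quantity_strips_prob,
                              n, nq), arr.ind = TRUE)
  if (nrow(low)) {
    ev <- c(ev, list(data.frame(
      patient_id = patient_id[low[, 1]],
      date = as.character(runif_dates(qt$start[low[, 2]], qt$end[low[, 2]] - 1L)),
      event_code = "STRIPS_RX",
      quantity = sample(50:199, nrow(low), replace = TRUE),
      setting = "outpatient", stringsAsFactors = FALSE)))
  }

  ev <- c(ev, list(
    emit_annual(c(sp$adherent[["retinopathy"]], sp$gaps[["retinopathy"]]),
                "RETINOPATHY_SCREEN"),
    emit_annual(c(sp$adherent[["cholesterol"]], sp$gaps[["cholesterol"]]),
                "CHOLESTEROL_SCREEN"),
    emit_annual(c(sp$adherent[["thyroid"]], sp$gaps[["thyroid"]]),
                "THYROID_SCREEN")))

  # planted hospital-outpatient patients: contacts in 10 of 12 quarters
  # billed through a hospital outpatient center
  if (length(ho_idx)) {
    hq <- vapply(ho_idx, function(i) sort(sample.int(nq, 10L)), integer(10))
    ev <- c(ev, list(data.frame(
      patient_id = rep(patient_id[ho_idx], each = 10L),
      date = as.character(runif_dates(qt$start[as.vector(hq)],
                                      qt$end[as.vector(hq)] - 1L)),
      event_code = "OUTPATIENT_CONTACT", quantity = NA_real_,
      setting = "hospital_outpatient", stringsAsFactors = FALSE)))
  }

  events <- do.call(rbind, ev[!vapply(ev, is.null, logical(1))])
  events <- events[order(events$patient_id, events$date, events$event_code), ]
  rownames(events) <- NULL

  ## --- hospitalizations -------------------------------------------------
  rate <- ifelse(adherent, config$hosp_rate_adherent, config$hosp_rate_gaps)
  n_hosp <- rpois(n, rate)
  n_other <- rpois(n, config$hosp_nonprimary_rate)
  mk_hosp <- function(counts, primary) {
    who <- rep(seq_len(n), counts)
    if (!length(who)) {
      return(data.frame(patient_id = character(0), date = character(0),
                        primary_t1dm = logical(0), stringsAsFactors = FALSE))
    }
    data.frame(patient_id = patient_id[who],
               date = as.character(runif_dates(rep(window[1], length(who)),
                                               rep(window[2], length(who)))),
               primary_t1dm = primary, stringsAsFactors = FALSE)
  }
  hospitalizations <- rbind(mk_hosp(n_hosp, TRUE), mk_hosp(n_other, FALSE))
  hospitalizations <- hospitalizations[order(hospitalizations$patient_id,
                                             hospitalizations$date), ]
  rownames(hospitalizations) <- NULL

  list(patients = patients, diagnoses = diagnoses, events = events,
       hospitalizations = hospitalizations, truth = truth, config = config)
}

#' Write generated tables to CSV fixtures
#'
#' Writes `patients.csv`, `diagnoses.csv`, `events.csv`,
#' `hospitalizations.csv` and `truth.csv` (generator-only ground truth, never
#' read by the pipeline) plus a `generator_config.json` sidecar recording the
#' configuration and seed.
#'
#' @param tables list as returned by [generate_cohort()].
#' @param directory output directory, created if needed.
#' @return invisibly, named character vector of file paths.
#' @export
write_fixture <- function(tables, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create directory '%s'", directory), call. = FALSE)
  }
  paths <- c()
  for (nm in c("patients", "diagnoses", "events", "hospitalizations", "truth")) {
    path <- file.path(directory, paste0(nm, ".csv"))
    write.csv(tables[[nm]], path, row.names = FALSE, quote = TRUE)
    paths[nm] <- path
  }
  if (!is.null(tables$config)) {
    cfgpath <- file.path(directory, "generator_config.json")
    jsonlite::write_json(unclass(tables$config), cfgpath,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths["config"] <- cfgpath
  }
  invisible(paths)
}

#' Read claims tables from a fixture directory
#'
#' Counterpart of [write_fixture()]; round-trips the generated tables
#' losslessly. The `truth.csv` ground-truth table is only read on request.
#'
#' @param directory directory containing the CSV tables.
#' @param truth whether to also read `truth.csv`.
#' @return list of data.frames.
#' @export
read_fixture <- function(directory, truth = FALSE) {
  rd <- function(nm, classes) {
    path <- file.path(directory, paste0(nm, ".csv"))
    if (!file.exists(path)) stop(sprintf("missing input file '%s'", path), call. = FALSE)
    read.csv(path, stringsAsFactors = FALSE, colClasses = classes)
  }
  out <- list(
    patients = rd("patients", c(
      patient_id = "character", birth_year = "integer", sex = "character",
      dmp_enrolled = "logical", autoimmune = "logical", asthma = "logical",
      psychological = "logical", cardiovascular = "logical",
      education_abitur = "logical", university_degree = "logical",
      job_type = "character", unemployed = "logical",
      migration_history = "logical", district_type = "character",
      coverage = "character")),
    diagnoses = rd("diagnoses", c(patient_id = "character", date = "character",
                                  setting = "character", code = "character")),
    events = rd("events", c(patient_id = "character", date = "character",
                            event_code = "character", quantity = "numeric",
                            setting = "character")),
    hospitalizations = rd("hospitalizations",
                          c(patient_id = "character", date = "character",
                            primary_t1dm = "logical")))
  if (truth) {
    out$truth <- rd("truth", c(patient_id = "character", archetype = "character"))
  }
  out
}
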