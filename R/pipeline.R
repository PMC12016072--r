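#' Pipeline configuration
#'
#' Collects every analysis parameter in one validated object. Inputs are
#' either a directory of CSV tables (`input_dir`) or a synthetic-data
#' generator configuration (`generator`).
#'
#' @param input_dir directory with `patients.csv`, `diagnoses.csv`,
#'   `events.csv`, `hospitalizations.csv`; `NULL` to use the generator.
#' @param generator a [generator_config()] (used when `input_dir` is `NULL`).
#' @param observation_window ISO `c(start, end)`, quarter-aligned.
#' @param lookback_year diagnosis-confirmation year.
#' @param birth_year_range inclusive eligible birth years.
#' @param coverage_span required continuous-insurance span.
#' @param strips_threshold quarterly test-strip quantity threshold
#'   (default 200).
#' @param min_ho_quarters hospital-outpatient exclusion threshold
#'   (default 8 of 12).
#' @param k_min,k_max candidate cluster counts (default 2..10).
#' @param normalization `"observed"` or `"theoretical"` min-max denominator.
#' @param out_dir output directory for the report bundle; `NULL` to skip
#'   writing.
#' @param seed seed overriding the generator's.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input_dir = NULL,
                            generator = generator_config(),
                            observation_window = c("2017-01-01", "2019-12-31"),
                            lookback_year = 2016L,
                            birth_year_range = c(2003L, 2006L),
                            coverage_span = c("2016-01-01", "2019-12-31"),
                            strips_threshold = 200,
                            min_ho_quarters = 8L,
                            k_min = 2L, k_max = 10L,
                            normalization = c("observed", "theoretical"),
                            out_dir = NULL,
                            seed = NULL) {
  normalization <- match.arg(normalization)
  if (strips_threshold <= 0) stop("strips_threshold must be positive", call. = FALSE)
  if (min_ho_quarters <= 0) stop("min_ho_quarters must be positive", call. = FALSE)
  if (k_min < 2L || k_max < k_min) stop("invalid k range", call. = FALSE)
  build_timeline(observation_window, "quarter")  # validates alignment
  if (!is.null(seed) && !is.null(generator)) generator$seed <- as.integer(seed)
  structure(list(input_dir = input_dir, generator = generator,
                 observation_window = observation_window,
                 lookback_year = as.integer(lookback_year),
                 birth_year_range = as.integer(birth_year_range),
                 coverage_span = coverage_span,
                 strips_threshold = strips_threshold,
                 min_ho_quarters = as.integer(min_ho_quarters),
                 k_min = as.integer(k_min), k_max = as.integer(k_max),
                 normalization = normalization,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of the YAML file map one-to-one onto [pipeline_config()]
#' arguments; a `generator:` block maps onto [generator_config()] arguments.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen_args <- y$generator %||% list()
  if (!is.null(gen_args$event_probs))
    gen_args$event_probs <- lapply(gen_args$event_probs, unlist)
  if (!is.null(gen_args$screening_probs))
    gen_args$screening_probs <- lapply(gen_args$screening_probs, unlist)
  if (!is.null(gen_args$ses_logit_coefficients))
    gen_args$ses_logit_coefficients <- unlist(gen_args$ses_logit_coefficients)
  y$generator <- do.call(generator_config, gen_args)
  do.call(pipeline_config, y)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

# rolling polynomial hash (mod 2^31 - 1) of the serialized configuration,
# recorded in the run manifest as a reproducibility fingerprint
config_hash <- function(config) {
  bytes <- utf8ToInt(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                      digits = NA, force = TRUE))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full care-pathway analysis pipeline
#'
#' Orchestrates all stages: data input (synthetic generation or CSV tables),
#' cohort selection, three-dimension state-sequence encoding, per-dimension
#' LCS distances with min-max normalization and pooling, PAM clustering with
#' quality-index selection of the cluster count, cluster orientation and
#' profiling (descriptive table, logistic membership model, hospitalization
#' outcomes), and reporting tables (state distributions, top-10 sequence
#' frequencies). With an `out_dir`, all tables are written as CSV/JSON with a
#' run manifest; figures are written alongside their CSV twins. Re-running
#' with an identical configuration and seed reproduces all non-figure outputs
#' byte-identically.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @return invisibly, the report bundle: a list with `tables`, `cohort`,
#'   `flags`, `attrition`, `sequences`, `distances`, `quality`, `clustering`,
#'   `cluster_labels`, `summary_table`, `membership_model`, `outcomes`,
#'   `state_distributions`, `top_sequences`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))

  tables <- run_stage("input", {
    if (!is.null(config$input_dir)) read_fixture(config$input_dir)
    else generate_cohort(config$generator)
  })

  sel <- run_stage("cohort", select_cohort(
    tables, lookback_year = config$lookback_year,
    birth_year_range = config$birth_year_range,
    coverage_span = config$coverage_span,
    window = config$observation_window,
    min_ho_quarters = config$min_ho_quarters))
  cohort <- sel$cohort
  if (nrow(cohort) < config$k_max + 1L)
    stop(sprintf("pipeline stage 'cohort' failed: only %d patients included",
                 nrow(cohort)), call. = FALSE)

  seqs <- run_stage("sequences", encode_cohort(
    tables$events, cohort$patient_id, config$observation_window,
    config$strips_threshold))

  dists <- run_stage("distance", {
    lapply(seqs, function(s) {
      raw <- pairwise_distances(s)
      minmax_normalize(raw, denominator = config$normalization,
                       sequence_length = ncol(s))
    })
  })
  pooled <- run_stage("distance", pool_distances(dists))

  quality <- run_stage("clustering", select_k(pooled, config$k_min, config$k_max))
  fit <- quality$clusterings[[as.character(quality$recommended_k)]]
  cluster_labels <- run_stage("clustering", {
    if (quality$recommended_k == 2L) orient_clusters(fit$assignment, seqs$diagnostics)
    else factor(fit$assignment)
  })

  summary_table <- run_stage("profiling", summarize_clusters(cohort, cluster_labels))
  membership <- run_stage("profiling", {
    if (nlevels(cluster_labels) == 2L && "adherent" %in% levels(cluster_labels))
      fit_membership_model(cohort, cluster_labels)
    else NULL
  })
  outcomes <- run_stage("profiling", hospitalization_outcomes(
    cohort, tables$hospitalizations, cluster_labels, config$observation_window))

  distributions <- run_stage("reporting", lapply(seqs, state_distribution,
                                                 group = cluster_labels))
  topseq <- run_stage("reporting", lapply(seqs, top_sequences, n = 10))

  manifest <- list(
    package_version = as.character(utils::packageVersion("carepath")),
    r_version = R.version.string,
    seed = config$seed %||% config$generator$seed,
    config_hash = config_hash(config),
    stage_rows = list(
      input_patients = nrow(tables$patients),
      cohort = nrow(cohort),
      attrition = as.list(sel$attrition$removed),
      events = nrow(tables$events),
      hospitalizations = nrow(tables$hospitalizations)),
    recommended_k = quality$recommended_k)

  bundle <- list(tables = tables, cohort = cohort, flags = sel$flags,
                 attrition = sel$attrition, sequences = seqs,
                 distances = dists, pooled = pooled, quality = quality,
                 clustering = fit, cluster_labels = cluster_labels,
                 summary_table = summary_table, membership_model = membership,
                 outcomes = outcomes, state_distributions = distributions,
                 top_sequences = topseq, manifest = manifest,
                 config = config)

  if (!is.null(config$out_dir)) run_stage("output", write_bundle(bundle, config$out_dir))
  invisible(bundle)
}

#' Write a report bundle to disk
#'
#' @param bundle output of [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the output directory.
#' @export
write_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wcsv <- function(x, nm) write.csv(x, file.path(out_dir, nm), row.names = FALSE)
  wcsv(bundle$cohort, "cohort.csv")
  wcsv(bundle$flags, "flags.csv")
  jsonlite::write_json(bundle$attrition, file.path(out_dir, "attrition.json"),
                       auto_unbox = TRUE, digits = NA)
  for (dim in names(bundle$sequences)) {
    wcsv(sequences_long(bundle$sequences[[dim]]),
         sprintf("sequences_%s.csv", dim))
    write_distance_matrix(bundle$distances[[dim]],
                          file.path(out_dir, sprintf("distance_%s.csv", dim)))
    wcsv(bundle$state_distributions[[dim]],
         sprintf("state_distribution_%s.csv", dim))
    wcsv(bundle$top_sequences[[dim]], sprintf("top_sequences_%s.csv", dim))
  }
  write_distance_matrix(bundle$pooled, file.path(out_dir, "distance_pooled.csv"))
  wcsv(bundle$quality$profile, "quality_profile.csv")
  wcsv(data.frame(patient_id = bundle$cohort$patient_id,
                  cluster = as.character(bundle$cluster_labels)),
       "assignments.csv")
  jsonlite::write_json(
    list(k = bundle$clustering$k, medoids = bundle$clustering$medoid_ids,
         total_cost = bundle$clustering$total_cost),
    file.path(out_dir, "medoids.json"), auto_unbox = TRUE, digits = NA)
  wcsv(bundle$summary_table, "table1.csv")
  if (!is.null(bundle$membership_model)) {
    wcsv(bundle$membership_model$estimates, "table2.csv")
  }
  jsonlite::write_json(
    list(outcomes = bundle$outcomes, manifest = bundle$manifest),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  # figures (CSV twins written above); device failures are non-fatal
  for (dim in names(bundle$sequences)) {
    try({
      p <- plot_state_distribution(bundle$state_distributions[[dim]],
                                   title = paste("State distribution:", dim))
      ggplot2::ggsave(file.path(out_dir, sprintf("state_distribution_%s.png", dim)),
                      p, width = 8, height = 5, dpi = 120)
      p2 <- plot_top_sequences(bundle$top_sequences[[dim]],
                               title = paste("Top sequences:", dim))
      ggplot2::ggsave(file.path(out_dir, sprintf("top_sequences_%s.png", dim)),
                      p2, width = 8, height = 5, dpi = 120)
    }, silent = TRUE)
  }
  invisible(out_dir)
}
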