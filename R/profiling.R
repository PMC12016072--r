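#' Orient a two-cluster solution by care content
#'
#' Cluster labels from PAM are arbitrary; the analysis names them post hoc
#' from care content. The cluster whose members have the higher mean number
#' of quarters with an HbA1c measurement (`H` or `HB` diagnostics states) is
#' labeled `"adherent"`, the other `"gaps"`.
#'
#' @param assignment integer cluster vector with exactly 2 clusters.
#' @param diagnostics diagnostics state matrix (patients x 12) in the same
#'   row order.
#' @return factor with levels `c("adherent", "gaps")`.
#' @export
orient_clusters <- function(assignment, diagnostics) {
  lev <- sort(unique(assignment))
  if (length(lev) != 2L)
    stop("cluster orientation is defined for exactly 2 clusters", call. = FALSE)
  hq <- rowSums(matrix(diagnostics %in% c("H", "HB"),
                       nrow(diagnostics), ncol(diagnostics)))
  means <- tapply(hq, assignment, mean)
  adherent <- lev[which.max(means[as.character(lev)])]
  factor(ifelse(assignment == adherent, "adherent", "gaps"),
         levels = c("adherent", "gaps"))
}

prop_pct <- function(x) 100 * mean(x, na.rm = TRUE)

chisq_p <- function(x, g) {
  tab <- table(x, g)
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(NA_real_)
  suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
}

kruskal_p <- function(x, g) {
  if (length(unique(x[!is.na(x)])) < 2L) return(NA_real_)
  kruskal.test(x, g)$p.value
}

#' Cluster-stratified descriptive table
#'
#' Produces a descriptive comparison of the clusters over demographics,
#' comorbidities, parental socioeconomic covariates and missingness. Binary
#' covariates are tested with an (uncorrected) chi-square test, ordered
#' multi-category covariates (year of birth, job type, district type) with a
#' Kruskal-Wallis test. Patients with missing socioeconomic data are retained
#' and reported as their own row. Covariates with a single observed level are
#' skipped with a note instead of a p-value.
#'
#' @param patients cohort patient table.
#' @param cluster factor of cluster labels (e.g. from [orient_clusters()]).
#' @return data.frame with one row per covariate level: overall and
#'   per-cluster percentages, test name and p-value (on the covariate's first
#'   row only).
#' @export
summarize_clusters <- function(patients, cluster) {
  stopifnot(nrow(patients) == length(cluster))
  cluster <- droplevels(as.factor(cluster))
  lev <- levels(cluster)
  rows <- list()
  add <- function(covariate, level, values, test, p) {
    overall <- prop_pct(values)
    per <- vapply(lev, function(cl) prop_pct(values[cluster == cl]), numeric(1))
    rows[[length(rows) + 1L]] <<- data.frame(
      covariate = covariate, level = level, overall_pct = overall,
      rbind(per) , test = test, p_value = p,
      stringsAsFactors = FALSE, row.names = NULL)
  }

  add_binary <- function(covariate, values) {
    ok <- !is.na(values)
    if (length(unique(values[ok])) < 2L) {
      add(covariate, "yes", values, "skipped: single level", NA_real_)
    } else {
      add(covariate, "yes", values,
          "chi_square", chisq_p(values[ok], cluster[ok]))
    }
  }
  add_ordered <- function(covariate, values, levels_order) {
    ranks <- match(values, levels_order)
    p <- kruskal_p(ranks, cluster)
    test <- if (is.na(p)) "skipped: single level" else "kruskal_wallis"
    for (i in seq_along(levels_order)) {
      add(covariate, levels_order[i], values == levels_order[i],
          if (i == 1L) test else "", if (i == 1L) p else NA_real_)
    }
  }

  add_ordered("birth_year", as.character(patients$birth_year),
              as.character(sort(unique(patients$birth_year))))
  add_binary("sex_female", patients$sex == "female")
  add_binary("dmp_enrolled", patients$dmp_enrolled)
  add_binary("autoimmune", patients$autoimmune)
  add_binary("asthma", patients$asthma)
  add_binary("psychological", patients$psychological)
  add_binary("cardiovascular", patients$cardiovascular)
  add_binary("ses_missing", is.na(patients$education_abitur))
  add_binary("education_abitur", patients$education_abitur)
  add_binary("university_degree", patients$university_degree)
  add_ordered("job_type", patients$job_type,
              c("unskilled", "specialist", "complex_specialist", "highly_complex"))
  add_binary("migration_history", patients$migration_history)
  add_binary("unemployed", patients$unemployed)
  add_ordered("district_type", patients$district_type,
              c("large_city", "urban", "rural_agglomeration", "sparse"))

  out <- do.call(rbind, rows)
  names(out)[4:(3 + length(lev))] <- paste0("pct_", lev)
  attr(out, "n_per_cluster") <- table(cluster)
  out
}

#' Logistic regression for cluster membership
#'
#' Fits a maximum-likelihood logistic regression of adherent-cluster
#' membership on mean-centered year of birth, disease-management-program
#' enrollment, autoimmune comorbidity, parental university entrance diploma
#' (Abitur) and parental unemployment. Patients with missing socioeconomic
#' data are excluded (their count is reported). Effects are reported as odds
#' ratios with Wald 95% confidence intervals computed on the log-odds scale
#' and exponentiated.
#'
#' @param patients cohort patient table.
#' @param cluster factor with level `"adherent"` coding the outcome 1.
#' @param predictors character vector of patient-table columns (plus the
#'   derived `birth_year_centered`) to include.
#' @return object of class `"membership_model"`: list with `estimates`
#'   (term, odds_ratio, ci_low, ci_high, p_value), `n_used`,
#'   `excluded_missing_ses`, `converged`.
#' @export
fit_membership_model <- function(patients, cluster,
                                 predictors = c("birth_year_centered",
                                                "dmp_enrolled", "autoimmune",
                                                "education_abitur", "unemployed")) {
  stopifnot(nrow(patients) == length(cluster))
  outcome <- as.factor(cluster) == "adherent"
  df <- patients
  df$birth_year_centered <- NA_real_  # centered on the analysis sample below
  ses_cols <- intersect(c("education_abitur", "university_degree",
                          "job_type", "unemployed"), names(df))
  miss <- Reduce(`|`, lapply(ses_cols, function(cl) is.na(df[[cl]])))
  used <- !miss & !is.na(outcome)
  mf <- df[used, , drop = FALSE]
  mf$birth_year_centered <- mf$birth_year - mean(mf$birth_year)
  mf <- mf[, predictors, drop = FALSE]
  mf$.outcome <- outcome[used]

  fit <- glm(.outcome ~ ., family = binomial(), data = mf)
  est <- coef(summary(fit))
  se <- est[, "Std. Error"]
  converged <- isTRUE(fit$converged) && all(abs(est[, "Estimate"]) < 15) &&
    all(se < 15)
  if (!converged)
    warning("membership model did not converge cleanly (possible separation)",
            call. = FALSE)
  z <- qnorm(0.975)
  estimates <- data.frame(
    term = rownames(est),
    odds_ratio = exp(est[, "Estimate"]),
    ci_low = exp(est[, "Estimate"] - z * se),
    ci_high = exp(est[, "Estimate"] + z * se),
    p_value = est[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(estimates = estimates, n_used = sum(used),
                 excluded_missing_ses = sum(miss), converged = converged,
                 fit = fit),
            class = "membership_model")
}

#' @export
print.membership_model <- function(x, ...) {
  cat(sprintf("logistic membership model: n = %d (%d excluded for missing SES)%s\n",
              x$n_used, x$excluded_missing_ses,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$estimates, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Hospitalization outcomes by cluster
#'
#' Two outcomes over the observation window, restricted to hospitalizations
#' with a diabetes primary diagnosis: a binary indicator of at least one
#' hospitalization (compared between clusters by chi-square test) and the
#' per-patient hospitalization count (compared by Welch t-test). Also reports
#' the ratio of mean counts, second cluster level over first (with the
#' conventional orientation: gaps over adherent).
#'
#' @param patients cohort patient table.
#' @param hospitalizations hospitalization table (`patient_id`, `date`,
#'   `primary_t1dm`).
#' @param cluster factor of cluster labels.
#' @param window observation window; hospitalizations outside it are ignored.
#' @return list with per-cluster proportions and means, test p-values, and
#'   `count_ratio`.
#' @export
hospitalization_outcomes <- function(patients, hospitalizations, cluster,
                                     window = c("2017-01-01", "2019-12-31")) {
  stopifnot(nrow(patients) == length(cluster))
  cluster <- droplevels(as.factor(cluster))
  if (nlevels(cluster) < 2L || any(table(cluster) == 0))
    stop("hospitalization outcomes require at least two nonempty clusters",
         call. = FALSE)
  h <- hospitalizations[hospitalizations$primary_t1dm, , drop = FALSE]
  if (nrow(h)) {
    d <- as_date_strict(h$date, "hospitalization date")
    w <- as_date_strict(window)
    h <- h[d >= w[1] & d <= w[2], , drop = FALSE]
  }
  counts <- table(factor(h$patient_id, levels = patients$patient_id))
  counts <- as.integer(counts)
  any_hosp <- counts >= 1L

  prop <- tapply(any_hosp, cluster, mean)
  mean_count <- tapply(counts, cluster, mean)
  if (all(counts == 0)) {
    return(list(proportion = prop, mean_count = mean_count,
                p_binary = NA_real_, p_count = NA_real_,
                count_ratio = NA_real_,
                note = "no primary-diagnosis hospitalizations observed"))
  }
  p_binary <- chisq_p(any_hosp, cluster)
  p_count <- t.test(counts ~ cluster)$p.value
  lev <- levels(cluster)
  ratio <- unname(mean_count[lev[2]] / mean_count[lev[1]])
  list(proportion = prop, mean_count = mean_count,
       p_binary = p_binary, p_count = p_count, count_ratio = ratio)
}
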