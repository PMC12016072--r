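---
title: "Multidimensional state sequence analysis of care pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidimensional state sequence analysis of care pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The method

`carepath` reconstructs and clusters 3-year care trajectories of pediatric
type 1 diabetes patients from claims-like event tables. The analysis treats
each patient as a bundle of three categorical state sequences:

* **HCP contact** (quarterly, 12 intervals): was there at least one
  diabetes-related outpatient contact in the quarter? States `O` / `N`.
* **Diagnostics** (quarterly, 12 intervals): HbA1c measurement (`H`) and a
  quarterly test-strip supply of at least 200 units (`B`), combined into
  `N`, `H`, `B`, `HB`.
* **Screening** (annual, 3 intervals): retinopathy (`R`), cholesterol (`C`)
  and thyroid (`T`) screening, combined into the 8 presence labels
  `N`, `R`, `C`, `T`, `RC`, `RT`, `CT`, `RCT` (letters always in R, C, T
  order).

The guideline reference against which trajectories are read: an outpatient
contact, an HbA1c measurement and a ≥200-strip supply in every quarter, and
over the 3 years at least two retinopathy-screen years, two thyroid-screen
years and one cholesterol-screen year (`assess_adherence()`).

Pairwise dissimilarity within each dimension is the longest common
subsequence (LCS) distance, `d(x, y) = |x| + |y| − 2·L(x, y)`, where
`L` counts the states occurring in the same order in both sequences without
requiring consecutive positions. Compound states such as `RT` are atomic
symbols: there is no partial credit between overlapping states, because the
unit of comparison is the state, not the underlying event. On fixed-length
sequences this distance is a metric; the test suite verifies the metric
axioms and checks `L` against brute-force subsequence enumeration.

Because the quarterly dimensions have a larger attainable maximum distance
(24) than the annual dimension (6), each raw matrix is min–max normalized
before the three matrices are summed into the pooled matrix on which
clustering operates. Two normalization choices deserve explanation:

* **The minimum is fixed at 0** rather than at the observed minimum
  off-diagonal entry. Subtracting a positive observed minimum would destroy
  the zero diagonal and with it identity of indiscernibles; 0 is the
  theoretical minimum of a dissimilarity, so dividing by the maximum is the
  only min–max variant that keeps the object a dissimilarity matrix.
* **The denominator is the observed maximum** (per matrix, a data-dependent
  rescaling), with `denominator = "theoretical"` available as a sensitivity
  switch that divides by `2 × sequence length` instead. Both variants put
  every dimension on a common `[0, 1]` scale; the observed-max variant is the
  default because the rescaling is defined matrix by matrix.

If a dimension is degenerate (all sequences identical), normalization warns
and returns the zero matrix, which is the additive identity under pooling.

## Clustering and model selection

Patients are partitioned around medoids (`pam_cluster()`) on the pooled
matrix. The implementation is the classic two-phase algorithm, made fully
deterministic: BUILD seeds the medoids greedily (first medoid minimizes total
distance; each next medoid maximizes the cost reduction), then SWAP applies
the single best improving (medoid, non-medoid) exchange repeatedly until no
exchange strictly reduces the total cost. Every tie — in BUILD selection, in
swap choice, and in point assignment — is broken toward the lowest index, so
identical inputs give identical partitions on any platform. A numerical
guard (`1e-12`) prevents floating-point noise from cycling the swap phase.

Like any single-exchange k-medoids search, SWAP terminates in a *local*
optimum of the total-cost landscape. On dissimilarities with recoverable
cluster structure this coincides with the exhaustive-search optimum — the
test suite verifies exact agreement with full medoid-set enumeration on 200
planted-structure instances, and agreement with the reference implementation
in the `cluster` package on the same family. On unstructured random
dissimilarities no single-swap algorithm (including the reference
implementation, which we verified behaves the same way) is guaranteed to
reach the global optimum; for that regime the tests assert what the
algorithm does guarantee: the result is swap-locally optimal, never better
than the exhaustive optimum, and never worse than the BUILD-phase cost.

The number of clusters is scanned over k = 2..10 and three quality indices
are reported for each candidate (`select_k()`):

* **Average silhouette width** (ASW), in `[−1, 1]`, higher better; members
  of singleton clusters contribute 0.
* **Point-biserial correlation**: the Pearson correlation over all unordered
  pairs between distance and the different-cluster indicator, higher better.
* **Hubert's C**: `(S_w − S_min) / (S_max − S_min)`, comparing the sum of
  within-cluster pair distances to the best and worst achievable sums over
  the same number of pairs, in `[0, 1]`, lower better.

The recommended k maximizes ASW (ties toward the smaller k). ASW is the
primary criterion because it is the index conventionally reported with the
final structure; the other two indices are retained in the profile table —
not aggregated, since no principled weighting exists — so that the scan can
also be inspected visually before accepting the recommendation.

Cluster labels from PAM are arbitrary, so a two-cluster solution is oriented
post hoc by care content: the cluster with the higher mean number of
HbA1c quarters is labeled *adherent*, the other *gaps*
(`orient_clusters()`).

## Profiling

`summarize_clusters()` produces the descriptive cluster comparison. Binary
covariates are tested with an uncorrected chi-square test; ordered
multi-category covariates (year of birth, job type, district type) with a
Kruskal–Wallis test; the per-patient hospitalization count with a Welch
t-test. No multiple-testing correction is applied — each test is reported at
the plain 5% level, matching standard practice for descriptive cohort
tables. Patients with missing socioeconomic (SES) data stay in the
clustering and the descriptives (missingness is its own row) and are only
excluded from the regression.

`fit_membership_model()` is a maximum-likelihood logistic regression of
adherent-cluster membership on mean-centered birth year, disease-management-
program (DMP) enrollment, autoimmune comorbidity, parental university
entrance diploma (Abitur), and parental unemployment. Effects are reported
as odds ratios with Wald 95% confidence intervals, computed on the log-odds
scale and exponentiated: the Wald form is the claims-analysis convention and
symmetric on the log scale. Centering uses the analysis sample (after the
missing-SES exclusion); this affects only the intercept. Apparent separation
(non-convergence, or absolute log-odds / standard errors above 15) is
flagged and warned about rather than silently returned.

`hospitalization_outcomes()` compares the two outcome definitions between
clusters — any diabetes-primary hospitalization (chi-square) and the
per-patient count (Welch t-test) — and reports the ratio of mean counts,
gaps over adherent.

## The synthetic-data generator

Real claims data of this kind are restricted, so the package ships a
generator (`generate_cohort()`) whose defaults emulate the statistical
structure of the study population the pipeline was designed for:

* a two-archetype mixture, 75% *adherent* / 25% *gaps*;
* archetype membership drawn from a logistic model of the SES covariates
  with log-odds taken from the published odds-ratio structure (DMP 2.428,
  autoimmune 1.695, Abitur 1.387, unemployment 0.433, birth year 0.875 per
  year). Because a marginal mixture proportion and covariate log-odds
  jointly over-determine the intercept, the intercept is calibrated at
  generation time (by uniroot on the realized covariates) so that the
  marginal adherent share equals the mixture target;
* per-quarter event probabilities per archetype — contact 0.97 / 0.92,
  HbA1c 0.85 / 0.35, ≥200-strip supply 0.65 / 0.25 — and annual screening
  probabilities 0.75/0.70/0.75 vs 0.30 each. These are fixed from the
  reported state-distribution summaries (e.g. HbA1c states in roughly 85% of
  adherent-cluster quarters vs roughly 35%); they are generator defaults,
  not ground truth the pipeline is asked to reproduce exactly;
* covariate marginals from the published cohort description (44.9% Abitur,
  47.8% DMP, 5.1% unemployment, the four-level job-type and district-type
  distributions, birth years 2003–2006);
* jointly missing parental SES (all four fields at once) for 16% of
  patients;
* Poisson diabetes-primary hospitalization counts with 3-year means 1.11
  (adherent) and 1.54 (gaps), plus a small rate (0.2) of non-primary
  hospitalizations so the primary-diagnosis filter is exercised;
* confirmation patterns in the lookback year — two outpatient diagnoses in
  distinct quarters for 90% of patients, one inpatient diagnosis for 10% —
  so both branches of the confirmation rule are exercised; and occasional
  sub-threshold strip prescriptions (quantity 50–199) so the ≥200 threshold
  is exercised;
* optionally, a planted fraction of hospital-outpatient patients (contacts
  billed in the hospital-outpatient setting in 10 of 12 quarters) to
  exercise the exclusion rule.

Events are conditionally independent across quarters and dimensions given
the archetype. This is the simplest structure consistent with the published
near-stationary state distributions, and it is also the generator's main
idealization: it produces **no within-patient temporal autocorrelation, no
seasonality, no care-provider effects, and no billing-code granularity**.
Passing tests therefore demonstrate that the pipeline recovers planted
structure of this kind — they do not demonstrate robustness to the temporal
dependence patterns of real claims. The identical config-plus-seed run is
byte-reproducible; the ground-truth archetype is written to a separate
`truth.csv` that no pipeline stage reads.

## Numerical and design choices

* Calendar quarters are Jan–Mar, Apr–Jun, Jul–Sep, Oct–Dec (German claims
  convention); intervals are half-open `[start, end)`, so a boundary-dated
  event belongs to the later interval.
* Strip quantities are summed within a quarter before the ≥200 threshold:
  total supplied quantity is what matters clinically when prescriptions are
  split.
* HbA1c events count toward the diagnostics state only in the outpatient
  setting (a documented switch point; inpatient measurements are part of the
  admission, not of ambulatory monitoring). Hospital-outpatient contacts
  never satisfy the contact state.
* "Continuously insured" means coverage intervals jointly spanning
  2016-01-01 through 2019-12-31 with no gap of one day or more.
* Diagnosis confirmation takes any two distinct outpatient quarters (not
  necessarily non-adjacent) and any inpatient record.
* The attrition log attributes each excluded patient to the first failing
  rule in the order confirmed diagnosis → age → continuous insurance →
  hospital-outpatient; the final cohort itself is order-invariant because
  the flags are conjunctive.
* Distances are exact integer arithmetic before normalization.
* Identical sequences are collapsed before the LCS dynamic program and the
  matrix expanded afterwards, so cost scales with the number of distinct
  trajectories.

## Problem sizes used in the tests

The end-to-end recovery checks run the full pipeline on the generator's
default study replica, n = 900 with a fixed seed: they require the
recommended k to be 2, adjusted Rand index ≥ 0.8 against the planted
archetypes, the DMP odds ratio inside (1.5, 4.0), and the hospitalization
mean ratio inside (1.2, 1.6). Confidence-interval calibration uses 200
generator replicates at n = 900, fitting the membership model on the planted
labels and requiring 90–99% Wald coverage of every planted coefficient. Rate
recovery uses a single n = 5000 cohort. The oracle suites use sequences of
length ≤ 7 (brute-force LCS), instances with n ≤ 12 (exhaustive medoid
search), and 5–8-point matrices (direct index formulas).

## Known limitations

* The generator's independence structure understates the serial persistence
  of real care patterns (see above).
* PAM is a local search; the package reports the deterministic solution, not
  a certified global optimum (see the clustering section).
* ASW on pooled multichannel distances tends to sit lower than on
  single-channel analyses; the profile table is reported so the scan can be
  judged rather than reduced to one number.
* The membership model fits the reduced predictor set by default; other
  covariates from the descriptive table can be passed through `predictors`,
  but no variable-selection procedure is implied.
* District types are consumed as plain categories; no geographic derivation
  is attempted, and billing-code operationalization is out of scope — the
  event codes are assumed pre-resolved in the input tables.
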