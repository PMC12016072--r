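# carepath

Multidimensional state sequence analysis of pediatric type 1 diabetes care
pathways from health-claims tables.

Children with type 1 diabetes need tightly orchestrated long-term care:
quarterly outpatient contact, quarterly HbA1c measurement, an adequate
supply of blood-glucose test strips, and regular screening for retinopathy,
thyroid disease and hypercholesterolemia. Whether the *same* children fall
short on *several* of these dimensions at once is invisible to
one-dimension-at-a-time analyses. `carepath` answers that question the way a
sequence analyst would: it encodes each patient's 3-year trajectory on three
categorical channels, clusters patients by trajectory similarity, and then
asks which socioeconomic factors predict membership in the less
guideline-adherent cluster and what it costs in hospitalizations. It is
aimed at health-services researchers working with claims-like longitudinal
event tables; because real claims of this kind are access-restricted, the
package includes a calibrated synthetic-data generator so the entire
pipeline is runnable and testable out of the box.

## Method

Each patient is represented on three channels: HCP contact per quarter
(states `O`/`N`), diagnostics per quarter (`N`/`H`/`B`/`HB`: HbA1c and/or a
≥200-unit strip supply), and screening per year (the 8 combinations of
retinopathy `R`, cholesterol `C`, thyroid `T`). Pairwise dissimilarity on a
channel is the longest-common-subsequence distance

    d(x, y) = |x| + |y| − 2·L(x, y),

with `L(x, y)` the length of the longest common (not necessarily contiguous)
subsequence. Each channel's matrix is min–max normalized (division by the
maximum observed entry, minimum fixed at the theoretical 0) and the three
matrices are summed:

    D = Σ_c  D_c / max(D_c).

Patients are partitioned around medoids (deterministic BUILD + SWAP with
lowest-index tie-breaking) on `D`, with the number of clusters selected over
k = 2..10 by average silhouette width and reported alongside point-biserial
correlation and Hubert's C. A two-cluster solution is oriented by care
content (more HbA1c quarters = "adherent"), profiled with chi-square /
Kruskal–Wallis / Welch tests, and modeled with a logistic regression of
adherent-cluster membership (odds ratios, Wald 95% CIs). Hospitalization
outcomes compare the clusters on any diabetes-primary admission and on the
admission count.

## Worked example

```r
library(carepath)

cfg <- pipeline_config(generator = generator_config(n_patients = 900, seed = 1))
bundle <- run_pipeline(cfg)

bundle$quality
#>   k        asw point_biserial huberts_c
#>   2 0.29424365      0.6459690 0.1071667
#>   3 0.11859843      0.4495696 0.2113255
#>   4 0.08685809      0.3396293 0.2551301
#>   ...
#> recommended k (max ASW): 2

table(bundle$cluster_labels)
#> adherent     gaps
#>      666      234

bundle$membership_model
#> logistic membership model: n = 761 (139 excluded for missing SES)
#>                  term odds_ratio ci_low ci_high   p_value
#>           (Intercept)     1.7994 1.3765   2.352 1.723e-05
#>   birth_year_centered     0.8803 0.7577   1.023 9.600e-02
#>      dmp_enrolledTRUE     1.9151 1.3710   2.675 1.386e-04
#>        autoimmuneTRUE     1.7530 1.0808   2.843 2.293e-02
#>  education_abiturTRUE     1.1597 0.8313   1.618 3.831e-01
#>        unemployedTRUE     1.2213 0.5676   2.628 6.091e-01

bundle$outcomes$mean_count
#> adherent     gaps
#>     1.11     1.44
bundle$outcomes$count_ratio
#> [1] 1.29

head(bundle$top_sequences$hcp_contact, 3)
#>                  sequence count percentage cumulative_percentage
#> 1 O-O-O-O-O-O-O-O-O-O-O-O   561  62.333333              62.33333
#> 2 O-O-O-O-O-N-O-O-O-O-O-O    26   2.888889              65.22222
#> 3 N-O-O-O-O-O-O-O-O-O-O-O    21   2.333333              67.55556
```

Reading the output: the quality scan recommends two clusters (ASW 0.29, well
above every k > 2); 666 of 900 synthetic patients land in the
guideline-adherent cluster, close to the planted 75/25 mixture. The
membership model recovers the planted effect directions — disease-management-
program enrollment and autoimmune comorbidity raise the odds of adherent-
cluster membership — and the care-with-gaps cluster averages 1.29× as many
diabetes-primary hospitalizations (planted rates 1.54 vs 1.11 per 3 years).
The most common contact trajectory is an outpatient contact in all 12
quarters. Passing `out_dir` to `pipeline_config()` writes every table
(cohort, flags, attrition, per-dimension sequences and distance matrices,
quality profile, assignments, summary and regression tables, state
distributions, top-10 sequence frequencies) as CSV/JSON plus figures.

A thin command-line wrapper is installed under `inst/cli/`:

```sh
Rscript inst/cli/carepath.R simulate --seed 1 --out data/
Rscript inst/cli/carepath.R run --config cfg.yaml --seed 1 --out results/
```

## Package layout

| Module | Contents |
|---|---|
| `R/generator.R` | synthetic claims generator with planted archetypes (`generator_config`, `generate_cohort`, `write_fixture`, `read_fixture`) |
| `R/cohort.R` | inclusion/exclusion rules and attrition accounting (`confirm_diagnosis`, `age_filter`, `is_continuously_insured`, `flag_hospital_outpatient`, `select_cohort`) |
| `R/sequences.R` | timelines, state alphabets, encoding, guideline adherence (`build_timeline`, `state_alphabet`, `encode_dimension`, `encode_cohort`, `assess_adherence`) |
| `R/distance.R` | LCS distances, normalization, pooling (`lcs_length`, `lcs_distance`, `pairwise_distances`, `minmax_normalize`, `pool_distances`) |
| `R/clustering.R` | deterministic PAM, quality indices, model selection (`pam_cluster`, `average_silhouette_width`, `point_biserial`, `huberts_c`, `select_k`, `adjusted_rand_index`) |
| `R/profiling.R` | cluster descriptives, membership regression, outcomes (`orient_clusters`, `summarize_clusters`, `fit_membership_model`, `hospitalization_outcomes`) |
| `R/report.R`, `R/pipeline.R` | reporting tables and plots, configuration, orchestration (`state_distribution`, `top_sequences`, `pipeline_config`, `run_pipeline`) |

The methods vignette (`vignettes/care-pathway-analysis.Rmd`) documents the
model, the normalization and clustering decisions, what the generator does
and does not emulate, and known limitations.
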