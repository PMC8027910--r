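# trialmatchr

Tools for asking, with electronic health record (EHR) data, how clinical
trial participants differ from the patients who were never enrolled — the
generalizability question. Given OMOP-style relational tables, an
enrollment report (person, trial, status, status date), and registry-style
trial metadata, the package:

1. selects **trial participants** by locating each person's index
   condition occurrence — the trial's condition of focus, or a descendant
   in the concept hierarchy, closest to the earliest trial status date
   within a 365-day window — and applies a prior-year *reassurance
   requirement*;
2. draws **matched nonparticipants** by repeated 1:1 exact matching on the
   triple (index condition code, index calendar year-month, number of
   visits in the prior 365 days), resampled (1000 iterations by default)
   with never-matched participants excluded;
3. screens **covariate balance** per disease domain with the binary
   standardized difference

   d = (p₁ − p₂) / √((p₁(1−p₁) + p₂(1−p₂)) / 2),

   where p₁ is the participant prevalence and p₂ the across-iteration
   mean nonparticipant prevalence, flagging |d| ≥ 0.1;
4. scans **covariate × trial-characteristic associations** among
   participants with χ² / Fisher exact tests, Bonferroni-corrected within
   each disease domain at the two-tailed 0.01 level, with Manhattan-like
   plot output.

A bundled synthetic-data generator (`sim_config()`, `simulate_study()`,
`make_study_preset()`) fabricates linked EHR, enrollment, and
trial-metadata files with known ground truth — configurable covariate
prevalences, enrollment log-odds biases, visit rates, and a multi-level
concept hierarchy — so the full pipeline is testable without access to
protected data.

It is aimed at biomedical informaticians and biostatisticians studying
trial generalizability at institutions where enrollment records are
linkable to an OMOP-style EHR.

## Worked example

```r
library(trialmatchr)

cfg <- sim_config(seed = 42, n_patients = 3000, n_enrollable = 150,
                  n_trials = 20)
sim <- simulate_study(cfg)
sel <- select_participants(sim$store)
str(sel$audit)
#> List of 6
#>  $ persons_screened          : int 150
#>  $ trials_excluded_unmappable: int 1
#>  $ excluded_unmappable_trial : int 11
#>  $ excluded_no_index_code    : int 0
#>  $ excluded_reassurance      : int 0
#>  $ selected                  : int 139
```

Of 150 screened persons, the 11 whose earliest trial had no concept
conversion are excluded with their trial; the remaining 139 all carry a
qualifying index code and pass reassurance (the generator guarantees
both).

```r
mr <- run_resampling(sel$participants, sim$store, n_iterations = 100,
                     seed = 7)
mr
#> <matching_result> 139 participants, 2594 candidate records, 100 iterations
#>   never matched: 24
```

24 participants have no exact-key partner (typically an unusual
prior-year visit count) and drop out, as the never-matched rule
prescribes. Comparing cohorts:

```r
pa <- tibble::tibble(person_id = sel$participants$person_id,
                     index_date = sel$participants$index_date)
ca <- tibble::tibble(person_id = mr$candidates$person_id,
                     index_date = mr$candidates$candidate_index_date)
pm <- extract_covariates(pa, sim$covariate_defs, sim$store)
cm <- extract_covariates(ca, sim$covariate_defs, sim$store)
domains <- assign_domains(dplyr::filter(sim$store$trials, mappable),
                          sim$store, sim$domain_concepts)
cmp <- compare_cohorts(pm, mr, cm, domains,
                       sel$participants[c("person_id", "trial_id")])
head(cmp[order(-abs(cmp$std_diff)), ])
#>   domain       covariate             p_participant p_nonparticipant std_diff_rounded flagged
#> 1 neoplastic   hypertensive disorder        0.171            0.466            -0.667 TRUE
#> 2 inflammatory immunosuppressant med…       0                0.175            -0.651 TRUE
#> 3 neoplastic   lesion of liver              0.286            0.0794            0.554 TRUE
#> ...
```

The generator's default bias profile makes participants healthier, and
the screen recovers it: hypertensive disorder is far rarer among
participants (17.1% vs 46.6%, d = −0.667) while lesion of liver, biased
positive, is more common (28.6% vs 7.9%, d = +0.554). At this small
simulated scale the differences are exaggerated relative to any real
cohort; `make_study_preset()` runs the same machinery at a
202-trial / 1645-participant magnitude.

`run_all(run_config(cfg, n_iterations = 1000, seed = 1), "out/")`
executes every stage and writes per-domain comparison and association
tables, Manhattan plots, and a `manifest.json` with checksums;
`inst/cli/trialmatchr.R` wraps `simulate` and `run-all` for the shell.
The methods vignette (`vignettes/trial-generalizability.Rmd`) documents
the model, parameter conventions, and the generator's scope.

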