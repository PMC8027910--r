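---
title: "Assessing trial generalizability with matched EHR nonparticipants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing trial generalizability with matched EHR nonparticipants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialmatchr)
```

## The problem

A recurring question about clinical trials is how well their results travel
to the patients who were never enrolled. When an institution's trial
enrollment records can be linked to its electronic health record (EHR),
that question becomes empirical: for each trial participant one can draw a
comparable nonparticipant from the same EHR and compare their clinical
profiles covariate by covariate. `trialmatchr` implements that design as a
reusable pipeline over OMOP-style relational tables, together with a
synthetic data generator so that every stage is testable without access to
protected health data.

The pipeline has five analysis stages:

1. **Participant selection.** Each enrolled person is restricted to their
   earliest trial (minimal status date, ties broken by trial id). Their
   record must contain a condition code matching one of the trial's
   conditions of focus — a direct match *or a descendant* in the concept
   hierarchy — within the 365 days up to and including the status date.
   The qualifying code closest to the status date defines the *index
   date*. A *reassurance requirement* then demands the index condition (or
   a descendant) also appear in the year strictly before the index date,
   i.e. in `[index - 365, index - 1]`; persons failing any step are
   excluded and counted in the audit.
2. **Nonparticipant matching.** Candidates are never-enrolled persons with
   the participant's *exact* index condition code (no hierarchy expansion)
   in the participant's index calendar month, passing the same reassurance
   rule at their own candidate index date (the earliest qualifying event
   in that month). Each participant is matched 1:1, exactly, on the triple
   (index condition code, index year-month, number of visits in the prior
   365 days), drawing uniformly at random without replacement; the
   procedure is repeated (1000 iterations by default) and participants
   matched in *no* iteration are excluded.
3. **Covariate extraction.** A person qualifies for a covariate if at
   least one condition or drug event with a concept in the covariate's
   descendant-expanded concept set falls in `[index - 365, index]` (the
   index date counts, unlike the visit-count window). Demographics are age
   at the index date (floored whole years, grouped <18 / 18–64 / ≥65),
   sex, race, and ethnicity.
4. **Balance screening.** For each disease domain the participant
   prevalence is compared with the across-iteration mean nonparticipant
   prevalence using the binary standardized difference
   $d = (p_1 - p_2) / \sqrt{(p_1(1-p_1) + p_2(1-p_2))/2}$, flagged at
   $|d| \ge 0.1$.
5. **Association scan.** Among participants only, every covariate is
   cross-tabulated against every trial characteristic (phase, arms,
   randomization, blinding, intervention model, sponsor, data monitoring
   committee, multisite, enrollment bins, status) within each disease
   domain, tested by χ² or an exact test, with a Bonferroni correction
   *within each domain* at the two-tailed 0.01 level, and displayed as
   Manhattan-like plots.

Disease domains are derived from the concept hierarchy: a trial belongs to
a domain when any of its focus concepts is the domain's anchor concept or
one of its descendants, so domains are not mutually exclusive.

## A worked example

```{r example}
cfg <- sim_config(seed = 42, n_patients = 3000, n_enrollable = 150,
                  n_trials = 20)
sim <- simulate_study(cfg)
sel <- select_participants(sim$store)
str(sel$audit)
```

The audit accounts for every screened person exactly once: persons whose
earliest trial has no concept conversion are excluded with the trial, then
persons with no qualifying code, then reassurance failures.

```{r example-match}
mr <- run_resampling(sel$participants, sim$store, n_iterations = 100,
                     seed = 7)
mr
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
head(cmp[order(-abs(cmp$std_diff)), c("domain", "covariate", "p_participant",
                                      "p_nonparticipant", "std_diff_rounded",
                                      "flagged")])
```

The full pipeline, including the association scan, a manifest with
checksums, and per-domain output files, runs through `run_all()`; the
script `inst/cli/trialmatchr.R` wraps `simulate` and `run-all` for shell
use.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| lookback | 365 d | all clinical windows; covariate and index windows are closed and include the anchor day, visit-count and reassurance windows end at `anchor - 1` |
| `n_iterations` | 1000 | matching resamples; the across-iteration mean is the nonparticipant estimate |
| `flag_threshold` | 0.1 | absolute standardized difference marking substantial imbalance |
| `alpha` | 0.01 | two-tailed family level of the association scan, divided by the number of tested pairings per domain |
| `k_domains` | 4 | domains with the most trials retained for stratified reporting |

Interval conventions follow the window language of the underlying design:
"within the 365 days before and including" is the closed 366-day interval
`[t - 365, t]`; "365 days before, but not including" is `[t - 365, t - 1]`.
Each caller states its endpoints explicitly, and date ties for "closest to
the status date" break deterministically by smallest concept id.

## The synthetic generator: what it emulates and what it does not

`sim_config()` / `simulate_study()` fabricate the three linked sources the
analysis consumes — OMOP-style EHR tables, an enrollment report, and
AACT-like trial metadata — with known ground truth:

* A condition-concept tree (4 roots × branching 3 × depth 3 by default)
  whose roots anchor the disease domains, whose mid-level nodes serve as
  trial focus concepts, and whose leaves anchor condition covariates; drug
  covariates are classes with product descendants. Ancestry is stored as
  an explicit transitive closure, mirroring the OMOP `concept_ancestor`
  table.
* Person-level covariate indicators drawn Bernoulli at configured
  baseline prevalences. Enrollment is selected by weighted sampling
  without replacement with weights $\exp(\sum_j \beta_j x_{ij})$ — a
  logistic selection mechanism with an exact cohort size, so a negative
  log-odds shift $\beta_j$ makes covariate $j$ rarer among participants
  (the "healthier participant" phenomenon) with a controllable effect
  size.
* Forced index and reassurance events for every enrolled person in a
  mappable trial, so selection operates on a non-degenerate cohort whose
  recovery is exactly checkable against ground truth; one trial per
  preset is flagged unmappable to exercise the exclusion rule.
* Background persons that each *echo* one participant's index concept and
  calendar month, with Poisson visit counts at the configured rate, so
  matching strata are populated realistically (ties in integer visit
  counts arise naturally).
* Covariate events dated uniformly in `[anchor - 365, anchor - 1]` and
  anchored at the person's index (or candidate-index) date, so configured
  prevalences are exactly what the extraction stage recovers.

`make_study_preset()` scales this to the magnitude of the motivating
study: 202 trials, 1645 enrollable persons, a 20-fold background
population, and 48 covariates (31 conditions, 17 drug classes) with
background prevalences typical of a tertiary-care population and a mostly
negative bias profile. With a 20× background and exact visit-count
matching, roughly 5–15% of participants find no exact-key partner and are
excluded by the never-matched rule — the same behavior the matched design
produces on real data.

The generator makes **no** claim of clinical realism beyond these
mechanisms: no disease trajectories, no coded-vocabulary realism, no
longitudinal visit patterns, no correlation structure between covariates,
and no dependence of trial characteristics on patient covariates (which is
precisely what makes it a null model for the association scan). Passing
tests on synthetic data therefore demonstrate the correctness of the
pipeline's logic and its statistical calibration under the generator's
assumptions, not fidelity to any particular EHR.

## Numerical and design choices

* **Standardized differences** are computed on the participant prevalence
  versus the across-iteration *mean* nonparticipant prevalence (mean
  count / mean matched-set size), not as a mean of per-iteration
  standardized differences; this is the reading that reproduces published
  balance tables from their printed percentages. Report values round half
  away from zero at 3 decimals. The degenerate case $p_1 = p_2 \in \{0,
  1\}$ is defined as $d = 0$ with a warning.
* **Exact-code candidate matching**: candidates must carry the same
  condition code, not a descendant; the hierarchy is used for index-event
  search, reassurance, and covariate expansion only.
* **Candidate index date within the month**: the earliest qualifying
  event, which is deterministic and order-independent.
* **Sub-seeding**: matching iteration $i$ runs on a stream seeded
  `seed + i`, so single iterations are individually reproducible and
  results are independent of execution order.
* **Never-matched exclusion** is read as "unmatched in every iteration":
  dropping participants who are *ever* unmatched would shrink the cohort
  whenever strata are contended; retained participants simply contribute
  no pair in iterations where their stratum is exhausted.
* **Test selection** in the scan follows the Cochran rule: χ² without
  continuity correction when all expected counts are ≥ 5; otherwise the
  conditional Fisher exact test for 2×2 tables and a seeded Monte-Carlo
  exact p-value (10⁴ resamples) for larger sparse tables. Degenerate
  pairings (a constant covariate or characteristic within a domain) are
  skipped and excluded from the Bonferroni family size. Note that with
  10⁴ resamples the smallest attainable simulated p-value, about 10⁻⁴,
  can exceed a per-domain Bonferroni threshold, so sparse non-2×2
  pairings are conservatively never significant at default settings.
* **Odds ratios** are sample cross-products with a log-scale Wald
  interval and the Haldane 0.5 correction when a cell is zero. Published
  odds ratios from exact-test workflows are sometimes conditional
  maximum-likelihood estimates, which differ slightly (e.g. a printed
  0.14 versus a cross-product 0.148 from the same counts); the package
  reports the cross-product and leaves the estimator choice visible
  rather than guessing.
* **Problem sizes in tests**: unit fixtures use hand-traced 7-person
  stores; calibration and recovery properties run the generator at
  1645 (null, 20 seeds, 100 iterations) and 1000 (recovery, 20 seeds)
  enrollable persons, sizes at which the standardized-difference sampling
  error is a few hundredths and the properties are sharp.

## Known limitations

* Trials defined by multiple simultaneous conditions are not modeled; the
  index condition is a single code.
* The matching key is exact; near-miss visit counts (e.g. 7 vs 8) never
  match, which inflates the never-matched rate when the candidate pool is
  thin.
* The aggregated nonparticipant cohort is a mean over correlated
  iterations, so its effective sample size is smaller than the printed
  `n`; the balance screen inherits that extra Monte-Carlo noise.
* Concept ids are opaque: no particular vocabulary (SNOMED, RxNorm, ...)
  is assumed, only the transitive-closure ancestry contract.
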