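test_that("binary standardized differences reproduce closed-form values", {
  # derived by hand: d = (0.5 - 0) / sqrt((0.25 + 0) / 2) = 0.5 / sqrt(0.125)
  expect_equal(std_diff_binary(0.5, 0.0), 0.5 / sqrt(0.125), tolerance = 1e-12)
  expect_equal(round(std_diff_binary(0.5, 0.0), 5), 1.41421)
  expect_equal(std_diff_binary(0.3, 0.3), 0)
  expect_warning(z <- std_diff_binary(0, 0), "zero pooled variance")
  expect_equal(z, 0)
  expect_warning(o <- std_diff_binary(1, 1), "zero pooled variance")
  expect_equal(o, 0)
})

test_that("std_diff_binary is antisymmetric over a grid of prevalences", {
  p <- seq(0.01, 0.99, by = 0.07)
  grid <- expand.grid(p1 = p, p2 = p)
  expect_equal(std_diff_binary(grid$p1, grid$p2),
               -std_diff_binary(grid$p2, grid$p1), tolerance = 1e-12)
})

test_that("continuous standardized differences follow the pooled-SD formula", {
  expect_equal(std_diff_continuous(0, 1, 0, 1), 0)
  expect_equal(std_diff_continuous(1, 1, 0, 1), 1.0)
  expect_equal(std_diff_continuous(5, 0, 5, 0), 0)
  expect_error(std_diff_continuous(1, 0, 0, 0), "zero pooled spread")
})

test_that("covariate extraction uses the closed 366-day window and the hierarchy", {
  store <- make_tiny_store()
  defs <- tibble::tibble(
    name = c("heart disease", "beta blocking agents"),
    kind = c("condition", "drug_class"),
    concept_id = c(11L, 50L)
  )
  idx <- as.Date("2015-06-15")
  anchors <- tibble::tibble(person_id = c(1L, 5L, 2L), index_date = idx)
  mat <- extract_covariates(anchors, defs, store)

  expect_true(mat["1", "heart disease"])          # event on the index date
  expect_true(mat["1", "beta blocking agents"])   # product under the class
  expect_true(mat["5", "beta blocking agents"])
  # p2's only event, anchored 366 days later, sits just outside the window
  anchors366 <- tibble::tibble(person_id = 2L,
                               index_date = as.Date("2014-06-19") + 366L)
  expect_false(extract_covariates(anchors366, defs, store)[1, "heart disease"])
  anchors365 <- tibble::tibble(person_id = 2L,
                               index_date = as.Date("2014-06-19") + 365L)
  expect_true(extract_covariates(anchors365, defs, store)[1, "heart disease"])

  expect_error(extract_covariates(anchors, transform(defs, kind = "foo"),
                                  store), "unknown covariate kind")
})

test_that("a drug event counts only for drug-class covariates and vice versa", {
  store <- make_tiny_store()
  # concept 11 as a drug_class definition must not match condition events
  defs <- tibble::tibble(name = "misfiled", kind = "drug_class",
                         concept_id = 11L)
  anchors <- tibble::tibble(person_id = 1L, index_date = as.Date("2015-06-15"))
  expect_false(extract_covariates(anchors, defs, store)[1, 1])
})

test_that("demographics floor age at the index date and group as published", {
  idx <- as.Date("2015-06-15")
  person <- tibble::tibble(
    person_id = 1:4,
    birth_date = c(idx - round(18 * 365.25),            # turns 18 today
                   as.Date("1950-06-16"),               # 64 years + 364 days
                   as.Date("1950-06-15"),               # exactly 65
                   as.Date("2005-01-01")),              # child
    sex = c("male", "female", "male", "female"),
    race = c("white", "gibberish_free_text", "black", "unknown"),
    ethnicity = c("hispanic", "not_hispanic", "unknown", "unknown")
  )
  person$race[2] <- "unknown"  # unmapped strings arrive as "unknown"
  anchors <- tibble::tibble(person_id = 1:4, index_date = idx)
  demo <- demographic_covariates(person, anchors)
  expect_equal(demo$age, c(18L, 64L, 65L, 10L))
  expect_equal(as.character(demo$age_group),
               c("18-64", "18-64", ">=65", "<18"))
  ind <- demographic_indicators(demo)
  expect_equal(unname(colSums(ind[, grepl("^age", colnames(ind))])),
               c(1, 2, 1))
  expect_error(
    demographic_covariates(person,
                           tibble::tibble(person_id = 4L,
                                          index_date = as.Date("2004-01-01"))),
    "birth date after index")
})

test_that("compare_cohorts flags at |d| >= 0.1 and reports both arms", {
  sim <- simulate_study(sim_config(seed = 51, n_patients = 2500,
                                   n_enrollable = 120, n_trials = 8))
  store <- sim$store
  sel <- select_participants(store)
  mr <- run_resampling(sel$participants, store, n_iterations = 25, seed = 4)
  pa <- tibble::tibble(person_id = sel$participants$person_id,
                       index_date = sel$participants$index_date)
  ca <- tibble::tibble(person_id = mr$candidates$person_id,
                       index_date = mr$candidates$candidate_index_date)
  pm <- extract_covariates(pa, sim$covariate_defs, store)
  cm <- extract_covariates(ca, sim$covariate_defs, store)
  domains <- assign_domains(store$trials[store$trials$mappable, ], store,
                            sim$domain_concepts)
  cmp <- compare_cohorts(pm, mr, cm, domains,
                         sel$participants[c("person_id", "trial_id")])

  expect_true(all(cmp$flagged == (abs(cmp$std_diff) >= 0.1)))
  expect_equal(cmp$std_diff,
               std_diff_binary(cmp$p_participant, cmp$p_nonparticipant))
  expect_equal(cmp$std_diff_rounded, round_half_up(cmp$std_diff, 3))
  expect_true(all(cmp$p_participant >= 0 & cmp$p_participant <= 1))
  expect_true(all(cmp$p_nonparticipant >= 0 & cmp$p_nonparticipant <= 1))
  # one row per (domain, covariate)
  expect_equal(nrow(cmp),
               dplyr::n_distinct(domains$domain) * ncol(pm))
  # identical prevalences on both sides give an unflagged zero row
  same <- compare_cohorts(pm, mr, cm, domains,
                          sel$participants[c("person_id", "trial_id")],
                          flag_threshold = 2)
  expect_false(any(same$flagged))
})

test_that("report rounding is half-away-from-zero at three decimals", {
  expect_equal(round_half_up(c(0.2265, -0.2265, 0.0005, -0.0005), 3),
               c(0.227, -0.227, 0.001, -0.001))
  expect_equal(round_half_up(2.5, 0), 3)
  expect_equal(round_half_up(-2.5, 0), -3)
})
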