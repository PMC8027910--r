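test_that("build_table cross-tabulates and drops empty levels", {
  cov <- c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  chr <- c("a", "a", "a", "a", "b", "b", "b", "b", "b", "b")
  tab <- build_table(cov, chr)
  expect_equal(unname(tab["TRUE", "a"]), 2)
  expect_equal(unname(tab["FALSE", "b"]), 4)

  # 3-level x 4-level cross gives a 3x4 table
  age <- factor(rep(c("<18", "18-64", ">=65"), 4))
  phase <- factor(rep(1:4, each = 3))
  expect_equal(dim(build_table(age, phase)), c(3L, 4L))

  # a constant covariate collapses to a single row: degenerate, skipped
  const <- build_table(rep(TRUE, 10), chr)
  expect_equal(nrow(const), 1)
  res <- test_table(const)
  expect_equal(res$test_used, "skipped")
  expect_true(is.na(res$p_value))
})

test_that("test selection follows the expected-count rule", {
  balanced <- as.table(matrix(c(10, 10, 10, 10), 2))
  res <- test_table(balanced)
  expect_equal(res$test_used, "chi_square")
  expect_equal(res$p_value, 1.0)

  big <- as.table(matrix(c(50, 50, 50, 50), 2))
  expect_equal(test_table(big)$p_value, 1.0)

  sparse <- as.table(matrix(c(5, 0, 0, 5), 2))
  res2 <- test_table(sparse)
  expect_equal(res2$test_used, "fisher_exact")
  # full enumeration by hand: 2 / choose(10, 5) = 2/252
  expect_equal(res2$p_value, 2 / 252, tolerance = 1e-12)

  wide_sparse <- as.table(matrix(c(4, 0, 1, 3, 2, 2), 2))
  res3 <- test_table(wide_sparse, b = 2000, seed = 11)
  expect_equal(res3$test_used, "fisher_simulated")
  expect_true(res3$p_value > 0 && res3$p_value <= 1)
  # seeded Monte-Carlo p-values reproduce
  expect_equal(test_table(wide_sparse, b = 2000, seed = 11)$p_value,
               res3$p_value)
})

test_that("Bonferroni families use only tested pairings and strict inequality", {
  cells <- tibble::tibble(
    domain = c("d1", "d1", "d1", "d2"),
    covariate = c("c1", "c2", "c3", "c1"),
    characteristic = "phase",
    test_used = c("chi_square", "chi_square", "skipped", "chi_square"),
    p_value = c(0.0003, 0.02, NA, 0.009)
  )
  out <- bonferroni_family(cells, alpha = 0.01)
  expect_equal(out$m_domain, c(2L, 2L, 2L, 1L))
  expect_equal(out$bonferroni_threshold, c(0.005, 0.005, 0.005, 0.01))
  expect_equal(out$significant, c(TRUE, FALSE, FALSE, TRUE))

  # m = 1 gives the uncorrected 0.01 threshold; m = 50 gives 0.0002, and a
  # p of 0.0003 flips from significant (m = 20) to not (m = 50)
  p <- 0.0003
  m50 <- bonferroni_family(tibble::tibble(
    domain = "d", p_value = c(p, rep(0.5, 49))), alpha = 0.01)
  expect_false(m50$significant[1])
  m20 <- bonferroni_family(tibble::tibble(
    domain = "d", p_value = c(p, rep(0.5, 19))), alpha = 0.01)
  expect_true(m20$significant[1])

  # p exactly equal to the threshold is not significant
  edge <- bonferroni_family(tibble::tibble(domain = "d", p_value = 0.01),
                            alpha = 0.01)
  expect_false(edge$significant)

  # increasing m never turns a non-significant cell significant
  for (m in c(1, 2, 5, 10, 40)) {
    fam_small <- bonferroni_family(tibble::tibble(
      domain = "d", p_value = c(p, rep(0.5, m - 1))))
    fam_large <- bonferroni_family(tibble::tibble(
      domain = "d", p_value = c(p, rep(0.5, 4 * m - 1))))
    expect_true(fam_small$significant[1] || !fam_large$significant[1])
  }
})

test_that("odds ratios use the cross product with Haldane fallback", {
  even <- as.table(matrix(c(1, 1, 1, 1), 2))
  expect_equal(odds_ratio_2x2(even)$or, 1.0)

  # counts reported for pediatric inclusion vs industry sponsorship
  tab <- as.table(matrix(c(33, 575, 36, 93), 2))
  res <- odds_ratio_2x2(tab)
  expect_equal(res$or, (33 * 93) / (36 * 575), tolerance = 1e-12)
  expect_equal(round(res$or, 3), 0.148)
  expect_false(res$haldane)
  expect_true(res$ci_lower < res$or && res$or < res$ci_upper)

  diagonal <- as.table(matrix(c(2, 0, 0, 2), 2))
  corrected <- odds_ratio_2x2(diagonal)
  expect_true(corrected$haldane)
  expect_equal(corrected$or, 25.0)  # (2.5 * 2.5) / (0.5 * 0.5)
  expect_error(odds_ratio_2x2(as.table(matrix(c(0, 0, 3, 4), nrow = 2,
                                              byrow = TRUE))),
               "all-zero margin")
})

test_that("the scan tests every pairing within each domain and corrects within it", {
  sim <- simulate_study(sim_config(seed = 61, n_patients = 2500,
                                   n_enrollable = 150, n_trials = 10))
  store <- sim$store
  sel <- select_participants(store)
  domains <- assign_domains(store$trials[store$trials$mappable, ], store,
                            sim$domain_concepts)
  pa <- tibble::tibble(person_id = sel$participants$person_id,
                       index_date = sel$participants$index_date)
  pm <- extract_covariates(pa, sim$covariate_defs, store)
  demo <- demographic_covariates(store$person, pa)
  dat <- dplyr::bind_cols(sel$participants[c("person_id", "trial_id")],
                          demo[c("age_group", "sex")],
                          tibble::as_tibble(pm))
  cells <- scan_associations(
    dat, c("age_group", "sex", colnames(pm)),
    bin_trial(store$trials[store$trials$mappable, ]),
    characteristic_cols = c("phase_group", "randomized", "industry"),
    domains = domains, seed = 17)

  expect_setequal(unique(cells$domain), unique(domains$domain))
  per_domain <- dplyr::count(cells, domain)
  expect_true(all(per_domain$n == (2 + ncol(pm)) * 3))
  tested <- cells[!is.na(cells$p_value), ]
  expect_true(all(tested$bonferroni_threshold ==
                    0.01 / tested$m_domain))
  expect_true(all(tested$significant ==
                    (tested$p_value < tested$bonferroni_threshold)))
  # deterministic under the same seed
  cells2 <- scan_associations(
    dat, c("age_group", "sex", colnames(pm)),
    bin_trial(store$trials[store$trials$mappable, ]),
    characteristic_cols = c("phase_group", "randomized", "industry"),
    domains = domains, seed = 17)
  expect_equal(cells$p_value, cells2$p_value)
})

test_that("manhattan output draws the threshold line and strict significance", {
  cells <- bonferroni_family(tibble::tibble(
    domain = "d",
    covariate = c("a", "b", "c", "d_skip"),
    characteristic = "phase",
    test_used = c("chi_square", "chi_square", "chi_square", "skipped"),
    p_value = c(0.0001, 0.01 / 3, 0.5, NA)))
  out <- manhattan_output(cells)
  expect_equal(nrow(out$data), 3)                 # skipped cell excluded
  expect_equal(unique(out$data$threshold_line),
               -log10(0.01 / 3))
  # covariate "b" sits exactly on the line: not significant
  expect_false(out$data$significant[out$data$covariate == "b"])
  expect_true(out$data$significant[out$data$covariate == "a"])
  expect_s3_class(out$plots$d, "ggplot")
})
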