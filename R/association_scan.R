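# Secondary analysis: covariate x trial-characteristic association tests
# among participants, stratified by disease domain, with a per-domain
# Bonferroni correction and Manhattan-like plot output.

#' Cross-tabulate a covariate against a trial characteristic
#'
#' @param covariate Vector (logical or factor) of covariate levels, one per
#'   participant in the stratum.
#' @param characteristic Vector of trial-characteristic levels, aligned with
#'   `covariate`.
#' @return Integer contingency table with empty levels dropped.
#' @export
build_table <- function(covariate, characteristic) {
  tab <- table(covariate = as.character(covariate),
               characteristic = as.character(characteristic))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  tab
}

is_degenerate_table <- function(tab) {
  length(dim(tab)) != 2 || nrow(tab) < 2 || ncol(tab) < 2 || sum(tab) == 0
}

#' Two-sided conditional Fisher exact p-value for a 2x2 table
#'
#' The hypergeometric-enumeration p-value used by [test_table()] for sparse
#' 2x2 tables.
#'
#' @param tab 2x2 contingency table.
#' @return P-value in `(0, 1]`.
#' @export
fisher_exact_2x2 <- function(tab) {
  stopifnot(length(dim(tab)) == 2, all(dim(tab) == 2))
  fisher.test(tab)$p.value
}

#' Test a contingency table
#'
#' The chi-squared test without continuity correction is the default. When
#' any expected count falls below 5 (the classical Cochran criterion), a
#' 2x2 table switches to the conditional Fisher exact test and a larger
#' table to a Monte-Carlo exact chi-squared p-value with `b` resamples.
#' Degenerate tables (fewer than two populated rows or columns) yield a
#' skip signal rather than a p-value.
#'
#' @param tab Contingency table from [build_table()].
#' @param b Number of Monte-Carlo resamples for larger sparse tables.
#' @param seed Optional seed for the Monte-Carlo draw (reproducibility).
#' @return List with `test_used` (`"chi_square"`, `"fisher_exact"`,
#'   `"fisher_simulated"`, or `"skipped"`) and `p_value` (`NA` when
#'   skipped).
#' @export
test_table <- function(tab, b = 10000L, seed = NULL) {
  if (is_degenerate_table(tab)) {
    return(list(test_used = "skipped", p_value = NA_real_))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    test <- "chi_square"
  } else if (nrow(tab) == 2 && ncol(tab) == 2) {
    p <- fisher_exact_2x2(tab)
    test <- "fisher_exact"
  } else {
    run <- function() suppressWarnings(
      chisq.test(tab, simulate.p.value = TRUE, B = b)$p.value)
    p <- if (is.null(seed)) run() else with_rng(seed, run())
    test <- "fisher_simulated"
  }
  list(test_used = test, p_value = max(min(p, 1), .Machine$double.xmin))
}

#' Odds ratio of a 2x2 table with Wald confidence interval
#'
#' Sample cross-product odds ratio; when any cell is zero the Haldane
#' correction (0.5 added to every cell) is applied and noted in the result.
#'
#' @param tab 2x2 contingency table.
#' @param conf_level Confidence level for the log-scale Wald interval.
#' @return List with `or`, `ci_lower`, `ci_upper`, `haldane` (logical).
#' @export
odds_ratio_2x2 <- function(tab, conf_level = 0.95) {
  stopifnot(length(dim(tab)) == 2, all(dim(tab) == 2))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("odds_ratio_2x2: table has an all-zero margin")
  }
  haldane <- any(tab == 0)
  x <- tab + if (haldane) 0.5 else 0
  or <- (x[1, 1] * x[2, 2]) / (x[1, 2] * x[2, 1])
  se <- sqrt(sum(1 / x))
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(or = unname(or),
       ci_lower = unname(exp(log(or) - z * se)),
       ci_upper = unname(exp(log(or) + z * se)),
       haldane = haldane)
}

#' Apply the per-domain Bonferroni correction
#'
#' Within each domain the threshold is `alpha / m_domain`, where `m_domain`
#' counts only the pairings that produced a p-value (skipped degenerate
#' pairings are excluded). Significance is the strict inequality
#' `p < threshold`.
#'
#' @param cells Tibble of association cells with columns `domain`,
#'   `p_value`.
#' @param alpha Family significance level (default 0.01, two-tailed).
#' @return `cells` with `m_domain`, `bonferroni_threshold`, `neg_log10_p`,
#'   and `significant` columns added.
#' @export
bonferroni_family <- function(cells, alpha = 0.01) {
  cells |>
    mutate(m_domain = sum(!is.na(.data$p_value)), .by = "domain") |>
    mutate(
      bonferroni_threshold = alpha / .data$m_domain,
      neg_log10_p = -log10(.data$p_value),
      significant = !is.na(.data$p_value) &
        .data$p_value < .data$bonferroni_threshold
    )
}

#' Scan covariate x trial-characteristic associations
#'
#' For each disease domain, cross-tabulates every covariate against every
#' trial characteristic over the participants in that domain and tests the
#' pairing with [test_table()]; p-values then receive the per-domain
#' Bonferroni correction via [bonferroni_family()].
#'
#' @param participant_data Tibble with one row per participant: `person_id`,
#'   `trial_id`, the factor covariates to scan (see `covariate_cols`), and
#'   nothing else required.
#' @param covariate_cols Character vector naming the covariate columns of
#'   `participant_data` (logical or factor).
#' @param trial_categorical Output of [bin_trial()].
#' @param characteristic_cols Characteristics to scan (default: all
#'   categorical columns of [bin_trial()] except `trial_id`).
#' @param domains Long tibble (`trial_id`, `domain`).
#' @param alpha Family significance level (default 0.01).
#' @param b Monte-Carlo resamples for sparse non-2x2 tables.
#' @param seed Seed controlling the Monte-Carlo draws.
#' @return Tibble of association cells (`domain`, `covariate`,
#'   `characteristic`, `test_used`, `p_value`, `m_domain`,
#'   `bonferroni_threshold`, `neg_log10_p`, `significant`); skipped
#'   degenerate pairings are retained with `NA` p-values for audit.
#' @export
scan_associations <- function(participant_data, covariate_cols,
                              trial_categorical,
                              characteristic_cols = setdiff(
                                names(trial_categorical), "trial_id"),
                              domains, alpha = 0.01, b = 10000L, seed = 1L) {
  dat <- participant_data |>
    inner_join(trial_categorical, by = "trial_id") |>
    inner_join(domains, by = "trial_id", relationship = "many-to-many")
  cell_seed <- 0L
  cells <- purrr::map_dfr(sort(unique(dat$domain)), function(dom) {
    sub <- dat |> filter(.data$domain == dom)
    purrr::map_dfr(covariate_cols, function(cv) {
      purrr::map_dfr(characteristic_cols, function(ch) {
        tab <- build_table(sub[[cv]], sub[[ch]])
        cell_seed <<- cell_seed + 1L
        res <- test_table(tab, b = b, seed = seed + cell_seed)
        tibble(domain = dom, covariate = cv, characteristic = ch,
               test_used = res$test_used, p_value = res$p_value)
      })
    })
  })
  bonferroni_family(cells, alpha = alpha)
}

#' Manhattan-like plot data and figures
#'
#' Per domain: covariates along the x axis, `-log10(p)` on the y axis, one
#' panel per trial characteristic, and a horizontal dashed line at the
#' Bonferroni threshold. Points exactly on the line are not significant
#' (strict inequality).
#'
#' @param cells Output of [scan_associations()] (or [bonferroni_family()]).
#' @return List with `data` (plot-ready tibble: tested cells only, with
#'   `threshold_line = -log10(bonferroni_threshold)`) and `plots` (named
#'   list of ggplot objects, one per domain).
#' @export
manhattan_output <- function(cells) {
  plot_data <- cells |>
    filter(!is.na(.data$p_value)) |>
    mutate(threshold_line = -log10(.data$bonferroni_threshold))
  plots <- lapply(sort(unique(plot_data$domain)), function(dom) {
    dd <- plot_data |> filter(.data$domain == dom)
    ggplot2::ggplot(dd, ggplot2::aes(x = .data$covariate,
                                     y = .data$neg_log10_p)) +
      ggplot2::geom_point(ggplot2::aes(colour = .data$significant),
                          show.legend = FALSE) +
      ggplot2::geom_hline(ggplot2::aes(yintercept = .data$threshold_line),
                          linetype = "dashed") +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                              `TRUE` = "firebrick")) +
      ggplot2::facet_wrap(~characteristic) +
      ggplot2::labs(title = dom, x = NULL, y = expression(-log[10](italic(p)))) +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                         vjust = 0.5,
                                                         hjust = 1,
                                                         size = 5))
  })
  names(plots) <- sort(unique(plot_data$domain))
  list(data = plot_data, plots = plots)
}
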