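# Covariate extraction with a 365-day inclusive lookback, demographic
# covariates, standardized differences, and the participant-vs-nonparticipant
# balance table stratified by disease domain.

#' Binary covariate extraction
#'
#' A person qualifies for a covariate when at least one event of the
#' covariate's kind (condition or drug) carries a concept in the covariate's
#' concept set - expanded through descendants - dated in the closed interval
#' `[index_date - 365, index_date]` (the index date itself counts).
#'
#' @param anchors Tibble (`person_id`, `index_date`): persons with their
#'   assigned index dates (participants' index dates or candidates' own
#'   candidate index dates).
#' @param definitions Covariate definitions: tibble with `name`, `kind`
#'   (`"condition"` or `"drug_class"`), and `concept_id` (anchor concept;
#'   alternatively `concept_ids` as a list column of sets).
#' @param store A validated `cdm_store`.
#' @return Logical matrix, rows aligned with `anchors` (rownames are person
#'   ids), one column per covariate.
#' @export
extract_covariates <- function(anchors, definitions, store) {
  definitions <- as_tibble(definitions)
  if (!all(definitions$kind %in% c("condition", "drug_class"))) {
    abort(sprintf("unknown covariate kind: %s",
                  paste(setdiff(definitions$kind,
                                c("condition", "drug_class")), collapse = ", ")))
  }
  sets <- if ("concept_ids" %in% names(definitions)) {
    definitions$concept_ids
  } else {
    as.list(definitions$concept_id)
  }
  # expand each covariate's concept set through the hierarchy once
  concept_map <- purrr::map_dfr(seq_len(nrow(definitions)), function(i) {
    tibble(covariate = definitions$name[i],
           kind = definitions$kind[i],
           concept_id = expand_concepts(sets[[i]], store$concept_ancestor))
  })
  events <- dplyr::bind_rows(
    store$condition_occurrence |> mutate(event_kind = "condition"),
    store$drug_exposure |> mutate(event_kind = "drug_class")
  )
  hits <- events |>
    inner_join(anchors, by = "person_id", relationship = "many-to-many") |>
    inner_join(concept_map, by = "concept_id",
               relationship = "many-to-many") |>
    filter(.data$event_kind == .data$kind,
           .data$event_date >= .data$index_date - 365L,
           .data$event_date <= .data$index_date) |>
    dplyr::distinct(.data$person_id, .data$index_date, .data$covariate)

  mat <- matrix(FALSE, nrow(anchors), nrow(definitions),
                dimnames = list(anchors$person_id, definitions$name))
  if (nrow(hits) > 0) {
    anchor_key <- paste(anchors$person_id, anchors$index_date)
    row_idx <- match(paste(hits$person_id, hits$index_date), anchor_key)
    col_idx <- match(hits$covariate, definitions$name)
    mat[cbind(row_idx, col_idx)] <- TRUE
  }
  mat
}

#' Demographic covariates at the index date
#'
#' Age is floored whole years at the index date and grouped `<18`, `18-64`,
#' `>=65`; sex, race, and ethnicity pass through as the reporting
#' categories (including "unknown").
#'
#' @param person The person table (or the subset of interest).
#' @param anchors Tibble (`person_id`, `index_date`).
#' @return Tibble with `person_id`, `index_date`, `age`, `age_group`, `sex`,
#'   `race`, `ethnicity`.
#' @export
demographic_covariates <- function(person, anchors) {
  dat <- anchors |>
    inner_join(person, by = "person_id")
  if (any(dat$birth_date > dat$index_date)) {
    abort("demographic_covariates: birth date after index date")
  }
  dat |>
    mutate(
      age = floor_age(.data$birth_date, .data$index_date),
      age_group = factor(dplyr::case_when(
        .data$age < 18 ~ "<18",
        .data$age <= 64 ~ "18-64",
        .default = ">=65"
      ), levels = c("<18", "18-64", ">=65")),
      sex = factor(.data$sex, levels = SEX_CODES),
      race = factor(.data$race, levels = RACE_CODES),
      ethnicity = factor(.data$ethnicity, levels = ETHNICITY_CODES)
    ) |>
    dplyr::select("person_id", "index_date", "age", "age_group", "sex",
                  "race", "ethnicity")
}

#' Expand demographics to binary indicator columns
#'
#' One indicator per reporting row: the three age groups, both sexes, the
#' four race categories, and the three ethnicity categories.
#'
#' @param demographics Output of [demographic_covariates()].
#' @return Logical matrix with one row per person-anchor.
#' @export
demographic_indicators <- function(demographics) {
  lvl <- function(f, prefix) {
    m <- vapply(levels(f), function(l) f == l, logical(length(f)))
    if (is.null(dim(m))) m <- matrix(m, nrow = length(f))
    colnames(m) <- paste0(prefix, ": ", levels(f))
    m
  }
  out <- cbind(
    lvl(demographics$age_group, "age"),
    lvl(demographics$sex, "sex"),
    lvl(demographics$race, "race"),
    lvl(demographics$ethnicity, "ethnicity")
  )
  rownames(out) <- demographics$person_id
  out
}

#' Standardized difference for a binary covariate
#'
#' `d = (p1 - p2) / sqrt((p1 (1 - p1) + p2 (1 - p2)) / 2)`. Antisymmetric in
#' its arguments and zero when the prevalences agree; the degenerate case
#' `p1 = p2` with both 0 or both 1 (zero pooled variance) is defined as 0
#' with a warning.
#'
#' @param p1,p2 Proportions in `[0, 1]` (vectorised).
#' @return Numeric vector of standardized differences.
#' @export
std_diff_binary <- function(p1, p2) {
  stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1))
  pooled <- (p1 * (1 - p1) + p2 * (1 - p2)) / 2
  zero <- pooled == 0 & p1 == p2
  if (any(zero)) {
    warn("std_diff_binary: zero pooled variance; standardized difference set to 0")
  }
  ifelse(zero, 0, (p1 - p2) / sqrt(pooled))
}

#' Standardized difference for a continuous covariate
#'
#' `d = (m1 - m2) / sqrt((s1^2 + s2^2) / 2)`; zero when both spreads vanish
#' with equal means, an error when they vanish with different means.
#'
#' @param m1,s1 Mean and standard deviation in group 1.
#' @param m2,s2 Mean and standard deviation in group 2.
#' @return Numeric scalar.
#' @export
std_diff_continuous <- function(m1, s1, m2, s2) {
  stopifnot(s1 >= 0, s2 >= 0)
  pooled <- (s1^2 + s2^2) / 2
  if (pooled == 0) {
    if (m1 == m2) return(0)
    abort("std_diff_continuous: zero pooled spread with unequal means")
  }
  (m1 - m2) / sqrt(pooled)
}

#' Participant vs nonparticipant balance table
#'
#' One row per (domain, covariate): the participant prevalence in the
#' domain's participant stratum against the across-iteration mean
#' nonparticipant prevalence from [aggregate_counts()], with the
#' standardized difference and the imbalance flag at `|d| >= 0.1`.
#'
#' @param participant_covariates Logical matrix (participants x covariates;
#'   rownames are person ids).
#' @param result A `matching_result` for those participants (persons never
#'   matched are dropped from both arms).
#' @param candidate_covariates Logical matrix aligned with
#'   `result$candidates`, same columns as `participant_covariates`.
#' @param domains Named list: domain label -> trial ids, or a long tibble
#'   (`trial_id`, `domain`); combined with the participants' trials to form
#'   strata.
#' @param participant_trials Tibble (`person_id`, `trial_id`) giving each
#'   participant's trial.
#' @param flag_threshold Absolute standardized-difference cutoff
#'   (default 0.1).
#' @return Tibble of comparison rows sorted by domain then covariate.
#' @export
compare_cohorts <- function(participant_covariates, result,
                            candidate_covariates, domains,
                            participant_trials, flag_threshold = 0.1) {
  stopifnot(identical(colnames(participant_covariates),
                      colnames(candidate_covariates)))
  if (!is.data.frame(domains)) {
    domains <- purrr::imap_dfr(domains, ~ tibble(trial_id = .x, domain = .y))
  }
  retained <- setdiff(result$participants$person_id, result$never_matched)
  strata <- participant_trials |>
    inner_join(domains, by = "trial_id", relationship = "many-to-many") |>
    filter(.data$person_id %in% retained)

  purrr::map_dfr(sort(unique(strata$domain)), function(dom) {
    ids <- strata$person_id[strata$domain == dom]
    pmat <- participant_covariates[
      rownames(participant_covariates) %in% as.character(ids), , drop = FALSE]
    agg <- aggregate_counts(result, candidate_covariates,
                            participant_subset = ids)
    p1 <- colMeans(pmat)
    p2 <- setNames(agg$prevalence, agg$covariate)[names(p1)]
    # a covariate absent from both arms is a well-defined zero row here
    d <- withCallingHandlers(
      std_diff_binary(p1, p2),
      warning = function(w) {
        if (grepl("zero pooled variance", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    tibble(
      domain = dom,
      covariate = names(p1),
      n_participants = nrow(pmat),
      p_participant = unname(p1),
      mean_n_nonparticipant = attr(agg, "mean_matched_n"),
      p_nonparticipant = unname(p2),
      std_diff = unname(d),
      std_diff_rounded = round_half_up(unname(d), 3),
      flagged = abs(unname(d)) >= flag_threshold
    )
  }) |>
    arrange(.data$domain, .data$covariate)
}
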