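# Nonparticipant candidate pools and 1:1 exact matching with resampling.
# The matching stratum is the exact triple (index condition code, calendar
# year-month of the index date, number of visits in the prior 365 days);
# within an iteration a nonparticipant can partner at most one participant.

#' Count healthcare visits in the year before an index date
#'
#' Visits dated in the closed interval `[index_date - 365, index_date - 1]`;
#' a visit on the index date itself is not counted ("before the index
#' date"), unlike the covariate window which includes it.
#'
#' @param visits Data frame of one person's visits (`visit_date`).
#' @param index_date Anchor date.
#' @return Nonnegative integer.
#' @export
prior_visit_count <- function(visits, index_date) {
  sum(visits$visit_date >= index_date - 365L &
        visits$visit_date <= index_date - 1L)
}

# Vectorised prior-year visit counts for many (person, date) anchors.
prior_visit_counts <- function(visit_occurrence, anchors) {
  joined <- visit_occurrence |>
    inner_join(anchors, by = "person_id", relationship = "many-to-many") |>
    filter(.data$visit_date >= .data$anchor_date - 365L,
           .data$visit_date <= .data$anchor_date - 1L) |>
    count(.data$person_id, .data$anchor_date, name = "prior_visits")
  anchors |>
    left_join(joined, by = c("person_id", "anchor_date")) |>
    mutate(prior_visits = dplyr::coalesce(.data$prior_visits, 0L))
}

#' Build the candidate pool for one participant
#'
#' Candidates are persons with no enrollment record of any kind who carry
#' the participant's exact index condition code (no hierarchy expansion)
#' dated in the participant's index calendar month. The candidate index date
#' is the earliest such event in that month; the prior-year reassurance
#' requirement must hold at that date, and the candidate's match key (visit
#' count included) is computed from the candidate's own dates.
#'
#' @param participant One row of the participant table from
#'   [select_participants()].
#' @param store A validated `cdm_store`.
#' @return Tibble of candidate records (`person_id`, `candidate_index_date`,
#'   `index_concept_id`, `index_year_month`, `prior_visits`).
#' @export
build_candidate_pool <- function(participant, store) {
  pools <- build_candidate_pools(
    tibble(index_concept_id = participant$index_concept_id,
           index_date = participant$index_date),
    store)
  pools |>
    filter(.data$index_concept_id == participant$index_concept_id,
           .data$index_year_month == year_month(participant$index_date))
}

#' Build candidate pools for all participant strata
#'
#' One pool per distinct (index concept, index year-month) pair; see
#' [build_candidate_pool()] for the candidate definition.
#'
#' @param participants Participant table (needs `index_concept_id`,
#'   `index_date`).
#' @param store A validated `cdm_store`.
#' @return Tibble of candidate records across all strata.
#' @export
build_candidate_pools <- function(participants, store) {
  strata <- tibble(
    index_concept_id = participants$index_concept_id,
    index_year_month = year_month(participants$index_date)
  ) |> dplyr::distinct()
  enrolled_ids <- unique(store$enrollment$person_id)

  cand_events <- store$condition_occurrence |>
    filter(!(.data$person_id %in% enrolled_ids)) |>
    mutate(index_year_month = year_month(.data$event_date)) |>
    inner_join(strata,
               by = c("concept_id" = "index_concept_id", "index_year_month")) |>
    arrange(.data$person_id, .data$concept_id, .data$event_date) |>
    dplyr::slice(1, .by = c("person_id", "concept_id", "index_year_month")) |>
    transmute(.data$person_id, index_concept_id = .data$concept_id,
              .data$index_year_month, candidate_index_date = .data$event_date)
  if (nrow(cand_events) == 0) {
    return(tibble(person_id = integer(), candidate_index_date = as.Date(character()),
                  index_concept_id = integer(), index_year_month = character(),
                  prior_visits = integer()))
  }

  # reassurance at the candidate's own index date
  reass_map <- tibble(index_concept_id = unique(cand_events$index_concept_id)) |>
    dplyr::reframe(
      concept_id = descendants_of(.data$index_concept_id[1],
                                  store$concept_ancestor),
      .by = "index_concept_id")
  reassured <- store$condition_occurrence |>
    inner_join(cand_events[c("person_id", "index_concept_id",
                             "candidate_index_date")],
               by = "person_id", relationship = "many-to-many") |>
    semi_join(reass_map, by = c("index_concept_id", "concept_id")) |>
    filter(.data$event_date >= .data$candidate_index_date - 365L,
           .data$event_date <= .data$candidate_index_date - 1L) |>
    dplyr::distinct(.data$person_id, .data$index_concept_id,
                    .data$candidate_index_date)
  cand <- cand_events |>
    semi_join(reassured,
              by = c("person_id", "index_concept_id", "candidate_index_date"))

  counts <- prior_visit_counts(
    store$visit_occurrence,
    cand |> dplyr::distinct(.data$person_id,
                            anchor_date = .data$candidate_index_date))
  cand |>
    left_join(counts, by = c("person_id",
                             "candidate_index_date" = "anchor_date")) |>
    mutate(prior_visits = dplyr::coalesce(.data$prior_visits, 0L)) |>
    arrange(.data$person_id, .data$index_concept_id, .data$candidate_index_date)
}

# Internal: assemble the matching problem. Returns participant match keys,
# the candidate table, and for each participant the integer indices of
# key-compatible candidate rows.
build_matching_problem <- function(participants, store) {
  part_counts <- prior_visit_counts(
    store$visit_occurrence,
    tibble(person_id = participants$person_id,
           anchor_date = participants$index_date))
  part <- participants |>
    mutate(index_year_month = year_month(.data$index_date)) |>
    left_join(part_counts, by = c("person_id", "index_date" = "anchor_date"))
  cand <- build_candidate_pools(part, store)
  key <- function(concept, ym, visits) paste(concept, ym, visits, sep = "|")
  cand_key <- key(cand$index_concept_id, cand$index_year_month,
                  cand$prior_visits)
  part_key <- key(part$index_concept_id, part$index_year_month,
                  part$prior_visits)
  by_key <- split(seq_along(cand_key), cand_key)
  pools <- lapply(part_key, function(k) {
    p <- by_key[[k]]
    if (is.null(p)) integer() else p
  })
  list(participants = part, candidates = cand, pools = pools)
}

#' One matching iteration
#'
#' Participants are processed in random order; each draws uniformly at
#' random one unused candidate whose match key (index concept, index
#' year-month, prior-year visit count) equals the participant's. Candidates
#' are consumed without replacement across the whole iteration, so a
#' nonparticipant person partners at most one participant.
#'
#' @param pools List (one element per participant) of integer indices into
#'   the candidate table.
#' @param cand_person Integer vector: person id of each candidate row.
#' @return Integer vector, per participant the matched candidate row index
#'   (`NA` when no compatible candidate remained).
#' @export
match_iteration <- function(pools, cand_person) {
  n_part <- length(pools)
  person_index <- match(cand_person, unique(cand_person))
  person_taken <- rep(FALSE, max(c(person_index, 0L)))
  out <- rep(NA_integer_, n_part)
  order <- sample.int(n_part)
  for (i in order) {
    pool <- pools[[i]]
    if (length(pool) == 0) next
    avail <- pool[!person_taken[person_index[pool]]]
    if (length(avail) == 0) next
    pick <- avail[sample.int(length(avail), 1L)]
    out[i] <- pick
    person_taken[person_index[pick]] <- TRUE
  }
  out
}

#' Repeat exact matching with resampling
#'
#' Runs [match_iteration()] `n_iterations` times; iteration `i` uses the RNG
#' stream seeded with `seed + i`, so individual iterations are reproducible.
#' Participants matched in no iteration at all are reported as
#' `never_matched` and are excluded from the downstream cohort; a retained
#' participant may still contribute no pair in some iterations.
#'
#' @param participants Participant table from [select_participants()].
#' @param store A validated `cdm_store`.
#' @param n_iterations Number of matching iterations (the analysis default
#'   is 1000).
#' @param seed Master seed.
#' @return A `matching_result`: list with `participants` (with match keys),
#'   `candidates`, `pairs` (participant x iteration matrix of candidate row
#'   indices), `never_matched` (person ids), `n_iterations`, `seed`.
#' @export
run_resampling <- function(participants, store, n_iterations = 1000L,
                           seed = 1L) {
  stopifnot(n_iterations >= 1)
  problem <- build_matching_problem(participants, store)
  n_part <- nrow(problem$participants)
  cand_person <- problem$candidates$person_id
  pairs <- matrix(NA_integer_, nrow = n_part, ncol = n_iterations)
  for (it in seq_len(n_iterations)) {
    pairs[, it] <- with_rng(seed + it,
                            match_iteration(problem$pools, cand_person))
    row_persons <- cand_person[pairs[, it]]
    row_persons <- row_persons[!is.na(row_persons)]
    if (anyDuplicated(row_persons) > 0) {
      abort("internal error: nonparticipant matched twice in one iteration")
    }
  }
  ever <- rowSums(!is.na(pairs)) > 0
  structure(list(
    participants = problem$participants,
    candidates = problem$candidates,
    pairs = pairs,
    never_matched = problem$participants$person_id[!ever],
    n_iterations = as.integer(n_iterations),
    seed = as.integer(seed)
  ), class = "matching_result")
}

#' @export
print.matching_result <- function(x, ...) {
  cat(sprintf(
    "<matching_result> %d participants, %d candidate records, %d iterations\n",
    nrow(x$participants), nrow(x$candidates), x$n_iterations))
  cat(sprintf("  never matched: %d\n", length(x$never_matched)))
  invisible(x)
}

#' Aggregate covariate counts over matching iterations
#'
#' For each covariate, the across-iteration mean of the per-iteration count
#' among that iteration's matched nonparticipants; the aggregated prevalence
#' is mean count / mean matched-set size. Covariates must have been computed
#' at each candidate's own index date.
#'
#' @param result A `matching_result`.
#' @param candidate_covariates Logical matrix, one row per candidate row of
#'   `result$candidates`, one column per covariate.
#' @param participant_subset Optional person ids restricting the aggregation
#'   to the pairs of those participants (e.g. a disease-domain stratum).
#' @return Tibble (`covariate`, `mean_count`, `prevalence`) plus attribute
#'   `mean_matched_n`.
#' @export
aggregate_counts <- function(result, candidate_covariates,
                             participant_subset = NULL) {
  stopifnot(inherits(result, "matching_result"))
  stopifnot(nrow(candidate_covariates) == nrow(result$candidates))
  rows <- seq_len(nrow(result$participants))
  if (!is.null(participant_subset)) {
    rows <- which(result$participants$person_id %in% participant_subset)
  }
  pairs <- result$pairs[rows, , drop = FALSE]
  k <- ncol(candidate_covariates)
  counts <- matrix(0, result$n_iterations, k)
  sizes <- numeric(result$n_iterations)
  for (it in seq_len(result$n_iterations)) {
    idx <- pairs[, it]
    idx <- idx[!is.na(idx)]
    sizes[it] <- length(idx)
    if (length(idx) > 0) {
      counts[it, ] <- colSums(candidate_covariates[idx, , drop = FALSE])
    }
  }
  mean_count <- colMeans(counts)
  mean_n <- mean(sizes)
  out <- tibble(
    covariate = colnames(candidate_covariates),
    mean_count = mean_count,
    prevalence = if (mean_n > 0) mean_count / mean_n else NA_real_
  )
  attr(out, "mean_matched_n") <- mean_n
  out
}
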