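# Trial-participant selection: earliest trial per person, index-event search
# in the 365-day window up to the status date, prior-year reassurance
# requirement, and trial/person exclusions with a full audit trail.

#' Earliest enrollment record of one person
#'
#' The record with the minimal status date; ties are broken by the
#' lexicographically smallest trial id so selection is deterministic.
#'
#' @param enrollments Data frame of one person's enrollment records
#'   (`trial_id`, `status`, `status_date`, optionally `person_id`).
#' @return The single earliest row.
#' @export
earliest_enrollment <- function(enrollments) {
  if (nrow(enrollments) == 0) {
    abort("earliest_enrollment: no enrollment records")
  }
  enrollments |>
    arrange(.data$status_date, .data$trial_id) |>
    dplyr::slice(1)
}

#' Find a participant's index condition event
#'
#' Searches the person's condition events for a concept that is a focus
#' concept of the trial or a descendant of one, dated in the closed 366-day
#' interval `[status_date - 365, status_date]`. The event closest to the
#' status date wins; date ties are broken by the smallest concept id, then
#' by input order.
#'
#' @param conditions The person's condition events (`concept_id`,
#'   `event_date`).
#' @param trial A single trial row (must be mappable, with
#'   `focus_concept_ids` a list column or integer vector).
#' @param status_date The person's trial status date.
#' @param ancestry A `cdm_store` or ancestry pair table.
#' @return A one-row tibble (`index_concept_id`, `index_date`,
#'   `days_from_status`), or `NULL` when no event qualifies.
#' @export
find_index_event <- function(conditions, trial, status_date, ancestry) {
  focus <- trial$focus_concept_ids
  if (is.list(focus)) focus <- focus[[1]]
  if (length(focus) == 0) {
    abort("find_index_event: trial has no focus concepts (unmappable?)")
  }
  qualifying <- expand_concepts(focus, ancestry)
  hits <- conditions |>
    filter(.data$concept_id %in% qualifying,
           .data$event_date >= status_date - 365L,
           .data$event_date <= status_date)
  if (nrow(hits) == 0) {
    return(NULL)
  }
  best <- hits |>
    arrange(desc(.data$event_date), .data$concept_id) |>
    dplyr::slice(1)
  tibble(
    index_concept_id = best$concept_id,
    index_date = best$event_date,
    days_from_status = as.integer(status_date - best$event_date)
  )
}

#' Prior-year reassurance check
#'
#' True when the index condition (or one of its descendants) also appears in
#' the year strictly before the index date, i.e. in the closed interval
#' `[index_date - 365, index_date - 1]`. An event on the index date itself
#' does not count.
#'
#' @param conditions The person's condition events.
#' @param index_concept The designated index concept id.
#' @param index_date The index date.
#' @param ancestry A `cdm_store` or ancestry pair table.
#' @return Logical scalar.
#' @export
reassurance_check <- function(conditions, index_concept, index_date, ancestry) {
  has_code_in_window(conditions, index_concept, ancestry,
                     index_date - 365L, index_date - 1L)$has_code
}

#' Select trial participants from a store
#'
#' Runs the selection pipeline over every person with an enrollment record:
#' earliest trial, exclusion of persons whose trial is unmappable, index
#' event search, and the reassurance requirement. The audit accounts for
#' every screened person exactly once.
#'
#' @param store A validated `cdm_store`.
#' @return A list with `participants` (tibble: `person_id`, `trial_id`,
#'   `status_date`, `index_concept_id`, `index_date`, `days_from_status`)
#'   and `audit` (named list of counts).
#' @export
select_participants <- function(store) {
  stopifnot(inherits(store, "cdm_store"))
  empty <- tibble(person_id = integer(), trial_id = character(),
                  status_date = as.Date(character()),
                  index_concept_id = integer(),
                  index_date = as.Date(character()),
                  days_from_status = integer())
  n_trials_unmappable <- sum(!store$trials$mappable)
  if (nrow(store$enrollment) == 0) {
    return(list(participants = empty, audit = list(
      persons_screened = 0L, trials_excluded_unmappable = n_trials_unmappable,
      excluded_unmappable_trial = 0L, excluded_no_index_code = 0L,
      excluded_reassurance = 0L, selected = 0L)))
  }

  earliest <- store$enrollment |>
    arrange(.data$person_id, .data$status_date, .data$trial_id) |>
    dplyr::slice(1, .by = "person_id")
  screened <- nrow(earliest)

  earliest <- earliest |>
    left_join(store$trials[c("trial_id", "mappable", "focus_concept_ids")],
              by = "trial_id")
  mappable <- earliest |> filter(.data$mappable)
  excluded_unmappable <- screened - nrow(mappable)

  # expand each mappable trial's focus set through the hierarchy once
  focus_map <- mappable |>
    dplyr::distinct(.data$trial_id, .keep_all = TRUE) |>
    dplyr::reframe(
      concept_id = expand_concepts(.data$focus_concept_ids[[1]],
                                   store$concept_ancestor),
      .by = "trial_id")

  hits <- store$condition_occurrence |>
    inner_join(mappable[c("person_id", "trial_id", "status_date")],
               by = "person_id") |>
    semi_join(focus_map, by = c("trial_id", "concept_id")) |>
    filter(.data$event_date >= .data$status_date - 365L,
           .data$event_date <= .data$status_date)
  index <- hits |>
    arrange(.data$person_id, desc(.data$event_date), .data$concept_id) |>
    dplyr::slice(1, .by = "person_id") |>
    transmute(.data$person_id, .data$trial_id, .data$status_date,
              index_concept_id = .data$concept_id,
              index_date = .data$event_date,
              days_from_status = as.integer(.data$status_date - .data$event_date))
  excluded_no_code <- nrow(mappable) - nrow(index)

  # reassurance: the index concept or a descendant in [index - 365, index - 1]
  reass_map <- tibble(index_concept_id = unique(index$index_concept_id)) |>
    dplyr::reframe(
      concept_id = descendants_of(.data$index_concept_id[1],
                                  store$concept_ancestor),
      .by = "index_concept_id")
  reassured_ids <- store$condition_occurrence |>
    inner_join(index[c("person_id", "index_concept_id", "index_date")],
               by = "person_id", relationship = "many-to-many") |>
    semi_join(reass_map, by = c("index_concept_id", "concept_id")) |>
    filter(.data$event_date >= .data$index_date - 365L,
           .data$event_date <= .data$index_date - 1L) |>
    dplyr::distinct(.data$person_id)
  participants <- index |>
    semi_join(reassured_ids, by = "person_id") |>
    arrange(.data$person_id)
  excluded_reassurance <- nrow(index) - nrow(participants)

  audit <- list(
    persons_screened = screened,
    trials_excluded_unmappable = n_trials_unmappable,
    excluded_unmappable_trial = excluded_unmappable,
    excluded_no_index_code = excluded_no_code,
    excluded_reassurance = excluded_reassurance,
    selected = nrow(participants)
  )
  stopifnot(audit$excluded_unmappable_trial + audit$excluded_no_index_code +
              audit$excluded_reassurance + audit$selected ==
              audit$persons_screened)
  list(participants = participants, audit = audit)
}
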