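# Minimal OMOP-style relational store: load, validate, and query the tables
# the pipeline consumes (person, condition_occurrence, drug_exposure,
# visit_occurrence, concept, concept_ancestor, enrollment, trials).

CDM_TABLE_COLUMNS <- list(
  person              = c("person_id", "birth_date", "sex", "race", "ethnicity"),
  condition_occurrence = c("person_id", "concept_id", "event_date"),
  drug_exposure       = c("person_id", "concept_id", "event_date"),
  visit_occurrence    = c("person_id", "visit_date"),
  concept             = c("concept_id", "name", "domain"),
  concept_ancestor    = c("ancestor_id", "descendant_id"),
  enrollment          = c("person_id", "trial_id", "status", "status_date"),
  trials              = c("trial_id", "focus_concept_ids", "mappable", "phase",
                          "arms", "randomized", "blinded", "model", "industry",
                          "dmc", "multisite", "overall_enrollment",
                          "site_enrollment", "status")
)

SEX_CODES <- c("male", "female")
RACE_CODES <- c("white", "black", "other", "unknown")
ETHNICITY_CODES <- c("hispanic", "not_hispanic", "unknown")

#' Construct a validated CDM store from in-memory tables
#'
#' Assembles the eight tables the pipeline consumes into a `cdm_store` object
#' and runs the full schema / referential-integrity / hierarchy validation.
#' `focus_concept_ids` in `trials` may be given either as a `';'`-joined
#' character column (the file format) or as a list column of integer vectors.
#'
#' @param person,condition_occurrence,drug_exposure,visit_occurrence,concept,concept_ancestor,enrollment,trials
#'   Data frames with the columns listed for the corresponding file in
#'   [load_store()].
#' @return A validated `cdm_store` object (a named list of tibbles).
#' @export
cdm_store <- function(person, condition_occurrence, drug_exposure,
                      visit_occurrence, concept, concept_ancestor,
                      enrollment, trials) {
  tables <- list(
    person = as_tibble(person),
    condition_occurrence = as_tibble(condition_occurrence),
    drug_exposure = as_tibble(drug_exposure),
    visit_occurrence = as_tibble(visit_occurrence),
    concept = as_tibble(concept),
    concept_ancestor = as_tibble(concept_ancestor),
    enrollment = as_tibble(enrollment),
    trials = as_tibble(trials)
  )
  for (nm in names(CDM_TABLE_COLUMNS)) {
    missing <- setdiff(CDM_TABLE_COLUMNS[[nm]], names(tables[[nm]]))
    if (length(missing) > 0) {
      abort(sprintf("schema error: table '%s' is missing column(s): %s",
                    nm, paste(missing, collapse = ", ")))
    }
    tables[[nm]] <- tables[[nm]][CDM_TABLE_COLUMNS[[nm]]]
  }
  if (is.character(tables$trials$focus_concept_ids)) {
    tables$trials$focus_concept_ids <-
      parse_focus_concepts(tables$trials$focus_concept_ids)
  }
  store <- structure(tables, class = "cdm_store")
  validate_store(store)
  store
}

parse_focus_concepts <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE), function(ids) {
    ids <- ids[nzchar(ids)]
    as.integer(ids)
  })
}

#' Load a CDM store from delimited files
#'
#' Reads the eight comma-separated tables (header row, UTF-8, ISO-8601 dates)
#' and validates them: schema, referential integrity (every event `person_id`
#' must exist in `person.csv`, ancestry ids in `concept.csv`), uniqueness
#' constraints, and hierarchy well-formedness (acyclic, transitively closed,
#' no self pairs).
#'
#' @param path Either a directory containing `person.csv`,
#'   `condition_occurrence.csv`, `drug_exposure.csv`, `visit_occurrence.csv`,
#'   `concept.csv`, `concept_ancestor.csv`, `enrollment.csv`, and
#'   `trials.csv`, or a named character vector of file paths with those table
#'   names.
#' @param quiet Suppress the per-table row-count messages.
#' @return A validated `cdm_store` object.
#' @export
load_store <- function(path, quiet = TRUE) {
  if (length(path) == 1 && is.null(names(path))) {
    files <- setNames(file.path(path, paste0(names(CDM_TABLE_COLUMNS), ".csv")),
                      names(CDM_TABLE_COLUMNS))
  } else {
    files <- path
  }
  missing <- setdiff(names(CDM_TABLE_COLUMNS), names(files))
  if (length(missing) > 0) {
    abort(sprintf("load_store: no path given for table(s): %s",
                  paste(missing, collapse = ", ")))
  }
  absent <- files[!file.exists(files)]
  if (length(absent) > 0) {
    abort(sprintf("load_store: file(s) not found: %s",
                  paste(absent, collapse = ", ")))
  }
  col_types <- list(
    person = readr::cols(person_id = "i", birth_date = "D", sex = "c",
                         race = "c", ethnicity = "c"),
    condition_occurrence = readr::cols(person_id = "i", concept_id = "i",
                                       event_date = "D"),
    drug_exposure = readr::cols(person_id = "i", concept_id = "i",
                                event_date = "D"),
    visit_occurrence = readr::cols(person_id = "i", visit_date = "D"),
    concept = readr::cols(concept_id = "i", name = "c", domain = "c"),
    concept_ancestor = readr::cols(ancestor_id = "i", descendant_id = "i"),
    enrollment = readr::cols(person_id = "i", trial_id = "c", status = "c",
                             status_date = "D"),
    trials = readr::cols(trial_id = "c", focus_concept_ids = "c",
                         mappable = "l", phase = "c", arms = "i",
                         randomized = "l", blinded = "l", model = "c",
                         industry = "l", dmc = "l", multisite = "l",
                         overall_enrollment = "i", site_enrollment = "i",
                         status = "c")
  )
  tables <- lapply(names(CDM_TABLE_COLUMNS), function(nm) {
    tbl <- readr::read_csv(files[[nm]], col_types = col_types[[nm]],
                           progress = FALSE)
    if (!quiet) inform(sprintf("loaded %s: %d rows", nm, nrow(tbl)))
    tbl
  })
  names(tables) <- names(CDM_TABLE_COLUMNS)
  do.call(cdm_store, tables)
}

#' Write a CDM store back to delimited files
#'
#' Inverse of [load_store()] up to row order: values round-trip byte-stably
#' (ISO dates, `';'`-joined focus concept sets).
#'
#' @param store A `cdm_store`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_store <- function(store, dir) {
  stopifnot(inherits(store, "cdm_store"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- setNames(file.path(dir, paste0(names(CDM_TABLE_COLUMNS), ".csv")),
                    names(CDM_TABLE_COLUMNS))
  for (nm in names(CDM_TABLE_COLUMNS)) {
    tbl <- store[[nm]]
    if (nm == "trials") {
      tbl$focus_concept_ids <- vapply(tbl$focus_concept_ids, paste,
                                      character(1), collapse = ";")
    }
    readr::write_csv(tbl, paths[[nm]], progress = FALSE)
  }
  invisible(paths)
}

validate_store <- function(store) {
  person <- store$person
  if (anyDuplicated(person$person_id) > 0) {
    abort("integrity error: duplicate person_id in person table")
  }
  bad_sex <- setdiff(unique(person$sex), SEX_CODES)
  if (length(bad_sex) > 0) {
    abort(sprintf("schema error: unknown sex code(s): %s",
                  paste(bad_sex, collapse = ", ")))
  }
  bad_race <- setdiff(unique(person$race), RACE_CODES)
  if (length(bad_race) > 0) {
    abort(sprintf("schema error: unknown race code(s): %s",
                  paste(bad_race, collapse = ", ")))
  }
  bad_eth <- setdiff(unique(person$ethnicity), ETHNICITY_CODES)
  if (length(bad_eth) > 0) {
    abort(sprintf("schema error: unknown ethnicity code(s): %s",
                  paste(bad_eth, collapse = ", ")))
  }

  check_fk <- function(ids, universe, what, table) {
    missing_at <- which(!(ids %in% universe))
    if (length(missing_at) > 0) {
      abort(sprintf(
        "integrity error: %s row %d references unknown %s (%s)",
        table, missing_at[1], what, ids[missing_at[1]]))
    }
  }
  check_fk(store$condition_occurrence$person_id, person$person_id,
           "person_id", "condition_occurrence")
  check_fk(store$drug_exposure$person_id, person$person_id,
           "person_id", "drug_exposure")
  check_fk(store$visit_occurrence$person_id, person$person_id,
           "person_id", "visit_occurrence")
  check_fk(store$enrollment$person_id, person$person_id,
           "person_id", "enrollment")
  concept_ids <- store$concept$concept_id
  check_fk(store$condition_occurrence$concept_id, concept_ids,
           "concept_id", "condition_occurrence")
  check_fk(store$drug_exposure$concept_id, concept_ids,
           "concept_id", "drug_exposure")
  check_fk(store$concept_ancestor$ancestor_id, concept_ids,
           "ancestor_id", "concept_ancestor")
  check_fk(store$concept_ancestor$descendant_id, concept_ids,
           "descendant_id", "concept_ancestor")
  focus_ids <- unique(unlist(store$trials$focus_concept_ids))
  if (length(focus_ids) > 0) {
    check_fk(focus_ids, concept_ids, "focus concept_id", "trials")
  }

  # birth_date must not postdate any event of the person
  first_event <- dplyr::bind_rows(
    store$condition_occurrence[c("person_id", "event_date")],
    store$drug_exposure[c("person_id", "event_date")],
    tibble(person_id = store$visit_occurrence$person_id,
           event_date = store$visit_occurrence$visit_date)
  ) |>
    summarise(first_date = min(.data$event_date), .by = "person_id")
  offenders <- first_event |>
    inner_join(person[c("person_id", "birth_date")], by = "person_id") |>
    filter(.data$birth_date > .data$first_date)
  if (nrow(offenders) > 0) {
    abort(sprintf(
      "integrity error: person %d has an event before their birth date",
      offenders$person_id[1]))
  }

  validate_ancestry(store$concept_ancestor)

  enr_key <- store$enrollment |>
    dplyr::distinct(.data$person_id, .data$trial_id, .data$status_date)
  if (nrow(enr_key) != nrow(store$enrollment)) {
    abort("integrity error: duplicate (person_id, trial_id, status_date) in enrollment")
  }
  mappable_empty <- vapply(store$trials$focus_concept_ids, length,
                           integer(1)) == 0 & store$trials$mappable
  if (any(mappable_empty)) {
    abort(sprintf(
      "integrity error: mappable trial %s has no focus concepts",
      store$trials$trial_id[which(mappable_empty)[1]]))
  }
  invisible(store)
}

# Stored ancestry must exclude self-pairs, be acyclic, and be its own
# transitive closure (the OMOP concept_ancestor convention minus self rows).
validate_ancestry <- function(ancestry) {
  if (nrow(ancestry) == 0) {
    return(invisible(ancestry))
  }
  if (any(ancestry$ancestor_id == ancestry$descendant_id)) {
    abort("validation error: concept_ancestor contains self pairs")
  }
  key <- paste(ancestry$ancestor_id, ancestry$descendant_id)
  if (anyDuplicated(key) > 0) {
    abort("validation error: duplicate pairs in concept_ancestor")
  }
  reverse <- paste(ancestry$descendant_id, ancestry$ancestor_id)
  if (any(reverse %in% key)) {
    abort("validation error: concept_ancestor contains a cycle")
  }
  # closure: compose the relation with itself; every implied pair must exist
  implied <- ancestry |>
    inner_join(ancestry, by = c("descendant_id" = "ancestor_id"),
               suffix = c("", ".y"), relationship = "many-to-many")
  implied_key <- paste(implied$ancestor_id, implied$descendant_id.y)
  if (nrow(implied) > 0 && !all(implied_key %in% key)) {
    abort("validation error: concept_ancestor is not transitively closed")
  }
  invisible(ancestry)
}

as_ancestry <- function(x) {
  if (inherits(x, "cdm_store")) x$concept_ancestor else as_tibble(x)
}

#' Descendants of a concept (inclusive)
#'
#' Returns the concept itself plus every stored descendant; ancestry is kept
#' as an explicit transitive closure, so this is a set lookup with no graph
#' traversal.
#'
#' @param concept_id A single concept id.
#' @param ancestry A `cdm_store` or a data frame with columns
#'   `ancestor_id`, `descendant_id`.
#' @return Integer vector of concept ids, starting with `concept_id`.
#' @export
descendants_of <- function(concept_id, ancestry) {
  stopifnot(length(concept_id) == 1, !is.na(concept_id))
  concept_id <- as.integer(concept_id)
  if (inherits(ancestry, "cdm_store")) {
    if (!(concept_id %in% ancestry$concept$concept_id)) {
      abort(sprintf("unknown concept id: %d", concept_id))
    }
  }
  pairs <- as_ancestry(ancestry)
  unique(c(concept_id,
           pairs$descendant_id[pairs$ancestor_id == concept_id]))
}

# Vectorised inclusive expansion of a set of concept ids.
expand_concepts <- function(concept_ids, ancestry) {
  pairs <- as_ancestry(ancestry)
  concept_ids <- as.integer(concept_ids)
  unique(c(concept_ids,
           pairs$descendant_id[pairs$ancestor_id %in% concept_ids]))
}

#' Does a person have a qualifying code in a date window?
#'
#' True when at least one condition event has a concept equal to
#' `target_concept` or one of its descendants, dated inside the closed
#' interval `[window_start, window_end]` (both endpoints inclusive).
#'
#' @param events Data frame of one person's condition events
#'   (`concept_id`, `event_date`).
#' @param target_concept Concept id to match (expanded through descendants).
#' @param ancestry A `cdm_store` or ancestry pair table.
#' @param window_start,window_end Closed interval endpoints (`Date`).
#' @return A list with `has_code` (logical) and `dates` (sorted `Date` vector
#'   of the matching event dates).
#' @export
has_code_in_window <- function(events, target_concept, ancestry,
                               window_start, window_end) {
  stopifnot(window_start <= window_end)
  if (nrow(events) == 0) {
    return(list(has_code = FALSE, dates = as.Date(character())))
  }
  concepts <- descendants_of(target_concept, ancestry)
  hit <- events$concept_id %in% concepts &
    events$event_date >= window_start & events$event_date <= window_end
  list(has_code = any(hit), dates = sort(events$event_date[hit]))
}

#' @export
print.cdm_store <- function(x, ...) {
  cat("<cdm_store>\n")
  for (nm in names(CDM_TABLE_COLUMNS)) {
    cat(sprintf("  %-21s %6d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}
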