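# Disease-domain derivation from concept ancestry and recoding of trial
# metadata into the analysis categories (phase collapsing, arm and
# enrollment bins, status normalization).

TRIAL_STATUS_LEVELS <- c("completed", "recruiting", "active_not_recruiting",
                         "terminated_suspended_withdrawn", "unknown_status")

#' Collapse a trial phase label to its latest phase
#'
#' Combination labels map to the later phase: phase 1/phase 2 is analyzed as
#' phase 2, phase 2/phase 3 as phase 3. Matching is case-insensitive.
#'
#' @param phase_label Character vector of registry phase labels.
#' @return Integer vector of phase groups (1-4).
#' @export
collapse_phase <- function(phase_label) {
  vapply(phase_label, function(x) {
    digits <- regmatches(x, gregexpr("[1-4]", x))[[1]]
    if (length(digits) == 0 || !grepl("phase", tolower(x))) {
      abort(sprintf("unknown phase label: '%s'", x))
    }
    max(as.integer(digits))
  }, integer(1), USE.NAMES = FALSE)
}

#' Normalize a registry status string
#'
#' Case-insensitive mapping onto the five analysis status rows; terminated,
#' suspended, and withdrawn collapse into one category, and anything
#' unrecognized becomes `unknown_status`.
#'
#' @param status Character vector.
#' @return Factor with levels `completed`, `recruiting`,
#'   `active_not_recruiting`, `terminated_suspended_withdrawn`,
#'   `unknown_status`.
#' @export
normalize_status <- function(status) {
  x <- tolower(trimws(status))
  out <- dplyr::case_when(
    x == "completed" ~ "completed",
    x %in% c("recruiting", "enrolling by invitation") ~ "recruiting",
    x == "active, not recruiting" ~ "active_not_recruiting",
    x %in% c("terminated", "suspended", "withdrawn") ~
      "terminated_suspended_withdrawn",
    .default = "unknown_status"
  )
  factor(out, levels = TRIAL_STATUS_LEVELS)
}

#' Enrollment and arm bins
#'
#' Overall trial enrollment bins as `<50` / `50-499` / `>=500`,
#' institution-specific enrollment as `<5` / `5-19` / `>=20`, and treatment
#' arms as `1` / `2` / `3+`; the bins partition the nonnegative integers.
#'
#' @param n Nonnegative integer counts.
#' @return Factor of bin labels.
#' @export
bin_overall_enrollment <- function(n) {
  if (any(n < 0)) abort("negative enrollment")
  cut(n, breaks = c(-Inf, 49, 499, Inf), labels = c("lt50", "50to499", "ge500"))
}

#' @rdname bin_overall_enrollment
#' @export
bin_site_enrollment <- function(n) {
  if (any(n < 0)) abort("negative enrollment")
  cut(n, breaks = c(-Inf, 4, 19, Inf), labels = c("lt5", "5to19", "ge20"))
}

#' @rdname bin_overall_enrollment
#' @param arms Positive integer arm counts.
#' @export
bin_arms <- function(arms) {
  if (any(arms < 1)) abort("arms must be positive")
  factor(ifelse(arms >= 3, "3plus", as.character(arms)),
         levels = c("1", "2", "3plus"))
}

#' Recode trial metadata into analysis categories
#'
#' Phase labels collapse to their latest phase; treatment arms bin as
#' 1 / 2 / 3+; overall enrollment bins as <50 / 50-499 / >=500 and
#' institution-specific enrollment as <5 / 5-19 / >=20 (anticipated values
#' stand in when actual enrollment is absent, which is how the enrollment
#' columns are expected to be populated upstream); booleans and the
#' intervention model pass through; status strings are normalized.
#'
#' @param trials Trials table of a `cdm_store` (or a compatible data frame).
#' @return Tibble with one row per trial: `trial_id`, `phase_group`,
#'   `arms_group`, `randomized`, `blinded`, `model`, `industry`, `dmc`,
#'   `multisite`, `overall_enrollment_bin`, `site_enrollment_bin`,
#'   `status_group`.
#' @export
bin_trial <- function(trials) {
  trials <- as_tibble(trials)
  tibble(
    trial_id = trials$trial_id,
    phase_group = factor(collapse_phase(trials$phase), levels = 1:4),
    arms_group = bin_arms(trials$arms),
    randomized = trials$randomized,
    blinded = trials$blinded,
    model = factor(trials$model, levels = c("single_group", "parallel", "other")),
    industry = trials$industry,
    dmc = trials$dmc,
    multisite = trials$multisite,
    overall_enrollment_bin = bin_overall_enrollment(trials$overall_enrollment),
    site_enrollment_bin = bin_site_enrollment(trials$site_enrollment),
    status_group = normalize_status(trials$status)
  )
}

#' Assign disease domains to trials from concept ancestry
#'
#' A trial qualifies for a domain when any of its focus concepts is the
#' domain's anchor concept or a descendant of it; domains are therefore not
#' mutually exclusive. Unmappable trials are an error here - they must have
#' been excluded upstream.
#'
#' @param trials Trials table (or a single-row trial) with `trial_id`,
#'   `focus_concept_ids` (list column), `mappable`.
#' @param ancestry A `cdm_store` or ancestry pair table.
#' @param domain_concepts Named integer vector: domain label -> anchor
#'   concept id.
#' @return Long tibble (`trial_id`, `domain`); trials whose focus concepts
#'   relate to no anchor contribute no rows.
#' @export
assign_domains <- function(trials, ancestry, domain_concepts) {
  trials <- as_tibble(trials)
  if (any(!trials$mappable)) {
    abort(sprintf("assign_domains: trial %s is unmappable",
                  trials$trial_id[!trials$mappable][1]))
  }
  domain_sets <- lapply(domain_concepts, descendants_of, ancestry = ancestry)
  purrr::map_dfr(names(domain_sets), function(lab) {
    hit <- vapply(trials$focus_concept_ids, function(f) {
      any(f %in% domain_sets[[lab]])
    }, logical(1))
    tibble(trial_id = trials$trial_id[hit], domain = lab)
  }) |>
    arrange(.data$trial_id, .data$domain)
}

#' Keep the domains with the most trials
#'
#' @param domains Long (`trial_id`, `domain`) assignment table.
#' @param k Number of domains to keep (ties broken alphabetically).
#' @return The assignment table restricted to the top-`k` domains.
#' @export
top_domains <- function(domains, k = 4) {
  counts <- domains |>
    count(.data$domain, name = "n_trials") |>
    arrange(desc(.data$n_trials), .data$domain)
  keep <- head(counts$domain, k)
  domains |> filter(.data$domain %in% keep)
}
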