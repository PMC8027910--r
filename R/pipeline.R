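# End-to-end orchestration: simulate (or load) -> select -> match ->
# extract -> compare -> associate, with structured per-stage logging, stable
# file outputs, and a run manifest with checksums.

#' Assemble a pipeline run configuration
#'
#' @param input Either a [sim_config()] (the study is simulated) or a path
#'   to a directory of input tables as written by [simulate_study()]
#'   (`load_store()` tables plus `covariates.csv` and
#'   `domain_concepts.csv`).
#' @param n_iterations Matching iterations (analysis default 1000).
#' @param seed Master seed for matching and Monte-Carlo tests.
#' @param alpha Family significance level of the association scan.
#' @param flag_threshold Absolute standardized-difference cutoff.
#' @param k_domains How many of the most trial-rich domains to analyze.
#' @return A `run_config` object.
#' @export
run_config <- function(input, n_iterations = 1000L, seed = 1L, alpha = 0.01,
                       flag_threshold = 0.1, k_domains = 4L) {
  if (!inherits(input, "sim_config")) {
    if (!is.character(input) || length(input) != 1) {
      abort("config error: `input` must be a sim_config or a directory path")
    }
    needed <- file.path(input, c("person.csv", "covariates.csv",
                                 "domain_concepts.csv"))
    missing <- needed[!file.exists(needed)]
    if (length(missing) > 0) {
      abort(sprintf("config error: missing input file(s): %s",
                    paste(missing, collapse = ", ")))
    }
  }
  structure(list(input = input, n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), alpha = alpha,
                 flag_threshold = flag_threshold,
                 k_domains = as.integer(k_domains)),
            class = "run_config")
}

stage_log <- function(quiet, stage, ...) {
  if (!quiet) inform(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full pipeline
#'
#' Executes every stage and writes each module's artifact plus
#' `manifest.json` (config echo, seed, package version, row counts, md5
#' checksums of every output). Re-running with the same configuration
#' reproduces identical checksums.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created; existing files overwritten).
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with the main in-memory results
#'   (`participants`, `audit`, `matching`, `comparison`, `associations`,
#'   `manifest`).
#' @export
run_all <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- inputs -------------------------------------------------------------
  if (inherits(config$input, "sim_config")) {
    sim <- simulate_study(config$input)
    store <- sim$store
    cov_defs <- sim$covariate_defs
    domain_concepts <- sim$domain_concepts
    stage_log(quiet, "simulate", "%d persons, %d trials, %d condition events",
              nrow(store$person), nrow(store$trials),
              nrow(store$condition_occurrence))
  } else {
    store <- load_store(config$input)
    cov_defs <- readr::read_csv(file.path(config$input, "covariates.csv"),
                                col_types = "cci", progress = FALSE)
    dc <- readr::read_csv(file.path(config$input, "domain_concepts.csv"),
                          col_types = "ci", progress = FALSE)
    domain_concepts <- setNames(dc$concept_id, dc$domain)
    stage_log(quiet, "load", "%d persons, %d trials",
              nrow(store$person), nrow(store$trials))
  }

  # --- trial characterization --------------------------------------------
  mappable_trials <- store$trials |> filter(.data$mappable)
  domains <- assign_domains(mappable_trials, store, domain_concepts) |>
    top_domains(config$k_domains)
  trial_cat <- bin_trial(store$trials)
  readr::write_csv(domains, file.path(out_dir, "domains.csv"), progress = FALSE)
  readr::write_csv(trial_cat, file.path(out_dir, "trial_categorical.csv"),
                   progress = FALSE)
  stage_log(quiet, "characterize", "%d trials across %d domains",
            dplyr::n_distinct(domains$trial_id),
            dplyr::n_distinct(domains$domain))

  # --- participant selection ---------------------------------------------
  sel <- select_participants(store)
  participants <- sel$participants
  readr::write_csv(participants, file.path(out_dir, "participants.csv"),
                   progress = FALSE)
  jsonlite::write_json(sel$audit, file.path(out_dir, "selection_audit.json"),
                       auto_unbox = TRUE, digits = NA)
  stage_log(quiet, "select", "%d screened -> %d selected (%d/%d/%d excluded)",
            sel$audit$persons_screened, sel$audit$selected,
            sel$audit$excluded_unmappable_trial,
            sel$audit$excluded_no_index_code, sel$audit$excluded_reassurance)

  # --- matching -----------------------------------------------------------
  matching <- run_resampling(participants, store,
                             n_iterations = config$n_iterations,
                             seed = config$seed)
  pair_long <- purrr::map_dfr(seq_len(matching$n_iterations), function(it) {
    idx <- matching$pairs[, it]
    keep <- !is.na(idx)
    tibble(iteration = it,
           participant_id = matching$participants$person_id[keep],
           nonparticipant_id = matching$candidates$person_id[idx[keep]])
  })
  readr::write_csv(pair_long, file.path(out_dir, "matches.csv"),
                   progress = FALSE)
  readr::write_csv(tibble(person_id = matching$never_matched),
                   file.path(out_dir, "never_matched.csv"), progress = FALSE)
  stage_log(quiet, "match", "%d iterations; %d participants never matched",
            matching$n_iterations, length(matching$never_matched))

  # --- covariate extraction ----------------------------------------------
  part_anchor <- tibble(person_id = participants$person_id,
                        index_date = participants$index_date)
  cand_anchor <- tibble(person_id = matching$candidates$person_id,
                        index_date = matching$candidates$candidate_index_date)
  part_clin <- extract_covariates(part_anchor, cov_defs, store)
  cand_clin <- extract_covariates(cand_anchor, cov_defs, store)
  part_demo <- demographic_covariates(store$person, part_anchor)
  cand_demo <- demographic_covariates(store$person, cand_anchor)
  part_mat <- cbind(demographic_indicators(part_demo), part_clin)
  cand_mat <- cbind(demographic_indicators(cand_demo), cand_clin)
  agg <- aggregate_counts(matching, cand_mat)
  readr::write_csv(agg, file.path(out_dir, "aggregate_counts.csv"),
                   progress = FALSE)
  stage_log(quiet, "covariates", "%d covariate columns extracted",
            ncol(part_mat))

  # --- comparison ---------------------------------------------------------
  comparison <- compare_cohorts(
    part_mat, matching, cand_mat, domains,
    participant_trials = participants[c("person_id", "trial_id")],
    flag_threshold = config$flag_threshold)
  for (dom in unique(comparison$domain)) {
    readr::write_csv(comparison |> filter(.data$domain == dom),
                     file.path(out_dir, sprintf("comparison_%s.csv", dom)),
                     progress = FALSE)
  }
  stage_log(quiet, "compare", "%d rows, %d flagged at |d| >= %.2f",
            nrow(comparison), sum(comparison$flagged), config$flag_threshold)

  # --- association scan ---------------------------------------------------
  retained <- participants |>
    filter(!(.data$person_id %in% matching$never_matched))
  scan_dat <- dplyr::bind_cols(
    retained[c("person_id", "trial_id")],
    part_demo[match(retained$person_id, part_demo$person_id),
              c("age_group", "sex", "race", "ethnicity")],
    as_tibble(part_clin[match(as.character(retained$person_id),
                              rownames(part_clin)), , drop = FALSE])
  )
  covariate_cols <- c("age_group", "sex", "race", "ethnicity",
                      colnames(part_clin))
  associations <- scan_associations(
    scan_dat, covariate_cols, trial_cat |> filter(.data$trial_id %in%
                                                    mappable_trials$trial_id),
    domains = domains, alpha = config$alpha, seed = config$seed)
  for (dom in unique(associations$domain)) {
    readr::write_csv(associations |> filter(.data$domain == dom),
                     file.path(out_dir, sprintf("associations_%s.csv", dom)),
                     progress = FALSE)
  }
  manhattan <- manhattan_output(associations)
  readr::write_csv(manhattan$data, file.path(out_dir, "manhattan_data.csv"),
                   progress = FALSE)
  for (dom in names(manhattan$plots)) {
    f <- file.path(out_dir, sprintf("manhattan_%s.png", dom))
    grDevices::png(f, width = 2400, height = 1600, res = 200)
    print(manhattan$plots[[dom]])
    grDevices::dev.off()
  }
  stage_log(quiet, "associate", "%d cells tested, %d significant",
            sum(!is.na(associations$p_value)), sum(associations$significant))

  # --- manifest -----------------------------------------------------------
  outputs <- sort(list.files(out_dir, pattern = "\\.(csv|json)$"))
  outputs <- setdiff(outputs, "manifest.json")
  checksums <- tools::md5sum(file.path(out_dir, outputs))
  manifest <- list(
    package_version = as.character(utils::packageVersion("trialmatchr")),
    seed = config$seed,
    n_iterations = config$n_iterations,
    alpha = config$alpha,
    flag_threshold = config$flag_threshold,
    input = if (inherits(config$input, "sim_config")) {
      config_echo(config$input)
    } else {
      normalizePath(config$input)
    },
    row_counts = list(
      persons = nrow(store$person),
      trials = nrow(store$trials),
      participants_selected = nrow(participants),
      participants_retained = nrow(retained),
      candidate_records = nrow(matching$candidates),
      comparison_rows = nrow(comparison),
      association_cells = nrow(associations)
    ),
    checksums = as.list(setNames(unname(checksums), outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(participants = participants, audit = sel$audit,
                 matching = matching, comparison = comparison,
                 associations = associations, manifest = manifest))
}
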