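# Linked synthetic EHR / enrollment-report / trial-metadata generator with
# known ground truth. The generator fabricates a multi-level condition
# hierarchy, a drug-class hierarchy, persons with configurable covariate
# prevalences, enrollment selected by a logistic (log-odds) bias on those
# covariates, trial metadata drawn from configurable categorical
# distributions, and the condition/drug/visit events needed so that the
# participant-selection and matching stages operate on a non-degenerate
# cohort: every enrolled person in a mappable trial receives a focus-condition
# event inside the index window and another inside the prior-year reassurance
# window, and every background person "echoes" one participant's index
# concept and calendar month so matching pools are populated.

#' Build a synthetic-study configuration
#'
#' @param seed Integer master seed; a fixed config (including seed) yields
#'   byte-identical output files.
#' @param n_patients Total number of persons (enrollable plus background).
#' @param n_enrollable Number of persons given a trial enrollment record.
#' @param study_start,study_end Closed calendar window for the study; status
#'   dates are drawn no earlier than `study_start + 731` days so every
#'   lookback window stays inside a person's record.
#' @param hierarchy List with `n_roots`, `branching`, `depth` describing the
#'   condition-concept tree. Roots act as disease-domain anchors, level-2
#'   nodes are the trial focus concepts, and leaves anchor condition
#'   covariates; `depth >= 3` keeps those three roles distinct.
#' @param covariates Tibble with columns `name`, `kind`
#'   (`"condition"`/`"drug_class"`), `prevalence` (baseline in `[0, 1]`), and
#'   `bias` (log-odds shift applied when selecting who enrolls; negative
#'   values make the covariate rarer among participants).
#' @param visit_rate Mean healthcare visits per person per year (Poisson).
#' @param n_trials Number of trials.
#' @param trial_params Categorical distributions for trial metadata; see
#'   [default_trial_params()].
#' @param domain_labels Character labels for the disease-domain root
#'   concepts; length must not exceed `hierarchy$n_roots`.
#' @param candidate_reassurance_rate Probability that a background person's
#'   echo condition also receives a prior-year reassurance event (persons
#'   without one are screened out of matching pools).
#' @param second_enrollment_rate Fraction of enrolled persons given a second,
#'   later enrollment record (exercises earliest-trial selection).
#' @param index_lag_max Maximum days between the generated index condition
#'   event and the trial status date.
#' @param n_unmappable Number of trials flagged as having no concept
#'   conversion (their participants must be excluded downstream).
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 2000L,
                       n_enrollable = 100L,
                       study_start = as.Date("1996-09-01"),
                       study_end = as.Date("2019-01-31"),
                       hierarchy = list(n_roots = 4L, branching = 3L, depth = 3L),
                       covariates = default_covariates(),
                       visit_rate = 3,
                       n_trials = 20L,
                       trial_params = default_trial_params(),
                       domain_labels = c("neoplastic", "digestive",
                                         "inflammatory", "cardiovascular"),
                       candidate_reassurance_rate = 0.9,
                       second_enrollment_rate = 0.05,
                       index_lag_max = 30L,
                       n_unmappable = 1L) {
  cfg <- structure(list(
    seed = as.integer(seed),
    n_patients = as.integer(n_patients),
    n_enrollable = as.integer(n_enrollable),
    study_start = as.Date(study_start),
    study_end = as.Date(study_end),
    hierarchy = hierarchy,
    covariates = as_tibble(covariates),
    visit_rate = visit_rate,
    n_trials = as.integer(n_trials),
    trial_params = trial_params,
    domain_labels = domain_labels,
    candidate_reassurance_rate = candidate_reassurance_rate,
    second_enrollment_rate = second_enrollment_rate,
    index_lag_max = as.integer(index_lag_max),
    n_unmappable = as.integer(n_unmappable)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  h <- cfg$hierarchy
  if (any(vapply(h[c("n_roots", "branching", "depth")], is.null, logical(1)))) {
    abort("config error: hierarchy needs n_roots, branching, depth")
  }
  if (h$n_roots < 1 || h$branching < 1 || h$depth < 3) {
    abort("config error: hierarchy must have n_roots >= 1, branching >= 1, depth >= 3")
  }
  cov <- cfg$covariates
  need <- c("name", "kind", "prevalence", "bias")
  if (!all(need %in% names(cov))) {
    abort("config error: covariates need columns name, kind, prevalence, bias")
  }
  if (any(cov$prevalence < 0 | cov$prevalence > 1)) {
    abort("config error: covariate prevalences must lie in [0, 1]")
  }
  if (!all(cov$kind %in% c("condition", "drug_class"))) {
    abort("config error: covariate kind must be 'condition' or 'drug_class'")
  }
  if (anyDuplicated(cov$name) > 0) {
    abort("config error: duplicate covariate names")
  }
  n_leaves <- h$n_roots * h$branching^(h$depth - 1)
  n_cond <- sum(cov$kind == "condition")
  if (n_cond > n_leaves) {
    abort(sprintf(
      "config error: %d condition covariates but only %d hierarchy leaves",
      n_cond, n_leaves))
  }
  if (cfg$n_trials > 0 && h$n_roots * h$branching < 1) {
    abort("config error: trials requested but the hierarchy has no focus-eligible concepts")
  }
  if (cfg$n_enrollable >= cfg$n_patients) {
    abort("config error: n_enrollable must be smaller than n_patients")
  }
  if (cfg$n_unmappable >= cfg$n_trials) {
    abort("config error: n_unmappable must be smaller than n_trials")
  }
  if (length(cfg$domain_labels) > h$n_roots) {
    abort("config error: more domain labels than hierarchy roots")
  }
  if (cfg$visit_rate <= 0) {
    abort("config error: visit_rate must be positive")
  }
  if (as.integer(cfg$study_end - cfg$study_start) < 1096) {
    abort("config error: study window must span at least 3 years")
  }
  invisible(cfg)
}

#' Default trial-metadata distributions
#'
#' Marginal frequencies loosely follow the registry mix typical of an
#' academic medical center: phase 2/3 dominate, most trials are randomized,
#' industry sponsored, multisite, and use a data monitoring committee.
#' Combination phase labels are included so latest-phase collapsing is
#' exercised.
#'
#' @return Named list of categorical distributions.
#' @export
default_trial_params <- function() {
  list(
    phase_probs = c("phase 1" = 0.10, "phase 1/phase 2" = 0.08,
                    "phase 2" = 0.32, "phase 2/phase 3" = 0.07,
                    "phase 3" = 0.33, "phase 4" = 0.10),
    arms_probs = c("1" = 0.28, "2" = 0.44, "3" = 0.14, "4" = 0.09, "5" = 0.05),
    p_randomized = 0.58,
    p_blinded = 0.40,
    model_probs = c(single_group = 0.33, parallel = 0.62, other = 0.05),
    p_industry = 0.90,
    p_dmc = 0.69,
    p_multisite = 0.84,
    enrollment_meanlog = 5.0,
    enrollment_sdlog = 1.3,
    site_mean = 10,
    p_second_focus = 0.25,
    status_probs = c("Completed" = 0.54, "Recruiting" = 0.10,
                     "Active, not recruiting" = 0.20, "Terminated" = 0.06,
                     "Suspended" = 0.03, "Withdrawn" = 0.03,
                     "Unknown status" = 0.04)
  )
}

#' Small default covariate panel
#'
#' Eight condition and four drug-class covariates with mixed prevalences and
#' a mildly "healthier participant" bias profile; useful for unit-scale
#' simulations. [make_study_preset()] supplies the full 48-covariate
#' panel.
#'
#' @return Tibble of covariate specifications.
#' @export
default_covariates <- function() {
  tibble(
    name = c("hypertensive disorder", "diabetes", "heart failure",
             "depressive disorder", "renal impairment", "obesity",
             "pneumonia", "lesion of liver",
             "antithrombotic agents", "beta blocking agents",
             "opioids", "immunosuppressant medications"),
    kind = c(rep("condition", 8), rep("drug_class", 4)),
    prevalence = c(0.40, 0.18, 0.09, 0.11, 0.17, 0.06, 0.12, 0.11,
                   0.50, 0.28, 0.55, 0.13),
    bias = c(-0.45, -0.45, -0.45, -0.45, -0.45, -0.45, -0.45, 0.45,
             -0.45, -0.45, 0, 0.35)
  )
}

#' Paper-scale preset configuration
#'
#' A configuration at the magnitude of the motivating study: roughly 200
#' trials, ~1600 enrollable persons with a 20-fold background population, 31
#' condition covariates and 17 drug-class covariates. Baseline prevalences
#' follow the background (nonparticipant-like) rates of a large academic
#' medical center; most covariates carry a negative enrollment log-odds
#' shift so participants come out healthier, with a few positive or null
#' shifts mixed in.
#'
#' @param seed Master seed stored in the configuration.
#' @param n_enrollable,background_factor Cohort scale; `n_patients` is
#'   `n_enrollable * (background_factor + 1)`.
#' @param bias_scale Multiplier applied to every enrollment log-odds shift
#'   (`0` gives the null configuration with no participant/nonparticipant
#'   difference beyond sampling noise).
#' @return A `sim_config`.
#' @export
make_study_preset <- function(seed = 1L, n_enrollable = 1645L,
                                   background_factor = 20L, bias_scale = 1) {
  cond <- tibble(
    name = c("acute respiratory disease", "chronic liver disease",
             "chronic obstructive lung disease", "depressive disorder",
             "diabetes", "gastroesophageal reflux disease", "hyperlipidemia",
             "hypertensive disorder", "lesion of liver", "obesity",
             "osteoarthritis", "pneumonia", "renal impairment",
             "urinary tract infectious diseases", "viral hepatitis C infection",
             "visual system disorder", "atrial fibrillation",
             "cerebrovascular disease", "coronary arteriosclerosis",
             "heart disease", "heart failure", "ischemic heart disease",
             "peripheral vascular disease", "venous thrombosis",
             "hematologic neoplasm", "malignant lymphoma",
             "malignant neoplastic disease", "malignant tumor of breast",
             "malignant tumor of lung", "malignant tumor of urinary bladder",
             "primary malignant neoplasm of prostate"),
    kind = "condition",
    prevalence = c(0.097, 0.056, 0.079, 0.113, 0.179, 0.144, 0.255, 0.427,
                   0.110, 0.059, 0.176, 0.122, 0.173, 0.126, 0.046, 0.141,
                   0.086, 0.060, 0.124, 0.369, 0.087, 0.055, 0.022, 0.081,
                   0.428, 0.236, 0.480, 0.164, 0.094, 0.089, 0.088),
    bias = c(-0.45, 0, -0.45, -0.45, -0.45, -0.45, -0.45, -0.45,
             0.45, -0.45, -0.45, -0.45, -0.45, -0.45, 0, -0.45,
             -0.45, -0.45, -0.45, -0.45, -0.45, -0.45, -0.45, -0.45,
             0, 0, 0, -0.2, 0.3, 0, 0)
  )
  drug <- tibble(
    name = c("agents acting on the renin-angiotensin system",
             "antibacterial medications for systemic use",
             "antidepressant medications", "antiepileptic medications",
             "anti-inflammatory and antirheumatic products",
             "antineoplastic agents", "antithrombotic agents",
             "beta blocking agents", "calcium channel blockers",
             "diuretic medications", "drugs for acid-related disorders",
             "drugs for obstructive airway diseases", "drugs used in diabetes",
             "immunosuppressant medications", "lipid-modifying agents",
             "opioids", "psycholeptic medications"),
    kind = "drug_class",
    prevalence = c(0.273, 0.625, 0.207, 0.233, 0.297, 0.463, 0.539, 0.279,
                   0.228, 0.297, 0.586, 0.237, 0.214, 0.129, 0.310, 0.555,
                   0.490),
    bias = c(-0.45, -0.45, 0, -0.45, -0.45, -0.45, -0.45, -0.45,
             -0.45, -0.45, -0.45, -0.45, -0.45, 0.35, -0.45, 0, 0)
  )
  covariates <- dplyr::bind_rows(cond, drug)
  covariates$bias <- covariates$bias * bias_scale
  sim_config(
    seed = seed,
    n_patients = as.integer(n_enrollable) * (as.integer(background_factor) + 1L),
    n_enrollable = n_enrollable,
    hierarchy = list(n_roots = 4L, branching = 3L, depth = 3L),
    covariates = covariates,
    visit_rate = 3,
    n_trials = 202L,
    domain_labels = c("neoplastic", "digestive", "inflammatory",
                      "cardiovascular"),
    n_unmappable = 1L
  )
}

# ---------------------------------------------------------------------------
# Concept hierarchy construction

build_hierarchy <- function(cfg) {
  h <- cfg$hierarchy
  cov <- cfg$covariates
  next_id <- 1001L
  nodes <- tibble(concept_id = integer(), parent_id = integer(),
                  level = integer(), root = integer())
  # level 1: roots (domain anchors)
  roots <- next_id + seq_len(h$n_roots) - 1L
  next_id <- next_id + h$n_roots
  nodes <- dplyr::bind_rows(nodes, tibble(
    concept_id = roots, parent_id = NA_integer_, level = 1L,
    root = seq_len(h$n_roots)))
  prev <- nodes
  for (lev in 2:h$depth) {
    kids <- tibble(
      parent_id = rep(prev$concept_id, each = h$branching),
      root = rep(prev$root, each = h$branching),
      level = lev
    )
    kids$concept_id <- next_id + seq_len(nrow(kids)) - 1L
    next_id <- next_id + nrow(kids)
    nodes <- dplyr::bind_rows(nodes, kids)
    prev <- kids
  }
  # drug classes with product children (flat two-level hierarchy)
  drug_cov <- cov[cov$kind == "drug_class", ]
  n_classes <- nrow(drug_cov)
  products_per_class <- 3L
  class_ids <- if (n_classes > 0) next_id + seq_len(n_classes) - 1L else integer()
  next_id <- next_id + n_classes
  product_ids <- if (n_classes > 0) {
    next_id + seq_len(n_classes * products_per_class) - 1L
  } else integer()

  # concept names: domain labels on roots, covariate names on their anchor
  # concepts, generic names elsewhere
  cond_nodes <- nodes
  cond_nodes$name <- sprintf("condition %d (level %d)",
                             cond_nodes$concept_id, cond_nodes$level)
  lab <- cfg$domain_labels
  cond_nodes$name[seq_along(lab)] <- lab
  leaves <- cond_nodes$concept_id[cond_nodes$level == h$depth]
  cond_cov <- cov[cov$kind == "condition", ]
  anchor_leaves <- leaves[seq_len(nrow(cond_cov))]
  cond_nodes$name[match(anchor_leaves, cond_nodes$concept_id)] <- cond_cov$name

  concept <- dplyr::bind_rows(
    tibble(concept_id = cond_nodes$concept_id, name = cond_nodes$name,
           domain = "Condition"),
    tibble(concept_id = class_ids, name = drug_cov$name, domain = "Drug"),
    tibble(concept_id = product_ids,
           name = sprintf("drug product %d", product_ids),
           domain = "Drug")
  )

  # transitive closure of the condition tree (proper ancestors only)
  parent <- setNames(cond_nodes$parent_id, cond_nodes$concept_id)
  closure <- list()
  for (i in seq_len(nrow(cond_nodes))) {
    node <- cond_nodes$concept_id[i]
    anc <- parent[[as.character(node)]]
    while (!is.na(anc)) {
      closure[[length(closure) + 1L]] <- c(anc, node)
      anc <- parent[[as.character(anc)]]
    }
  }
  ancestry <- if (length(closure) > 0) {
    m <- do.call(rbind, closure)
    tibble(ancestor_id = as.integer(m[, 1]), descendant_id = as.integer(m[, 2]))
  } else {
    tibble(ancestor_id = integer(), descendant_id = integer())
  }
  if (n_classes > 0) {
    ancestry <- dplyr::bind_rows(ancestry, tibble(
      ancestor_id = rep(class_ids, each = products_per_class),
      descendant_id = product_ids))
  }

  cov_defs <- dplyr::bind_rows(
    tibble(name = cond_cov$name, kind = "condition", concept_id = anchor_leaves),
    tibble(name = drug_cov$name, kind = "drug_class", concept_id = class_ids)
  )
  # restore the configured covariate ordering
  cov_defs <- cov_defs[match(cov$name, cov_defs$name), ]

  list(
    concept = concept,
    ancestry = ancestry,
    focus_eligible = cond_nodes$concept_id[cond_nodes$level == 2L],
    focus_root = setNames(cond_nodes$root, cond_nodes$concept_id),
    domain_concepts = setNames(roots[seq_along(lab)], lab),
    covariate_defs = cov_defs,
    drug_products = if (n_classes > 0) {
      split(product_ids, rep(drug_cov$name, each = products_per_class))
    } else list()
  )
}

# ---------------------------------------------------------------------------
# Study simulation

#' Simulate a linked synthetic study
#'
#' Generates the full table bundle consumed by [load_store()] plus ground
#' truth. Enrollment is selected by weighted sampling with person weights
#' `exp(sum of covariate log-odds shifts)`, so a negative shift on a
#' covariate makes it rarer among participants. Every enrolled person in a
#' mappable trial is guaranteed an index-window focus-condition event and a
#' prior-year reassurance event; each background person echoes one
#' participant's index concept and calendar month so matching pools are
#' non-degenerate.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; when given, the store tables,
#'   `covariates.csv`, `domain_concepts.csv`, `ground_truth.json`, and
#'   `config_used.yaml` are written there.
#' @return A list with `store` (validated `cdm_store`), `ground_truth`,
#'   `covariate_defs`, `domain_concepts`, `flags` (person-by-covariate truth
#'   matrix), and `config`.
#' @export
simulate_study <- function(config, dir = NULL) {
  validate_sim_config(config)
  out <- with_rng(config$seed, simulate_study_impl(config))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_store(out$store, dir)
    defs <- out$covariate_defs
    readr::write_csv(defs, file.path(dir, "covariates.csv"), progress = FALSE)
    readr::write_csv(
      tibble(domain = names(out$domain_concepts),
             concept_id = unname(out$domain_concepts)),
      file.path(dir, "domain_concepts.csv"), progress = FALSE)
    gt <- out$ground_truth
    jsonlite::write_json(
      list(
        covariates = gt$covariates,
        enrollable = gt$enrollable,
        trials = tibble(trial_id = gt$trials$trial_id,
                        mappable = gt$trials$mappable,
                        focus_concept_ids = vapply(
                          gt$trials$focus_concept_ids, paste, character(1),
                          collapse = ";")),
        persons = gt$persons
      ),
      file.path(dir, "ground_truth.json"),
      dataframe = "columns", auto_unbox = TRUE, digits = NA, Date = "ISO8601")
    yaml::write_yaml(config_echo(config), file.path(dir, "config_used.yaml"))
    out$paths <- dir
  }
  out
}

config_echo <- function(cfg) {
  list(
    seed = cfg$seed,
    n_patients = cfg$n_patients,
    n_enrollable = cfg$n_enrollable,
    study_start = as.character(cfg$study_start),
    study_end = as.character(cfg$study_end),
    hierarchy = cfg$hierarchy,
    visit_rate = cfg$visit_rate,
    n_trials = cfg$n_trials,
    n_unmappable = cfg$n_unmappable,
    candidate_reassurance_rate = cfg$candidate_reassurance_rate,
    second_enrollment_rate = cfg$second_enrollment_rate,
    index_lag_max = cfg$index_lag_max,
    domain_labels = as.list(cfg$domain_labels),
    covariates = lapply(seq_len(nrow(cfg$covariates)), function(i) {
      as.list(cfg$covariates[i, ])
    })
  )
}

simulate_study_impl <- function(cfg) {
  hier <- build_hierarchy(cfg)
  n <- cfg$n_patients
  cov <- cfg$covariates
  k <- nrow(cov)

  # person-level covariate truth
  flags <- matrix(FALSE, n, k, dimnames = list(NULL, cov$name))
  for (j in seq_len(k)) {
    flags[, j] <- rbinom(n, 1, cov$prevalence[j]) == 1
  }

  # logistic enrollment selection: weight = exp(X %*% bias)
  eta <- as.vector(flags %*% cov$bias)
  weights <- exp(eta - max(eta))
  enrolled_idx <- sort(sample.int(n, cfg$n_enrollable, prob = weights))
  is_enrolled <- rep(FALSE, n)
  is_enrolled[enrolled_idx] <- TRUE

  # trials
  tp <- cfg$trial_params
  n_trials <- cfg$n_trials
  trial_id <- sprintf("NCT%08d", 10000000L + seq_len(n_trials))
  focus1 <- sample(hier$focus_eligible, n_trials, replace = TRUE)
  has_second <- runif(n_trials) < tp$p_second_focus
  focus2 <- sample(hier$focus_eligible, n_trials, replace = TRUE)
  focus <- lapply(seq_len(n_trials), function(i) {
    f <- focus1[i]
    if (has_second[i] && focus2[i] != focus1[i]) f <- c(f, focus2[i])
    as.integer(sort(f))
  })
  mappable <- rep(TRUE, n_trials)
  if (cfg$n_unmappable > 0) {
    unmap <- seq(n_trials, by = -1L, length.out = cfg$n_unmappable)
    mappable[unmap] <- FALSE
    focus[unmap] <- replicate(length(unmap), integer(), simplify = FALSE)
  }
  overall <- pmax(1L, as.integer(round(stats::rlnorm(
    n_trials, tp$enrollment_meanlog, tp$enrollment_sdlog))))
  site <- pmin(overall, 1L + rpois(n_trials, tp$site_mean))
  trials <- tibble(
    trial_id = trial_id,
    focus_concept_ids = focus,
    mappable = mappable,
    phase = sample(names(tp$phase_probs), n_trials, replace = TRUE,
                   prob = tp$phase_probs),
    arms = as.integer(sample(names(tp$arms_probs), n_trials, replace = TRUE,
                             prob = tp$arms_probs)),
    randomized = runif(n_trials) < tp$p_randomized,
    blinded = runif(n_trials) < tp$p_blinded,
    model = sample(names(tp$model_probs), n_trials, replace = TRUE,
                   prob = tp$model_probs),
    industry = runif(n_trials) < tp$p_industry,
    dmc = runif(n_trials) < tp$p_dmc,
    multisite = runif(n_trials) < tp$p_multisite,
    overall_enrollment = overall,
    site_enrollment = site,
    status = sample(names(tp$status_probs), n_trials, replace = TRUE,
                    prob = tp$status_probs)
  )

  # enrollment records and generator-designated index assignments
  n_enr <- cfg$n_enrollable
  enr_trial_idx <- sample.int(n_trials, n_enr, replace = TRUE)
  status_date <- runif_dates(n_enr, cfg$study_start + 731L, cfg$study_end)
  index_lag <- sample.int(cfg$index_lag_max + 1L, n_enr, replace = TRUE) - 1L
  index_date <- status_date - index_lag
  index_concept <- vapply(enr_trial_idx, function(ti) {
    f <- focus[[ti]]
    if (length(f) == 0) NA_integer_ else f[sample.int(length(f), 1)]
  }, integer(1))

  enrollment <- tibble(
    person_id = enrolled_idx,
    trial_id = trial_id[enr_trial_idx],
    status = sample(c("randomized", "completed", "enrolled"), n_enr,
                    replace = TRUE, prob = c(0.5, 0.3, 0.2)),
    status_date = status_date
  )
  # a fraction of participants get a later, second enrollment record
  second <- which(runif(n_enr) < cfg$second_enrollment_rate)
  if (length(second) > 0 && n_trials > 1) {
    other_trial <- vapply(enr_trial_idx[second], function(ti) {
      sample(setdiff(seq_len(n_trials), ti), 1)
    }, integer(1))
    enrollment <- dplyr::bind_rows(enrollment, tibble(
      person_id = enrolled_idx[second],
      trial_id = trial_id[other_trial],
      status = "randomized",
      status_date = status_date[second] +
        sample.int(400L, length(second), replace = TRUE) + 29L
    ))
  }

  # anchors: enrolled persons are anchored at their index date; background
  # persons echo a random mappable-trial participant's index concept + month
  anchor <- rep(cfg$study_start, n)
  anchor[enrolled_idx] <- index_date
  bg_idx <- which(!is_enrolled)
  echo_ok <- which(!is.na(index_concept))
  echo_events <- NULL
  reassurance_bg <- NULL
  if (length(bg_idx) > 0 && length(echo_ok) > 0) {
    tgt <- echo_ok[sample.int(length(echo_ok), length(bg_idx), replace = TRUE)]
    tgt_month <- as.Date(format(index_date[tgt], "%Y-%m-01"))
    month_len <- as.integer(
      (as.Date(format(tgt_month + 31L, "%Y-%m-01")) - tgt_month))
    echo_date <- tgt_month +
      floor(runif(length(bg_idx)) * month_len)
    anchor[bg_idx] <- echo_date
    echo_events <- tibble(
      person_id = bg_idx,
      concept_id = index_concept[tgt],
      event_date = echo_date
    )
    has_reass <- runif(length(bg_idx)) < cfg$candidate_reassurance_rate
    reassurance_bg <- tibble(
      person_id = bg_idx[has_reass],
      concept_id = index_concept[tgt][has_reass],
      event_date = echo_date[has_reass] -
        (sample.int(336L, sum(has_reass), replace = TRUE) + 29L)
    )
  } else if (length(bg_idx) > 0) {
    anchor[bg_idx] <- runif_dates(length(bg_idx), cfg$study_start + 731L,
                                  cfg$study_end)
  }

  # forced index + reassurance events for enrolled persons in mappable trials
  forced_ok <- which(!is.na(index_concept))
  forced_index <- tibble(
    person_id = enrolled_idx[forced_ok],
    concept_id = index_concept[forced_ok],
    event_date = index_date[forced_ok]
  )
  forced_reass <- tibble(
    person_id = enrolled_idx[forced_ok],
    concept_id = index_concept[forced_ok],
    event_date = index_date[forced_ok] -
      (sample.int(336L, length(forced_ok), replace = TRUE) + 29L)
  )

  # covariate events, dated in [anchor - 365, anchor - 1]
  true_cells <- which(flags, arr.ind = TRUE)
  cell_person <- true_cells[, 1]
  cell_cov <- true_cells[, 2]
  cell_date <- anchor[cell_person] -
    sample.int(365L, length(cell_person), replace = TRUE)
  cond_cells <- cov$kind[cell_cov] == "condition"
  cond_events <- tibble(
    person_id = cell_person[cond_cells],
    concept_id = hier$covariate_defs$concept_id[cell_cov[cond_cells]],
    event_date = cell_date[cond_cells]
  )
  drug_cell_cov <- cell_cov[!cond_cells]
  drug_events <- if (any(!cond_cells)) {
    prod_mat <- do.call(cbind, hier$drug_products)
    pos <- match(cov$name[drug_cell_cov], colnames(prod_mat))
    row_pick <- sample.int(nrow(prod_mat), length(pos), replace = TRUE)
    tibble(
      person_id = cell_person[!cond_cells],
      concept_id = as.integer(prod_mat[cbind(row_pick, pos)]),
      event_date = cell_date[!cond_cells]
    )
  } else {
    tibble(person_id = integer(), concept_id = integer(),
           event_date = as.Date(character()))
  }

  condition_occurrence <- dplyr::bind_rows(
    cond_events, forced_index, forced_reass, echo_events, reassurance_bg) |>
    arrange(.data$person_id, .data$event_date, .data$concept_id)

  # visits in [anchor - 365, anchor - 1], Poisson count per person-year
  n_visits <- rpois(n, cfg$visit_rate)
  visit_person <- rep(seq_len(n), n_visits)
  visit_occurrence <- tibble(
    person_id = visit_person,
    visit_date = anchor[visit_person] -
      sample.int(365L, length(visit_person), replace = TRUE)
  ) |>
    arrange(.data$person_id, .data$visit_date)

  # demographics; birth precedes every generated event by construction
  age <- sample(3:90, n, replace = TRUE,
                prob = c(rep(1, 15), rep(3, 47), rep(2, 26)))
  person <- tibble(
    person_id = seq_len(n),
    birth_date = anchor - as.integer(age * 365.25) -
      sample.int(200L, n, replace = TRUE),
    sex = sample(SEX_CODES, n, replace = TRUE, prob = c(0.55, 0.45)),
    race = sample(RACE_CODES, n, replace = TRUE,
                  prob = c(0.45, 0.10, 0.05, 0.40)),
    ethnicity = sample(ETHNICITY_CODES, n, replace = TRUE,
                       prob = c(0.15, 0.45, 0.40))
  )

  store <- cdm_store(
    person = person,
    condition_occurrence = condition_occurrence,
    drug_exposure = drug_events |>
      arrange(.data$person_id, .data$event_date, .data$concept_id),
    visit_occurrence = visit_occurrence,
    concept = hier$concept,
    concept_ancestor = hier$ancestry |>
      arrange(.data$ancestor_id, .data$descendant_id),
    enrollment = enrollment |>
      arrange(.data$person_id, .data$status_date, .data$trial_id),
    trials = trials
  )

  ground_truth <- list(
    covariates = tibble(
      name = cov$name,
      configured_prevalence = cov$prevalence,
      bias = cov$bias,
      prevalence_enrolled = unname(colMeans(flags[enrolled_idx, , drop = FALSE])),
      prevalence_nonenrolled = unname(colMeans(flags[bg_idx, , drop = FALSE]))
    ),
    enrollable = tibble(
      person_id = enrolled_idx,
      trial_id = trial_id[enr_trial_idx],
      mappable = mappable[enr_trial_idx],
      status_date = status_date,
      index_concept_id = index_concept,
      index_date = index_date
    ),
    trials = trials[c("trial_id", "mappable", "focus_concept_ids")],
    persons = tibble(
      person_id = seq_len(n),
      anchor_date = anchor,
      enrolled = is_enrolled
    )
  )

  list(store = store, ground_truth = ground_truth,
       covariate_defs = hier$covariate_defs,
       domain_concepts = hier$domain_concepts,
       flags = flags, config = cfg)
}
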