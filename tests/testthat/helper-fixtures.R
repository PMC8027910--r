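# Hand-built fixture store and independent oracles used across the suite.

# Concept layout:
#   10 (root "cardiometabolic")
#     11 -> 111, 112
#     12 -> 121
#   20 (root "neoplastic"), leaf-free
#   drug class 50 -> products 51, 52
tiny_concepts <- function() {
  tibble::tibble(
    concept_id = c(10L, 11L, 12L, 111L, 112L, 121L, 20L, 50L, 51L, 52L),
    name = c("cardiometabolic disease", "heart disease", "kidney disease",
             "heart failure", "ischemic heart disease", "renal impairment",
             "neoplastic disease", "beta blocking agents",
             "metoprolol", "atenolol"),
    domain = c(rep("Condition", 7), rep("Drug", 3))
  )
}

tiny_ancestry <- function() {
  tibble::tibble(
    ancestor_id   = c(10L, 10L, 10L, 10L, 10L, 11L, 11L, 12L, 50L, 50L),
    descendant_id = c(11L, 12L, 111L, 112L, 121L, 111L, 112L, 121L, 51L, 52L)
  )
}

# Four screened persons exercising every selection outcome, plus candidate
# persons for the matching stage:
#   p1 selected (index = concept 111 five days before status, reassured)
#   p2 excluded: no qualifying code in the index window
#   p3 excluded: qualifying code but no prior-year reassurance
#   p4 excluded: enrolled in the unmappable trial TU
#   p5, p6 non-enrolled candidates carrying code 111 in p1's index month
#   p7 non-enrolled but failing candidate reassurance
make_tiny_store <- function() {
  status1 <- as.Date("2015-06-20")
  person <- tibble::tibble(
    person_id = 1:7,
    birth_date = as.Date(c("1950-01-15", "1980-03-02", "2000-07-09",
                           "1965-11-30", "1948-05-05", "1990-12-25",
                           "1970-01-01")),
    sex = c("male", "female", "male", "female", "male", "female", "male"),
    race = c("white", "black", "other", "unknown", "white", "white", "black"),
    ethnicity = c("not_hispanic", "hispanic", "unknown", "not_hispanic",
                  "unknown", "hispanic", "not_hispanic")
  )
  condition_occurrence <- tibble::tibble(
    person_id = c(1L, 1L, 1L,          # index candidates + reassurance
                  2L,                  # code outside window only
                  3L,                  # code in window, no reassurance
                  4L, 4L,              # unmappable trial, events irrelevant
                  5L, 5L,              # candidate + reassurance
                  6L, 6L,              # candidate + reassurance (descendant)
                  7L),                 # candidate without reassurance
    concept_id = c(111L, 111L, 111L,
                   111L,
                   112L,
                   111L, 111L,
                   111L, 111L,
                   111L, 112L,
                   111L),
    event_date = as.Date(c("2015-06-15", "2014-08-24", "2014-09-01",
                           "2014-06-19",          # 366 d before status1
                           "2015-06-01",
                           "2015-06-10", "2014-10-01",
                           "2015-06-05", "2014-11-20",
                           "2015-06-25", "2015-01-10",
                           "2015-06-08"))
  )
  drug_exposure <- tibble::tibble(
    person_id = c(1L, 5L),
    concept_id = c(51L, 52L),
    event_date = as.Date(c("2015-03-01", "2015-02-14"))
  )
  visit_occurrence <- tibble::tibble(
    person_id = c(1L, 1L, 5L, 5L, 6L),
    visit_date = as.Date(c("2015-01-10", "2014-12-01",
                           "2015-02-01", "2014-07-07",
                           "2015-03-03"))
  )
  enrollment <- tibble::tibble(
    person_id = c(1L, 2L, 3L, 4L),
    trial_id = c("T1", "T1", "T1", "TU"),
    status = "randomized",
    status_date = as.Date(c("2015-06-20", "2015-06-20", "2015-06-20",
                            "2015-06-20"))
  )
  trials <- tibble::tibble(
    trial_id = c("T1", "TB", "TU"),
    focus_concept_ids = list(11L, 12L, integer()),
    mappable = c(TRUE, TRUE, FALSE),
    phase = c("phase 2", "phase 1/phase 2", "phase 3"),
    arms = c(2L, 1L, 4L),
    randomized = c(TRUE, FALSE, TRUE),
    blinded = c(TRUE, FALSE, FALSE),
    model = c("parallel", "single_group", "other"),
    industry = c(TRUE, TRUE, FALSE),
    dmc = c(TRUE, FALSE, TRUE),
    multisite = c(TRUE, FALSE, TRUE),
    overall_enrollment = c(120L, 49L, 500L),
    site_enrollment = c(12L, 4L, 20L),
    status = c("Completed", "Recruiting", "Terminated")
  )
  cdm_store(person, condition_occurrence, drug_exposure, visit_occurrence,
            tiny_concepts(), tiny_ancestry(), enrollment, trials)
}

# Independent Fisher oracle: full hypergeometric enumeration of 2x2 tables,
# two-sided by summing all tables no more probable than the observed one
# (with the conventional 1e-7 relative tolerance for ties).
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
  x <- lo:hi
  probs <- stats::dhyper(x, c1, n - c1, r1)
  sum(probs[probs <= probs[x == a] * (1 + 1e-7)])
}

# Brute-force bipartite matching oracle: enumerate all assignments of
# participants to candidate persons, record the maximum matching size and
# the union of participants matched in at least one maximum matching.
oracle_max_matchable <- function(pools) {
  n <- length(pools)
  best_size <- 0L
  matchable <- logical(n)
  recurse <- function(i, used, matched) {
    if (i > n) {
      size <- sum(matched)
      if (size > best_size) {
        best_size <<- size
        matchable <<- logical(n)
      }
      if (size == best_size) {
        matchable[matched] <<- TRUE
      }
      return(invisible())
    }
    recurse(i + 1L, used, matched)      # leave participant i unmatched
    for (c in setdiff(pools[[i]], used)) {
      m <- matched; m[i] <- TRUE
      recurse(i + 1L, c(used, c), m)
    }
  }
  recurse(1L, integer(), logical(n))
  list(size = best_size, matchable = which(matchable))
}

# Random small matching instance: pools of candidate person ids (possibly
# empty, with deliberate contention through shared candidates).
random_matching_instance <- function(n_part, n_cand_persons) {
  pools <- lapply(seq_len(n_part), function(i) {
    k <- sample(0:min(3, n_cand_persons), 1)
    sort(sample.int(n_cand_persons, k))
  })
  pools
}
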