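# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (double loops, pairwise enumeration) so they cannot
# share a defect with the vectorized implementations they check.

library(data.table)

# the five-patient toy cohort used throughout the association tests
toy_episodes <- function() {
  data.table(
    patient_id = paste0("P", 1:5),
    referral_date = as.Date("2019-06-01") + 0:4,
    visit_date = as.Date("2019-07-01") + 0:4,
    query_items = list("X", c("X", "Y"), "Y", "X", "Y"),
    target_items = list(c("L1", "L2"), "L1", "L2", "L1", character(0))
  )
}

# brute-force association counts: explicit loop over patients and pairs
oracle_matrix <- function(episodes) {
  n <- nrow(episodes)
  qc <- list(); tc <- list(); pc <- list()
  for (i in seq_len(n)) {
    q <- unique(episodes$query_items[[i]])
    t <- unique(episodes$target_items[[i]])
    for (a in q) qc[[a]] <- (qc[[a]] %||% 0L) + 1L
    for (b in t) tc[[b]] <- (tc[[b]] %||% 0L) + 1L
    for (a in q) for (b in t) {
      key <- paste(a, b, sep = "\r")
      pc[[key]] <- (pc[[key]] %||% 0L) + 1L
    }
  }
  list(n_cohort = n,
       query_counts = unlist(qc),
       target_counts = unlist(tc),
       pair_counts = pc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# compare an assoc_matrix against the oracle, exactly
expect_matrix_equals_oracle <- function(m, episodes) {
  o <- oracle_matrix(episodes)
  expect_identical(m$n_cohort, o$n_cohort)
  expect_identical(as.integer(m$query_counts[sort(names(o$query_counts))]),
                   as.integer(o$query_counts[sort(names(o$query_counts))]))
  expect_identical(sort(names(m$query_counts)), sort(names(o$query_counts)))
  expect_identical(as.integer(m$target_counts[sort(names(o$target_counts))]),
                   as.integer(o$target_counts[sort(names(o$target_counts))]))
  expect_identical(sort(names(m$target_counts)), sort(names(o$target_counts)))
  impl_pairs <- m$pair_counts[n_ab > 0]
  expect_identical(nrow(impl_pairs), length(o$pair_counts))
  for (k in names(o$pair_counts)) {
    ab <- strsplit(k, "\r", fixed = TRUE)[[1]]
    expect_identical(as.integer(impl_pairs[query == ab[1] & target == ab[2], n_ab]),
                     as.integer(o$pair_counts[[k]]))
  }
}

# random small episode table for property tests
random_episodes <- function(seed, max_patients = 50, max_items = 20) {
  set.seed(seed)
  n <- sample(2:max_patients, 1)
  qv <- paste0("Q", seq_len(sample(2:max_items, 1)))
  tv <- paste0("T", seq_len(sample(2:max_items, 1)))
  data.table(
    patient_id = sprintf("P%03d", seq_len(n)),
    referral_date = as.Date("2018-01-01") + sample(0:700, n, TRUE),
    visit_date = as.Date("2018-02-01") + sample(0:700, n, TRUE),
    query_items = lapply(seq_len(n), function(i)
      sample(qv, sample(0:min(5, length(qv)), 1))),
    target_items = lapply(seq_len(n), function(i)
      sample(tv, sample(0:min(5, length(tv)), 1)))
  )
}

# AUC by explicit enumeration of all positive-negative pairs, midrank ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# small well-formed event table for IO tests
make_event_table <- function(n = 50, seed = 42) {
  set.seed(seed)
  data.table(
    patient_id = sprintf("P%02d", sample(1:10, n, TRUE)),
    concept_id = sample(c("DX_A", "DX_B", "LAB_T", "MED_Z"), n, TRUE),
    domain = NA_character_,
    event_date = as.Date("2019-01-01") + sample(0:600, n, TRUE),
    numeric_value = NA_real_, ref_low = NA_real_, ref_high = NA_real_
  )[, domain := fifelse(concept_id == "LAB_T", "measurement",
               fifelse(concept_id == "MED_Z", "medication", "condition"))][
    concept_id == "LAB_T",
    `:=`(numeric_value = round(runif(.N, 1, 9), 3), ref_low = 3, ref_high = 6)][]
}
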