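#' Configuration for the synthetic referral-cohort generator
#'
#' @description
#' Describes a synthetic pediatric specialty referral cohort with known
#' ground truth, shaped like the OMOP-lite tables the rest of the package
#' consumes. Each simulated patient receives one (sometimes two) latent
#' specialty conditions; the condition plants
#'
#' * a coded diagnosis on the pre-referral chart,
#' * sometimes a characteristic abnormal lab result (e.g. a high TSH for the
#'   hypothyroidism-like condition), and
#' * conditional probabilities `P(order B | condition)` for the workup
#'   orders the specialist places at the first visit. Multi-condition
#'   patients combine their conditions' order probabilities by noisy-OR, so
#'   ground truth stays well defined.
#'
#' On top of the signal, every chart accrues high-prevalence primary-care
#' noise items (common diagnoses and medications with identical prevalence
#' inside and outside the cohort, hence zero predictive signal and planted
#' relative risk 1), routine pre-referral screening labs, and stale events
#' older than the query lookback window. A small fraction of visit delays
#' exceeds the six-month wait window so episode exclusion is exercised.
#'
#' Defaults are desk scale -- 2500 patients (an expected 2000 referred
#' before the test year and 500 during it), 50,000 background outpatients,
#' and roughly 200 vocabulary items -- large enough for stable co-occurrence
#' statistics yet quick to regenerate.
#'
#' @param n_patients referral cohort size (train + test).
#' @param n_outpt outpatient background population size (patients outside
#'   the referral cohort).
#' @param n_conditions number of latent specialty conditions.
#' @param n_labs,n_generic_labs number of orderable labs, of which the first
#'   `n_generic_labs` are generic screening panels ordered for everyone at
#'   `baseline_order_rate` and commonly seen before referral.
#' @param n_imaging number of orderable imaging procedures.
#' @param n_noise_conditions,n_noise_meds counts of specialty-irrelevant
#'   primary-care noise items.
#' @param noise_prevalence_range prevalence range for noise items (spread
#'   evenly across items; identical inside and outside the cohort).
#' @param year_range first and last referral year; the last year is the
#'   held-out test year.
#' @param p_test_year fraction of patients referred in the test year.
#' @param lookback_days query window length used when dating chart events.
#' @param mean_visit_delay mean referral-to-visit delay in days (geometric,
#'   plus a 7-day floor); about 2% of delays exceed 183 days.
#' @param p_second_condition probability a patient carries a second latent
#'   condition.
#' @param p_condition_coded probability an assigned condition is coded on
#'   the pre-referral chart.
#' @param p_abnormal_lab_query probability an assigned condition plants its
#'   characteristic abnormal lab result on the pre-referral chart.
#' @param p_generic_query per-lab probability a generic screening lab
#'   (mostly normal) appears on the pre-referral chart.
#' @param baseline_order_rate probability each generic lab is ordered at the
#'   specialty visit regardless of condition.
#' @param profile_probs planted `P(order | condition)` for each condition's
#'   block of specific labs, best first.
#' @param profile_stride offset between consecutive conditions' lab blocks;
#'   smaller strides share more labs between conditions.
#' @param p_imaging planted probability of each condition's characteristic
#'   imaging order.
#' @param rr_enrichment planted relative risk of condition diagnoses and
#'   abnormal lab results (cohort prevalence over outside-cohort
#'   prevalence).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 2500,
                       n_outpt = 50000,
                       n_conditions = 12,
                       n_labs = 40,
                       n_generic_labs = 5,
                       n_imaging = 10,
                       n_noise_conditions = 40,
                       n_noise_meds = 30,
                       noise_prevalence_range = c(0.05, 0.6),
                       year_range = c(2015, 2020),
                       p_test_year = 0.2,
                       lookback_days = 183,
                       mean_visit_delay = 45,
                       p_second_condition = 0.2,
                       p_condition_coded = 0.9,
                       p_abnormal_lab_query = 0.5,
                       p_generic_query = 0.3,
                       baseline_order_rate = 0.25,
                       profile_probs = c(0.8, 0.6, 0.45, 0.3),
                       profile_stride = 3,
                       p_imaging = 0.3,
                       rr_enrichment = 20) {
  stopifnot(n_patients >= 1, n_outpt > n_patients,
            diff(year_range) >= 1, p_test_year >= 0, p_test_year < 1,
            all(profile_probs >= 0 & profile_probs <= 1),
            baseline_order_rate >= 0 & baseline_order_rate <= 1,
            p_second_condition >= 0 & p_second_condition <= 1,
            rr_enrichment > 0, n_labs > n_generic_labs)
  cf <- as.list(environment())

  K <- n_conditions
  cf$condition_concepts <- sprintf("ENDO_C%02d", seq_len(K))
  cf$lab_concepts <- sprintf("LAB_%02d", seq_len(n_labs))
  cf$generic_labs <- cf$lab_concepts[seq_len(n_generic_labs)]
  specific <- cf$lab_concepts[-seq_len(n_generic_labs)]
  cf$imaging_concepts <- sprintf("IMG_%02d", seq_len(n_imaging))
  cf$noise_concepts <- c(sprintf("PRIM_C%02d", seq_len(n_noise_conditions)),
                         sprintf("MED_%02d", seq_len(n_noise_meds)))
  cf$noise_domains <- c(rep("condition", n_noise_conditions),
                        rep("medication", n_noise_meds))
  n_noise <- length(cf$noise_concepts)
  cf$noise_prevalence <- seq(noise_prevalence_range[1],
                             noise_prevalence_range[2], length.out = n_noise)

  # lab reference ranges: distinct per lab, all positive
  cf$lab_ref <- data.table(concept_id = cf$lab_concepts,
                           ref_low = 10 * seq_len(n_labs),
                           ref_high = 10 * seq_len(n_labs) + 8)

  # planted P(order | condition) profile over all target concepts
  targets <- c(cf$lab_concepts, cf$imaging_concepts)
  P <- matrix(0, K, length(targets), dimnames = list(cf$condition_concepts,
                                                     targets))
  n_spec <- length(specific)
  width <- length(profile_probs)
  abn_lab <- character(K)
  abn_dir <- character(K)
  for (j in seq_len(K)) {
    block <- specific[((j - 1) * profile_stride + seq_len(width) - 1) %% n_spec + 1]
    P[j, block] <- profile_probs
    P[j, cf$imaging_concepts[(j - 1) %% n_imaging + 1]] <- p_imaging
    abn_lab[j] <- block[1]
    abn_dir[j] <- if (j %% 2 == 1) "high" else "low"
  }
  cf$profile <- P
  cf$abnormal_lab <- abn_lab
  cf$abnormal_dir <- abn_dir
  cf$baseline <- setNames(
    ifelse(targets %in% cf$generic_labs, baseline_order_rate, 0), targets)

  # outpatient prevalences (outside the referral cohort)
  p_has_cond <- (1 + p_second_condition) / K
  cohort_cond_prev <- p_has_cond * p_condition_coded
  cohort_abn_prev <- p_has_cond * p_abnormal_lab_query
  lab_idx <- seq_len(n_labs)
  p_out_order <- ifelse(
    cf$lab_concepts %in% cf$generic_labs,
    0.15 + 0.02 * lab_idx,
    0.002 + 0.03 * ((lab_idx * 7) %% 11) / 11)
  img_idx <- seq_len(n_imaging)
  bg <- rbind(
    data.table(item = cf$condition_concepts,
               p_out = cohort_cond_prev / rr_enrichment),
    data.table(item = item_key(abn_lab, abn_dir),
               p_out = cohort_abn_prev / rr_enrichment),
    data.table(item = item_key(cf$generic_labs, "normal"),
               p_out = 0.9 * p_generic_query / 1.35),
    data.table(item = item_key(cf$generic_labs, "high"),
               p_out = 0.1 * p_generic_query / 1.35),
    data.table(item = cf$noise_concepts, p_out = cf$noise_prevalence),
    data.table(item = cf$lab_concepts, p_out = p_out_order),
    data.table(item = cf$imaging_concepts,
               p_out = 0.001 + 0.009 * ((img_idx * 3) %% 7) / 7)
  )
  cf$background_catalog <- unique(bg, by = "item")
  cf$true_rr <- c(setNames(rep(rr_enrichment, K), cf$condition_concepts),
                  setNames(rep(rr_enrichment, K), item_key(abn_lab, abn_dir)),
                  setNames(rep(1, n_noise), cf$noise_concepts))
  structure(cf, class = "sim_config")
}

#' Generate a synthetic referral cohort with known ground truth
#'
#' Draws the three OMOP-lite tables ([read_events()], [read_referrals()],
#' [read_visits()] layouts) plus the planted truth, fully deterministically
#' for a given seed. See [sim_config()] for the generative model.
#'
#' @param config a `sim_config`.
#' @param seed integer seed.
#' @return a list with `events`, `referrals`, `visits` (`data.table`s) and
#'   `truth`: planted `condition_profiles` (`P(order | condition)` matrix),
#'   `baseline_rates`, `true_rr`, per-patient latent `conditions`, the
#'   per-patient order probabilities `p_targets`, and `optimal_topk` (the
#'   best possible top-4 per patient).
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(seed)
  n <- cf$n_patients
  pid <- sprintf("P%05d", seq_len(n))
  K <- cf$n_conditions

  # referral and visit dates; exact train/test-year allocation
  train_years <- cf$year_range[1]:(cf$year_range[2] - 1)
  n_test <- round(n * cf$p_test_year)
  year_vec <- sample(c(rep(train_years, length.out = n - n_test),
                       rep(cf$year_range[2], n_test)))
  referral_date <- as.Date(sprintf("%d-01-01", year_vec)) +
    sample(0:364, n, replace = TRUE)
  delay <- 7 + rgeom(n, 1 / cf$mean_visit_delay)
  visit_date <- referral_date + delay

  # latent conditions: one always, a second sometimes (distinct)
  cond1 <- sample.int(K, n, replace = TRUE)
  has2 <- runif(n) < cf$p_second_condition
  cond2 <- ifelse(has2, (cond1 - 1 + sample.int(K - 1, n, replace = TRUE)) %% K + 1,
                  NA_integer_)

  ev <- list()
  add <- function(dt) ev[[length(ev) + 1L]] <<- dt
  qdate <- function(idx) referral_date[idx] - sample(0:cf$lookback_days,
                                                     length(idx), replace = TRUE)
  ref_of <- function(concepts) cf$lab_ref[match(concepts, concept_id)]

  # coded condition diagnoses on the pre-referral chart
  for (which_cond in list(cond1, ifelse(has2, cond2, NA_integer_))) {
    coded <- which(!is.na(which_cond) & runif(n) < cf$p_condition_coded)
    if (length(coded)) {
      add(data.table(patient_id = pid[coded],
                     concept_id = cf$condition_concepts[which_cond[coded]],
                     domain = "condition", event_date = qdate(coded),
                     numeric_value = NA_real_, ref_low = NA_real_,
                     ref_high = NA_real_))
    }
  }

  # characteristic abnormal lab results
  for (which_cond in list(cond1, ifelse(has2, cond2, NA_integer_))) {
    hit <- which(!is.na(which_cond) & runif(n) < cf$p_abnormal_lab_query)
    if (length(hit)) {
      cidx <- which_cond[hit]
      labs <- cf$abnormal_lab[cidx]
      rr <- ref_of(labs)
      dir <- cf$abnormal_dir[cidx]
      value <- ifelse(dir == "high",
                      runif(length(hit), rr$ref_high * 1.05, rr$ref_high * 1.5),
                      runif(length(hit), rr$ref_low * 0.5, rr$ref_low * 0.95))
      add(data.table(patient_id = pid[hit], concept_id = labs,
                     domain = "measurement", event_date = qdate(hit),
                     numeric_value = value, ref_low = rr$ref_low,
                     ref_high = rr$ref_high))
    }
  }

  # routine pre-referral screening labs, mostly normal
  for (lab in cf$generic_labs) {
    hit <- which(runif(n) < cf$p_generic_query)
    if (length(hit)) {
      rr <- ref_of(rep(lab, length(hit)))
      abn <- runif(length(hit)) < 0.1
      value <- ifelse(abn, runif(length(hit), rr$ref_high * 1.05, rr$ref_high * 1.4),
                      runif(length(hit), rr$ref_low, rr$ref_high))
      add(data.table(patient_id = pid[hit], concept_id = lab,
                     domain = "measurement", event_date = qdate(hit),
                     numeric_value = value, ref_low = rr$ref_low,
                     ref_high = rr$ref_high))
    }
  }

  # primary-care noise items (zero signal, planted RR = 1)
  for (i in seq_along(cf$noise_concepts)) {
    hit <- which(runif(n) < cf$noise_prevalence[i])
    if (length(hit)) {
      add(data.table(patient_id = pid[hit], concept_id = cf$noise_concepts[i],
                     domain = cf$noise_domains[i], event_date = qdate(hit),
                     numeric_value = NA_real_, ref_low = NA_real_,
                     ref_high = NA_real_))
    }
  }

  # stale events older than the lookback window (must never enter queries)
  stale_item <- sample.int(length(cf$noise_concepts), n, replace = TRUE)
  add(data.table(patient_id = pid,
                 concept_id = cf$noise_concepts[stale_item],
                 domain = cf$noise_domains[stale_item],
                 event_date = referral_date - cf$lookback_days - 17 -
                   sample(0:200, n, replace = TRUE),
                 numeric_value = NA_real_, ref_low = NA_real_,
                 ref_high = NA_real_))

  # specialist workup orders at the visit: noisy-OR over latent conditions
  targets <- colnames(cf$profile)
  p0 <- matrix(cf$baseline, n, length(targets), byrow = TRUE)
  a1 <- cf$profile[cond1, , drop = FALSE]
  a2 <- matrix(0, n, length(targets))
  if (any(has2)) a2[has2, ] <- cf$profile[cond2[has2], , drop = FALSE]
  p_targets <- 1 - (1 - p0) * (1 - a1) * (1 - a2)
  ordered <- matrix(runif(n * length(targets)), n, length(targets)) < p_targets
  ord_idx <- which(ordered, arr.ind = TRUE)
  ord_concepts <- targets[ord_idx[, 2]]
  is_lab <- ord_concepts %in% cf$lab_concepts
  # lab orders come back with results: mostly normal, occasionally flagged
  lab_rr <- ref_of(ord_concepts)
  lab_val <- rep(NA_real_, nrow(ord_idx))
  if (any(is_lab)) {
    nl <- sum(is_lab)
    lo <- lab_rr$ref_low[is_lab]
    hi <- lab_rr$ref_high[is_lab]
    u <- runif(nl)
    lab_val[is_lab] <- ifelse(u < 0.85, runif(nl, lo, hi),
                       ifelse(u < 0.95, runif(nl, hi * 1.05, hi * 1.4),
                              runif(nl, lo * 0.55, lo * 0.95)))
  }
  add(data.table(patient_id = pid[ord_idx[, 1]],
                 concept_id = ord_concepts,
                 domain = ifelse(is_lab, "measurement", "procedure"),
                 event_date = visit_date[ord_idx[, 1]],
                 numeric_value = lab_val,
                 ref_low = ifelse(is_lab, lab_rr$ref_low, NA_real_),
                 ref_high = ifelse(is_lab, lab_rr$ref_high, NA_real_)))

  events <- rbindlist(ev)
  setorder(events, patient_id, event_date, concept_id)

  dimnames(p_targets) <- list(pid, targets)
  truth <- list(
    condition_profiles = cf$profile,
    baseline_rates = cf$baseline,
    true_rr = cf$true_rr,
    conditions = data.table(patient_id = pid, condition_1 = cond1,
                            condition_2 = cond2),
    p_targets = p_targets,
    optimal_topk = apply(p_targets, 1, function(p)
      names(sort(p, decreasing = TRUE))[1:4], simplify = FALSE)
  )
  list(
    events = events[],
    referrals = data.table(patient_id = pid, referral_date = referral_date,
                           encounter_id = sprintf("E%05d", seq_len(n))),
    visits = data.table(patient_id = pid, visit_date = visit_date),
    truth = truth
  )
}

#' Generate outpatient background statistics with planted enrichment
#'
#' Draws, for every vocabulary item, the number of patients carrying it in a
#' background population of `n_outpt` outpatients *outside* the referral
#' cohort, as a binomial with the configured outside-cohort prevalence.
#' Condition diagnoses and characteristic abnormal labs are planted
#' `rr_enrichment` times rarer outside than inside the cohort; noise items
#' have identical prevalence (planted relative risk 1).
#'
#' @param config a `sim_config`.
#' @param seed integer seed.
#' @return a `background_stats` object.
#' @export
generate_background <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  cat_ <- config$background_catalog
  counts <- rbinom(nrow(cat_), config$n_outpt, pmin(cat_$p_out, 1))
  background_stats(setNames(counts, cat_$item), config$n_outpt)
}
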