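#' Assemble referral episodes from event, referral, and visit tables
#'
#' A referral episode is the unit of analysis: one patient's referral order
#' plus their first specialty visit within the allowed wait window. Query
#' items are the patient's clinical items dated in the closed interval
#' `[referral_date - lookback_days, referral_date]`; target items are the
#' laboratory and imaging orders (domains `measurement` and `procedure`)
#' dated on the visit day. Both are deduplicated sets. Orders are identified
#' by concept only -- the specialist orders "TSH", not "TSH:high" -- so
#' target keys carry no abnormality qualifier even when the stored event
#' does. Patients whose referral has no visit within `max_wait_days` are
#' excluded, and a patient with several qualifying referrals contributes only
#' the earliest one.
#'
#' @param events categorized event table (see [categorize_events()]),
#'   typically after [filter_rare_items()].
#' @param referrals `data.table` with `patient_id`, `referral_date`.
#' @param visits `data.table` with `patient_id`, `visit_date`.
#' @param lookback_days length of the query window before the referral, in
#'   days (default 183, i.e. six months).
#' @param max_wait_days maximum referral-to-visit delay, in days (default 183).
#' @return a `data.table` with one row per episode: `patient_id`,
#'   `referral_date`, `visit_date`, and list columns `query_items`,
#'   `target_items` (character vectors of item keys).
#' @export
build_episodes <- function(events, referrals, visits,
                           lookback_days = 183, max_wait_days = 183) {
  ev <- as.data.table(events)
  refs <- as.data.table(referrals)
  vis <- as.data.table(visits)
  .check_columns(refs, c("patient_id", "referral_date"), "referrals")
  .check_columns(vis, c("patient_id", "visit_date"), "visits")
  .check_columns(ev, c("patient_id", "item_key", "domain", "event_date"),
                 "categorized events")
  if (nrow(refs) == 0) {
    warning("empty referral table: no episodes built")
    return(data.table(patient_id = character(), referral_date = as.Date(character()),
                      visit_date = as.Date(character()),
                      query_items = list(), target_items = list()))
  }
  refs <- copy(refs)[, referral_date := as.Date(referral_date)]
  vis <- copy(vis)[, visit_date := as.Date(visit_date)]

  pairs <- merge(refs[, .(patient_id, referral_date)],
                 vis[, .(patient_id, visit_date)],
                 by = "patient_id", allow.cartesian = TRUE)
  pairs <- pairs[visit_date >= referral_date &
                   visit_date - referral_date <= max_wait_days]
  if (nrow(pairs) == 0) {
    warning("no referral has a specialty visit within ", max_wait_days, " days")
    return(data.table(patient_id = character(), referral_date = as.Date(character()),
                      visit_date = as.Date(character()),
                      query_items = list(), target_items = list()))
  }
  setorder(pairs, patient_id, referral_date, visit_date)
  # earliest qualifying referral per patient, then its first visit
  episodes <- pairs[, .SD[1], by = patient_id]

  qev <- merge(ev[, .(patient_id, item_key, domain, event_date)],
               episodes[, .(patient_id, referral_date, visit_date)],
               by = "patient_id", allow.cartesian = TRUE)
  qkeys <- qev[event_date >= referral_date - lookback_days &
                 event_date <= referral_date,
               .(items = list(sort(unique(item_key)))), by = patient_id]
  tkeys <- qev[event_date == visit_date & domain %in% c("measurement", "procedure"),
               .(items = list(sort(unique(sub(":.*$", "", item_key))))),
               by = patient_id]

  episodes[, query_items := list(list(character(0)))]
  episodes[, target_items := list(list(character(0)))]
  episodes[qkeys, query_items := i.items, on = "patient_id"]
  episodes[tkeys, target_items := i.items, on = "patient_id"]
  setorder(episodes, patient_id)
  episodes[]
}

#' Split referral episodes into temporal train and test sets
#'
#' Episodes whose referral predates `test_year` form the training set and
#' those referred during `test_year` the test set, so the model is always
#' evaluated on referrals from after its training period. Episodes dated
#' after `test_year` indicate a misconfigured split and raise an error.
#'
#' @param episodes episode table from [build_episodes()].
#' @param test_year calendar year of the held-out test set (default 2020).
#' @return a list with `train` and `test` episode tables.
#' @export
split_by_year <- function(episodes, test_year = 2020) {
  ep <- as.data.table(episodes)
  .check_columns(ep, "referral_date", "episodes")
  yr <- as.integer(format(as.Date(ep$referral_date), "%Y"))
  if (any(yr > test_year)) {
    stop("episode referral dated after test year ", test_year,
         ": configuration error")
  }
  train <- ep[yr < test_year]
  test <- ep[yr == test_year]
  if (nrow(train) == 0) warning("temporal split produced an empty training set")
  list(train = train, test = test)
}

#' Read referral and visit tables
#'
#' `referrals.csv` has columns `patient_id, referral_date[, encounter_id]`;
#' `visits.csv` has `patient_id, visit_date`. Dates are ISO-8601.
#'
#' @param path file path.
#' @return a typed `data.table`.
#' @export
read_referrals <- function(path) {
  r <- .read_table(path, required = c("patient_id", "referral_date"),
                   optional = "encounter_id")
  r[, referral_date := .parse_dates(referral_date, path, "referral_date")]
  r[]
}

#' @rdname read_referrals
#' @export
read_visits <- function(path) {
  v <- .read_table(path, required = c("patient_id", "visit_date"))
  v[, visit_date := .parse_dates(visit_date, path, "visit_date")]
  v[]
}

#' Write / read episodes as JSON lines
#'
#' One JSON object per line with fields `patient_id`, `referral_date`,
#' `visit_date`, `query_items`, `target_items`.
#'
#' @param episodes episode table.
#' @param path file path.
#' @return `path` (write) or the episode table (read).
#' @export
write_episodes <- function(episodes, path) {
  ep <- as.data.table(episodes)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(ep))) {
    writeLines(jsonlite::toJSON(list(
      patient_id = ep$patient_id[i],
      referral_date = format(ep$referral_date[i]),
      visit_date = format(ep$visit_date[i]),
      query_items = ep$query_items[[i]],
      target_items = ep$target_items[[i]]
    ), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_episodes
#' @export
read_episodes <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, jsonlite::fromJSON)
  data.table(
    patient_id = vapply(rows, `[[`, "", "patient_id"),
    referral_date = as.Date(vapply(rows, `[[`, "", "referral_date")),
    visit_date = as.Date(vapply(rows, `[[`, "", "visit_date")),
    query_items = lapply(rows, function(r) as.character(r$query_items)),
    target_items = lapply(rows, function(r) as.character(r$target_items))
  )
}
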