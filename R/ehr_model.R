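#' Build item keys from concept identifiers and qualifiers
#'
#' A clinical item is identified by its concept and, for categorized numeric
#' laboratory results, an abnormality qualifier: `"TSH"` queried as a plain
#' concept is a different vocabulary item from `"TSH:high"` or `"TSH:low"`.
#' Keys are `concept_id` when the qualifier is `"none"` and
#' `concept_id:qualifier` otherwise, so `":"` must not occur in concept
#' identifiers.
#'
#' @param concept_id character vector of concept identifiers.
#' @param qualifier character vector in `c("none", "normal", "high", "low")`,
#'   recycled to the length of `concept_id`.
#' @return character vector of item keys.
#' @examples
#' item_key(c("TSH", "TSH", "OBESITY"), c("high", "low", "none"))
#' @export
item_key <- function(concept_id, qualifier = "none") {
  stopifnot(is.character(concept_id))
  if (any(grepl(":", concept_id, fixed = TRUE))) {
    stop("concept_id must not contain ':' (reserved as qualifier separator)")
  }
  bad <- !qualifier %in% .qualifiers
  if (any(bad)) {
    stop("unknown qualifier(s): ", paste(unique(qualifier[bad]), collapse = ", "))
  }
  qualifier <- rep_len(qualifier, length(concept_id))
  ifelse(qualifier == "none", concept_id,
         paste(concept_id, qualifier, sep = ":"))
}

#' Split item keys back into concept and qualifier
#'
#' @param key character vector of item keys produced by [item_key()].
#' @return a `data.table` with columns `concept_id` and `qualifier`.
#' @export
split_item_key <- function(key) {
  has_q <- grepl(":", key, fixed = TRUE)
  concept <- sub(":.*$", "", key)
  qual <- ifelse(has_q, sub("^.*:", "", key), "none")
  data.table(concept_id = concept, qualifier = qual)
}

#' Categorize a numeric laboratory result against its reference range
#'
#' Results strictly below the lower reference bound are `"low"`, strictly
#' above the upper bound `"high"`, and everything else `"normal"` -- values
#' equal to a bound do not trip an abnormality flag, matching the convention
#' by which clinical lab systems flag results strictly outside range.
#'
#' @param value numeric vector of lab results.
#' @param ref_low,ref_high numeric vectors of reference range bounds;
#'   `ref_low <= ref_high` element-wise.
#' @return character vector in `c("low", "normal", "high")`.
#' @examples
#' categorize_measurement(c(3, 5, 7, 4), 4, 6)  # low normal high normal
#' @export
categorize_measurement <- function(value, ref_low, ref_high) {
  stopifnot(is.numeric(value), is.numeric(ref_low), is.numeric(ref_high))
  n <- length(value)
  ref_low <- rep_len(ref_low, n)
  ref_high <- rep_len(ref_high, n)
  if (anyNA(value) || anyNA(ref_low) || anyNA(ref_high)) {
    stop("categorize_measurement requires complete value and range; ",
         "use categorize_events() for tables with missing ranges")
  }
  if (any(ref_low > ref_high)) {
    stop("invalid reference range: ref_low > ref_high")
  }
  out <- rep("normal", n)
  out[value < ref_low] <- "low"
  out[value > ref_high] <- "high"
  out
}

#' Attach abnormality qualifiers and item keys to an event table
#'
#' Measurement events carrying a numeric value and a complete reference range
#' are qualified `"low"`/`"normal"`/`"high"` via [categorize_measurement()];
#' measurements without a usable range, and all non-measurement events, keep
#' qualifier `"none"` (they stay in the vocabulary as plain concepts rather
#' than being dropped). Adds `qualifier` and `item_key` columns.
#'
#' @param events event `data.table` as returned by [read_events()].
#' @return a copy of `events` with `qualifier` and `item_key` columns.
#' @export
categorize_events <- function(events) {
  ev <- as.data.table(events)
  .check_columns(ev, c("patient_id", "concept_id", "domain"), "events")
  if (!"numeric_value" %in% names(ev)) ev[, numeric_value := NA_real_]
  if (!"ref_low" %in% names(ev)) ev[, ref_low := NA_real_]
  if (!"ref_high" %in% names(ev)) ev[, ref_high := NA_real_]
  ev <- copy(ev)
  bad_range <- !is.na(ev$ref_low) & !is.na(ev$ref_high) & ev$ref_low > ev$ref_high
  if (any(bad_range)) {
    stop("invalid reference range (ref_low > ref_high) in ",
         sum(bad_range), " event row(s)")
  }
  val_outside_meas <- !is.na(ev$numeric_value) & ev$domain != "measurement"
  if (any(val_outside_meas)) {
    stop("numeric_value present on non-measurement rows: ",
         sum(val_outside_meas), " row(s)")
  }
  ev[, qualifier := "none"]
  usable <- ev$domain == "measurement" & !is.na(ev$numeric_value) &
    !is.na(ev$ref_low) & !is.na(ev$ref_high)
  if (any(usable)) {
    ev[usable, qualifier := categorize_measurement(numeric_value, ref_low, ref_high)]
  }
  ev[, item_key := item_key(concept_id, qualifier)]
  ev[]
}

#' Read an OMOP-lite event table
#'
#' Expects a delimited text file with header
#' `patient_id, concept_id, domain, event_date, numeric_value, ref_low, ref_high`
#' (`event_date` ISO-8601; the three numeric columns may be empty). Malformed
#' rows are rejected with their line numbers rather than silently coerced.
#'
#' @param path path to the events file.
#' @return a `data.table` with typed columns (`event_date` as `Date`).
#' @export
read_events <- function(path) {
  ev <- .read_table(path, required = c("patient_id", "concept_id", "domain",
                                       "event_date"),
                    optional = c("numeric_value", "ref_low", "ref_high"))
  ev[, event_date := .parse_dates(event_date, path, "event_date")]
  for (col in c("numeric_value", "ref_low", "ref_high")) {
    if (!col %in% names(ev)) {
      ev[, (col) := NA_real_]
    } else {
      ev[, (col) := .parse_numeric(get(col), path, col)]
    }
  }
  bad_dom <- !ev$domain %in% .domains
  if (any(bad_dom)) {
    stop("unknown domain(s) in ", path, ": ",
         paste(unique(ev$domain[bad_dom]), collapse = ", "))
  }
  ev[]
}

#' Write an event table in the OMOP-lite layout read by [read_events()]
#'
#' @param events event `data.table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  cols <- c("patient_id", "concept_id", "domain", "event_date",
            "numeric_value", "ref_low", "ref_high")
  ev <- as.data.table(events)
  for (col in c("numeric_value", "ref_low", "ref_high")) {
    if (!col %in% names(ev)) ev[, (col) := NA_real_]
  }
  fwrite(ev[, cols, with = FALSE], path, na = "")
  invisible(path)
}

#' Drop clinical items observed in too few patients
#'
#' Items are counted once per patient (duplicate events within a patient do
#' not add support) on the qualified vocabulary, i.e. after lab
#' categorization, so `"TSH:high"` and `"TSH:low"` accrue support
#' independently. Items under the support threshold are removed from the
#' event table and excluded from the vocabulary.
#'
#' @param events categorized event table (see [categorize_events()]).
#' @param min_support minimum number of distinct patients an item must appear
#'   in to be retained; items in fewer than `min_support` patients are
#'   dropped. Default 10.
#' @return a list with `events` (filtered table) and `vocabulary` (a
#'   `data.table` with `item_key`, `concept_id`, `qualifier`, `domain`,
#'   `patient_support`).
#' @export
filter_rare_items <- function(events, min_support = 10) {
  ev <- as.data.table(events)
  if (nrow(ev) == 0) stop("filter_rare_items: empty event table")
  .check_columns(ev, c("patient_id", "item_key", "concept_id", "qualifier",
                       "domain"), "categorized events")
  support <- unique(ev[, .(patient_id, item_key, concept_id, qualifier,
                           domain)])[
    , .(patient_support = .N), by = .(item_key, concept_id, qualifier, domain)]
  vocab <- support[patient_support >= min_support]
  setorder(vocab, item_key)
  filtered <- ev[item_key %in% vocab$item_key]
  list(events = filtered[], vocabulary = vocab[])
}

#' Write / read a vocabulary table
#'
#' @param vocabulary vocabulary `data.table` from [filter_rare_items()].
#' @param path file path.
#' @return `path` (write) or the vocabulary `data.table` (read).
#' @export
write_vocabulary <- function(vocabulary, path) {
  fwrite(as.data.table(vocabulary)[
    , .(concept_id, qualifier, domain, patient_support)], path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  v <- .read_table(path, required = c("concept_id", "qualifier", "domain",
                                      "patient_support"))
  v[, patient_support := as.integer(patient_support)]
  v[, item_key := item_key(concept_id, qualifier)]
  setcolorder(v, c("item_key", "concept_id", "qualifier", "domain",
                   "patient_support"))
  v[]
}

# ---- internal table plumbing -----------------------------------------------

.check_columns <- function(dt, required, what) {
  missing <- setdiff(required, names(dt))
  if (length(missing) > 0) {
    stop("missing required column(s) in ", what, ": ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

.read_table <- function(path, required, optional = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread(path, colClasses = "character", na.strings = "")
  .check_columns(dt, required, path)
  keep <- intersect(c(required, optional), names(dt))
  dt <- dt[, keep, with = FALSE]
  for (col in required) {
    blank <- is.na(dt[[col]]) | dt[[col]] == ""
    if (col %in% c("patient_id", "concept_id", "domain") && any(blank)) {
      stop("missing ", col, " in ", path, " at line(s) ",
           paste(head(which(blank) + 1L, 5), collapse = ", "))
    }
  }
  dt
}

.parse_dates <- function(x, path, col) {
  parsed <- as.Date(x, format = "%Y-%m-%d")
  bad <- is.na(parsed) & !is.na(x)
  if (any(bad)) {
    stop("unparseable ", col, " in ", path, " at line(s) ",
         paste(head(which(bad) + 1L, 5), collapse = ", "),
         " (expected ISO-8601 YYYY-MM-DD)")
  }
  if (anyNA(parsed)) {
    stop("missing ", col, " in ", path, " at line(s) ",
         paste(head(which(is.na(parsed)) + 1L, 5), collapse = ", "))
  }
  parsed
}

.parse_numeric <- function(x, path, col) {
  parsed <- suppressWarnings(as.numeric(x))
  bad <- is.na(parsed) & !is.na(x) & x != ""
  if (any(bad)) {
    stop("unparseable ", col, " in ", path, " at line(s) ",
         paste(head(which(bad) + 1L, 5), collapse = ", "))
  }
  parsed
}
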