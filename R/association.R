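#' Train the item co-occurrence association matrix
#'
#' Counts, over the training referral episodes, how many distinct patients
#' carry each query item in their pre-referral window (`N_A`), how many
#' received each workup order at the first specialty visit (`N_B`), and how
#' many have both (`N_AB`). Items are counted once per patient, so all
#' derived statistics read as patient prevalences. Counting is directional:
#' pairs link a chart item before referral to an order placed at the visit,
#' never orders to each other or chart items to each other.
#'
#' The result is stored sparsely (only observed pairs), which is what makes
#' vocabularies of thousands of items tractable.
#'
#' @param train_episodes episode table from [build_episodes()] /
#'   [split_by_year()].
#' @return an object of class `assoc_matrix`: a list with `n_cohort`
#'   (number of training patients), `query_counts` and `target_counts`
#'   (named integer vectors of per-item patient counts), and `pair_counts`
#'   (a `data.table` with `query`, `target`, `n_ab`).
#' @examples
#' ep <- data.table::data.table(
#'   patient_id = c("P1", "P2"),
#'   referral_date = as.Date("2019-06-01"), visit_date = as.Date("2019-06-20"),
#'   query_items = list("HYPOTHYROIDISM", c("HYPOTHYROIDISM", "TSH:high")),
#'   target_items = list(c("TSH", "FT4"), "TSH"))
#' m <- build_matrix(ep)
#' ppv(m, "HYPOTHYROIDISM", "TSH")
#' @export
build_matrix <- function(train_episodes) {
  ep <- as.data.table(train_episodes)
  if (nrow(ep) == 0) stop("build_matrix: no training episodes")
  .check_columns(ep, c("query_items", "target_items"), "episodes")
  n <- nrow(ep)
  q <- data.table(episode = rep(seq_len(n), lengths(ep$query_items)),
                  item = as.character(unlist(ep$query_items)))
  tg <- data.table(episode = rep(seq_len(n), lengths(ep$target_items)),
                   item = as.character(unlist(ep$target_items)))
  q <- unique(q)
  tg <- unique(tg)

  qc <- q[, .N, by = item]
  tc <- tg[, .N, by = item]
  pairs <- tg[q, on = "episode", allow.cartesian = TRUE, nomatch = NULL]
  pair_counts <- pairs[, .(n_ab = .N), by = .(query = i.item, target = item)]
  setkey(pair_counts, query, target)

  structure(list(
    n_cohort = n,
    query_counts = setNames(as.integer(qc$N), qc$item),
    target_counts = setNames(as.integer(tc$N), tc$item),
    pair_counts = pair_counts
  ), class = "assoc_matrix")
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat("Item association matrix\n")
  cat("  training patients :", x$n_cohort, "\n")
  cat("  query items       :", length(x$query_counts), "\n")
  cat("  target items      :", length(x$target_counts), "\n")
  cat("  observed pairs    :", nrow(x$pair_counts), "\n")
  invisible(x)
}

#' Background (outpatient) item statistics
#'
#' Patient counts for clinical items among outpatients *outside* the
#' specialty referral cohort. They provide the denominator of the relative
#' risk weight -- how common an item is in general pediatric outpatient care
#' -- and the outpatient-prevalence baseline ranker.
#'
#' @param counts named numeric/integer vector: per-item distinct patient
#'   counts among outpatients.
#' @param n_outpt total number of outpatients the counts are drawn from.
#' @return an object of class `background_stats`.
#' @export
background_stats <- function(counts, n_outpt) {
  stopifnot(!is.null(names(counts)), n_outpt > 0, all(counts >= 0),
            all(counts <= n_outpt))
  structure(list(counts = setNames(as.integer(counts), names(counts)),
                 n_outpt = as.integer(n_outpt)),
            class = "background_stats")
}

#' @export
print.background_stats <- function(x, ...) {
  cat("Outpatient background statistics\n")
  cat("  outpatients :", x$n_outpt, "\n")
  cat("  items       :", length(x$counts), "\n")
  invisible(x)
}

#' Positive predictive value of a target order given a query item
#'
#' `P(B | A) = N_AB / N_A`: among training patients whose chart carried query
#' item `A` before referral, the fraction for whom the specialist placed
#' order `B` at the first visit. No smoothing is applied; the rare-item
#' filter bounds the variance of these raw ratios.
#'
#' @param matrix an `assoc_matrix`.
#' @param query a single query item key.
#' @param target character vector of target item keys.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
ppv <- function(matrix, query, target) {
  stopifnot(inherits(matrix, "assoc_matrix"), length(query) == 1)
  n_a <- matrix$query_counts[query]
  if (is.na(n_a) || n_a == 0) {
    stop("ppv undefined: query item '", query, "' has no training support")
  }
  n_ab <- .pair_lookup(matrix, query, target)
  unname(n_ab / n_a)
}

#' Relative risk weight of a query item
#'
#' Ratio of the item's prevalence inside the referral cohort to its
#' prevalence among outpatients outside the cohort. Items characteristic of
#' the specialty (an abnormal TSH, an endocrine diagnosis) get large weights;
#' ubiquitous primary-care items (well-child visits, common viral illnesses)
#' get weights near or below 1 and contribute little to the aggregated score.
#'
#' @param matrix an `assoc_matrix`.
#' @param background a `background_stats` object (outside-cohort population).
#' @param query character vector of query item keys.
#' @param max_weight cap applied when the item is unseen outside the cohort,
#'   where the raw ratio is undefined or explosive (default 100).
#' @return numeric vector of nonnegative weights.
#' @export
relative_risk_weight <- function(matrix, background, query, max_weight = 100) {
  stopifnot(inherits(matrix, "assoc_matrix"),
            inherits(background, "background_stats"))
  n_a <- matrix$query_counts[query]
  n_a[is.na(n_a)] <- 0L
  cohort_prev <- n_a / matrix$n_cohort
  bg <- background$counts[query]
  bg[is.na(bg)] <- 0L
  outpt_prev <- bg / background$n_outpt
  rr <- ifelse(outpt_prev > 0, cohort_prev / outpt_prev,
               ifelse(cohort_prev > 0, max_weight, 0))
  unname(pmin(rr, max_weight))
}

#' Relative ratio of a target order with respect to a query item
#'
#' `P(B | A) / P(B | not A)`: how much more likely the order is when the
#' query item is present than when it is absent. Values far above 1 flag
#' orders that are *specific* to a finding (e.g. total tri-iodothyronine for
#' a suppressed TSH) even when their raw PPV is modest; values near 1 mark
#' orders placed regardless of the finding.
#'
#' Returns `Inf` when the order never occurs without the query item but does
#' occur with it, and `NaN` when it occurs in neither group.
#'
#' @param matrix an `assoc_matrix`.
#' @param query a single query item key with `0 < N_A < n_cohort`.
#' @param target character vector of target item keys.
#' @return numeric vector of nonnegative ratios (possibly `Inf`/`NaN`).
#' @export
relative_ratio <- function(matrix, query, target) {
  stopifnot(inherits(matrix, "assoc_matrix"), length(query) == 1)
  n_a <- matrix$query_counts[query]
  if (is.na(n_a) || n_a == 0 || n_a >= matrix$n_cohort) {
    stop("relative_ratio requires 0 < N_A < n_cohort for query '", query, "'")
  }
  n_ab <- .pair_lookup(matrix, query, target)
  n_b <- matrix$target_counts[target]
  n_b[is.na(n_b)] <- 0L
  p_given_a <- n_ab / n_a
  p_given_not_a <- (n_b - n_ab) / (matrix$n_cohort - n_a)
  unname(p_given_a / p_given_not_a)
}

# keyed lookup of N_AB; absent pairs are zero. Local names avoid capture by
# the pair_counts columns inside the join.
.pair_lookup <- function(matrix, query_item, target_item) {
  n_ab <- matrix$pair_counts[J(query_item, target_item), n_ab]
  n_ab[is.na(n_ab)] <- 0L
  n_ab
}

#' Patient prevalence of an item in the cohort or the outpatient background
#'
#' For an `assoc_matrix`, `side = "target"` (the default) gives the fraction
#' of cohort patients who received the order -- the "endocrine prevalence"
#' column of a recommendation report -- while `side = "query"` gives the
#' fraction whose pre-referral chart carried the item. For
#' `background_stats` it is the outpatient prevalence. Unknown items yield 0
#' with a warning.
#'
#' @param x an `assoc_matrix` or `background_stats` object.
#' @param items character vector of item keys.
#' @param ... passed to methods.
#' @return numeric vector of probabilities.
#' @export
prevalence <- function(x, items, ...) UseMethod("prevalence")

#' @rdname prevalence
#' @param side `"target"` or `"query"` counts (assoc_matrix method only).
#' @export
prevalence.assoc_matrix <- function(x, items, side = c("target", "query"), ...) {
  side <- match.arg(side)
  counts <- if (side == "target") x$target_counts else x$query_counts
  n <- counts[items]
  if (anyNA(n)) {
    warning("unknown item(s) treated as prevalence 0: ",
            paste(head(items[is.na(n)], 5), collapse = ", "))
    n[is.na(n)] <- 0L
  }
  unname(n / x$n_cohort)
}

#' @rdname prevalence
#' @export
prevalence.background_stats <- function(x, items, ...) {
  n <- x$counts[items]
  if (anyNA(n)) {
    warning("unknown item(s) treated as prevalence 0: ",
            paste(head(items[is.na(n)], 5), collapse = ", "))
    n[is.na(n)] <- 0L
  }
  unname(n / x$n_outpt)
}

#' Persist / load an association matrix as a sparse triplet table
#'
#' One CSV holds three row kinds: `pair` rows carry `(query, target, n_ab)`,
#' `query` rows carry items with training support but (possibly) no observed
#' pair, and `target` rows carry per-order patient counts. `n_cohort` is
#' repeated on every row. [read_matrix()] inverts [write_matrix()] exactly.
#'
#' @param matrix an `assoc_matrix`.
#' @param path file path.
#' @return `path` (write) or the `assoc_matrix` (read).
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "assoc_matrix"))
  qk <- split_item_key(names(matrix$query_counts))
  rows <- rbind(
    data.table(kind = "query",
               query_concept = qk$concept_id, query_qualifier = qk$qualifier,
               target_concept = "", n_a = as.integer(matrix$query_counts),
               n_ab = NA_integer_, n_b = NA_integer_),
    data.table(kind = "target",
               query_concept = "", query_qualifier = "",
               target_concept = names(matrix$target_counts),
               n_a = NA_integer_, n_ab = NA_integer_,
               n_b = as.integer(matrix$target_counts)),
    {
      pk <- split_item_key(matrix$pair_counts$query)
      data.table(kind = "pair",
                 query_concept = pk$concept_id, query_qualifier = pk$qualifier,
                 target_concept = matrix$pair_counts$target,
                 n_a = as.integer(
                   matrix$query_counts[matrix$pair_counts$query]),
                 n_ab = matrix$pair_counts$n_ab, n_b = NA_integer_)
    }
  )
  rows[, n_cohort := matrix$n_cohort]
  fwrite(rows, path, na = "")
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  dt <- .read_table(path, required = c("kind", "n_cohort"),
                    optional = c("query_concept", "query_qualifier",
                                 "target_concept", "n_a", "n_ab", "n_b"))
  dt[is.na(query_qualifier) | query_qualifier == "", query_qualifier := "none"]
  qrows <- dt[kind == "query"]
  trows <- dt[kind == "target"]
  prows <- dt[kind == "pair"]
  pair_counts <- data.table(
    query = item_key(prows$query_concept, prows$query_qualifier),
    target = prows$target_concept,
    n_ab = as.integer(prows$n_ab))
  setkey(pair_counts, query, target)
  structure(list(
    n_cohort = as.integer(dt$n_cohort[1]),
    query_counts = setNames(as.integer(qrows$n_a),
                            item_key(qrows$query_concept, qrows$query_qualifier)),
    target_counts = setNames(as.integer(trows$n_b), trows$target_concept),
    pair_counts = pair_counts
  ), class = "assoc_matrix")
}

#' Persist / load outpatient background statistics
#'
#' CSV columns: `concept, qualifier, n_outpt_item, n_outpt`.
#'
#' @param background a `background_stats` object.
#' @param path file path.
#' @return `path` (write) or the `background_stats` (read).
#' @export
write_background <- function(background, path) {
  stopifnot(inherits(background, "background_stats"))
  k <- split_item_key(names(background$counts))
  fwrite(data.table(concept = k$concept_id, qualifier = k$qualifier,
                    n_outpt_item = as.integer(background$counts),
                    n_outpt = background$n_outpt), path)
  invisible(path)
}

#' @rdname write_background
#' @export
read_background <- function(path) {
  dt <- .read_table(path, required = c("concept", "qualifier",
                                       "n_outpt_item", "n_outpt"))
  dt[is.na(qualifier) | qualifier == "", qualifier := "none"]
  background_stats(
    setNames(as.integer(dt$n_outpt_item), item_key(dt$concept, dt$qualifier)),
    as.integer(dt$n_outpt[1]))
}
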