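#' Weighting schemes for query items
#'
#' @description
#' When a patient's chart carries `q` query items, each item contributes a
#' ranked list of candidate orders; the lists are merged into weighted
#' pseudo-counts, and the weight `W_A` controls how much each query item is
#' trusted:
#'
#' * `uniform`: `W_A = 1` -- every chart item counts equally.
#' * `inverse_frequency`: `W_A = 1 / ln(1 + N_A)` -- penalizes items common
#'   in the referral cohort, IDF-style (a `1 / N_A` variant is available via
#'   `inverse_form = "reciprocal"`).
#' * `relative_risk`: `W_A = RR_A` -- upweights items enriched in the
#'   specialty cohort relative to general outpatients
#'   (see [relative_risk_weight()]).
#' * `combined`: `W_A = RR_A / ln(1 + N_A)` -- both effects at once; the
#'   default scheme, and the one cross-validation typically selects when
#'   queries are diluted by common specialty-irrelevant items.
#'
#' Items absent from the training vocabulary get weight 0 under every scheme
#' and contribute nothing.
#'
#' @param scheme one of `"uniform"`, `"inverse_frequency"`,
#'   `"relative_risk"`, `"combined"`.
#' @param matrix an `assoc_matrix`.
#' @param background a `background_stats` object (required for the
#'   relative-risk schemes).
#' @param query character vector of query item keys.
#' @param max_rr_cap cap for relative risk weights (default 100).
#' @param inverse_form `"log"` for `1/ln(1+N_A)` (default) or
#'   `"reciprocal"` for `1/N_A`.
#' @return numeric vector of nonnegative weights, one per query item.
#' @export
item_weight <- function(scheme, matrix, background = NULL, query,
                        max_rr_cap = 100, inverse_form = c("log", "reciprocal")) {
  scheme <- match.arg(scheme, .schemes)
  inverse_form <- match.arg(inverse_form)
  stopifnot(inherits(matrix, "assoc_matrix"))
  n_a <- matrix$query_counts[query]
  n_a[is.na(n_a)] <- 0L
  known <- n_a > 0
  inv <- function(n) if (inverse_form == "log") 1 / log(1 + n) else 1 / n
  w <- switch(scheme,
    uniform = rep(1, length(query)),
    inverse_frequency = ifelse(known, inv(n_a), 0),
    relative_risk = {
      stopifnot(inherits(background, "background_stats"))
      relative_risk_weight(matrix, background, query, max_weight = max_rr_cap)
    },
    combined = {
      stopifnot(inherits(background, "background_stats"))
      rr <- relative_risk_weight(matrix, background, query,
                                 max_weight = max_rr_cap)
      ifelse(known, rr * inv(n_a), 0)
    })
  w[!known] <- 0
  unname(w)
}

.schemes <- c("uniform", "inverse_frequency", "relative_risk", "combined")

#' Aggregate per-query-item evidence into scores for every candidate order
#'
#' Computes the weighted pseudo-count score
#' `score(B) = sum_i W_{A_i} * P(B | A_i)` over the query items with training
#' support. The candidate set is every target order seen in training;
#' candidates never paired with any effective query item score 0.
#' Normalization by the summed weights is omitted because it does not change
#' any ranking.
#'
#' @inheritParams item_weight
#' @param query character vector of query item keys (the patient's chart).
#' @param ... passed on to [item_weight()].
#' @return named numeric vector of scores over all candidate orders, with
#'   attribute `"sum_weights"`; `NULL` when no query item is in the training
#'   vocabulary (the cold-start signal).
#' @export
aggregate_scores <- function(query, matrix, background = NULL,
                             scheme = "combined", ...) {
  stopifnot(inherits(matrix, "assoc_matrix"))
  query <- unique(as.character(query))
  n_a <- matrix$query_counts[query]
  effective <- query[!is.na(n_a) & n_a > 0]
  candidates <- names(matrix$target_counts)
  if (length(effective) == 0) return(NULL)
  w <- item_weight(scheme, matrix, background, effective, ...)
  wdt <- data.table(query = effective, weight = w,
                    n_a = as.numeric(matrix$query_counts[effective]))
  contrib <- matrix$pair_counts[wdt, on = "query", nomatch = NULL]
  scored <- contrib[, .(score = sum(weight * n_ab / n_a)), by = target]
  scores <- setNames(numeric(length(candidates)), candidates)
  scores[scored$target] <- scored$score
  attr(scores, "sum_weights") <- sum(w)
  scores
}

#' Rank the recommended workup orders for a patient
#'
#' Scores every candidate order with [aggregate_scores()] and returns the
#' top `k`, annotated with the statistics a reviewer needs to judge each
#' suggestion: the (weight-averaged) PPV, the relative ratio (single-item
#' queries only -- it is a pairwise statistic), and the order's prevalence
#' in the referral cohort and among general outpatients.
#'
#' When none of the query items is in the training vocabulary (the cold
#' start), the ranking falls back to a "best seller list": orders ranked by
#' their prevalence in the referral cohort, with `fallback_used = TRUE`.
#' A query item that is itself an orderable lab may be recommended back --
#' specialists routinely repeat an abnormal TSH.
#'
#' Ties in score are broken by descending cohort prevalence, then
#' lexicographically by item key, so rankings are deterministic.
#'
#' @inheritParams aggregate_scores
#' @param k number of recommendations to return (default 4, the average
#'   number of workup orders at a first specialty visit). If fewer
#'   candidates exist, the full list is returned without padding.
#' @return a `data.table` of class `recommendation_list` with columns
#'   `item`, `score`, `ppv`, `relative_ratio`, `endocrine_prevalence`,
#'   `outpatient_prevalence`, and attributes `scheme` and `fallback_used`.
#' @export
recommend <- function(query, matrix, background = NULL, scheme = "combined",
                      k = 4, ...) {
  stopifnot(inherits(matrix, "assoc_matrix"), k >= 1)
  if (length(matrix$target_counts) == 0) {
    stop("untrained matrix: no target orders observed")
  }
  scores <- aggregate_scores(query, matrix, background, scheme, ...)
  fallback <- is.null(scores)
  if (fallback) {
    scores <- matrix$target_counts / matrix$n_cohort
    sum_w <- NA_real_
  } else {
    sum_w <- attr(scores, "sum_weights")
  }
  ranked <- .rank_targets(scores, matrix)
  top <- head(ranked, k)

  endo_prev <- suppressWarnings(prevalence(matrix, top, side = "target"))
  outpt_prev <- if (!is.null(background)) {
    suppressWarnings(prevalence(background, top))
  } else rep(NA_real_, length(top))

  effective <- if (fallback) character(0) else {
    q <- unique(as.character(query))
    q[q %in% names(matrix$query_counts)[matrix$query_counts > 0]]
  }
  rel <- rep(NA_real_, length(top))
  if (length(effective) == 1 &&
      matrix$query_counts[effective] < matrix$n_cohort) {
    rel <- relative_ratio(matrix, effective, top)
  }
  out <- data.table(
    item = top,
    score = unname(scores[top]),
    ppv = if (fallback) rep(NA_real_, length(top)) else
      unname(scores[top]) / sum_w,
    relative_ratio = rel,
    endocrine_prevalence = endo_prev,
    outpatient_prevalence = outpt_prev
  )
  setattr(out, "class", c("recommendation_list", class(out)))
  setattr(out, "scheme", if (fallback) "endocrine_prevalence_fallback" else scheme)
  setattr(out, "fallback_used", fallback)
  out
}

#' @export
print.recommendation_list <- function(x, ...) {
  cat("Recommended workup orders (scheme: ", attr(x, "scheme"),
      if (isTRUE(attr(x, "fallback_used"))) ", cold-start fallback", ")\n",
      sep = "")
  NextMethod()
  invisible(x)
}

# deterministic full ranking of candidate orders:
# score desc, then cohort prevalence desc, then item key
.rank_targets <- function(scores, matrix) {
  items <- names(scores)
  prev <- as.numeric(matrix$target_counts[items])
  prev[is.na(prev)] <- 0
  items[order(-as.numeric(scores), -prev, items, method = "radix")]
}

#' Select the query-weighting scheme by cross-validation
#'
#' Splits the training episodes into `n_folds` patient-level folds (each
#' episode is one patient, so no patient appears in two folds), rebuilds the
#' association matrix on each fold's complement, scores the held-out
#' episodes under every candidate scheme, and returns the scheme with the
#' best mean metric. Ties go to the earliest scheme in `schemes`. Fold
#' assignment is a seeded permutation, so results are reproducible.
#'
#' @param train_episodes training episode table.
#' @param background a `background_stats` object.
#' @param schemes candidate schemes, in tie-break priority order.
#' @param n_folds number of folds (default 10).
#' @param k cutoff for the ranking metric (default 4).
#' @param metric `"precision_at_k"` or `"recall_at_k"`.
#' @param seed integer seed for the fold permutation.
#' @param ... passed to [item_weight()] via [aggregate_scores()].
#' @return a list with `best_scheme` and `cv_table` (a `data.table` of
#'   per-scheme, per-fold means plus the overall mean).
#' @export
select_weighting <- function(train_episodes, background,
                             schemes = .schemes, n_folds = 10, k = 4,
                             metric = c("precision_at_k", "recall_at_k"),
                             seed = 1, ...) {
  metric <- match.arg(metric)
  ep <- as.data.table(train_episodes)
  if (n_folds < 2) stop("n_folds must be at least 2")
  if (nrow(ep) < n_folds) stop("fewer episodes than folds")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), nrow(ep)))

  rows <- list()
  for (f in seq_len(n_folds)) {
    m <- build_matrix(ep[fold != f])
    held <- ep[fold == f]
    for (s in schemes) {
      vals <- vapply(seq_len(nrow(held)), function(i) {
        actual <- held$target_items[[i]]
        if (length(actual) == 0) return(NA_real_)
        scores <- aggregate_scores(held$query_items[[i]], m, background, s, ...)
        if (is.null(scores)) scores <- m$target_counts / m$n_cohort
        pr <- precision_recall_at_k(.rank_targets(scores, m), actual, k)
        if (metric == "precision_at_k") pr[["precision"]] else pr[["recall"]]
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.table(
        scheme = s, fold = f, metric_mean = mean(vals, na.rm = TRUE))
    }
  }
  cv <- rbindlist(rows)
  summary <- cv[, .(metric_mean = mean(metric_mean)), by = scheme]
  summary[, scheme := factor(scheme, levels = schemes)]
  setorder(summary, scheme)
  best <- as.character(summary$scheme[which.max(summary$metric_mean)])
  list(best_scheme = best, cv_table = cv[], cv_summary = summary[])
}
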