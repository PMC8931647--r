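#' Precision and recall of a ranked recommendation list at cutoff k
#'
#' Precision is the number of top-`k` recommendations the specialist
#' actually ordered divided by `k` -- the denominator stays `k` even when
#' fewer than `k` candidates were available, so short lists are implicitly
#' padded with misses. Recall is the number of hits divided by the number of
#' orders actually placed; it is undefined (`NA`) when the actual set is
#' empty, and such episodes are excluded from averaging upstream.
#'
#' @param recommended character vector of item keys, best first.
#' @param actual character vector (set) of item keys actually ordered.
#' @param k cutoff (default 4).
#' @return named numeric vector `c(precision =, recall =)`.
#' @examples
#' precision_recall_at_k(c("a", "b", "c", "d"), c("a", "c", "e"))
#' # precision 0.5, recall 2/3
#' @export
precision_recall_at_k <- function(recommended, actual, k = 4) {
  stopifnot(k >= 1)
  hits <- sum(head(recommended, k) %in% actual)
  c(precision = hits / k,
    recall = if (length(actual) == 0) NA_real_ else hits / length(actual))
}

#' Pooled ROC AUC over ranked candidate orders
#'
#' Pools every (episode, candidate order) pair across episodes: the label is
#' whether the specialist placed that order for that patient, the score is
#' the recommender's aggregated score (0 for candidates it never scored).
#' The AUC is the Wilcoxon rank statistic with midrank tie handling, i.e.
#' the probability that a randomly chosen placed order outscores a randomly
#' chosen unplaced one, ties counting one half. `pooling = "per_episode"`
#' instead averages the per-episode AUCs (episodes lacking both a positive
#' and a negative are dropped).
#'
#' @param scored_candidates list of named numeric score vectors, one per
#'   episode, over the candidate order vocabulary.
#' @param actuals list of character vectors: the orders actually placed.
#' @param pooling `"pooled"` (default) or `"per_episode"`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scored_candidates, actuals, pooling = c("pooled", "per_episode")) {
  pooling <- match.arg(pooling)
  stopifnot(length(scored_candidates) == length(actuals))
  if (pooling == "pooled") {
    scores <- unlist(lapply(scored_candidates, as.numeric), use.names = FALSE)
    labels <- unlist(Map(function(s, a) names(s) %in% a,
                         scored_candidates, actuals), use.names = FALSE)
    .auc_midrank(scores, labels)
  } else {
    vals <- Map(function(s, a) {
      lab <- names(s) %in% a
      if (all(lab) || !any(lab)) return(NA_real_)
      .auc_midrank(as.numeric(s), lab)
    }, scored_candidates, actuals)
    mean(unlist(vals), na.rm = TRUE)
  }
}

# Wilcoxon/Mann-Whitney AUC with midrank ties
.auc_midrank <- function(scores, labels) {
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined: need at least one positive and one negative")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Percentile bootstrap confidence interval for an episode-level metric
#'
#' Resamples episodes (patients) with replacement and reports the percentile
#' interval of the metric across resamples. If the metric is undefined on a
#' resample (returns `NA`), that resample is redrawn, up to ten attempts.
#'
#' @param metric_fn function mapping an episode collection (rows of a
#'   `data.frame`/`data.table`, or elements of a vector/list) to one number.
#' @param episodes the episode collection to resample.
#' @param n_resamples number of bootstrap resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return named numeric vector `c(point =, lower =, upper =)`.
#' @export
bootstrap_ci <- function(metric_fn, episodes, n_resamples = 1000,
                         level = 0.95, seed = 1) {
  n <- if (is.data.frame(episodes)) nrow(episodes) else length(episodes)
  stopifnot(n > 0)
  take <- function(idx) {
    if (is.data.frame(episodes)) episodes[idx, , drop = FALSE]
    else episodes[idx]
  }
  point <- metric_fn(episodes)
  set.seed(seed)
  stats <- numeric(n_resamples)
  for (b in seq_len(n_resamples)) {
    val <- NA_real_
    for (attempt in 1:10) {
      val <- metric_fn(take(sample.int(n, n, replace = TRUE)))
      if (!is.na(val)) break
    }
    if (is.na(val)) stop("metric undefined on 10 consecutive bootstrap resamples")
    stats[b] <- val
  }
  alpha <- (1 - level) / 2
  ci <- quantile(stats, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(point = point, lower = ci[1], upper = ci[2])
}

#' Rankers: the recommender and its reference baselines
#'
#' @description
#' A ranker is a function of `(query, episode_index)` returning a named
#' score vector over the candidate order vocabulary. `make_ranker()` wraps
#' the trained recommender (with cold-start fallback to cohort prevalence);
#' `baseline_ranker()` builds the reference benchmarks:
#'
#' * `endocrine_prevalence` -- scores every order by its prevalence in the
#'   referral cohort, ignoring the query ("most common workup orders").
#' * `outpatient_prevalence` -- scores by prevalence among general
#'   outpatients, ignoring the query.
#' * `random` -- a fresh seeded random permutation of the candidates for
#'   each episode.
#'
#' @param matrix an `assoc_matrix`.
#' @param background a `background_stats` object.
#' @param scheme weighting scheme for the recommender ranker.
#' @param kind baseline kind (see above).
#' @param seed integer seed for the random baseline.
#' @param ... passed to [aggregate_scores()].
#' @return a function `(query, episode_index) -> named numeric scores`,
#'   with attribute `"name"`.
#' @export
make_ranker <- function(matrix, background = NULL, scheme = "combined", ...) {
  candidates <- names(matrix$target_counts)
  prev <- matrix$target_counts / matrix$n_cohort
  f <- function(query, episode_index = NA_integer_) {
    scores <- aggregate_scores(query, matrix, background, scheme, ...)
    if (is.null(scores)) return(prev)
    scores
  }
  attr(f, "name") <- paste0("recommender_", scheme)
  f
}

#' @rdname make_ranker
#' @export
baseline_ranker <- function(kind = c("endocrine_prevalence",
                                     "outpatient_prevalence", "random"),
                            matrix, background = NULL, seed = 1) {
  kind <- match.arg(kind)
  candidates <- names(matrix$target_counts)
  f <- switch(kind,
    endocrine_prevalence = {
      scores <- matrix$target_counts / matrix$n_cohort
      function(query, episode_index = NA_integer_) scores
    },
    outpatient_prevalence = {
      stopifnot(inherits(background, "background_stats"))
      scores <- suppressWarnings(
        setNames(prevalence(background, candidates), candidates))
      function(query, episode_index = NA_integer_) scores
    },
    random = {
      function(query, episode_index = 1L) {
        set.seed(seed * 1000L + as.integer(episode_index))
        setNames(runif(length(candidates)), candidates)
      }
    })
  attr(f, "name") <- kind
  f
}

# score all episodes with a ranker; returns list(scores=list, actuals=list,
# precision=vec, recall=vec) over episodes with nonempty targets
.score_episodes <- function(ranker, episodes, matrix, k = 4) {
  ep <- as.data.table(episodes)
  keep <- lengths(ep$target_items) > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " episode(s) without target orders excluded from metrics")
  }
  ep <- ep[keep]
  scores <- vector("list", nrow(ep))
  prec <- rec <- numeric(nrow(ep))
  for (i in seq_len(nrow(ep))) {
    s <- ranker(ep$query_items[[i]], i)
    scores[[i]] <- s
    ranked <- .rank_targets(s, matrix)
    pr <- precision_recall_at_k(ranked, ep$target_items[[i]], k)
    prec[i] <- pr[["precision"]]
    rec[i] <- pr[["recall"]]
  }
  list(scores = scores, actuals = ep$target_items, precision = prec,
       recall = rec, n_episodes = nrow(ep), n_dropped = n_dropped)
}

#' Evaluate rankers on held-out referral episodes
#'
#' Scores each ranker on every test episode and reports mean precision@k,
#' mean recall@k, and pooled ROC AUC, each with a percentile bootstrap
#' confidence interval over episodes (patients). Episodes with no target
#' orders are excluded (recall is undefined for them) and counted in the
#' output. The result mirrors the usual benchmark table: one row per
#' ranker.
#'
#' @param rankers named list of ranker functions (see [make_ranker()]).
#' @param episodes test episode table.
#' @param matrix the trained `assoc_matrix` (defines candidates and
#'   tie-breaking).
#' @param k cutoff for precision/recall (default 4).
#' @param n_bootstrap bootstrap resamples for the CIs (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return a `data.table` with one row per ranker: point estimates and CI
#'   bounds for precision, recall, and AUC, plus episode counts.
#' @export
evaluate_rankers <- function(rankers, episodes, matrix, k = 4,
                             n_bootstrap = 1000, level = 0.95, seed = 1) {
  if (is.null(names(rankers))) {
    names(rankers) <- vapply(rankers, function(r) attr(r, "name"), "")
  }
  rows <- lapply(names(rankers), function(nm) {
    sc <- .score_episodes(rankers[[nm]], episodes, matrix, k)
    boot <- function(metric_fn) {
      bootstrap_ci(metric_fn, seq_len(sc$n_episodes), n_resamples = n_bootstrap,
                   level = level, seed = seed)
    }
    p_ci <- boot(function(idx) mean(sc$precision[idx]))
    r_ci <- boot(function(idx) mean(sc$recall[idx], na.rm = TRUE))
    a_ci <- boot(function(idx) roc_auc(sc$scores[idx], sc$actuals[idx]))
    data.table(
      ranker = nm, k = k,
      precision = p_ci[["point"]], precision_lo = p_ci[["lower"]],
      precision_hi = p_ci[["upper"]],
      recall = r_ci[["point"]], recall_lo = r_ci[["lower"]],
      recall_hi = r_ci[["upper"]],
      auc = a_ci[["point"]], auc_lo = a_ci[["lower"]], auc_hi = a_ci[["upper"]],
      n_episodes = sc$n_episodes, n_excluded = sc$n_dropped,
      n_bootstrap = n_bootstrap, seed = seed)
  })
  rbindlist(rows)
}

#' Paired bootstrap comparison of two rankers
#'
#' Evaluates both rankers on the same episodes, bootstraps the *difference*
#' of the chosen metric over shared resamples (pairing removes
#' between-patient variance), and reports the point difference, its
#' percentile CI, and a two-sided p-value from the bootstrap distribution's
#' tail fraction (the fraction of resampled differences on the far side of
#' zero, doubled and capped at 1).
#'
#' @param ranker1,ranker2 ranker functions (see [make_ranker()]).
#' @param episodes test episode table.
#' @param matrix the trained `assoc_matrix`.
#' @param metric `"precision_at_k"`, `"recall_at_k"`, or `"auc"`.
#' @param k cutoff for the precision/recall metrics.
#' @param n_resamples bootstrap resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return a list with `delta` (metric1 - metric2), `ci`, and `p_value`.
#' @export
compare_rankers <- function(ranker1, ranker2, episodes, matrix,
                            metric = c("precision_at_k", "recall_at_k", "auc"),
                            k = 4, n_resamples = 1000, level = 0.95, seed = 1) {
  metric <- match.arg(metric)
  s1 <- .score_episodes(ranker1, episodes, matrix, k)
  s2 <- .score_episodes(ranker2, episodes, matrix, k)
  stopifnot(s1$n_episodes == s2$n_episodes)
  m <- function(sc, idx) switch(metric,
    precision_at_k = mean(sc$precision[idx]),
    recall_at_k = mean(sc$recall[idx], na.rm = TRUE),
    auc = roc_auc(sc$scores[idx], sc$actuals[idx]))
  n <- s1$n_episodes
  delta <- m(s1, seq_len(n)) - m(s2, seq_len(n))
  set.seed(seed)
  deltas <- numeric(n_resamples)
  for (b in seq_len(n_resamples)) {
    idx <- sample.int(n, n, replace = TRUE)
    deltas[b] <- m(s1, idx) - m(s2, idx)
  }
  alpha <- (1 - level) / 2
  ci <- quantile(deltas, c(alpha, 1 - alpha), names = FALSE)
  p <- 2 * min(mean(deltas <= 0), mean(deltas >= 0))
  p <- max(min(p, 1), 1 / n_resamples)
  list(delta = delta, ci = c(lower = ci[1], upper = ci[2]), p_value = p,
       metric = metric, n_episodes = n, n_resamples = n_resamples)
}
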