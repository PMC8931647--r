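test_that("precision and recall at k use a fixed-k denominator", {
  pr <- precision_recall_at_k(c("a", "b", "c", "d"), c("a", "c", "e"))
  expect_equal(pr[["precision"]], 0.5)
  expect_equal(pr[["recall"]], 2 / 3)

  # perfect top-4
  pr2 <- precision_recall_at_k(letters[1:6], letters[1:4], k = 4)
  expect_equal(unname(pr2), c(1, 1))

  # a 2-item list with one hit at k = 4 is penalized as if padded by misses
  pr3 <- precision_recall_at_k(c("a", "x"), c("a", "b"), k = 4)
  expect_equal(pr3[["precision"]], 0.25)

  # empty actual set: recall undefined
  expect_true(is.na(precision_recall_at_k("a", character(0))[["recall"]]))

  # brute-force set arithmetic on random fixtures
  set.seed(5)
  for (i in 1:25) {
    rec <- sample(letters, sample(1:10, 1))
    act <- sample(letters, sample(1:8, 1))
    k <- sample(1:6, 1)
    pr <- precision_recall_at_k(rec, act, k)
    hits <- length(intersect(rec[seq_len(min(k, length(rec)))], act))
    expect_equal(pr[["precision"]], hits / k)
    expect_equal(pr[["recall"]], hits / length(act))
  }
})

test_that("pooled AUC matches hand values and the pairwise oracle", {
  # perfect separation
  s <- list(setNames(c(0.9, 0.8, 0.1, 0.2), c("a", "b", "c", "d")))
  expect_equal(roc_auc(s, list(c("a", "b"))), 1.0)

  # midrank hand value: pos {3, 2}, neg {2, 1} -> 0.875
  s2 <- list(setNames(c(3, 2, 2, 1), c("p1", "p2", "n1", "n2")))
  expect_equal(roc_auc(s2, list(c("p1", "p2"))), 0.875)

  # all labels identical is undefined
  expect_error(roc_auc(s, list(c("a", "b", "c", "d"))), "undefined")

  # random instances, including across-episode pooling, equal the oracle
  set.seed(11)
  for (i in 1:50) {
    n_ep <- sample(1:3, 1)
    scores <- list(); actuals <- list()
    for (e in seq_len(n_ep)) {
      items <- paste0("i", 1:sample(3:12, 1))
      scores[[e]] <- setNames(sample(0:5, length(items), TRUE) / 2, items)
      actuals[[e]] <- sample(items, sample(1:(length(items) - 1), 1))
    }
    pooled_scores <- unlist(lapply(scores, as.numeric))
    pooled_labels <- unlist(Map(function(s, a) names(s) %in% a, scores, actuals))
    if (all(pooled_labels) || !any(pooled_labels)) next
    expect_equal(roc_auc(scores, actuals),
                 oracle_auc(pooled_scores, pooled_labels))
  }
})

test_that("label-permuted scores average to chance AUC", {
  set.seed(21)
  items <- paste0("i", 1:30)
  scores <- setNames(runif(30), items)
  aucs <- replicate(400, {
    actual <- sample(items, 10)   # labels permuted independently of scores
    roc_auc(list(scores), list(actual))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("bootstrap CI collapses on constant metrics and is seeded", {
  ci <- bootstrap_ci(function(x) 0.7, 1:50, n_resamples = 100, seed = 3)
  expect_identical(unname(ci), c(0.7, 0.7, 0.7))

  set.seed(1)
  vals <- c(rbinom(80, 4, 0.5) / 4)
  ci1 <- bootstrap_ci(mean, vals, n_resamples = 200, seed = 9)
  ci2 <- bootstrap_ci(mean, vals, n_resamples = 200, seed = 9)
  expect_identical(ci1, ci2)
  ci3 <- bootstrap_ci(mean, vals, n_resamples = 200, seed = 10)
  expect_false(identical(ci1, ci3))
  expect_lte(ci1[["lower"]], ci1[["point"]])
  expect_gte(ci1[["upper"]], ci1[["point"]])
})

test_that("bootstrap CIs shrink as the episode count grows", {
  set.seed(17)
  gen <- function(n) rbinom(n, 4, 0.5) / 4
  w <- function(n, seed) {
    ci <- bootstrap_ci(mean, gen(n), n_resamples = 300, seed = seed)
    ci[["upper"]] - ci[["lower"]]
  }
  expect_lt(w(2000, 1), w(200, 2))
})

test_that("baseline rankers behave as documented", {
  m <- build_matrix(toy_episodes())
  bg <- background_stats(c(L1 = 500, L2 = 1500), n_outpt = 10000)

  endo <- baseline_ranker("endocrine_prevalence", m)
  expect_identical(endo("anything", 1), endo(c("X", "Y"), 2))
  expect_identical(workuprec:::.rank_targets(endo("q", 1), m), c("L1", "L2"))

  outpt <- baseline_ranker("outpatient_prevalence", m, bg)
  expect_identical(workuprec:::.rank_targets(outpt("q", 1), m), c("L2", "L1"))

  rand <- baseline_ranker("random", m, seed = 5)
  expect_identical(rand("q", 3), rand("q", 3))        # reproducible
  expect_false(identical(rand("q", 3), rand("q", 4))) # varies per episode
})

test_that("evaluate_rankers produces a benchmark row per ranker", {
  cf <- sim_config(n_patients = 300)
  sim <- generate_cohort(cf, seed = 61)
  bg <- generate_background(cf, seed = 62)
  filt <- filter_rare_items(categorize_events(sim$events), min_support = 5)
  sp <- split_by_year(build_episodes(filt$events, sim$referrals, sim$visits))
  m <- build_matrix(sp$train)
  rankers <- list(rec = make_ranker(m, bg, "combined"),
                  endo = baseline_ranker("endocrine_prevalence", m))
  rep <- suppressMessages(
    evaluate_rankers(rankers, sp$test, m, n_bootstrap = 50, seed = 4))
  expect_identical(rep$ranker, c("rec", "endo"))
  expect_true(all(rep$precision >= 0 & rep$precision <= 1))
  expect_true(all(rep$auc >= 0 & rep$auc <= 1))
  expect_true(all(rep$precision_lo <= rep$precision &
                    rep$precision <= rep$precision_hi))
  expect_true(all(rep$auc_lo <= rep$auc & rep$auc <= rep$auc_hi))
})

test_that("paired ranker comparison is antisymmetric with an honest null", {
  cf <- sim_config(n_patients = 300)
  sim <- generate_cohort(cf, seed = 71)
  bg <- generate_background(cf, seed = 72)
  filt <- filter_rare_items(categorize_events(sim$events), min_support = 5)
  sp <- split_by_year(build_episodes(filt$events, sim$referrals, sim$visits))
  m <- build_matrix(sp$train)
  rec <- make_ranker(m, bg, "combined")
  endo <- baseline_ranker("endocrine_prevalence", m)

  suppressMessages({
    self <- compare_rankers(rec, rec, sp$test, m, metric = "precision_at_k",
                            n_resamples = 100, seed = 8)
    ab <- compare_rankers(rec, endo, sp$test, m, metric = "precision_at_k",
                          n_resamples = 100, seed = 8)
    ba <- compare_rankers(endo, rec, sp$test, m, metric = "precision_at_k",
                          n_resamples = 100, seed = 8)
  })
  expect_identical(self$delta, 0)
  expect_gte(self$p_value, 0.99)
  expect_equal(ab$delta, -ba$delta)
})
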