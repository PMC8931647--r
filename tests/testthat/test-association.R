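test_that("association counts on the five-patient toy cohort are exact", {
  m <- build_matrix(toy_episodes())
  expect_identical(m$n_cohort, 5L)
  expect_identical(unname(m$query_counts[c("X", "Y")]), c(3L, 3L))
  expect_identical(unname(m$target_counts[c("L1", "L2")]), c(3L, 2L))
  expect_identical(m$pair_counts[query == "X" & target == "L1", n_ab], 3L)
  expect_identical(m$pair_counts[query == "X" & target == "L2", n_ab], 1L)
  expect_identical(m$pair_counts[query == "Y" & target == "L1", n_ab], 1L)
  expect_identical(m$pair_counts[query == "Y" & target == "L2", n_ab], 1L)
  expect_matrix_equals_oracle(m, toy_episodes())
})

test_that("duplicated events within a patient do not change the matrix", {
  ep <- toy_episodes()
  dup <- copy(ep)
  dup$query_items[[1]] <- rep(dup$query_items[[1]], 3)
  dup$target_items[[1]] <- rep(dup$target_items[[1]], 2)
  expect_equal(build_matrix(dup), build_matrix(ep))

  single <- data.table(patient_id = "P1",
                       referral_date = as.Date("2019-01-01"),
                       visit_date = as.Date("2019-02-01"),
                       query_items = list("A"), target_items = list("B"))
  m1 <- build_matrix(single)
  expect_identical(m1$n_cohort, 1L)
  expect_identical(unname(m1$query_counts), 1L)
  expect_identical(m1$pair_counts$n_ab, 1L)
})

test_that("matrix is invariant to patient and item ordering", {
  ep <- random_episodes(seed = 9)
  shuffled <- ep[sample(nrow(ep))]
  shuffled$query_items <- lapply(shuffled$query_items, rev)
  m1 <- build_matrix(ep)
  m2 <- build_matrix(shuffled)
  expect_identical(m1$n_cohort, m2$n_cohort)
  expect_identical(m1$query_counts[sort(names(m1$query_counts))],
                   m2$query_counts[sort(names(m2$query_counts))])
  expect_equal(m1$pair_counts, m2$pair_counts)
})

test_that("build_matrix matches the brute-force oracle on random cohorts", {
  for (s in 1:15) {
    ep <- random_episodes(seed = 200 + s)
    expect_matrix_equals_oracle(build_matrix(ep), ep)
  }
})

test_that("ppv is the exact conditional patient fraction", {
  m <- build_matrix(toy_episodes())
  expect_identical(ppv(m, "X", "L1"), 1.0)
  expect_equal(ppv(m, "X", "L2"), 1 / 3)
  expect_identical(ppv(m, "Y", c("L1", "L2")), c(1 / 3, 1 / 3))
  # unobserved pair scores zero; self-pairs are well-defined
  expect_identical(ppv(m, "X", "UNSEEN"), 0.0)
  expect_error(ppv(m, "NOPE", "L1"), "no training support")
  for (q in c("X", "Y")) {
    expect_true(all(ppv(m, q, c("L1", "L2")) >= 0))
    expect_true(all(ppv(m, q, c("L1", "L2")) <= 1))
  }
})

test_that("relative ratio compares order rates with and without the item", {
  m <- build_matrix(toy_episodes())
  # P(L1|X) = 1, P(L1|not X) = 0/2 -> infinity sentinel
  expect_identical(relative_ratio(m, "X", "L1"), Inf)
  # P(L2|X) = 1/3, P(L2|not X) = 1/2
  expect_equal(relative_ratio(m, "X", "L2"), (1 / 3) / (1 / 2))
  # both zero -> undefined sentinel
  expect_true(is.nan(relative_ratio(m, "X", "UNSEEN")))
  expect_error(relative_ratio(m, "NOPE", "L1"), "relative_ratio requires")

  # hand ratio: P(B|A)=0.5 vs P(B|notA)=0.25 -> 2
  ep <- data.table(patient_id = paste0("P", 1:8),
                   referral_date = as.Date("2019-01-01"),
                   visit_date = as.Date("2019-02-01"),
                   query_items = c(rep(list("A"), 4), rep(list("Z"), 4)),
                   target_items = c(list("B", "B", character(0), character(0)),
                                    list("B", character(0), character(0),
                                         character(0))))
  expect_equal(relative_ratio(build_matrix(ep), "A", "B"), 2.0)
})

test_that("prevalence reads per-population patient fractions", {
  m <- build_matrix(toy_episodes())
  expect_equal(prevalence(m, "L1"), 3 / 5)
  expect_equal(prevalence(m, c("X", "Y"), side = "query"), c(3 / 5, 3 / 5))
  expect_warning(p <- prevalence(m, "UNKNOWN"), "unknown")
  expect_identical(p, 0)

  bg <- background_stats(c(FLU = 5000, TSH = 100), n_outpt = 10000)
  expect_equal(prevalence(bg, c("FLU", "TSH")), c(0.5, 0.01))
  # an item held by everyone
  expect_equal(prevalence(background_stats(c(A = 10), 10), "A"), 1.0)
})

test_that("relative risk weight is the cohort/outside prevalence ratio", {
  ep <- copy(toy_episodes())
  m <- build_matrix(ep)
  # X: cohort prevalence 3/5; outside prevalence 0.06 -> RR = 10
  bg <- background_stats(c(X = 600, Y = 6000), n_outpt = 10000)
  expect_equal(relative_risk_weight(m, bg, "X"), 10)
  # equal prevalences -> 1
  expect_equal(relative_risk_weight(m, bg, "Y"), 1)
  # unseen outside the cohort -> capped
  bg0 <- background_stats(c(X = 0, Y = 6000), n_outpt = 10000)
  expect_equal(relative_risk_weight(m, bg0, "X"), 100)
  expect_equal(relative_risk_weight(m, bg0, "X", max_weight = 7), 7)
  # unknown in cohort -> 0
  expect_equal(relative_risk_weight(m, bg, "NOPE"), 0)
})

test_that("matrix and background persistence round-trip exactly", {
  ep <- random_episodes(seed = 77)
  ep$query_items <- lapply(ep$query_items, function(q)
    if (length(q)) item_key(q, sample(c("none", "high", "low"), length(q), TRUE))
    else q)
  m <- build_matrix(ep)
  path <- withr::local_tempfile(fileext = ".csv")
  write_matrix(m, path)
  back <- read_matrix(path)
  expect_identical(back$n_cohort, m$n_cohort)
  expect_identical(back$query_counts[sort(names(m$query_counts))],
                   m$query_counts[sort(names(m$query_counts))])
  expect_identical(back$target_counts[sort(names(m$target_counts))],
                   m$target_counts[sort(names(m$target_counts))])
  expect_equal(setkey(copy(back$pair_counts), query, target),
               setkey(copy(m$pair_counts), query, target))

  bg <- background_stats(c("TSH:high" = 40, FLU = 2000), n_outpt = 9999)
  bpath <- withr::local_tempfile(fileext = ".csv")
  write_background(bg, bpath)
  expect_equal(read_background(bpath), bg)
})
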