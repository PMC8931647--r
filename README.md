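# workuprec

When a primary-care provider refers a patient to a specialty clinic, the
first specialist visit is often wasted because the diagnostic workup the
specialist needs — a handful of labs and imaging studies — was never ordered
beforehand. `workuprec` implements an item-association recommender for this
problem: given the clinical items on a patient's chart at the moment of
referral (diagnoses, categorized lab results, medications, procedures), it
ranks the workup orders a specialist would be likely to place at the first
visit, learned purely from how specialists handled similar referrals in the
past. The package targets clinical informatics researchers who want to
train, inspect, and benchmark such a recommender on OMOP-style flat event
tables — or, since real referral extracts are rarely shareable, on the
bundled synthetic EHR generator with planted ground truth.

## The method

Training counts, over a cohort of `N` historical referral episodes, how many
distinct patients carried each chart item `A` in the six months up to
referral (`N_A`) and how many of those went on to receive each workup order
`B` at the first specialty visit (`N_AB`). Duplicates count once per
patient, so every statistic reads as a patient prevalence. Candidate orders
are ranked for a single query item by the positive predictive value

    PPV(B | A) = N_AB / N_A ,

and a patient with query items `A_1 … A_q` gets weighted pseudo-count scores

    score(B) = Σ_i  W_{A_i} · PPV(B | A_i) .

The weight `W_A` decides how much each chart item is trusted. Outpatient
charts are full of specialty-irrelevant material (well-child checks, viral
illnesses, routine meds), so besides uniform weights the package provides an
IDF-style penalty `W_A = 1 / ln(1 + N_A)`, a relative-risk weight
`W_A = RR_A` (the item's prevalence in the referral cohort over its
prevalence among outpatients outside it), their combination
`RR_A / ln(1 + N_A)` (the default), and 10-fold cross-validated selection
among them. Each recommendation is reported with its PPV, relative ratio
`P(B|A) / P(B|¬A)` (flags orders *specific* to a finding), and both cohort
and outpatient prevalence. Queries with no trained item fall back to a
"best seller" list ranked by cohort prevalence.

Evaluation against held-out episodes (a temporal split: train on earlier
referral years, test on the last) reports precision@k and recall@k (k = 4,
the typical number of first-visit workup orders), pooled ROC AUC with
midrank tie handling, percentile bootstrap CIs, and comparisons against
endocrine-prevalence, outpatient-prevalence, and random baseline rankers.

## Worked example

Train on the default synthetic benchmark and query it for a patient carrying
an endocrine diagnosis plus a high result on its characteristic lab:

```r
library(workuprec)
cf  <- sim_config()                                   # 2500 patients, ~200 items
sim <- generate_cohort(cf, seed = 7)
bg  <- generate_background(cf, seed = 8)
ev  <- filter_rare_items(categorize_events(sim$events), min_support = 10)
ep  <- build_episodes(ev$events, sim$referrals, sim$visits)
sp  <- split_by_year(ep, test_year = 2020)
m   <- build_matrix(sp$train)
recommend(c("ENDO_C01", item_key("LAB_06", "high")), m, bg,
          scheme = "combined", k = 4)
```

```
Recommended workup orders (scheme: combined)
     item    score       ppv relative_ratio endocrine_prevalence outpatient_prevalence
1: LAB_06 6.749054 0.7394143             NA           0.12500000               0.02590
2: LAB_07 4.881939 0.5348565             NA           0.09552846               0.01694
3: LAB_08 3.898283 0.4270890             NA           0.04674797               0.00490
4: IMG_01 3.113684 0.3411296             NA           0.07266260               0.00522
```

The top recommendations are the condition's planted workup block — note the
recommender re-orders the abnormal lab itself (`LAB_06`, the analogue of
repeating a flagged TSH), and that the `ppv` column is the weight-averaged
conditional probability of each order given this chart (0.74 for the top
order). The relative-ratio column is reported for single-item queries, where
it is defined. Benchmarking against the most-common-orders baseline on the
held-out test year:

```r
rankers <- list(recommender = make_ranker(m, bg, "combined"),
                endocrine_prevalence = baseline_ranker("endocrine_prevalence", m))
evaluate_rankers(rankers, sp$test, m, k = 4, n_bootstrap = 200, seed = 1)
```

```
                 ranker precision    recall       auc
1:          recommender 0.4774127 0.5027639 0.9248057
2: endocrine_prevalence 0.2582136 0.2479988 0.6954483
```

Personalized association ranking roughly doubles precision and recall over
the popularity baseline and lifts pooled AUC from 0.70 to 0.92 on this
benchmark, the same qualitative pattern the method shows on real referral
data.

A command-line front end over the same functions ships in
`inst/scripts/workuprec` (subcommands `simulate`, `build-matrix`,
`recommend`, `evaluate`, `run-all`).

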