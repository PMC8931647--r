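---
title: "Recommending initial specialty workup from item associations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recommending initial specialty workup from item associations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the model behind the
recommender, the parameters that matter and why they default as they do, what
the synthetic generator does and does not emulate, and the numerical and
design choices made where the design was genuinely open.

## The problem and the model

A specialty referral is effective when the specialist can act at the first
visit, which requires the right diagnostic workup to exist by then. The
recommender treats this as an item-association problem of the
"customers who bought A also bought B" family, transplanted to the EHR: chart
items present at referral time play the role of purchase history, and the
labs/imaging the specialist orders at the first visit are the items to
recommend.

The unit of analysis is the **referral episode**: one patient, the referral
order, and the first specialty visit no more than 183 days later. The
**query set** is every vocabulary item dated within the closed 183-day
window ending on the referral date; the **target set** is the lab and
imaging orders placed on the visit day. Training counts patients, never
events: `N_A` patients carry query item A, `N_B` received order B, `N_AB`
both. The per-item ranking statistic is the positive predictive value
$\mathrm{PPV}(B \mid A) = N_{AB} / N_A$, interpretable as a post-test
probability, and a multi-item query aggregates weighted pseudo-counts

$$\mathrm{score}(B) = \sum_{i=1}^{q} W_{A_i}\,\mathrm{PPV}(B \mid A_i).$$

We deliberately omit normalization by $\sum_i W_{A_i}$ from the score: it is
constant across candidates for a given patient and therefore rank-invariant
(the `ppv` column of a recommendation list reports the normalized value,
which *is* interpretable as a probability).

Counting is **directional** — pre-referral item to visit-day order — rather
than symmetric co-occurrence among all items. The conditional the ranking
needs is "A then ordered B", and a symmetric matrix would dilute it with
order–order and chart–chart associations; we treat the directional design as
the method, not a configuration.

### Query-item weighting

Outpatient charts carry many items with no bearing on the specialty
(well-child visits, upper respiratory infections, routine medications).
Under uniform weights their accumulated PPV columns — each approximately the
marginal order prevalence — swamp the one or two informative items, and the
ranking degenerates toward a popularity list. Four weighting schemes are
provided:

| scheme | $W_A$ | rationale |
|---|---|---|
| `uniform` | $1$ | baseline |
| `inverse_frequency` | $1/\ln(1+N_A)$ | IDF-style penalty on cohort-common items |
| `relative_risk` | $RR_A$ | upweight specialty-characteristic items |
| `combined` | $RR_A/\ln(1+N_A)$ | both; the default |

$RR_A$ is the item's prevalence inside the referral cohort divided by its
prevalence among outpatients **outside** the cohort. We model the background
population as outside-cohort by construction (rather than all-outpatient
with a subtraction) because the ratio is then exact at any cohort size; with
a realistic background tens of times larger than the cohort the two
conventions are numerically indistinguishable. When an item is unseen
outside the cohort the raw ratio is undefined or explosive, so the weight is
capped (`max_rr_cap`, default 100); unbounded weights would let a single
ultra-rare item dictate the entire ranking.

The logarithmic inverse-frequency form is our choice among standard
frequency penalties: it is bounded, smooth, and never zero for supported
items; a plain $1/N_A$ variant sits behind `inverse_form = "reciprocal"` for
sensitivity analysis. `combined` is the default because cross-validated
selection on noisy cohorts reliably prefers it (the acceptance suite
reproduces this), and `select_weighting()` can re-run that selection on any
training set with patient-level folds.

### Cold start and ties

A query with no trained item falls back to the cohort "best seller" list —
orders ranked by training prevalence — with `fallback_used` flagged. Score
ties break by descending cohort prevalence and then lexicographic item key,
so every ranking is deterministic; the prevalence tie-break encodes the same
popularity prior the fallback uses.

## Data model choices

* **Item identity.** A categorized lab result is its own vocabulary item:
  `TSH:high` and `TSH:low` carry opposite clinical meaning and must
  associate with different workups. Values *on* a reference bound are
  `normal` — lab systems flag strictly outside range. Measurements without a
  usable reference range stay in the vocabulary unqualified rather than
  being dropped, since nothing guarantees every lab has a range.
* **Order identity.** Targets are concept-only (`TSH`, never `TSH:high`):
  the specialist places an order, whose result does not exist at ordering
  time. This also makes re-ordering a query lab (repeat TSH after an
  abnormal TSH) a well-formed recommendation.
* **Rare-item filter.** Items seen in fewer than 10 distinct patients are
  removed, after lab categorization (so each qualified variant must clear
  the bar on its own). The filter bounds the variance of the unsmoothed PPV
  ratios; we add no smoothing on top of it.
* **Windows.** "Six months" is fixed at 183 days, closed on both ends, for
  both the lookback and the maximum referral-to-visit wait; a day-exact
  convention keeps results bit-reproducible. One episode per patient — the
  earliest qualifying referral — so cohort counts equal patient counts.
* **Temporal split.** Train on referrals before the test year, evaluate on
  the test year; an episode dated after the test year is a configuration
  error, not data.

## Evaluation machinery

Precision@k divides hits by k even when fewer than k candidates exist
(shorter lists are implicitly padded with misses): the metric answers "of
the k suggestions a decision-support panel would show, how many were
right?". Recall@k divides by the actual order count; episodes with no
target orders are excluded from all metrics and counted in the report. The
default k = 4 matches the typical number of first-visit workup orders.

ROC analysis pools every (episode, candidate-order) pair, labels each by
whether the order was placed, scores unranked candidates 0, and computes the
Wilcoxon rank statistic with midrank ties — exactly the probability that a
random placed order outscores a random unplaced one. Pooling is an
assumption (the construction is not uniquely determined by "ROC analysis"),
so a per-episode-average AUC sits behind `pooling = "per_episode"`.

Confidence intervals are percentile bootstrap over episodes (patients),
1000 resamples by default; a metric undefined on a resample triggers a
redraw (at most ten). Ranker comparisons bootstrap the *paired* metric
difference on shared resamples and report a two-sided tail-fraction
p-value, floored at 1/B. Baselines are cohort-prevalence,
outpatient-prevalence, and a per-episode seeded random permutation.

## The synthetic cohort generator

Real referral extracts cannot ship with a package, so `generate_cohort()`
produces one with planted, recoverable truth. Each patient draws one latent
specialty condition (uniform over 12), plus a second with probability 0.2.
A condition codes itself on the chart with probability 0.9, plants its
characteristic abnormal lab result with probability 0.5 (high or low by
condition, with numeric values drawn outside the lab's reference range),
and assigns conditional order probabilities (0.8, 0.6, 0.45, 0.3) to its
block of four specific labs plus 0.3 to one imaging study; blocks overlap
across conditions (stride 3) so labs are shared, and multi-condition
patients combine probabilities by noisy-OR, keeping ground truth well
defined. Five generic screening labs are ordered for everyone at rate 0.25
and commonly appear (mostly normal) on pre-referral charts. Seventy noise
items with prevalences 0.05–0.6 — identical inside and outside the cohort,
hence planted relative risk 1 — populate every chart, and stale events
older than the lookback exercise the window logic. Visit delays are 7 days
plus a geometric with mean 45, putting roughly 2% of visits beyond the
183-day wait so episode exclusion is exercised. Condition diagnoses and
abnormal labs are planted 20× enriched relative to a 50,000-outpatient
background.

The default scale — 2500 patients split ~2000/~500 by referral year over
2015–2020 — is large enough that planted conditionals are recovered within
binomial error and the ranker ordering (recommender > cohort prevalence >
outpatient prevalence > random) is stable, yet the whole benchmark builds in
seconds; these are also the problem sizes the test suite and the acceptance
script use. What the generator does **not** emulate: real ontologies and
their code granularity, correlated comorbidity structure beyond two latent
conditions, temporal disease progression, unit heterogeneity, and
documentation artifacts (billing-driven coding, missing referrals). Passing
tests therefore demonstrate that the machinery is correct and that the
method behaves as designed under its own assumptions — not that any
particular performance level transfers to institutional EHR data.

## Numerical conventions and degenerate inputs

* PPV on an unsupported query item is an error (the recommender falls back
  instead of guessing); an unobserved pair scores 0.
* Relative ratio returns `Inf` when the order never occurs without the item
  but does with it, and `NaN` when it occurs in neither group; both are
  sentinels, not errors, and the statistic is only reported for single-item
  queries where it is defined.
* Empty referral tables and empty training partitions warn and return empty
  results; an untrained matrix refuses to recommend.
* Every stochastic step — generation, fold assignment, the random baseline,
  every bootstrap — takes an explicit integer seed, and the pipeline derives
  all of them from one master seed, so a pipeline run is byte-reproducible.

## Known limitations

The recommender is a first-order association model: it cannot represent
interactions where a pair of query items implies a workup neither implies
alone, and it inherits whatever ordering habits — good or bad — dominate the
training institution. Popularity leakage is only mitigated, not removed, by
weighting. The evaluation treats the specialist's actual orders as ground
truth, which conflates "appropriate" with "customary"; judging clinical
appropriateness requires expert review outside the package's scope.
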