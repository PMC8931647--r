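#' Build a pipeline run configuration
#'
#' Bundles every tunable of the end-to-end run with the defaults used
#' throughout the package: a 183-day query lookback and visit wait window,
#' the 10-patient rare-item filter, a 2020 test year, the combined
#' relative-risk / inverse-frequency weighting scheme, top-4
#' recommendations, and 1000 bootstrap resamples.
#'
#' @param events,referrals,visits,background input table paths; leave `NULL`
#'   with `simulate = TRUE` to generate them.
#' @param out_dir output directory for artifacts.
#' @param simulate generate synthetic input tables first.
#' @param sim a [sim_config()] for the generator.
#' @param lookback_days,max_wait_days,min_support,test_year,scheme,k,n_bootstrap
#'   pipeline settings (see the stage functions).
#' @param select_scheme if `TRUE`, pick the weighting scheme by 10-fold
#'   cross-validation on the training set instead of using `scheme`.
#' @param seed integer master seed: simulation, cross-validation, the random
#'   baseline, and the bootstrap all derive from it.
#' @return a list of class `run_config`.
#' @export
run_config <- function(events = NULL, referrals = NULL, visits = NULL,
                       background = NULL, out_dir = "workuprec_out",
                       simulate = is.null(events), sim = sim_config(),
                       lookback_days = 183, max_wait_days = 183,
                       min_support = 10, test_year = 2020,
                       scheme = "combined", select_scheme = FALSE,
                       k = 4, n_bootstrap = 1000, seed = 7) {
  stopifnot(lookback_days > 0, max_wait_days >= 0, min_support >= 1,
            k >= 1, n_bootstrap >= 1)
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; a `sim:` block
#' mirrors [sim_config()].
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim
  raw$sim <- NULL
  cfg <- do.call(run_config, raw)
  if (!is.null(sim_args)) cfg$sim <- do.call(sim_config, sim_args)
  cfg
}

#' Run the full pipeline: simulate, train, recommend, evaluate
#'
#' Executes every stage behind the package's file formats: (optionally)
#' generates the synthetic tables, reads them back, categorizes labs,
#' filters rare items, builds referral episodes, splits them temporally,
#' trains the association matrix, (optionally) selects the weighting scheme
#' by cross-validation, and evaluates the recommender against the
#' endocrine-prevalence, outpatient-prevalence, and random baselines on the
#' test episodes. Episode counts at each filtering step are logged for
#' auditability. All randomness derives from `config$seed`, so two runs with
#' the same configuration produce byte-identical artifacts.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return a list with the evaluation `report` (one row per ranker), the
#'   trained `matrix`, `background`, the episode `split`, the scheme used,
#'   and the paths of written artifacts.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)

  if (isTRUE(config$simulate)) {
    say("stage simulate: generating synthetic cohort")
    sim <- generate_cohort(config$sim, seed = config$seed)
    bg <- generate_background(config$sim, seed = config$seed + 1L)
    write_events(sim$events, p("events.csv"))
    fwrite(sim$referrals, p("referrals.csv"))
    fwrite(sim$visits, p("visits.csv"))
    write_background(bg, p("background.csv"))
    jsonlite::write_json(
      list(true_rr = as.list(sim$truth$true_rr),
           baseline_rates = as.list(sim$truth$baseline_rates)),
      p("truth.json"), auto_unbox = TRUE, digits = NA)
    config$events <- p("events.csv")
    config$referrals <- p("referrals.csv")
    config$visits <- p("visits.csv")
    config$background <- p("background.csv")
  }
  for (f in c("events", "referrals", "visits", "background")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]])) {
      stop("pipeline stage 'input': missing ", f, " file: ",
           if (is.null(config[[f]])) "(not configured)" else config[[f]])
    }
  }

  say("stage input: reading tables")
  events <- read_events(config$events)
  referrals <- read_referrals(config$referrals)
  visits <- read_visits(config$visits)
  background <- read_background(config$background)
  say("  events: ", nrow(events), " rows; referrals seen: ", nrow(referrals))

  say("stage vocabulary: categorizing labs, filtering rare items")
  events <- categorize_events(events)
  filt <- filter_rare_items(events, min_support = config$min_support)
  say("  vocabulary retained: ", nrow(filt$vocabulary), " items")
  write_vocabulary(filt$vocabulary, p("items.csv"))

  say("stage episodes: building referral episodes")
  episodes <- build_episodes(filt$events, referrals, visits,
                             lookback_days = config$lookback_days,
                             max_wait_days = config$max_wait_days)
  say("  visits matched: ", nrow(episodes), " of ", nrow(referrals),
      " referrals")
  split <- split_by_year(episodes, test_year = config$test_year)
  say("  episodes retained: ", nrow(split$train), " train / ",
      nrow(split$test), " test")
  write_episodes(split$test, p("test_episodes.jsonl"))

  say("stage train: building association matrix")
  matrix <- build_matrix(split$train)
  write_matrix(matrix, p("matrix.csv"))

  scheme <- config$scheme
  cv <- NULL
  if (isTRUE(config$select_scheme)) {
    say("stage select: 10-fold cross-validation over weighting schemes")
    cv <- select_weighting(split$train, background, seed = config$seed + 2L)
    scheme <- cv$best_scheme
    say("  selected scheme: ", scheme)
  }

  say("stage evaluate: scoring test episodes (scheme: ", scheme, ")")
  rankers <- list(
    recommender = make_ranker(matrix, background, scheme),
    endocrine_prevalence = baseline_ranker("endocrine_prevalence", matrix),
    outpatient_prevalence = baseline_ranker("outpatient_prevalence", matrix,
                                            background),
    random = baseline_ranker("random", matrix, seed = config$seed + 3L))
  report <- suppressMessages(
    evaluate_rankers(rankers, split$test, matrix, k = config$k,
                     n_bootstrap = config$n_bootstrap,
                     seed = config$seed + 4L))
  report[, scheme := c(scheme, NA, NA, NA)]
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  fwrite(report, p("report.csv"))
  say("done: report written to ", p("report.json"))

  list(report = report[], matrix = matrix, background = background,
       split = split, scheme = scheme, cv = cv,
       paths = list(report = p("report.json"), matrix = p("matrix.csv")))
}
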