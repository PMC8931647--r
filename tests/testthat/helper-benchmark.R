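# Default synthetic benchmark (2500 patients -> ~2000 train / ~500 test),
# built once per test run and shared by the heavier checks.
.bench_env <- new.env(parent = emptyenv())

benchmark_fixture <- function(seed = 42) {
  key <- paste0("s", seed)
  if (!exists(key, envir = .bench_env)) {
    cf <- sim_config()
    sim <- generate_cohort(cf, seed = seed)
    bg <- generate_background(cf, seed = seed + 1L)
    filt <- filter_rare_items(categorize_events(sim$events), min_support = 10)
    ep <- build_episodes(filt$events, sim$referrals, sim$visits)
    sp <- split_by_year(ep, test_year = 2020)
    assign(key, list(config = cf, background = bg, split = sp,
                     matrix = build_matrix(sp$train), truth = sim$truth),
           envir = .bench_env)
  }
  get(key, envir = .bench_env)
}
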